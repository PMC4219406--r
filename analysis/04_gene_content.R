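#!/usr/bin/env Rscript
# Stage 4: gene-content comparisons.
#
# Builds the genome x COG presence/absence matrix, reports shared and unique
# COG counts for in-group vs out-group genome pairs, lists COGs present in
# every in-group genome but absent from all out-group genomes, and scans
# contig annotations for putative plasmid/prophage content.

suppressMessages(library(symbioscreen))

ds <- load_dataset("results/dataset")
cogm <- read_table_tsv("results/cog_members.tsv")

m <- build_content_matrix(cogm, genomes = ds$genomes)
cat(sprintf("presence matrix: %d genomes x %d COGs\n", nrow(m), ncol(m)))

in_group <- c("g1", "g2", "g3")
out_group <- setdiff(ds$genomes, in_group)

pair_rows <- list()
for (a in in_group) for (b in out_group) {
  pc <- pairwise_content(m, a, b)
  pair_rows[[paste(a, b)]] <- data.frame(
    A = a, B = b, shared = pc$shared,
    unique_A = pc$unique_A, unique_B = pc$unique_B)
}
pairs <- do.call(rbind, pair_rows)
cat("shared / unique COG counts (first rows):\n")
print(utils::head(pairs, 3), row.names = FALSE)
write_table(pairs, "results/content_pairs.tsv", sort_by = c("A", "B"))

excl <- group_exclusive_cogs(m, in_group, out_group)
cat(sprintf("COGs in all in-group, absent from all out-group: %d\n",
            length(excl)))
writeLines(excl, "results/group_exclusive_cogs.txt")

ann <- read_table_tsv("results/dataset/annotation/annotations.tsv")
contig_lengths <- unlist(unname(lapply(ds$assemblies,
                                       function(a) a$contig_lengths)))
scan <- mobile_element_scan(ann, contig_lengths)
cat(sprintf("contigs flagged putative mobile: %d of %d (%d listed for review)\n",
            sum(scan$flagged), nrow(scan), sum(scan$for_review)))
write_table(scan, "results/mobile_contigs.tsv", sort_by = "contig_id")
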