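test_that("protein FASTA parsing preserves ids, splits annotations, normalizes residues", {
  p <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 aldehyde dehydrogenase", "MKVLITAGG",
               ">p2", "mkvagg",
               ">p3 selenoprotein", "MKULITB"), p)
  recs <- read_protein_fasta(p, "g1")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$protein_id, c("p1", "p2", "p3"))
  expect_equal(recs$annotation[1], "aldehyde dehydrogenase")
  expect_equal(recs$annotation[2], "")
  expect_equal(recs$residues[2], "MKVAGG")        # uppercased
  expect_equal(recs$residues[3], "MKXLITX")       # U and B mapped to X
  expect_equal(recs$genome_id, rep("g1", 3))
})

test_that("protein FASTA rejects empty files and duplicate ids by name", {
  p <- withr::local_tempfile(fileext = ".faa")
  file.create(p)
  expect_error(read_protein_fasta(p, "g1"), "empty")
  writeLines(c(">dup", "MKV", ">dup", "MKL"), p)
  expect_error(read_protein_fasta(p, "g1"), "dup")
})

test_that("GFF3 genes get per-contig ordinals by start with id tie-break", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "c1\tsrc\tCDS\t5000\t5500\t.\t+\t0\tID=pC",
    "c1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=pA",
    "c1\tsrc\tCDS\t900\t1400\t.\t-\t0\tID=pB",
    "c2\tsrc\tCDS\t50\t70\t.\t+\t0\tID=pD"), p)
  co <- read_gff3_genes(p)
  expect_equal(co$protein_id[co$contig_id == "c1"], c("pA", "pB", "pC"))
  expect_equal(co$ordinal[co$contig_id == "c1"], 1:3)
  expect_equal(co$ordinal[co$contig_id == "c2"], 1L)  # ordinals restart
  # ordinal assignment is a bijection onto 1..n per contig
  for (cg in unique(co$contig_id))
    expect_setequal(co$ordinal[co$contig_id == cg],
                    seq_len(sum(co$contig_id == cg)))
})

test_that("GFF3 parsing enforces the format contract", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "c1\tsrc\tCDS\t100\t400\t.\t+\t0"), p)               # 8 columns
  expect_error(read_gff3_genes(p), "line 2")
  writeLines(c("##gff-version 3",
    "c1\tsrc\tCDS\t500\t400\t.\t+\t0\tID=bad"), p)        # start > end
  expect_error(read_gff3_genes(p), "start > end")
  writeLines(c("##gff-version 3",
    "c1\tsrc\tCDS\t10\t40\t.\t+\t0\tNote=x",
    "c1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=ok"), p)         # missing ID
  expect_warning(co <- read_gff3_genes(p), "without an ID")
  expect_equal(co$protein_id, "ok")
})

test_that("write_table produces deterministic sanitized TSV that round-trips", {
  p <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(id = c("b", "a"), note = c("has\ttab", "plain"),
                   x = c(2L, 1L), stringsAsFactors = FALSE)
  written <- write_table(df, p, sort_by = "id")
  expect_equal(written$id, c("a", "b"))
  expect_false(any(grepl("\t", written$note)))
  back <- read_table_tsv(p)
  expect_equal(back, written)
  # empty rows give a header-only file
  write_table(df[0, ], p)
  expect_equal(readLines(p), "id\tnote\tx")
  expect_equal(nrow(read_table_tsv(p)), 0L)
  expect_error(write_table(df, file.path(p, "nope", "x.tsv")), "cannot write")
})

test_that("aligned FASTA round-trips an alignment matrix", {
  aln <- rbind(a = c("M", "K", "-", "V"), b = c("M", "-", "A", "V"))
  p <- withr::local_tempfile(fileext = ".afa")
  write_msa_fasta(aln, p)
  expect_equal(read_msa_fasta(p), aln)
})

test_that("taxon groups validate membership", {
  expect_error(taxon_group("solo", "g1"), "at least 2")
  g <- taxon_group("fly", c("g1", "g2", "g1"))
  expect_equal(g$members, c("g1", "g2"))
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fly:", "  - g1", "  - g2"), p)
  gl <- read_taxon_groups(p, genomes = c("g1", "g2", "g3"))
  expect_equal(gl$fly$members, c("g1", "g2"))
  expect_error(read_taxon_groups(p, genomes = c("g1")), "unknown genome")
})
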