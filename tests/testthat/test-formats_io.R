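meme_text <- function(rows8 = NULL, bg = NULL) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  if (!is.null(bg)) {
    lines <- c(lines, "Background letter frequencies",
               sprintf("A %s C %s G %s T %s", bg[1], bg[2], bg[3], bg[4]), "")
  }
  rows8 <- rows8 %||% rep("0.25 0.25 0.25 0.25", 8)
  c(lines, "MOTIF M1",
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            length(rows8)),
    rows8, "")
}

test_that("MEME reader parses width, background, and renormalizes rows", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme_text(bg = c(0.3, 0.2, 0.2, 0.3)), f)
  m <- read_meme_motifs(f)
  expect_length(m, 1)
  expect_equal(m[[1]]$width, 8)
  expect_equal(m[[1]]$background, c(0.3, 0.2, 0.2, 0.3))

  # row summing to 0.98 is renormalized to 1 within 1e-9
  writeLines(meme_text(rows8 = c("0.48 0.25 0.125 0.125",
                                 rep("0.25 0.25 0.25 0.25", 3))), f)
  m <- read_meme_motifs(f)
  expect_equal(rowSums(m[[1]]$probs), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(m[[1]]$probs[1, "A"]), 0.48 / 0.98, tolerance = 1e-12)
})

test_that("MEME reader rejects malformed input naming the line", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("not a meme file", "MOTIF X"), f)
  expect_error(read_meme_motifs(f), "MEME version")

  txt <- meme_text()
  txt[grep("^0.25", txt)[2]] <- "0.25 0.25 0.25"   # short row
  writeLines(txt, f)
  expect_error(read_meme_motifs(f), "line [0-9]+: expected 4 probabilities")

  txt <- meme_text()
  txt[grep("^0.25", txt)[1]] <- "1.25 0.25 0.25 0.25"
  writeLines(txt, f)
  expect_error(read_meme_motifs(f), "outside \\[0, 1\\]")
})

test_that("duplicate motif names get ordinal suffixes and writer round-trips", {
  f <- withr::local_tempfile(fileext = ".meme")
  block <- c("MOTIF CTCF",
             "letter-probability matrix: alength= 4 w= 2 nsites= 20 E= 0",
             "0.7 0.1 0.1 0.1", "0.1 0.7 0.1 0.1", "")
  writeLines(c("MEME version 4", "", block, block), f)
  m <- read_meme_motifs(f)
  expect_equal(names(m), c("CTCF", "CTCF_2"))

  f2 <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(m, f2)
  m2 <- read_meme_motifs(f2)
  expect_equal(m2[["CTCF"]]$probs, m[["CTCF"]]$probs, tolerance = 1e-6)
})

test_that("narrowPeak reader filters on -log10(q) and handles missing summits", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tTFA_p1\t0\t.\t5\t5\t2.0\t30",
               "chr1\t300\t400\tTFA_p2\t0\t.\t5\t5\t1.0\t10",
               "chr1\t500\t600\tTFA_p3\t0\t.\t5\t5\t3.0\t-1"), f)
  pk <- read_narrowpeak(f, q_threshold = 0.05)
  expect_equal(pk$peak_id, c("TFA_p1", "TFA_p3"))   # 1.0 < 1.30103 dropped
  expect_equal(pk$summit_offset[pk$peak_id == "TFA_p3"], 50)  # midpoint
  expect_equal(pk$tf_name, c("TFA", "TFA"))
  # no silent loss: retained + dropped = input
  expect_equal(nrow(pk) + nrow(attr(pk, "dropped")), attr(pk, "n_input"))

  writeLines("chr1\t100\t200\tx\t0\t.\t5\t5\t2.0", f)  # 9 columns
  expect_error(read_narrowpeak(f), "10 columns")
  writeLines("chr1\t-5\t200\tx\t0\t.\t5\t5\t2.0\t10", f)
  expect_error(read_narrowpeak(f), "negative")
})

test_that("VCF reader converts coordinates, expands alts, skips indels", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t101\trs1\tA\tG\t.\t.\tMAF=0.2;LOCUS=L1",
               "chr1\t201\trs2\tAT\tA\t.\t.\t.",
               "chr1\t301\trs3\tC\tG,T\t.\t.\t."), f)
  snps <- read_snvs(f, dialect = "vcf")
  expect_equal(snps$position[snps$snp_id == "rs1"], 100)
  expect_equal(snps$maf[snps$snp_id == "rs1"], 0.2)
  expect_equal(snps$locus_id[snps$snp_id == "rs1"], "L1")
  expect_false("rs2" %in% snps$snp_id)
  expect_equal(attr(snps, "n_skipped_indels"), 1)
  expect_equal(sum(snps$snp_id == "rs3"), 2)
  expect_equal(unique(snps$position[snps$snp_id == "rs3"]), 300)

  # write -> read round-trip restores the identical records
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_snvs_vcf(snps, f2)
  again <- read_snvs(f2, dialect = "vcf")
  attr(snps, "n_skipped_indels") <- NULL
  attr(again, "n_skipped_indels") <- NULL
  expect_equal(again, snps)
})

test_that("SNV validation rejects conflicting coordinates and bad alleles", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tcontig\tposition\tref\talt",
               "rs1\tchr1\t100\tA\tG",
               "rs1\tchr2\t100\tA\tC"), f)
  expect_error(read_snvs(f, dialect = "tsv"), "conflicting coordinates")
  writeLines(c("snp_id\tcontig\tposition\tref\talt",
               "rs1\tchr1\t100\tA\tA"), f)
  expect_error(read_snvs(f, dialect = "tsv"), "identical ref and alt")
  writeLines(c("snp_id\tcontig\tposition\tref",
               "rs1\tchr1\t100\tA"), f)
  expect_error(read_snvs(f, dialect = "tsv"), "missing mandatory column")
})

test_that("write_table is deterministic and round-trips", {
  df <- data.frame(id = c("a", "b"), x = c(1.25, -3.5),
                   flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f1)
  write_table(df, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(read_table_file(f1), df)

  write_table(df[0, ], f1)   # empty list -> header-only file
  expect_equal(readLines(f1), "id\tx\tflag")
})

test_that("genome FASTA round-trips and rejects foreign characters", {
  g <- c(chr1 = "ACGTNNACGT", chr2 = "GGGGCCCC")
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  g2 <- read_genome_fasta(f)
  expect_equal(g2, g)
  expect_equal(genome_fetch(g2, "chr1", 2, 6), "GTNN")
  expect_error(genome_fetch(g2, "chr3", 0, 2), "unknown contig")
  expect_error(genome_fetch(g2, "chr1", 5, 20), "out of range")
})
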