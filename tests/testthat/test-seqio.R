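test_that("FASTA reading normalises, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_length(read_fasta(f), 0L)

  writeLines(c(">a", "ACGT"), f)
  x <- read_fasta(f)
  expect_identical(names(x), "a")
  expect_identical(as.character(x[[1]]), "ACGT")

  # U -> T, lowercase -> uppercase, coverage parsed from header
  writeLines(c(">c1 cov=12.5", "acgu", ">c2_length_9_cov_40", "ACGTNACGT"), f)
  y <- read_fasta(f)
  expect_identical(as.character(y[[1]]), "ACGT")
  expect_equal(S4Vectors::mcols(y)$coverage, c(12.5, 40))

  # round trip
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(y, f2)
  z <- read_fasta(f2)
  expect_identical(as.character(z), as.character(y))
  expect_identical(names(z), names(y))

  # errors name the offending record
  writeLines(c(">ok", "ACGT", ">bad", ""), f)
  expect_error(read_fasta(f), "bad")
  writeLines(c(">amb", "ACRT"), f)
  expect_error(read_fasta(f), "invalid character 'R'")
  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("paired FASTQ reading handles interleaved, split and gzip layouts", {
  fq <- function(ids, seqs) {
    unlist(mapply(function(i, s) c(paste0("@", i), s, "+",
                                   strrep("I", nchar(s))),
                  ids, seqs, SIMPLIFY = FALSE), use.names = FALSE)
  }
  inter <- withr::local_tempfile(fileext = ".fastq")
  writeLines(fq(c("p1/1", "p1/2", "p2/1", "p2/2"),
                c("ACGT", "TTTT", "GGGG", "CCCC")), inter)
  p <- read_paired_fastq(inter)
  expect_length(p, 2L)
  expect_identical(p$seq1, c("ACGT", "GGGG"))
  expect_identical(p$seq2, c("TTTT", "CCCC"))

  # odd interleaved count
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(fq(c("a", "b", "c"), c("AC", "GT", "CA")), bad)
  expect_error(read_paired_fastq(bad), "odd record count \\(3\\)")

  # split, gzipped
  r1 <- withr::local_tempfile(fileext = ".fastq.gz")
  r2 <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(r1, "w"); writeLines(fq(c("x", "y", "z"),
                                        c("AAAA", "CCCC", "GGGG")), con)
  close(con)
  con <- gzfile(r2, "w"); writeLines(fq(c("x", "y", "z"),
                                        c("TTTT", "ACGT", "CGCG")), con)
  close(con)
  sp <- read_paired_fastq(r1, r2)
  expect_length(sp, 3L)
  expect_identical(sp$seq2, c("TTTT", "ACGT", "CGCG"))

  # mate-count mismatch
  r3 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(fq(c("x", "y"), c("TT", "AA")), r3)
  expect_error(read_paired_fastq(r1, r3), "mate-count mismatch")

  # interleaved write/read round trip preserves pairs and qualities
  out <- withr::local_tempfile(fileext = ".fastq")
  write_interleaved_fastq(sp, out)
  back <- read_paired_fastq(out)
  expect_identical(back$seq1, sp$seq1)
  expect_identical(back$seq2, sp$seq2)
  expect_identical(back$qual1, sp$qual1)
})

test_that("reverse_complement is an involution and rejects bad alphabets", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAA"), "TTT")
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACXG"), "invalid character")
  set.seed(42)
  for (i in 1:100) {
    s <- random_dna(sample(1:80, 1), bases = c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), rc_str(s))
  }
})

test_that("cmsearch tblout parsing maps models, strands and coordinates", {
  lines <- c(
    "#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description of target",
    "#------- --------- ---------",
    "ctg1 - RNaseP_bact_a RF00010 cm 1 367 1200 1560 + no 1 0.31 0.0 78.2 1.2e-15 ! -",
    "ctg1 - 5S_rRNA RF00001 cm 1 119 5000 4890 - no 1 0.55 0.0 90.1 3e-20 ! -",
    "ctg2 - tRNA RF00005 cm 1 71 300 371 + no 1 0.50 0.0 55.0 1e-9 ! -")
  f <- withr::local_tempfile(fileext = ".tblout")
  writeLines(lines, f)
  ft <- parse_cmsearch_tblout(f)
  expect_length(ft, 3L)
  expect_identical(S4Vectors::mcols(ft)$kind, c("RNaseP", "rRNA_5S", "tRNA"))
  expect_equal(S4Vectors::mcols(ft)$score, c(78.2, 90.1, 55.0))
  # minus-strand hit: from > to swapped to an ordered range
  expect_equal(GenomicRanges::start(ft)[2], 4890)
  expect_equal(GenomicRanges::end(ft)[2], 5000)
  expect_identical(as.character(GenomicRanges::strand(ft))[2], "-")
  expect_identical(as.character(GenomicRanges::strand(ft))[1], "+")

  writeLines(lines[1:2], f)
  expect_length(parse_cmsearch_tblout(f), 0L)

  writeLines(c(lines[1], "ctg1 broken row"), f)
  expect_error(parse_cmsearch_tblout(f), "line 2")
})

test_that("tRNAscan parsing keeps isotypes and spans introns", {
  lines <- c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t---\t----\t-----\t-----\t---\t-----",
    "ctg1\t1\t1000\t1072\tTrp\tCCA\t0\t0\t85.3",
    "ctg1\t2\t2200\t2110\tIle\tGAT\t2150\t2130\t70.1")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, f)
  ft <- parse_trnascan(f)
  expect_length(ft, 2L)
  expect_identical(S4Vectors::mcols(ft)$isotype, c("Trp", "Ile"))
  expect_identical(as.character(GenomicRanges::strand(ft)), c("+", "-"))
  # intron-containing tRNA keeps one spanning feature
  expect_equal(GenomicRanges::start(ft)[2], 2110)
  expect_equal(GenomicRanges::end(ft)[2], 2200)
  expect_equal(S4Vectors::mcols(ft)$intron_begin[2], 2150)

  writeLines(lines[1:3], f)
  expect_length(parse_trnascan(f), 0L)

  writeLines(c(lines[1:3], "ctg1\t1\t10\t80"), f)
  expect_error(parse_trnascan(f), "missing columns")
})

test_that("20-isotype tRNAscan fixture reports 20 distinct isotypes", {
  rows <- sprintf("ctg1\t%d\t%d\t%d\t%s\tNNN\t0\t0\t60.0",
                  seq_along(standard_isotypes),
                  1000 * seq_along(standard_isotypes),
                  1000 * seq_along(standard_isotypes) + 72,
                  standard_isotypes)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(rows, f)
  ft <- parse_trnascan(f)
  expect_length(ft, 20L)
  expect_setequal(S4Vectors::mcols(ft)$isotype, standard_isotypes)
})

test_that("GFF3 round trip preserves feature kinds and coordinates", {
  gr <- feature_table(rep("g", 4), c(100, 500, 900, 2000),
                      c(250, 800, 975, 2900), c("+", "-", "+", "+"),
                      c("rRNA_16S", "tRNA", "RNaseP", "CDS"),
                      contig_lengths = c(g = 10000),
                      isotype = c(NA, "Trp", NA, NA))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(gr, f)
  back <- read_features_gff3(f)
  expect_identical(S4Vectors::mcols(back)$kind, S4Vectors::mcols(gr)$kind)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(gr)))
  expect_identical(S4Vectors::mcols(back)$isotype[2], "Trp")
})

test_that("coordinate conversions are exact inverses on random features", {
  set.seed(7)
  start1 <- sample.int(1e6, 200)
  end1 <- start1 + sample.int(5000, 200)
  z <- coords_to_0based(start1, end1)
  back <- coords_to_1based(z$start, z$end)
  expect_identical(back$start, start1)
  expect_identical(back$end, end1)
  # half-open length equals closed length
  expect_equal(z$end - z$start, end1 - start1 + 1L)
})

test_that("feature_table enforces its invariants", {
  expect_error(feature_table("g", 10, 5, "+", "tRNA"), "start > end")
  expect_error(feature_table("g", 10, 20, "+", "banana"), "unknown feature kind")
  expect_error(feature_table("g", 10, 20, "+", "tRNA",
                             contig_lengths = c(other = 100)),
               "absent from contig_lengths")
  expect_error(feature_table("g", 10, 200, "+", "tRNA",
                             contig_lengths = c(g = 100)),
               "past its contig end")
})
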