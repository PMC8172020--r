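test_that("archetypal layouts classify to their defining types", {
  L <- 1e6
  base <- function(extra = NULL) {
    df <- rbind(
      data.frame(start = 1000, end = 2500, strand = "+", kind = "rRNA_16S"),
      data.frame(start = 2700, end = 5600, strand = "+", kind = "rRNA_23S"),
      data.frame(start = 5700, end = 5810, strand = "+", kind = "rRNA_5S"),
      extra)
    feature_table(rep("g", nrow(df)), df$start, df$end, df$strand, df$kind,
                  contig_lengths = c(g = L))
  }
  # A: clean operon, empty spacers
  expect_identical(classify_rrna_linkage(base())$type, "A")

  # B: tRNAs in the 16S-23S spacer, same strand
  b <- base(data.frame(start = c(2520, 2610), end = c(2595, 2680),
                       strand = "+", kind = "tRNA"))
  expect_identical(classify_rrna_linkage(b)$type, "B")

  # C: a protein-coding gene in the spacer
  cc <- base(data.frame(start = 2520, end = 2660, strand = "+", kind = "CDS"))
  expect_identical(classify_rrna_linkage(cc)$type, "C")

  # E: 16S on the opposite strand
  e <- feature_table(rep("g", 3), c(1000, 2700, 5700), c(2500, 5600, 5810),
                     c("-", "+", "+"),
                     c("rRNA_16S", "rRNA_23S", "rRNA_5S"),
                     contig_lengths = c(g = L))
  expect_identical(classify_rrna_linkage(e)$type, "E")

  # D: same strand but a quarter-megabase downstream spacer
  d <- feature_table(rep("g", 3), c(1000, 252700, 255700),
                     c(2500, 255600, 255810), "+",
                     c("rRNA_16S", "rRNA_23S", "rRNA_5S"),
                     contig_lengths = c(g = L))
  call_d <- classify_rrna_linkage(d)
  expect_identical(call_d$type, "D")
  expect_equal(call_d$d_16S_23S, 252700 - 2500 - 1)
})

test_that("an opposite-strand intervening gene unlinks an otherwise short spacer", {
  L <- 1e6
  df <- rbind(
    data.frame(start = 1000, end = 2500, strand = "+", kind = "rRNA_16S"),
    data.frame(start = 4000, end = 6900, strand = "+", kind = "rRNA_23S"),
    data.frame(start = 7000, end = 7110, strand = "+", kind = "rRNA_5S"),
    data.frame(start = 2800, end = 3600, strand = "-", kind = "CDS"))
  ft <- feature_table(rep("g", 4), df$start, df$end, df$strand, df$kind,
                      contig_lengths = c(g = L))
  call <- classify_rrna_linkage(ft)
  expect_identical(call$type, "D")
  expect_match(call$notes, "opposite-strand", all = FALSE)
})

test_that("a chain of same-strand genes keeps a long spacer operonic", {
  L <- 1e6
  # 16S ... 5 kb spacer bridged by two CDS with every gap under max_gap
  df <- rbind(
    data.frame(start = 1000, end = 2500, strand = "+", kind = "rRNA_16S"),
    data.frame(start = 4000, end = 4900, strand = "+", kind = "CDS"),
    data.frame(start = 6000, end = 6900, strand = "+", kind = "CDS"),
    data.frame(start = 7500, end = 10400, strand = "+", kind = "rRNA_23S"),
    data.frame(start = 10500, end = 10610, strand = "+", kind = "rRNA_5S"))
  ft <- feature_table(rep("g", 5), df$start, df$end, df$strand, df$kind,
                      contig_lengths = c(g = L))
  call <- classify_rrna_linkage(ft)
  expect_identical(call$type, "C")
  expect_match(call$notes, "conservatively counted operonic", all = FALSE)
  # removing the chain reverts to unlinked-by-distance
  ft2 <- ft[S4Vectors::mcols(ft)$kind != "CDS"]
  expect_identical(classify_rrna_linkage(ft2)$type, "D")
})

test_that("rRNA multiplicity is an error and distances are minimum arcs", {
  L <- 1e6
  dup <- feature_table(rep("g", 4), c(1000, 50000, 2700, 5700),
                       c(2500, 51500, 5600, 5810), "+",
                       c("rRNA_16S", "rRNA_16S", "rRNA_23S", "rRNA_5S"),
                       contig_lengths = c(g = L))
  expect_error(classify_rrna_linkage(dup), "multiplicity")

  # circular minimum arc: a gene placed across the origin side
  wide <- feature_table(rep("g", 3), c(1000, 900000, 905000),
                        c(2500, 902900, 905110), "+",
                        c("rRNA_16S", "rRNA_23S", "rRNA_5S"),
                        contig_lengths = c(g = L))
  call <- classify_rrna_linkage(wide)
  expect_lte(call$d_16S_23S, L / 2)
  # arc through the origin: 23S end 902900 -> around -> 16S start 1000
  expect_equal(call$d_16S_23S, (L - 902900) + 1000 - 1)
})

test_that("generated fixtures classify to their generating type (all five)", {
  set.seed(41)
  for (type in c("A", "B", "C", "D", "E")) {
    for (i in 1:10) {
      ft <- make_feature_fixture(type, genome_length = 1e6,
                                 seed = 1000 * i + match(type, LETTERS))
      call <- classify_rrna_linkage(ft)
      expect_identical(call$type, type,
                       info = sprintf("type %s seed %d", type, i))
    }
  }
})

test_that("classification is invariant under rotation and reverse complement", {
  set.seed(43)
  L <- 1e6
  for (type in c("A", "B", "C", "D", "E")) {
    ft <- make_feature_fixture(type, genome_length = L, seed = 77)
    call0 <- classify_rrna_linkage(ft)
    for (r in 1:3) {
      off <- safe_offset(ft, L)
      call_r <- classify_rrna_linkage(rotate_features(ft, off, L))
      expect_identical(call_r$type, call0$type)
      expect_equal(call_r$d_16S_23S, call0$d_16S_23S)
    }
    call_rc <- classify_rrna_linkage(revcomp_features(ft, L))
    expect_identical(call_rc$type, call0$type)
    expect_equal(call_rc$d_16S_23S, call0$d_16S_23S)
  }
})

test_that("summarize_linkage tallies types and the unlinked fraction", {
  mk <- function(type) structure(list(type = type), class = "operon_call")
  calls <- c(lapply(1:7, function(i) mk("A")),
             lapply(1:20, function(i) mk("D")),
             lapply(1:7, function(i) mk("E")))
  s <- summarize_linkage(calls)
  expect_equal(s$n, 34)
  expect_equal(unname(s$counts[c("A", "D", "E")]), c(7L, 20L, 7L))
  expect_equal(s$fraction_unlinked, 27 / 34, tolerance = 1e-12)
  expect_equal(sum(s$counts), s$n) # the tally conserves the total

  expect_equal(summarize_linkage(lapply(1:5, function(i)
    mk("A")))$fraction_unlinked, 0)
  expect_error(summarize_linkage(list()), "no operon calls")
})
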