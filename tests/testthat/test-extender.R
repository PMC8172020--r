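# deterministically tiled error-free read pairs covering a genome end to end
tile_reads <- function(g, read_len = 100L, step = 10L) {
  L <- nchar(g)
  starts <- seq(1L, L - read_len + 1L, by = step)
  reads <- substring(g, starts, starts + read_len - 1L)
  # double up the terminal read so the last bases keep >= 2 supporting votes
  c(reads, substr(g, L - read_len + 1L, L), substr(g, L - read_len + 1L, L))
}

test_that("extend_end grows a contig to the genome end on tiled reads", {
  set.seed(5)
  g <- random_dna(3000)
  reads <- tile_reads(g)
  params <- extension_params(min_overlap = 30, min_support = 2,
                             max_step = 10000)
  contig <- substr(g, 1, 500)
  ext <- extend_end(contig, reads, params)
  expect_identical(paste0(contig, ext), g)

  # no qualifying reads -> empty extension
  expect_identical(extend_end(contig, c("ACGTACGTACGTACGTACGT"), params), "")
  expect_identical(extend_end(substr(g, 1, 10), reads, params), "")

  # reverse-complemented reads work identically (orientation internal)
  ext_rc <- extend_end(contig, rc_str(reads), params)
  expect_identical(ext_rc, ext)

  # max_step truncates
  short <- extend_end(contig, reads, extension_params(min_overlap = 30,
                                                      max_step = 17))
  expect_identical(short, substr(ext, 1, 17))
})

test_that("extension halts on ties and on balanced conflicts", {
  set.seed(6)
  base <- random_dna(200)
  # two read populations agree on the anchor but vote A vs C at the next base
  follow_a <- paste0(substr(base, 151, 200), "A", random_dna(30))
  follow_c <- paste0(substr(base, 151, 200), "C", random_dna(30))
  params <- extension_params(min_overlap = 50, min_support = 2)
  # exact tie: 2 vs 2
  expect_identical(extend_end(base, c(follow_a, follow_a, follow_c, follow_c),
                              params), "")
  # balanced conflict: 3 vs 2 (runner-up >= min_support and > winner/4)
  expect_identical(extend_end(base, c(rep(follow_a, 3), rep(follow_c, 2)),
                              params), "")
  # an isolated minority voice below min_support does not halt extension
  ext <- extend_end(base, c(rep(follow_a, 6), follow_c), params)
  expect_gte(nchar(ext), 1L)
  expect_identical(substr(ext, 1, 1), "A")
})

test_that("read coherence: extension windows are substrings of input reads", {
  set.seed(8)
  g <- random_dna(4000)
  reads <- tile_reads(g, read_len = 90L, step = 7L)
  params <- extension_params(min_overlap = 30, min_support = 2,
                             max_step = 10000)
  contig <- substr(g, 1, 400)
  ext <- extend_end(contig, reads, params)
  expect_gt(nchar(ext), 1000)
  grown <- paste0(contig, ext)
  both <- c(reads, rc_str(reads))
  w <- params$min_overlap + 1L
  starts <- seq(nchar(contig) - w + 1L, nchar(grown) - w + 1L, by = 13L)
  for (st in starts) {
    win <- substr(grown, st, st + w - 1L)
    expect_true(any(vapply(both, function(r) grepl(win, r, fixed = TRUE),
                           logical(1))),
                info = sprintf("window at %d not read-supported", st))
  }
})

test_that("merge_contigs fuses unambiguous exact end overlaps", {
  set.seed(9)
  g <- random_dna(1200)
  a <- substr(g, 1, 600)
  b <- substr(g, 551, 1200)
  m <- merge_contigs(c(a = a, b = b), min_overlap = 40)
  expect_length(m, 1L)
  expect_identical(unname(m), g)
  expect_identical(names(m), "a")
  expect_equal(unname(nchar(m)), 600 + 650 - 50)

  # reverse-complemented partner: same fusion up to orientation
  m2 <- merge_contigs(c(a = a, b = rc_str(b)), min_overlap = 40)
  expect_length(m2, 1L)
  expect_true(unname(m2) == g || unname(m2) == rc_str(g))

  # disjoint random contigs stay untouched
  d <- c(x = random_dna(300), y = random_dna(300))
  expect_identical(merge_contigs(d, 40), d[order(names(d))])

  # overlap below the threshold is ignored
  m3 <- merge_contigs(c(a = substr(g, 1, 600), b = substr(g, 581, 1200)), 40)
  expect_length(m3, 2L)
})

test_that("ambiguous overlap partners block merging (repeat safety)", {
  set.seed(10)
  rep_unit <- random_dna(120)
  x1 <- paste0(random_dna(300), rep_unit) # two contigs ending in the repeat
  x2 <- paste0(random_dna(300), rep_unit)
  y1 <- paste0(rep_unit, random_dna(300)) # two starting with it
  y2 <- paste0(rep_unit, random_dna(300))
  m <- merge_contigs(c(x1 = x1, x2 = x2, y1 = y1, y2 = y2), min_overlap = 40)
  expect_length(m, 4L) # any fusion would be an arbitrary, possibly chimeric pick
})

test_that("reassemble reaches a fixpoint and reconstructs linear genomes", {
  set.seed(11)
  g <- random_dna(6000)
  reads <- tile_reads(g)
  params <- extension_params(min_overlap = 30, min_support = 2,
                             max_step = 10000)

  # complete input is a fixpoint
  out <- reassemble(reads, c(g = g), params)
  expect_identical(out, c(g = g))

  # three fragments + tiled error-free reads -> exactly the genome
  seeds <- c(s1 = substr(g, 1, 2000), s2 = substr(g, 2500, 4200),
             s3 = substr(g, 4600, 6000))
  out2 <- reassemble(reads, seeds, params)
  expect_length(out2, 1L)
  expect_identical(unname(out2), g)

  # strand symmetry: reverse-complementing reads and seeds mirrors the output
  out3 <- reassemble(rc_str(reads), setNames(rc_str(seeds), names(seeds)),
                     params)
  expect_length(out3, 1L)
  expect_true(unname(out3) == g || unname(out3) == rc_str(g))

  # determinism
  expect_identical(reassemble(reads, seeds, params), out2)
})

test_that("reassemble on sampled reads recovers a linear genome body", {
  spec <- sim_spec(length = 50000, seed = 13, coverage = 60, err_rate = 0,
                   circular = FALSE)
  g <- simulate_genome(spec)
  gs <- unname(g)
  sim <- simulate_reads(g, spec)
  seeds <- c(s1 = substr(gs, 1, 17000), s2 = substr(gs, 18500, 33000),
             s3 = substr(gs, 34500, 50000))
  out <- reassemble(sim$pairs, seeds, extension_params())
  expect_length(out, 1L)
  # uniform fragment starts rarely cover the terminal bases of a linear
  # molecule, so the reconstruction is a near-complete substring of the truth
  expect_true(grepl(unname(out), gs, fixed = TRUE) ||
                grepl(rc_str(unname(out)), gs, fixed = TRUE))
  expect_gte(nchar(out), 0.99 * nchar(gs))
})

test_that("reassemble of a circular genome presents a terminal overlap", {
  spec <- sim_spec(length = 30000, seed = 17, coverage = 60, err_rate = 0)
  g <- simulate_genome(spec)
  gs <- unname(g)
  sim <- simulate_reads(g, spec)
  seeds <- c(s1 = substr(gs, 1, 9500), s2 = substr(gs, 10500, 20000),
             s3 = substr(gs, 21000, 29500))
  out <- reassemble(sim$pairs, seeds, extension_params())
  expect_length(out, 1L)
  expect_gte(terminal_overlap(unname(out)), 40L)
})

test_that("external_assembler adapter validates the command and its output", {
  seeds <- withr::local_tempfile(fileext = ".fasta")
  reads <- withr::local_tempfile(fileext = ".fastq")
  write_fasta(c(s = "ACGTACGTACGT"), seeds)
  writeLines(c("@r/1", "ACGT", "+", "IIII"), reads)

  out <- external_assembler(reads, seeds,
                            "true {reads} && cp {seeds} {output}",
                            workdir = withr::local_tempdir())
  expect_identical(as.character(read_fasta(out)[[1]]), "ACGTACGTACGT")

  expect_error(external_assembler(reads, seeds, "cp {seeds}"),
               "placeholder")
  expect_error(
    external_assembler(reads, seeds,
                       "/no/such/binary {reads} {seeds} {output}",
                       workdir = withr::local_tempdir()),
    "failed")
  expect_error(
    external_assembler(reads, seeds,
                       "true {reads} {seeds} && touch {output}",
                       workdir = withr::local_tempdir()),
    "no output")
})
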