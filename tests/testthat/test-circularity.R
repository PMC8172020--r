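test_that("terminal_overlap equals the classical string border", {
  expect_equal(terminal_overlap("ACGTTACG"), 3L)
  expect_equal(terminal_overlap("AAAA"), 3L)
  expect_equal(terminal_overlap("ACGT"), 0L)
  set.seed(14)
  for (i in 1:200) {
    s <- random_dna(sample(2:120, 1), bases = sample(c("A", "C"), 2))
    expect_equal(terminal_overlap(s), naive_border(s), info = s)
  }
})

test_that("longest_repeat_excluding_terminal agrees with the naive oracle", {
  set.seed(15)
  for (i in 1:150) {
    # biased alphabets provoke repeats and palindromes
    ab <- sample(list(c("A", "C", "G", "T"), c("A", "C"), c("A", "T")), 1)[[1]]
    s <- random_dna(sample(10:250, 1), bases = ab)
    t <- terminal_overlap(s)
    expect_equal(longest_repeat_excluding_terminal(s, t),
                 naive_longest_repeat(s, t), info = s)
    expect_equal(longest_repeat_excluding_terminal(s, 0),
                 naive_longest_repeat(s, 0), info = s)
  }
})

test_that("planted repeats are measured at their full length", {
  set.seed(16)
  for (i in 1:20) {
    spec <- sim_spec(length = 5000, seed = i, planted_repeats = list(c(200, 2)))
    g <- unname(simulate_genome(spec))
    contig <- paste0(g, substr(g, 1, 150))
    expect_gte(longest_repeat_excluding_terminal(contig, 150), 200)
  }
})

test_that("assess_circularity applies the three clauses with reasons", {
  set.seed(17)
  spec <- sim_spec(length = 5000, seed = 99)
  g <- unname(simulate_genome(spec))

  v <- assess_circularity(paste0(g, substr(g, 1, 150)))
  expect_true(v$is_circular)
  expect_equal(v$terminal_overlap, 150L)
  expect_equal(v$terminal_copy_count, 2L)
  expect_length(v$reasons, 0L)

  # overlap below the 100 nt minimum
  v80 <- assess_circularity(paste0(g, substr(g, 1, 80)))
  expect_false(v80$is_circular)
  expect_match(v80$reasons, "terminal_overlap_below_min", all = FALSE)

  # internal repeat at least as long as the terminal overlap
  spec_rep <- sim_spec(length = 5000, seed = 7,
                       planted_repeats = list(c(200, 2)))
  grep_ <- unname(simulate_genome(spec_rep))
  vrep <- assess_circularity(paste0(grep_, substr(grep_, 1, 150)))
  expect_false(vrep$is_circular)
  expect_match(vrep$reasons, "internal_repeat_not_shorter", all = FALSE)

  # terminal repeat occurring more than twice
  tri <- paste0(substr(g, 1, 150), random_dna(1000), g, substr(g, 1, 150))
  vtri <- assess_circularity(tri)
  expect_false(vtri$is_circular)
  expect_match(vtri$reasons, "terminal_copy_count_not_2", all = FALSE)
})

test_that("verdicts are invariant under reverse complement", {
  set.seed(18)
  for (i in 1:10) {
    spec <- sim_spec(length = 3000, seed = 300 + i)
    g <- unname(simulate_genome(spec))
    ctg <- paste0(g, substr(g, 1, sample(c(80, 150), 1)))
    v1 <- assess_circularity(ctg)
    v2 <- assess_circularity(rc_str(ctg))
    expect_equal(v1$is_circular, v2$is_circular)
    expect_equal(v1$terminal_overlap, v2$terminal_overlap)
    expect_equal(v1$longest_other_repeat, v2$longest_other_repeat)
  }
})

test_that("circularize trims exactly one terminal copy and reconstructs", {
  set.seed(19)
  spec <- sim_spec(length = 4000, seed = 55)
  g <- as.character(simulate_genome(spec))
  ctg <- paste0(g, substr(g, 1, 150))
  trimmed <- circularize(ctg)
  expect_identical(trimmed, g)
  expect_equal(nchar(trimmed), nchar(ctg) - 150L)
  # re-appending the junction copy restores a circular verdict
  again <- assess_circularity(paste0(trimmed, substr(trimmed, 1, 150)))
  expect_true(again$is_circular)
  expect_equal(again$terminal_overlap, 150L)
  # contract error on a non-circular input
  expect_error(circularize("ACGTACGT"), "non-circular")
})

test_that("rotate_seq is a group action preserving circular k-mer content", {
  set.seed(20)
  s <- random_dna(500)
  expect_identical(rotate_seq(s, 0), s)
  x <- sample.int(499, 1)
  expect_identical(rotate_seq(rotate_seq(s, x), 500L - x), s)
  expect_error(rotate_seq(s, 500), "offset")
  expect_error(rotate_seq(s, -1), "offset")
  circular_kmers <- function(g, k) {
    d <- paste0(g, substr(g, 1, k - 1))
    sort(substring(d, 1:nchar(g), 1:nchar(g) + k - 1))
  }
  for (off in sample.int(499, 3)) {
    expect_identical(circular_kmers(rotate_seq(s, off), 21),
                     circular_kmers(s, 21))
  }
})

test_that("paired-end topology separates circular from linear replicons", {
  spec_c <- sim_spec(length = 20000, seed = 23, coverage = 40, err_rate = 0)
  gc_ <- simulate_genome(spec_c)
  sim_c <- simulate_reads(gc_, spec_c)
  topo_c <- topology_from_pairs(unname(gc_), sim_c$pairs)
  expect_gt(topo_c$outward_pairs, 0L)
  expect_gt(topo_c$spanning_pairs, 0L)

  spec_l <- sim_spec(length = 20000, seed = 24, coverage = 40, err_rate = 0,
                     circular = FALSE)
  gl <- simulate_genome(spec_l)
  sim_l <- simulate_reads(gl, spec_l)
  topo_l <- topology_from_pairs(unname(gl), sim_l$pairs)
  expect_equal(topo_l$outward_pairs, 0L)
  expect_gt(topo_l$inward_end_pairs, 0L)

  # empty pair set -> all zero
  topo_0 <- topology_from_pairs(unname(gl),
                                read_pairs(character(), character(),
                                           character()))
  expect_equal(unlist(unclass(topo_0)),
               c(outward_pairs = 0L, inward_end_pairs = 0L,
                 spanning_pairs = 0L))
})

test_that("mapped_depth recovers uniform circular coverage", {
  spec <- sim_spec(length = 15000, seed = 27, coverage = 40, err_rate = 0)
  g <- simulate_genome(spec)
  sim <- simulate_reads(g, spec)
  d_lin <- mapped_depth(unname(g), sim$pairs)
  d_circ <- mapped_depth(unname(g), sim$pairs, circular = TRUE)
  expect_equal(mean(d_circ), 40, tolerance = 0.05)
  # linear mapping of a circular molecule leaves a depth hole at the ends
  expect_lt(min(d_lin), 0.3 * mean(d_lin))
  expect_gt(min(d_circ), 0.3 * mean(d_circ))
})
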