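# Independent brute-force oracles and shared fixture builders.
# The oracles deliberately use plain-R string operations, not the package's
# compiled kernels.

# pure-R reverse complement (oracle-side)
rc_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# longest proper prefix == suffix, by direct comparison
naive_border <- function(s) {
  L <- nchar(s)
  for (t in (L - 1):1) {
    if (t < 1) break
    if (substr(s, 1, t) == substr(s, L - t + 1, L)) return(t)
  }
  0L
}

max_true_run <- function(eq) {
  if (!length(eq)) return(0L)
  r <- rle(eq)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

# longest repeat, both strands, excluding direct matches at offset L - t and
# self-mirror palindrome pairs; N never matches.  Run-length scan over all
# alignment offsets of s vs itself and s vs revcomp(s).
naive_longest_repeat <- function(s, t) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  best <- 0L
  for (d in seq_len(L - 1)) {
    if (d == L - t) next
    a <- ch[1:(L - d)]
    b <- ch[(1 + d):L]
    best <- max(best, max_true_run(a == b & a != "N"))
  }
  r <- strsplit(rc_str(s), "")[[1]]
  for (off in (-(L - 1)):(L - 1)) {
    i1 <- max(1L, 1L - off)
    i2 <- min(L, L - off)
    if (i2 < i1) next
    idx <- i1:i2
    eq <- ch[idx] == r[idx + off] & ch[idx] != "N"
    rl <- rle(eq)
    starts <- cumsum(c(0L, head(rl$lengths, -1L))) + i1
    for (k in seq_along(rl$lengths)) {
      if (!rl$values[k]) next
      RL <- rl$lengths[k]
      i0 <- starts[k]
      # the run maps fwd [i0, i0+RL-1] onto its mirror image; when the two
      # intervals coincide (a perfect palindrome matching itself), only the
      # length RL-1 sub-pair has distinct intervals
      self <- (2L * i0 == L - off - RL + 2L)
      best <- max(best, if (self) RL - 1L else RL)
    }
  }
  best
}

# occurrences of pat in s on both strands (overlapping; palindrome counted once)
naive_count_occurrences <- function(s, pat) {
  cnt <- function(p) { # overlapping occurrences
    n <- 0L
    start <- 1L
    while (start + nchar(p) - 1L <= nchar(s)) {
      i <- regexpr(p, substr(s, start, nchar(s)), fixed = TRUE)
      if (i == -1) break
      n <- n + 1L
      start <- start + i
    }
    n
  }
  r <- rc_str(pat)
  cnt(pat) + if (r != pat) cnt(r) else 0L
}

# --- baiting oracle ---------------------------------------------------------

# canonical k-mer windows of a sequence (NA for windows containing N)
oracle_windows <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  st <- 1:(L - k + 1)
  w <- substring(s, st, st + k - 1)
  r <- rc_str(s)
  wr <- substring(r, rev(st), rev(st) + k - 1)
  can <- pmin(w, wr)
  can[grepl("N", w, fixed = TRUE)] <- NA_character_
  can
}

oracle_kmer_set <- function(contigs, k) {
  sort(unique(na.omit(unlist(lapply(contigs, oracle_windows, k = k)))))
}

oracle_mate_hits <- function(seqs, kset, k) {
  vapply(seqs, function(s) {
    w <- oracle_windows(s, k)
    sum(w %in% kset)
  }, integer(1), USE.NAMES = FALSE)
}

oracle_bait_keep <- function(pairs, contigs, k, min_hits) {
  kset <- oracle_kmer_set(contigs, k)
  h1 <- oracle_mate_hits(pairs$seq1, kset, k)
  h2 <- oracle_mate_hits(pairs$seq2, kset, k)
  h1 >= min_hits | h2 >= min_hits
}

# --- feature-table transforms (for invariance tests) ------------------------

rotate_features <- function(gr, off, L) {
  st <- ((GenomicRanges::start(gr) - 1L + off) %% L) + 1L
  en <- ((GenomicRanges::end(gr) - 1L + off) %% L) + 1L
  stopifnot(all(st <= en)) # caller must pick an offset that wraps no feature
  feature_table(as.character(GenomeInfoDb::seqnames(gr)), st, en,
                as.character(GenomicRanges::strand(gr)),
                S4Vectors::mcols(gr)$kind,
                contig_lengths = stats::setNames(
                  L, GenomeInfoDb::seqlevels(gr)[1]),
                isotype = S4Vectors::mcols(gr)$isotype)
}

# an offset rotating no feature across the origin
safe_offset <- function(gr, L) {
  repeat {
    off <- sample.int(L, 1L)
    st <- ((GenomicRanges::start(gr) - 1L + off) %% L) + 1L
    en <- ((GenomicRanges::end(gr) - 1L + off) %% L) + 1L
    if (all(st <= en)) return(off)
  }
}

revcomp_features <- function(gr, L) {
  st <- L - GenomicRanges::end(gr) + 1L
  en <- L - GenomicRanges::start(gr) + 1L
  sd <- c("+" = "-", "-" = "+")[as.character(GenomicRanges::strand(gr))]
  feature_table(as.character(GenomeInfoDb::seqnames(gr)), st, en, unname(sd),
                S4Vectors::mcols(gr)$kind,
                contig_lengths = stats::setNames(
                  L, GenomeInfoDb::seqlevels(gr)[1]),
                isotype = S4Vectors::mcols(gr)$isotype)
}

# --- community fixture (the standard recovery scenario) ---------------------

# 200 kb circular target at 80X with two 100 kb backgrounds at 30X;
# 150 nt reads, fragments 400 +/- 40, 0.5% substitution errors.
community_specs <- function(seed) {
  list(
    target = sim_spec(length = 200000, gc = 0.45, coverage = 80,
                      err_rate = 0.005, frag_mean = 400, frag_sd = 40,
                      read_len = 150, seed = seed * 10L + 1L,
                      name = "target"),
    bg1 = sim_spec(length = 100000, gc = 0.55, coverage = 30,
                   err_rate = 0.005, frag_mean = 400, frag_sd = 40,
                   read_len = 150, seed = seed * 10L + 2L, name = "bg1"),
    bg2 = sim_spec(length = 100000, gc = 0.38, coverage = 30,
                   err_rate = 0.005, frag_mean = 400, frag_sd = 40,
                   read_len = 150, seed = seed * 10L + 3L, name = "bg2"))
}

# three 60 kb seed fragments, evenly spaced on the circle (gaps ~6.7 kb)
seed_fragments <- function(gs) {
  c(f1 = substr(gs, 1, 60000),
    f2 = substr(gs, 66668, 126667),
    f3 = substr(gs, 133335, 193334))
}

# rotation/revcomp-equivalence of a recovered circle against the truth
rotation_equivalent <- function(genome, truth) {
  if (nchar(genome) != nchar(truth)) return(FALSE)
  doubled <- paste0(truth, truth)
  grepl(genome, doubled, fixed = TRUE) ||
    grepl(rc_str(genome), doubled, fixed = TRUE)
}

# memoised end-to-end recovery runs shared between acceptance blocks;
# a run requested with an output_dir is always executed (determinism checks
# compare the files of two independent executions), but its in-memory result
# still seeds the cache
.community_cache <- new.env(parent = emptyenv())
community_recovery_run <- function(seed, output_dir = NULL) {
  key <- as.character(seed)
  if (is.null(output_dir) && !is.null(.community_cache[[key]]))
    return(.community_cache[[key]])
  specs <- community_specs(seed)
  comm <- simulate_community(specs, seed = seed * 10L + 4L)
  gs <- comm$genomes[["target"]]
  run <- circularize_bin(seed_fragments(gs), comm$pairs,
                         bin_config(seed = seed), output_dir = output_dir)
  res <- list(run = run, truth = gs)
  if (is.null(.community_cache[[key]])) .community_cache[[key]] <- res
  res
}

# the same community with a 1.5 kb exact repeat planted in two seed gaps
community_repeat_setup <- function(seed) {
  specs <- community_specs(seed)
  g0 <- simulate_genome(specs$target)
  gs <- unname(g0)
  unit <- substr(gs, 61800, 63299)            # inside gap 1 (60000..66668)
  substr(gs, 129250, 130749) <- unit          # inside gap 2 (126667..133335)
  names(gs) <- "target"
  attr(gs, "circular") <- TRUE
  sims <- list(simulate_reads(gs, specs$target),
               simulate_reads(simulate_genome(specs$bg1), specs$bg1),
               simulate_reads(simulate_genome(specs$bg2), specs$bg2))
  pairs <- read_pairs(unlist(lapply(sims, function(s) s$pairs$id)),
                      unlist(lapply(sims, function(s) s$pairs$seq1)),
                      unlist(lapply(sims, function(s) s$pairs$seq2)))
  list(genome = gs, pairs = pairs, seeds = seed_fragments(gs))
}
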