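#' @title Synthetic genomes, read libraries and annotation fixtures
#' @description Generators with the statistical structure the pipeline
#'   assumes: small circular genomes at a target GC with exact planted
#'   repeats, paired-end libraries whose fragments wrap the origin of a
#'   circular replicon, multi-genome communities at uneven abundance, and
#'   rRNA-arrangement feature fixtures.  Every generator is a pure function
#'   of its spec and seed.
#' @name simdata
NULL

# evaluate expr under a private RNG state (restores the caller's stream)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation spec
#'
#' @param length genome length (nt)
#' @param gc GC fraction in (0, 1)
#' @param circular is the genome a circular replicon
#' @param planted_repeats list of `c(length, n_copies)` exact repeats to
#'   plant at random non-overlapping positions (total planted bases must be
#'   under half the genome)
#' @param coverage target mean read depth (X)
#' @param read_len read length (nt)
#' @param frag_mean,frag_sd fragment length distribution (normal, truncated
#'   below at `2 * read_len`)
#' @param err_rate per-base substitution probability (0..0.05)
#' @param seed integer seed; every generator consuming the spec derives its
#'   randomness from it
#' @param name genome name
#' @return a `sim_spec` list
#' @export
sim_spec <- function(length, gc = 0.50, circular = TRUE,
                     planted_repeats = list(), coverage = 60,
                     read_len = 150L, frag_mean = 400, frag_sd = 40,
                     err_rate = 0, seed = 1L, name = "sim_genome") {
  stopifnot(length >= 1000, gc > 0, gc < 1, err_rate >= 0, err_rate <= 0.05,
            frag_mean >= 2 * read_len, coverage > 0)
  planted <- lapply(planted_repeats, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] < 1L || r[2] < 2L)
      stop("each planted repeat is c(length, n_copies) with n_copies >= 2",
           call. = FALSE)
    r
  })
  tot <- sum(vapply(planted, function(r) r[1] * r[2], numeric(1)))
  if (tot >= length / 2)
    stop("planted repeats must total less than half the genome", call. = FALSE)
  structure(list(length = as.integer(length), gc = gc, circular = circular,
                 planted_repeats = planted, coverage = coverage,
                 read_len = as.integer(read_len), frag_mean = frag_mean,
                 frag_sd = frag_sd, err_rate = err_rate,
                 seed = as.integer(seed), name = name),
            class = "sim_spec")
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a genome
#'
#' I.i.d. bases at the target GC; planted repeats are exact copies of a
#' fresh random unit written over non-overlapping random positions.
#'
#' @param spec a [sim_spec()]
#' @return a single named character sequence; attribute `"repeats"` is a
#'   data.frame of planted copies (1-based `start`, `end`, `repeat_id`),
#'   attribute `"circular"` the topology flag
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    g <- .random_dna(spec$length, spec$gc)
    placed <- data.frame(repeat_id = integer(), start = integer(),
                         end = integer())
    occupied <- matrix(numeric(0), ncol = 2)
    for (ri in seq_along(spec$planted_repeats)) {
      r <- spec$planted_repeats[[ri]]
      unit <- .random_dna(r[1], spec$gc)
      for (copy in seq_len(r[2])) {
        ok <- FALSE
        for (try in 1:1000) {
          s <- sample.int(spec$length - r[1] + 1L, 1L)
          e <- s + r[1] - 1L
          if (!nrow(placed) ||
              all(e < placed$start - 1L | s > placed$end + 1L)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place planted repeats (genome too crowded)",
                      call. = FALSE)
        substr(g, s, e) <- unit
        placed <- rbind(placed,
                        data.frame(repeat_id = ri, start = s, end = e))
      }
    }
    names(g) <- spec$name
    attr(g, "repeats") <- placed
    attr(g, "circular") <- spec$circular
    g
  })
}

#' Simulate a paired-end library
#'
#' Fragment lengths are normal (`frag_mean`, `frag_sd`) truncated below at
#' `2 * read_len`; start positions are uniform; on a circular genome
#' fragments wrap the origin.  Mates are the fragment's two ends, inner
#' facing (the second mate reverse complemented).  Substitution errors are
#' i.i.d. at `err_rate`.  Pair count is
#' `round(coverage * L / (2 * read_len))`.
#'
#' @param genome a single (named) sequence, e.g. from [simulate_genome()]
#' @param spec the [sim_spec()] (read/fragment/error/coverage parameters)
#' @param seed seed for the library draw; defaults to `spec$seed + 1`
#' @param coverage override of `spec$coverage`
#' @return a list with `pairs` (a [read_pairs]) and `truth` (data.frame of
#'   1-based fragment `start`, `frag_len`, `wraps`)
#' @export
simulate_reads <- function(genome, spec, seed = spec$seed + 1L,
                           coverage = spec$coverage) {
  stopifnot(inherits(spec, "sim_spec"))
  L <- nchar(genome)
  rl <- spec$read_len
  n <- round(coverage * L / (2 * rl))
  nm <- if (!is.null(names(genome))) names(genome) else "genome"
  circular <- isTRUE(attr(genome, "circular")) || spec$circular
  with_seed(seed, {
    frag <- round(rnorm(n, spec$frag_mean, spec$frag_sd))
    while (any(bad <- frag < 2 * rl))
      frag[bad] <- round(rnorm(sum(bad), spec$frag_mean, spec$frag_sd))
    frag <- pmin(frag, L)
    if (circular) {
      start <- sample.int(L, n, replace = TRUE)
      src <- paste0(genome, substr(genome, 1L, max(frag)))
    } else {
      start <- 1L + floor(runif(n) * (L - frag + 1))
      src <- unname(genome)
    }
    fragment <- substring(src, start, start + frag - 1L)
    seq1 <- substring(fragment, 1L, rl)
    seq2 <- reverse_complement(substring(fragment, frag - rl + 1L, frag))
    seq1 <- mutate_seqs_cpp(seq1, spec$err_rate)
    seq2 <- mutate_seqs_cpp(seq2, spec$err_rate)
    pairs <- read_pairs(sprintf("%s_p%06d", nm, seq_len(n)), seq1, seq2)
    list(pairs = pairs,
         truth = data.frame(id = pairs$id, genome = nm, start = start,
                            frag_len = frag,
                            wraps = circular & (start + frag - 1L > L)))
  })
}

#' Simulate a multi-genome community
#'
#' Genomes are simulated from their specs; per-genome coverage either comes
#' from each spec or is `abundance * total_depth` when `abundances` are
#' given (they must sum to 1).  All pairs are pooled and shuffled
#' deterministically.
#'
#' @param specs list of [sim_spec()] (names/seeds should differ)
#' @param abundances optional relative abundances, summing to 1
#' @param total_depth total community depth (X), required with `abundances`
#' @param seed seed for the pooling shuffle
#' @return list with `pairs`, `truth` (pooled, shuffled in step), `genomes`
#'   (named character vector) and `coverages`
#' @export
simulate_community <- function(specs, abundances = NULL, total_depth = NULL,
                               seed = 1L) {
  stopifnot(length(specs) >= 1L)
  if (!is.null(abundances)) {
    if (length(abundances) != length(specs))
      stop("abundances must match specs", call. = FALSE)
    if (abs(sum(abundances) - 1) > 1e-8)
      stop("abundances must sum to 1", call. = FALSE)
    if (is.null(total_depth))
      stop("total_depth is required with abundances", call. = FALSE)
    coverages <- abundances * total_depth
  } else {
    coverages <- vapply(specs, function(s) s$coverage, numeric(1))
  }
  genomes <- character(0)
  all_pairs <- list()
  all_truth <- list()
  for (i in seq_along(specs)) {
    g <- simulate_genome(specs[[i]])
    genomes[names(g)] <- unname(g)
    sim <- simulate_reads(g, specs[[i]], coverage = coverages[i])
    all_pairs[[i]] <- sim$pairs
    all_truth[[i]] <- sim$truth
  }
  id <- unlist(lapply(all_pairs, `[[`, "id"))
  seq1 <- unlist(lapply(all_pairs, `[[`, "seq1"))
  seq2 <- unlist(lapply(all_pairs, `[[`, "seq2"))
  truth <- do.call(rbind, all_truth)
  ord <- with_seed(seed, sample.int(length(id)))
  list(pairs = read_pairs(id[ord], seq1[ord], seq2[ord]),
       truth = truth[ord, , drop = FALSE],
       genomes = genomes, coverages = coverages)
}

#' Generate an rRNA-arrangement feature fixture
#'
#' Places 16S/23S/5S rRNA genes (plus, optionally, the 20 standard tRNA
#' isotypes, RNase P RNA and protein-coding genes) in the geometry of one
#' of the five linkage layouts of [classify_rrna_linkage()], with
#' randomised positions satisfying that layout's defining constraints.
#'
#' @param arrangement_type one of "A".."E"
#' @param genome_length genome length (must fit the layout)
#' @param with_trnas,with_rnasep include scattered tRNAs (all isotypes) and
#'   RNase P
#' @param drop_isotype isotypes to omit (completeness-failure fixtures)
#' @param max_gap linkage distance threshold the fixture is built against
#' @param seed integer seed
#' @return a `GRanges` feature table with `seqlengths` set; attribute
#'   `"arrangement_type"` records the generating layout
#' @export
make_feature_fixture <- function(arrangement_type, genome_length = 1e6,
                                 with_trnas = TRUE, with_rnasep = TRUE,
                                 drop_isotype = character(),
                                 max_gap = 2000L, seed = 1L) {
  type <- match.arg(arrangement_type, c("A", "B", "C", "D", "E"))
  L <- as.integer(genome_length)
  len16 <- 1500L; len23 <- 2900L; len5 <- 110L
  with_seed(seed, {
    s <- sample(c("+", "-"), 1L) # strand of the 23S/5S
    gap2 <- sample(30:200, 1L)
    rows <- list()
    add <- function(start, len, strand, kind, iso = NA_character_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        start = as.integer(start), end = as.integer(start + len - 1L),
        strand = strand, kind = kind, isotype = iso,
        stringsAsFactors = FALSE)
    }
    # layout in a transcription-direction frame starting at `cur`
    gap1 <- switch(type,
      A = sample(50:400, 1L),
      B = sample(700:1600, 1L),
      C = sample(900:1900, 1L),
      D = sample((max_gap + 500L):(max_gap * 10L), 1L),
      E = sample(50:400, 1L))
    span <- len16 + gap1 + len23 + gap2 + len5
    if (L < span + 70000L)
      stop("genome_length too small for fixture placement", call. = FALSE)
    cur <- sample.int(L - span - 70000L + 1L, 1L)
    s16 <- if (type == "E") setdiff(c("+", "-"), s) else s
    add(cur, len16, s16, "rRNA_16S")
    spacer1_start <- cur + len16
    cur <- cur + len16 + gap1
    add(cur, len23, s, "rRNA_23S")
    cur <- cur + len23 + gap2
    add(cur, len5, s, "rRNA_5S")
    cluster_end <- cur + len5
    if (type == "B") {
      n_t <- sample(1:2, 1L)
      at <- spacer1_start + 30L
      for (i in seq_len(n_t)) {
        add(at, 75L, s, "tRNA", sample(c("Ile", "Ala"), 1L))
        at <- at + 75L + sample(20:120, 1L)
      }
    } else if (type == "C") {
      add(spacer1_start + 40L, 75L, s, "tRNA", "Ile")
      add(spacer1_start + 200L, sample(300:500, 1L), s, "CDS")
    } else if (type == "D" && runif(1) < 0.5) {
      # an opposite-strand gene inside the long spacer
      add(spacer1_start + sample(200:(gap1 - 600L), 1L), 400L,
          setdiff(c("+", "-"), s), "CDS")
    }
    # scattered features outside the cluster region
    free_lo <- cluster_end + 5000L
    free_hi <- L - 2000L
    if (free_hi - free_lo < 50000L)
      stop("genome_length too small for fixture placement", call. = FALSE)
    at <- free_lo
    if (with_trnas) {
      for (iso in setdiff(standard_isotypes, drop_isotype)) {
        add(at, 75L, sample(c("+", "-"), 1L), "tRNA", iso)
        at <- at + sample(800:1500, 1L)
      }
    }
    if (with_rnasep) {
      add(at, 350L, sample(c("+", "-"), 1L), "RNaseP")
      at <- at + 1000L
    }
    for (i in 1:3) {
      add(at, sample(600:1500, 1L), sample(c("+", "-"), 1L), "CDS")
      at <- at + sample(1500:2500, 1L)
    }
    if (at >= free_hi) stop("fixture overflow; increase genome_length",
                            call. = FALSE)
    df <- do.call(rbind, rows)
    # orientation of the whole layout was drawn via `s`; when s == "-" the
    # transcription frame runs right-to-left, so mirror the coordinates
    if (s == "-") {
      tmp <- L - df$end + 1L
      df$end <- L - df$start + 1L
      df$start <- tmp
    }
    gr <- feature_table(rep("sim_genome", nrow(df)), df$start, df$end,
                        df$strand, df$kind,
                        contig_lengths = c(sim_genome = L),
                        isotype = df$isotype)
    attr(gr, "arrangement_type") <- type
    gr
  })
}
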