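#' Pipeline configuration
#'
#' Every numeric threshold of the pipeline in one serialisable object.
#'
#' @param k bait k-mer length (odd)
#' @param min_hits matching k-mer windows required in a mate to bait a pair
#' @param min_repeat minimum exact terminal repeat to call circularity (nt)
#' @param max_iter maximum bait/reassemble iterations
#' @param min_contig_len contigs shorter than this are dropped between
#'   iterations (nt)
#' @param cov_dev_frac relative deviation from the length-weighted median
#'   coverage beyond which a contig is removed as a suspected contaminant
#' @param cov_even_frac coverage-evenness threshold (min/mean)
#' @param chaos_factor fold increase in contig count (with an N50 drop)
#'   that flags the chaos outcome
#' @param bin_max_contigs,bin_min_cov candidate-bin selection: at most this
#'   many contigs and mean coverage strictly above this depth
#' @param max_gap operon linkage distance threshold (nt)
#' @param rnasep_reduction bits below the noise cutoff still accepted for
#'   RNase P RNA
#' @param min_overlap,min_support,max_step extension parameters (see
#'   [extension_params()])
#' @param frag_max,end_window paired-end topology parameters (see
#'   [topology_from_pairs()])
#' @param seed integer seed recorded with the run
#' @return a `bin_config` list
#' @export
bin_config <- function(k = 33L, min_hits = 1L, min_repeat = 100L,
                       max_iter = 10L, min_contig_len = 1000L,
                       cov_dev_frac = 0.10, cov_even_frac = 0.30,
                       chaos_factor = 3.0, bin_max_contigs = 5L,
                       bin_min_cov = 40, max_gap = 2000L,
                       rnasep_reduction = 5, min_overlap = 40L,
                       min_support = 2L, max_step = 5000L,
                       frag_max = 1000L, end_window = 800L, seed = 1L) {
  cfg <- list(k = as.integer(k), min_hits = as.integer(min_hits),
              min_repeat = as.integer(min_repeat),
              max_iter = as.integer(max_iter),
              min_contig_len = as.integer(min_contig_len),
              cov_dev_frac = cov_dev_frac, cov_even_frac = cov_even_frac,
              chaos_factor = chaos_factor,
              bin_max_contigs = as.integer(bin_max_contigs),
              bin_min_cov = bin_min_cov, max_gap = as.integer(max_gap),
              rnasep_reduction = rnasep_reduction,
              min_overlap = as.integer(min_overlap),
              min_support = as.integer(min_support),
              max_step = as.integer(max_step),
              frag_max = as.integer(frag_max),
              end_window = as.integer(end_window), seed = as.integer(seed))
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(vapply(cfg[num], function(v) v <= 0, logical(1)) &
          names(cfg)[num] != "seed"))
    stop("all thresholds must be positive", call. = FALSE)
  structure(cfg, class = "bin_config")
}

#' A metagenome bin
#'
#' @param id bin id
#' @param contigs named character vector or DNAStringSet
#' @param coverage optional per-contig mean depth; taken from the contigs'
#'   metadata when absent
#' @return a `bin_record`: `id`, `contigs`, `coverage`, `n_contigs`,
#'   `total_len`, `mean_coverage` (length-weighted)
#' @export
bin_record <- function(id, contigs, coverage = NULL) {
  contigs <- as_contig_vector(contigs)
  if (is.null(coverage)) coverage <- attr(contigs, "coverage")
  if (is.null(coverage)) coverage <- rep(NA_real_, length(contigs))
  stopifnot(length(coverage) == length(contigs))
  lens <- nchar(contigs)
  mean_cov <- if (all(is.na(coverage))) NA_real_ else
    sum(coverage * lens, na.rm = TRUE) / sum(lens[!is.na(coverage)])
  structure(list(id = id, contigs = contigs, coverage = as.numeric(coverage),
                 n_contigs = length(contigs), total_len = sum(lens),
                 mean_coverage = mean_cov),
            class = "bin_record")
}

#' @export
print.bin_record <- function(x, ...) {
  cat(sprintf("bin_record '%s': %d contigs, %d bp, %.0fX\n", x$id,
              x$n_contigs, x$total_len, x$mean_coverage))
  invisible(x)
}

#' Select candidate bins for circularization
#'
#' Keeps bins with at most `bin_max_contigs` contigs and length-weighted
#' mean coverage strictly above `bin_min_cov`; `override` admits promising
#' exceptions by id.
#'
#' @param bins list of [bin_record()]s
#' @param config a [bin_config()]
#' @param override character vector of bin ids to admit regardless
#' @return the selected subset of `bins`
#' @export
select_candidate_bins <- function(bins, config = bin_config(),
                                  override = character()) {
  keep <- vapply(bins, function(b) {
    b$id %in% override ||
      (b$n_contigs <= config$bin_max_contigs &&
         !is.na(b$mean_coverage) && b$mean_coverage > config$bin_min_cov)
  }, logical(1))
  bins[keep]
}

#' N50 of a set of contig lengths
#'
#' @param lengths integer vector of contig lengths (or a named character
#'   vector of contigs)
#' @return the N50 (0 for an empty set)
#' @export
contig_n50 <- function(lengths) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  if (!length(lengths)) return(0L)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Filter contigs by length and coverage deviation
#'
#' Drops contigs shorter than `min_contig_len`, then contigs whose coverage
#' deviates from the length-weighted median coverage of the survivors by
#' more than `cov_dev_frac` relatively (suspected contaminants).  The
#' length-weighted median — not the mean — anchors the deviation so the
#' contaminant being removed cannot drag the reference with it.
#'
#' @param contigs named character vector (or DNAStringSet)
#' @param config a [bin_config()]
#' @param coverage per-contig mean depth (taken from the contigs' attribute
#'   when absent; contigs without coverage are never removed on coverage)
#' @return the filtered contigs (with a `coverage` attribute); attribute
#'   `"removed"` reports every removal with its reason
#' @export
filter_contigs <- function(contigs, config = bin_config(), coverage = NULL) {
  contigs <- as_contig_vector(contigs)
  if (is.null(coverage)) coverage <- attr(contigs, "coverage")
  if (is.null(coverage)) coverage <- rep(NA_real_, length(contigs))
  lens <- nchar(contigs)
  removed <- data.frame(id = character(), reason = character())
  short <- lens < config$min_contig_len
  if (any(short))
    removed <- rbind(removed, data.frame(
      id = names(contigs)[short],
      reason = sprintf("short:%dnt<%d", lens[short], config$min_contig_len)))
  keep <- !short
  cov <- coverage[keep]
  if (any(keep) && any(!is.na(cov))) {
    wmed <- weighted_median(cov[!is.na(cov)], lens[keep][!is.na(cov)])
    dev <- abs(cov - wmed) / wmed
    bad <- !is.na(dev) & dev > config$cov_dev_frac
    if (any(bad)) {
      ids <- names(contigs)[keep][bad]
      removed <- rbind(removed, data.frame(
        id = ids,
        reason = sprintf("coverage_deviant:%.1fX_vs_median_%.1fX",
                         cov[bad], wmed)))
      keep[keep] <- !bad
    }
  }
  if (!any(keep))
    stop("all contigs removed by filtering - empty bin (restart signal)",
         call. = FALSE)
  out <- contigs[keep]
  attr(out, "coverage") <- coverage[keep]
  attr(out, "removed") <- removed
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(as.numeric(w)) / sum(as.numeric(w))
  x[which(cw >= 0.5)[1L]]
}

#' Classify the outcome of one bait/reassemble iteration
#'
#' * `CIRCULARIZED` — a single contig whose [assess_circularity()] verdict
#'   is circular;
#' * `CHAOS` — the contig count blew up by `chaos_factor` or more while the
#'   N50 dropped (the bin shattered);
#' * `IDEMPOTENT` — the canonical sequence sets (each sequence replaced by
#'   the lexicographic minimum of itself and its reverse complement) of the
#'   two iterations are identical;
#' * `CONTINUE` otherwise.
#'
#' @param prev,curr named character vectors of contigs before/after the
#'   iteration
#' @param config a [bin_config()]
#' @return one of "CONTINUE", "CIRCULARIZED", "IDEMPOTENT", "CHAOS"
#' @export
detect_state <- function(prev, curr, config = bin_config()) {
  prev <- as_contig_vector(prev)
  curr <- as_contig_vector(curr)
  if (length(curr) == 1L &&
      assess_circularity(unname(curr), config$min_repeat)$is_circular)
    return("CIRCULARIZED")
  if (length(curr) >= config$chaos_factor * max(length(prev), 1L) &&
      contig_n50(curr) < contig_n50(prev))
    return("CHAOS")
  canon <- function(x) sort(pmin(unname(x), rc_cpp(unname(x))))
  if (length(prev) == length(curr) && identical(canon(prev), canon(curr)))
    return("IDEMPOTENT")
  "CONTINUE"
}

#' Estimate per-contig coverage from a read pool
#'
#' Reads are assigned to the contig with which they share most (sampled)
#' canonical k-mers; a contig's coverage estimate is the total length of
#' its assigned reads over its own length.  An estimate, not an alignment:
#' reads from shared regions are attributed to one contig.
#'
#' @param contigs named character vector
#' @param reads character vector of reads
#' @param k k-mer length
#' @return numeric coverage per contig
#' @export
estimate_coverage <- function(contigs, reads, k = 33L) {
  contigs <- as_contig_vector(contigs)
  assign0 <- assign_reads_cpp(reads, unname(contigs), as.integer(k), 8L)
  cov <- numeric(length(contigs))
  ok <- assign0 >= 0L
  if (any(ok)) {
    bases <- tapply(nchar(reads)[ok], assign0[ok], sum)
    cov[as.integer(names(bases)) + 1L] <- as.numeric(bases)
  }
  setNames(cov / nchar(contigs), names(contigs))
}

#' Iteratively circularize a metagenome bin
#'
#' The core loop: build a k-mer index from the current contigs, bait read
#' pairs from the full library, reassemble the bin from the baited reads
#' (read-coherent extension + merging), filter short/coverage-deviant
#' contigs, and classify the outcome — until `CIRCULARIZED`, `IDEMPOTENT`,
#' `CHAOS`, or `max_iter`.  On circularization the terminal repeat is
#' trimmed, the genome is rotated by half its length (so the junction can
#' be re-examined away from the ends), and paired-end topology, coverage
#' evenness and (when features are supplied) the ncRNA complement are
#' checked.
#'
#' @param bin a [bin_record()], named character vector or DNAStringSet
#' @param pairs the full read library as a [read_pairs] object
#' @param config a [bin_config()]
#' @param features optional `GRanges` feature table for the completeness
#'   gate
#' @param extra_bait optional extra bait contigs (never added automatically)
#' @param output_dir optional directory for per-iteration FASTAs,
#'   `iterations.tsv`, final FASTAs and `report.json`
#' @param verbose print one line per iteration
#' @return a `circbin_run` list: `state`, `iterations` (data.frame),
#'   `contigs`, and on circularization `genome`, `genome_rotated`,
#'   `verdict`, `topology`, `topology_rotated`, `coverage`, `rna`
#' @export
circularize_bin <- function(bin, pairs, config = bin_config(),
                            features = NULL, extra_bait = NULL,
                            output_dir = NULL, verbose = FALSE) {
  contigs <- if (inherits(bin, "bin_record")) bin$contigs else
    as_contig_vector(bin)
  if (!length(contigs)) stop("empty bin", call. = FALSE)
  stopifnot(inherits(pairs, "read_pairs"))
  if (!is.null(extra_bait)) extra_bait <- as_contig_vector(extra_bait)
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- extension_params(min_overlap = config$min_overlap,
                             min_support = config$min_support,
                             max_step = config$max_step,
                             self_overlap_cap = 10L * config$min_repeat)
  iters <- data.frame()
  state <- "CONTINUE"
  for (iter in seq_len(config$max_iter)) {
    bait <- c(contigs, extra_bait)
    idx <- build_kmer_index(bait, config$k)
    br <- bait_pairs(pairs, idx, config$min_hits)
    if (br$n_kept == 0L)
      stop("no read pair shares k-mer content with the bin - aborting",
           call. = FALSE)
    reads <- c(br$kept$seq1, br$kept$seq2)
    out <- reassemble(reads, contigs, params)
    cov <- estimate_coverage(out, reads, config$k)
    filtered <- filter_contigs(out, config, coverage = cov)
    state <- detect_state(contigs, filtered, config)
    iters <- rbind(iters, data.frame(
      iter = iter, n_baited = br$n_kept, n_contigs = length(filtered),
      total_len = sum(nchar(filtered)), n50 = contig_n50(filtered),
      state = state))
    if (verbose)
      message(sprintf("iter %d: %d pairs baited, %d contigs, %d bp, N50 %d, %s",
                      iter, br$n_kept, length(filtered),
                      sum(nchar(filtered)), contig_n50(filtered), state))
    if (!is.null(output_dir))
      write_fasta(unclass(filtered),
                  file.path(output_dir, sprintf("iteration_%02d.fasta", iter)))
    contigs <- filtered
    if (state != "CONTINUE") break
  }
  res <- list(state = state, iterations = iters, contigs = contigs,
              config = config)
  if (state == "CIRCULARIZED") {
    contig <- unname(contigs[1L])
    res$verdict <- assess_circularity(contig, config$min_repeat)
    genome <- circularize(contig, config$min_repeat)
    names(genome) <- names(contigs)[1L]
    rotated <- rotate_seq(unname(genome), nchar(genome) %/% 2L)
    names(rotated) <- paste0(names(contigs)[1L], "_rotated")
    res$genome <- genome
    res$genome_rotated <- rotated
    res$topology <- topology_from_pairs(unname(genome), pairs,
                                        config$frag_max, config$end_window)
    res$topology_rotated <- topology_from_pairs(unname(rotated), pairs,
                                                config$frag_max,
                                                config$end_window)
    depth <- mapped_depth(unname(genome), pairs, circular = TRUE)
    res$coverage <- coverage_evenness(depth, config$cov_even_frac)
    if (!is.null(features)) res$rna <- check_rna_complement(features)
  }
  class(res) <- "circbin_run"
  if (!is.null(output_dir)) {
    if (state == "CIRCULARIZED") {
      write_fasta(res$genome, file.path(output_dir, "genome.fasta"))
      write_fasta(res$genome_rotated,
                  file.path(output_dir, "genome_rotated.fasta"))
    }
    utils::write.table(iters, file.path(output_dir, "iterations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(run_report(res),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' JSON-ready summary of a pipeline run
#'
#' @param run a `circbin_run`
#' @return a plain list (no sequences) suitable for [jsonlite::write_json()]
#' @export
run_report <- function(run) {
  rep <- list(state = run$state,
              config = unclass(run$config),
              iterations = run$iterations)
  if (!is.null(run$verdict)) {
    rep$circularity <- list(
      is_circular = run$verdict$is_circular,
      terminal_overlap = run$verdict$terminal_overlap,
      longest_other_repeat = run$verdict$longest_other_repeat,
      terminal_copy_count = run$verdict$terminal_copy_count,
      reasons = run$verdict$reasons)
    rep$genome_length <- nchar(run$genome)
    rep$topology <- unclass(run$topology)
    rep$topology_rotated <- unclass(run$topology_rotated)
    rep$coverage <- unclass(run$coverage)
    if (!is.null(run$rna))
      rep$rna <- list(ok = run$rna$ok, reasons = run$rna$reasons)
  }
  rep
}

#' @export
print.circbin_run <- function(x, ...) {
  cat(sprintf("circbin_run: %s after %d iteration(s)\n", x$state,
              nrow(x$iterations)))
  if (!is.null(x$genome))
    cat(sprintf("  genome: %d bp (terminal overlap %d nt trimmed)\n",
                nchar(x$genome), x$verdict$terminal_overlap))
  invisible(x)
}

#' Final quality checks on a circularized genome
#'
#' Re-appends the first `2 * min_repeat` bases to the trimmed genome and
#' re-assesses circularity; gathers paired-end topology evidence on the
#' genome and its half rotation; checks coverage evenness (depth from
#' exact-match mapping when not supplied) and, when features are given, the
#' ncRNA complement.  Overall pass requires every gate to pass.  Consensus
#' polishing of the junction is delegated to an external polisher through
#' [external_assembler()]-style adapters and is not re-implemented here.
#'
#' @param genome the circular-trimmed genome (single sequence)
#' @param pairs the read library ([read_pairs])
#' @param config a [bin_config()]
#' @param features optional `GRanges` feature table
#' @param depth optional per-base depth track
#' @return a `final_checks` list with `circularity`, `topology`,
#'   `topology_rotated`, `coverage`, `rna`, `pass`
#' @export
final_checks <- function(genome, pairs, config = bin_config(),
                         features = NULL, depth = NULL) {
  genome <- unname(genome)
  L <- nchar(genome)
  re <- paste0(genome, substr(genome, 1L, min(2L * config$min_repeat, L)))
  verdict <- assess_circularity(re, config$min_repeat)
  topo <- topology_from_pairs(genome, pairs, config$frag_max,
                              config$end_window)
  topo_rot <- topology_from_pairs(rotate_seq(genome, L %/% 2L), pairs,
                                  config$frag_max, config$end_window)
  if (is.null(depth)) depth <- mapped_depth(genome, pairs, circular = TRUE)
  cov <- coverage_evenness(depth, config$cov_even_frac)
  rna <- if (!is.null(features)) check_rna_complement(features)
  pass <- verdict$is_circular &&
    (topo$outward_pairs > 0L || topo_rot$spanning_pairs > 0L) &&
    cov$pass && (is.null(rna) || rna$ok)
  structure(list(circularity = verdict, topology = topo,
                 topology_rotated = topo_rot, coverage = cov, rna = rna,
                 pass = pass),
            class = "final_checks")
}

#' @export
print.final_checks <- function(x, ...) {
  cat(sprintf("final_checks: %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$circularity)
  print(x$topology)
  print(x$coverage)
  if (!is.null(x$rna)) print(x$rna)
  invisible(x)
}
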