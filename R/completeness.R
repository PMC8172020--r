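#' The 20 standard amino-acid tRNA isotypes
#' @export
standard_isotypes <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                       "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                       "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

#' Check the non-coding RNA complement of a genome
#'
#' A complete small genome is expected to carry its full complement of
#' ribosomal RNAs (16S, 23S, 5S), a tRNA for every one of the 20 standard
#' amino acids, and RNase P RNA (nearly universally required to mature
#' pre-tRNA 5' ends).  Selenocysteine/pyrrolysine tRNAs are reported but
#' never required.
#'
#' @param features a `GRanges` feature table (see [feature_table()])
#' @param expected_rrna_copies expected copy number of each rRNA gene
#'   (1 for clades known to carry a single ribosomal operon)
#' @return an `rna_complement` list: per-rRNA copy counts and booleans,
#'   isotypes found/missing, `has_rnasep`, overall `ok` and `reasons`
#' @export
check_rna_complement <- function(features, expected_rrna_copies = 1L) {
  kind <- S4Vectors::mcols(features)$kind
  if (is.null(kind)) stop("features lack a 'kind' column", call. = FALSE)
  nc <- function(k) sum(kind == k)
  counts <- c(rRNA_16S = nc("rRNA_16S"), rRNA_23S = nc("rRNA_23S"),
              rRNA_5S = nc("rRNA_5S"))
  iso <- character()
  if (any(kind == "tRNA")) {
    iso <- S4Vectors::mcols(features)$isotype[kind == "tRNA"]
    iso <- unique(iso[!is.na(iso)])
  }
  missing_iso <- setdiff(standard_isotypes, iso)
  has_rnasep <- nc("RNaseP") > 0L
  reasons <- character()
  for (k in names(counts)) {
    if (counts[[k]] != expected_rrna_copies)
      reasons <- c(reasons, sprintf("%s count %d != expected %d",
                                    sub("rRNA_", "", k), counts[[k]],
                                    expected_rrna_copies))
  }
  if (length(missing_iso))
    reasons <- c(reasons, paste0("missing tRNA isotypes: ",
                                 paste(missing_iso, collapse = ",")))
  if (!has_rnasep) reasons <- c(reasons, "RNase P RNA absent")
  structure(list(
    counts = counts,
    has_16S = counts[["rRNA_16S"]] == expected_rrna_copies,
    has_23S = counts[["rRNA_23S"]] == expected_rrna_copies,
    has_5S = counts[["rRNA_5S"]] == expected_rrna_copies,
    trna_isotypes_found = sort(intersect(iso, standard_isotypes)),
    extra_isotypes = sort(setdiff(iso, standard_isotypes)),
    missing_isotypes = sort(missing_iso),
    has_rnasep = has_rnasep,
    ok = length(reasons) == 0L,
    reasons = reasons), class = "rna_complement")
}

#' @export
print.rna_complement <- function(x, ...) {
  cat(sprintf("rna_complement: %s (16S:%d 23S:%d 5S:%d, %d/20 isotypes, RNase P %s)\n",
              if (x$ok) "complete" else "INCOMPLETE",
              x$counts[["rRNA_16S"]], x$counts[["rRNA_23S"]],
              x$counts[["rRNA_5S"]], length(x$trna_isotypes_found),
              if (x$has_rnasep) "present" else "ABSENT"))
  if (length(x$reasons)) cat("  ", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Accept RNase P hits below the model noise cutoff
#'
#' Diverged RNase P RNAs can score below the covariance model's noise cutoff
#' (the score conventionally regarded as the highest-scoring expected false
#' positive).  This scan accepts hits with
#' `score >= noise_cutoff - reduction` (default: 5 bits below the cutoff) and
#' flags every accepted sub-cutoff hit for manual curation.
#'
#' @param hits a `GRanges` (or data.frame) with a `score` column
#' @param noise_cutoff the model's noise cutoff (bits)
#' @param reduction bits below the cutoff still accepted (>= 0); with
#'   `mode = "absolute"` the accepting threshold is `reduction` itself
#' @param mode `"reduce_by"` (threshold = cutoff - reduction) or
#'   `"absolute"` (threshold = reduction)
#' @return the accepted hits with a logical `below_noise_cutoff` column and
#'   a `flag` note on sub-cutoff hits
#' @export
relaxed_rnasep_scan <- function(hits, noise_cutoff, reduction = 5,
                                mode = c("reduce_by", "absolute")) {
  mode <- match.arg(mode)
  if (reduction < 0) stop("reduction must be >= 0", call. = FALSE)
  score <- if (is(hits, "GRanges")) S4Vectors::mcols(hits)$score else
    hits$score
  if (is.null(score)) stop("hits lack a 'score' column", call. = FALSE)
  threshold <- if (mode == "reduce_by") noise_cutoff - reduction else
    reduction
  keep <- score >= threshold
  out <- if (is.data.frame(hits)) hits[keep, , drop = FALSE] else hits[keep]
  sub <- score[keep] < noise_cutoff
  flag <- ifelse(sub, "below noise cutoff - manual curation advised", "")
  if (is(out, "GRanges")) {
    S4Vectors::mcols(out)$below_noise_cutoff <- sub
    S4Vectors::mcols(out)$flag <- flag
  } else {
    out$below_noise_cutoff <- sub
    out$flag <- flag
  }
  out
}

#' Coverage evenness check
#'
#' Passes iff the minimum per-base depth is at least `min_frac` of the mean
#' depth (default 30%).  Assemblies that rely on a handful of reads for
#' continuity anywhere along the genome fail this gate.  A warning is
#' emitted when mean depth is below 30X — the regime where reassembly
#' typically degenerates rather than converges.
#'
#' @param depth_track numeric vector of per-base depths
#' @param min_frac minimum allowed `min(depth)/mean(depth)`
#' @return a `coverage_evenness` list: `pass`, `min_over_mean`,
#'   `mean_depth`, `min_depth`
#' @export
coverage_evenness <- function(depth_track, min_frac = 0.30) {
  if (!length(depth_track)) stop("empty depth track", call. = FALSE)
  if (any(depth_track < 0)) stop("negative depth", call. = FALSE)
  mu <- mean(depth_track)
  mn <- min(depth_track)
  ratio <- if (mu > 0) mn / mu else 0
  if (mu < 30)
    warning("mean coverage ", signif(mu, 3),
            "X is below 30X; reassembly outcomes are unreliable at low coverage")
  structure(list(pass = ratio >= min_frac, min_over_mean = ratio,
                 mean_depth = mu, min_depth = mn),
            class = "coverage_evenness")
}

#' @export
print.coverage_evenness <- function(x, ...) {
  cat(sprintf("coverage_evenness: %s (min/mean = %.3f, mean %.1fX)\n",
              if (x$pass) "pass" else "FAIL", x$min_over_mean, x$mean_depth))
  invisible(x)
}

#' Full completeness report
#'
#' Combines the non-coding RNA complement and the coverage-evenness gate.
#' The verdict passes only when all three rRNAs are present at the expected
#' copy number, no standard tRNA isotype is missing, RNase P RNA is present
#' and coverage is even.
#'
#' @param features a `GRanges` feature table
#' @param depth_track per-base depths (a single contig's, or concatenated;
#'   the mean is then length-weighted by construction)
#' @param expected_rrna_copies expected rRNA copy number
#' @param min_frac coverage-evenness threshold
#' @return a `completeness_report` list with components `rna`, `coverage`,
#'   `verdict`, `reasons`
#' @export
completeness_report <- function(features, depth_track,
                                expected_rrna_copies = 1L, min_frac = 0.30) {
  rna <- check_rna_complement(features, expected_rrna_copies)
  cov <- coverage_evenness(depth_track, min_frac)
  reasons <- rna$reasons
  if (!cov$pass)
    reasons <- c(reasons, sprintf("uneven coverage: min/mean %.3f < %.2f",
                                  cov$min_over_mean, min_frac))
  structure(list(rna = rna, coverage = cov,
                 verdict = rna$ok && cov$pass, reasons = reasons),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("completeness_report: %s\n",
              if (x$verdict) "PASS" else "FAIL"))
  print(x$rna)
  print(x$coverage)
  invisible(x)
}
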