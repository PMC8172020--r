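#' Build a canonical k-mer index from bait contigs
#'
#' Every N-free window of length `k` of every contig is stored as its
#' canonical form (the lexicographic minimum of the k-mer and its reverse
#' complement), so membership is strand-independent.  `k` must be odd (an
#' even k admits reverse-complement palindromes, which would make canonical
#' form ambiguous between the two identical strands) and at least 11.
#'
#' @param contigs named character vector or [Biostrings::DNAStringSet] of
#'   bait contigs; must be non-empty
#' @param k k-mer length (odd, 11..63)
#' @return an object of class `kmer_index`: a list with `k` and the sorted
#'   character vector `kmers` of canonical k-mers
#' @export
build_kmer_index <- function(contigs, k = 33L) {
  contigs <- as_contig_vector(contigs)
  if (!length(contigs)) stop("empty contig set", call. = FALSE)
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd (canonical form is ambiguous for palindromic even k-mers)",
         call. = FALSE)
  if (k < 11L || k > 63L) stop("k must be in 11..63", call. = FALSE)
  structure(list(k = k, kmers = build_kmer_index_cpp(unname(contigs), k)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d canonical %d-mers\n", length(x$kmers), x$k))
  invisible(x)
}

#' @export
length.kmer_index <- function(x) length(x$kmers)

#' Select read pairs sharing k-mer content with the bait
#'
#' A pair is kept iff either mate contains at least `min_hits` windows whose
#' canonical k-mer is in the index; both mates of a kept pair are retained
#' (pair-level baiting).  Reads matching several baits are deliberately kept
#' for each — no multi-bin disambiguation is attempted.  Windows containing
#' N never match.
#'
#' @param pairs a [read_pairs] object
#' @param index a [build_kmer_index()] result
#' @param min_hits minimum matching windows in a single mate (>= 1)
#' @return a `bait_result`: list with `kept` (a [read_pairs]), `n_input`,
#'   `n_kept`
#' @export
bait_pairs <- function(pairs, index, min_hits = 1L) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(index, "kmer_index"))
  min_hits <- as.integer(min_hits)
  if (min_hits < 1L) stop("min_hits must be >= 1", call. = FALSE)
  n <- length(pairs)
  if (n && index$k > max(nchar(pairs$seq1), nchar(pairs$seq2))) {
    warning("k (", index$k, ") exceeds every mate length; no pair can match")
    keep <- rep(FALSE, n)
  } else if (!length(index$kmers)) {
    keep <- rep(FALSE, n)
  } else {
    keep <- bait_cpp(pairs$seq1, pairs$seq2, index$kmers, index$k, min_hits)
  }
  structure(list(kept = pairs[keep], n_input = n, n_kept = sum(keep)),
            class = "bait_result")
}

#' @export
print.bait_result <- function(x, ...) {
  cat(sprintf("bait_result: kept %d / %d pairs\n", x$n_kept, x$n_input))
  invisible(x)
}

# normalise contig input (DNAStringSet or character) to a validated named
# character vector carrying an optional "coverage" attribute
as_contig_vector <- function(contigs) {
  cov <- NULL
  if (is(contigs, "DNAStringSet") || is(contigs, "XStringSet")) {
    md <- S4Vectors::mcols(contigs)
    if (!is.null(md) && "coverage" %in% names(md)) cov <- md$coverage
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  if (!is.character(contigs)) stop("contigs must be character or DNAStringSet",
                                   call. = FALSE)
  if (length(contigs)) {
    if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
      stop("contigs must be named", call. = FALSE)
    if (anyDuplicated(names(contigs)))
      stop("contig ids must be unique", call. = FALSE)
    .validate_dna(contigs, names(contigs), "contig")
    if (any(!nzchar(contigs))) stop("empty contig sequence", call. = FALSE)
  }
  if (!is.null(cov)) attr(contigs, "coverage") <- as.numeric(cov)
  contigs
}
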