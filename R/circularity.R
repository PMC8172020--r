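#' Length of the exact terminal overlap of a contig
#'
#' The longest proper prefix of the sequence that is also its suffix (the
#' classical string border).  A circular replicon assembled past its origin
#' shows up as such an exact terminal repeat.
#'
#' @param seq a single sequence (character)
#' @return overlap length in nt (0 when none)
#' @export
terminal_overlap <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  border_cpp(seq)
}

#' Longest repeat excluding the terminal copy pair
#'
#' Exact length of the longest substring with two distinct occurrences in
#' the contig, counting both strands (an inverted repeat counts; a
#' palindrome matching its own reverse complement at the identical interval
#' does not).  The designated terminal pair — the forward-strand
#' correspondence between prefix `[1, t]` and suffix `[L-t+1, L]`, i.e. any
#' direct match at offset exactly `L - t` — is excluded, so the quantity
#' measures the longest repeat *competing* with the candidate circular
#' junction.  Windows containing N never match.
#'
#' @param seq a single sequence
#' @param t the designated terminal overlap (0 <= t <= terminal_overlap(seq))
#' @return repeat length in nt (0 when none)
#' @export
longest_repeat_excluding_terminal <- function(seq, t = terminal_overlap(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  t <- as.integer(t)
  if (t < 0 || t > terminal_overlap(seq))
    stop("t must satisfy 0 <= t <= terminal_overlap(seq)", call. = FALSE)
  longest_repeat_cpp(seq, t)
}

#' Decide circularity of a contig from its terminal repeat
#'
#' A contig is called circular iff (i) its exact terminal overlap is at
#' least `min_repeat` nt, (ii) that overlap is strictly longer than any
#' other repeat in the contig (both strands), and (iii) the terminal repeat
#' string occurs exactly twice in the contig (both strands counted) — it
#' does not match any further repeat copy.
#'
#' @param seq a single sequence
#' @param min_repeat minimum terminal repeat length (nt); 100 by default
#' @return a `circularity_verdict`: list with `is_circular`,
#'   `terminal_overlap`, `longest_other_repeat`, `terminal_copy_count`,
#'   `reasons` (codes for every failed clause)
#' @export
assess_circularity <- function(seq, min_repeat = 100L) {
  min_repeat <- as.integer(min_repeat)
  if (min_repeat < 1L) stop("min_repeat must be >= 1", call. = FALSE)
  t <- terminal_overlap(seq)
  other <- longest_repeat_excluding_terminal(seq, t)
  copies <- if (t > 0L) count_occurrences_cpp(seq, substr(seq, 1L, t)) else 0L
  reasons <- character()
  if (t < min_repeat)
    reasons <- c(reasons, sprintf("terminal_overlap_below_min:%d<%d", t,
                                  min_repeat))
  if (t > 0L && other >= t)
    reasons <- c(reasons, sprintf("internal_repeat_not_shorter:%d>=%d",
                                  other, t))
  if (t >= min_repeat && copies != 2L)
    reasons <- c(reasons, sprintf("terminal_copy_count_not_2:%d", copies))
  structure(list(is_circular = length(reasons) == 0L,
                 terminal_overlap = t,
                 longest_other_repeat = other,
                 terminal_copy_count = copies,
                 reasons = reasons),
            class = "circularity_verdict")
}

#' @export
print.circularity_verdict <- function(x, ...) {
  cat(sprintf("circularity_verdict: %s (terminal overlap %d nt, longest other repeat %d nt, %d terminal copies)\n",
              if (x$is_circular) "CIRCULAR" else "not circular",
              x$terminal_overlap, x$longest_other_repeat,
              x$terminal_copy_count))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "),
                             "\n")
  invisible(x)
}

#' Trim the duplicated terminal copy of a circular contig
#'
#' @param seq a single sequence whose [assess_circularity()] verdict is
#'   circular
#' @param min_repeat passed through to the verdict check
#' @return the sequence with the terminal suffix copy removed (length
#'   `L - terminal_overlap`); the circular junction sits at position 1
#' @export
circularize <- function(seq, min_repeat = 100L) {
  v <- assess_circularity(seq, min_repeat)
  if (!v$is_circular)
    stop("circularize() called on a non-circular contig (",
         paste(v$reasons, collapse = "; "), ")", call. = FALSE)
  substr(seq, 1L, nchar(seq) - v$terminal_overlap)
}

#' Rotate a (circular) sequence
#'
#' @param seq a single sequence
#' @param offset rotation offset, `0 <= offset < nchar(seq)`; the returned
#'   sequence is `seq[offset+1:] + seq[:offset]`
#' @return the rotated sequence
#' @export
rotate_seq <- function(seq, offset) {
  stopifnot(is.character(seq), length(seq) == 1L)
  offset <- as.integer(offset)
  L <- nchar(seq)
  if (offset < 0L || offset >= L)
    stop("offset must satisfy 0 <= offset < nchar(seq)", call. = FALSE)
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, L), substr(seq, 1L, offset))
}

#' Map mates by exact substring search
#'
#' Each mate is located as a verbatim substring of the genome (either
#' orientation); a mate with any mismatch does not map.  Used for
#' paired-end topology evidence and the exact-match depth track.
#'
#' @param genome a single sequence
#' @param pairs a [read_pairs] object
#' @return a data.frame with 1-based `pos1`, `strand1`, `len1`, `pos2`,
#'   `strand2`, `len2` (NA when unmapped)
#' @export
map_pairs <- function(genome, pairs) {
  stopifnot(inherits(pairs, "read_pairs"))
  m <- map_mates_cpp(genome, pairs$seq1, pairs$seq2)
  as.data.frame(m)
}

#' Per-base depth from exact-match read mapping
#'
#' With `circular = TRUE` the genome is extended by a one-read-length wrap
#' margin before mapping and the margin depth is folded back onto the
#' origin, so junction-spanning reads contribute; a linearly represented
#' circular replicon would otherwise show an artifactual depth hole at its
#' ends.
#'
#' @param genome a single sequence
#' @param pairs a [read_pairs] object
#' @param circular treat the sequence as a circular replicon
#' @return integer vector of per-base depth (length `nchar(genome)`)
#' @export
mapped_depth <- function(genome, pairs, circular = FALSE) {
  L0 <- nchar(genome)
  margin <- 0L
  if (circular && L0 > 1L) {
    margin <- min(L0 - 1L, max(nchar(pairs$seq1), nchar(pairs$seq2), 0L))
    genome <- paste0(genome, substr(genome, 1L, margin))
  }
  m <- map_pairs(genome, pairs)
  L <- nchar(genome)
  ok1 <- !is.na(m$pos1); ok2 <- !is.na(m$pos2)
  starts <- c(m$pos1[ok1], m$pos2[ok2])
  ends <- starts + c(m$len1[ok1], m$len2[ok2]) # first position past the read
  delta <- tabulate(starts, nbins = L + 1L) - tabulate(ends, nbins = L + 1L)
  depth <- cumsum(delta)[seq_len(L)]
  if (margin > 0L) {
    fold <- depth[(L0 + 1L):L]
    depth <- depth[seq_len(L0)]
    depth[seq_len(margin)] <- depth[seq_len(margin)] + fold
  }
  depth
}

#' Paired-end topology evidence for circularity
#'
#' Mates are mapped by exact substring search.  A pair whose mates sit near
#' opposite ends of the sequence and point outward (the minus-strand mate at
#' the left end, the plus-strand mate at the right end) is the paired-end
#' signature of a circular replicon assembled as a linear contig.  Properly
#' oriented pairs confined to a terminal window are counted as
#' `inward_end_pairs` (linear-end evidence).  The genome is additionally
#' rotated by half its length and properly oriented pairs spanning the
#' original junction are counted as `spanning_pairs`.
#'
#' @param genome a single sequence
#' @param pairs a [read_pairs] object
#' @param frag_max maximum plausible fragment length for a proper pair (nt)
#' @param end_window how far from a sequence end a mate may sit to count as
#'   terminal; about twice the mean fragment length is sensible
#' @return a `topology_evidence` list: `outward_pairs`, `inward_end_pairs`,
#'   `spanning_pairs`
#' @export
topology_from_pairs <- function(genome, pairs, frag_max = 1000L,
                                end_window = 800L) {
  L <- nchar(genome)
  m <- map_pairs(genome, pairs)
  both <- !is.na(m$pos1) & !is.na(m$pos2)
  outward <- 0L
  inward <- 0L
  if (any(both)) {
    p1 <- m$pos1[both]; s1 <- m$strand1[both]; l1 <- m$len1[both]
    p2 <- m$pos2[both]; s2 <- m$strand2[both]; l2 <- m$len2[both]
    near_left <- function(p, l, s) p <= end_window & s == -1L
    near_right <- function(p, l, s) (p + l - 1L) >= (L - end_window + 1L) &
      s == 1L
    outward <- sum((near_left(p1, l1, s1) & near_right(p2, l2, s2)) |
                   (near_left(p2, l2, s2) & near_right(p1, l1, s1)))
    # properly oriented (forward-reverse, implied fragment <= frag_max)
    plus_first <- s1 == 1L & s2 == -1L & p1 <= p2
    minus_first <- s2 == 1L & s1 == -1L & p2 <= p1
    fp <- ifelse(plus_first, p1, ifelse(minus_first, p2, NA))
    fe <- ifelse(plus_first, p2 + l2 - 1L, ifelse(minus_first, p1 + l1 - 1L,
                                                  NA))
    proper <- !is.na(fp) & (fe - fp + 1L) <= frag_max & fe >= fp
    inward <- sum(proper & (fe <= end_window | fp >= L - end_window + 1L))
  }
  spanning <- 0L
  if (L >= 2L) {
    off <- L %/% 2L
    rot <- rotate_seq(genome, off)
    junction <- L - off # original position 1 boundary in rotated coordinates
    mr <- map_pairs(rot, pairs)
    bothr <- !is.na(mr$pos1) & !is.na(mr$pos2)
    if (any(bothr)) {
      p1 <- mr$pos1[bothr]; s1 <- mr$strand1[bothr]; l1 <- mr$len1[bothr]
      p2 <- mr$pos2[bothr]; s2 <- mr$strand2[bothr]; l2 <- mr$len2[bothr]
      plus_first <- s1 == 1L & s2 == -1L & p1 <= p2
      minus_first <- s2 == 1L & s1 == -1L & p2 <= p1
      fp <- ifelse(plus_first, p1, ifelse(minus_first, p2, NA))
      fe <- ifelse(plus_first, p2 + l2 - 1L, ifelse(minus_first,
                                                    p1 + l1 - 1L, NA))
      proper <- !is.na(fp) & (fe - fp + 1L) <= frag_max & fe >= fp
      spanning <- sum(proper & fp <= junction & fe > junction)
    }
  }
  structure(list(outward_pairs = as.integer(outward),
                 inward_end_pairs = as.integer(inward),
                 spanning_pairs = as.integer(spanning)),
            class = "topology_evidence")
}

#' @export
print.topology_evidence <- function(x, ...) {
  cat(sprintf("topology_evidence: %d outward, %d inward-at-end, %d junction-spanning pairs\n",
              x$outward_pairs, x$inward_end_pairs, x$spanning_pairs))
  invisible(x)
}
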