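#' Classify ribosomal RNA operon linkage
#'
#' Classifies the arrangement of the 16S, 23S and 5S rRNA genes of a
#' (typically circular) genome into five layouts:
#'
#' * **A** — operonic: 16S, 23S and 5S co-oriented with empty spacers;
#' * **B** — operonic with tRNAs in the 16S-23S spacer (same strand);
#' * **C** — operonic with tRNAs and/or protein-coding genes in the spacers;
#' * **D** — unlinked by distance: same strand, but the downstream spacer
#'   from the 16S to the 23S exceeds `max_gap` with no chain of same-strand
#'   genes bridging it (consecutive gaps each `<= max_gap`), or an
#'   intervening gene on the opposite strand interrupts it;
#' * **E** — unlinked by strand: the 16S lies on the opposite strand from
#'   the 23S and 5S.
#'
#' The decision order is E, then D, then A/B/C by spacer content.  The
#' 23S-5S linkage is assessed with the same rules and reported separately
#' (`unlinked_23S_5S`).  On a circular genome spacers are evaluated along
#' the direction of transcription across the origin, and the reported
#' distances are minimum-arc distances (never more than half the genome).
#' Intra-operon gaps of 300 nt or more (but within `max_gap`) are counted
#' as operonic, with a note attached so the call can be revisited.
#'
#' @param features a `GRanges` feature table containing exactly one 16S,
#'   one 23S and one 5S rRNA (a different copy number is an error: the
#'   method targets single-operon genomes), plus any tRNA/CDS features
#' @param genome_length genome length (nt); defaults to the feature table's
#'   `seqlengths` when set
#' @param is_circular treat coordinates circularly
#' @param max_gap maximum spacer (and chain-link) distance for linkage (nt)
#' @return an `operon_call`: list with `type`, `d_16S_23S`, `d_23S_5S`,
#'   `spacer_16S_23S`, `spacer_23S_5S` (kinds of same-strand spacer genes),
#'   `unlinked_23S_5S`, `notes`
#' @export
classify_rrna_linkage <- function(features, genome_length = NULL,
                                  is_circular = TRUE, max_gap = 2000L) {
  kind <- S4Vectors::mcols(features)$kind
  if (is.null(genome_length)) {
    sl <- GenomeInfoDb::seqlengths(features)
    if (length(sl) == 1L && !is.na(sl)) genome_length <- unname(sl)
    else stop("genome_length must be given (or set as seqlengths)",
              call. = FALSE)
  }
  L <- as.integer(genome_length)
  pick <- function(k) {
    i <- which(kind == k)
    if (length(i) != 1L)
      stop(sprintf("rRNA multiplicity error: %d copies of %s (need exactly 1)",
                   length(i), sub("rRNA_", "", k)), call. = FALSE)
    i
  }
  i16 <- pick("rRNA_16S"); i23 <- pick("rRNA_23S"); i5 <- pick("rRNA_5S")
  st <- as.character(GenomicRanges::strand(features))
  s16 <- st[i16]; s23 <- st[i23]; s5 <- st[i5]
  notes <- character()

  # work in the frame where the 23S is on "+" (flip the genome otherwise)
  flip <- s23 == "-"
  fstart <- GenomicRanges::start(features)
  fend <- GenomicRanges::end(features)
  if (flip) {
    tmp <- L - fend + 1L
    fend <- L - fstart + 1L
    fstart <- tmp
    st <- c("+" = "-", "-" = "+")[st]
  }
  other <- setdiff(seq_along(features), c(i16, i23, i5))

  # downstream spacer from gene a (3' end) to gene b (5' start) on "+"
  spacer_info <- function(ia, ib) {
    gap <- fstart[ib] - fend[ia] - 1L
    if (is_circular) gap <- ((gap %% L) + L) %% L
    else if (gap < 0L) return(list(gap = NA_integer_, inside = integer(),
                                   chain_ok = FALSE, opp = FALSE,
                                   big_gaps = FALSE))
    u <- function(p) if (is_circular) ((p - fend[ia] - 1L) %% L) else
      p - fend[ia] - 1L
    us <- u(fstart[other]); ue <- u(fend[other])
    inside <- other[!is.na(us) & us >= 0L & ue >= us & ue < gap]
    same <- inside[st[inside] == "+"]
    opp <- any(st[inside] == "-")
    chain_ok <- FALSE; big_gaps <- FALSE
    if (gap <= max_gap) {
      chain_ok <- TRUE
      big_gaps <- gap >= 300L
    } else if (length(same)) {
      # gaps: a-end .. first gene, consecutive genes, last gene .. b-start
      o <- same[order(u(fstart[same]))]
      lead <- u(fstart[o])[1]
      mids <- if (length(o) > 1L)
        u(fstart[o])[-1L] - u(fend[o])[-length(o)] - 1L else integer()
      trail <- gap - 1L - u(fend[o])[length(o)]
      allg <- c(lead, mids, trail)
      chain_ok <- all(allg <= max_gap)
      big_gaps <- any(allg >= 300L)
    }
    list(gap = gap, inside = inside, chain_ok = chain_ok, opp = opp,
         big_gaps = big_gaps)
  }

  min_arc <- function(ia, ib) {
    if (is_circular) {
      d1 <- ((fstart[ib] - fend[ia] - 1L) %% L)
      d2 <- ((fstart[ia] - fend[ib] - 1L) %% L)
      min(d1, d2)
    } else {
      if (fend[ia] < fstart[ib]) fstart[ib] - fend[ia] - 1L
      else if (fend[ib] < fstart[ia]) fstart[ia] - fend[ib] - 1L
      else 0L
    }
  }

  sp1 <- spacer_info(i16, i23)
  content_kinds <- function(sp) {
    same <- sp$inside[st[sp$inside] == "+"]
    kind[same]
  }

  # 23S - 5S linkage
  unlinked_5S <- FALSE
  sp2 <- NULL
  if (s5 != s23) {
    unlinked_5S <- TRUE
    notes <- c(notes, "5S on opposite strand from 23S")
  } else {
    sp2 <- spacer_info(i23, i5)
    if (is.na(sp2$gap) || (sp2$gap > max_gap && !sp2$chain_ok) || sp2$opp)
      unlinked_5S <- TRUE
    if (!is.null(sp2) && !unlinked_5S && sp2$big_gaps)
      notes <- c(notes,
                 "large gaps between 23S-5S operon genes; conservatively counted operonic")
  }

  type <- NULL
  if (s16 != s23) {
    type <- "E"
  } else if (is.na(sp1$gap) || (sp1$gap > max_gap && !sp1$chain_ok) ||
             sp1$opp) {
    type <- "D"
    if (is.na(sp1$gap)) notes <- c(notes, "rRNA genes out of canonical order")
    if (sp1$opp) notes <- c(notes, "opposite-strand gene in 16S-23S spacer")
  } else {
    if (sp1$big_gaps)
      notes <- c(notes,
                 "large gaps between 16S-23S operon genes; conservatively counted operonic")
    ck <- c(content_kinds(sp1),
            if (!is.null(sp2) && !unlinked_5S) content_kinds(sp2))
    if (!length(ck)) type <- "A"
    else if (all(ck == "tRNA")) type <- "B"
    else type <- "C"
  }

  structure(list(type = type,
                 d_16S_23S = min_arc(i16, i23),
                 d_23S_5S = min_arc(i23, i5),
                 spacer_16S_23S = content_kinds(sp1),
                 spacer_23S_5S = if (!is.null(sp2)) content_kinds(sp2) else
                   character(),
                 unlinked_23S_5S = unlinked_5S,
                 notes = notes),
            class = "operon_call")
}

#' @export
print.operon_call <- function(x, ...) {
  cat(sprintf("operon_call: type %s (d(16S,23S)=%d nt, d(23S,5S)=%d nt%s)\n",
              x$type, x$d_16S_23S, x$d_23S_5S,
              if (x$unlinked_23S_5S) ", 23S-5S unlinked" else ""))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tally operon types and the unlinked fraction
#'
#' @param calls a list of [classify_rrna_linkage()] results
#' @return a list with `counts` (named A-E), `n`, and `fraction_unlinked`
#'   (types D or E for the 16S-23S relation)
#' @export
summarize_linkage <- function(calls) {
  if (!length(calls)) stop("no operon calls to summarise", call. = FALSE)
  types <- vapply(calls, function(x) x$type, character(1))
  tab <- table(factor(types, levels = c("A", "B", "C", "D", "E")))
  counts <- setNames(as.integer(tab), names(tab))
  structure(list(counts = counts, n = length(types),
                 fraction_unlinked = sum(types %in% c("D", "E")) /
                   length(types)),
            class = "linkage_summary")
}

#' @export
print.linkage_summary <- function(x, ...) {
  cat("linkage_summary:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                                collapse = " "),
      sprintf(" unlinked fraction %.3f (n=%d)\n", x$fraction_unlinked, x$n))
  invisible(x)
}
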