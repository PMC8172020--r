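#' Extension parameters
#'
#' Parameters of the read-coherent extension/merging surrogate assembler.
#'
#' @param min_overlap exact suffix/prefix match length (nt, at least 20)
#'   required both for a read to vote at a contig end and for two contigs to
#'   be fused
#' @param min_support independent reads (at least 2) that must agree on an
#'   extension base.  Two concordant reads behind a `min_overlap`-nt exact
#'   anchor are already a stringent requirement; see the package vignette.
#' @param max_step maximum bases added per contig end per extension round
#' @param max_rounds maximum extend/merge rounds inside [reassemble()]
#' @param self_overlap_cap once a contig's terminal self-overlap reaches this
#'   many nt (a closed circle), its ends are no longer extended
#' @return a list of class `extension_params`
#' @export
extension_params <- function(min_overlap = 40L, min_support = 2L,
                             max_step = 5000L, max_rounds = 20L,
                             self_overlap_cap = 1000L) {
  min_overlap <- as.integer(min_overlap)
  min_support <- as.integer(min_support)
  if (min_overlap < 20L) stop("min_overlap must be >= 20", call. = FALSE)
  if (min_support < 2L) stop("min_support must be >= 2", call. = FALSE)
  structure(list(min_overlap = min_overlap, min_support = min_support,
                 max_step = as.integer(max_step),
                 max_rounds = as.integer(max_rounds),
                 self_overlap_cap = as.integer(self_overlap_cap)),
            class = "extension_params")
}

#' Extend the 3' end of a contig by read consensus
#'
#' Grows the end base by base.  A read votes while it aligns exactly against
#' the trailing `min_overlap` window of the growing sequence (both read
#' orientations are considered; a mismatching vote suspends a read until the
#' mismatch leaves the window).  Extension stops at `max_step`, when fewer
#' than `min_support` reads support the best base, at an exact tie, or at a
#' balanced conflict — a runner-up base carried by at least `min_support`
#' reads and by more than a quarter of the winner's support.  The balanced-
#' conflict stop is what makes extension halt at the exit of a repeat longer
#' than the read span, where two genomic contexts vote against each other,
#' while isolated sequencing errors (rare and dispersed) do not halt it.
#' Existing contig bases are never edited.
#'
#' @param contig a single sequence (character)
#' @param reads character vector of reads
#' @param params an [extension_params()] object
#' @return the extension string for the 3' end ("" when no read qualifies)
#' @export
extend_end <- function(contig, reads, params = extension_params()) {
  stopifnot(is.character(contig), length(contig) == 1L)
  if (!length(reads)) return("")
  extend_end_cpp(contig, reads, params$min_overlap, params$min_support,
                 params$max_step)
}

#' Merge contigs on exact end overlaps
#'
#' While two contigs (in either orientation) share an exact end overlap of
#' at least `min_overlap` nt, they are fused into a sequence of length
#' `len(a) + len(b) - overlap`; longest overlap first, ties broken on contig
#' ids.  A fusion is only performed when it is unambiguous: each
#' participating end must have exactly one overlap partner (a contig end
#' that matches several others — e.g. two contigs terminating in the same
#' long repeat — is left unmerged rather than joined arbitrarily).
#'
#' @param contigs named character vector (or DNAStringSet) of contigs
#' @param min_overlap minimum exact overlap (nt)
#' @return named character vector of merged contigs, sorted by id; a fused
#'   contig takes the lexicographically smaller of its parents' ids
#' @export
merge_contigs <- function(contigs, min_overlap = 40L) {
  contigs <- as_contig_vector(contigs)
  if (length(contigs) < 2L) return(contigs)
  merge_contigs_cpp(contigs, as.integer(min_overlap))
}

#' Reassemble seed contigs from a read pool
#'
#' The built-in surrogate for an external overlap-consensus reassembly
#' stage: alternates [extend_end()] (both ends, both orientations) and
#' [merge_contigs()] until a fixpoint or `max_rounds`, then deduplicates
#' (no output contig is a substring of another, in either orientation).
#' Deterministic: no randomness, fixed tie rules.
#'
#' @param reads character vector of reads, or a [read_pairs] object (both
#'   mates are used)
#' @param seed_contigs named character vector or DNAStringSet
#' @param params an [extension_params()] object
#' @return named character vector of contigs
#' @export
reassemble <- function(reads, seed_contigs, params = extension_params()) {
  if (inherits(reads, "read_pairs")) reads <- c(reads$seq1, reads$seq2)
  seed_contigs <- as_contig_vector(seed_contigs)
  if (!length(seed_contigs)) return(seed_contigs)
  reassemble_cpp(seed_contigs, reads, params$min_overlap, params$min_support,
                 params$max_step, params$max_rounds, params$self_overlap_cap)
}

#' Run an external assembler through a command template
#'
#' Adapter so a real overlap-consensus assembler can replace the built-in
#' surrogate.  The template must contain the placeholders `{reads}`,
#' `{seeds}` and `{output}`; stdout/stderr are captured to `assembler.log`
#' in `workdir`.
#'
#' @details Typical templates wrap the assembler invocation in a small
#' shell pipeline ending with a copy of its contig FASTA to `{output}`.
#' For a MIRA-style manifest-driven run the template generates the
#' manifest (reads = `{reads}`, backbone = `{seeds}`, with the
#' conservative settings `-NW:cac=warn -CO:fnic=yes -AS:nop=6:sdlpo=no
#' -KS:fenn=0.3`) and copies `*_out.unpadded.fasta` to `{output}`; for
#' SPAdes:
#' `spades.py --12 {reads} --trusted-contigs {seeds} -o spades_out &&
#' cp spades_out/contigs.fasta {output}`.
#'
#' @param reads_path FASTQ of reads
#' @param seeds_path FASTA of seed contigs
#' @param command_template shell command with `{reads}`, `{seeds}`,
#'   `{output}` placeholders
#' @param workdir working directory (created if needed)
#' @return path to the output contig FASTA
#' @export
external_assembler <- function(reads_path, seeds_path, command_template,
                               workdir = tempfile("assembler")) {
  for (ph in c("{reads}", "{seeds}", "{output}")) {
    if (!grepl(ph, command_template, fixed = TRUE))
      stop("command_template lacks placeholder ", ph, call. = FALSE)
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  out_path <- file.path(workdir, "contigs.fasta")
  log_path <- file.path(workdir, "assembler.log")
  cmd <- command_template
  cmd <- gsub("{reads}", shQuote(reads_path), cmd, fixed = TRUE)
  cmd <- gsub("{seeds}", shQuote(seeds_path), cmd, fixed = TRUE)
  cmd <- gsub("{output}", shQuote(out_path), cmd, fixed = TRUE)
  status <- suppressWarnings(
    system(paste0("(", cmd, ") > ", shQuote(log_path), " 2>&1")))
  log_tail <- if (file.exists(log_path))
    paste(utils::tail(readLines(log_path, warn = FALSE), 10), collapse = "\n")
  else ""
  if (status != 0L)
    stop("external assembler failed (exit ", status, "):\n", log_tail,
         call. = FALSE)
  if (!file.exists(out_path) || file.size(out_path) == 0L)
    stop("external assembler produced no output FASTA:\n", log_tail,
         call. = FALSE)
  out_path
}
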