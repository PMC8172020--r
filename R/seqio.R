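#' @title Sequence and annotation input/output
#' @description Readers and writers for the formats the pipeline touches:
#'   FASTA contigs (optionally with coverage in the header), paired FASTQ
#'   (interleaved or split, plain or gzipped), Infernal `cmsearch --tblout`
#'   hits, tRNAscan-SE tabular output and GFF3 feature tables.  All parsers
#'   normalise to a five-letter alphabet (A, C, G, T, N; U is mapped to T)
#'   and to the 1-based closed coordinates of [GenomicRanges::GRanges].
#' @name seqio
NULL

.validate_dna <- function(seqs, ids, context = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- sub(".*?([^ACGTN]).*", "\\1", seqs[i])
    stop(sprintf("%s '%s' contains invalid character '%s' (alphabet is A,C,G,T,N)",
                 context, ids[i], ch), call. = FALSE)
  }
  invisible(TRUE)
}

.normalize_dna <- function(seqs) chartr("u", "T", chartr("U", "T", toupper(seqs)))

#' Read a FASTA file of contigs
#'
#' Sequences are uppercased, U is mapped to T, and any character outside
#' A/C/G/T/N is an error.  If a header carries a token of the form
#' `cov=<number>` or a trailing `_cov_<number>` (SPAdes style), it is parsed
#' into a `coverage` metadata column.
#'
#' @param path path to a FASTA file (may be gzipped)
#' @return a [Biostrings::DNAStringSet]; names are the first whitespace-token
#'   of each header and must be unique; `mcols()$coverage` holds per-contig
#'   mean depth (NA when absent)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("malformed FASTA in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  headers <- names(x)
  if (length(x) && (is.null(headers) || any(!nzchar(headers))))
    stop("malformed FASTA in '", path, "': record with empty header",
         call. = FALSE)
  ids <- sub("\\s.*$", "", headers)
  seqs <- .normalize_dna(as.character(x))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1L]],
         "' in '", path, "'", call. = FALSE)
  }
  .validate_dna(seqs, ids, "FASTA record")
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[duplicated(ids)][1L], "' in '", path,
         "'", call. = FALSE)
  cov <- rep(NA_real_, length(ids))
  m <- regmatches(headers, regexpr("cov[=_]([0-9.]+)", headers))
  has <- grepl("cov[=_][0-9.]+", headers)
  cov[has] <- as.numeric(sub("cov[=_]", "", m))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$coverage <- cov
  out
}

#' Write contigs to FASTA
#'
#' @param x a named character vector or [Biostrings::DNAStringSet]
#' @param path output path
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named", call. = FALSE)
    x <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Construct a collection of read pairs
#'
#' A plain container for mated reads: parallel character vectors for the two
#' mates plus optional per-base quality strings.
#'
#' @param id character vector of pair ids
#' @param seq1,seq2 mate sequences (A/C/G/T/N)
#' @param qual1,qual2 optional quality strings, same lengths as the mates
#' @return an object of class `read_pairs`
#' @export
read_pairs <- function(id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
  id <- as.character(id)
  seq1 <- .normalize_dna(as.character(seq1))
  seq2 <- .normalize_dna(as.character(seq2))
  stopifnot(length(id) == length(seq1), length(seq1) == length(seq2))
  .validate_dna(seq1, id, "read")
  .validate_dna(seq2, id, "read")
  if (!is.null(qual1) && any(nchar(qual1) != nchar(seq1)))
    stop("quality string length differs from sequence length (mate 1)",
         call. = FALSE)
  if (!is.null(qual2) && any(nchar(qual2) != nchar(seq2)))
    stop("quality string length differs from sequence length (mate 2)",
         call. = FALSE)
  structure(list(id = id, seq1 = seq1, seq2 = seq2,
                 qual1 = qual1, qual2 = qual2),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
`[.read_pairs` <- function(x, i) {
  read_pairs(x$id[i], x$seq1[i], x$seq2[i],
             if (!is.null(x$qual1)) x$qual1[i],
             if (!is.null(x$qual2)) x$qual2[i])
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs%s\n", length(x),
              if (is.null(x$qual1)) " (no qualities)" else ""))
  invisible(x)
}

.read_fastq_one <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = sub("\\s.*$", "", names(x)),
       seq = .normalize_dna(as.character(x)),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Read paired-end FASTQ
#'
#' Supports an interleaved file (mates at records 2i-1, 2i) or split R1/R2
#' files; plain or gzip.  Interleaved pairing is positional, not name based.
#'
#' @param path1 interleaved FASTQ, or the R1 file when `path2` is given
#' @param path2 optional R2 file
#' @return a [read_pairs] object preserving input order
#' @export
read_paired_fastq <- function(path1, path2 = NULL) {
  a <- .read_fastq_one(path1)
  if (is.null(path2)) {
    n <- length(a$id)
    if (n %% 2L != 0L)
      stop(sprintf("interleaved FASTQ '%s' has an odd record count (%d)",
                   path1, n), call. = FALSE)
    i1 <- seq(1L, n, by = 2L); i2 <- seq(2L, n, by = 2L)
    read_pairs(a$id[i1], a$seq[i1], a$seq[i2], a$qual[i1], a$qual[i2])
  } else {
    b <- .read_fastq_one(path2)
    if (length(a$id) != length(b$id))
      stop(sprintf("mate-count mismatch: '%s' has %d records, '%s' has %d",
                   path1, length(a$id), path2, length(b$id)), call. = FALSE)
    read_pairs(a$id, a$seq, b$seq, a$qual, b$qual)
  }
}

#' Write read pairs as interleaved FASTQ
#'
#' @param pairs a [read_pairs] object
#' @param path output path (`.gz` suffix gzips)
#' @return `path`, invisibly
#' @export
write_interleaved_fastq <- function(pairs, path) {
  n <- length(pairs)
  q1 <- pairs$qual1
  q2 <- pairs$qual2
  if (is.null(q1)) q1 <- vapply(nchar(pairs$seq1), function(l)
    strrep("I", l), character(1))
  if (is.null(q2)) q2 <- vapply(nchar(pairs$seq2), function(l)
    strrep("I", l), character(1))
  lines <- character(8L * n)
  if (n) {
    idx <- seq_len(n)
    lines[8 * idx - 7] <- paste0("@", pairs$id, "/1")
    lines[8 * idx - 6] <- pairs$seq1
    lines[8 * idx - 5] <- "+"
    lines[8 * idx - 4] <- q1
    lines[8 * idx - 3] <- paste0("@", pairs$id, "/2")
    lines[8 * idx - 2] <- pairs$seq2
    lines[8 * idx - 1] <- "+"
    lines[8 * idx] <- q2
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Reverse complement
#'
#' Standard complement over A/C/G/T with N self-complementary; vectorised.
#'
#' @param seq character vector of sequences
#' @return reverse-complemented sequences
#' @export
reverse_complement <- function(seq) {
  .validate_dna(seq, if (is.null(names(seq))) seq_along(seq) else names(seq))
  rc_cpp(seq)
}

# -- feature tables ----------------------------------------------------------

.feature_kinds <- c("rRNA_16S", "rRNA_23S", "rRNA_5S", "tRNA", "RNaseP",
                    "CDS", "other")

#' Build a feature table
#'
#' A feature table is a [GenomicRanges::GRanges] whose `kind` metadata column
#' takes values in `rRNA_16S`, `rRNA_23S`, `rRNA_5S`, `tRNA`, `RNaseP`,
#' `CDS`, `other`.  Coordinates are 1-based closed (the GRanges convention);
#' parsers convert external conventions at the boundary.
#'
#' @param contig_id,start,end,strand,kind parallel vectors (start/end 1-based
#'   closed, strand "+" or "-")
#' @param contig_lengths optional named vector of contig lengths, attached as
#'   `seqlengths`
#' @param ... further metadata columns (e.g. `isotype`, `score`, `model`)
#' @return a `GRanges` feature table
#' @export
feature_table <- function(contig_id, start, end, strand, kind,
                          contig_lengths = NULL, ...) {
  if (!all(kind %in% .feature_kinds))
    stop("unknown feature kind: ",
         paste(setdiff(kind, .feature_kinds), collapse = ", "), call. = FALSE)
  if (any(start > end)) stop("feature with start > end", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = contig_id,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand)
  S4Vectors::mcols(gr)$kind <- kind
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  if (!is.null(contig_lengths)) {
    missing_ctg <- setdiff(as.character(GenomeInfoDb::seqnames(gr)),
                           names(contig_lengths))
    if (length(missing_ctg))
      stop("feature on contig absent from contig_lengths: ",
           missing_ctg[1L], call. = FALSE)
    if (any(GenomicRanges::end(gr) >
            contig_lengths[as.character(GenomeInfoDb::seqnames(gr))]))
      stop("feature extends past its contig end", call. = FALSE)
    GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(gr) <- as.integer(contig_lengths)
  }
  gr
}

.model_to_kind <- function(query, accession = "") {
  key <- paste(query, accession)
  first_match <- function(pats, kinds) {
    out <- rep("other", length(key))
    for (i in seq_along(pats)) {
      hit <- grepl(pats[i], key, ignore.case = TRUE) & out == "other"
      out[hit] <- kinds[i]
    }
    out
  }
  first_match(
    c("RF00010|RNase_?P", "RF00001|\\b5S", "RF00177|SSU|16S",
      "RF02541|LSU|23S", "RF00005|tRNA"),
    c("RNaseP", "rRNA_5S", "rRNA_16S", "rRNA_23S", "tRNA"))
}

#' Parse Infernal cmsearch --tblout output
#'
#' One feature per hit row.  Hit coordinates (1-based closed, `seq from` >
#' `seq to` on the minus strand) are normalised to ordered 1-based closed
#' ranges with an explicit strand.  The covariance-model name/accession is
#' mapped to a feature kind (RF00010 -> RNaseP, RF00001 -> 5S rRNA, SSU/LSU
#' models -> 16S/23S); the bit score, E-value and model name are kept as
#' metadata.
#'
#' @param path a `--tblout` file
#' @param contig_lengths optional named contig lengths for the table
#' @return a `GRanges` feature table with columns `kind`, `model`,
#'   `accession`, `score`, `evalue`
#' @export
parse_cmsearch_tblout <- function(path, contig_lengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows))
    return(feature_table(character(), integer(), integer(), character(),
                         character(), contig_lengths = contig_lengths,
                         model = character(), accession = character(),
                         score = numeric(), evalue = numeric()))
  parts <- strsplit(trimws(lines[rows]), "[[:space:]]+")
  n_ok <- lengths(parts) >= 17L
  if (any(!n_ok))
    stop(sprintf("unparseable cmsearch tblout row at line %d of '%s'",
                 rows[which(!n_ok)[1L]], path), call. = FALSE)
  fld <- function(i) vapply(parts, `[[`, character(1), i)
  from <- suppressWarnings(as.integer(fld(8)))
  to <- suppressWarnings(as.integer(fld(9)))
  score <- suppressWarnings(as.numeric(fld(15)))
  evalue <- suppressWarnings(as.numeric(fld(16)))
  bad <- is.na(from) | is.na(to) | is.na(score)
  if (any(bad))
    stop(sprintf("unparseable cmsearch tblout row at line %d of '%s'",
                 rows[which(bad)[1L]], path), call. = FALSE)
  minus <- from > to
  feature_table(
    contig_id = fld(1),
    start = ifelse(minus, to, from),
    end = ifelse(minus, from, to),
    strand = ifelse(minus, "-", "+"),
    kind = .model_to_kind(fld(3), fld(4)),
    contig_lengths = contig_lengths,
    model = fld(3), accession = fld(4), score = score, evalue = evalue)
}

#' Parse tRNAscan-SE tabular output
#'
#' Returns one spanning feature per tRNA with its isotype; an intron, when
#' reported, is recorded in `intron_begin`/`intron_end` metadata but the
#' feature still spans the full locus.
#'
#' @param path tRNAscan-SE output (the default tabular format, with or
#'   without its three header lines)
#' @param contig_lengths optional named contig lengths
#' @return a `GRanges` feature table with columns `kind` (= "tRNA"),
#'   `isotype`, `anticodon`, `score`, `intron_begin`, `intron_end`
#' @export
parse_trnascan <- function(path, contig_lengths = NULL) {
  lines <- readLines(path)
  # drop the standard 3-line header if present
  hdr <- grepl("^(Sequence|Name|-+\\s)", lines) | grepl("^-+$", lines)
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (!length(body))
    return(feature_table(character(), integer(), integer(), character(),
                         character(), contig_lengths = contig_lengths,
                         isotype = character(), anticodon = character(),
                         score = numeric(),
                         intron_begin = integer(), intron_end = integer()))
  parts <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(parts) < 9L))
    stop("tRNAscan row with missing columns (need at least 9, incl. isotype): '",
         body[which(lengths(parts) < 9L)[1L]], "'", call. = FALSE)
  fld <- function(i) vapply(parts, `[[`, character(1), i)
  begin <- suppressWarnings(as.integer(fld(3)))
  end <- suppressWarnings(as.integer(fld(4)))
  if (any(is.na(begin) | is.na(end)))
    stop("unparseable tRNAscan coordinates", call. = FALSE)
  iso <- fld(5)
  if (any(!nzchar(iso)))
    stop("tRNAscan row with missing isotype column", call. = FALSE)
  minus <- begin > end
  feature_table(
    contig_id = fld(1),
    start = ifelse(minus, end, begin),
    end = ifelse(minus, begin, end),
    strand = ifelse(minus, "-", "+"),
    kind = "tRNA",
    contig_lengths = contig_lengths,
    isotype = iso,
    anticodon = fld(6),
    score = suppressWarnings(as.numeric(fld(9))),
    intron_begin = suppressWarnings(as.integer(fld(7))),
    intron_end = suppressWarnings(as.integer(fld(8))))
}

#' Read a feature table from GFF3
#'
#' The GFF3 `type` column is mapped onto the package's feature kinds; `rRNA`
#' and `tRNA` records are refined through their `product`/`isotype`
#' attributes (e.g. `product=tRNA-Trp` yields isotype `Trp`).
#'
#' @param path GFF3 file
#' @return a `GRanges` feature table
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  md <- S4Vectors::mcols(gr)
  prod <- if ("product" %in% names(md)) as.character(md$product) else
    rep(NA_character_, length(gr))
  kind <- ifelse(ty %in% .feature_kinds, ty, "other")
  is_rrna <- ty == "rRNA"
  kind[is_rrna & grepl("16S", prod)] <- "rRNA_16S"
  kind[is_rrna & grepl("23S", prod)] <- "rRNA_23S"
  kind[is_rrna & grepl("5S", prod)] <- "rRNA_5S"
  kind[ty == "tRNA"] <- "tRNA"
  kind[grepl("RNase_?P", ty, ignore.case = TRUE) |
         grepl("RNase_?P", prod, ignore.case = TRUE)] <- "RNaseP"
  kind[ty == "CDS"] <- "CDS"
  S4Vectors::mcols(gr)$kind <- kind
  iso <- if ("isotype" %in% names(md)) as.character(md$isotype) else
    rep(NA_character_, length(gr))
  need <- kind == "tRNA" & is.na(iso) & !is.na(prod) & grepl("^tRNA-", prod)
  iso[need] <- sub("^tRNA-", "", prod[need])
  S4Vectors::mcols(gr)$isotype <- iso
  gr
}

#' Write a feature table to GFF3
#'
#' @param features a `GRanges` feature table (with a `kind` column)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_features_gff3 <- function(features, path) {
  gr <- features
  S4Vectors::mcols(gr)$type <- S4Vectors::mcols(gr)$kind
  S4Vectors::mcols(gr)$phase <- ifelse(S4Vectors::mcols(gr)$kind == "CDS",
                                       0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert between 1-based closed and 0-based half-open coordinates
#'
#' External tabular formats (GFF3, cmsearch tblout, tRNAscan) report 1-based
#' closed intervals; some downstream tools want 0-based half-open.  These two
#' helpers are exact inverses.
#'
#' @param start,end interval bounds
#' @return a list with converted `start` and `end`
#' @export
coords_to_0based <- function(start, end) list(start = start - 1L, end = end)

#' @rdname coords_to_0based
#' @export
coords_to_1based <- function(start, end) list(start = start + 1L, end = end)
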