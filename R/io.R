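#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' `DNAStringSet`.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet-class] object.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `DNAStringSet` or named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(as_seq_chr(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a GFF3 file into a tibble
#'
#' Features are returned with 0-based half-open coordinates (`start`,
#' `end`), the internal convention of this package; the GFF3 file itself
#' is 1-based inclusive. Attribute columns parsed by
#' [rtracklayer::readGFF()] are kept.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase` plus any attribute columns.
#' @export
read_gff3 <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff$start <- as.integer(gff$start) - 1L
  gff$end <- as.integer(gff$end)
  for (col in names(gff)) {
    if (is.factor(gff[[col]])) gff[[col]] <- as.character(gff[[col]])
    if (is.list(gff[[col]])) {
      gff[[col]] <- vapply(gff[[col]], function(x) {
        if (length(x) == 0) NA_character_ else paste(x, collapse = ",")
      }, character(1))
    }
  }
  as_tibble(gff)
}

#' Write features to a GFF3 file
#'
#' The input tibble uses 0-based half-open `start`/`end`; coordinates are
#' emitted 1-based inclusive. Columns other than the eight fixed GFF3
#' fields are serialized as `key=value` attributes.
#'
#' @param features Tibble with `seqid`, `type`, `start`, `end` and
#'   optionally `source`, `score`, `strand`, `phase` plus attribute
#'   columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(all(c("seqid", "type", "start", "end") %in% names(features)))
  if (any(features$start >= features$end)) {
    stop("write_gff3: start must be < end (0-based half-open)")
  }
  fixed <- c("seqid", "source", "type", "start", "end", "score", "strand",
             "phase")
  attr_cols <- setdiff(names(features), fixed)
  fmt <- function(col, default) {
    if (col %in% names(features)) {
      x <- as.character(features[[col]])
      x[is.na(x)] <- default
      x
    } else {
      rep(default, nrow(features))
    }
  }
  attrs <- rep("", nrow(features))
  for (col in attr_cols) {
    val <- as.character(features[[col]])
    keep <- !is.na(val)
    piece <- paste0(col, "=", val)
    attrs[keep] <- ifelse(attrs[keep] == "", piece[keep],
                          paste0(attrs[keep], ";", piece[keep]))
  }
  attrs[attrs == ""] <- "."
  lines <- paste(
    fmt("seqid", "."), fmt("source", "panploid"), fmt("type", "."),
    features$start + 1L, features$end, fmt("score", "."),
    fmt("strand", "."), fmt("phase", "."), attrs,
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a BED file into a tibble
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path Path to a BED file (3+ columns).
#' @return Tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed) <- cols[seq_len(ncol(bed))]
  if (any(bed$start >= bed$end)) {
    bad <- which(bed$start >= bed$end)[1]
    stop("read_bed: start >= end on line ", bad)
  }
  as_tibble(bed)
}

#' Write intervals to a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read PAF-like alignment records
#'
#' Accepts the 12 mandatory PAF columns (tab-separated, no header).
#' Alignment identity is computed as residue matches divided by the
#' alignment block length. Coordinates are 0-based half-open as in PAF.
#'
#' @param path Path to a PAF file.
#' @return A tibble of alignment records with columns `query_id`,
#'   `query_len`, `query_start`, `query_end`, `strand`, `target_id`,
#'   `target_len`, `target_start`, `target_end`, `matches`, `block_len`,
#'   `mapq`, `identity`.
#' @export
read_paf <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 12L)
  if (length(bad) > 0) {
    stop("read_paf: fewer than 12 columns on line ", bad[1])
  }
  take <- function(i, as = as.character) as(vapply(fields, `[[`, character(1), i))
  out <- tibble(
    query_id = take(1),
    query_len = take(2, as.integer),
    query_start = take(3, as.integer),
    query_end = take(4, as.integer),
    strand = take(5),
    target_id = take(6),
    target_len = take(7, as.integer),
    target_start = take(8, as.integer),
    target_end = take(9, as.integer),
    matches = take(10, as.integer),
    block_len = take(11, as.integer),
    mapq = take(12, as.integer)
  )
  bad <- which(out$query_end <= out$query_start |
                 out$target_end <= out$target_start)
  if (length(bad) > 0) {
    stop("read_paf: end <= start on line ", bad[1])
  }
  out$identity <- out$matches / out$block_len
  out
}

#' Read/write a genes-by-accessions presence matrix
#'
#' The TSV has a `gene` column followed by one 0/1 column per accession.
#'
#' @param path Path to the TSV file.
#' @return `read_pav_matrix`: a tibble with `gene` plus accession
#'   columns. `write_pav_matrix`: `path`, invisibly.
#' @export
read_pav_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_pav_matrix
#' @param pav Tibble with a `gene` column plus one column per accession.
#' @export
write_pav_matrix <- function(pav, path) {
  readr::write_tsv(pav, path)
  invisible(path)
}
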