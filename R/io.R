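# File formats and sample metadata.
#
# Sequences travel through the package as named character vectors of
# upper-case IUPAC DNA; FASTQ qualities are kept as an attribute but are not
# used by the screen. All coordinates in the package are 1-based inclusive.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

.check_dna <- function(seqs, where = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad)) {
    stop(sprintf("non-IUPAC characters in %s: %s", where,
                 paste(utils::head(names(seqs)[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seqs)
}

#' Read a FASTA file
#'
#' Returns the records as a named character vector of upper-case sequences,
#' in file order. Non-IUPAC characters are rejected, never silently dropped.
#'
#' @param path path to a FASTA file (gzip accepted).
#' @return named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  .check_dna(seqs, where = path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path (".gz" suffix triggers gzip compression).
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads all records, returning a named character vector of upper-case reads
#' with per-read quality strings attached as the \code{"quality"} attribute.
#' For constant-memory consumption of large files use [fastq_apply()].
#'
#' @param path FASTQ file, optionally gzipped.
#' @return named character vector with a \code{"quality"} attribute.
#' @export
read_fastq <- function(path) {
  acc <- list()
  fastq_apply(path, function(chunk) acc[[length(acc) + 1L]] <<- chunk)
  if (length(acc) == 0L) {
    warning("empty FASTQ file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  reads <- unlist(acc, use.names = TRUE)
  attr(reads, "quality") <- unlist(lapply(acc, attr, "quality"),
                                   use.names = FALSE)
  reads
}

#' Stream a FASTQ file in bounded-size chunks
#'
#' Applies \code{fun} to successive chunks of reads so that no more than
#' \code{chunk_size} records are held in memory at a time. Each chunk is a
#' named character vector of upper-case sequences with a \code{"quality"}
#' attribute. Malformed records (quality/sequence length mismatch, truncated
#' final record, bad separators) raise an error naming the record index.
#'
#' @param path FASTQ file, optionally gzipped.
#' @param fun function called on each chunk; return values are discarded.
#' @param chunk_size records per chunk.
#' @return number of records processed, invisibly.
#' @export
fastq_apply <- function(path, fun, chunk_size = 50000L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  n_done <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      stop(sprintf("truncated FASTQ record at record %d in %s",
                   n_done + length(lines) %/% 4L + 1L, path), call. = FALSE)
    }
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- toupper(lines[idx + 1L])
    sep <- lines[idx + 2L]
    qual <- lines[idx + 3L]
    bad_hdr <- !startsWith(hdr, "@") | !startsWith(sep, "+")
    if (any(bad_hdr)) {
      stop(sprintf("malformed FASTQ record %d in %s",
                   n_done + which(bad_hdr)[1L], path), call. = FALSE)
    }
    len_bad <- nchar(seqs) != nchar(qual)
    if (any(len_bad)) {
      stop(sprintf("sequence/quality length mismatch at record %d in %s",
                   n_done + which(len_bad)[1L], path), call. = FALSE)
    }
    chunk <- setNames(seqs, sub("^@", "", sub("\\s.*$", "", hdr)))
    attr(chunk, "quality") <- qual
    fun(chunk)
    n_done <- n_done + length(seqs)
  }
  invisible(n_done)
}

#' Write reads to FASTQ
#'
#' @param reads named character vector; a \code{"quality"} attribute is used
#'   when present, otherwise a constant quality of "I" is written.
#' @param path output path (".gz" suffix triggers gzip compression).
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- attr(reads, "quality")
  if (is.null(qual)) qual <- vapply(nchar(reads), function(n)
    strrep("I", n), character(1))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Construct annotation
#'
#' Describes the transformation construct: total length, the 1-based
#' inclusive T-DNA interval, and named features (e.g. the HPT selection
#' marker and Cas9) as 1-based inclusive intervals.
#'
#' @param construct_id identifier of the construct sequence.
#' @param length construct length in bp.
#' @param tdna_start,tdna_end 1-based inclusive T-DNA interval.
#' @param features data.frame with columns \code{name}, \code{start},
#'   \code{end} (and optionally \code{strand}); may be empty.
#' @return object of class \code{construct_annotation}.
#' @export
construct_annotation <- function(construct_id, length, tdna_start = 1L,
                                 tdna_end,
                                 features = data.frame(name = character(0),
                                                       start = integer(0),
                                                       end = integer(0))) {
  stopifnot(length >= 1, tdna_start >= 1, tdna_start <= tdna_end,
            tdna_end <= length)
  features <- as.data.frame(features)
  if (nrow(features)) {
    if (any(features$start < 1 | features$end > length |
              features$start > features$end)) {
      stop("feature interval outside [1, length]", call. = FALSE)
    }
  }
  structure(list(construct_id = construct_id, length = as.integer(length),
                 tdna_start = as.integer(tdna_start),
                 tdna_end = as.integer(tdna_end), features = features),
            class = "construct_annotation")
}

#' @export
print.construct_annotation <- function(x, ...) {
  cat(sprintf("Construct %s: %s bp, T-DNA %d-%d bp, %d feature(s)\n",
              x$construct_id, format(x$length, big.mark = ","),
              x$tdna_start, x$tdna_end, nrow(x$features)))
  if (nrow(x$features)) {
    for (i in seq_len(nrow(x$features)))
      cat(sprintf("  %-8s %6d-%6d\n", x$features$name[i],
                  x$features$start[i], x$features$end[i]))
  }
  invisible(x)
}

#' Read a 4-column feature table (name, start, end, strand)
#'
#' @param path TSV file with a header line.
#' @return data.frame with columns name, start, end (strand kept if present).
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("feature table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{role}
#' (negative_control / positive_control / query), \code{generation} and
#' \code{read_paths} (semicolon-separated). A screening run requires exactly
#' one negative control and unique sample ids.
#'
#' @param path TSV file.
#' @return data.frame; \code{read_paths} is a list-column of path vectors.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "generation", "read_paths")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  }
  roles <- c("negative_control", "positive_control", "query")
  if (!all(df$role %in% roles)) {
    stop("role must be one of: ", paste(roles, collapse = ", "), call. = FALSE)
  }
  if (sum(df$role == "negative_control") != 1L) {
    stop("a screening run needs exactly one negative_control sample",
         call. = FALSE)
  }
  df$read_paths <- strsplit(df$read_paths, ";", fixed = TRUE)
  df
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return reverse complements.
#' @export
rev_comp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}
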