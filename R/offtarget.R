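# Exhaustive off-target site scanning.
#
# Every genomic window on either strand whose 3-nt PAM window matches the
# IUPAC PAM pattern and whose 20-nt protospacer window lies within a Hamming
# distance bound of the guide is reported. Mismatches are counted over the
# protospacer only; the PAM must match its pattern (N matches anything).

#' Guide site (protospacer + PAM)
#'
#' @param protospacer 20-nt DNA string (the genomic target of the guide).
#' @param pam_pattern IUPAC PAM pattern, default "NGG" (SpCas9).
#' @return object of class \code{guide_site} with \code{protospacer},
#'   \code{pam_pattern} and \code{combined_query}.
#' @export
guide_site <- function(protospacer, pam_pattern = "NGG") {
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (nchar(protospacer) != 20L) {
    stop("protospacer must be 20 nt", call. = FALSE)
  }
  if (nchar(pam_pattern) != 3L) stop("PAM pattern must be 3 nt", call. = FALSE)
  if (grepl("[^ACGT]", protospacer)) {
    stop("protospacer must be unambiguous ACGT", call. = FALSE)
  }
  .check_dna(setNames(pam_pattern, "pam"), "PAM pattern")
  structure(list(protospacer = protospacer, pam_pattern = pam_pattern,
                 combined_query = paste0(protospacer, pam_pattern)),
            class = "guide_site")
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("Guide site: 5'-%s %s-3' (protospacer + PAM)\n",
              x$protospacer, x$pam_pattern))
  invisible(x)
}

#' Find candidate off-target sites in a genome
#'
#' Exhaustive scan of both strands: reports every position where the 3-nt
#' window downstream of a 20-nt window matches the PAM pattern under IUPAC
#' rules and the 20-nt window is within \code{max_mismatches} of the
#' protospacer. Ambiguity codes in the genome count as mismatches unless the
#' guide base is contained in the code's set. Perfect matches are flagged
#' \code{on_target}. PAM-less matches are not reported.
#'
#' @param genome named character vector of sequences (e.g. [read_fasta()]).
#' @param guide a [guide_site()].
#' @param max_mismatches maximum protospacer mismatches (default 3).
#' @return data.frame of class \code{offtarget_hits} with columns seq_id,
#'   start, end (1-based inclusive protospacer interval on the plus strand),
#'   strand, mismatches, site_sequence (strand-oriented protospacer+PAM) and
#'   on_target; sorted by (seq_id, start, strand).
#' @export
find_offtarget_sites <- function(genome, guide, max_mismatches = 3L) {
  stopifnot(inherits(guide, "guide_site"), max_mismatches >= 0L)
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  ids <- names(genome)
  if (is.null(ids)) ids <- paste0("seq", seq_along(genome))
  min_len <- nchar(guide$protospacer) + nchar(guide$pam_pattern)
  too_short <- nchar(genome) < min_len
  if (any(too_short)) {
    warning(sprintf("skipping %d record(s) shorter than %d nt",
                    sum(too_short), min_len), call. = FALSE)
  }
  hits <- cpp_scan_offtargets(toupper(unname(genome)), ids,
                              guide$protospacer, guide$pam_pattern,
                              as.integer(max_mismatches))
  hits <- hits[order(hits$seq_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("offtarget_hits", "data.frame")
  hits
}

#' Tabulate off-target hits with flanking context
#'
#' Produces a per-hit report (with +/-200 bp flanking context for primer
#' design when the genome is supplied) and a per-sequence tally.
#'
#' @param hits a [find_offtarget_sites()] result.
#' @param genome optional named character vector used to extract flanks.
#' @param flank flank width in bp (default 200).
#' @return list with data.frames \code{sites} (one row per distinct
#'   (seq_id, start, strand)) and \code{tally} (hits per sequence).
#' @export
site_report <- function(hits, genome = NULL, flank = 200L) {
  hits <- as.data.frame(hits)
  hits <- hits[!duplicated(hits[c("seq_id", "start", "strand")]), ,
               drop = FALSE]
  if (nrow(hits) && !is.null(genome)) {
    lo <- pmax(1L, hits$start - flank)
    hi <- pmin(nchar(genome[hits$seq_id]), hits$end + 3L + flank)
    hits$context <- substring(genome[hits$seq_id], lo, hi)
  } else {
    hits$context <- character(nrow(hits))
  }
  tally <- if (nrow(hits)) {
    as.data.frame(table(seq_id = hits$seq_id), stringsAsFactors = FALSE,
                  responseName = "n_sites")
  } else {
    data.frame(seq_id = character(0), n_sites = integer(0))
  }
  rownames(hits) <- NULL
  list(sites = hits, tally = tally)
}
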