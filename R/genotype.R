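# Target-site genotyping from resolved amplicon sequences.
#
# Alleles arrive as per-allele sequences (cloned amplicons or manually
# resolved Sanger traces); mixed chromatograms are not deconvolved. Each
# allele is globally aligned to the reference with affine gap scoring, the
# edits are merged and left-aligned (VCF convention), and the allele set is
# classified into wild type / homozygous / heterozygous / biallelic /
# mosaic.

#' Expected SpCas9 cut site
#'
#' Locates the protospacer (on either strand, required to occur exactly
#' once) and returns the blunt-cut position 3 bp 5' of the PAM, i.e. between
#' protospacer bases 17 and 18. The cut is reported as the plus-strand
#' coordinate \code{cut} such that the break falls between \code{cut} and
#' \code{cut + 1}.
#'
#' @param ref reference amplicon sequence (single string).
#' @param guide a [guide_site()].
#' @return list with \code{cut}, \code{strand} and \code{start} (protospacer
#'   start on the plus strand).
#' @export
expected_cut_site <- function(ref, guide) {
  stopifnot(inherits(guide, "guide_site"))
  ref <- toupper(unname(ref[1]))
  fwd <- gregexpr(guide$protospacer, ref, fixed = TRUE)[[1]]
  rev <- gregexpr(rev_comp(guide$protospacer), ref, fixed = TRUE)[[1]]
  fwd <- fwd[fwd > 0]
  rev <- rev[rev > 0]
  n <- length(fwd) + length(rev)
  if (n != 1L) {
    stop(sprintf("protospacer occurs %d times in the reference (need exactly 1)",
                 n), call. = FALSE)
  }
  if (length(fwd) == 1L) {
    list(cut = fwd + 16L, strand = "+", start = as.integer(fwd))
  } else {
    list(cut = rev + 2L, strand = "-", start = as.integer(rev))
  }
}

# columns of the gapped alignment -> run-length edit list
.alignment_edits <- function(aligned_ref, aligned_query) {
  r <- strsplit(aligned_ref, "")[[1]]
  q <- strsplit(aligned_query, "")[[1]]
  op <- ifelse(r == "-", "insertion",
               ifelse(q == "-", "deletion",
                      ifelse(r == q, "match", "mismatch")))
  ref_pos <- cumsum(r != "-")  # 0 before the first ref base
  rl <- rle(op)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  edits <- list()
  for (i in seq_along(rl$values)) {
    o <- rl$values[i]
    if (o == "match") next
    cols <- seq.int(starts[i], ends[i])
    edits[[length(edits) + 1L]] <- list(
      op = o,
      ref_pos = if (o == "insertion") ref_pos[cols[1]] else ref_pos[cols[1]],
      length = length(cols),
      sequence = if (o == "deletion") paste(r[cols], collapse = "")
      else paste(q[cols], collapse = ""))
  }
  edits
}

#' Global alignment of an amplicon to its reference
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap scoring via
#' Biostrings. Defaults (match +2, mismatch -4, gap open -6, gap extend -1)
#' keep a 13-bp deletion as a single gap rather than fragmenting it.
#'
#' @param ref,query DNA strings (ACGT).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; gap
#'   penalties are magnitudes (a gap of length L costs
#'   \code{gap_open + L * gap_extend}).
#' @return object of class \code{amplicon_alignment}: \code{aligned_ref},
#'   \code{aligned_query} (gapped, equal length), \code{score} and
#'   \code{edits} (list of op/ref_pos/length/sequence; insertions anchor to
#'   the reference base before the inserted bases).
#' @export
align_to_reference <- function(ref, query, match = 2, mismatch = -4,
                               gap_open = 6, gap_extend = 1) {
  ref_id <- if (!is.null(names(ref))) names(ref)[1] else "ref"
  query_id <- if (!is.null(names(query))) names(query)[1] else "query"
  ref <- toupper(unname(ref[1]))
  query <- toupper(unname(query[1]))
  if (!nzchar(ref) || !nzchar(query)) {
    stop("empty sequence", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aligned_query <- as.character(Biostrings::alignedPattern(aln))
  aligned_ref <- as.character(Biostrings::alignedSubject(aln))
  structure(list(ref_id = ref_id, query_id = query_id,
                 aligned_ref = aligned_ref, aligned_query = aligned_query,
                 score = Biostrings::score(aln),
                 edits = .alignment_edits(aligned_ref, aligned_query)),
            class = "amplicon_alignment")
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cat(sprintf("Alignment %s vs %s: score %.1f, %d edit(s)\n",
              x$query_id, x$ref_id, x$score, length(x$edits)))
  invisible(x)
}

# shift an indel left through repeat context (VCF-style normalisation)
.left_align_edit <- function(edit, ref) {
  if (edit$op == "deletion") {
    p <- edit$ref_pos
    len <- edit$length
    while (p > 1L && substr(ref, p - 1L, p - 1L) ==
             substr(ref, p + len - 1L, p + len - 1L)) {
      p <- p - 1L
    }
    edit$ref_pos <- p
    edit$sequence <- substr(ref, p, p + len - 1L)
  } else if (edit$op == "insertion") {
    p <- edit$ref_pos
    s <- edit$sequence
    len <- nchar(s)
    while (p >= 1L && p > 0L &&
             substr(ref, p, p) == substr(s, len, len)) {
      s <- paste0(substr(s, len, len), substr(s, 1L, len - 1L))
      p <- p - 1L
    }
    edit$ref_pos <- p
    edit$sequence <- s
  }
  edit
}

.edit_span <- function(e) {
  if (e$op == "insertion") c(e$ref_pos, e$ref_pos)
  else c(e$ref_pos, e$ref_pos + e$length - 1L)
}

#' Call an indel from an amplicon alignment
#'
#' Left-aligns indels in repeat context, merges adjacent edits into
#' clusters, and reports a single call. One cluster with a single edit gives
#' type insertion/deletion/substitution; anything else (multiple clusters or
#' mixed edits) is type \code{complex} with all clusters listed.
#'
#' @param alignment an [align_to_reference()] result.
#' @param cut optional expected cut position (from [expected_cut_site()]);
#'   when given, \code{offset_from_cut} is the signed distance from the cut
#'   to the nearest edited base (0 when the edit touches the cut).
#' @param merge_dist edits closer than this many reference bp are merged
#'   into one cluster.
#' @return object of class \code{indel_call}: \code{type} (none, insertion,
#'   deletion, substitution or complex), \code{length}, \code{sequence},
#'   \code{ref_pos}, \code{offset_from_cut} and \code{clusters}.
#' @export
call_indel <- function(alignment, cut = NULL, merge_dist = 10L) {
  stopifnot(inherits(alignment, "amplicon_alignment"))
  ref <- gsub("-", "", alignment$aligned_ref, fixed = TRUE)
  edits <- lapply(alignment$edits, .left_align_edit, ref = ref)
  if (length(edits) == 0L) {
    out <- list(type = "none", length = 0L, sequence = "",
                ref_pos = NA_integer_, offset_from_cut = NA_integer_,
                clusters = list())
    class(out) <- "indel_call"
    return(out)
  }
  ord <- order(vapply(edits, function(e) e$ref_pos, numeric(1)))
  edits <- edits[ord]
  clusters <- list(edits[1])
  for (e in edits[-1]) {
    last <- clusters[[length(clusters)]]
    last_end <- max(vapply(last, function(x) .edit_span(x)[2], numeric(1)))
    if (e$ref_pos - last_end <= merge_dist) {
      clusters[[length(clusters)]] <- c(last, list(e))
    } else {
      clusters[[length(clusters) + 1L]] <- list(e)
    }
  }
  if (length(clusters) == 1L && length(clusters[[1]]) == 1L) {
    e <- clusters[[1]][[1]]
    type <- switch(e$op, mismatch = "substitution", e$op)
    out <- list(type = type, length = e$length, sequence = e$sequence,
                ref_pos = as.integer(e$ref_pos))
  } else {
    spans <- do.call(rbind, lapply(unlist(clusters, recursive = FALSE),
                                   .edit_span))
    out <- list(type = "complex",
                length = sum(vapply(unlist(clusters, recursive = FALSE),
                                    function(e) e$length, numeric(1))),
                sequence = "", ref_pos = as.integer(min(spans[, 1])))
  }
  out$clusters <- clusters
  out$offset_from_cut <- if (is.null(cut)) NA_integer_ else {
    if (out$type == "insertion") {
      as.integer(out$ref_pos - cut)
    } else {
      span <- c(out$ref_pos, out$ref_pos + max(out$length - 1L, 0L))
      if (span[2] <= cut) as.integer(span[2] - cut)
      else if (span[1] > cut) as.integer(span[1] - cut)
      else 0L
    }
  }
  class(out) <- "indel_call"
  out
}

#' @export
print.indel_call <- function(x, ...) {
  if (x$type == "none") {
    cat("Indel call: none (wild type)\n")
  } else {
    cat(sprintf("Indel call: %s, %d bp%s%s\n", x$type, x$length,
                if (nzchar(x$sequence)) paste0(" [", x$sequence, "]") else "",
                if (!is.na(x$offset_from_cut))
                  sprintf(", offset from cut %+d", x$offset_from_cut) else ""))
  }
  invisible(x)
}

#' Apply a non-complex indel call to a reference sequence
#'
#' Reconstructs the allele sequence implied by an [call_indel()] result;
#' used for round-trip checks and by the amplicon generator.
#'
#' @param ref reference sequence (string).
#' @param call an \code{indel_call} (type none, insertion, deletion or
#'   substitution).
#' @return the edited sequence.
#' @export
apply_indel <- function(ref, call) {
  ref <- toupper(unname(ref[1]))
  switch(call$type,
         none = ref,
         insertion = paste0(substr(ref, 1L, call$ref_pos), call$sequence,
                            substr(ref, call$ref_pos + 1L, nchar(ref))),
         deletion = paste0(substr(ref, 1L, call$ref_pos - 1L),
                           substr(ref, call$ref_pos + call$length,
                                  nchar(ref))),
         substitution = paste0(substr(ref, 1L, call$ref_pos - 1L),
                               call$sequence,
                               substr(ref, call$ref_pos + call$length,
                                      nchar(ref))),
         stop("cannot apply a complex call", call. = FALSE))
}

.allele_key <- function(call) {
  if (call$type == "none") return("WT")
  paste(call$type, call$length, call$sequence, call$ref_pos, sep = ":")
}

#' Classify plant zygosity from an allele set
#'
#' Allele identity is (type, length, sequence, position). With a set of
#' distinct alleles attributed to one plant: all wild type -> wild_type; one
#' non-WT allele and no WT -> homozygous; one non-WT plus WT ->
#' heterozygous; two distinct non-WT -> biallelic; more than two distinct
#' alleles -> mosaic (chimeric).
#'
#' @param plant_id plant label.
#' @param allele_calls list of [call_indel()] results sampled from the
#'   plant.
#' @param counts optional supporting counts, one per call.
#' @return object of class \code{zygosity_call}: \code{plant_id},
#'   \code{genotype}, \code{alleles} (data.frame of distinct alleles with
#'   supporting counts).
#' @export
classify_zygosity <- function(plant_id, allele_calls, counts = NULL) {
  if (length(allele_calls) < 1L) stop("need at least one allele call",
                                      call. = FALSE)
  if (inherits(allele_calls, "indel_call")) allele_calls <- list(allele_calls)
  if (is.null(counts)) counts <- rep(1L, length(allele_calls))
  keys <- vapply(allele_calls, .allele_key, character(1))
  tab <- tapply(counts, keys, sum)
  distinct <- names(tab)
  non_wt <- setdiff(distinct, "WT")
  has_wt <- "WT" %in% distinct
  genotype <- if (length(distinct) > 2L) "mosaic"
  else if (length(non_wt) == 0L) "wild_type"
  else if (length(non_wt) == 1L && !has_wt) "homozygous"
  else if (length(non_wt) == 1L && has_wt) "heterozygous"
  else "biallelic"
  first <- allele_calls[match(distinct, keys)]
  alleles <- data.frame(
    allele = distinct,
    type = vapply(first, function(x) x$type, character(1)),
    length = vapply(first, function(x) as.integer(x$length), integer(1)),
    sequence = vapply(first, function(x) x$sequence, character(1)),
    support = as.integer(tab),
    stringsAsFactors = FALSE)
  rownames(alleles) <- NULL
  structure(list(plant_id = plant_id, genotype = genotype,
                 alleles = alleles),
            class = "zygosity_call")
}

#' @export
print.zygosity_call <- function(x, ...) {
  cat(sprintf("Plant %s: %s (%d distinct allele(s))\n", x$plant_id,
              x$genotype, nrow(x$alleles)))
  print(x$alleles)
  invisible(x)
}

#' Verify candidate off-target sites from amplicon pairs
#'
#' Cut-agnostic mutation check: each sample amplicon is aligned to its
#' site's reference amplicon and a site is clean when no edit is called
#' (substitution calls of at most \code{max_substitutions} total bases are
#' treated as sequencing noise; default 0 tolerates none).
#'
#' @param ref_amplicons,sample_amplicons named character vectors, matched by
#'   position (one pair per candidate site).
#' @param max_substitutions substitution bases tolerated as noise.
#' @return data.frame with columns site, type, length and mutated, plus a
#'   \code{"summary"} attribute like "0/6 mutated".
#' @export
verify_offtarget_amplicons <- function(ref_amplicons, sample_amplicons,
                                       max_substitutions = 0L) {
  if (length(ref_amplicons) != length(sample_amplicons)) {
    stop("need one sample amplicon per reference amplicon", call. = FALSE)
  }
  sites <- names(ref_amplicons)
  if (is.null(sites)) sites <- paste0("site", seq_along(ref_amplicons))
  rows <- lapply(seq_along(ref_amplicons), function(i) {
    call <- call_indel(align_to_reference(ref_amplicons[[i]],
                                          sample_amplicons[[i]]))
    clean <- call$type == "none" ||
      (call$type == "substitution" && call$length <= max_substitutions)
    data.frame(site = sites[i], type = call$type,
               length = as.integer(call$length), mutated = !clean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- sprintf("%d/%d mutated", sum(out$mutated),
                                  nrow(out))
  out
}
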