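# Alignment-free transgene screen.
#
# Reads are decomposed into k-mers (k = 20 by default) and matched against
# the transformation construct in canonical orientation; each match
# increments the construct START position(s) of that k-mer. Per-position
# sample-vs-control enrichment is assessed with an exact conditional
# binomial test, FDR-adjusted with Benjamini-Hochberg, and maximal
# significant runs are called, masked (shared host background /
# low-complexity sequence) and summarised into a transgene call.
#
# The start-position counting convention makes an f-bp residual fragment
# light up exactly f - k + 1 consecutive positions, so a significant run of
# r positions corresponds to a matched length of r + k - 1 bp.

#' Build a k-mer index of a construct
#'
#' Indexes every length-k substring of the construct by its 1-based start
#' position(s). Matching is performed in canonical orientation (a k-mer and
#' its reverse complement are the same key), so reads from either strand hit
#' the same positions.
#'
#' @param construct single DNA string (the construct sequence).
#' @param k k-mer length (default 20); must satisfy 8 <= k <= 31 and
#'   k <= nchar(construct).
#' @param construct_id identifier stored with the index.
#' @return object of class \code{kmer_index} with elements \code{k},
#'   \code{construct_id}, \code{sequence} and \code{n_positions}
#'   (= L - k + 1).
#' @export
build_kmer_index <- function(construct, k = 20L, construct_id = NULL) {
  if (is.null(construct_id)) {
    construct_id <- if (!is.null(names(construct))) names(construct)[1]
    else "construct"
  }
  construct <- toupper(unname(construct[1]))
  k <- as.integer(k)
  if (k < 8L || k > 31L) stop("k must be between 8 and 31", call. = FALSE)
  if (nchar(construct) < k) {
    stop("k exceeds the construct length", call. = FALSE)
  }
  structure(list(k = k, construct_id = construct_id, sequence = construct,
                 n_positions = nchar(construct) - k + 1L),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index of %s: k=%d, %s indexed start positions\n",
              x$construct_id, x$k, format(x$n_positions, big.mark = ",")))
  invisible(x)
}

#' Start positions of a k-mer in the indexed construct
#'
#' Looks up the construct start positions of a k-mer, matching in canonical
#' orientation (the reverse complement hits the same positions).
#'
#' @param index a [build_kmer_index()] object.
#' @param kmer length-k DNA string.
#' @return integer vector of 1-based start positions (may be empty).
#' @export
kmer_positions <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  kmer <- toupper(kmer)
  if (nchar(kmer) != index$k) stop("kmer length differs from index k",
                                   call. = FALSE)
  L <- nchar(index$sequence)
  starts <- seq_len(index$n_positions)
  all_kmers <- substring(index$sequence, starts, starts + index$k - 1L)
  sort(unique(c(which(all_kmers == kmer), which(all_kmers == rev_comp(kmer)))))
}

#' Count read k-mers on the construct
#'
#' For every k-mer occurrence in every read (matched in canonical
#' orientation, so a read and its reverse complement produce identical
#' counts), increments all construct start positions stored for that k-mer.
#' K-mers containing non-ACGT characters are skipped and tallied; reads
#' shorter than k are skipped and tallied.
#'
#' @param reads character vector of reads, or a vector of FASTQ file paths
#'   (each existing file is streamed in bounded-size chunks).
#' @param index a [build_kmer_index()] object.
#' @param sample_id label stored with the track.
#' @return object of class \code{position_track} with \code{counts}
#'   (integer, one per construct start position), \code{total_read_kmers},
#'   \code{matched_kmers}, \code{skipped_kmers} and \code{short_reads}.
#' @export
count_read_kmers <- function(reads, index, sample_id = "sample") {
  stopifnot(inherits(index, "kmer_index"))
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  is_files <- all(file.exists(reads)) && all(nchar(reads) < 1000)
  counts <- integer(index$n_positions)
  total <- matched <- skipped <- 0
  short <- 0L
  tally <- function(chunk) {
    res <- cpp_count_kmers(index$sequence, index$k, toupper(chunk))
    counts <<- counts + res$counts
    total <<- total + res$total_read_kmers
    matched <<- matched + res$matched_kmers
    skipped <<- skipped + res$skipped_kmers
    short <<- short + res$short_reads
  }
  if (is_files) {
    for (f in reads) fastq_apply(f, tally)
  } else {
    tally(reads)
  }
  if (short > 0L) {
    message(sprintf("count_read_kmers: skipped %d read(s) shorter than k=%d",
                    short, index$k))
  }
  structure(list(sample_id = sample_id, construct_id = index$construct_id,
                 k = index$k, counts = counts, total_read_kmers = total,
                 matched_kmers = matched, skipped_kmers = skipped,
                 short_reads = short),
            class = "position_track")
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf(paste0("Position count track for %s on %s (k=%d)\n",
                     "  %s read k-mers examined, %s matched;",
                     " mean %.2f counts/position\n"),
              x$sample_id, x$construct_id, x$k,
              format(x$total_read_kmers, big.mark = ","),
              format(x$matched_kmers, big.mark = ","), mean(x$counts)))
  invisible(x)
}

# start positions whose k-mer lies fully inside the T-DNA
.tdna_positions <- function(annotation, k, n_positions) {
  lo <- max(1L, annotation$tdna_start)
  hi <- min(n_positions, annotation$tdna_end - k + 1L)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Region averages of a count track
#'
#' Mean counts per k-mer start position over the T-DNA region, the non-T-DNA
#' (backbone) region, and the whole construct. A start position belongs to
#' the T-DNA when its whole k-mer lies inside the annotated interval.
#'
#' @param track a [count_read_kmers()] track.
#' @param annotation a [construct_annotation()].
#' @return object of class \code{region_averages}: named numeric vector with
#'   elements \code{tdna}, \code{non_tdna} and \code{total}.
#' @export
region_averages <- function(track, annotation) {
  stopifnot(inherits(track, "position_track"),
            inherits(annotation, "construct_annotation"))
  if (!is.null(track$construct_id) &&
        !identical(track$construct_id, annotation$construct_id)) {
    stop("track and annotation refer to different constructs", call. = FALSE)
  }
  n <- length(track$counts)
  tdna <- .tdna_positions(annotation, track$k, n)
  non <- setdiff(seq_len(n), tdna)
  if (length(tdna) == 0L || length(non) == 0L) {
    stop("empty region: cannot average", call. = FALSE)
  }
  out <- c(tdna = mean(track$counts[tdna]),
           non_tdna = mean(track$counts[non]),
           total = mean(track$counts))
  class(out) <- "region_averages"
  out
}

#' @export
print.region_averages <- function(x, digits = 1, ...) {
  cat(sprintf("Average counts/position: T-DNA %.*f, non-T-DNA %.*f, total %.*f\n",
              digits, x[["tdna"]], digits, x[["non_tdna"]],
              digits, x[["total"]]))
  invisible(x)
}

#' Per-position enrichment test against the negative control
#'
#' Exact one-sided conditional test for sample enrichment over the control
#' at each construct position. Given m = c_sample + c_control matches at a
#' position, the p-value is P(X >= c_sample) with X ~ Binomial(m, t) and
#' t = T_s / (T_s + T_c), where T are the samples' total examined read
#' k-mers (depth normalisation). Positions with m = 0 have p = 1.
#'
#' @param sample,control [count_read_kmers()] tracks on the same construct
#'   and k, both with positive totals.
#' @return numeric vector of p-values, one per position.
#' @export
position_test <- function(sample, control) {
  stopifnot(inherits(sample, "position_track"),
            inherits(control, "position_track"))
  if (sample$k != control$k ||
        length(sample$counts) != length(control$counts)) {
    stop("tracks disagree on construct or k", call. = FALSE)
  }
  if (sample$total_read_kmers <= 0 || control$total_read_kmers <= 0) {
    stop("both tracks need a positive total of examined read k-mers",
         call. = FALSE)
  }
  cs <- sample$counts
  m <- cs + control$counts
  t <- sample$total_read_kmers /
    (sample$total_read_kmers + control$total_read_kmers)
  p <- rep(1, length(cs))
  has <- m > 0L
  p[has] <- pbinom(cs[has] - 1L, m[has], t, lower.tail = FALSE)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone in sorted order and capped at 1.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

# Shannon entropy (bits) of the base composition of each k-mer starting at
# the given positions
.local_entropy <- function(construct, positions, k) {
  vapply(positions, function(p) {
    counts <- table(strsplit(substr(construct, p, p + k - 1L), "")[[1]])
    f <- counts / sum(counts)
    -sum(f * log2(f))
  }, numeric(1))
}

#' Call significant runs and mask shared-background runs
#'
#' Finds maximal runs of consecutive positions with q < alpha, then moves a
#' run to the masked set when it looks like shared host background rather
#' than transgene evidence: when more than \code{mask_fraction} of its
#' positions are control-elevated (control count at least
#' max(\code{elev_min}, \code{elev_mult} x the control's genome-wide mean
#' count)), or when the mean Shannon entropy of the local construct k-mers
#' falls below \code{entropy_min} bits (low-complexity sequence such as the
#' C-rich stretch that attracts reads in every sample).
#'
#' @param qvalues FDR-adjusted per-position values; NA marks untestable
#'   positions (no counts in either sample) and is never significant.
#' @param alpha significance level (default 0.01, the screen's 1% threshold).
#' @param k k-mer length used by the screen.
#' @param control the negative-control [count_read_kmers()] track (optional;
#'   without it no control-elevation masking is done).
#' @param construct construct sequence (optional; without it no
#'   low-complexity masking is done).
#' @param elev_min,elev_mult control-elevation threshold parameters.
#' @param mask_fraction fraction of elevated positions above which a run is
#'   masked.
#' @param entropy_min minimum mean local k-mer entropy (bits).
#' @return list with data.frames \code{significant_runs} and
#'   \code{masked_runs}, each with columns start, end, length,
#'   matched_length (= length + k - 1) and, for masked runs, reason.
#' @export
call_runs <- function(qvalues, alpha = 0.01, k = 20L, control = NULL,
                      construct = NULL, elev_min = 3, elev_mult = 5,
                      mask_fraction = 0.5, entropy_min = 1.0) {
  stopifnot(alpha > 0, alpha < 1)
  k <- as.integer(k)
  sig <- !is.na(qvalues) & qvalues < alpha
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), matched_length = integer(0))
  if (!any(sig)) {
    return(list(significant_runs = empty,
                masked_runs = cbind(empty, reason = character(0))))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- data.frame(start = starts[keep], end = ends[keep])
  runs$length <- runs$end - runs$start + 1L
  runs$matched_length <- runs$length + k - 1L

  elev_thr <- if (!is.null(control)) {
    max(elev_min, elev_mult * mean(control$counts))
  } else Inf
  reason <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    pos <- seq.int(runs$start[i], runs$end[i])
    why <- character(0)
    if (!is.null(control)) {
      frac_elev <- mean(control$counts[pos] >= elev_thr)
      if (frac_elev > mask_fraction) why <- c(why, "control_elevated")
    }
    if (!is.null(construct)) {
      ent <- mean(.local_entropy(construct, pos, k))
      if (ent < entropy_min) why <- c(why, "low_complexity")
    }
    reason[i] <- paste(why, collapse = "+")
  }
  masked <- nzchar(reason)
  sig_runs <- runs[!masked, , drop = FALSE]
  masked_runs <- runs[masked, , drop = FALSE]
  masked_runs$reason <- reason[masked]
  rownames(sig_runs) <- rownames(masked_runs) <- NULL
  list(significant_runs = sig_runs, masked_runs = masked_runs)
}

#' Compare a sample track against the negative control
#'
#' Runs the per-position conditional test, adjusts with Benjamini-Hochberg
#' across the testable positions (those with at least one match in either
#' sample; positions with no counts carry no test and get q = NA), and calls
#' significant and masked runs.
#'
#' @param sample,control [count_read_kmers()] tracks.
#' @param construct construct sequence used for low-complexity masking
#'   (defaults to none).
#' @param alpha significance level for runs (default 0.01).
#' @param ... masking parameters passed to [call_runs()].
#' @return object of class \code{screen_comparison}: pvalues, qvalues,
#'   neglog10_fdr, alpha, significant_runs, masked_runs, n_testable.
#' @export
compare_tracks <- function(sample, control, construct = NULL, alpha = 0.01,
                           ...) {
  p <- position_test(sample, control)
  testable <- (sample$counts + control$counts) > 0L
  q <- rep(NA_real_, length(p))
  if (any(testable)) q[testable] <- bh_adjust(p[testable])
  runs <- call_runs(q, alpha = alpha, k = sample$k, control = control,
                    construct = construct, ...)
  structure(list(sample_id = sample$sample_id,
                 control_id = control$sample_id, k = sample$k,
                 alpha = alpha, pvalues = p, qvalues = q,
                 neglog10_fdr = -log10(pmax(q, .Machine$double.xmin)),
                 significant_runs = runs$significant_runs,
                 masked_runs = runs$masked_runs,
                 n_testable = sum(testable)),
            class = "screen_comparison")
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat(sprintf(paste0("Screen comparison %s vs %s (k=%d, alpha=%g):\n",
                     "  %d testable position(s), %d significant run(s),",
                     " %d masked run(s)\n"),
              x$sample_id, x$control_id, x$k, x$alpha, x$n_testable,
              nrow(x$significant_runs), nrow(x$masked_runs)))
  invisible(x)
}

#' Classify transgene status from a screen comparison
#'
#' \code{present} when unmasked significant runs cover more than
#' \code{present_min} of the T-DNA positions; \code{residual_fragments} when
#' unmasked runs exist but all have matched_length <= 2k + fragment_slack;
#' \code{absent} when there is no unmasked significant run; otherwise
#' \code{inconclusive}.
#'
#' @param comparison a [compare_tracks()] object.
#' @param annotation a [construct_annotation()].
#' @param present_min minimum T-DNA coverage fraction for "present".
#' @param fragment_slack slack on the residual-fragment length bound.
#' @return object of class \code{transgene_call} with \code{status} and
#'   \code{evidence} (runs, T-DNA coverage fraction).
#' @export
classify_transgene <- function(comparison, annotation, present_min = 0.5,
                               fragment_slack = 5L) {
  stopifnot(inherits(comparison, "screen_comparison"),
            inherits(annotation, "construct_annotation"))
  k <- comparison$k
  n_pos <- length(comparison$pvalues)
  tdna <- .tdna_positions(annotation, k, n_pos)
  runs <- comparison$significant_runs
  if (nrow(runs) == 0L) {
    status <- "absent"
    coverage <- 0
  } else {
    covered <- unique(unlist(Map(seq.int, runs$start, runs$end)))
    coverage <- length(intersect(covered, tdna)) / length(tdna)
    if (coverage > present_min) {
      status <- "present"
    } else if (all(runs$matched_length <= 2L * k + fragment_slack)) {
      status <- "residual_fragments"
    } else {
      status <- "inconclusive"
    }
  }
  structure(list(status = status,
                 evidence = list(significant_runs = runs,
                                 masked_runs = comparison$masked_runs,
                                 tdna_coverage = coverage)),
            class = "transgene_call")
}

#' @export
print.transgene_call <- function(x, ...) {
  cat(sprintf("Transgene call: %s (T-DNA coverage %.1f%%, %d run(s), %d masked)\n",
              x$status, 100 * x$evidence$tdna_coverage,
              nrow(x$evidence$significant_runs),
              nrow(x$evidence$masked_runs)))
  invisible(x)
}

#' In-silico marker presence (PCR analogue)
#'
#' Declares a named construct feature (e.g. HPT or Cas9) present when its
#' mean count per position exceeds \code{bg_mult} times the sample's
#' non-T-DNA background (floored at \code{min_mean} counts/position).
#'
#' @param track a [count_read_kmers()] track.
#' @param annotation a [construct_annotation()] carrying the feature.
#' @param marker feature name.
#' @param bg_mult background multiple (default 5).
#' @param min_mean floor on the background (counts/position).
#' @return list with \code{present} (logical), \code{mean_count} and
#'   \code{background}.
#' @export
marker_presence <- function(track, annotation, marker, bg_mult = 5,
                            min_mean = 1) {
  stopifnot(inherits(track, "position_track"),
            inherits(annotation, "construct_annotation"))
  f <- annotation$features
  i <- match(marker, f$name)
  if (is.na(i)) stop("unknown feature: ", marker, call. = FALSE)
  k <- track$k
  n <- length(track$counts)
  lo <- f$start[i]
  hi <- min(n, f$end[i] - k + 1L)
  if (hi < lo) stop("feature shorter than k", call. = FALSE)
  mean_count <- mean(track$counts[lo:hi])
  tdna <- .tdna_positions(annotation, k, n)
  bg <- mean(track$counts[setdiff(seq_len(n), tdna)])
  list(present = mean_count > bg_mult * max(bg, min_mean / bg_mult) &&
         mean_count >= min_mean,
       mean_count = mean_count, background = bg)
}

#' Run the whole transgene screen for one sample
#'
#' Counts k-mers for the sample and the negative control, compares them,
#' computes region averages and classifies transgene status.
#'
#' @param sample_reads,control_reads character vectors of reads or FASTQ
#'   paths (see [count_read_kmers()]).
#' @param construct construct sequence (single named or unnamed string).
#' @param annotation a [construct_annotation()].
#' @param k k-mer length (default 20).
#' @param alpha run-calling significance level (default 0.01).
#' @param sample_id,control_id labels.
#' @param ... masking parameters passed on to [call_runs()].
#' @return object of class \code{transgene_screen} bundling the two tracks,
#'   the comparison, per-sample region averages and the transgene call.
#' @export
transgene_screen <- function(sample_reads, control_reads, construct,
                             annotation, k = 20L, alpha = 0.01,
                             sample_id = "sample", control_id = "control",
                             ...) {
  index <- build_kmer_index(construct, k = k,
                            construct_id = annotation$construct_id)
  ts <- count_read_kmers(sample_reads, index, sample_id = sample_id)
  tc <- count_read_kmers(control_reads, index, sample_id = control_id)
  cmp <- compare_tracks(ts, tc, construct = index$sequence, alpha = alpha,
                        ...)
  call <- classify_transgene(cmp, annotation)
  structure(list(sample = ts, control = tc, comparison = cmp, call = call,
                 averages = list(sample = region_averages(ts, annotation),
                                 control = region_averages(tc, annotation)),
                 annotation = annotation),
            class = "transgene_screen")
}

#' @export
print.transgene_screen <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("  %s region averages: ", x$sample$sample_id))
  print(x$averages$sample)
  cat(sprintf("  %s region averages: ", x$control$sample_id))
  print(x$averages$control)
  print(x$call)
  invisible(x)
}

#' @export
summary.transgene_screen <- function(object, ...) {
  list(status = object$call$status,
       tdna_coverage = object$call$evidence$tdna_coverage,
       significant_runs = object$comparison$significant_runs,
       masked_runs = object$comparison$masked_runs,
       averages = object$averages)
}

#' Plot a transgene screen
#'
#' Two stacked panels: per-position k-mer counts for sample and control, and
#' -log10 FDR with the significance threshold.
#'
#' @param x a [transgene_screen()] object.
#' @param ... passed to plot().
#' @export
plot.transgene_screen <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  n <- length(x$sample$counts)
  plot(seq_len(n), x$sample$counts, type = "h", col = "goldenrod",
       xlab = "construct position (bp)", ylab = "k-mer count",
       main = sprintf("%s vs %s", x$sample$sample_id,
                      x$control$sample_id), ...)
  lines(seq_len(n), x$control$counts, type = "h", col = "steelblue")
  abline(v = x$annotation$tdna_end, lty = 3)
  legend("topright", legend = c(x$sample$sample_id, x$control$sample_id),
         col = c("goldenrod", "steelblue"), lty = 1, bty = "n")
  nl <- x$comparison$neglog10_fdr
  nl[is.na(x$comparison$qvalues)] <- 0
  plot(seq_len(n), nl, type = "h", col = "firebrick",
       xlab = "construct position (bp)", ylab = "-log10(FDR)")
  abline(h = -log10(x$comparison$alpha), lty = 2, col = "darkgreen")
  abline(v = x$annotation$tdna_end, lty = 3)
  invisible(x)
}
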