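# Seeded synthetic data with the structure the screen assumes:
# a host genome; a transformation construct whose T-DNA carries a segment
# copied from the host (host-derived promoter analogue, the source of
# shared background counts) and a low-complexity C-rich decoy that is also
# present in variable copy number in every individual's genome (the source
# of the false-positive region seen in all samples); insertion events
# (none, full T-DNA, short fragments); and paired 150-bp reads with
# substitution errors. All generators draw from R's RNG, so set.seed()
# (or the seed arguments) makes every output bit-reproducible.

#' Default screening scenario
#'
#' Bundles the scenario parameters: a 1-Mb host at barley-like GC, the
#' 19,074-bp construct with its T-DNA spanning 1-12,584 bp, HPT and Cas9
#' features, a 600-bp host-homologous segment inside the T-DNA, the 21-bp
#' C-rich decoy at 2,069-2,089 bp present in 30-50 genomic copies per
#' individual, and 150-bp paired reads at the given template depth with
#' 0.5% substitution errors.
#'
#' @param host_length host genome length (bp).
#' @param gc host GC fraction.
#' @param construct_length,tdna_end construct geometry (bp).
#' @param homology list(length, at): host-homologous segment inside the
#'   T-DNA.
#' @param decoy list(sequence, at, host_copies = c(min, max)).
#' @param depth sequencing template depth (each template emits two 150-bp
#'   mates, so base coverage is about twice this value).
#' @param read_length,error_rate read simulation parameters.
#' @param k screen k-mer size.
#' @return list of class \code{screen_scenario}.
#' @export
screen_scenario <- function(host_length = 1e6, gc = 0.44,
                            construct_length = 19074L, tdna_end = 12584L,
                            homology = list(length = 600L, at = 3000L),
                            decoy = list(sequence = "CCTCCCCCCCCCCCCCTCTCT",
                                         at = 2069L,
                                         host_copies = c(30L, 50L)),
                            depth = 10, read_length = 150L,
                            error_rate = 0.005, k = 20L) {
  stopifnot(tdna_end < construct_length, depth > 0,
            host_length >= 10000)
  decoy$end <- decoy$at + nchar(decoy$sequence) - 1L
  homology$end <- homology$at + homology$length - 1L
  if (decoy$end > tdna_end || homology$end > tdna_end) {
    stop("decoy and homology segment must lie inside the T-DNA",
         call. = FALSE)
  }
  if (max(decoy$at, homology$at) <= min(decoy$end, homology$end)) {
    stop("decoy and homology placements overlap", call. = FALSE)
  }
  structure(list(host_length = as.integer(host_length), gc = gc,
                 construct_length = as.integer(construct_length),
                 tdna_end = as.integer(tdna_end), homology = homology,
                 decoy = decoy, depth = depth,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, k = as.integer(k),
                 features = data.frame(
                   name = c("HPT", "Cas9"),
                   start = c(6000L, 8000L), end = c(7025L, 12100L))),
            class = "screen_scenario")
}

#' Generate a random host genome
#'
#' @param length genome length in bp.
#' @param gc GC fraction.
#' @param seed optional seed (set.seed is called when given).
#' @return named character vector of length 1 ("host").
#' @export
generate_host_genome <- function(length, gc = 0.44, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  setNames(cpp_random_dna(as.integer(length), gc), "host")
}

.splice <- function(s, at, replacement) {
  # overwrite s[at .. at+nchar(replacement)-1] with replacement
  paste0(substr(s, 1L, at - 1L), replacement,
         substr(s, at + nchar(replacement), nchar(s)))
}

.insert_at <- function(s, after, insert) {
  paste0(substr(s, 1L, after), insert, substr(s, after + 1L, nchar(s)))
}

# Insert at a random locus whose junction bases differ from the construct's
# own flanking bases. A k-mer straddling an insertion junction contains the
# genomic base adjacent to the insert; requiring that base to differ from
# the construct's flank guarantees no junction k-mer matches the construct,
# so a planted f-bp segment lights exactly f - k + 1 positions.
.insert_at_random <- function(g, insert, left_bad = NA, right_bad = NA) {
  L <- nchar(g)
  repeat {
    locus <- sample.int(L - 1L, 1L)
    ok_left <- is.na(left_bad) || substr(g, locus, locus) != left_bad
    ok_right <- is.na(right_bad) ||
      substr(g, locus + 1L, locus + 1L) != right_bad
    if (ok_left && ok_right) break
  }
  .insert_at(g, locus, insert)
}

.flank <- function(con, pos) {
  if (pos < 1L || pos > nchar(con)) NA_character_
  else substr(con, pos, pos)
}

#' Generate the transformation construct for a scenario
#'
#' Random vector sequence with the T-DNA interval [1, tdna_end], a segment
#' copied verbatim from the host (embedded host homology) and the C-rich
#' decoy, plus HPT and Cas9 features inside the T-DNA.
#'
#' @param host host genome (from [generate_host_genome()]).
#' @param scenario a [screen_scenario()].
#' @return list with \code{sequence} (named character) and
#'   \code{annotation} (a [construct_annotation()] that also records the
#'   homology and decoy intervals as features).
#' @export
generate_construct <- function(host, scenario = screen_scenario()) {
  host <- unname(host[1])
  if (nchar(host) < 2L * scenario$homology$length) {
    stop("host too short to donate the homology segment", call. = FALSE)
  }
  con <- cpp_random_dna(scenario$construct_length, 0.5)
  host_at <- nchar(host) %/% 2L
  hom_seq <- substr(host, host_at, host_at + scenario$homology$length - 1L)
  con <- .splice(con, scenario$homology$at, hom_seq)
  con <- .splice(con, scenario$decoy$at, scenario$decoy$sequence)
  feats <- rbind(scenario$features,
                 data.frame(name = c("host_homology", "decoy"),
                            start = c(scenario$homology$at,
                                      scenario$decoy$at),
                            end = c(scenario$homology$end,
                                    scenario$decoy$end)))
  ann <- construct_annotation("construct", scenario$construct_length,
                              tdna_start = 1L,
                              tdna_end = scenario$tdna_end,
                              features = feats)
  list(sequence = setNames(con, "construct"), annotation = ann,
       homology_host_at = host_at)
}

# construct intervals that short planted fragments must avoid (so a planted
# f-bp fragment lights exactly f-k+1 positions of its own)
.reserved_intervals <- function(scenario) {
  rbind(c(scenario$homology$at, scenario$homology$end),
        c(scenario$decoy$at, scenario$decoy$end))
}

#' Apply an insertion event to the host genome
#'
#' \code{none} leaves the host unchanged; \code{full_insertion} inserts the
#' whole T-DNA at a random locus; \code{fragment} inserts one substring of
#' the T-DNA per requested length, each at a random locus, avoiding the
#' homology/decoy intervals so the planted signal is unambiguous. Fragment
#' lengths below the screen's k are accepted with a warning (undetectable
#' by design).
#'
#' @param host host genome (named character, length 1).
#' @param construct construct sequence (named character, length 1).
#' @param annotation the construct's [construct_annotation()].
#' @param event "none", "full_insertion" or "fragment".
#' @param fragment_lengths fragment sizes in bp (fragment event only).
#' @param scenario a [screen_scenario()] (for reserved intervals and k).
#' @return list with \code{genome} (named character) and \code{inserted}
#'   (data.frame of construct_start, construct_end, length per insert).
#' @export
apply_event <- function(host, construct, annotation,
                        event = c("none", "full_insertion", "fragment"),
                        fragment_lengths = c(20L, 21L),
                        scenario = screen_scenario()) {
  event <- match.arg(event)
  g <- unname(host[1])
  con <- unname(construct[1])
  inserted <- data.frame(construct_start = integer(0),
                         construct_end = integer(0), length = integer(0))
  if (event == "full_insertion") {
    tdna <- substr(con, annotation$tdna_start, annotation$tdna_end)
    g <- .insert_at_random(g, tdna,
                           left_bad = .flank(con, annotation$tdna_start - 1L),
                           right_bad = .flank(con, annotation$tdna_end + 1L))
    inserted <- data.frame(construct_start = annotation$tdna_start,
                           construct_end = annotation$tdna_end,
                           length = nchar(tdna))
  } else if (event == "fragment") {
    if (any(fragment_lengths < scenario$k)) {
      warning("fragment(s) shorter than k are undetectable by design",
              call. = FALSE)
    }
    avoid <- .reserved_intervals(scenario)
    taken <- matrix(numeric(0), ncol = 2)
    k <- scenario$k
    for (len in fragment_lengths) {
      repeat {
        start <- sample.int(annotation$tdna_end - len + 1L, 1L)
        iv <- c(start - k, start + len - 1L + k)  # keep k bp clearance
        clash <- function(m) {
          nrow(m) > 0 && any(pmax(m[, 1], iv[1]) <= pmin(m[, 2], iv[2]))
        }
        if (!clash(avoid) && !clash(taken)) break
      }
      taken <- rbind(taken, c(start, start + len - 1L))
      frag <- substr(con, start, start + len - 1L)
      g <- .insert_at_random(g, frag,
                             left_bad = .flank(con, start - 1L),
                             right_bad = .flank(con, start + len))
      inserted <- rbind(inserted,
                        data.frame(construct_start = start,
                                   construct_end = start + len - 1L,
                                   length = len))
    }
  }
  list(genome = setNames(g, "edited"), inserted = inserted, event = event)
}

#' Simulate sequencing reads
#'
#' Uniformly placed sequencing templates on either strand with independent
#' per-base substitution errors. \code{round(depth * L / read_length)}
#' templates are drawn; with \code{paired = TRUE} (the default) each
#' template emits an R1/R2 mate pair in FR orientation (the mate is the
#' adjacent downstream window), so the emitted base coverage is about twice
#' \code{depth}. The screen treats mates as independent reads.
#'
#' @param genome genome sequence (named character, length 1).
#' @param depth template depth (templates x read_length / genome length).
#' @param read_length read length in bp (default 150).
#' @param error_rate per-base substitution probability.
#' @param paired emit mate pairs (default) or single-end reads.
#' @param seed optional seed (set.seed is called when given).
#' @return named character vector of reads (pairs interleaved:
#'   \code{<id>/1}, \code{<id>/2}).
#' @export
simulate_reads <- function(genome, depth, read_length = 150L,
                           error_rate = 0.005, paired = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- unname(genome[1])
  n <- round(depth * nchar(g) / read_length)
  if (n < 1) stop("depth x length yields no reads", call. = FALSE)
  reads <- cpp_simulate_reads(g, as.integer(n), as.integer(read_length),
                              error_rate, paired)
  ids <- if (paired) {
    paste0("t", rep(seq_len(n), each = 2L), "/", rep(1:2, n))
  } else {
    paste0("t", seq_len(n))
  }
  setNames(reads, ids)
}

# per-individual genome: host plus a random number of extra decoy copies
# (repeat copy-number variation between individuals), then the event.
# Decoy copies never land inside the host's homology-donor segment: the
# screen's premise is that the host background is *shared* between control
# and query, and an insertion splitting that segment in only one individual
# would fabricate a private signal.
.individual_genome <- function(host, construct, annotation, scenario,
                               event, fragment_lengths = c(20L, 21L),
                               avoid_host = NULL) {
  g <- unname(host[1])
  con <- unname(construct[1])
  rng <- scenario$decoy$host_copies
  n_copies <- sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
  left_bad <- .flank(con, scenario$decoy$at - 1L)
  right_bad <- .flank(con, scenario$decoy$end + 1L)
  loci <- integer(0)
  while (length(loci) < n_copies) {
    locus <- sample.int(nchar(g) - 1L, 1L)
    if (!is.null(avoid_host) &&
          locus >= avoid_host[1] && locus <= avoid_host[2]) next
    if ((is.na(left_bad) || substr(g, locus, locus) != left_bad) &&
          (is.na(right_bad) ||
             substr(g, locus + 1L, locus + 1L) != right_bad)) {
      loci <- c(loci, locus)
    }
  }
  # insert right-to-left so loci stay valid in original host coordinates
  for (locus in sort(loci, decreasing = TRUE)) {
    g <- .insert_at(g, locus, scenario$decoy$sequence)
  }
  ev <- apply_event(setNames(g, "host"), construct, annotation,
                    event = event, fragment_lengths = fragment_lengths,
                    scenario = scenario)
  ev$decoy_copies <- n_copies
  ev
}

#' Simulate a complete screening experiment
#'
#' Generates a host, the construct, a negative-control individual and a
#' query individual carrying the requested event, sequences both and runs
#' the full [transgene_screen()]. Both individuals carry independent
#' random copy numbers of the C-rich decoy repeat, which is what makes the
#' decoy a realistic false-positive signal.
#'
#' @param scenario a [screen_scenario()].
#' @param event "none", "full_insertion" or "fragment".
#' @param fragment_lengths fragment sizes for the fragment event.
#' @param seed optional seed (set.seed is called when given).
#' @return list of class \code{screen_simulation}: \code{screen} (a
#'   [transgene_screen()] object), \code{truth} (event, inserted fragments,
#'   decoy copy numbers) and \code{scenario}.
#' @export
simulate_screen <- function(scenario = screen_scenario(), event = "none",
                            fragment_lengths = c(20L, 21L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  host <- generate_host_genome(scenario$host_length, scenario$gc)
  built <- generate_construct(host, scenario)
  avoid <- c(built$homology_host_at - scenario$k,
             built$homology_host_at + scenario$homology$length)
  ctrl <- .individual_genome(host, built$sequence, built$annotation,
                             scenario, event = "none", avoid_host = avoid)
  qry <- .individual_genome(host, built$sequence, built$annotation,
                            scenario, event = event,
                            fragment_lengths = fragment_lengths,
                            avoid_host = avoid)
  ctrl_reads <- simulate_reads(ctrl$genome, scenario$depth,
                               scenario$read_length, scenario$error_rate)
  qry_reads <- simulate_reads(qry$genome, scenario$depth,
                              scenario$read_length, scenario$error_rate)
  screen <- transgene_screen(qry_reads, ctrl_reads, built$sequence,
                             built$annotation, k = scenario$k,
                             sample_id = "query", control_id = "control")
  structure(list(screen = screen,
                 truth = list(event = event,
                              inserted = qry$inserted,
                              decoy_copies = c(control = ctrl$decoy_copies,
                                               query = qry$decoy_copies)),
                 scenario = scenario),
            class = "screen_simulation")
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat(sprintf("Screen simulation (planted event: %s)\n", x$truth$event))
  print(x$screen)
  invisible(x)
}

#' Generate per-allele amplicon sequences
#'
#' One record per allele: \code{none} copies the reference; deletions
#' remove \code{length} bases spanning (or starting at) the given position;
#' insertions add \code{sequence} (or \code{length} random bases) after the
#' given position.
#'
#' @param ref_region reference amplicon (named character, length 1).
#' @param alleles list of allele specs: list(label, type, length, at,
#'   sequence). \code{at} defaults to \code{cut}; a deletion without
#'   \code{at} is centred on the cut.
#' @param cut default edit position (e.g. from [expected_cut_site()]).
#' @param seed optional seed for random insertion bases.
#' @return named character vector of allele sequences.
#' @export
generate_amplicons <- function(ref_region, alleles, cut = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- toupper(unname(ref_region[1]))
  L <- nchar(ref)
  out <- character(0)
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    label <- if (!is.null(a$label)) a$label else paste0("allele", i)
    type <- a$type
    if (type == "none") {
      out[label] <- ref
      next
    }
    len <- as.integer(a$length)
    at <- if (!is.null(a$at)) as.integer(a$at)
    else if (type == "deletion") cut - len %/% 2L + 1L
    else cut
    if (is.null(at)) stop("allele needs `at` or a cut position",
                          call. = FALSE)
    if (type == "deletion") {
      if (at < 1L || at + len - 1L > L) stop("edit outside region",
                                             call. = FALSE)
      call <- structure(list(type = "deletion", ref_pos = at, length = len),
                        class = "indel_call")
    } else if (type == "insertion") {
      if (at < 0L || at > L) stop("edit outside region", call. = FALSE)
      s <- if (!is.null(a$sequence)) toupper(a$sequence)
      else cpp_random_dna(len, 0.5)
      call <- structure(list(type = "insertion", ref_pos = at,
                             length = nchar(s), sequence = s),
                        class = "indel_call")
    } else if (type == "substitution") {
      if (at < 1L || at + len - 1L > L) stop("edit outside region",
                                             call. = FALSE)
      s <- if (!is.null(a$sequence)) toupper(a$sequence)
      else cpp_random_dna(len, 0.5)
      call <- structure(list(type = "substitution", ref_pos = at,
                             length = len, sequence = s),
                        class = "indel_call")
    } else {
      stop("unknown allele type: ", type, call. = FALSE)
    }
    out[label] <- apply_indel(ref, call)
  }
  out
}

#' Generate raw per-individual trait data from group parameters
#'
#' Normal draws per group; summarising the output recovers the requested
#' means and SDs within sampling error.
#'
#' @param groups data.frame with columns label, n, mean, sd (sd > 0,
#'   n >= 2), or a list of [group_summary()] objects.
#' @param seed optional seed (set.seed is called when given).
#' @return data.frame with columns \code{label} and \code{value}.
#' @export
generate_trait_data <- function(groups, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- do.call(rbind, lapply(groups, function(g)
      data.frame(label = g$label, n = g$n, mean = g$mean, sd = g$sd)))
  }
  stopifnot(all(c("label", "n", "mean", "sd") %in% names(groups)))
  if (any(groups$sd <= 0)) stop("sd must be positive", call. = FALSE)
  if (any(groups$n < 2)) stop("need n >= 2 per group", call. = FALSE)
  do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(label = groups$label[i],
               value = rnorm(groups$n[i], groups$mean[i], groups$sd[i]))
  }))
}
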