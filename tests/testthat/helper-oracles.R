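# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths on small instances.

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-position k-mer counting: substring comparisons, canonical
# orientation, every stored construct start position incremented once per
# read k-mer occurrence
count_oracle <- function(reads, construct, k) {
  L <- nchar(construct)
  starts <- seq_len(L - k + 1L)
  con_kmers <- substring(construct, starts, starts + k - 1L)
  counts <- integer(length(starts))
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(r, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      hit <- which(con_kmers == w | con_kmers == rc_oracle(w))
      counts[hit] <- counts[hit] + 1L
    }
  }
  counts
}

# hand-written Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# naive off-target scan: explicit window loops on both strands
offtarget_oracle <- function(genome, proto, pam = "NGG", max_mm = 3L) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
                R = c("A", "G"), Y = c("C", "T"))
  pam_ok <- function(site_pam) {
    all(mapply(function(pat, base) base %in% iupac[[pat]],
               strsplit(pam, "")[[1]], strsplit(site_pam, "")[[1]]))
  }
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  hits <- list()
  for (sid in names(genome)) {
    g <- genome[[sid]]
    L <- nchar(g)
    W <- nchar(proto) + nchar(pam)
    for (i in seq_len(L - W + 1L)) {
      win <- substr(g, i, i + W - 1L)
      # plus strand
      if (pam_ok(substr(win, nchar(proto) + 1L, W))) {
        mm <- hamming(substr(win, 1L, nchar(proto)), proto)
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- data.frame(
            seq_id = sid, start = i, end = i + nchar(proto) - 1L,
            strand = "+", mismatches = mm, site_sequence = win,
            on_target = mm == 0L)
        }
      }
      # minus strand: the site read 5'->3' is the reverse complement
      rc <- rc_oracle(win)
      if (pam_ok(substr(rc, nchar(proto) + 1L, W))) {
        mm <- hamming(substr(rc, 1L, nchar(proto)), proto)
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- data.frame(
            seq_id = sid, start = i + nchar(pam), end = i + W - 1L,
            strand = "-", mismatches = mm, site_sequence = rc,
            on_target = mm == 0L)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), site_sequence = character(0),
                      on_target = logical(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$seq_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# quadratic-space affine-gap global alignment score (Gotoh), with the same
# gap cost convention as the package: a gap of length g costs open + g*ext
nw_affine_score <- function(a, b, match = 2, mismatch = -4, open = 6,
                            ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (deletion of a chars)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Monte-Carlo evaluation of the two-sided Dunnett adjusted p
dunnett_mc <- function(t, n0, n, df, B = 1e6) {
  K <- length(n)
  lam <- sqrt(n / (n + n0))
  a <- sqrt(1 - lam^2)
  z0 <- rnorm(B)
  S <- sqrt(rchisq(B, df) / df)
  mx <- rep(0, B)
  for (j in seq_len(K)) mx <- pmax(mx, abs(a[j] * rnorm(B) - lam[j] * z0) / S)
  mean(mx >= abs(t))
}

# fabricate a position_track for unit tests
fake_track <- function(counts, total, id = "s", k = 20L,
                       construct_id = "construct") {
  structure(list(sample_id = id, construct_id = construct_id, k = k,
                 counts = as.integer(counts), total_read_kmers = total,
                 matched_kmers = sum(counts), skipped_kmers = 0,
                 short_reads = 0L),
            class = "position_track")
}
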