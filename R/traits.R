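# Agronomic trait statistics.
#
# Dunnett's many-to-one comparisons are computed directly from group
# summaries (n, mean, SD), because that is what is typically published.
# With pooled variance s^2 = sum((n_i-1) sd_i^2) / sum(n_i-1) over all
# groups (df = sum(n_i-1)) and t_i = (m_i - m_0) / (s sqrt(1/n_i + 1/n_0)),
# the two-sided adjusted p is P(max_j |T_j| >= |t_i|) under the K-variate t
# with correlations rho_ij = lambda_i lambda_j, lambda_i =
# sqrt(n_i/(n_i+n_0)). Writing T_i = (a_i Z_i - lambda_i Z_0)/S with
# a_i^2 = 1 - lambda_i^2, Z iid N(0,1) and S^2 ~ chi^2_df/df, the
# probability factorises given (Z_0, S), so it is evaluated by
# deterministic two-dimensional Gauss-Legendre quadrature.

#' Group summary (n, mean, SD)
#'
#' @param label group label.
#' @param n number of replicates (>= 2).
#' @param mean group mean.
#' @param sd sample standard deviation (>= 0).
#' @return object of class \code{group_summary}.
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

# quadrature nodes/weights cached per (df, nodes)
.dunnett_grid <- function(df, n_nodes) {
  gz <- pracma::gaussLegendre(n_nodes, -9, 9)
  s_hi <- sqrt(qchisq(1 - 1e-13, df) / df)
  s_lo <- sqrt(qchisq(1e-13, df) / df)
  gs <- pracma::gaussLegendre(n_nodes, s_lo, s_hi)
  # density of S = sqrt(chi^2_df / df)
  fs <- dchisq(df * gs$x^2, df) * 2 * df * gs$x
  list(z = gz$x, wz = gz$w * stats::dnorm(gz$x), s = gs$x, ws = gs$w * fs)
}

# P(max_j |T_j| < q) for the Dunnett statistic set
.dunnett_pless <- function(q, lambda, df, grid) {
  if (q <= 0) return(0)
  a <- sqrt(1 - lambda^2)
  # outer: s nodes; inner: z0 nodes; product over comparisons
  inner <- vapply(grid$s, function(s) {
    prod_term <- rep(1, length(grid$z))
    for (j in seq_along(lambda)) {
      hi <- (q * s + lambda[j] * grid$z) / a[j]
      lo <- (-q * s + lambda[j] * grid$z) / a[j]
      prod_term <- prod_term * (pnorm(hi) - pnorm(lo))
    }
    sum(grid$wz * prod_term)
  }, numeric(1))
  min(1, sum(grid$ws * inner))
}

#' Dunnett-adjusted two-sided p-values
#'
#' Adjusted p for each of K treatment-vs-control t statistics sharing a
#' pooled variance estimate: p_i = P(max_j |T_j| >= |t_i|) under the
#' equicorrelated K-variate t distribution, evaluated by deterministic
#' quadrature (self-checked so that the quadrature error is below 1e-6).
#'
#' @param t vector of t statistics (one per treatment).
#' @param n0 control group size.
#' @param n vector of treatment group sizes (same length as \code{t}).
#' @param df pooled degrees of freedom.
#' @param n_nodes quadrature nodes per dimension.
#' @return vector of adjusted p-values in [0, 1].
#' @export
dunnett_p_adjust <- function(t, n0, n, df, n_nodes = 128L) {
  stopifnot(length(n) == length(t), df >= 1)
  lambda <- sqrt(n / (n + n0))
  grid <- .dunnett_grid(df, n_nodes)
  vapply(abs(t), function(q) {
    max(0, min(1, 1 - .dunnett_pless(q, lambda, df, grid)))
  }, numeric(1))
}

.sig_label <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "n.s."), right = FALSE) |> as.character()
}

#' Dunnett's many-to-one test from group summaries
#'
#' Classical (equal-variance) two-sided Dunnett comparisons of each
#' treatment group against a shared control, computed from (n, mean, SD)
#' summaries. Significance labels: *** p < 0.001, ** p < 0.01, * p < 0.05,
#' n.s. otherwise.
#'
#' @param control a [group_summary()] for the control group.
#' @param treatments list of [group_summary()] objects (>= 1).
#' @param n_nodes quadrature nodes per dimension for the adjusted p.
#' @return object of class \code{dunnett_test}: \code{control_label},
#'   \code{df}, \code{pooled_sd} and \code{comparisons} (data.frame with
#'   label, n, mean, sd, diff, t, p_adjusted, significance).
#' @export
dunnett_from_summary <- function(control, treatments, n_nodes = 128L) {
  stopifnot(inherits(control, "group_summary"))
  if (inherits(treatments, "group_summary")) treatments <- list(treatments)
  stopifnot(length(treatments) >= 1,
            all(vapply(treatments, inherits, logical(1), "group_summary")))
  groups <- c(list(control), treatments)
  ns <- vapply(groups, function(g) g$n, numeric(1))
  sds <- vapply(groups, function(g) g$sd, numeric(1))
  if (all(sds == 0)) stop("all groups have zero SD: variance is degenerate",
                          call. = FALSE)
  df <- sum(ns - 1)
  s2 <- sum((ns - 1) * sds^2) / df
  s <- sqrt(s2)
  n <- ns[-1]
  means <- vapply(treatments, function(g) g$mean, numeric(1))
  diffs <- means - control$mean
  t <- diffs / (s * sqrt(1 / n + 1 / control$n))
  p <- dunnett_p_adjust(t, n0 = control$n, n = n, df = df,
                        n_nodes = n_nodes)
  comparisons <- data.frame(
    label = vapply(treatments, function(g) g$label, character(1)),
    n = as.integer(n),
    mean = means,
    sd = vapply(treatments, function(g) g$sd, numeric(1)),
    diff = diffs, t = t, p_adjusted = p,
    significance = .sig_label(p),
    stringsAsFactors = FALSE)
  structure(list(control_label = control$label, control_n = control$n,
                 control_mean = control$mean, df = df, pooled_sd = s,
                 comparisons = comparisons),
            class = "dunnett_test")
}

#' @export
print.dunnett_test <- function(x, digits = 6, ...) {
  cat(sprintf("Dunnett's many-to-one comparisons vs %s (df = %d, pooled SD = %.4g)\n",
              x$control_label, x$df, x$pooled_sd))
  out <- x$comparisons
  out$t <- round(out$t, 3)
  out$p_adjusted <- signif(out$p_adjusted, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Percent change of a treatment mean relative to control
#'
#' @param treatment_mean,control_mean trait means; \code{control_mean} must
#'   be positive.
#' @return 100 * (treatment - control) / control.
#' @export
percent_change <- function(treatment_mean, control_mean) {
  if (any(control_mean <= 0)) stop("control mean must be positive",
                                   call. = FALSE)
  100 * (treatment_mean - control_mean) / control_mean
}

#' Germination rate with binomial standard error
#'
#' @param germinated number of germinated grains (0 <= germinated <= total).
#' @param total grains tested (> 0).
#' @return list with \code{rate} and \code{se} = sqrt(p(1-p)/total).
#' @export
germination_rate <- function(germinated, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(germinated < 0 | germinated > total)) {
    stop("germinated must lie in [0, total]", call. = FALSE)
  }
  p <- germinated / total
  list(rate = p, se = sqrt(p * (1 - p) / total))
}

#' Dunnett comparisons for a table of trait summaries
#'
#' Runs [dunnett_from_summary()] once per trait on a long-format summary
#' table (the shape in which such results are usually published).
#'
#' @param data data.frame with columns trait, label, n, mean, sd.
#' @param control_label label of the control group (must appear once per
#'   trait).
#' @return data.frame with columns trait, label, n, mean, sd, diff, t, df,
#'   p_adjusted, significance (one row per treatment group).
#' @export
dunnett_from_table <- function(data, control_label) {
  stopifnot(all(c("trait", "label", "n", "mean", "sd") %in% names(data)))
  out <- lapply(split(data, data$trait), function(d) {
    ci <- which(d$label == control_label)
    if (length(ci) != 1L) {
      stop("control label must appear exactly once per trait", call. = FALSE)
    }
    ctrl <- group_summary(d$label[ci], d$n[ci], d$mean[ci], d$sd[ci])
    trt <- lapply(setdiff(seq_len(nrow(d)), ci), function(i)
      group_summary(d$label[i], d$n[i], d$mean[i], d$sd[i]))
    fit <- dunnett_from_summary(ctrl, trt)
    cbind(trait = d$trait[1], fit$comparisons[c("label", "n", "mean", "sd",
                                                "diff", "t")],
          df = fit$df, fit$comparisons[c("p_adjusted", "significance")])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise raw per-individual trait data into group summaries
#'
#' Raw-data path for [dunnett_from_summary()]: computes (n, mean, SD) per
#' group and delegates.
#'
#' @param data data.frame with columns \code{label} and \code{value}.
#' @return named list of [group_summary()] objects.
#' @export
summarize_trait_data <- function(data) {
  stopifnot(all(c("label", "value") %in% names(data)))
  out <- lapply(split(data$value, data$label), function(v) {
    if (length(v) < 2) stop("need n >= 2 per group", call. = FALSE)
    group_summary("", length(v), mean(v), stats::sd(v))
  })
  for (lab in names(out)) out[[lab]]$label <- lab
  out
}
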