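#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median of the ratios of
#' a sample's counts to the per-feature geometric mean, restricted to
#' features with no zero count, then rescaled so the factors themselves have
#' geometric mean one.
#'
#' @param x A [count_matrix()].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  ok <- rowSums(cts == 0) == 0
  if (!any(ok))
    stop("no feature has positive counts in every sample")
  logc <- log(cts[ok, , drop = FALSE])
  loggeo <- rowMeans(logc)
  logratios <- logc - loggeo
  sf <- exp(apply(logratios, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(cts)
  sf
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; order-preserving wrapper around the standard
#' implementation, with input validation. `NA` p-values propagate to `NA`
#' q-values and do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Fit a mean-dispersion trend a0 + a1/mu by one round of gamma-family
# regression on the per-feature moment estimates, as in parametric
# dispersion trends for bulk RNA-seq. Falls back to the median dispersion
# when too few features inform the fit.
fit_dispersion_trend <- function(mu, disp) {
  use <- is.finite(mu) & is.finite(disp) & mu > 0 & disp > 1e-8
  if (sum(use) < 10) {
    med <- if (any(use)) stats::median(disp[use]) else 0.1
    return(function(m) rep(med, length(m)))
  }
  m <- mu[use]; d <- disp[use]
  fit <- try(suppressWarnings(
    stats::glm(d ~ I(1 / m), family = stats::Gamma(link = "identity"),
               start = c(stats::median(d), 1))), silent = TRUE)
  if (inherits(fit, "try-error") || any(!is.finite(stats::coef(fit))) ||
      stats::coef(fit)[1] < 0) {
    med <- stats::median(d)
    return(function(mm) rep(med, length(mm)))
  }
  a <- stats::coef(fit)
  a[2] <- max(a[2], 0)
  function(mm) pmax(a[1] + a[2] / pmax(mm, 1e-8), 1e-8)
}

#' Region-wise differential test for count features
#'
#' Negative-binomial Wald test of treated versus sham for every feature of
#' a count matrix (genes or peaks; the same engine serves both). The model
#' is NB with variance `mu + alpha * mu^2`; per-feature dispersions are
#' method-of-moments estimates shrunk 50/50 toward a fitted mean-dispersion
#' trend. The Wald statistic is the log2 fold-change of normalized condition
#' means (pseudocount 0.5) over its delta-method standard error. BH
#' correction is applied across tested features; features with all-zero
#' counts are reported `ns` with `NA` p and q.
#'
#' Differential status follows the thresholds used throughout region-wise
#' DEG/DA calling: `up` when `log2FC >= fcThreshold` and `q <= qThreshold`,
#' `down` symmetrically.
#'
#' @param x A [count_matrix()] containing both conditions of one region.
#' @param size_factors Optional size factors; computed with
#'   [estimate_size_factors()] when omitted.
#' @param fc_threshold Minimum absolute log2 fold-change (default
#'   `log2(1.25)`).
#' @param q_threshold Maximum FDR q-value (default 0.1).
#' @return Data frame with one row per feature: `featureId`, `baseMean`,
#'   `log2FC`, `pValue`, `qValue`, `status`, ordered as the input features.
#' @export
test_differential <- function(x, size_factors = NULL,
                              fc_threshold = log2(1.25),
                              q_threshold = 0.1) {
  stopifnot(inherits(x, "count_matrix"))
  cond <- x$meta$condition
  if (length(unique(cond)) < 2)
    stop("both conditions must be present")
  if (min(table(cond)) < 2)
    stop("at least 2 replicates per condition are required")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(x)
  if (!all(size_factors > 0)) stop("size factors must be positive")
  cts <- x$counts
  norm <- sweep(cts, 2, size_factors, "/")
  is_t <- cond == "treated"
  nt <- sum(is_t); ns <- sum(!is_t)

  mean_t <- rowMeans(norm[, is_t, drop = FALSE])
  mean_s <- rowMeans(norm[, !is_t, drop = FALSE])
  base_mean <- rowMeans(norm)
  var_t <- apply(norm[, is_t, drop = FALSE], 1, stats::var)
  var_s <- apply(norm[, !is_t, drop = FALSE], 1, stats::var)

  # Moment dispersion from within-condition residual variance on the
  # normalized scale: Var(K/s) ~ mu/s + alpha mu^2; average the 1/s
  # correction over samples of the group.
  inv_s_t <- mean(1 / size_factors[is_t])
  inv_s_s <- mean(1 / size_factors[!is_t])
  pool_num <- (nt - 1) * (var_t - mean_t * inv_s_t) +
    (ns - 1) * (var_s - mean_s * inv_s_s)
  pool_den <- (nt - 1) * mean_t^2 + (ns - 1) * mean_s^2
  disp_mom <- ifelse(pool_den > 0, pmax(pool_num / pool_den, 0), NA_real_)

  tested <- rowSums(cts) > 0
  trend <- fit_dispersion_trend(base_mean[tested],
                                disp_mom[tested])
  disp_tr <- trend(base_mean)
  disp <- ifelse(is.na(disp_mom), disp_tr,
                 0.5 * pmax(disp_mom, 0) + 0.5 * disp_tr)
  disp <- pmax(disp, 1e-8)

  log2fc <- log2((mean_t + 0.5) / (mean_s + 0.5))
  # delta-method variance of log2(mean + 0.5) under NB counts
  v_mean_t <- (mean_t * inv_s_t + disp * mean_t^2) / nt
  v_mean_s <- (mean_s * inv_s_s + disp * mean_s^2) / ns
  se2 <- v_mean_t / ((mean_t + 0.5)^2) + v_mean_s / ((mean_s + 0.5)^2)
  se_log2 <- sqrt(se2) / log(2)
  z <- ifelse(se_log2 > 0, log2fc / se_log2, 0)
  # t reference with moderated degrees of freedom: the 50/50 shrinkage
  # toward the trend acts like an equal-weight prior, doubling the
  # effective residual df of the dispersion estimate
  df <- 2 * (nt + ns - 2)
  p <- 2 * stats::pt(-abs(z), df = df)
  p[!tested] <- NA_real_
  log2fc[!tested] <- 0
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_adjust(p[tested])

  status <- rep("ns", length(p))
  status[tested & log2fc >= fc_threshold & !is.na(q) & q <= q_threshold] <- "up"
  status[tested & log2fc <= -fc_threshold & !is.na(q) & q <= q_threshold] <- "down"

  # stable output order by feature id on ties is guaranteed by keeping the
  # input feature order throughout
  data.frame(featureId = rownames(cts),
             baseMean = base_mean,
             log2FC = log2fc,
             pValue = p,
             qValue = q,
             status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential tests for every region of a multi-region count matrix
#'
#' Splits a matrix by the `region` metadata column, normalizes and tests
#' each region separately (BH within region, mirroring region-wise DEG/DA
#' calling), and returns a named list of differential tables.
#'
#' @inheritParams test_differential
#' @return Named list (region -> data frame as in [test_differential()]).
#' @export
test_differential_by_region <- function(x, fc_threshold = log2(1.25),
                                        q_threshold = 0.1) {
  stopifnot(inherits(x, "count_matrix"))
  regions <- unique(x$meta$region)
  res <- lapply(regions, function(r) {
    sub <- subset_counts(x, samples = x$meta$region == r)
    test_differential(sub, fc_threshold = fc_threshold,
                      q_threshold = q_threshold)
  })
  names(res) <- regions
  res
}
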