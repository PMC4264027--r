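#' Fit a single Gaussian to a residual-current sample
#'
#' Histograms the values with Freedman-Diaconis bins (density scaling) and
#' least-squares fits an amplitude-scaled Gaussian to the bin heights; the
#' peak position and width are the reported mean/SD, the convention for
#' locating blockade peaks in current histograms. Falls back to sample
#' moments when the curve fit fails or the sample is degenerate. A
#' goodness-of-fit statistic (R-squared of the histogram fit) flags
#' non-Gaussian, e.g. bimodal, inputs.
#'
#' @param residuals_pA Numeric vector of per-event mean residual currents
#'   (>= 30 values).
#' @param gof_threshold R-squared below which the fit is flagged poor
#'   (default 0.8).
#' @return List of class `gauss_component`: `mean_pA`, `sd_pA`, `weight`
#'   (1), `method` ("histogram" or "moments"), `gof`, `poor_fit`,
#'   `degenerate`.
#' @export
fit_single_gaussian <- function(residuals_pA, gof_threshold = 0.8) {
  if (length(residuals_pA) < 30)
    stop("insufficient data: need >= 30 residual values")
  if (stats::sd(residuals_pA) == 0)
    return(structure(list(mean_pA = residuals_pA[1], sd_pA = 0, weight = 1,
                          method = "moments", gof = NA_real_,
                          poor_fit = FALSE, degenerate = TRUE),
                     class = "gauss_component"))
  h <- graphics::hist(residuals_pA, breaks = "FD", plot = FALSE)
  df <- data.frame(mid = h$mids, y = h$density)
  m0 <- mean(residuals_pA); s0 <- stats::sd(residuals_pA)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(mid - m)^2 / (2 * s^2)), data = df,
                      start = list(a = max(df$y), m = m0, s = s0),
                      lower = c(0, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(mean_pA = m0, sd_pA = s0, weight = 1,
                          method = "moments", gof = NA_real_,
                          poor_fit = TRUE, degenerate = FALSE),
                     class = "gauss_component"))
  }
  cf <- stats::coef(fit)
  gof <- 1 - sum(stats::resid(fit)^2) / sum((df$y - mean(df$y))^2)
  structure(list(mean_pA = unname(cf[["m"]]), sd_pA = unname(cf[["s"]]),
                 weight = 1, method = "histogram", gof = gof,
                 poor_fit = gof < gof_threshold, degenerate = FALSE),
            class = "gauss_component")
}

#' @export
print.gauss_component <- function(x, ...) {
  cat(sprintf("<gauss_component> %.1f +/- %.1f pA (w=%.2f, %s%s)\n",
              x$mean_pA, x$sd_pA, x$weight, x$method,
              if (isTRUE(x$poor_fit)) ", poor fit" else ""))
  invisible(x)
}

# one EM run for a k-component univariate Gaussian mixture
.em_once <- function(x, mu, sgm, w, max_iter = 5000, tol = 1e-12) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sgm[j]),
                   numeric(n))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    r <- dens / rowsum_
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)       # component collapsed
    w <- nk / n
    mu <- colSums(r * x) / nk
    sgm <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, 1e-12))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sgm, w = w, loglik = ll)
}

#' Two-component Gaussian mixture of residual currents
#'
#' Expectation-maximization with multiple random restarts (initial means
#' drawn from random data quantile pairs, pooled SD, equal weights); the
#' run with the best log-likelihood is kept and components are returned
#' ordered by mean, descending. Used to resolve the two homopolymer peaks
#' in a mixed-sample residual-current histogram.
#'
#' Values farther than `trim_mad` robust SDs from the median are dropped
#' before the fit: a Gaussian fitted to a histogram is insensitive to a few
#' stray far-off bins, but EM is not, so gross outliers (e.g. blockades
#' whose depth the detector could not pin down) would otherwise capture a
#' component of their own.
#'
#' @param residuals_pA Numeric vector (>= 100 values for `k = 2`).
#' @param seed Integer RNG seed (restart initialization).
#' @param k Number of components (default 2; other k exposed but the
#'   two-component case is the validated one).
#' @param restarts Number of random restarts (default 10).
#' @param trim_mad Outlier trim radius in MAD-based SD units (default 5;
#'   `Inf` disables trimming).
#' @return Data frame of class `gauss_mixture` with one row per component:
#'   `mean_pA`, `sd_pA`, `weight` (ordered by mean descending); attributes
#'   `loglik` and `n_used`.
#' @export
fit_two_gaussian_mixture <- function(residuals_pA, seed = 1, k = 2,
                                     restarts = 10, trim_mad = 5) {
  x <- residuals_pA
  if (length(x) < 50 * k)
    stop("insufficient data: need >= ", 50 * k, " values")
  if (is.finite(trim_mad) && stats::mad(x) > 0)
    x <- x[abs(x - stats::median(x)) <= trim_mad * stats::mad(x)]
  set.seed(seed)
  best <- NULL
  s0 <- stats::sd(x)
  if (s0 == 0) {
    out <- data.frame(mean_pA = rep(x[1], k), sd_pA = 0, weight = 1 / k)
    class(out) <- c("gauss_mixture", "data.frame")
    return(out)
  }
  for (r in seq_len(restarts)) {
    q <- stats::quantile(x, sort(stats::runif(k, 0.05, 0.95)), names = FALSE)
    fit <- .em_once(x, mu = q, sgm = rep(s0 / sqrt(k), k),
                    w = rep(1 / k, k))
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed: no restart converged")
  ord <- order(best$mu, decreasing = TRUE)
  out <- data.frame(mean_pA = best$mu[ord], sd_pA = best$sigma[ord],
                    weight = best$w[ord])
  attr(out, "loglik") <- best$loglik
  attr(out, "n_used") <- length(x)
  class(out) <- c("gauss_mixture", "data.frame")
  out
}

#' Residual current as a percentage of the open-pore current
#'
#' `100 * residual / (G V)` with the open-pore current formed from the
#' measured open conductance and bias (nS * mV = pA).
#'
#' @param residual_pA Residual current in pA.
#' @param open_conductance_nS Open-pore conductance in nS.
#' @param bias_mV Applied voltage in mV (> 0).
#' @return Percent of the open-pore current.
#' @examples
#' residual_fraction(688.4, 6.95, 200)  # ~49.5
#' @export
residual_fraction <- function(residual_pA, open_conductance_nS, bias_mV) {
  if (any(bias_mV <= 0)) stop("bias_mV must be positive")
  if (any(open_conductance_nS <= 0))
    stop("open_conductance_nS must be positive")
  100 * residual_pA / (open_conductance_nS * bias_mV)
}

#' Blockade conductance of a residual-current level
#'
#' `(I0 - residual) / V` in pS, with `I0 = G V`: the conductance removed
#' from the pore while the molecule resides in it, the cross-platform
#' per-nucleotide signature.
#'
#' @inheritParams residual_fraction
#' @return Blockade conductance in pS. Residuals exceeding the open-pore
#'   current give a negative value with a warning.
#' @examples
#' blockade_conductance(688.4, 6.95, 200)  # ~3508
#' @export
blockade_conductance <- function(residual_pA, open_conductance_nS, bias_mV) {
  if (any(bias_mV <= 0)) stop("bias_mV must be positive")
  if (any(open_conductance_nS <= 0))
    stop("open_conductance_nS must be positive")
  I0_pA <- open_conductance_nS * bias_mV
  out <- (I0_pA - residual_pA) / bias_mV * 1000
  if (any(out < 0))
    warning("residual current exceeds open-pore current; negative blockade")
  out
}

#' Rank homopolymers by blockade conductance
#'
#' Orders labels by descending blockade conductance (the deeper blocker
#' first), joined with `>`; ties break alphabetically. Also reports the
#' minimum pairwise gap, the resolution the ranking rests on.
#'
#' @param rows Data frame with columns `label` and `dI_block_pS` (>= 2 rows,
#'   unique labels).
#' @return List with `order` (e.g. `"T>C>A"`) and `min_delta_pS`.
#' @examples
#' rank_homopolymers(data.frame(label = c("A", "T", "C"),
#'                              dI_block_pS = c(3510, 3800, 3670)))
#' @export
rank_homopolymers <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) < 2) stop("need >= 2 rows")
  if (anyDuplicated(rows$label)) stop("duplicate labels")
  ord <- order(-rows$dI_block_pS, rows$label)
  d <- rows$dI_block_pS[ord]
  list(order = paste(rows$label[ord], collapse = ">"),
       min_delta_pS = min(abs(diff(d))))
}

#' Reference blockade-conductance table
#'
#' Static literature comparison of per-nucleotide blockade conductances
#' (pS) across protein pores and solid-state devices, including the
#' quartz-substrate solid-state row this package's pipeline reproduces
#' (A 3510, T 3800, C 3670 pS at 6950 pS open conductance and 200 mV,
#' rank T>C>A, minimum gap 130 pS). Shipped as data, not computed.
#'
#' @return Data frame with columns `pore`, `A_pS`, `T_pS`, `C_pS`, `G_pS`,
#'   `open_pS`, `bias_mV`, `rank`, `min_delta_pS`, `source`.
#' @export
blockade_reference_table <- function() {
  data.frame(
    pore = c(rep("alpha-hemolysin", 5), rep("MspA", 5),
             "solid-state", "solid-state quartz"),
    A_pS = c(778, 806, 805, 639, 139, 1442, 1490, 1345, 1314, 367, 5100, 3510),
    T_pS = c(805, 799, 808, 645, 144, 1573, 1627, 1500, 1546, 489, 4800, 3800),
    C_pS = c(790, 778, 814, 656, 111, 1537, 1593, 1612, 1360, 385, 4200, 3670),
    G_pS = c(NA, NA, 802, 627, 167, 1476, 1534, 1606, 1263, 425, NA, NA),
    open_pS = c(958, 958, 1019, 1050, 300, 1806, 1801, 1822, 1822, 611,
                NA, 6950),
    bias_mV = c(120, 120, 160, 160, 180, 180, 140, 180, 180, 180, 1000, 200),
    rank = c("T>C>A", "A>T>C", "C>T>A>G", "C>T>A>G", "G>T>A>C",
             "T>C>G>A", "T>C>G>A", "C>G>T>A", "T>C>A>G", "T>G>C>A",
             "A>T>C", "T>C>A"),
    min_delta_pS = c(12, 7, 3, 6, 5, 34, 34, 6, 46, 18, NA, 130),
    source = c("3' lead", "5' lead", "3' lead WT", "3' lead MT", "single nt",
               "3' lead", "3' lead", "3' lead", "5' lead", "3' lead",
               "literature", "this pipeline's reference device"),
    stringsAsFactors = FALSE)
}
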