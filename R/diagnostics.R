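#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half; with m resulting sequences of length n,
#' W = mean within-sequence variance, B/n = variance of sequence means, and
#' Rhat = sqrt(((n-1)/n * W + B/n) / W). Values near 1 indicate convergence.
#'
#' @param x Matrix of draws, iterations by chains (>= 2 chains, length >= 4).
#' @return Rhat (numeric scalar); 1 with a warning if every sequence is
#'   constant.
#' @export
gelman_rubin <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 4)
    stop_data("need >= 2 chains of length >= 4")
  half <- nrow(x) %/% 2
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[half + seq_len(half), , drop = FALSE])
  W <- mean(apply(splits, 2, stats::var))
  if (W == 0) {
    warning("zero within-chain variance; Rhat defined as 1")
    return(1)
  }
  B_over_n <- stats::var(colMeans(splits))
  n <- half
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS with Geyer's initial-positive-sequence
#' truncation: chain autocorrelations are averaged across chains, summed over
#' consecutive lag pairs while the pair sums stay positive, and
#' ESS = total draws / (1 + 2 * sum of retained autocorrelations), capped at
#' the total number of retained draws.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return ESS (numeric scalar); total draws with a warning for constant
#'   chains.
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 1 || n < 4) stop_data("need chains of length >= 4")
  total <- n * m
  vars <- apply(x, 2, stats::var)
  if (all(vars == 0)) {
    warning("constant chains; ESS reported as total draws")
    return(total)
  }
  max_lag <- min(n - 1, 1000)
  # mean autocorrelation across chains, weighted by chain variance
  rho <- rowMeans(sapply(seq_len(m), function(ch) {
    if (vars[ch] == 0) return(rep(0, max_lag))
    a <- stats::acf(x[, ch], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
    as.numeric(a)
  }))
  tau <- 1
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  min(total, total / tau)
}

#' Deviance information criterion
#'
#' D(theta) = -2 log p(y | theta); DIC = mean deviance + pD with
#' pD = mean deviance - deviance at the posterior mean of the parameters
#' (the classic JAGS pD variant). A negative pD is reported with a warning.
#'
#' @param chains A [run_mcmc()] result.
#' @return list(dic, mean_deviance, pD, deviance_at_mean).
#' @export
dic <- function(chains) {
  dev <- deviance_draws(chains)
  d_bar <- mean(dev)
  theta_bar <- colMeans(do.call(rbind, chains$draws))
  d_hat <- deviance_at(theta_bar, chains)
  if (!is.finite(d_hat)) stop_data("non-finite deviance at the posterior mean")
  pd <- d_bar - d_hat
  if (pd < 0) warning("negative pD; model deviance surface is non-regular")
  list(dic = d_bar + pd, mean_deviance = d_bar, pD = pd,
       deviance_at_mean = d_hat)
}

# linear predictor eta (n x draws) for a block of draws
eta_matrix <- function(theta, chains) {
  design <- chains$design
  X <- design$X
  beta <- theta[, colnames(X), drop = FALSE]
  eta <- X %*% t(beta)
  if (!is.null(design$id_index)) {
    an <- paste0("alpha[", design$id_levels, "]")
    eta <- eta + t(theta[, an, drop = FALSE])[design$id_index, , drop = FALSE]
  }
  eta
}

deviance_draws <- function(chains) {
  theta <- do.call(rbind, chains$draws)
  eta <- eta_matrix(theta, chains)
  sy <- if ("sigma_y" %in% chains$param_names) theta[, "sigma_y"]
        else rep(chains$priors$fix_sigma_y, nrow(theta))
  y <- chains$design$y
  sapply(seq_len(nrow(theta)), function(d)
    -2 * sum(stats::dnorm(y, eta[, d], sy[d], log = TRUE)))
}

deviance_at <- function(theta_vec, chains) {
  theta <- matrix(theta_vec, 1, dimnames = list(NULL, names(theta_vec)))
  eta <- eta_matrix(theta, chains)[, 1]
  sy <- if ("sigma_y" %in% names(theta_vec)) theta_vec[["sigma_y"]]
        else chains$priors$fix_sigma_y
  -2 * sum(stats::dnorm(chains$design$y, eta, sy, log = TRUE))
}

#' Posterior predictive check
#'
#' For each retained draw (optionally subsampled), simulates a replicated
#' response vector from the fitted likelihood and reports, per test
#' statistic, the tail probability P(stat(y_rep) >= stat(y_obs)). For a
#' well-calibrated model the probabilities sit away from 0 and 1.
#'
#' @param chains A [run_mcmc()] result.
#' @param stats Named list of statistics of a numeric vector.
#' @param max_draws Subsample cap on the number of replicates.
#' @return Named numeric of tail probabilities in [0, 1].
#' @export
posterior_predictive_check <- function(chains,
                                       stats = list(mean = mean, sd = stats::sd,
                                                    min = min, max = max),
                                       max_draws = 1000) {
  theta <- do.call(rbind, chains$draws)
  if (nrow(theta) > max_draws)
    theta <- theta[round(seq(1, nrow(theta), length.out = max_draws)), ,
                   drop = FALSE]
  eta <- eta_matrix(theta, chains)
  sy <- if ("sigma_y" %in% chains$param_names) theta[, "sigma_y"]
        else rep(chains$priors$fix_sigma_y, nrow(theta))
  y <- chains$design$y
  n <- length(y)
  obs <- vapply(stats, function(f) f(y), numeric(1))
  ge <- matrix(0, nrow(theta), length(stats))
  for (d in seq_len(nrow(theta))) {
    yrep <- stats::rnorm(n, eta[, d], sy[d])
    ge[d, ] <- vapply(seq_along(stats),
                      function(k) as.numeric(stats[[k]](yrep) >= obs[k]),
                      numeric(1))
  }
  out <- colMeans(ge)
  names(out) <- names(stats)
  out
}

#' Classify a coefficient's credibility from its interval quantiles
#'
#' The coefficient-display shading rule: "strong" if 0 lies outside the 95\%
#' credible interval (2.5-97.5\%), "moderate" if 0 lies outside the 50\%
#' interval (25-75\%) but inside the 95\%, "none" if 0 lies inside the 50\%
#' interval.
#'
#' @param q2.5,q25,q75,q97.5 Interval quantiles, or pass a one-row
#'   [summarize_posterior()] data.frame as the first argument.
#' @return "strong", "moderate" or "none".
#' @export
classify_credibility <- function(q2.5, q25 = NULL, q75 = NULL, q97.5 = NULL) {
  if (is.data.frame(q2.5)) {
    row <- q2.5
    q25 <- row$q25; q75 <- row$q75; q97.5 <- row$q97.5; q2.5 <- row$q2.5
  }
  if (q2.5 > 0 || q97.5 < 0) return("strong")
  if (q25 > 0 || q75 < 0) return("moderate")
  "none"
}

#' Coefficient display of composition slopes with 50/95\% intervals
#'
#' Draws the composition slopes by group with their 50\% and 95\% credible
#' intervals; point shading encodes [classify_credibility()]: closed black =
#' strong, closed gray = moderate, open gray = none.
#'
#' @param summary A [summarize_posterior()] data.frame.
#' @param file Output path (.svg or .png); NULL draws on the current device.
#' @param main Plot title.
#' @return Invisibly, the plotted subset with a `credibility` column.
#' @export
plot_credibility <- function(summary, file = NULL, main = "Composition slopes") {
  rows <- summary[summary$parameter %in% cmp_labels, , drop = FALSE]
  if (nrow(rows) == 0) stop_data("no composition-slope rows in summary")
  rows$credibility <- vapply(seq_len(nrow(rows)), function(i)
    classify_credibility(rows[i, ]), character(1))
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 4.5)
    else grDevices::png(file, width = 700, height = 450)
    on.exit(grDevices::dev.off())
  }
  k <- nrow(rows)
  ylim <- range(rows$q2.5, rows$q97.5, 0)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = "Posterior effect (log index scale)",
                 main = main)
  graphics::axis(1, at = seq_len(k), labels = rows$parameter, las = 2,
                 cex.axis = 0.8)
  graphics::abline(h = 0, lty = 2, col = "gray60")
  for (i in seq_len(k)) {
    graphics::segments(i, rows$q2.5[i], i, rows$q97.5[i], col = "gray40")
    graphics::segments(i, rows$q25[i], i, rows$q75[i], lwd = 3, col = "gray40")
    pch <- switch(rows$credibility[i], strong = 19, moderate = 19, none = 1)
    col <- switch(rows$credibility[i], strong = "black", moderate = "gray55",
                  none = "gray55")
    graphics::points(i, rows$mean[i], pch = pch, col = col, cex = 1.2)
  }
  invisible(rows)
}
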