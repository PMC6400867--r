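test_that("split-chain Rhat: white noise near 1, separated chains far above, constants warn", {
  set.seed(41)
  x <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(gelman_rubin(x) - 1), 0.01)

  y <- cbind(rnorm(1000, 0), rnorm(1000, 100))
  # formula oracle computed directly on the split sequences
  half <- 500
  sp <- cbind(y[1:half, ], y[half + (1:half), ])
  W <- mean(apply(sp, 2, var))
  B_over_n <- var(colMeans(sp))
  expect_equal(gelman_rubin(y),
               sqrt(((half - 1) / half * W + B_over_n) / W), tolerance = 1e-12)
  expect_gt(gelman_rubin(y), 10)

  expect_warning(r <- gelman_rubin(matrix(2, 100, 2)), "zero within-chain")
  expect_equal(r, 1)
  expect_error(gelman_rubin(matrix(1:3, 3, 1)), ">= 2 chains")
})

test_that("ESS: near-total for iid draws, AR(1) closed form, capped, constants warn", {
  set.seed(43)
  iid <- matrix(rnorm(7500), 2500, 3)
  ess <- effective_sample_size(iid)
  expect_gte(ess, 6500); expect_lte(ess, 7500)

  rho <- 0.9
  ar <- sapply(1:3, function(i) as.numeric(arima.sim(list(ar = rho), 4000)))
  got <- effective_sample_size(ar)
  expected <- 12000 * (1 - rho) / (1 + rho)
  expect_lt(abs(got - expected) / expected, 0.25)
  expect_lte(got, 12000)

  expect_warning(e <- effective_sample_size(matrix(5, 100, 2)), "constant")
  expect_equal(e, 200)
})

test_that("Rhat and ESS are invariant to affine transformation of the draws", {
  set.seed(47)
  x <- sapply(1:3, function(i) as.numeric(arima.sim(list(ar = 0.5), 800)))
  y <- 3 - 2.5 * x
  expect_equal(gelman_rubin(y), gelman_rubin(x), tolerance = 1e-10)
  expect_equal(effective_sample_size(y), effective_sample_size(x),
               tolerance = 1e-6)
})

test_that("DIC: point-mass chains give pD = 0 and DIC = D(theta0)", {
  y <- c(-0.3, 0.2, 0.5)
  d <- toy_design(y, matrix(1, 3, 1, dimnames = list(NULL, "mu")))
  theta0 <- cbind(mu = rep(0.1, 200), sigma_y = rep(0.9, 200))
  ch <- fake_chains(list(theta0, theta0), d, toy_priors())
  out <- dic(ch)
  expect_equal(out$pD, 0, tolerance = 1e-10)
  expect_equal(out$dic, -2 * sum(dnorm(y, 0.1, 0.9, log = TRUE)),
               tolerance = 1e-10)
})

test_that("DIC matches an independent per-draw recomputation on a real fit", {
  set.seed(51)
  obs <- simulate_observations(n_ig = 5, n_cg = 3)
  spec <- model_spec("BHLM2")
  fit <- run_mcmc(build_design(obs, spec), spec$prior_set, tiny_mcmc(seed = 8))
  out <- dic(fit)
  # brute-force oracle: loop over draws, recompute the linear predictor rowwise
  all_draws <- do.call(rbind, fit$draws)
  d <- fit$design
  dev <- numeric(nrow(all_draws))
  for (k in seq_len(nrow(all_draws))) {
    th <- all_draws[k, ]
    eta <- as.numeric(d$X %*% th[colnames(d$X)]) +
      th[paste0("alpha[", d$id_levels, "]")][d$id_index]
    dev[k] <- -2 * sum(dnorm(d$y, eta, th["sigma_y"], log = TRUE))
  }
  th_bar <- colMeans(all_draws)
  eta_bar <- as.numeric(d$X %*% th_bar[colnames(d$X)]) +
    th_bar[paste0("alpha[", d$id_levels, "]")][d$id_index]
  d_hat <- -2 * sum(dnorm(d$y, eta_bar, th_bar["sigma_y"], log = TRUE))
  expect_equal(out$mean_deviance, mean(dev), tolerance = 1e-8)
  expect_equal(out$pD, mean(dev) - d_hat, tolerance = 1e-8)
  expect_equal(out$dic, out$mean_deviance + out$pD, tolerance = 1e-12)
})

test_that("an irrelevant covariate does not decrease mean deviance on average", {
  delta <- sapply(1:10, function(seed) {
    set.seed(seed)
    n <- 60
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, 0, 0.7)
    junk <- rnorm(n)
    base <- toy_design(y, cbind(x = x))
    extra <- toy_design(y, cbind(x = x, junk = junk))
    cfg <- mcmc_config(chains = 2, iterations = 500, burn_in = 250,
                       thinning = 1, seed = seed)
    dic(run_mcmc(extra, toy_priors(prec_cov = 1), cfg))$mean_deviance -
      dic(run_mcmc(base, toy_priors(prec_cov = 1), cfg))$mean_deviance
  })
  expect_gte(mean(delta), 0)
})

test_that("posterior predictive checks are calibrated under the true model and flag gross misfit", {
  probs <- sapply(1:10, function(seed) {
    set.seed(seed)
    n <- 50
    x <- rnorm(n)
    y <- 0.8 * x + rnorm(n, 0, 1)
    d <- toy_design(y, cbind(x = x))
    fit <- run_mcmc(d, toy_priors(prec_cov = 1),
                    mcmc_config(chains = 2, iterations = 800, burn_in = 400,
                                thinning = 1, seed = seed))
    posterior_predictive_check(fit, max_draws = 200)
  })
  expect_true(all(probs >= 0 & probs <= 1))
  inside <- colSums(probs > 0.05 & probs < 0.95) == nrow(probs)
  expect_gte(sum(inside), 9)

  # shift y_obs by +10 sd: the mean statistic's tail probability collapses
  set.seed(3)
  y <- rnorm(40)
  d <- toy_design(y, matrix(1, 40, 1, dimnames = list(NULL, "mu")))
  fit <- run_mcmc(d, toy_priors(prec_cov = 1),
                  mcmc_config(chains = 2, iterations = 600, burn_in = 300,
                              thinning = 1, seed = 4))
  fit$design$y <- fit$design$y + 10
  p <- posterior_predictive_check(fit, max_draws = 200)
  expect_lt(p[["mean"]], 0.01)
})

test_that("credibility classification follows the interval shading rule and is monotone", {
  expect_equal(classify_credibility(q2.5 = -1, q25 = -0.5, q75 = 0.5, q97.5 = 1),
               "none")
  expect_equal(classify_credibility(q2.5 = -0.1, q25 = 0.2, q75 = 0.8, q97.5 = 1.4),
               "moderate")
  expect_equal(classify_credibility(q2.5 = 0.3, q25 = 0.5, q75 = 0.9, q97.5 = 1.2),
               "strong")

  # widening intervals never moves the label toward "strong"
  rank <- c(none = 0, moderate = 1, strong = 2)
  set.seed(61)
  for (i in 1:50) {
    q <- sort(rnorm(4, mean = runif(1, -1, 1)))
    before <- classify_credibility(q[1], q[2], q[3], q[4])
    w <- abs(rnorm(1)) + 0.1
    after <- classify_credibility(q[1] - w, q[2] - w, q[3] + w, q[4] + w)
    expect_lte(rank[[after]], rank[[before]])
  }
})

test_that("plot_credibility writes an SVG keyed by the classification", {
  set.seed(6)
  obs <- simulate_observations(n_ig = 5, n_cg = 3)
  spec <- model_spec("BHLM2")
  fit <- run_mcmc(build_design(obs, spec), spec$prior_set, tiny_mcmc(seed = 3))
  s <- summarize_posterior(fit)
  f <- withr::local_tempfile(fileext = ".svg")
  rows <- plot_credibility(s, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_equal(nrow(rows), 6)
  expect_true(all(rows$credibility %in% c("strong", "moderate", "none")))
})
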