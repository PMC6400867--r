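obs_row <- function(y = 0, id = "S001", group = "IG", gender = "female",
                    season = "fall", comp = c(0.5, 0.3, 0.2),
                    timepoint = NA_character_) {
  data.frame(y = y, id = id, group = group, gender = gender, season = season,
             sb = comp[1], lpa = comp[2], mvpa = comp[3],
             timepoint = timepoint, stringsAsFactors = FALSE)
}

test_that("build_design expands the 6-column group-by-composition block", {
  spec <- model_spec("BHLM2")  # AUCi: no timepoint covariate
  d <- build_design(obs_row(group = "IG", comp = c(0.5, 0.3, 0.2)), spec)
  expect_equal(unname(d$X[1, 1:6]), c(0, 0, 0, 0.5, 0.3, 0.2))
  expect_equal(colnames(d$X)[1:6],
               c("SB (CG)", "LPA (CG)", "MVPA (CG)",
                 "SB (IG)", "LPA (IG)", "MVPA (IG)"))

  two <- rbind(obs_row(id = "S001", group = "CG"),
               obs_row(id = "S002", group = "IG"))
  d2 <- build_design(two, spec)
  # group blocks occupy disjoint column triples
  expect_true(all(d2$X[1, 4:6] == 0) && all(d2$X[1, 1:3] > 0))
  expect_true(all(d2$X[2, 1:3] == 0) && all(d2$X[2, 4:6] > 0))
})

test_that("build_design bookkeeping matches group-wise composition sums on a full cohort", {
  set.seed(3)
  obs <- simulate_observations(n_ig = 10, n_cg = 5)
  d <- build_design(obs, model_spec("BHLM4"))
  cg <- obs$group == "CG"
  expect_equal(unname(colSums(d$X[, 1:3])),
               unname(colSums(as.matrix(obs[cg, c("sb", "lpa", "mvpa")]))))
  expect_equal(unname(colSums(d$X[, 4:6])),
               unname(colSums(as.matrix(obs[!cg, c("sb", "lpa", "mvpa")]))))
  expect_equal(length(d$id_levels), 15)
  expect_equal(d$id_index, match(obs$id, sort(unique(obs$id))))
})

test_that("build_design rejects bad levels, NAs, broken closure, missing timepoint", {
  spec2 <- model_spec("BHLM2")
  expect_error(build_design(obs_row(group = "XX"), spec2), "unknown group.*1")
  bad <- obs_row(); bad$y <- NA
  expect_error(build_design(bad, spec2), "NA in required field y")
  open <- obs_row(comp = c(0.5, 0.3, 0.3))
  expect_error(build_design(open, spec2), "not closed")
  expect_error(build_design(obs_row(), model_spec("BHLM1")), "timepoint")
  ok <- build_design(obs_row(timepoint = "noon"), model_spec("BHLM1"))
  expect_true("timepoint[noon]" %in% colnames(ok$X))
})

test_that("model_spec wires analyte, index, timepoint and priors consistently", {
  s1 <- model_spec("BHLM1"); s4 <- model_spec("BHLM4")
  expect_equal(s1$analyte, "cortisol"); expect_equal(s1$index, "PR")
  expect_true(s1$include_timepoint)
  expect_equal(s4$analyte, "cfdna"); expect_equal(s4$index, "AUCi")
  expect_false(s4$include_timepoint)
  # precision reading: cortisol N(0, 5) -> sd 1/sqrt(5); cfDNA super-vague
  expect_equal(s1$prior_set$prec_cov, 5)
  expect_equal(s4$prior_set$prec_cov, 1e-6)
  expect_equal(s4$prior_set$hc_scale_y, 25)
  # variance reading flag
  pv <- prior_set("cortisol", normal_second_arg = "variance")
  expect_equal(pv$prec_cov, 1 / 5)
})

test_that("log_posterior equals a term-by-term hand oracle", {
  spec <- model_spec("BHLM2")
  d <- build_design(obs_row(y = 0, comp = c(1, 0, 0), group = "IG"), spec)
  pr <- spec$prior_set
  params <- list(alpha = 0, beta = rep(0, ncol(d$X)), mu_alpha = 0,
                 sigma_y = 1, sigma_alpha = 1)
  # oracle written out term by term
  hc <- function(x, s) log(2) - log(pi * s) - log1p((x / s)^2)
  oracle <- dnorm(0, 0, 1, log = TRUE) +              # likelihood of y = 0
    dnorm(0, 0, 1, log = TRUE) +                      # alpha_1 ~ N(0, 1)
    6 * dnorm(0, 0, 1, log = TRUE) +                  # beta_cmp ~ N(mu_a, 1)
    dnorm(0, 0, 1 / sqrt(5), log = TRUE) +            # mu_a ~ N(0, prec 5)
    1 * dnorm(0, 0, 1 / sqrt(5), log = TRUE) +        # gender slope prior
    hc(1, 5) + hc(1, 5)                               # sigma_y, sigma_alpha
  expect_equal(log_posterior(params, d, pr), oracle, tolerance = 1e-12)

  # rejected, not thrown, outside the support
  params$sigma_y <- -1
  expect_identical(log_posterior(params, d, pr), -Inf)
})

test_that("duplicating rows adds exactly the likelihood term; order is irrelevant", {
  set.seed(4)
  obs <- simulate_observations(n_ig = 4, n_cg = 2)
  spec <- model_spec("BHLM2")
  d1 <- build_design(obs, spec)
  d2 <- build_design(rbind(obs, obs), spec)
  pr <- spec$prior_set
  params <- list(alpha = rnorm(6, 0, 0.3), beta = rnorm(ncol(d1$X), 0, 0.5),
                 mu_alpha = 0.2, sigma_y = 0.8, sigma_alpha = 0.5)
  eta <- as.numeric(d1$X %*% params$beta) + params$alpha[d1$id_index]
  loglik <- sum(dnorm(d1$y, eta, params$sigma_y, log = TRUE))
  expect_equal(log_posterior(params, d2, pr),
               log_posterior(params, d1, pr) + loglik, tolerance = 1e-9)

  perm <- sample(nrow(obs))
  d3 <- build_design(obs[perm, ], spec)
  expect_equal(log_posterior(params, d3, pr), log_posterior(params, d1, pr),
               tolerance = 1e-9)
})

test_that("the full sampler reproduces the conjugate closed form on a toy", {
  set.seed(21)
  n <- 10
  y <- rnorm(n, 1.5, 1)
  d <- toy_design(y, matrix(1, n, 1, dimnames = list(NULL, "mu")))
  pr <- toy_priors(prec_cov = 1, fix_sigma_y = 1)
  fit <- run_mcmc(d, pr, mcmc_config(chains = 3, iterations = 1500,
                                     burn_in = 500, thinning = 1, seed = 2))
  draws <- do.call(rbind, fit$draws)[, "mu"]
  post_mean <- n * mean(y) / (n + 1)
  post_sd <- sqrt(1 / (n + 1))
  mcse <- post_sd / sqrt(length(draws) / 2)  # conservative effective n
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
  expect_lt(abs(sd(draws) - post_sd), 0.05)
})

test_that("a zero-data run recovers the prior moments", {
  d <- toy_design(numeric(0),
                  matrix(numeric(0), 0, 1, dimnames = list(NULL, "gender[male]")))
  pr <- toy_priors(prec_cov = 5, fix_sigma_y = 1)
  fit <- run_mcmc(d, pr, mcmc_config(chains = 3, iterations = 3000,
                                     burn_in = 1000, thinning = 1, seed = 9))
  draws <- do.call(rbind, fit$draws)[, "gender[male]"]
  expect_lt(abs(mean(draws)), 3 * (1 / sqrt(5)) / sqrt(length(draws)))
  expect_equal(sd(draws), 1 / sqrt(5), tolerance = 0.05)
})

test_that("run_mcmc retains (iterations - burn_in)/thinning draws per chain and is seed-stable", {
  set.seed(6)
  obs <- simulate_observations(n_ig = 4, n_cg = 2)
  spec <- model_spec("BHLM2")
  d <- build_design(obs, spec)
  cfg <- tiny_mcmc(seed = 33)
  fit <- run_mcmc(d, spec$prior_set, cfg)
  expect_length(fit$draws, 2)
  expect_equal(nrow(fit$draws[[1]]), (600 - 300) / 2)
  fit2 <- run_mcmc(d, spec$prior_set, cfg)
  expect_identical(fit$draws, fit2$draws)
  # distinct chains are genuinely distinct
  expect_false(identical(fit$draws[[1]], fit$draws[[2]]))
})

test_that("summarize_posterior pools draws, orders quantiles, labels slopes", {
  set.seed(6)
  obs <- simulate_observations(n_ig = 5, n_cg = 3)
  spec <- model_spec("BHLM2")
  fit <- run_mcmc(build_design(obs, spec), spec$prior_set, tiny_mcmc(seed = 3))
  s <- summarize_posterior(fit)
  expect_true(all(c("SB (CG)", "MVPA (IG)", "mu_alpha", "sigma_y",
                    "sigma_alpha") %in% s$parameter))
  qs <- as.matrix(s[, c("q2.5", "q25", "q50", "q75", "q97.5")])
  expect_true(all(diff(t(qs)) >= 0))
  expect_true(all(s$ess <= sum(sapply(fit$draws, nrow)) + 1e-9))
  # invariant to chain relabeling
  flipped <- fit; flipped$draws <- rev(fit$draws)
  expect_equal(summarize_posterior(flipped), s, tolerance = 1e-12)
})
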