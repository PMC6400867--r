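# Shared fixtures: everything is generated in code at test time.

# a noise-free, effect-free parameter set for closed-form checks
quiet_params <- function(intercept = log(10), slope_ig = -0.2, slope_cg = -0.1) {
  true_params(
    cortisol_intercept = c(IG = intercept, CG = intercept),
    cortisol_slope = c(IG = slope_ig, CG = slope_cg),
    sigma_alpha = 0, sigma_y = 0, sigma_slope = 0,
    beta_cmp = list(cortisol = list(IG = c(0, 0, 0), CG = c(0, 0, 0)),
                    cfdna = list(IG = c(0, 0, 0), CG = c(0, 0, 0))),
    season_effect = c(fall = 0, spring = 0, summer = 0),
    gender_effect = 0)
}

one_student <- function(group = "IG", gender = "female", id = "S001") {
  data.frame(id = id, group = group, gender = gender, stringsAsFactors = FALSE)
}

zero_effects <- list(intercept = 0, intercept_cfdna = 0, slope = 0)

# short MCMC schedule for unit tests (not the published run)
tiny_mcmc <- function(seed = 1, chains = 2, iterations = 600, burn_in = 300,
                      thinning = 2) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              thinning = thinning, seed = seed)
}

# a generic design outside build_design(), for toy models:
# y ~ N(X beta, sigma_y^2) with N(0, 1/prec) priors on beta
toy_design <- function(y, X, cmp_cols = integer(0)) {
  structure(list(y = y, X = X, cmp_cols = cmp_cols,
                 id_index = NULL, id_levels = NULL),
            class = "bhlm_design")
}

toy_priors <- function(prec_cov = 1, fix_sigma_y = NULL) {
  p <- prior_set("cortisol", fix_sigma_y = fix_sigma_y)
  p$prec_cov <- prec_cov
  p
}

# manually assembled chains object (for diagnostics unit tests)
fake_chains <- function(draw_list, design, priors) {
  structure(list(draws = draw_list, param_names = colnames(draw_list[[1]]),
                 design = design, priors = priors,
                 config = mcmc_config(chains = length(draw_list),
                                      iterations = 2 * nrow(draw_list[[1]]),
                                      burn_in = nrow(draw_list[[1]]),
                                      thinning = 1)),
            class = "bhlm_chains")
}
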