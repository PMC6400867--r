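#' Model specification for the four hierarchical models
#'
#' BHLM 1: cortisol PR; BHLM 2: cortisol AUCi; BHLM 3: cfDNA PR;
#' BHLM 4: cfDNA AUCi. The PR models (1, 3) additionally include the
#' timepoint covariate (midmorning/noon) because PR is emitted once per
#' post-baseline timepoint. Prior sets follow the analyte.
#'
#' @param model_id One of "BHLM1".."BHLM4".
#' @param prior_set Optional [prior_set()] override; defaults to the
#'   analyte's set.
#' @return A list of class \code{model_spec}.
#' @export
model_spec <- function(model_id = c("BHLM1", "BHLM2", "BHLM3", "BHLM4"),
                       prior_set = NULL) {
  model_id <- match.arg(model_id)
  analyte <- if (model_id %in% c("BHLM1", "BHLM2")) "cortisol" else "cfdna"
  index <- if (model_id %in% c("BHLM1", "BHLM3")) "PR" else "AUCi"
  structure(list(model_id = model_id, analyte = analyte, index = index,
                 include_timepoint = index == "PR",
                 prior_set = prior_set %||% compstress::prior_set(analyte)),
            class = "model_spec")
}

#' Prior set for a hierarchical model
#'
#' Encodes the two published prior columns. Under the default JAGS-style
#' precision reading: random intercepts alpha_id ~ N(0, sigma_alpha^2);
#' composition slopes beta_cmp ~ N(mu_alpha, 1) (shared ridge prior,
#' hierarchically centered on the intercept hyper-mean mu_alpha); for the
#' cortisol set mu_alpha and the covariate slopes get N(0, precision 5)
#' (sd ~ 0.447) and both scales get half-Cauchy(0, 5); for the super-vague
#' cfDNA reference set the Normals get precision 1e-6 (sd 1000) and the
#' scales half-Cauchy(0, 25).
#'
#' @param analyte "cortisol" or "cfdna".
#' @param normal_second_arg Read the second Normal argument as "precision"
#'   (JAGS convention, default) or "variance".
#' @param half_cauchy_on Place the half-Cauchy on the "sd" (default, the
#'   usual recommendation) or on the "variance" as literally notated.
#' @param fix_sigma_y,fix_sigma_alpha Optional fixed values for the scales
#'   (used by reduced/toy models); NULL means sampled.
#' @return A list of class \code{prior_set} with resolved sds/precisions.
#' @export
prior_set <- function(analyte = c("cortisol", "cfdna"),
                      normal_second_arg = c("precision", "variance"),
                      half_cauchy_on = c("sd", "variance"),
                      fix_sigma_y = NULL, fix_sigma_alpha = NULL) {
  analyte <- match.arg(analyte)
  normal_second_arg <- match.arg(normal_second_arg)
  half_cauchy_on <- match.arg(half_cauchy_on)
  arg2 <- if (analyte == "cortisol") 5 else 1e-6
  hc <- if (analyte == "cortisol") 5 else 25
  to_prec <- function(a) if (normal_second_arg == "precision") a else 1 / a
  structure(list(analyte = analyte,
                 normal_second_arg = normal_second_arg,
                 half_cauchy_on = half_cauchy_on,
                 prec_cmp = 1,            # N(mu_alpha, 1): same under both readings
                 prec_cov = to_prec(arg2),
                 prec_mu = to_prec(arg2),
                 hc_scale_y = hc, hc_scale_alpha = hc,
                 fix_sigma_y = fix_sigma_y,
                 fix_sigma_alpha = fix_sigma_alpha),
            class = "prior_set")
}

#' MCMC configuration
#'
#' Defaults reproduce the published run: 50,000 iterations per chain with a
#' 25,000 burn-in and thinning 10, i.e. 2,500 retained draws per chain;
#' 3 chains give 7,500 retained draws total.
#'
#' @param chains Number of chains.
#' @param iterations,burn_in,thinning Per-chain schedule.
#' @param seed Integer seed; chain c uses seed + c - 1.
#' @return A list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 3, iterations = 50000, burn_in = 25000,
                        thinning = 10, seed = 1L) {
  if (burn_in >= iterations) stop_config("burn_in must be < iterations")
  if (thinning < 1) stop_config("thinning must be >= 1")
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thinning = as.integer(thinning),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

cmp_labels <- c("SB (CG)", "LPA (CG)", "MVPA (CG)",
                "SB (IG)", "LPA (IG)", "MVPA (IG)")

#' Build the model design from observation rows
#'
#' The composition block has six columns — each behavior fraction interacted
#' with the group indicator — so every behavior receives a group-specific
#' slope (labels "SB (CG)" ... "MVPA (IG)"). Season, gender and (for PR
#' models) timepoint enter as indicator contrasts with reference levels
#' fall / female / midmorning. Ids are mapped to consecutive indices in
#' sorted order.
#'
#' @param observations data.frame with columns y, id, group, gender, season,
#'   sb, lpa, mvpa and (PR models) timepoint.
#' @param spec A [model_spec()].
#' @return A list of class \code{bhlm_design}: y, X, cmp_cols, id_index,
#'   id_levels, spec.
#' @export
build_design <- function(observations, spec) {
  obs <- observations
  if (nrow(obs) == 0) stop_data("no observations to model")
  req <- c("y", "id", "group", "gender", "season", "sb", "lpa", "mvpa")
  for (f in req) {
    if (is.null(obs[[f]])) stop_data("missing required field ", f)
    bad <- which(is.na(obs[[f]]))
    if (length(bad) > 0)
      stop_data("NA in required field ", f, " at row(s) ",
                paste(utils::head(bad, 10), collapse = ", "))
  }
  bad_grp <- which(!obs$group %in% c("CG", "IG"))
  if (length(bad_grp) > 0)
    stop_data("unknown group level at row(s) ", paste(bad_grp, collapse = ", "))
  bad_gdr <- which(!obs$gender %in% c("female", "male"))
  if (length(bad_gdr) > 0)
    stop_data("unknown gender level at row(s) ", paste(bad_gdr, collapse = ", "))
  closure <- abs(obs$sb + obs$lpa + obs$mvpa - 1)
  bad_cmp <- which(closure > 1e-8 | obs$sb < 0 | obs$lpa < 0 | obs$mvpa < 0)
  if (length(bad_cmp) > 0)
    stop_data("composition not closed at row(s) ", paste(bad_cmp, collapse = ", "))
  if (spec$include_timepoint) {
    bad_tp <- which(is.na(obs$timepoint) | !obs$timepoint %in% c("midmorning", "noon"))
    if (length(bad_tp) > 0)
      stop_data("PR model needs timepoint midmorning/noon at row(s) ",
                paste(bad_tp, collapse = ", "))
  }

  n <- nrow(obs)
  cg <- as.numeric(obs$group == "CG")
  ig <- 1 - cg
  X <- cbind(obs$sb * cg, obs$lpa * cg, obs$mvpa * cg,
             obs$sb * ig, obs$lpa * ig, obs$mvpa * ig)
  colnames(X) <- cmp_labels
  season_levels <- c("fall", setdiff(sort(unique(obs$season)), "fall"))
  for (s in season_levels[-1]) {
    X <- cbind(X, as.numeric(obs$season == s))
    colnames(X)[ncol(X)] <- paste0("season[", s, "]")
  }
  X <- cbind(X, as.numeric(obs$gender == "male"))
  colnames(X)[ncol(X)] <- "gender[male]"
  if (spec$include_timepoint) {
    X <- cbind(X, as.numeric(obs$timepoint == "noon"))
    colnames(X)[ncol(X)] <- "timepoint[noon]"
  }
  id_levels <- sort(unique(as.character(obs$id)))
  structure(list(y = as.numeric(obs$y), X = X, cmp_cols = 1:6,
                 id_index = match(as.character(obs$id), id_levels),
                 id_levels = id_levels,
                 season_levels = season_levels, spec = spec),
            class = "bhlm_design")
}

# column-wise prior precisions and (mu_alpha-dependent) prior means
design_prior_prec <- function(design, priors) {
  p <- ncol(design$X)
  prec <- rep(priors$prec_cov, p)
  prec[design$cmp_cols] <- priors$prec_cmp
  prec
}

#' Joint log posterior density of a parameter state
#'
#' Sum of the Normal likelihood of y given the linear predictor and sigma_y,
#' the N(0, sigma_alpha^2) terms for the random intercepts, the shared
#' N(mu_alpha, 1) ridge terms for the six composition slopes, the hyperprior
#' on mu_alpha, the Normal priors on the remaining slopes, and the
#' half-Cauchy priors on the scales. Returns -Inf (a rejected state, not an
#' error) for non-positive scales.
#'
#' @param params list(alpha, beta, mu_alpha, sigma_y, sigma_alpha); alpha may
#'   be NULL for designs without random intercepts.
#' @param design A [build_design()] result (or compatible list).
#' @param priors A [prior_set()].
#' @return Log density (numeric scalar).
#' @export
log_posterior <- function(params, design, priors) {
  sy <- params$sigma_y %||% priors$fix_sigma_y
  sa <- params$sigma_alpha %||% priors$fix_sigma_alpha
  if (!is.null(sy) && sy <= 0) return(-Inf)
  if (!is.null(sa) && sa <= 0) return(-Inf)
  eta <- as.numeric(design$X %*% params$beta)
  if (!is.null(design$id_index) && !is.null(params$alpha))
    eta <- eta + params$alpha[design$id_index]
  lp <- sum(stats::dnorm(design$y, eta, sy, log = TRUE))
  if (!is.null(params$alpha) && !is.null(sa))
    lp <- lp + sum(stats::dnorm(params$alpha, 0, sa, log = TRUE))
  mu <- params$mu_alpha %||% 0
  cmp <- design$cmp_cols
  if (length(cmp) > 0) {
    lp <- lp + sum(stats::dnorm(params$beta[cmp], mu, 1 / sqrt(priors$prec_cmp),
                                log = TRUE))
    lp <- lp + stats::dnorm(mu, 0, 1 / sqrt(priors$prec_mu), log = TRUE)
  }
  cov_cols <- setdiff(seq_along(params$beta), cmp)
  if (length(cov_cols) > 0)
    lp <- lp + sum(stats::dnorm(params$beta[cov_cols], 0,
                                1 / sqrt(priors$prec_cov), log = TRUE))
  if (is.null(priors$fix_sigma_y))
    lp <- lp + scale_log_prior(sy, priors$hc_scale_y, priors$half_cauchy_on)
  if (!is.null(params$alpha) && is.null(priors$fix_sigma_alpha))
    lp <- lp + scale_log_prior(sa, priors$hc_scale_alpha, priors$half_cauchy_on)
  lp
}

scale_log_prior <- function(sigma, scale, on) {
  if (on == "sd") dhalfcauchy_log(sigma, scale)
  else dhalfcauchy_log(sigma^2, scale) + log(2 * sigma)
}

# univariate stepping-out slice sampler on an unbounded axis
slice_sample <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  y <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Run the Gibbs/slice MCMC sampler
#'
#' Conjugate Gibbs blocks for the slope vector (jointly multivariate Normal),
#' the random intercepts and the hyper-mean mu_alpha; stepping-out slice
#' updates on the log scale for sigma_y and sigma_alpha under their
#' half-Cauchy priors. Chains are initialized overdispersed from the priors
#' and are fully reproducible from \code{config$seed}.
#'
#' @param design A [build_design()] result.
#' @param priors A [prior_set()].
#' @param config An [mcmc_config()].
#' @return A list of class \code{bhlm_chains}: \code{draws} (one retained
#'   draws-by-parameter matrix per chain), \code{param_names}, plus the
#'   design, priors and config used.
#' @export
run_mcmc <- function(design, priors, config = mcmc_config()) {
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  has_alpha <- !is.null(design$id_index)
  J <- if (has_alpha) length(design$id_levels) else 0
  cmp <- design$cmp_cols
  has_mu <- length(cmp) > 0

  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  if (has_alpha) {
    grp <- factor(design$id_index, levels = seq_len(J))
    TX <- rowsum(X, grp)                  # J x p column sums of X by id
    Ty <- as.numeric(rowsum(y, grp))
    n_j <- as.numeric(table(grp))
  }
  P0 <- design_prior_prec(design, priors)
  prior_mean_mask <- as.numeric(seq_len(p) %in% cmp)

  n_keep <- (config$iterations - config$burn_in) %/% config$thinning
  pnames <- c(if (has_alpha) paste0("alpha[", design$id_levels, "]"),
              colnames(X),
              if (has_mu) "mu_alpha",
              if (is.null(priors$fix_sigma_y)) "sigma_y",
              if (has_alpha && is.null(priors$fix_sigma_alpha)) "sigma_alpha")

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch - 1L)
    # overdispersed initialization from the priors (scales truncated to a
    # numerically safe band; retried if the joint density is non-finite)
    for (try in 1:20) {
      mu_alpha <- if (has_mu) stats::rnorm(1, 0, 1 / sqrt(priors$prec_mu)) else 0
      beta <- stats::rnorm(p, prior_mean_mask * mu_alpha,
                           1 / sqrt(P0))
      sigma_y <- priors$fix_sigma_y %||%
        min(max(abs(stats::rcauchy(1, 0, priors$hc_scale_y)), 0.05), 50)
      sigma_alpha <- if (!has_alpha) NULL else priors$fix_sigma_alpha %||%
        min(max(abs(stats::rcauchy(1, 0, priors$hc_scale_alpha)), 0.05), 50)
      alpha <- if (has_alpha) stats::rnorm(J, 0, sigma_alpha) else NULL
      lp <- log_posterior(list(alpha = alpha, beta = beta, mu_alpha = mu_alpha,
                               sigma_y = sigma_y, sigma_alpha = sigma_alpha),
                          design, priors)
      if (is.finite(lp)) break
      if (try == 20) stop("non-finite posterior at initialization after 20 retries")
    }

    draws <- matrix(NA_real_, n_keep, length(pnames),
                    dimnames = list(NULL, pnames))
    keep_row <- 0L
    for (it in seq_len(config$iterations)) {
      # beta | rest : N(A^-1 b, A^-1)
      A <- XtX / sigma_y^2
      diag(A) <- diag(A) + P0
      b <- Xty
      if (has_alpha) b <- b - as.numeric(crossprod(TX, alpha))
      b <- b / sigma_y^2 + P0 * (prior_mean_mask * mu_alpha)
      U <- chol(A)
      m <- backsolve(U, backsolve(U, b, transpose = TRUE))
      beta <- m + backsolve(U, stats::rnorm(p))

      # alpha | rest (vectorized over ids)
      if (has_alpha) {
        s <- Ty - as.numeric(TX %*% beta)
        prec <- n_j / sigma_y^2 + 1 / sigma_alpha^2
        alpha <- stats::rnorm(J, (s / sigma_y^2) / prec, 1 / sqrt(prec))
      }

      # mu_alpha | beta_cmp
      if (has_mu) {
        prec_mu <- length(cmp) * priors$prec_cmp + priors$prec_mu
        mu_alpha <- stats::rnorm(1, priors$prec_cmp * sum(beta[cmp]) / prec_mu,
                                 1 / sqrt(prec_mu))
      }

      # scales | rest, via slice sampling on log sigma
      if (is.null(priors$fix_sigma_y)) {
        r <- y - as.numeric(X %*% beta)
        if (has_alpha) r <- r - alpha[design$id_index]
        ss <- sum(r * r)
        logf <- function(th) {
          s <- exp(th)
          -n * th - ss / (2 * s^2) +
            scale_log_prior(s, priors$hc_scale_y, priors$half_cauchy_on) + th
        }
        sigma_y <- exp(slice_sample(log(sigma_y), logf))
      }
      if (has_alpha && is.null(priors$fix_sigma_alpha)) {
        ssa <- sum(alpha * alpha)
        logf <- function(th) {
          s <- exp(th)
          -J * th - ssa / (2 * s^2) +
            scale_log_prior(s, priors$hc_scale_alpha, priors$half_cauchy_on) + th
        }
        sigma_alpha <- exp(slice_sample(log(sigma_alpha), logf))
      }

      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thinning == 0) {
        keep_row <- keep_row + 1L
        draws[keep_row, ] <- c(if (has_alpha) alpha, beta,
                               if (has_mu) mu_alpha,
                               if (is.null(priors$fix_sigma_y)) sigma_y,
                               if (has_alpha && is.null(priors$fix_sigma_alpha))
                                 sigma_alpha)
      }
    }
    chains[[ch]] <- draws
  }
  structure(list(draws = chains, param_names = pnames, design = design,
                 priors = priors, config = config),
            class = "bhlm_chains")
}

#' Summarize posterior draws
#'
#' Pooled-draw posterior mean, sd and the 2.5/25/50/75/97.5\% quantiles per
#' parameter, plus split-chain Rhat and effective sample size. Composition
#' slopes keep their "SB (CG)" ... "MVPA (IG)" labels.
#'
#' @param chains A [run_mcmc()] result.
#' @param params Optional subset of parameter names.
#' @return data.frame with columns parameter, mean, sd, q2.5, q25, q50, q75,
#'   q97.5, rhat, ess.
#' @export
summarize_posterior <- function(chains, params = NULL) {
  if (length(chains$draws) < 2) stop_data("need >= 2 chains to summarize")
  if (nrow(chains$draws[[1]]) < 100)
    stop_data("need >= 100 retained draws per chain")
  params <- params %||% chains$param_names
  pooled <- do.call(rbind, chains$draws)
  rows <- lapply(params, function(pm) {
    x <- pooled[, pm]
    qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    per_chain <- sapply(chains$draws, function(d) d[, pm])
    data.frame(parameter = pm, mean = mean(x), sd = stats::sd(x),
               q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4],
               q97.5 = qs[5],
               rhat = gelman_rubin(per_chain),
               ess = effective_sample_size(per_chain),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
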