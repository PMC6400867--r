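#' Generative ("true") parameters for the synthetic cohort
#'
#' Bundles every quantity the simulator treats as ground truth: per-group
#' diurnal log-cortisol intercepts and slopes, per-group log-cfDNA means and
#' timepoint bumps, the between-subject intercept sd (\code{sigma_alpha}), the
#' residual sd (\code{sigma_y}), a between-subject diurnal-slope sd
#' (\code{sigma_slope}; without it the subject intercept would cancel exactly
#' in the change-from-baseline indices and the index-scale hierarchical model
#' would have nothing subject-specific to estimate), per-group behavior
#' mixtures (target SB/LPA/MVPA fractions of wear time), the composition
#' effects injected into the index response, and season/gender level effects.
#'
#' Defaults describe a school morning: cortisol starts near 9 nmol/L at 08:30
#' and declines faster in the outdoor-taught intervention group (IG, -0.20/h on
#' the log scale) than in the indoor control group (CG, -0.10/h); cfDNA has no
#' seasonal pattern; the CG mixture is more sedentary with less MVPA. The
#' injected composition effects default to the magnitudes a study of this
#' design reports (|effect| roughly 0.2-1.6 on the log-index scale).
#'
#' @param cortisol_intercept,cortisol_slope Named numeric (IG, CG): log
#'   concentration at the first sample time, and change per hour.
#' @param cfdna_intercept Named numeric (IG, CG): log concentration level.
#' @param cfdna_timepoint Named numeric (midmorning, noon): log-scale bumps
#'   relative to baseline.
#' @param sigma_alpha,sigma_y,sigma_slope Positive sds: between-subject
#'   intercept, residual noise per sample, between-subject diurnal slope.
#' @param mixture Named list (IG, CG) of length-3 numerics (SB, LPA, MVPA)
#'   summing to 1: target wear-time fractions, shared across seasons.
#' @param dirichlet_kappa Concentration of the per-student-day Dirichlet draw
#'   around the group mixture; larger = less between-subject spread.
#' @param beta_cmp Named list (cortisol, cfdna), each a named list (IG, CG) of
#'   length-3 numerics: composition effects injected into the index response.
#' @param season_effect Named numeric over seasons: cortisol level shifts.
#' @param gender_effect Numeric: level shift for gender "male" vs "female".
#' @return A list of class \code{true_params}.
#' @export
true_params <- function(cortisol_intercept = c(IG = log(9), CG = log(9)),
                        cortisol_slope = c(IG = -0.20, CG = -0.10),
                        cfdna_intercept = c(IG = log(100), CG = log(100)),
                        cfdna_timepoint = c(midmorning = 0.10, noon = 0.05),
                        sigma_alpha = 0.30,
                        sigma_y = 0.25,
                        sigma_slope = 0.05,
                        mixture = list(IG = c(SB = 0.50, LPA = 0.32, MVPA = 0.18),
                                       CG = c(SB = 0.62, LPA = 0.30, MVPA = 0.08)),
                        dirichlet_kappa = 60,
                        beta_cmp = list(
                          cortisol = list(IG = c(SB = 0, LPA = -0.728, MVPA = 0),
                                          CG = c(SB = -0.215, LPA = 0, MVPA = -0.499)),
                          cfdna = list(IG = c(SB = 1.285, LPA = 1.231, MVPA = 0.649),
                                       CG = c(SB = 0, LPA = 1.643, MVPA = 1.574))),
                        season_effect = c(fall = 0, spring = -0.10, summer = -0.15),
                        gender_effect = 0.05) {
  # zero sds are admitted so noise-free closed-form checks are expressible
  if (any(c(sigma_alpha, sigma_y, sigma_slope) < 0))
    stop_config("sds must be >= 0")
  for (g in names(mixture)) {
    m <- mixture[[g]]
    if (length(m) != 3 || any(m < 0) || abs(sum(m) - 1) > 1e-9)
      stop_config("mixture for ", g, " must be 3 non-negative parts summing to 1")
  }
  structure(list(cortisol_intercept = cortisol_intercept,
                 cortisol_slope = cortisol_slope,
                 cfdna_intercept = cfdna_intercept,
                 cfdna_timepoint = cfdna_timepoint,
                 sigma_alpha = sigma_alpha, sigma_y = sigma_y,
                 sigma_slope = sigma_slope,
                 mixture = mixture, dirichlet_kappa = dirichlet_kappa,
                 beta_cmp = beta_cmp,
                 season_effect = season_effect, gender_effect = gender_effect),
            class = "true_params")
}

#' Missingness configuration for the synthetic cohort
#'
#' @param saliva_dropout Probability that a student-day's saliva samples are
#'   unusable and the whole day is dropped.
#' @param sensor_loss Named numeric over seasons: probability that the
#'   accelerometer fell off during that day's window (children are instructed
#'   not to re-attach it, so loss right-truncates the count series).
#' @return A list of class \code{missingness_config}.
#' @export
missingness_config <- function(saliva_dropout = 0.10,
                               sensor_loss = c(fall = 0.03, spring = 0.03,
                                               summer = 0.12)) {
  assert_prob(saliva_dropout, "saliva_dropout")
  assert_prob(sensor_loss, "sensor_loss")
  structure(list(saliva_dropout = saliva_dropout, sensor_loss = sensor_loss),
            class = "missingness_config")
}

#' Cohort configuration
#'
#' @param n_ig,n_cg Number of students in the intervention (outdoor-taught)
#'   and control (indoor-taught) groups; defaults 37 and 11.
#' @param seasons Measurement seasons, one measurement day per student each.
#' @param sample_times_h Saliva clock times in decimal hours (08:30, 10:30,
#'   12:30 by default); strictly increasing.
#' @param epoch_length_s Accelerometer epoch length in seconds.
#' @param seed Integer seed; every simulation run under this config is
#'   reproducible from it.
#' @param true_params A [true_params()] object.
#' @param missingness A [missingness_config()] object.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_ig = 37, n_cg = 11,
                          seasons = c("fall", "spring", "summer"),
                          sample_times_h = c(8.5, 10.5, 12.5),
                          epoch_length_s = 15,
                          seed = 1L,
                          true_params = compstress::true_params(),
                          missingness = missingness_config()) {
  if (n_ig < 1 || n_cg < 1) stop_config("n_ig and n_cg must both be >= 1")
  if (any(diff(sample_times_h) <= 0))
    stop_config("sample_times_h must be strictly increasing")
  if (epoch_length_s <= 0) stop_config("epoch_length_s must be > 0")
  structure(list(n_ig = as.integer(n_ig), n_cg = as.integer(n_cg),
                 seasons = seasons, sample_times_h = sample_times_h,
                 epoch_length_s = epoch_length_s, seed = as.integer(seed),
                 true_params = true_params, missingness = missingness),
            class = "cohort_config")
}

#' Generate the student roster
#'
#' Draws a cohort of `n_ig + n_cg` students with unique ids, group labels and
#' a seeded random gender assignment.
#'
#' @param config A [cohort_config()].
#' @return data.frame with columns id, group (CG/IG), gender (female/male).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_ig + config$n_cg
  data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = rep(c("IG", "CG"), c(config$n_ig, config$n_cg)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

draw_composition <- function(group, params) {
  p <- rdirichlet1(params$dirichlet_kappa * params$mixture[[group]])
  names(p) <- c("SB", "LPA", "MVPA")
  p
}

#' Simulate one student's saliva day
#'
#' Generates cortisol and cfDNA concentrations at each sample time on the
#' natural-log scale as (group diurnal mean + subject random effects +
#' season/gender effects + injected composition effect + Normal noise), then
#' exponentiates. The composition effect is ramped linearly from 0 at baseline
#' to its full value at the last sample, so that the noon change-from-baseline
#' index recovers exactly the injected per-group effect.
#'
#' @param student One-row data.frame (id, group, gender) as from
#'   [generate_cohort()].
#' @param season Season label.
#' @param params A [true_params()].
#' @param times_h Sample clock times in hours.
#' @param composition Named length-3 SB/LPA/MVPA fractions for this
#'   student-day; drawn from the group mixture when NULL.
#' @param subject_effects Optional list(intercept=, slope=, intercept_cfdna=)
#'   of subject-level deviations, so the same student keeps their effects
#'   across seasons; drawn when NULL.
#' @return data.frame with columns id, season, time_h, cortisol, cfdna
#'   (concentration scale, all positive).
#' @export
simulate_saliva_day <- function(student, season, params,
                                times_h = c(8.5, 10.5, 12.5),
                                composition = NULL,
                                subject_effects = NULL) {
  g <- student$group
  if (is.null(composition)) composition <- draw_composition(g, params)
  if (is.null(subject_effects)) subject_effects <- draw_subject_effects(params)
  dt <- times_h - times_h[1]
  ramp <- if (max(dt) > 0) dt / max(dt) else dt
  season_eff <- unname(params$season_effect[season] %||% 0)
  if (is.na(season_eff)) season_eff <- 0
  gender_eff <- if (identical(student$gender, "male")) params$gender_effect else 0

  inj_cort <- sum(params$beta_cmp$cortisol[[g]] * composition)
  m_cort <- params$cortisol_intercept[g] +
    (params$cortisol_slope[g] + subject_effects$slope) * dt +
    subject_effects$intercept + season_eff + gender_eff +
    inj_cort * ramp +
    stats::rnorm(length(times_h), 0, params$sigma_y)

  tp_eff <- c(0, params$cfdna_timepoint[c("midmorning", "noon")])[seq_along(times_h)]
  inj_cf <- sum(params$beta_cmp$cfdna[[g]] * composition)
  m_cf <- params$cfdna_intercept[g] + tp_eff +
    subject_effects$intercept_cfdna + gender_eff +
    inj_cf * ramp +
    stats::rnorm(length(times_h), 0, params$sigma_y)

  data.frame(id = student$id, season = season, time_h = times_h,
             cortisol = exp(unname(m_cort)), cfdna = exp(unname(m_cf)),
             stringsAsFactors = FALSE)
}

draw_subject_effects <- function(params) {
  list(intercept = stats::rnorm(1, 0, params$sigma_alpha),
       intercept_cfdna = stats::rnorm(1, 0, params$sigma_alpha),
       slope = stats::rnorm(1, 0, params$sigma_slope))
}

#' Simulate one student's accelerometer day
#'
#' Draws per-epoch vector-magnitude counts over the 08:30-12:30 wear window
#' from a 3-state mixture whose state probabilities are the student-day
#' composition and whose state-specific count distributions straddle the
#' configured cut-points (uniform on [0, sb_max], (sb_max, mvpa_min) and
#' [mvpa_min, 3*mvpa_min] respectively), so downstream classification
#' reproduces the mixture in expectation.
#'
#' @param student One-row roster data.frame.
#' @param season Season label.
#' @param params A [true_params()].
#' @param cuts A [cut_points()] object.
#' @param composition Optional SB/LPA/MVPA state probabilities; drawn from the
#'   group mixture when NULL.
#' @param window_h Start/end of the wear window in clock hours.
#' @param truncate_at Optional fraction in (0, 1]: keep only this leading
#'   share of epochs (sensor fell off and was not re-attached).
#' @return data.frame with columns id, season, epoch_start_s, vm_counts.
#' @export
simulate_accelerometry <- function(student, season, params,
                                   cuts = cut_points("romanzini_vm"),
                                   composition = NULL,
                                   window_h = c(8.5, 12.5),
                                   truncate_at = NULL) {
  len <- cuts$epoch_length_s
  window_s <- (window_h[2] - window_h[1]) * 3600
  if (window_s %% len != 0)
    stop_config("epoch length ", len, " s does not divide the wear window")
  n_epochs <- window_s / len
  g <- student$group
  if (is.null(composition)) composition <- draw_composition(g, params)
  state <- sample.int(3, n_epochs, replace = TRUE, prob = composition)
  counts <- integer(n_epochs)
  counts[state == 1] <- sample.int(cuts$sb_max + 1, sum(state == 1), replace = TRUE) - 1L
  n_lpa_vals <- cuts$mvpa_min - cuts$sb_max - 1
  counts[state == 2] <- cuts$sb_max + sample.int(n_lpa_vals, sum(state == 2), replace = TRUE)
  counts[state == 3] <- cuts$mvpa_min - 1L +
    sample.int(2 * cuts$mvpa_min + 1, sum(state == 3), replace = TRUE)
  if (!is.null(truncate_at)) {
    keep <- max(1L, floor(truncate_at * n_epochs))
    counts <- counts[seq_len(keep)]
    n_epochs <- keep
  }
  data.frame(id = student$id, season = season,
             epoch_start_s = (seq_len(n_epochs) - 1L) * len,
             vm_counts = counts, stringsAsFactors = FALSE)
}

#' Apply sample/sensor missingness to simulated cohort tables
#'
#' Each student-day's saliva samples are dropped with probability
#' `missingness$saliva_dropout`; each student-day's count series is
#' right-truncated at a uniform random point with the per-season sensor-loss
#' probability. Remaining rows are unchanged. A manifest of affected units is
#' attached.
#'
#' @param tables list(students=, saliva=, counts=) of cohort tables.
#' @param missingness A [missingness_config()].
#' @return The tables list with rows removed/truncated, plus a `manifest`
#'   data.frame (id, season, table, action).
#' @export
apply_missingness <- function(tables, missingness) {
  manifest <- data.frame(id = character(), season = character(),
                         table = character(), action = character(),
                         stringsAsFactors = FALSE)
  sal <- tables$saliva
  if (!is.null(sal) && nrow(sal) > 0) {
    days <- unique(sal[, c("id", "season")])
    drop <- stats::runif(nrow(days)) < missingness$saliva_dropout
    if (any(drop)) {
      dropped <- days[drop, , drop = FALSE]
      key <- paste(sal$id, sal$season)
      sal <- sal[!(key %in% paste(dropped$id, dropped$season)), , drop = FALSE]
      manifest <- rbind(manifest,
                        data.frame(id = dropped$id, season = dropped$season,
                                   table = "saliva", action = "dropped",
                                   stringsAsFactors = FALSE))
    }
  }
  cnt <- tables$counts
  if (!is.null(cnt) && nrow(cnt) > 0) {
    days <- unique(cnt[, c("id", "season")])
    p <- missingness$sensor_loss[days$season]
    p[is.na(p)] <- 0
    lost <- stats::runif(nrow(days)) < p
    if (any(lost)) {
      kept <- vector("list", nrow(days))
      for (k in seq_len(nrow(days))) {
        rows <- cnt$id == days$id[k] & cnt$season == days$season[k]
        day <- cnt[rows, , drop = FALSE]
        if (lost[k]) {
          at <- max(1L, floor(stats::runif(1) * nrow(day)))
          day <- day[seq_len(at), , drop = FALSE]
        }
        kept[[k]] <- day
      }
      cnt <- do.call(rbind, kept)
      ld <- days[lost, , drop = FALSE]
      manifest <- rbind(manifest,
                        data.frame(id = ld$id, season = ld$season,
                                   table = "counts", action = "truncated",
                                   stringsAsFactors = FALSE))
    }
  }
  list(students = tables$students, saliva = sal, counts = cnt,
       manifest = manifest)
}

#' Simulate a complete study
#'
#' Runs roster generation, per-student-day composition draws, accelerometer
#' and saliva simulation, and missingness, all from `config$seed`. The same
#' Dirichlet composition draw drives both the count mixture and the injected
#' composition effect, coupling behavior and biomarker response as the
#' analysis assumes.
#'
#' @param config A [cohort_config()].
#' @param cuts A [cut_points()] object used for the count-state distributions.
#' @return list(students, saliva, counts, true_compositions, manifest).
#' @export
simulate_study <- function(config, cuts = cut_points("romanzini_vm", config$epoch_length_s)) {
  students <- generate_cohort(config)   # seeds the RNG from config$seed
  params <- config$true_params
  eff <- lapply(seq_len(nrow(students)), function(i) draw_subject_effects(params))
  saliva <- list(); counts <- list(); comps <- list()
  k <- 0
  for (i in seq_len(nrow(students))) {
    st <- students[i, ]
    for (season in config$seasons) {
      k <- k + 1
      comp <- draw_composition(st$group, params)
      comps[[k]] <- data.frame(id = st$id, season = season,
                               sb = comp[1], lpa = comp[2], mvpa = comp[3],
                               stringsAsFactors = FALSE, row.names = NULL)
      counts[[k]] <- simulate_accelerometry(st, season, params, cuts = cuts,
                                            composition = comp)
      saliva[[k]] <- simulate_saliva_day(st, season, params,
                                         times_h = config$sample_times_h,
                                         composition = comp,
                                         subject_effects = eff[[i]])
    }
  }
  tables <- list(students = students,
                 saliva = do.call(rbind, saliva),
                 counts = do.call(rbind, counts))
  out <- apply_missingness(tables, config$missingness)
  out$true_compositions <- do.call(rbind, comps)
  out
}

#' Write the three cohort CSV tables
#'
#' @param study Output of [simulate_study()] (or any list with students,
#'   saliva, counts data.frames of the documented schemas).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(students = file.path(dir, "students.csv"),
             saliva = file.path(dir, "saliva.csv"),
             counts = file.path(dir, "counts.csv"))
  utils::write.csv(study$students, paths["students"], row.names = FALSE)
  utils::write.csv(study$saliva, paths["saliva"], row.names = FALSE)
  utils::write.csv(study$counts, paths["counts"], row.names = FALSE)
  invisible(paths)
}

#' Simulate index-scale observations with known composition slopes
#'
#' Generates modeling rows directly on the response-index scale:
#' y = alpha_id + beta[group] . composition + season + gender (+ timepoint)
#' + Normal noise. This is the ground-truth generator used for parameter
#' recovery: the slopes passed in are exactly what the hierarchical model
#' should recover.
#'
#' @param n_ig,n_cg Group sizes.
#' @param seasons Season labels (one observation unit per student-season).
#' @param beta Named list (IG, CG) of length-3 numerics: true composition
#'   slopes (SB, LPA, MVPA).
#' @param season_effect,gender_effect,timepoint_effect True covariate effects
#'   on the index scale (season_effect named over seasons, reference 0).
#' @param sigma_alpha,sigma_y True sd of subject intercepts and residuals.
#' @param mixture,dirichlet_kappa Composition model, as in [true_params()].
#' @param timepoints NULL for one row per student-season (AUCi-like), or a
#'   character vector such as c("midmorning","noon") for PR-like data with a
#'   timepoint covariate.
#' @return data.frame of observations (y, id, group, gender, season, sb, lpa,
#'   mvpa, timepoint) with the truth attached as attribute "truth".
#' @export
simulate_observations <- function(n_ig = 37, n_cg = 11,
                                  seasons = c("fall", "spring", "summer"),
                                  beta = list(IG = c(SB = 1.2, LPA = 0.8, MVPA = 1.0),
                                              CG = c(SB = 0.9, LPA = 1.3, MVPA = 0.7)),
                                  season_effect = c(fall = 0, spring = -0.1, summer = -0.15),
                                  gender_effect = 0.05,
                                  timepoint_effect = -0.2,
                                  sigma_alpha = 0.3, sigma_y = 0.25,
                                  mixture = list(IG = c(0.50, 0.32, 0.18),
                                                 CG = c(0.62, 0.30, 0.08)),
                                  dirichlet_kappa = 60,
                                  timepoints = NULL) {
  n <- n_ig + n_cg
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(c("IG", "CG"), c(n_ig, n_cg))
  gender <- sample(c("female", "male"), n, replace = TRUE)
  alpha <- stats::rnorm(n, 0, sigma_alpha)
  tps <- timepoints %||% NA_character_
  rows <- list(); k <- 0
  for (i in seq_len(n)) {
    for (season in seasons) {
      comp <- rdirichlet1(dirichlet_kappa * mixture[[grp[i]]])
      mu0 <- alpha[i] + sum(beta[[grp[i]]] * comp) +
        unname(season_effect[season]) +
        if (gender[i] == "male") gender_effect else 0
      for (tp in tps) {
        k <- k + 1
        mu <- mu0 + if (!is.na(tp) && tp == "noon") timepoint_effect else 0
        rows[[k]] <- data.frame(y = stats::rnorm(1, mu, sigma_y),
                                id = ids[i], group = grp[i], gender = gender[i],
                                season = season, sb = comp[1], lpa = comp[2],
                                mvpa = comp[3], timepoint = tp,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(beta = beta, alpha = stats::setNames(alpha, ids),
                             season_effect = season_effect,
                             gender_effect = gender_effect,
                             timepoint_effect = timepoint_effect,
                             sigma_alpha = sigma_alpha, sigma_y = sigma_y)
  out
}
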