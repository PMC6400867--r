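#' Pipeline configuration
#'
#' @param out_dir Directory for artifacts.
#' @param input_dir NULL for synthetic mode (tables are generated from
#'   \code{cohort}), else a directory containing students.csv, saliva.csv,
#'   counts.csv.
#' @param cohort A [cohort_config()] used in synthetic mode.
#' @param cuts A [cut_points()] object.
#' @param min_wear_minutes Wear-time validity threshold (of the 240-minute
#'   window).
#' @param detection_floor Concentration floor passed to the log transform.
#' @param pr_method PR definition switch.
#' @param models Character vector of model ids to fit (subset of
#'   BHLM1..BHLM4); empty vector fits nothing beyond the tables.
#' @param mcmc An [mcmc_config()].
#' @param seed Global seed; overrides cohort and MCMC seeds for end-to-end
#'   determinism.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = "compstress-artifacts",
                            input_dir = NULL,
                            cohort = cohort_config(),
                            cuts = cut_points("romanzini_vm",
                                              cohort$epoch_length_s),
                            min_wear_minutes = 120,
                            detection_floor = NULL,
                            pr_method = "per_timepoint",
                            models = c("BHLM1", "BHLM2", "BHLM3", "BHLM4"),
                            mcmc = mcmc_config(),
                            seed = 1L) {
  if (is.null(input_dir) && is.null(seed))
    stop_config("synthetic mode requires a seed")
  cohort$seed <- as.integer(seed)
  mcmc$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
                 cuts = cuts, min_wear_minutes = min_wear_minutes,
                 detection_floor = detection_floor, pr_method = pr_method,
                 models = models, mcmc = mcmc, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_study_tables <- function(dir) {
  paths <- file.path(dir, c("students.csv", "saliva.csv", "counts.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("cannot read input table(s): ", paste(missing, collapse = ", "))
  list(students = utils::read.csv(paths[1], stringsAsFactors = FALSE),
       saliva = utils::read.csv(paths[2], stringsAsFactors = FALSE),
       counts = utils::read.csv(paths[3], stringsAsFactors = FALSE))
}

#' Validate cohort input tables
#'
#' Schema, level and key-join checks over the three cohort tables. Problems
#' are returned, not thrown, and split into fatal errors and warnings.
#'
#' @param tables list(students, saliva, counts).
#' @param flooring Whether non-positive concentrations will be floored
#'   downstream (then a warning) or not (then fatal).
#' @return data.frame (severity, table, problem); zero rows when clean.
#' @export
validate_inputs <- function(tables, flooring = FALSE) {
  probs <- list()
  add <- function(severity, table, problem)
    probs[[length(probs) + 1]] <<- data.frame(severity = severity,
                                              table = table, problem = problem,
                                              stringsAsFactors = FALSE)
  st <- tables$students
  need <- list(students = c("id", "group", "gender"),
               saliva = c("id", "season", "time_h", "cortisol", "cfdna"),
               counts = c("id", "season", "epoch_start_s", "vm_counts"))
  for (tb in names(need)) {
    cols <- setdiff(need[[tb]], names(tables[[tb]]))
    if (length(cols) > 0)
      add("error", tb, paste("missing column(s):", paste(cols, collapse = ", ")))
  }
  if (length(probs) > 0) return(do.call(rbind, probs))
  if (anyDuplicated(st$id))
    add("error", "students", "duplicate ids")
  bad <- setdiff(unique(st$group), c("CG", "IG"))
  if (length(bad) > 0)
    add("error", "students", paste("unknown group level(s):",
                                   paste(bad, collapse = ", ")))
  for (tb in c("saliva", "counts")) {
    unknown <- setdiff(unique(tables[[tb]]$id), st$id)
    if (length(unknown) > 0)
      add("error", tb, paste("id(s) not in students table:",
                             paste(unknown, collapse = ", ")))
  }
  for (an in c("cortisol", "cfdna")) {
    n_bad <- sum(tables$saliva[[an]] <= 0, na.rm = TRUE)
    if (n_bad > 0)
      add(if (flooring) "warning" else "error", "saliva",
          paste0(n_bad, " non-positive ", an, " value(s)",
                 if (flooring) " (will be floored)"))
  }
  if (any(tables$counts$vm_counts < 0, na.rm = TRUE))
    add("error", "counts", "negative counts")
  if (length(probs) == 0)
    return(data.frame(severity = character(), table = character(),
                      problem = character(), stringsAsFactors = FALSE))
  do.call(rbind, probs)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: synthetic generation (or table ingest) -> accelerometer
#' classification and composition closure -> log transform and PR/AUCi
#' indices -> one hierarchical model fit per selected model -> diagnostics
#' and the coefficient display. Every CSV/JSON artifact is stamped with the
#' configuration hash and seed; a rerun with the same config is
#' bit-identical. A stage failure aborts with the stage named and removes the
#' partial output directory.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress the stage narration.
#' @return Invisibly, a list with the in-memory artifacts: tables,
#'   compositions, indices, fits (per model: summary, dic, ppc), paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[compstress] ", ...)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "ingest"
    if (is.null(config$input_dir)) {
      say("simulating synthetic cohort (seed ", config$seed, ")")
      tables <- simulate_study(config$cohort, cuts = config$cuts)
    } else {
      say("reading cohort tables from ", config$input_dir)
      tables <- read_study_tables(config$input_dir)
    }
    report <- validate_inputs(tables, flooring = !is.null(config$detection_floor))
    if (any(report$severity == "error"))
      stop("input validation failed:\n",
           paste(report$table, report$problem, collapse = "\n"))
    for (w in which(report$severity == "warning"))
      warning(report$table[w], ": ", report$problem[w], call. = FALSE)

    stage <- "accelerometry"
    say("classifying epochs (SB <= ", config$cuts$sb_max, ", MVPA >= ",
        config$cuts$mvpa_min, " counts/", config$cuts$epoch_length_s, " s)")
    compositions <- compose_counts(tables$counts, config$cuts,
                                   config$min_wear_minutes)
    write_stamped_csv(compositions, file.path(config$out_dir, "compositions.csv"),
                      hash, config$seed)
    made <- c(made, "compositions.csv")

    stage <- "indices"
    say("computing log-scale PR and AUCi indices")
    indices <- compute_indices(tables$saliva, floor = config$detection_floor,
                               pr_method = config$pr_method)
    write_stamped_csv(indices, file.path(config$out_dir, "indices.csv"),
                      hash, config$seed)
    made <- c(made, "indices.csv")

    fits <- list()
    summaries <- list()
    diag_report <- list()
    for (mid in config$models) {
      stage <- paste0("fit:", mid)
      spec <- model_spec(mid)
      obs <- assemble_observations(indices, compositions, tables$students, spec)
      say("fitting ", mid, " (", spec$analyte, " ", spec$index, ", n = ",
          nrow(obs), ")")
      design <- build_design(obs, spec)
      fit <- run_mcmc(design, spec$prior_set, config$mcmc)
      summ <- summarize_posterior(fit)
      summ$model <- mid
      summaries[[mid]] <- summ
      stage <- paste0("diagnose:", mid)
      d <- dic(fit)
      ppc <- posterior_predictive_check(fit)
      diag_report[[mid]] <- list(dic = d$dic, mean_deviance = d$mean_deviance,
                                 pD = d$pD,
                                 max_rhat = max(summ$rhat),
                                 min_ess = min(summ$ess),
                                 retained_draws = sum(sapply(fit$draws, nrow)),
                                 ppc_tail_probabilities = as.list(ppc))
      plot_credibility(summ, file.path(config$out_dir,
                                       paste0("credibility_", mid, ".svg")),
                       main = paste(mid, "composition slopes"))
      made <- c(made, paste0("credibility_", mid, ".svg"))
      fits[[mid]] <- fit
    }
    if (length(summaries) > 0) {
      all_summ <- do.call(rbind, summaries)
      rownames(all_summ) <- NULL
      write_stamped_csv(all_summ, file.path(config$out_dir,
                                            "posterior_summary.csv"),
                        hash, config$seed)
      made <- c(made, "posterior_summary.csv")
      jsonlite::write_json(
        c(list(config_hash = hash, seed = config$seed), diag_report),
        file.path(config$out_dir, "diagnostics.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      made <- c(made, "diagnostics.json")
    }
    say("done; artifacts in ", config$out_dir)
    invisible(list(tables = tables, compositions = compositions,
                   indices = indices, fits = fits,
                   summaries = summaries, diagnostics = diag_report,
                   config_hash = hash,
                   paths = file.path(config$out_dir, made)))
  }, error = function(e) {
    unlink(file.path(config$out_dir, made))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash, " seed=", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a stamped artifact CSV
#'
#' @param path Artifact path written by [run_pipeline()].
#' @param expect_hash Optional hash; a mismatch (artifacts from different
#'   configurations) is an error.
#' @return data.frame, with attributes config_hash and seed.
#' @export
read_stamped_csv <- function(path, expect_hash = NULL) {
  stamp <- readLines(path, n = 1)
  hash <- sub(".*config_hash=([0-9a-f]+).*", "\\1", stamp)
  seed <- as.integer(sub(".*seed=([0-9-]+).*", "\\1", stamp))
  if (!is.null(expect_hash) && !identical(hash, expect_hash))
    stop("artifact ", path, " was produced under config ", hash,
         ", expected ", expect_hash, "; refusing to combine")
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "config_hash") <- hash
  attr(out, "seed") <- seed
  out
}

#' Join indices, compositions and roster into modeling rows for one model
#'
#' Complete-case join on (id, season): keeps the model's analyte and index,
#' valid compositions only.
#'
#' @param indices Output of [compute_indices()].
#' @param compositions Output of [compose_counts()].
#' @param students Roster table.
#' @param spec A [model_spec()].
#' @return Observation data.frame ready for [build_design()].
#' @export
assemble_observations <- function(indices, compositions, students, spec) {
  idx <- indices[indices$analyte == spec$analyte & indices$index == spec$index, ,
                 drop = FALSE]
  comp <- compositions[compositions$valid, c("id", "season", "sb", "lpa", "mvpa")]
  out <- merge(idx, comp, by = c("id", "season"))
  out <- merge(out, students[, c("id", "group", "gender")], by = "id")
  out$y <- out$value
  out <- out[order(out$id, out$season,
                   if (spec$include_timepoint) out$timepoint else out$id), ]
  rownames(out) <- NULL
  out
}
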