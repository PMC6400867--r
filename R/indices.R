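#' Log-transform a trajectory
#'
#' Replaces each concentration by its natural log (configurable base). Values
#' at or below zero are floored to \code{floor} first when given, emulating an
#' assay detection limit; with flooring disabled they are an error naming the
#' offending record.
#'
#' @param trajectory data.frame with columns time_h and value (concentration),
#'   or a bare numeric vector of concentrations.
#' @param floor Detection floor for non-positive values; NULL disables.
#' @param base Log base (default natural log; affects only the scale of every
#'   downstream index).
#' @return Same shape as the input, concentrations replaced by logs.
#' @export
log_transform <- function(trajectory, floor = NULL, base = exp(1)) {
  vec <- !is.data.frame(trajectory)
  vals <- if (vec) trajectory else trajectory$value
  bad <- which(vals <= 0)
  if (length(bad) > 0) {
    if (is.null(floor))
      stop_data("non-positive concentration at record(s) ",
                paste(bad, collapse = ", "), " with flooring disabled")
    vals[bad] <- floor
  }
  out <- log(vals, base = base)
  if (vec) return(out)
  trajectory$value <- out
  trajectory
}

#' Area under the curve with respect to increase (AUCi)
#'
#' For a logged trajectory m(t) sampled at increasing times, the trapezoidal
#' ground area minus baseline times total elapsed time:
#' \deqn{AUCi = \sum_i \frac{m_{i+1}+m_i}{2}(t_{i+1}-t_i) - m_1 (t_{last}-t_1)}
#' Negative for declining trajectories; zero for flat ones; invariant to
#' adding a constant to every sample.
#'
#' @param m Log-concentrations (numeric), or a data.frame with columns time_h
#'   and value.
#' @param times_h Sample times in hours (ignored when `m` is a data.frame).
#' @return Numeric scalar, in log-concentration x hours.
#' @export
auc_increase <- function(m, times_h = c(8.5, 10.5, 12.5)) {
  if (is.data.frame(m)) { times_h <- m$time_h; m <- m$value }
  n <- length(m)
  if (n < 2) stop_data("AUCi needs at least 2 samples")
  if (any(diff(times_h) <= 0)) stop_data("times must be strictly increasing")
  dt <- diff(times_h)
  ground <- sum((m[-1] + m[-n]) / 2 * dt)
  ground - m[1] * (times_h[n] - times_h[1])
}

#' Peak reactivity (PR): change from baseline per post-baseline timepoint
#'
#' For the three-sample school-morning schedule, PR at midmorning is
#' m2 - m1 and PR at noon is m3 - m1, each emitted as its own observation so
#' a timepoint covariate (midmorning/noon) is well defined in the PR models.
#' The alternative single-number reading max(m) - m1 is available via
#' \code{method = "max_minus_baseline"}.
#'
#' @param m Log-concentrations, or a data.frame with columns time_h and value.
#' @param method "per_timepoint" (default) or "max_minus_baseline".
#' @param timepoint_labels Labels for the post-baseline samples.
#' @return Named numeric: one value per post-baseline timepoint, or a single
#'   unnamed value for the max-minus-baseline reading. Missing (NA) samples
#'   yield only the computable entries.
#' @export
peak_reactivity <- function(m, method = c("per_timepoint", "max_minus_baseline"),
                            timepoint_labels = c("midmorning", "noon")) {
  method <- match.arg(method)
  if (is.data.frame(m)) m <- m$value
  if (length(m) < 2) stop_data("PR needs a baseline and at least 1 later sample")
  if (is.na(m[1])) stop_data("PR undefined without a baseline sample")
  if (method == "max_minus_baseline")
    return(max(m[-1], na.rm = TRUE) - m[1])
  post <- m[-1]
  labs <- timepoint_labels[seq_along(post)]
  out <- post - m[1]
  names(out) <- labs
  out[!is.na(out)]
}

#' Compute PR and AUCi indices from a saliva table
#'
#' Log-transforms each student-day trajectory per analyte and emits its
#' summary indices: one AUCi row and one PR row per post-baseline timepoint.
#' Days with fewer than 2 usable samples are skipped and listed in the
#' attached \code{skipped} attribute.
#'
#' @param saliva data.frame with columns id, season, time_h, cortisol, cfdna
#'   (the saliva.csv schema).
#' @param floor Detection floor passed to [log_transform()].
#' @param pr_method PR definition switch, see [peak_reactivity()].
#' @param base Log base.
#' @return data.frame (id, season, analyte, index, timepoint, value) where
#'   timepoint is NA for AUCi rows.
#' @export
compute_indices <- function(saliva, floor = NULL,
                            pr_method = "per_timepoint", base = exp(1)) {
  key <- interaction(saliva$id, saliva$season, drop = TRUE)
  skipped <- list(); rows <- list(); k <- 0
  for (day in split(saliva, key)) {
    day <- day[order(day$time_h), , drop = FALSE]
    for (analyte in c("cortisol", "cfdna")) {
      conc <- day[[analyte]]
      ok <- !is.na(conc)
      if (sum(ok) < 2) {
        skipped[[length(skipped) + 1]] <-
          data.frame(id = day$id[1], season = day$season[1], analyte = analyte,
                     stringsAsFactors = FALSE)
        next
      }
      m_full <- rep(NA_real_, length(conc))
      m_full[ok] <- log_transform(conc[ok], floor = floor, base = base)
      k <- k + 1
      rows[[k]] <- data.frame(id = day$id[1], season = day$season[1],
                              analyte = analyte, index = "AUCi",
                              timepoint = NA_character_,
                              value = auc_increase(m_full[ok], day$time_h[ok]),
                              stringsAsFactors = FALSE)
      if (is.na(m_full[1])) next  # PR undefined without baseline; AUCi kept
      pr <- peak_reactivity(m_full, method = pr_method)
      if (is.null(names(pr))) {
        k <- k + 1
        rows[[k]] <- data.frame(id = day$id[1], season = day$season[1],
                                analyte = analyte, index = "PR",
                                timepoint = NA_character_, value = pr,
                                stringsAsFactors = FALSE)
      } else {
        for (tp in names(pr)) {
          k <- k + 1
          rows[[k]] <- data.frame(id = day$id[1], season = day$season[1],
                                  analyte = analyte, index = "PR",
                                  timepoint = tp, value = unname(pr[tp]),
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}
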