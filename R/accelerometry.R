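#' Accelerometer cut-points
#'
#' Count thresholds that classify each epoch's vector-magnitude counts into
#' sedentary behavior (SB, counts <= sb_max), moderate-to-vigorous physical
#' activity (MVPA, counts >= mvpa_min) and light activity (LPA) in between.
#'
#' The \code{"romanzini_vm"} preset ships SB <= 180 and MVPA >= 757 counts per
#' 15-s vector-magnitude epoch, the child/adolescent thresholds commonly
#' attributed to Romanzini and colleagues. They are configuration, not
#' constants: confirm them against the cited calibration source before any
#' substantive use, and scale them if you change the epoch length.
#'
#' @param preset Either a preset name (\code{"romanzini_vm"}) or a numeric
#'   \code{sb_max}.
#' @param epoch_length_s Epoch length in seconds the thresholds refer to.
#' @param mvpa_min Lower MVPA threshold (counts/epoch) when not using a preset.
#' @return A list of class \code{cut_points} with fields sb_max, mvpa_min,
#'   epoch_length_s.
#' @export
cut_points <- function(preset = "romanzini_vm", epoch_length_s = 15,
                       mvpa_min = NULL) {
  if (is.character(preset)) {
    preset <- match.arg(preset, "romanzini_vm")
    base <- c(sb_max = 180, mvpa_min = 757)  # counts per 15-s VM epoch
    scale <- epoch_length_s / 15
    sb_max <- round(base["sb_max"] * scale)
    mvpa_min <- round(base["mvpa_min"] * scale)
  } else {
    sb_max <- preset
    if (is.null(mvpa_min)) stop_config("mvpa_min required with numeric cut-points")
  }
  sb_max <- as.numeric(sb_max); mvpa_min <- as.numeric(mvpa_min)
  if (!(sb_max >= 0 && sb_max < mvpa_min))
    stop_config("cut-points must satisfy 0 <= sb_max < mvpa_min")
  structure(list(sb_max = unname(sb_max), mvpa_min = unname(mvpa_min),
                 epoch_length_s = epoch_length_s),
            class = "cut_points")
}

behavior_levels <- c("SB", "LPA", "MVPA")

#' Classify epochs into SB / LPA / MVPA
#'
#' @param series data.frame with columns vm_counts (and optionally
#'   epoch_start_s), or a bare numeric count vector. An attribute or column
#'   \code{epoch_length_s}, if present, is checked against the cut-points.
#' @param cuts A [cut_points()] object.
#' @return Factor of labels SB/LPA/MVPA, one per epoch.
#' @export
classify_epochs <- function(series, cuts) {
  counts <- if (is.data.frame(series)) series$vm_counts else series
  len <- attr(series, "epoch_length_s", exact = TRUE)
  if (!is.null(len) && len != cuts$epoch_length_s)
    stop_config("epoch length mismatch: series ", len, " s vs cut-points ",
                cuts$epoch_length_s, " s")
  if (length(counts) == 0)
    return(factor(character(), levels = behavior_levels))
  if (any(counts < 0)) stop_data("negative counts in series")
  lab <- ifelse(counts <= cuts$sb_max, "SB",
                ifelse(counts >= cuts$mvpa_min, "MVPA", "LPA"))
  factor(lab, levels = behavior_levels)
}

#' Close epoch labels into a 3-part behavior composition
#'
#' @param labels Factor/character vector of SB/LPA/MVPA labels.
#' @param epoch_length_s Epoch length in seconds.
#' @param min_wear_minutes Minimum classified wear time; a shorter day is
#'   returned with \code{valid = FALSE} and excluded from modeling.
#' @return A one-row data.frame (sb, lpa, mvpa, wear_minutes, valid) of class
#'   \code{behavior_composition}; parts sum to 1.
#' @export
compute_composition <- function(labels, epoch_length_s = 15,
                                min_wear_minutes = 120) {
  n <- length(labels)
  if (n == 0) stop_data("no epochs to compose")
  tab <- table(factor(labels, levels = behavior_levels))
  parts <- as.numeric(tab) / n
  wear <- n * epoch_length_s / 60
  out <- data.frame(sb = parts[1], lpa = parts[2], mvpa = parts[3],
                    wear_minutes = wear,
                    valid = wear >= min_wear_minutes)
  class(out) <- c("behavior_composition", "data.frame")
  out
}

#' Compositional (geometric) mean of behavior compositions
#'
#' Component-wise geometric mean across compositions, re-closed to sum 1.
#' Zero parts are first replaced multiplicatively: each zero is set to
#' \code{zero_floor} and the remaining parts of that row are shrunk
#' proportionally so the row still sums to 1 (standard compositional
#' zero handling).
#'
#' @param comps data.frame with columns sb, lpa, mvpa (one row per
#'   composition), e.g. stacked [compute_composition()] rows.
#' @param zero_floor Replacement value for zero parts; NULL disables
#'   replacement, in which case a zero part is an error naming the row.
#' @return Named numeric (sb, lpa, mvpa) summing to 1.
#' @export
compositional_mean <- function(comps, zero_floor = NULL) {
  x <- as.matrix(comps[, c("sb", "lpa", "mvpa")])
  if (nrow(x) == 0) stop_data("no compositions")
  if (any(x == 0)) {
    if (is.null(zero_floor))
      stop_data("zero part in composition row(s) ",
                paste(which(rowSums(x == 0) > 0), collapse = ", "),
                "; supply zero_floor to replace")
    for (i in which(rowSums(x == 0) > 0)) {
      z <- x[i, ] == 0
      x[i, z] <- zero_floor
      x[i, !z] <- x[i, !z] * (1 - sum(z) * zero_floor) / sum(x[i, !z])
    }
  }
  gm <- exp(colMeans(log(x)))
  out <- gm / sum(gm)
  names(out) <- c("sb", "lpa", "mvpa")
  out
}

#' Build the per-day composition table from an epoch count table
#'
#' Splits \code{counts} by (id, season), classifies each day with
#' [classify_epochs()] and closes it with [compute_composition()].
#'
#' @param counts data.frame with columns id, season, epoch_start_s, vm_counts.
#' @param cuts A [cut_points()] object.
#' @param min_wear_minutes Validity threshold passed through.
#' @return data.frame (id, season, sb, lpa, mvpa, wear_minutes, valid).
#' @export
compose_counts <- function(counts, cuts, min_wear_minutes = 120) {
  key <- interaction(counts$id, counts$season, drop = TRUE)
  rows <- lapply(split(counts, key), function(day) {
    labs <- classify_epochs(day, cuts)
    comp <- compute_composition(labs, cuts$epoch_length_s, min_wear_minutes)
    cbind(data.frame(id = day$id[1], season = day$season[1],
                     stringsAsFactors = FALSE),
          as.data.frame(comp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$id, out$season), , drop = FALSE]
}
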