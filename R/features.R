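# Scalar features of a 12-scale mMSE profile. Scale indices are 1-based:
# "fine" scales are 1-4, "coarse" scales 9-12; the curve typically peaks
# around scale 4 and stabilizes by scale 9, so DiffEnt = v9 - v4 is negative
# for inverted-U profiles.

#' Area under the mMSE curve (total complexity)
#'
#' Trapezoidal area under the profile at unit scale spacing:
#' `sum((v[i] + v[i+1]) / 2)` over consecutive scales.
#'
#' @param v numeric mMSE profile (all scales must be present) or an
#'   [mmse_vector()].
#' @return total complexity, or `NA` if any scale value is missing.
#' @export
mmse_auc <- function(v) {
  v <- as_profile(v)
  if (anyNA(v)) return(NA_real_)
  sum((v[-length(v)] + v[-1]) / 2)
}

#' Maximum fine-scale slope
#'
#' The maximum pairwise difference between the first four profile elements
#' divided by their index difference: `max (v[j] - v[i]) / (j - i)` over
#' `1 <= i < j <= 4`. Signed: rising fine-scale curves give positive values.
#'
#' @inheritParams mmse_auc
#' @param absolute if `TRUE`, maximize `|v[j] - v[i]| / (j - i)` instead.
#' @return fine-scale complexity change, or `NA` if any of the first four
#'   values is missing.
#' @export
mmse_max_slope <- function(v, absolute = FALSE) {
  v <- as_profile(v)
  if (length(v) < 4 || anyNA(v[1:4])) return(NA_real_)
  best <- -Inf
  for (i in 1:3) for (j in (i + 1):4) {
    s <- (v[j] - v[i]) / (j - i)
    if (absolute) s <- abs(s)
    if (s > best) best <- s
  }
  best
}

#' Average coarse-scale entropy
#'
#' Arithmetic mean of scales 9-12 of the profile: the baseline entropy level
#' at the low-frequency coarse scales.
#'
#' @inheritParams mmse_auc
#' @return coarse-scale entropy, or `NA` if any of scales 9-12 is missing.
#' @export
mmse_avg_ent <- function(v) {
  v <- as_profile(v)
  if (length(v) < 12 || anyNA(v[9:12])) return(NA_real_)
  mean(v[9:12])
}

#' Fine-to-coarse entropy change
#'
#' `v[9] - v[4]`: the difference between the entropy where the profile
#' stabilizes (scale 9) and its fine-scale peak region (scale 4). Negative
#' for inverted-U profiles.
#'
#' @inheritParams mmse_auc
#' @return entropy change, or `NA` if scale 4 or 9 is missing.
#' @export
mmse_diff_ent <- function(v) {
  v <- as_profile(v)
  if (length(v) < 9 || is.na(v[4]) || is.na(v[9])) return(NA_real_)
  v[9] - v[4]
}

as_profile <- function(v) {
  if (inherits(v, "mmse_vector")) v$values else as.numeric(v)
}

feature_row <- function(v) {
  c(AUC = mmse_auc(v), MaxSlope = mmse_max_slope(v),
    AvgEnt = mmse_avg_ent(v), DiffEnt = mmse_diff_ent(v))
}

#' Feature table from subject mMSE results
#'
#' Builds the subject x network feature table. Aggregate rows compute the
#' features of the epoch-averaged profile (`epoch = "aggregate"`); per-epoch
#' rows retain one feature set per epoch, the "items" used by segment-wise
#' reliability analysis.
#'
#' @param subjects list of [subject_network_mmse()] results (one per
#'   subject).
#' @param level `"aggregate"`, `"per-epoch"`, or `"both"`.
#' @return data.frame with columns subject_id, group, network, epoch
#'   (epoch index as character, or `"aggregate"`), AUC, MaxSlope, AvgEnt,
#'   DiffEnt.
#' @export
feature_table <- function(subjects, level = c("both", "aggregate", "per-epoch")) {
  level <- match.arg(level)
  rows <- list()
  for (su in subjects) {
    stopifnot(inherits(su, "subject_mmse"))
    for (nm in names(su$networks)) {
      net <- su$networks[[nm]]
      if (level %in% c("both", "aggregate")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = su$subject_id, group = su$group, network = nm,
          epoch = "aggregate", t(feature_row(net$values)),
          stringsAsFactors = FALSE)
      }
      if (level %in% c("both", "per-epoch")) {
        for (e in seq_len(nrow(net$per_epoch))) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = su$subject_id, group = su$group, network = nm,
            epoch = as.character(e), t(feature_row(net$per_epoch[e, ])),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
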