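# End-to-end orchestration: simulate -> preprocess -> mmse -> features ->
# stats from a single validated configuration, with per-stage logging, a
# manifest of checksums/timings, and deterministic seeding throughout.

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, preprocess = TRUE, mmse = TRUE,
                  features = TRUE, stats = TRUE),
    cohort = list(n_group_a = 20L, n_group_b = 20L,
                  n_epochs = 3L, epoch_length_s = 40, sampling_rate = 256,
                  scale_uv = 15,
                  spec_a = list(w_white = 0.8, w_pink = 0.2, w_ar = 0,
                                ar_coefficient = 0.9, mixing_strength = NULL,
                                subject_sd = 0.15),
                  spec_b = list(w_white = 0.2, w_pink = 0.8, w_ar = 0,
                                ar_coefficient = 0.9, mixing_strength = NULL,
                                subject_sd = 0.15)),
    preprocess = list(target_rate = 256, highpass_hz = 1, lowpass_hz = 40,
                      chan_sd_threshold_low_band = 5,
                      chan_sd_threshold_high_band = 2.5,
                      epoch_reject_uv_stage1 = 444,
                      epoch_reject_uv_stage2 = 222,
                      epoch_reject_uv_stage3 = 111,
                      epoch_samples = 10240,
                      # reference-free synthetic cohorts: the common-mode
                      # spatial mixing is annihilated by average referencing
                      # (see vignette), so the stage defaults to off here.
                      rereference = FALSE),
    mmse = list(m = 2, r = 0.15, tau = 1, max_scale = 12,
                segment_length = 1024),
    montage = "default",
    reliability_items = 3L)
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under '", path, "'") else "",
                 paste(unknown, collapse = ", ")))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, if (nzchar(path)) "/", nm))
    } else {
      defaults[nm] <- user[nm]    # keeps explicit NULLs
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills every omitted setting with the
#' analysis defaults (256 Hz, 1-40 Hz band, 444/222/111 microvolt rejection
#' stages, 10,240-sample epochs, m = 2, r = 0.15, tau = 1, 12 scales,
#' 1024-sample segments), rejects unknown keys, and checks cross-field
#' constraints (e.g. that the coarsest scale still leaves room for the
#' embedding).
#'
#' @param config path to a YAML file, or a (possibly partial) configuration
#'   list; `NULL` yields the full default configuration.
#' @return normalized configuration list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    yaml::read_yaml(config) %||% list()
  } else if (is.list(config)) config
  else stop("`config` must be a path, a list, or NULL")
  cfg <- merge_config(.default_config(), user)
  # constraint checks (raise before any computation)
  do.call(mmse_params, cfg$mmse)
  pp <- cfg$preprocess
  do.call(preprocess_config, pp[setdiff(names(pp), "rereference")])
  es <- cfg$cohort$epoch_length_s * cfg$cohort$sampling_rate
  if (cfg$stages$simulate && abs(es - round(es)) > 1e-9)
    stop("cohort epoch_length_s * sampling_rate must be an integer")
  if (cfg$preprocess$epoch_samples > es)
    stop(sprintf("epoch_samples (%d) exceeds the simulated epoch length (%d samples)",
                 cfg$preprocess$epoch_samples, round(es)))
  if (!identical(cfg$montage, "default") && !file.exists(cfg$montage))
    stop(sprintf("montage file not found: %s", cfg$montage))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

mixture_from_config <- function(sc) {
  noise_mixture_spec(w_white = sc$w_white, w_pink = sc$w_pink, w_ar = sc$w_ar,
                     ar_coefficient = sc$ar_coefficient,
                     mixing_strength = sc$mixing_strength,
                     subject_sd = sc$subject_sd)
}

cohort_from_config <- function(cfg) {
  co <- cfg$cohort
  cohort_spec(n_group_a = co$n_group_a, n_group_b = co$n_group_b,
              spec_a = mixture_from_config(co$spec_a),
              spec_b = mixture_from_config(co$spec_b),
              sampling_rate = co$sampling_rate,
              epoch_length_s = co$epoch_length_s,
              n_epochs = co$n_epochs, seed = cfg$seed,
              scale_uv = co$scale_uv)
}

file_checksum <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate -> preprocess -> mmse ->
#' features -> stats) and returns every stage's output plus a run manifest
#' (per-stage timing, rejection/missing-data tallies, and checksums of the
#' TSV artifacts when `out_dir` is set). Failure of a single subject at the
#' mmse stage is logged and the subject excluded rather than aborting the
#' cohort.
#'
#' @param config anything accepted by [validate_config()].
#' @param recordings optional list of [recording()]s to use instead of the
#'   simulate stage (which is then skipped).
#' @return An object of class `pipeline_result`: list with `config`,
#'   `recordings`, `epochs`, `subjects` (mMSE results), `features`
#'   (data.frame), `anova` (per feature), `posthoc` (per feature),
#'   `reliability`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, recordings = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  manifest <- list(timing = list(), tallies = list(), checksums = list(),
                   seed = cfg$seed)
  res <- list(config = cfg)
  tic <- function() proc.time()[["elapsed"]]
  montage <- if (identical(cfg$montage, "default")) default_montage()
  else load_montage(cfg$montage)

  if (is.null(recordings)) {
    if (!isTRUE(cfg$stages$simulate)) stop("no recordings and simulate stage disabled")
    t0 <- tic()
    recordings <- generate_cohort(cohort_from_config(cfg))
    manifest$timing$simulate <- tic() - t0
  }
  res$recordings <- recordings

  if (isTRUE(cfg$stages$preprocess)) {
    t0 <- tic()
    pconf <- do.call(preprocess_config,
                     cfg$preprocess[setdiff(names(cfg$preprocess), "rereference")])
    epochs <- lapply(recordings, function(rec) {
      preprocess_pipeline(rec, pconf,
                          rereference = isTRUE(cfg$preprocess$rereference))
    })
    manifest$tallies$epochs_rejected <- sum(vapply(epochs, function(e)
      sum(e$log$action == "reject_epoch"), numeric(1)))
    manifest$tallies$bad_channels <- sum(vapply(epochs, function(e)
      length(attr(e, "bad_labels")), numeric(1)))
    manifest$timing$preprocess <- tic() - t0
  } else {
    epochs <- lapply(recordings, extract_epochs,
                     epoch_samples = cfg$preprocess$epoch_samples)
  }
  res$epochs <- epochs

  if (!isTRUE(cfg$stages$mmse)) {
    res$manifest <- manifest
    class(res) <- "pipeline_result"
    return(res)
  }
  t0 <- tic()
  params <- do.call(mmse_params, cfg$mmse)
  subjects <- list()
  failed <- character(0)
  for (ep in epochs) {
    su <- tryCatch(
      subject_network_mmse(ep, montage, params,
                           bad_labels = attr(ep, "bad_labels") %||% character(0)),
      error = function(e) {
        message(sprintf("subject %s failed: %s", ep$subject_id, conditionMessage(e)))
        NULL
      })
    if (is.null(su)) failed <- c(failed, ep$subject_id)
    else subjects[[length(subjects) + 1L]] <- su
  }
  manifest$tallies$subjects_failed <- length(failed)
  manifest$timing$mmse <- tic() - t0
  res$subjects <- subjects

  if (isTRUE(cfg$stages$features)) {
    t0 <- tic()
    res$features <- feature_table(subjects, level = "both")
    manifest$timing$features <- tic() - t0
  }

  if (isTRUE(cfg$stages$stats) && !is.null(res$features)) {
    t0 <- tic()
    agg <- res$features[res$features$epoch == "aggregate", ]
    networks <- names(montage)
    res$anova <- list(); res$posthoc <- list()
    for (f in c("AUC", "MaxSlope", "AvgEnt", "DiffEnt")) {
      wide <- feature_matrix(agg, f, networks)
      if (nrow(wide$values) >= 4 && length(unique(wide$group)) == 2) {
        res$anova[[f]] <- mixed_anova(wide$values, wide$group, networks)
        res$posthoc[[f]] <- bonferroni_posthoc(wide$values, networks)
      }
    }
    res$reliability <- tryCatch(
      mmse_reliability(subjects, k_items = cfg$reliability_items),
      error = function(e) NULL)
    manifest$timing$stats <- tic() - t0
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$features)) {
      fpath <- file.path(cfg$out_dir, "features.tsv")
      write.table(res$features, fpath, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      manifest$checksums$features <- file_checksum(fpath)
    }
    if (!is.null(res$anova)) {
      apath <- file.path(cfg$out_dir, "anova.tsv")
      eff <- do.call(rbind, lapply(names(res$anova), function(f)
        cbind(feature = f, res$anova[[f]]$effects)))
      write.table(eff, apath, sep = "\t", row.names = FALSE, quote = FALSE)
      manifest$checksums$anova <- file_checksum(apath)
    }
  }
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$recordings))
    cat(sprintf("  %d recordings\n", length(x$recordings)))
  if (!is.null(x$features))
    cat(sprintf("  features: %d rows\n", nrow(x$features)))
  if (!is.null(x$anova))
    for (f in names(x$anova)) {
      e <- x$anova[[f]]$effects
      cat(sprintf("  %s: group F(%.0f, %.0f) = %.2f, p = %.3g\n", f,
                  e$df1_gg[1], e$df2_gg[1], e$F[1], e$p[1]))
    }
  invisible(x)
}

# Reshape the aggregate feature table into subjects x networks.
feature_matrix <- function(agg, feature, networks) {
  ids <- unique(agg$subject_id)
  vals <- matrix(NA_real_, length(ids), length(networks),
                 dimnames = list(ids, networks))
  grp <- setNames(character(length(ids)), ids)
  for (r in seq_len(nrow(agg))) {
    row <- agg[r, ]
    vals[row$subject_id, row$network] <- row[[feature]]
    grp[row$subject_id] <- row$group
  }
  list(values = vals, group = unname(grp))
}
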