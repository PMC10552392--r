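# Reliability and inference layer: Cronbach's alpha over repeated segments,
# Greenhouse-Geisser sphericity correction, split-plot (mixed
# within/between-subject) ANOVA with partial eta squared, and
# Bonferroni-corrected pairwise post-hocs over the seven networks.

#' Cronbach's alpha
#'
#' Internal-consistency coefficient over k "items" (here: successive 40-s
#' signal segments): `alpha = k/(k-1) * (1 - sum(var(item_i)) / var(sum))`,
#' with n-1 sample variances.
#'
#' @param items k x n numeric matrix: one row per item, one column per
#'   subject (k >= 2, n >= 3).
#' @return alpha (<= 1), or `NA` with attribute `undefined` when the total
#'   variance is zero.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- nrow(items); n <- ncol(items)
  if (k < 2) stop("Cronbach's alpha needs >= 2 items")
  if (n < 3) stop("Cronbach's alpha needs >= 3 observations per item")
  if (!all(is.finite(items))) stop("item matrix contains non-finite values")
  total_var <- var(colSums(items))
  if (total_var == 0) {
    out <- NA_real_; attr(out, "undefined") <- "zero_total_variance"
    return(out)
  }
  k / (k - 1) * (1 - sum(apply(items, 1L, var)) / total_var)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor estimated from the double-centered
#' within-subject covariance matrix S*: `epsilon = tr(S*)^2 / ((k-1) *
#' tr(S*^2))`, bounded to `[1/(k-1), 1]`.
#'
#' @param within_covariance symmetric k x k covariance matrix of the
#'   within-subject conditions (k >= 2).
#' @return epsilon in `[1/(k-1), 1]`, or `NA` (attribute `undefined`) for a
#'   degenerate (zero) covariance.
#' @export
gg_epsilon <- function(within_covariance) {
  S <- as.matrix(within_covariance)
  k <- nrow(S)
  if (k < 2 || ncol(S) != k) stop("covariance must be square, k >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance matrix must be symmetric")
  C <- diag(k) - matrix(1 / k, k, k)
  Sstar <- C %*% S %*% C
  tr <- sum(diag(Sstar))
  tr2 <- sum(Sstar * Sstar)       # tr(S*^2) for symmetric S*
  if (tr2 <= 0 || tr <= 0) {
    out <- NA_real_; attr(out, "undefined") <- "degenerate_covariance"
    return(out)
  }
  eps <- tr^2 / ((k - 1) * tr2)
  min(1, max(1 / (k - 1), eps))
}

#' Mixed within/between-subject ANOVA
#'
#' Split-plot decomposition for a complete-case subjects x conditions matrix
#' with one two-level between-subject factor: the between effect is tested
#' against subjects-within-groups; the within (condition) main effect and the
#' condition x group interaction are tested against the subject x condition
#' residual. Within-effect degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon estimated from the pooled within-group
#' covariance. Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`. Type III sums of squares
#' (unweighted group means) are used, so unbalanced groups are handled.
#'
#' @param values subjects x k numeric matrix (k within-subject conditions,
#'   e.g. the 7 networks); rows with any missing cell are dropped with a
#'   message.
#' @param group per-subject group labels (exactly 2 levels, >= 2 subjects
#'   each after complete-case filtering).
#' @param condition_names optional names for the within levels (defaults to
#'   column names).
#' @return An object of class `mixed_anova`: data.frame `effects` with rows
#'   `group`, `condition`, `condition:group` (columns ss, ss_error, df1, df2,
#'   gg_epsilon, df1_gg, df2_gg, F, p, partial_eta_sq) plus fields
#'   `n_dropped`, `n_subjects`, `group_levels`.
#' @export
mixed_anova <- function(values, group, condition_names = NULL) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2) stop("need >= 2 within-subject conditions")
  group <- as.character(group)
  if (length(group) != nrow(values)) stop("one group label per subject required")
  complete <- stats::complete.cases(values)
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(sprintf("mixed_anova: dropping %d incomplete subject(s)", n_dropped))
    values <- values[complete, , drop = FALSE]
    group <- group[complete]
  }
  lev <- sort(unique(group))
  if (length(lev) != 2) stop("exactly two groups required")
  n_g <- table(factor(group, levels = lev))
  if (any(n_g < 2)) stop("each group needs >= 2 subjects")
  N <- nrow(values)
  if (is.null(condition_names)) condition_names <- colnames(values)

  g <- ifelse(group == lev[1], 1, -1)      # effect coding
  X <- cbind(1, g)
  XtXi <- solve(crossprod(X))

  # Between-subject stratum on subject means, scaled by k.
  msub <- rowMeans(values)
  b_b <- XtXi %*% crossprod(X, msub)
  ss_group <- k * b_b[2]^2 / XtXi[2, 2]
  fit_b <- X %*% b_b
  ss_subj <- k * sum((msub - fit_b)^2)
  df_subj <- N - 2

  # Within-subject stratum in an orthonormal contrast space.
  Ct <- contrast_basis(k)                  # k x (k-1), orthonormal, 1' C = 0
  Z <- values %*% Ct
  B <- XtXi %*% crossprod(X, Z)            # 2 x (k-1)
  ss_cond <- sum(B[1, ]^2) / XtXi[1, 1]
  ss_inter <- sum(B[2, ]^2) / XtXi[2, 2]
  E <- crossprod(Z) - t(B) %*% crossprod(X) %*% B
  ss_err_w <- sum(diag(E))
  df_err_w <- (k - 1) * (N - 2)

  # zap floating-point dust so structurally null effects are exact zeros
  tol_ss <- 1e-20 * (sum(values^2) + 1)
  zap <- function(s) if (abs(s) < tol_ss) 0 else s
  ss_group <- zap(ss_group); ss_subj <- zap(ss_subj)
  ss_cond <- zap(ss_cond); ss_inter <- zap(ss_inter)
  ss_err_w <- zap(ss_err_w)

  eps <- gg_epsilon(pooled_within_cov(values, group))

  eff <- function(name, ss, ss_err, df1, df2, use_eps) {
    e <- if (use_eps && is.finite(eps)) eps else 1
    Fv <- if (ss_err == 0) { if (ss == 0) 0 else Inf }
    else (ss / df1) / (ss_err / df2)
    data.frame(effect = name, ss = ss, ss_error = ss_err,
               df1 = df1, df2 = df2,
               gg_epsilon = if (use_eps) eps else NA_real_,
               df1_gg = df1 * e, df2_gg = df2 * e,
               F = Fv, p = pf(Fv, df1 * e, df2 * e, lower.tail = FALSE),
               partial_eta_sq = if (ss == 0) 0 else ss / (ss + ss_err),
               stringsAsFactors = FALSE)
  }
  effects <- rbind(
    eff("group", ss_group, ss_subj, 1, df_subj, use_eps = FALSE),
    eff("condition", ss_cond, ss_err_w, k - 1, df_err_w, use_eps = TRUE),
    eff("condition:group", ss_inter, ss_err_w, k - 1, df_err_w, use_eps = TRUE))
  structure(list(effects = effects, n_dropped = n_dropped, n_subjects = N,
                 group_levels = lev, condition_names = condition_names),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("<mixed_anova> %d subjects (%s), %d dropped\n",
              x$n_subjects, paste(x$group_levels, collapse = " vs "),
              x$n_dropped))
  df <- x$effects
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$partial_eta_sq <- round(df$partial_eta_sq, 3)
  print(df[, c("effect", "df1_gg", "df2_gg", "F", "p", "partial_eta_sq")],
        row.names = FALSE)
  invisible(x)
}

# Orthonormal basis of the contrast space (columns orthogonal to 1).
contrast_basis <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2L, sqrt(colSums(H^2)), "/")
}

# Pooled (within-group) covariance of the condition columns.
pooled_within_cov <- function(values, group) {
  lev <- unique(group)
  acc <- 0
  for (l in lev) {
    v <- values[group == l, , drop = FALSE]
    acc <- acc + stats::cov(v) * (nrow(v) - 1)
  }
  acc / (nrow(values) - length(lev))
}

#' Bonferroni-corrected pairwise condition comparisons
#'
#' Paired t tests on subject-wise differences for all `k(k-1)/2` unordered
#' condition pairs; p values are multiplied by the number of pairs and capped
#' at 1. The family is the set of pairs within one feature.
#'
#' @param values subjects x k numeric matrix (complete cases used).
#' @param condition_names optional condition names.
#' @param alpha_level significance level applied to the adjusted p values.
#' @return data.frame: pair labels, mean difference (i - j), t, df, raw and
#'   adjusted p, significance flag.
#' @export
bonferroni_posthoc <- function(values, condition_names = NULL,
                               alpha_level = 0.05) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  k <- ncol(values)
  if (is.null(condition_names))
    condition_names <- colnames(values) %||% paste0("C", seq_len(k))
  n_pairs <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- values[, i] - values[, j]
    n <- length(d)
    md <- mean(d)
    sdd <- sd(d)
    if (sdd == 0) {
      tv <- if (md == 0) 0 else Inf
      p_raw <- if (md == 0) 1 else 0
    } else {
      tv <- md / (sdd / sqrt(n))
      p_raw <- 2 * pt(abs(tv), n - 1, lower.tail = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      i = condition_names[i], j = condition_names[j],
      mean_diff = md, t = tv, df = n - 1,
      p_raw = p_raw, p_adj = min(1, n_pairs * p_raw),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$significant <- res$p_adj < alpha_level
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment-wise reliability of mMSE profiles and features
#'
#' Treats the first `k_items` epochs (40-s segments) of every subject as
#' repeated "items" and computes Cronbach's alpha per network for (i) every
#' scale of the mMSE profile and (ii) every curve feature.
#'
#' @param subjects list of [subject_network_mmse()] results.
#' @param k_items number of segments used as items (default 3).
#' @return An object of class `mmse_reliability`: list with `alpha_scales`
#'   (networks x scales matrix), `alpha_features` (networks x 4 matrix),
#'   `k_items`, `n_subjects`.
#' @export
mmse_reliability <- function(subjects, k_items = 3) {
  stopifnot(length(subjects) >= 3)
  networks <- names(subjects[[1]]$networks)
  n_scales <- subjects[[1]]$params$max_scale
  feats <- c("AUC", "MaxSlope", "AvgEnt", "DiffEnt")
  a_sc <- matrix(NA_real_, length(networks), n_scales,
                 dimnames = list(networks, paste0("scale", seq_len(n_scales))))
  a_ft <- matrix(NA_real_, length(networks), length(feats),
                 dimnames = list(networks, feats))
  for (nm in networks) {
    per <- lapply(subjects, function(su) su$networks[[nm]]$per_epoch)
    enough <- vapply(per, function(m) !is.null(m) && nrow(m) >= k_items,
                     logical(1))
    per <- per[enough]
    if (length(per) < 3) next
    for (s in seq_len(n_scales)) {
      items <- vapply(per, function(m) m[seq_len(k_items), s],
                      numeric(k_items))
      if (all(is.finite(items)))
        a_sc[nm, s] <- cronbach_alpha(items)
    }
    for (f in feats) {
      fun <- switch(f, AUC = mmse_auc, MaxSlope = mmse_max_slope,
                    AvgEnt = mmse_avg_ent, DiffEnt = mmse_diff_ent)
      items <- vapply(per, function(m) {
        apply(m[seq_len(k_items), , drop = FALSE], 1L, fun)
      }, numeric(k_items))
      if (all(is.finite(items)))
        a_ft[nm, f] <- cronbach_alpha(items)
    }
  }
  structure(list(alpha_scales = a_sc, alpha_features = a_ft,
                 k_items = k_items, n_subjects = length(subjects)),
            class = "mmse_reliability")
}
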