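test_that("Cronbach's alpha matches hand-computed and limiting cases", {
  v <- matrix(rnorm(30), 1)
  ident <- rbind(v, v, v)
  expect_equal(cronbach_alpha(ident), 1)

  set.seed(42)
  indep <- matrix(rnorm(3 * 10000), 3)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)

  # 3 x 5 integer toy matrix; expected value from the definitional formula
  # evaluated by hand: item variances 2.5, 2.3, 2.7; var of sums 21.3;
  # alpha = 1.5 * (1 - 7.5/21.3) = 69/71.
  toy <- rbind(c(1, 2, 3, 4, 5), c(2, 2, 3, 5, 5), c(0, 1, 3, 3, 4))
  expect_equal(cronbach_alpha(toy), 69 / 71, tolerance = 1e-12)

  # invariances: constant shift of one item; common rescaling of all items
  expect_equal(cronbach_alpha(toy + c(10, 0, 0)), cronbach_alpha(toy))
  expect_equal(cronbach_alpha(toy * 3.7), cronbach_alpha(toy))

  const <- matrix(1, 3, 5)
  a <- cronbach_alpha(const)
  expect_true(is.na(a))
  expect_equal(attr(a, "undefined"), "zero_total_variance")
  expect_error(cronbach_alpha(toy[1, , drop = FALSE]), ">= 2 items")
})

test_that("Greenhouse-Geisser epsilon: sphericity, bounds, eigen-oracle", {
  # compound symmetry -> epsilon = 1
  cs <- matrix(0.4, 5, 5); diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1)

  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(rnorm(30 * 7), 30, 7) %*% matrix(rnorm(49), 7)
    S <- stats::cov(X)
    eps <- gg_epsilon(S)
    expect_gte(eps, 1 / 6)
    expect_lte(eps, 1)
    # eigen-decomposition oracle on the double-centered matrix
    k <- 7
    C <- diag(k) - 1 / k
    lam <- eigen(C %*% S %*% C, symmetric = TRUE)$values
    lam <- lam[lam > 1e-12]
    oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(eps, min(1, max(1 / (k - 1), oracle)), tolerance = 1e-10)
  }
  expect_true(is.na(gg_epsilon(matrix(0, 4, 4))))
})

test_that("mixed ANOVA null effects are exactly zero", {
  set.seed(1)
  base <- matrix(rnorm(10 * 7), 10, 7)
  vals <- rbind(base, base)              # both groups identical
  grp <- rep(c("a", "b"), each = 10)
  res <- mixed_anova(vals, grp)
  expect_equal(res$effects$F[res$effects$effect == "group"], 0)

  # identical condition columns per subject -> condition F = 0
  subj <- rnorm(12)
  vals2 <- matrix(rep(subj, 7), 12, 7)
  res2 <- mixed_anova(vals2, rep(c("a", "b"), each = 6))
  expect_equal(res2$effects$F[res2$effects$effect == "condition"], 0)
})

test_that("mixed ANOVA matches the aov split-plot oracle on balanced data", {
  set.seed(20)
  N <- 40; k <- 7
  net_off <- seq(0, 1.2, length.out = k)
  grp <- rep(c("a", "b"), each = N / 2)
  vals <- matrix(rnorm(N * k, sd = 0.8), N, k)
  vals <- sweep(vals, 2, net_off, "+")
  vals[grp == "a", ] <- vals[grp == "a", ] +
    outer(rep(1, N / 2), c(0.5, 0, -0.5, 0, 0.3, 0, -0.3))
  vals <- vals + rnorm(N)                 # subject random effect

  res <- mixed_anova(vals, grp)

  df <- data.frame(y = as.vector(vals),
                   subject = factor(rep(seq_len(N), k)),
                   network = factor(rep(seq_len(k), each = N)),
                   group = factor(rep(grp, k)))
  oracle <- summary(stats::aov(y ~ group * network + Error(subject / network),
                               data = df))
  o_between <- oracle[["Error: subject"]][[1]]
  o_within <- oracle[["Error: subject:network"]][[1]]

  eff <- res$effects
  expect_equal(eff$ss[eff$effect == "group"], o_between["group", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(eff$ss_error[eff$effect == "group"],
               o_between["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "group"], o_between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(eff$ss[eff$effect == "condition"],
               o_within["network", "Sum Sq"], tolerance = 1e-8)
  expect_equal(eff$ss[eff$effect == "condition:group"],
               o_within["group:network", "Sum Sq"], tolerance = 1e-8)
  expect_equal(eff$ss_error[eff$effect == "condition"],
               o_within["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "condition"],
               o_within["network", "F value"], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "condition:group"],
               o_within["group:network", "F value"], tolerance = 1e-8)
  # uncorrected dfs and the partial-eta-squared identity
  expect_equal(eff$df1, c(1, 6, 6))
  expect_equal(eff$df2, c(38, 228, 228))
  pe <- eff$F * eff$df1 / (eff$F * eff$df1 + eff$df2)
  expect_equal(eff$partial_eta_sq, pe, tolerance = 1e-10)
  # GG-corrected dfs are epsilon-scaled
  eps <- eff$gg_epsilon[2]
  expect_equal(eff$df1_gg[2], 6 * eps)
  expect_equal(eff$df2_gg[2], 228 * eps)
})

test_that("mixed ANOVA handles unbalanced groups and incomplete cases", {
  set.seed(3)
  vals <- matrix(rnorm(23 * 7), 23, 7)
  grp <- rep(c("a", "b"), c(10, 13))
  res <- mixed_anova(vals, grp)
  expect_equal(res$effects$df2[1], 21)
  vals[2, 3] <- NA
  expect_message(res2 <- mixed_anova(vals, grp), "dropping 1")
  expect_equal(res2$n_subjects, 22)
  expect_error(mixed_anova(vals[1:3, ], c("a", "a", "b")), ">= 2 subjects")
})

test_that("Bonferroni post-hoc table follows its definition", {
  set.seed(5)
  vals <- matrix(rnorm(30 * 7), 30, 7)
  colnames(vals) <- paste0("N", 1:7)
  vals[, 14 + 1 - 14] <- vals[, 1]       # no-op, keep shapes obvious
  res <- bonferroni_posthoc(vals)
  expect_equal(nrow(res), 21)
  # adjusted p = min(1, 21 * raw p) everywhere, raw p from a paired t oracle
  for (r in sample(nrow(res), 5)) {
    i <- match(res$i[r], colnames(vals)); j <- match(res$j[r], colnames(vals))
    tt <- stats::t.test(vals[, i], vals[, j], paired = TRUE)
    expect_equal(res$p_raw[r], tt$p.value, tolerance = 1e-12)
    expect_equal(res$p_adj[r], min(1, 21 * tt$p.value), tolerance = 1e-12)
  }
  # identical pair
  vals2 <- cbind(vals[, 1:6], vals[, 6])
  colnames(vals2) <- paste0("N", 1:7)
  res2 <- bonferroni_posthoc(vals2)
  row <- res2[res2$i == "N6" & res2$j == "N7", ]
  expect_equal(row$p_adj, 1)
  expect_equal(row$mean_diff, 0)
  # one condition offset by a large effect: exactly its 6 pairs significant
  vals3 <- matrix(rnorm(40 * 7, sd = 0.3), 40, 7)
  colnames(vals3) <- paste0("N", 1:7)
  vals3[, 4] <- vals3[, 4] + 2
  res3 <- bonferroni_posthoc(vals3)
  sig <- res3$significant
  has4 <- res3$i == "N4" | res3$j == "N4"
  expect_true(all(sig[has4]))
  expect_false(any(sig[!has4]))
})
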