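test_that("with no unpaired observations the Welch variant is the paired t test", {
  set.seed(1)
  x <- rnorm(10, 1, 2); y <- rnorm(10)
  ours <- partially_paired_test(paired_x = x, paired_y = y, var_equal = FALSE)
  ref <- t.test(x, y, paired = TRUE)
  expect_lt(abs(unname(ours$statistic) - unname(ref$statistic)), 1e-10)
  expect_equal(unname(ours$parameter), unname(ref$parameter))
  expect_lt(abs(ours$p.value - ref$p.value), 1e-10)
})

test_that("with no paired observations the pooled variant is the pooled two-sample t test", {
  set.seed(2)
  a <- rnorm(12, 0.5); b <- rnorm(15)
  ours <- partially_paired_test(unpaired_x = a, unpaired_y = b,
                                var_equal = TRUE)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_lt(abs(unname(ours$statistic) - unname(ref$statistic)), 1e-10)
  expect_equal(unname(ours$parameter), unname(ref$parameter))
})

test_that("the partially paired statistic is shift invariant and scale equivariant", {
  set.seed(3)
  px <- rnorm(7); py <- rnorm(7); ux <- rnorm(15); uy <- rnorm(12)
  base <- partially_paired_test(px, py, ux, uy)
  shift <- partially_paired_test(px + 5, py + 5, ux + 5, uy + 5)
  expect_equal(unname(shift$statistic), unname(base$statistic),
               tolerance = 1e-12)
  scaled <- partially_paired_test(3 * px, 3 * py, 3 * ux, 3 * uy)
  expect_equal(unname(scaled$statistic), unname(base$statistic),
               tolerance = 1e-12)
  expect_equal(unname(scaled$estimate), 3 * unname(base$estimate),
               tolerance = 1e-12)
})

test_that("degenerate partially paired inputs raise errors", {
  expect_error(partially_paired_test(paired_x = 1:3, paired_y = 1:2), "equal length")
  expect_error(partially_paired_test(paired_x = c(1, 1, 1), paired_y = c(2, 2, 2)),
               "variance|standard error")
  expect_error(partially_paired_test(unpaired_x = 1, unpaired_y = 1:5),
               "two observations")
})

test_that("Holm step-down matches the hand-worked example and p.adjust", {
  hb <- holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(hb$p.adjusted, c(0.03, 0.06, 0.06))
  expect_identical(hb$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(0.2)$p.adjusted, 0.2)
  all1 <- holm_bonferroni(rep(1, 5))
  expect_true(all(all1$p.adjusted == 1) && !any(all1$reject))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    hb <- holm_bonferroni(p)
    expect_equal(hb$p.adjusted, p.adjust(p, "holm"), tolerance = 1e-12)
    # every plain-Bonferroni rejection is also a Holm rejection
    bonf <- p.adjust(p, "bonferroni") < 0.05
    expect_true(all(hb$reject[bonf]))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("PLS selects one component with Q2 near 1 on noiseless rank-1 data", {
  set.seed(5)
  n <- 20
  t_lat <- rnorm(n)
  X <- outer(t_lat, c(1, -0.5, 2, 0.8, -1.2))
  y <- 2 * t_lat
  fit <- pls_fit_select(X, y)
  expect_identical(fit$n_components, 1L)
  expect_gt(fit$q2, 0.99)
  expect_gt(fit$r2, 0.999)
})

test_that("PLS reports a non-predictive model on permuted responses", {
  set.seed(6)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- drop(X %*% c(2, -1, 1, 0, 0, 0))
  # Q2 of the all-variable model at one component (the selected-prefix Q2
  # is maximized over prefixes and is optimistically biased by construction)
  q2s <- replicate(11, pls_fit_select(X, sample(y))$component_q2_trace[1])
  expect_lte(median(q2s), 0)
})

test_that("squared VIP scores average to one for any fitted model", {
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(25 * 8), 25, 8)
    y <- rnorm(25)
    f <- remodelr:::pls1_fit(scale(X), drop(scale(y)), sample(1:3, 1))
    expect_equal(mean(remodelr:::pls1_vip(f)^2), 1, tolerance = 1e-10)
  }
})

test_that("PLS selection is deterministic across reruns", {
  set.seed(8)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(X %*% c(1.5, -1, rep(0, 8))) + rnorm(30, 0, 0.3)
  a <- pls_fit_select(X, y)
  b <- pls_fit_select(X, y)
  expect_identical(a$variables, b$variables)
  expect_identical(a$q2, b$q2)
})

test_that("informative predictors take the top VIP ranks in at least 90% of replicates", {
  set.seed(9)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(40 * 12, 0, 0.5), 40, 12)
    X[, 1] <- X[, 1] + rnorm(40)            # effect SD 1 vs noise SD 0.5
    X[, 2] <- X[, 2] + rnorm(40)
    y <- X[, 1] + X[, 2] + rnorm(40, 0, 0.5)
    f <- remodelr:::pls1_fit(scale(X), drop(scale(y)), 2)
    top2 <- sort(order(remodelr:::pls1_vip(f), decreasing = TRUE)[1:2])
    if (identical(top2, c(1L, 2L))) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("NIPALS scores and predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(10)
  X <- matrix(rnorm(25 * 7), 25, 7)
  y <- drop(X %*% c(1, -2, 0.5, 0, 0, 1, 0)) + rnorm(25, 0, 0.2)
  mo <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = TRUE)
  ours <- remodelr:::pls1_fit(scale(X), drop(scale(y)), 2)
  expect_gt(abs(cor(mo$variates$X[, 1], ours$T[, 1])), 1 - 1e-8)
  expect_gt(abs(cor(mo$variates$X[, 2], ours$T[, 2])), 1 - 1e-8)
})

test_that("constant predictors are dropped with a warning; degenerate inputs error", {
  set.seed(11)
  X <- data.frame(a = rnorm(15), b = rep(1, 15), c = rnorm(15))
  y <- X$a + rnorm(15, 0, 0.1)
  expect_warning(fit <- pls_fit_select(X, y), "constant")
  expect_false("b" %in% fit$variables$variable)
  expect_error(pls_fit_select(X[, "a", drop = FALSE], rep(2, 15)), "response")
  expect_error(pls_fit_select(data.frame(a = c(1, NA, 3, 4)), 1:4), "missing")
})

test_that("tidy and glance return one-row-per-term summaries", {
  set.seed(12)
  X <- matrix(rnorm(20 * 4), 20, 4)
  colnames(X) <- paste0("v", 1:4)
  y <- drop(X %*% c(2, 1, 0, 0)) + rnorm(20, 0, 0.2)
  fit <- pls_fit_select(X, y)
  td <- tidy(fit)
  expect_true(all(c("variable", "vip", "coefficient") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  ht <- partially_paired_test(rnorm(6), rnorm(6), rnorm(5), rnorm(4))
  expect_identical(nrow(tidy(ht)), 1L)
})
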