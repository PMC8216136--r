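# Bespoke study statistics: the partially overlapping-samples t test
# (Derrick-style), Holm step-down correction, and PLS1 regression with
# leave-one-out Q2 component selection and VIP-sorted variable inclusion.

#' Partially overlapping-samples t test
#'
#' Compares two group means when some observations are paired across the
#' groups and the rest are independent, using both parts without discarding
#' either. The pooled-variance statistic (default) is
#' \deqn{t = (\bar x_1 - \bar x_2) / (S_p \sqrt{1/n_1 + 1/n_2 - 2 r n_{12}/(n_1 n_2)})}
#' with \eqn{S_p} the pooled SD over all observations, \eqn{r} the Pearson
#' correlation of the paired part, \eqn{n_{12}} the number of pairs, and
#' interpolated degrees of freedom
#' \eqn{\nu = (n_{12}-1) + \frac{n_a + n_b + n_{12} - 1}{n_a + n_b + 2 n_{12}} (n_a + n_b)}.
#' The unequal-variance variant replaces the pooled SD with per-group
#' variances (Welch form) and \eqn{(n_a+n_b)} in \eqn{\nu} with the
#' Welch-Satterthwaite degrees of freedom. With no pairs the pooled variant
#' reduces exactly to the pooled two-sample t test; with no unpaired
#' observations the unequal-variance variant reduces exactly to the paired
#' t test.
#'
#' @param paired_x,paired_y Paired observations (equal length; may be empty).
#' @param unpaired_x,unpaired_y Independent observations per group.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param var_equal Use the pooled-variance statistic (default TRUE).
#' @return Object of class `partially_paired_test` (and `htest`): statistic,
#'   df, p.value, estimate (mean difference).
#' @export
partially_paired_test <- function(paired_x = numeric(), paired_y = numeric(),
                                  unpaired_x = numeric(),
                                  unpaired_y = numeric(),
                                  alternative = c("two.sided", "less",
                                                  "greater"),
                                  var_equal = TRUE) {
  alternative <- match.arg(alternative)
  if (length(paired_x) != length(paired_y))
    abort("paired samples must have equal length")
  n12 <- length(paired_x)
  na <- length(unpaired_x); nb <- length(unpaired_y)
  x <- c(paired_x, unpaired_x); y <- c(paired_y, unpaired_y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("need at least two observations per group")
  s1 <- var(x); s2 <- var(y)
  if (s1 <= 0 && s2 <= 0) abort("all-zero variance in both groups")
  r <- if (n12 >= 2) stats::cor(paired_x, paired_y) else 0
  if (!is.finite(r)) r <- 0
  mdiff <- mean(x) - mean(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2 - 2 * r * n12 / (n1 * n2)))
    tail_df <- na + nb
  } else {
    se <- sqrt(s1 / n1 + s2 / n2 -
                 2 * r * sqrt(s1) * sqrt(s2) * n12 / (n1 * n2))
    welch <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
    tail_df <- if (na + nb > 0) min(na + nb, welch) else 0
  }
  if (!is.finite(se) || se <= 0) abort("degenerate standard error")
  stat <- mdiff / se
  df <- (n12 - 1) + (na + nb + n12 - 1) / (na + nb + 2 * n12) * tail_df
  if (n12 == 0) df <- if (var_equal) n1 + n2 - 2 else
    (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(stat), df),
              less = pt(stat, df),
              greater = pt(stat, df, lower.tail = FALSE))
  out <- list(statistic = c(t = stat), parameter = c(df = df), p.value = p,
              estimate = c(`mean difference` = mdiff),
              alternative = alternative,
              method = paste0("Partially overlapping-samples t test (",
                              if (var_equal) "pooled" else "unequal",
                              " variance)"),
              data.name = sprintf("%d paired, %d/%d unpaired", n12, na, nb))
  class(out) <- c("partially_paired_test", "htest")
  out
}

#' @method tidy partially_paired_test
#' @export
tidy.partially_paired_test <- function(x, ...) {
  tibble(estimate = unname(x$estimate), statistic = unname(x$statistic),
         df = unname(x$parameter), p.value = x$p.value,
         alternative = x$alternative, method = x$method)
}

#' Holm step-down multiple-testing correction
#'
#' Step-down adjustment: order the m raw p-values increasingly, multiply the
#' i-th by (m - i + 1), enforce monotonicity by running maxima, cap at 1.
#' A hypothesis is rejected when its adjusted p-value is below alpha.
#'
#' @param pvalues Raw p-values in `[0, 1]`.
#' @param alpha Familywise error rate.
#' @return Tibble: p.value, p.adjusted, reject (in input order).
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    abort("p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  adj <- pmin(1, pvalues[ord] * (m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  tibble(p.value = pvalues, p.adjusted = out, reject = out < alpha)
}

# ---- PLS1 (NIPALS) ----------------------------------------------------------

# core fit on standardized data; y univariate
pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp)
  Xd <- X
  yd <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    pv <- drop(crossprod(Xd, t)) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - q * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; qv[a] <- q
  }
  if (ncomp == 0) return(NULL)
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  beta <- W %*% solve(crossprod(P, W), qv)
  list(W = W, P = P, T = Tm, q = qv, beta = drop(beta), ncomp = ncomp)
}

pls1_vip <- function(fit) {
  ss <- fit$q^2 * colSums(fit$T^2)           # variance explained per component
  wn <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), "/")
  sqrt(nrow(fit$W) * drop(wn^2 %*% ss) / sum(ss))
}

# leave-one-out Q2 at a fixed number of components; standardization is done
# inside each fold (no leakage); TSS about each fold's training mean
pls1_q2 <- function(X, y, ncomp) {
  n <- nrow(X)
  press <- 0; tss <- 0
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]; yt <- y[-i]
    cx <- colMeans(Xt); sx <- apply(Xt, 2, sd)
    sx[sx < 1e-12] <- 1
    cy <- mean(yt); sy <- sd(yt)
    if (sy < 1e-12) sy <- 1
    fit <- pls1_fit(scale(Xt, cx, sx), (yt - cy) / sy, ncomp)
    pred <- if (is.null(fit)) cy else
      cy + sy * sum(((X[i, ] - cx) / sx) * fit$beta)
    press <- press + (y[i] - pred)^2
    tss <- tss + (y[i] - cy)^2
  }
  1 - press / tss
}

#' PLS regression with Q2-based component and VIP-based variable selection
#'
#' Implements the study's model-building procedure on a standardized
#' (mean 0, SD 1) predictor table and response: (1) components are added
#' while leave-one-out cross-validated Q2 improves by at least `delta_q2`
#' (0.0975 by default); (2) variables are sorted by VIP (variable influence
#' on projection) from the all-variable model and included iteratively,
#' refitting on each growing prefix, until Q2 no longer improves (strict
#' improvement by default). Constant predictors are dropped with a warning.
#' Deterministic: leave-one-out has no randomness.
#'
#' @param X Data frame or matrix of predictors (complete cases required).
#' @param y Numeric response.
#' @param max_components Cap on the number of latent components.
#' @param delta_q2 Minimum Q2 improvement to add a component.
#' @param variable_rule "strict" (stop when Q2 fails to exceed the best so
#'   far) or "delta" (require improvement of at least `delta_q2`).
#' @return A `pls_report`: selected variables with standardized coefficients
#'   and VIP scores, n_components, per-step Q2 trace, final R2 and Q2.
#' @export
pls_fit_select <- function(X, y, max_components = 5, delta_q2 = 0.0975,
                           variable_rule = c("strict", "delta")) {
  variable_rule <- match.arg(variable_rule)
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y))
    abort("missing values are not supported: incompletely measured variables must be excluded upstream")
  if (length(y) != nrow(X)) abort("X and y sizes differ")
  if (nrow(X) < 4) abort("need at least 4 observations")
  if (sd(y) < 1e-12) abort("degenerate (constant) response")
  keep <- vapply(X, function(col) sd(col) > 1e-12, logical(1))
  if (!all(keep)) {
    warn(paste0("dropping constant predictor(s): ",
                paste(names(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0) abort("no non-constant predictors")
  Xm <- as.matrix(X)
  n <- nrow(Xm)

  select_ncomp <- function(Xs, ys) {
    amax <- min(max_components, ncol(Xs), n - 2)
    q2 <- pls1_q2(Xs, ys, 1)
    trace <- q2
    a <- 1L
    while (a < amax) {
      q2_next <- pls1_q2(Xs, ys, a + 1L)
      trace <- c(trace, q2_next)
      if (q2_next - q2 < delta_q2) break
      q2 <- q2_next
      a <- a + 1L
    }
    list(ncomp = a, q2 = q2, trace = trace)
  }

  # full-variable model: components, VIP ranking
  full_sel <- select_ncomp(Xm, y)
  cx <- colMeans(Xm); sx <- apply(Xm, 2, sd)
  cy <- mean(y); sy <- sd(y)
  Xs_full <- scale(Xm, cx, sx); ys_full <- (y - cy) / sy
  full_fit <- pls1_fit(Xs_full, ys_full, full_sel$ncomp)
  vip <- pls1_vip(full_fit)
  names(vip) <- colnames(Xm)
  ord <- order(vip, decreasing = TRUE)

  # VIP-sorted iterative variable inclusion
  best_q2 <- -Inf
  best_k <- 1L
  steps <- list()
  sel_trace <- numeric(0)
  for (k in seq_along(ord)) {
    cols <- ord[seq_len(k)]
    sub <- select_ncomp(Xm[, cols, drop = FALSE], y)
    sel_trace[k] <- sub$q2
    improved <- if (variable_rule == "strict") sub$q2 > best_q2
                else sub$q2 - best_q2 >= delta_q2
    if (k == 1L || improved) {
      best_q2 <- sub$q2; best_k <- k
    } else break
  }
  cols <- ord[seq_len(best_k)]
  final_sel <- select_ncomp(Xm[, cols, drop = FALSE], y)
  Xf <- Xm[, cols, drop = FALSE]
  cxf <- colMeans(Xf); sxf <- apply(Xf, 2, sd)
  fitf <- pls1_fit(scale(Xf, cxf, sxf), (y - cy) / sy, final_sel$ncomp)
  yhat <- cy + sy * drop(scale(Xf, cxf, sxf) %*% fitf$beta)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - cy)^2)
  vipf <- pls1_vip(fitf); names(vipf) <- colnames(Xf)

  structure(list(
    variables = tibble(variable = colnames(Xf),
                       vip = unname(vipf),
                       coefficient = unname(fitf$beta)) |>
      arrange(desc(.data$vip)),
    n_components = final_sel$ncomp,
    q2 = final_sel$q2, r2 = r2,
    component_q2_trace = full_sel$trace,
    variable_q2_trace = sel_trace,
    vip_full = sort(vip, decreasing = TRUE),
    predictive = final_sel$q2 > 0,
    scaling = list(center = 0, sd = 1),
    n = n), class = "pls_report")
}

#' @export
print.pls_report <- function(x, ...) {
  cat(sprintf("<pls_report> %d component(s), Q2 = %.3f, R2 = %.3f%s\n",
              x$n_components, x$q2, x$r2,
              if (!x$predictive) "  [non-predictive]" else ""))
  print(x$variables)
  invisible(x)
}

#' @method tidy pls_report
#' @export
tidy.pls_report <- function(x, ...) x$variables

#' @method glance pls_report
#' @export
glance.pls_report <- function(x, ...) {
  tibble(n_components = x$n_components, q2 = x$q2, r2 = x$r2,
         n_variables = nrow(x$variables), n = x$n,
         predictive = x$predictive)
}
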