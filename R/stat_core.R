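# Self-contained statistical kernels shared by the pipeline. Each is
# written out from its defining formula so it can be cross-checked against
# an independent oracle (stats::t.test, stats::wilcox.test,
# stats::oneway.test, brute-force enumeration) in the test suite.
# All p-values are two-sided.

test_result <- function(statistic, p_value, df = NA_real_, method,
                        extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, df = df,
                   method = method), extra),
            class = "vp_test")
}

#' @export
print.vp_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (is.na(x$df)) "" else sprintf(", df = %.3g", x$df)))
  invisible(x)
}

#' Welch's unpaired two-sample t-test
#'
#' Heteroscedastic t statistic with Satterthwaite degrees of freedom;
#' `pooled = TRUE` gives the classical Student pooled-variance test
#' instead.
#'
#' @param a,b Numeric vectors, each with at least 2 non-missing values.
#' @param pooled Use the pooled-variance (Student) form.
#' @return A `vp_test` with `statistic` (t), `p_value` (two-sided), `df`.
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      stop("degenerate comparison: both groups constant and equal",
           call. = FALSE)
    }
    # constant but different groups: infinite separation
    return(test_result(sign(mean(a) - mean(b)) * Inf, 0, na + nb - 2,
                       if (pooled) "student_t" else "welch_t"))
  }
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    method <- "student_t"
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    method <- "welch_t"
  }
  t <- (mean(a) - mean(b)) / se
  p <- 2 * stats::pt(-abs(t), df)
  test_result(t, p, df, method,
              extra = list(mean_a = mean(a), mean_b = mean(b),
                           n_a = na, n_b = nb))
}

#' Mann-Whitney U test
#'
#' The U statistic follows the `stats::wilcox.test` orientation,
#' `U = #\{(i, j): a_i > b_j\} + ties / 2`. In `auto` mode the exact
#' permutation distribution (all `choose(n_a + n_b, n_a)` labelings) is
#' enumerated when both groups have at most 8 values and the data are
#' tie-free; otherwise the normal approximation with midranks, tie-corrected
#' variance and continuity correction is used. `exact` mode refuses ties and
#' falls back to `normal` with a warning.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A `vp_test` with `statistic` (U) and two-sided `p_value`;
#'   `method` records which path ran.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("each group needs >= 1 value", call. = FALSE)
  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0L
  if (mode == "exact" && has_ties) {
    warning("ties present: exact Mann-Whitney enumeration refused, ",
            "using normal approximation")
    mode <- "normal"
  }
  if (mode == "auto") {
    mode <- if (na <= 8L && nb <= 8L && !has_ties) "exact" else "normal"
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "exact") {
    p <- mw_exact_p(pooled, na, u)
    return(test_result(u, p, method = "mann_whitney_exact",
                       extra = list(n_a = na, n_b = nb)))
  }
  mu <- na * nb / 2
  n <- na + nb
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) {
    return(test_result(u, 1, method = "mann_whitney_normal",
                       extra = list(n_a = na, n_b = nb)))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(u, p, method = "mann_whitney_normal",
              extra = list(n_a = na, n_b = nb, z = z))
}

# Exact two-sided p by full enumeration of group labelings: p is the
# permutation probability of a U at least as far from n1*n2/2 as observed.
mw_exact_p <- function(pooled, na, u_obs) {
  n <- length(pooled)
  nb <- n - na
  r <- rank(pooled)
  combs <- utils::combn(n, na)
  offset <- na * (na + 1) / 2
  us <- colSums(matrix(r[combs], nrow = na)) - offset
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' One-way Welch (heteroscedastic) ANOVA
#'
#' Welch's F with adjusted denominator degrees of freedom. With exactly two
#' groups it reduces algebraically to the square of [welch_t()].
#'
#' @param groups List of numeric vectors, each with >= 2 values and nonzero
#'   variance (degenerate groups are rejected).
#' @return A `vp_test` with `statistic` (F), `p_value`, `df` (numerator),
#'   and `df2` (denominator).
#' @export
welch_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- Filter(function(g) length(g) >= 2L, groups)
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("zero-variance group in Welch ANOVA", call. = FALSE)
  w <- n / v
  sw <- sum(w)
  mw <- sum(w * m) / sw
  num <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- 3 * sum((1 - w / sw)^2 / (n - 1)) / (k^2 - 1)
  f <- num / (1 + 2 * lambda * (k - 2) / 3)
  df1 <- k - 1
  df2 <- 1 / lambda
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  test_result(f, p, df1, "welch_anova", extra = list(df2 = df2, n = n))
}

#' Dunnett many-to-one comparisons (seeded Monte-Carlo)
#'
#' Compares every treatment group against a control with Welch t statistics
#' and adjusts the family of two-sided p-values for the maximum-|t|
#' distribution under the standard Dunnett correlation structure
#' (`rho_ij = sqrt(lambda_i * lambda_j)` with
#' `lambda_i = (s0^2/n0) / (s0^2/n0 + s_i^2/n_i)`). The multivariate-t
#' integral is evaluated by seeded Monte-Carlo; with a single comparison
#' this reduces to the unadjusted Welch t-test (up to MC error).
#'
#' @param groups List of numeric vectors.
#' @param control_index Which element of `groups` is the control.
#' @param mc_draws Monte-Carlo sample size (default 1e5).
#' @param mc_seed Optional integer seed for the MC draw (local RNG stream;
#'   the caller's RNG state is untouched).
#' @return List with `raw`, `adjusted` (both length `length(groups) - 1`,
#'   in group order with the control removed), `statistic`, `df`,
#'   `comparison` labels, and `procedure = "dunnett"`.
#' @export
dunnett_adjust <- function(groups, control_index = 1L, mc_draws = 1e5,
                           mc_seed = NULL) {
  k_all <- length(groups)
  if (k_all < 2L) stop("need a control and >= 1 treatment group",
                       call. = FALSE)
  ctrl <- groups[[control_index]]
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) < 2L) stop("control group needs >= 2 values",
                              call. = FALSE)
  trt <- groups[-control_index]
  trt <- lapply(trt, function(g) g[!is.na(g)])
  if (any(lengths(trt) < 2L)) stop("treatment groups need >= 2 values",
                                   call. = FALSE)
  n0 <- length(ctrl); v0 <- stats::var(ctrl)
  k <- length(trt)
  tstat <- df <- lambda <- raw <- numeric(k)
  for (i in seq_len(k)) {
    res <- welch_t(trt[[i]], ctrl)
    tstat[i] <- res$statistic; df[i] <- res$df; raw[i] <- res$p_value
    vi <- stats::var(trt[[i]]); ni <- length(trt[[i]])
    lambda[i] <- (v0 / n0) / (v0 / n0 + vi / ni)
  }
  # MC draw of (T_1..T_k): shared control component gives the Dunnett
  # correlation; per-comparison chi-square denominators carry the df.
  draw_max <- local({
    run <- function() {
      z0 <- stats::rnorm(mc_draws)
      tmax <- rep(0, mc_draws)
      for (i in seq_len(k)) {
        zi <- sqrt(lambda[i]) * z0 + sqrt(1 - lambda[i]) * stats::rnorm(mc_draws)
        ti <- zi / sqrt(stats::rchisq(mc_draws, df[i]) / df[i])
        tmax <- pmax(tmax, abs(ti))
      }
      tmax
    }
    if (is.null(mc_seed)) run()
    else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(mc_seed)
      run()
    }
  })
  adjusted <- vapply(abs(tstat),
                     function(t0) mean(draw_max >= t0), numeric(1))
  adjusted <- pmin(1, pmax(adjusted, raw))  # adjusted >= raw, always
  names(adjusted) <- names(raw) <- names(trt)
  list(raw = raw, adjusted = adjusted, statistic = tstat, df = df,
       procedure = "dunnett", control_index = control_index)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the raw p-values ascending and applies the step-down Sidak
#' formula `1 - (1 - p_(j))^(m - j + 1)`, enforcing monotonicity with a
#' running maximum, then maps back to input order.
#'
#' @param raw Numeric vector of p-values in \[0, 1\].
#' @return List with `raw`, `adjusted` (input order) and
#'   `procedure = "holm_sidak"`.
#' @export
holm_sidak <- function(raw) {
  if (any(is.na(raw)) || any(raw < 0 | raw > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(raw)
  o <- order(raw)
  sorted <- raw[o]
  adj_sorted <- cummax(pmin(1, 1 - (1 - sorted)^(m - seq_len(m) + 1)))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(raw = raw, adjusted = adjusted, procedure = "holm_sidak")
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `d = (mean(a) - mean(b)) / s_p` with
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors, each with at least 2 non-missing values.
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values", call. = FALSE)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("pooled SD is zero: Cohen's d undefined", call. = FALSE)
  (mean(a) - mean(b)) / sp
}

#' Pearson correlation with t-distribution p-value
#'
#' `r` with a two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, computed over pairwise-complete values.
#'
#' @param x,y Numeric vectors of equal length with >= 3 complete pairs.
#' @return A `vp_test` with `statistic` (r), `p_value`, `df`, and `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  test_result(r, p, n - 2, "pearson_t", extra = list(n = n))
}
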