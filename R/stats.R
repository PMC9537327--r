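#' One-sample and paired t tests with Cohen's d
#'
#' Computed from the defining formulas: `t = (mean - mu0) / (sd / sqrt(n))`,
#' two-sided p from the central t distribution, and `d = (mean - mu0) / sd`.
#' A paired test supplies `y` and reduces to a one-sample test on the
#' differences.
#'
#' @param x numeric sample (or first member of the pairs).
#' @param mu0 null value (one-sample; default 0).
#' @param y optional second member of the pairs.
#' @return List of class `fl_test`: `statistic`, `df`, `p`, `d`, `mean`,
#'   `sd`, `n`, `method`.
#' @examples
#' t_tests(c(0.58, 0.62, 0.55, 0.65), mu0 = 0.5)
#' @export
t_tests <- function(x, mu0 = 0, y = NULL) {
  method <- "one-sample t"
  if (!is.null(y)) {
    fl_assert(length(x) == length(y), "fl_parameter_error",
              "paired test needs equal-length vectors")
    x <- x - y
    mu0 <- 0
    method <- "paired t"
  }
  fl_assert(length(x) >= 2 && all(is.finite(x)), "fl_parameter_error",
            "need >= 2 finite values")
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {                          # degenerate: no spread
    d <- if (m == mu0) 0 else sign(m - mu0) * Inf
  } else d <- (m - mu0) / s
  tt <- d * sqrt(n)
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  structure(list(statistic = tt, df = n - 1, p = p, d = d,
                 mean = m, sd = s, n = n, method = method),
            class = "fl_test")
}

#' @export
print.fl_test <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$method, x$df, x$statistic, x$p, x$d))
  invisible(x)
}

#' Holm (step-down Bonferroni) adjustment
#'
#' Sorts the p values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by running maxima, caps at 1 and
#' returns the values in the original order.
#'
#' @param p vector of p values in [0, 1].
#' @param method "holm" (default) or plain "bonferroni".
#' @return Adjusted p values.
#' @export
holm_adjust <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  fl_assert(all(p >= 0 & p <= 1), "fl_parameter_error",
            "p values must lie in [0, 1]")
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, p * m))
  o <- order(p)
  mult <- m - seq_len(m) + 1
  adj <- pmin(1, cummax(p[o] * mult))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA on one value per subject x cell
#' (cell means precomputed upstream). Each effect is tested against its own
#' subject-by-effect error stratum: `F_A = MS_A / MS_{A x S}`, and similarly
#' for B and the interaction against the three-way residual. Effect sizes
#' are partial eta squared, `SS_effect / (SS_effect + SS_error)`. The sum of
#' the seven components is verified against the total SS to 1e-10 relative
#' on every call. No sphericity correction is applied (the within-subject
#' F ratios are reported on their uncorrected degrees of freedom).
#'
#' @param data long-format data frame.
#' @param subject,factor_a,factor_b,value column names.
#' @return List of class `fl_anova` with per-effect `fl_test`-like entries
#'   (`A`, `B`, `AB`): F statistic, df pair, p, partial eta squared; plus the
#'   SS decomposition table.
#' @export
rm_anova_2way <- function(data, subject = "subject", factor_a = "A",
                          factor_b = "B", value = "value") {
  s <- factor(data[[subject]]); a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]]); v <- data[[value]]
  fl_assert(all(is.finite(v)), "fl_data_error", "non-finite values")
  ns <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  counts <- table(s, a, b)
  fl_assert(all(counts == 1), "fl_design_error",
            "design must be fully crossed with one value per cell per subject")

  g <- mean(v)
  mean_by <- function(...) tapply(v, list(...), mean)
  ma <- mean_by(a); mb <- mean_by(b); ms <- mean_by(s)
  mab <- mean_by(a, b); mas <- mean_by(a, s); mbs <- mean_by(b, s)

  ss_a <- nb * ns * sum((ma - g)^2)
  ss_b <- na * ns * sum((mb - g)^2)
  ss_s <- na * nb * sum((ms - g)^2)
  ss_ab <- ns * sum((mab - outer(ma - g, mb - g, "+") - g)^2)
  ss_as <- nb * sum((mas - outer(ma - g, ms - g, "+") - g)^2)
  ss_bs <- na * sum((mbs - outer(mb - g, ms - g, "+") - g)^2)
  ss_tot <- sum((v - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs

  decomp_err <- abs(ss_a + ss_b + ss_s + ss_ab + ss_as + ss_bs + ss_abs -
                      ss_tot)
  fl_assert(decomp_err <= 1e-10 * max(ss_tot, 1), "fl_numeric_error",
            "SS decomposition failed to close (residual %.3g)", decomp_err)

  eff <- function(ss_e, df_e, ss_r, df_r) {
    ms_e <- ss_e / df_e; ms_r <- ss_r / df_r
    f <- if (ms_r > 0) ms_e / ms_r else Inf
    list(F = f, df = c(df_e, df_r),
         p = if (is.finite(f)) stats::pf(f, df_e, df_r, lower.tail = FALSE)
             else 0,
         pes = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else NA_real_,
         ss_effect = ss_e, ss_error = ss_r)
  }
  structure(list(
    A = eff(ss_a, na - 1, ss_as, (na - 1) * (ns - 1)),
    B = eff(ss_b, nb - 1, ss_bs, (nb - 1) * (ns - 1)),
    AB = eff(ss_ab, (na - 1) * (nb - 1), ss_abs,
             (na - 1) * (nb - 1) * (ns - 1)),
    ss = c(A = ss_a, B = ss_b, S = ss_s, AB = ss_ab, AS = ss_as, BS = ss_bs,
           ABS = ss_abs, total = ss_tot),
    factors = c(A = factor_a, B = factor_b)
  ), class = "fl_anova")
}

#' @export
print.fl_anova <- function(x, ...) {
  for (nm in c("A", "B", "AB")) {
    e <- x[[nm]]
    label <- if (nm == "AB") paste(x$factors, collapse = " x ") else
      x$factors[[nm]]
    cat(sprintf("%-20s F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
                label, e$df[1], e$df[2], e$F, e$p, e$pes))
  }
  invisible(x)
}

#' Power of the one-sample/paired t test
#'
#' Exact power from the noncentral t distribution: with effect size `d`
#' (Cohen) and sample size `n`, the test statistic is noncentral t with
#' `df = n - 1` and noncentrality `d * sqrt(n)`.
#'
#' @param n sample size (>= 2).
#' @param d Cohen's d.
#' @param alpha significance level.
#' @param two_sided logical.
#' @return Power in (0, 1).
#' @export
power_t <- function(n, d, alpha = 0.05, two_sided = TRUE) {
  fl_assert(alpha > 0 && alpha < 1, "fl_parameter_error",
            "alpha must be in (0, 1)")
  fl_assert(all(n >= 2), "fl_parameter_error", "n must be >= 2")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (two_sided) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Minimal sample size for a target power
#'
#' Smallest integer n whose one-sample/paired t-test power reaches the
#' target. With `d = 1.00`, `alpha = 0.05` two-sided and target power 0.8
#' this returns 10.
#'
#' @param d Cohen's d (nonzero).
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param two_sided logical.
#' @param n_max search bound.
#' @return Integer sample size.
#' @examples
#' sample_size_t(d = 1.00, alpha = 0.05, power = 0.8)  # 10
#' @export
sample_size_t <- function(d, alpha = 0.05, power = 0.8, two_sided = TRUE,
                          n_max = 1e5) {
  fl_assert(d != 0, "fl_parameter_error", "d must be nonzero")
  fl_assert(power > 0 && power < 1, "fl_parameter_error",
            "power must be in (0, 1)")
  for (n in 2:n_max) {
    if (power_t(n, abs(d), alpha, two_sided) >= power) return(n)
  }
  fl_stop("fl_parameter_error", "no n <= %d reaches power %g", n_max, power)
}
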