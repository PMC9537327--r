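#' Aggregate 2AFC responses into a choice table
#'
#' Pools the binary "chose the comparison interval" responses over the two
#' presentation phases (merging first- and second-phase presentations removes
#' order bias, including any within-trial temporal trend) and tabulates the
#' choice proportion per participant, lag and sound condition. Trials flagged
#' `excluded` are dropped.
#'
#' @param records trial records with `participant_id`, `lag_ms`, `sound`,
#'   `choice_comparison` and optionally `excluded`.
#' @param by_sound keep the sound factor separate (default) or pool it.
#' @return Data frame `participant_id`, `lag_ms` (, `sound`), `n_trials`,
#'   `n_comparison_chosen`, `proportion`.
#' @export
choice_table <- function(records, by_sound = TRUE) {
  if (!is.null(records$excluded)) records <- records[records$excluded == 0L, ]
  fl_assert(nrow(records) > 0, "fl_data_error", "no unexcluded trials")
  fml <- if (by_sound && !is.null(records$sound) &&
             length(unique(records$sound)) > 1) {
    choice_comparison ~ participant_id + lag_ms + sound
  } else choice_comparison ~ participant_id + lag_ms
  agg <- stats::aggregate(fml, data = records,
                          FUN = function(z) c(n = length(z), k = sum(z)))
  out <- agg[setdiff(names(agg), "choice_comparison")]
  out$n_trials <- agg$choice_comparison[, "n"]
  out$n_comparison_chosen <- agg$choice_comparison[, "k"]
  out$proportion <- out$n_comparison_chosen / out$n_trials
  out[order(out$participant_id, out$lag_ms), , drop = FALSE]
}

# ---- Laplace machinery ------------------------------------------------------

# Bernoulli-probit log-likelihood derivatives w.r.t. the linear predictor.
# Returns list(ll, g1, w2) with w2 = -d2 ll / d eta^2 (>= 0). Stable via
# log-scale Mills ratios; eta clamped to +/-8.
probit_derivs <- function(eta, y) {
  eta <- pmax(-8, pmin(8, eta))
  lF <- stats::pnorm(eta, log.p = TRUE)
  lS <- stats::pnorm(eta, log.p = TRUE, lower.tail = FALSE)
  lphi <- stats::dnorm(eta, log = TRUE)
  s1 <- exp(lphi - lF)          # phi/Phi
  s0 <- exp(lphi - lS)          # phi/(1-Phi)
  ll <- ifelse(y == 1, lF, lS)
  g1 <- ifelse(y == 1, s1, -s0)
  w2 <- ifelse(y == 1, s1 * (eta + s1), s0 * (s0 - eta))
  list(ll = ll, g1 = g1, w2 = pmax(w2, 1e-10))
}

# Penalized-likelihood mode per subject by damped Newton.
# off: fixed-effect offset per row; Z: n x q random-effect design;
# dvar: length-q RE variances. Returns list(u, h, neg_hess).
inner_mode <- function(y, off, Z, dvar, u0 = NULL) {
  q <- ncol(Z)
  u <- if (is.null(u0)) numeric(q) else u0
  dinv <- 1 / dvar
  obj <- function(u) {
    d <- probit_derivs(off + drop(Z %*% u), y)
    sum(d$ll) - 0.5 * sum(u^2 * dinv)
  }
  f <- obj(u)
  for (it in 1:50) {
    d <- probit_derivs(off + drop(Z %*% u), y)
    grad <- drop(crossprod(Z, d$g1)) - u * dinv
    H <- crossprod(Z, Z * d$w2) + diag(dinv, q)
    step <- solve(H, grad)
    tt <- 1
    repeat {
      u_new <- u + tt * step
      f_new <- obj(u_new)
      if (f_new >= f - 1e-12 || tt < 1e-4) break
      tt <- tt / 2
    }
    moved <- max(abs(u_new - u))
    u <- u_new; f <- f_new
    if (moved < 1e-9) break
  }
  d <- probit_derivs(off + drop(Z %*% u), y)
  H <- crossprod(Z, Z * d$w2) + diag(1 / dvar, q)
  list(u = u, h = f, neg_hess = H)
}

# Laplace-approximated marginal log-likelihood for independent Gaussian
# random effects, summed over subjects. `cache` (environment) warm-starts
# the per-subject modes across optimizer evaluations.
laplace_loglik <- function(theta_f, log_sd, dat, cache = NULL) {
  dvar <- pmax(exp(2 * log_sd), 1e-12)
  off_all <- drop(dat$Xf %*% theta_f)
  total <- 0
  modes <- vector("list", length(dat$subjects))
  for (j in seq_along(dat$subjects)) {
    rows <- dat$rows[[j]]
    u0 <- if (!is.null(cache)) cache$modes[[j]] else NULL
    m <- inner_mode(dat$y[rows], off_all[rows],
                    dat$Z[rows, , drop = FALSE], dvar, u0)
    # log marginal: h(u_hat) - 1/2 sum(log dvar) - 1/2 log det(negH)
    ld <- determinant(m$neg_hess, logarithm = TRUE)$modulus
    total <- total + m$h - 0.5 * sum(log(dvar)) - 0.5 * as.numeric(ld)
    modes[[j]] <- m$u
  }
  if (!is.null(cache)) cache$modes <- modes
  attr(total, "modes") <- modes
  total
}

# Assemble per-model design matrices on internally scaled predictors.
glmm_design <- function(data, model) {
  fl_assert(all(c("participant_id", "x", "y") %in% names(data)),
            "fl_design_error",
            "data needs columns participant_id, x, y")
  if (model %in% c(2, 3)) {
    fl_assert("pd" %in% names(data) && !anyNA(data$pd), "fl_dependency_error",
              "models 2 and 3 need a complete pd column (delay-task probabilities)")
  }
  subjects <- sort(unique(data$participant_id))
  fl_assert(length(subjects) >= 2, "fl_design_error",
            "need >= 2 participants")
  xs <- data$x / 100                       # per 100 ms, O(1) optimizer scale
  pdc <- if (!is.null(data$pd)) data$pd - 0.5 else NULL
  per_subj_levels <- tapply(
    if (model == 2) pdc else xs, data$participant_id,
    function(v) length(unique(v)))
  fl_assert(all(per_subj_levels >= 2), "fl_design_error",
            "every participant needs >= 2 distinct predictor values")
  Xf <- switch(as.character(model),
    "1" = cbind(1, xs),
    "2" = cbind(1, pdc),
    "3" = cbind(1, xs, pdc))
  Z <- switch(as.character(model),
    "1" = cbind(1, xs),
    "2" = cbind(1, pdc),
    "3" = cbind(1, 1, xs, pdc))
  rows <- lapply(subjects, function(s) which(data$participant_id == s))
  list(y = data$y, Xf = Xf, Z = Z, subjects = subjects, rows = rows,
       model = model)
}

# Map internal (scaled) parameters to reporting scale: slope on x back to
# per-ms; pd slope reported per unit pd with intercept shifted back to the
# uncentered parameterization.
glmm_report_scale <- function(model, theta_f, sds) {
  theta_f <- unname(theta_f); sds <- unname(sds)
  if (model == 1) {
    fixed <- c(alpha = theta_f[1], beta = theta_f[2] / 100)
    re <- c(sd_alpha = sds[1], sd_beta = sds[2] / 100)
  } else if (model == 2) {
    fixed <- c(alpha = theta_f[1] - 0.5 * theta_f[2], beta_pd = theta_f[2])
    re <- c(sd_alpha_d = sds[1], sd_beta_pd = sds[2])
  } else {
    fixed <- c(alpha = theta_f[1] - 0.5 * theta_f[3],
               beta = theta_f[2] / 100, beta_pd = theta_f[3])
    re <- c(sd_alpha = sds[1], sd_alpha_d = sds[2],
            sd_beta = sds[3] / 100, sd_beta_pd = sds[4])
  }
  list(fixed = fixed, re_sd = re)
}

#' Fit a probit mixed psychometric model
#'
#' Maximizes the Laplace-approximated marginal likelihood of a probit GLMM
#' for binary 2AFC responses with independent Gaussian random effects per
#' participant. Three model structures are supported: model 1 regresses the
#' choice on the comparison lag `x` (ms) with random bias and slope; model 2
#' regresses on the participant's delay-detection probability `pd`; model 3
#' uses both predictors (with separate random bias terms for each, as well as
#' both random slopes).
#'
#' Estimation follows the classical nested scheme: per-participant
#' random-effect modes by damped Newton iterations inside, quasi-Newton
#' (L-BFGS-B) over the fixed effects and log-SDs outside, started from the
#' ordinary (no-random-effect) probit fit. Predictors are scaled internally
#' (lag per 100 ms, `pd` centered at 0.5) and estimates reported back on the
#' natural scale (slope per ms). The AIC counts fixed effects plus variance
#' components: 4 for models 1 and 2, 7 for model 3.
#'
#' @param data data frame with columns `participant_id`, `x` (signed lag,
#'   ms), `y` (0/1 choice), and `pd` for models 2/3.
#' @param model 1, 2 or 3.
#' @param se compute standard errors of the fixed effects from the numerical
#'   Hessian at the optimum (default TRUE).
#' @return An object of class `fl_glmm`: `fixed` (natural scale), `se`,
#'   `re_sd`, `ranef` (per-subject posterior-mode deviations, natural scale),
#'   `loglik`, `aic`, `k`, `model`, `converged`, `n_obs`, `subjects`.
#' @export
fit_probit_glmm <- function(data, model = 1, se = TRUE) {
  fl_assert(model %in% 1:3, "fl_parameter_error", "model must be 1, 2 or 3")
  dat <- glmm_design(data, model)
  n_fix <- ncol(dat$Xf)
  n_re <- ncol(dat$Z)

  # start from the plain probit fit, small RE variances
  start_glm <- stats::glm.fit(dat$Xf, dat$y,
                              family = stats::binomial("probit"))
  par0 <- c(start_glm$coefficients, rep(log(0.3), n_re))
  cache <- new.env(parent = emptyenv())
  cache$modes <- NULL

  negll <- function(par) {
    val <- laplace_loglik(par[seq_len(n_fix)], par[n_fix + seq_len(n_re)],
                          dat, cache)
    -as.numeric(val)
  }
  opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, n_fix), rep(log(1e-4), n_re)),
                      upper = c(rep(Inf, n_fix), rep(log(20), n_re)),
                      control = list(maxit = 500, factr = 1e9))
  theta_f <- opt$par[seq_len(n_fix)]
  log_sd <- opt$par[n_fix + seq_len(n_re)]
  ll <- laplace_loglik(theta_f, log_sd, dat, cache)
  modes <- attr(ll, "modes")
  ll <- as.numeric(ll)

  rep_scale <- glmm_report_scale(model, theta_f, exp(log_sd))
  # delta method maps the internal-scale covariance onto the natural scale
  A <- switch(as.character(model),
    "1" = diag(c(1, 1 / 100)),
    "2" = rbind(c(1, -0.5), c(0, 1)),
    "3" = rbind(c(1, 0, -0.5), c(0, 1 / 100, 0), c(0, 0, 1)))
  se_nat <- rep(NA_real_, n_fix)
  if (se) {
    H <- try(stats::optimHess(opt$par, negll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error")) {
        Vf <- V[seq_len(n_fix), seq_len(n_fix), drop = FALSE]
        dv <- diag(A %*% Vf %*% t(A))
        se_nat <- ifelse(dv > 0, sqrt(dv), NA_real_)
      }
    }
  }
  names(se_nat) <- names(rep_scale$fixed)

  ranef <- do.call(rbind, modes)
  colnames(ranef) <- paste0("u", seq_len(n_re))
  scale_cols <- switch(as.character(model),
    "1" = c(1, 1 / 100), "2" = c(1, 1), "3" = c(1, 1, 1 / 100, 1))
  ranef <- sweep(ranef, 2, scale_cols, "*")
  colnames(ranef) <- names(rep_scale$re_sd)
  ranef <- data.frame(participant_id = dat$subjects, ranef,
                      row.names = NULL, stringsAsFactors = FALSE)

  k <- n_fix + n_re
  structure(list(
    model = model, fixed = rep_scale$fixed, se = se_nat,
    re_sd = rep_scale$re_sd, ranef = ranef,
    loglik = ll, aic = -2 * ll + 2 * k, k = k,
    converged = opt$convergence == 0, optim_message = opt$message,
    n_obs = length(dat$y), subjects = dat$subjects,
    theta_internal = c(theta_f, log_sd)
  ), class = "fl_glmm")
}

#' @export
print.fl_glmm <- function(x, ...) {
  cat(sprintf("Probit mixed model %d (Laplace): logLik %.2f, AIC %.1f (k = %d)%s\n",
              x$model, x$loglik, x$aic, x$k,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate = x$fixed, se = x$se)
  print(round(est, 5))
  cat("Random-effect SDs:\n")
  print(round(x$re_sd, 5))
  invisible(x)
}

#' Compare models by AIC
#'
#' @param ... fitted `fl_glmm` objects (fit on identical response vectors).
#' @return Data frame ranked by AIC with `delta_aic`; best model first.
#' @export
model_comparison_aic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "fl_glmm")) fits <- fits[[1]]
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  fl_assert(length(unique(n_obs)) == 1, "fl_design_error",
            "AIC comparison requires fits on identical response vectors")
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' Participant-level slopes and their correlation across tasks
#'
#' Extracts the participant-level sensitivity `beta + beta_i` from two fits
#' (e.g. the fatigue task and the delay-detection task) and tests their
#' Pearson correlation across participants.
#'
#' @param fit_fatigue,fit_delay `fl_glmm` fits over the same participants.
#' @return List with `r`, `p`, `df`, `slopes` (per-participant data frame).
#' @export
slope_correlation <- function(fit_fatigue, fit_delay) {
  fl_assert(identical(fit_fatigue$subjects, fit_delay$subjects),
            "fl_design_error", "fits must share the same participant set")
  sf <- participant_slopes(fit_fatigue)
  sd_ <- participant_slopes(fit_delay)
  if (length(sf) >= 3) {
    ct <- stats::cor.test(sf, sd_)
    r <- unname(ct$estimate); p <- ct$p.value; df <- unname(ct$parameter)
  } else {                              # correlation needs >= 3 participants
    r <- NA_real_; p <- NA_real_; df <- NA_integer_
  }
  list(r = r, p = p, df = df,
       slopes = data.frame(participant_id = fit_fatigue$subjects,
                           slope_fatigue = sf, slope_delay = sd_))
}

# beta + beta_i on the natural (per ms / per unit pd) scale
participant_slopes <- function(fit) {
  slope_name <- intersect(c("beta", "beta_pd"), names(fit$fixed))[1]
  re_name <- intersect(c("sd_beta", "sd_beta_pd"), colnames(fit$ranef))[1]
  unname(fit$fixed[slope_name] + fit$ranef[[re_name]])
}
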