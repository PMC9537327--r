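# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-z^2))
# via the Golub-Welsch eigenvalue method.
gh_nodes <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(z = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Adaptive Gauss-Hermite marginal log-likelihood for the probit mixed model
# with independent Gaussian random bias/slope per subject. `theta` is the
# package's internal parameter vector (fixed effects on the scaled
# predictors, then log-SDs); the design is rebuilt here from scratch.
aghq_loglik <- function(data, theta, model = 1, n_nodes = 31) {
  xs <- data$x / 100
  pdc <- if (!is.null(data$pd)) data$pd - 0.5 else NULL
  Xf <- switch(as.character(model),
    "1" = cbind(1, xs), "2" = cbind(1, pdc), "3" = cbind(1, xs, pdc))
  Z <- switch(as.character(model),
    "1" = cbind(1, xs), "2" = cbind(1, pdc), "3" = cbind(1, 1, xs, pdc))
  n_fix <- ncol(Xf)
  q <- ncol(Z)
  sds <- exp(theta[n_fix + seq_len(q)])
  off_all <- drop(Xf %*% theta[seq_len(n_fix)])
  gh <- gh_nodes(n_nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), q)))
  logw <- rowSums(matrix(log(gh$w)[grid], nrow(grid)))
  zsq <- rowSums(matrix(gh$z[grid]^2, nrow(grid)))
  Zpts <- matrix(gh$z[grid], nrow(grid))

  total <- 0
  for (s in unique(data$participant_id)) {
    rows <- which(data$participant_id == s)
    y <- data$y[rows]; off <- off_all[rows]
    Zi <- Z[rows, , drop = FALSE]
    gfun <- function(u) {
      eta <- pmax(-8, pmin(8, off + drop(Zi %*% u)))
      sum(ifelse(y == 1, pnorm(eta, log.p = TRUE),
                 pnorm(eta, log.p = TRUE, lower.tail = FALSE))) -
        sum(u^2 / (2 * sds^2)) - sum(log(sds)) - q / 2 * log(2 * pi)
    }
    opt <- optim(numeric(q), function(u) -gfun(u), method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12))
    H <- optimHess(opt$par, function(u) -gfun(u))
    L <- chol((H + t(H)) / 2)
    A <- sqrt(2) * backsolve(L, diag(q))
    gv <- apply(Zpts, 1, function(z) gfun(opt$par + drop(A %*% z)))
    terms <- logw + zsq + gv
    m <- max(terms)
    total <- total + q / 2 * log(2) - sum(log(diag(L))) + m +
      log(sum(exp(terms - m)))
  }
  total
}

# Definitional Holm oracle: for each hypothesis, the adjusted p is the
# maximum over all subsets S containing it of min over S-style step-down;
# implemented as the closure max_{j <= i} (m - j + 1) p_(j) in sorted order,
# evaluated directly per element.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(seq_len(i), function(j) (m - j + 1) * p[o][j], numeric(1))
    adj[o[i]] <- min(1, max(vals))
  }
  adj
}

# Within-subject two-way ANOVA oracle through base aov() error strata.
aov_oracle <- function(df) {
  df$subject <- factor(df$subject)
  df$A <- factor(df$A); df$B <- factor(df$B)
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = df)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- grep(paste0("^", term, "\\s*$"), rownames(tab))
    list(F = tab[i, "F value"], df = c(tab[i, "Df"], tab[nrow(tab), "Df"]),
         p = tab[i, "Pr(>F)"],
         ss = tab[i, "Sum Sq"], ss_err = tab[nrow(tab), "Sum Sq"])
  }
  list(A = pick("Error: subject:A", "A"),
       B = pick("Error: subject:B", "B"),
       AB = pick("Error: subject:A:B", "A:B"))
}

# Brute-force integer-lag normalized cross-correlation scan.
xcorr_brute <- function(x, y, max_shift) {
  n <- length(x)
  x <- x - mean(x); y <- y - mean(y)
  shifts <- -max_shift:max_shift
  r <- vapply(shifts, function(s) {
    if (s >= 0) cor(x[1:(n - s)], y[(1 + s):n])
    else cor(x[(1 - s):n], y[1:(n + s)])
  }, numeric(1))
  list(shift = shifts[which.max(r)], peak = max(r))
}

# EMG-like spectrally shaped noise fixture at a given median frequency.
shape_noise_fixture <- function(mf, dur, fs = 500, log_bw = 0.35, seed = 1) {
  fatiguelag:::shape_emg_noise(dur * fs, fs, mf, log_bw, seed)
}

# Small synthetic choice dataset straight from the probit law (bypasses the
# package's cohort/schedule machinery).
probit_dataset <- function(n_subj, n_per_subj, alpha, beta_ms, sd_a, sd_b_ms,
                           lags = c(0, 50, 83), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    a <- rnorm(1, 0, sd_a); b <- rnorm(1, 0, sd_b_ms)
    x <- sample(lags, n_per_subj, replace = TRUE)
    p <- pnorm(alpha + a + (beta_ms + b) * x)
    data.frame(participant_id = sprintf("S%02d", i), x = x,
               y = as.integer(runif(n_per_subj) < p))
  }))
}
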