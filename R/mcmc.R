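# Adaptive random-walk Metropolis sampler used by the Bayesian
# concentration-response models. Deliberately small: a handful of
# parameters, short chains, fully deterministic under set.seed().

#' Adaptive Metropolis sampling from a log-posterior
#'
#' Componentwise Gaussian random-walk Metropolis with Robbins-Monro style
#' scale adaptation during burn-in (targeting ~0.35 acceptance), run as
#' multiple dispersed chains. Convergence is judged with the split-chain
#' potential scale reduction factor (R-hat).
#'
#' @param log_post function(theta) returning the unnormalized log posterior;
#'   may return `-Inf` outside the support.
#' @param init numeric matrix, one row per chain: starting points.
#' @param n_iter post-burn-in iterations per chain.
#' @param n_burn burn-in iterations (adaptation happens here only).
#' @param scale initial proposal SDs (recycled over parameters).
#' @return list with `samples` (matrix, chains stacked), `rhat` (per
#'   parameter), `accept` (mean acceptance rate), `converged`
#'   (all R-hat < `rhat_limit`).
#' @param rhat_limit convergence gate (default 1.05).
#' @keywords internal
mcmc_metropolis <- function(log_post, init, n_iter = 1500, n_burn = 750,
                            scale = 0.1, rhat_limit = 1.05) {
  init <- as.matrix(init)
  n_chain <- nrow(init); d <- ncol(init)
  scale <- rep_len(scale, d)
  keep <- array(NA_real_, dim = c(n_iter, d, n_chain))
  acc_total <- 0; prop_total <- 0

  for (ch in seq_len(n_chain)) {
    th <- init[ch, ]
    lp <- log_post(th)
    if (!is.finite(lp)) stop("initial point has zero posterior density")
    s <- scale
    for (it in seq_len(n_burn + n_iter)) {
      for (j in seq_len(d)) {
        cand <- th
        cand[j] <- cand[j] + stats::rnorm(1, 0, s[j])
        lp_c <- log_post(cand)
        accept <- is.finite(lp_c) && log(stats::runif(1)) < lp_c - lp
        if (accept) { th <- cand; lp <- lp_c }
        if (it <= n_burn) {
          # stochastic approximation towards 0.35 acceptance
          s[j] <- s[j] * exp((as.numeric(accept) - 0.35) / sqrt(it))
        } else {
          acc_total <- acc_total + accept; prop_total <- prop_total + 1
        }
      }
      if (it > n_burn) keep[it - n_burn, , ch] <- th
    }
  }

  rhat <- vapply(seq_len(d), function(j) split_rhat(keep[, j, , drop = FALSE]),
                 0)
  samples <- do.call(rbind, lapply(seq_len(n_chain), function(ch)
    keep[, , ch, drop = TRUE]))
  samples <- matrix(samples, ncol = d)
  list(samples = samples, rhat = rhat,
       accept = acc_total / max(prop_total, 1),
       converged = all(is.finite(rhat)) && all(rhat < rhat_limit))
}

# split-chain potential scale reduction factor for one parameter
# x: iterations x 1 x chains
split_rhat <- function(x) {
  n <- dim(x)[1]; m <- dim(x)[3]
  half <- floor(n / 2)
  segs <- list()
  for (ch in seq_len(m)) {
    segs[[length(segs) + 1L]] <- x[seq_len(half), 1, ch]
    segs[[length(segs) + 1L]] <- x[(n - half + 1):n, 1, ch]
  }
  means <- vapply(segs, mean, 0)
  vars <- vapply(segs, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Bayesian Hill fit of a concentration-response curve
#'
#' Fits the four-parameter Hill model
#' \deqn{y = low + (high - low) \frac{c^s}{IC_{50}^s + c^s}}
#' to percent-of-maximal-response data by MCMC. Priors are weakly
#' informative and centred per the screening convention: log-normal IC50
#' centred at the median tested concentration (sdlog 1), normal slope
#' centred at 1 (sd 0.5), and low/high responses held near 0% and 100%
#' (normal, sd 2). Gaussian likelihood with a half-normal prior on the
#' residual SD. The reported IC50 is the posterior median.
#'
#' @param concentrations strictly positive tested concentrations (uM); at
#'   least 6 distinct values for a reportable fit.
#' @param responses numeric vector (or matrix with replicates in columns)
#'   of responses in percent of the maximal reference response, aligned
#'   with `concentrations` (rows).
#' @param n_iter,n_burn MCMC lengths per chain (2 chains).
#' @param seed integer seed; fixed for reproducibility.
#' @return object of class `hill_fit`: list with `ic50` (posterior median,
#'   `NA` when not converged or no activity), `slope`, `low`, `high`,
#'   `posterior_samples` (matrix with named columns), `converged`, `rhat`.
#' @examples
#' conc <- 10^seq(-2, 2, length.out = 8)
#' y <- 100 * conc / (1 + conc)   # ic50 = 1, slope = 1
#' fit <- fit_hill_bayes(conc, y, n_iter = 400, n_burn = 400, seed = 1)
#' fit$ic50
#' @export
fit_hill_bayes <- function(concentrations, responses,
                           n_iter = 2000, n_burn = 1500, seed = 1L) {
  conc <- as.numeric(concentrations)
  stopifnot(all(conc > 0))
  if (length(unique(conc)) < 6)
    stop("at least 6 distinct concentrations required")
  y <- if (is.matrix(responses)) {
    stopifnot(nrow(responses) == length(conc))
    cbind(rep(conc, ncol(responses)), as.vector(responses))
  } else {
    stopifnot(length(responses) == length(conc))
    cbind(conc, as.numeric(responses))
  }
  cc <- y[, 1]; yy <- y[, 2]

  # flat (no-activity) gate: response spread indistinguishable from noise
  if (stats::sd(yy) < 1e-8 || diff(range(tapply(yy, cc, mean))) < 5) {
    return(structure(list(ic50 = NA_real_, slope = NA_real_, low = NA_real_,
                          high = NA_real_, posterior_samples = NULL,
                          converged = FALSE, rhat = NULL),
                     class = "hill_fit"))
  }

  med <- stats::median(conc)
  lc <- log(cc)
  # theta = (log_ic50, slope, low, high, log_sigma)
  # floor on the residual SD: 0.2% of the observed response range keeps
  # the likelihood proper on noise-free curves without affecting real data
  lsig_floor <- log(max(diff(range(yy)) * 0.002, 1e-6))
  log_post <- function(th) {
    lic <- th[1]; sl <- th[2]; lo <- th[3]; hi <- th[4]; lsig <- th[5]
    if (sl <= 0 || lsig > 10 || lsig < lsig_floor) return(-Inf)
    sig <- exp(lsig)
    mu <- lo + (hi - lo) * stats::plogis(sl * (lc - lic))
    ll <- sum(stats::dnorm(yy, mu, sig, log = TRUE))
    lp <- stats::dnorm(lic, log(med), 1, log = TRUE) +
      stats::dnorm(sl, 1, 0.5, log = TRUE) +
      stats::dnorm(lo, 0, 2, log = TRUE) +
      stats::dnorm(hi, 100, 2, log = TRUE) +
      stats::dnorm(lsig, 0, 2, log = TRUE)
    ll + lp
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  init <- rbind(c(log(med), 1, 0, 100, log(max(stats::sd(yy) / 4, 0.5))),
                c(log(med) + 0.5, 0.7, 1, 99, log(max(stats::sd(yy) / 2, 1))))
  fit <- mcmc_metropolis(log_post, init, n_iter = n_iter, n_burn = n_burn,
                         scale = c(0.2, 0.1, 0.5, 0.5, 0.2))
  colnames(fit$samples) <- c("log_ic50", "slope", "low", "high", "log_sigma")
  ic50 <- exp(stats::median(fit$samples[, "log_ic50"]))
  structure(list(
    ic50 = if (fit$converged) ic50 else NA_real_,
    slope = stats::median(fit$samples[, "slope"]),
    low = stats::median(fit$samples[, "low"]),
    high = stats::median(fit$samples[, "high"]),
    posterior_samples = fit$samples,
    converged = fit$converged, rhat = fit$rhat), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) cat("Hill fit: not converged / no activity\n")
  else cat(sprintf("Hill fit: IC50 %.4g uM, slope %.3g, range %.3g-%.3g%%\n",
                   x$ic50, x$slope, x$low, x$high))
  invisible(x)
}

#' Single-concentration screen follow-up gate
#'
#' In the two-phase profiling workflow a target is followed up with a full
#' concentration response only when the single-concentration screen shows
#' inhibition or stimulation of more than 50% of the maximal reference
#' response (strict inequality; sign carries direction).
#'
#' @param percent_effect percent effect at the screening concentration.
#' @return logical: follow up with phase two?
#' @export
screen_followup_gate <- function(percent_effect) {
  stopifnot(is.finite(percent_effect))
  abs(percent_effect) > 50
}
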