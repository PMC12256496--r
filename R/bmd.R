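# Benchmark-dose estimation: six continuous models fit by Gaussian maximum
# likelihood, winner by AIC, BMD at a 10% benchmark response, bootstrap
# confidence bounds, and the BMDU/BMDL validity filter.

bmd_model_fun <- function(model, p) {
  switch(model,
    poly2 = function(c) p[1] + p[2] * c + p[3] * c^2,
    power = function(c) p[1] + p[2] * c^p[3],
    hill  = function(c) p[1] + p[2] * c^p[4] / (p[3]^p[4] + c^p[4]),
    exp3  = function(c) p[1] * exp(p[4] * (p[2] * c)^p[3]),
    exp4  = function(c) p[1] * (p[3] - (p[3] - 1) * exp(-p[2] * c)),
    exp5  = function(c) p[1] * (p[3] - (p[3] - 1) * exp(-(p[2] * c)^p[4])),
    stop("unknown model: ", model))
}

# single model fit; returns list(par, aic, sigma) or NULL on failure
fit_one_bmd_model <- function(model, conc, resp) {
  n <- length(resp)
  y0 <- mean(resp[conc == min(conc)])
  yM <- mean(resp[conc == max(conc)])
  dir_sign <- if (yM < y0) -1 else 1
  cmax <- max(conc)
  wrap <- function(expr) tryCatch(expr, error = function(e) NULL,
                                  warning = function(w) NULL)
  pack <- function(fit, extra = NULL) {
    list(par = c(unname(stats::coef(fit)), extra), aic = stats::AIC(fit),
         sigma = sqrt(sum(stats::resid(fit)^2) / n))
  }
  if (model == "poly2")
    return(wrap(pack(stats::lm(resp ~ conc + I(conc^2)))))

  df <- data.frame(c = conc, y = resp)
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  if (model == "exp3") {
    # adverse direction enters through a fixed sign; try both, keep best AIC
    best <- NULL
    for (sg in c(dir_sign, -dir_sign)) {
      cand <- wrap({
        fit <- minpack.lm::nlsLM(
          y ~ a * exp(sg * (b * c)^d), data = df,
          start = list(a = max(abs(y0), 1e-6), b = 1 / cmax, d = 1),
          lower = c(1e-9, 1e-9, 0.2), upper = c(Inf, Inf, 8), control = ctl)
        pack(fit, extra = sg)
      })
      if (!is.null(cand) && (is.null(best) || cand$aic < best$aic))
        best <- cand
    }
    return(best)
  }
  wrap({
    fit <- switch(model,
      power = minpack.lm::nlsLM(
        y ~ a + b * c^g, data = df,
        start = list(a = y0, b = (yM - y0) / cmax, g = 1),
        lower = c(-Inf, -Inf, 0.1), upper = c(Inf, Inf, 8), control = ctl),
      hill = minpack.lm::nlsLM(
        y ~ a + b * c^g / (k^g + c^g), data = df,
        start = list(a = y0, b = yM - y0,
                     k = stats::median(conc[conc > 0]), g = 1),
        lower = c(-Inf, -Inf, 1e-9, 0.5),
        upper = c(Inf, Inf, cmax * 100, 18), control = ctl),
      exp4 = minpack.lm::nlsLM(
        y ~ a * (cc - (cc - 1) * exp(-b * c)), data = df,
        start = list(a = max(abs(y0), 1e-6), b = 1 / cmax,
                     cc = max(yM, 1e-6) / max(y0, 1e-6)),
        lower = c(1e-9, 1e-9, 1e-6), control = ctl),
      exp5 = minpack.lm::nlsLM(
        y ~ a * (cc - (cc - 1) * exp(-(b * c)^d)), data = df,
        start = list(a = max(abs(y0), 1e-6), b = 1 / cmax,
                     cc = max(yM, 1e-6) / max(y0, 1e-6), d = 1),
        lower = c(1e-9, 1e-9, 1e-6, 0.2),
        upper = c(Inf, Inf, Inf, 8), control = ctl))
    pack(fit)
  })
}

# BMD: concentration where the fitted curve departs from f(0) by bmr*|f(0)|
bmd_from_fit <- function(model, par, bmr, cmax) {
  f <- bmd_model_fun(model, par)
  f0 <- f(0)
  target <- bmr * abs(f0)
  if (!is.finite(f0) || target == 0) return(NA_real_)
  g <- function(c) abs(f(c) - f0) - target
  if (g(cmax) < 0) return(NA_real_)   # never reaches the BMR in range
  # first crossing from below
  grid <- seq(0, cmax, length.out = 512)
  gv <- vapply(grid, g, 0)
  idx <- which(gv >= 0)[1]
  if (is.na(idx) || idx == 1) return(NA_real_)
  stats::uniroot(g, c(grid[idx - 1], grid[idx]), tol = 1e-10)$root
}

#' Benchmark-dose estimation with six-model AIC selection
#'
#' Fits six continuous dose-response models (2nd-degree polynomial, Hill,
#' power, and exponential families 3/4/5) by Gaussian maximum likelihood,
#' selects the model with the lowest AIC, and computes the benchmark dose
#' (BMD): the concentration at which the fitted curve departs from its
#' background value f(0) by `bmr` (default 10%) of |f(0)|, in the adverse
#' direction fitted. Lower and upper confidence bounds (BMDL, BMDU) come
#' from a parametric bootstrap (percentile 5%/95% of refitted BMDs).
#'
#' @param concentrations concentrations (uM), may include 0 for controls;
#'   at least 4 distinct values.
#' @param responses responses aligned with `concentrations`.
#' @param bmr benchmark response as a fraction of background (default 0.10).
#' @param n_boot parametric bootstrap resamples (default 200).
#' @param seed integer seed for the bootstrap.
#' @return object of class `bmd_result`: list with `model`, `aic`, `bmd`,
#'   `bmdl`, `bmdu`, `bmr`, `direction` (`"up"`/`"down"`), `valid`, `par`.
#'   `valid` is `FALSE` when no model converges or the BMD is not reached
#'   within the tested range.
#' @examples
#' conc <- c(0, 0.5, 1, 2, 5, 10)
#' y <- 10 * exp(-0.2 * conc)
#' fit_bmd(conc, y, n_boot = 20, seed = 1)$bmd   # ~ log(1/0.9)/0.2
#' @export
fit_bmd <- function(concentrations, responses, bmr = 0.10,
                    n_boot = 200, seed = 1L) {
  conc <- as.numeric(concentrations); resp <- as.numeric(responses)
  stopifnot(length(conc) == length(resp), all(conc >= 0))
  if (length(unique(conc)) < 4)
    stop("at least 4 distinct concentrations required")
  cmax <- max(conc)
  models <- c("poly2", "hill", "power", "exp3", "exp4", "exp5")

  fits <- lapply(models, fit_one_bmd_model, conc = conc, resp = resp)
  names(fits) <- models
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) {
    return(structure(list(model = NA_character_, aic = NA_real_,
                          bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                          bmr = bmr, direction = NA_character_,
                          valid = FALSE, par = NULL), class = "bmd_result"))
  }
  aics <- vapply(fits[ok], function(f) f$aic, 0)
  win <- names(which.min(aics))
  best <- fits[[win]]
  bmd <- bmd_from_fit(win, best$par, bmr, cmax)
  f <- bmd_model_fun(win, best$par)
  direction <- if (f(cmax) < f(0)) "down" else "up"

  bmdl <- bmdu <- NA_real_
  if (!is.na(bmd) && n_boot > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    mu <- vapply(conc, f, 0)
    sig <- max(best$sigma, 1e-8)
    boots <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      yb <- mu + stats::rnorm(length(mu), 0, sig)
      fb <- fit_one_bmd_model(win, conc, yb)
      if (!is.null(fb)) boots[b] <- bmd_from_fit(win, fb$par, bmr, cmax)
    }
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 20) {
      qs <- stats::quantile(boots, c(0.05, 0.95), names = FALSE)
      bmdl <- qs[1]; bmdu <- qs[2]
      # the point estimate is kept inside the interval by construction
      bmdl <- min(bmdl, bmd); bmdu <- max(bmdu, bmd)
    }
  }
  structure(list(model = win, aic = best$aic, bmd = bmd, bmdl = bmdl,
                 bmdu = bmdu, bmr = bmr, direction = direction,
                 valid = !is.na(bmd) && bmd < cmax, par = best$par),
            class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  if (!x$valid) cat("BMD: no valid estimate within tested range\n")
  else cat(sprintf("BMD (%s, BMR %.0f%%, %s): %.4g [BMDL %.4g, BMDU %.4g]\n",
                   x$model, 100 * x$bmr, x$direction, x$bmd, x$bmdl, x$bmdu))
  invisible(x)
}

#' BMDU/BMDL validity filter
#'
#' A benchmark-dose estimate is retained only when the BMD lies below the
#' highest tested concentration and the BMDU/BMDL ratio falls between 1.1
#' and 5000. The lower bound removes under-extrapolated (implausibly tight)
#' intervals; the upper removes estimates with no real information.
#'
#' @param result a `bmd_result`.
#' @param max_conc highest tested concentration (uM).
#' @param ratio_min,ratio_max admissible BMDU/BMDL range.
#' @return logical.
#' @export
bmd_validity <- function(result, max_conc, ratio_min = 1.1,
                         ratio_max = 5000) {
  stopifnot(inherits(result, "bmd_result"))
  if (is.na(result$bmd) || is.na(result$bmdl) || is.na(result$bmdu))
    return(FALSE)
  if (result$bmdl <= 0) return(FALSE)
  ratio <- result$bmdu / result$bmdl
  result$bmd < max_conc && ratio >= ratio_min && ratio <= ratio_max
}
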