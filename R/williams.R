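# Williams-type trend screening used ahead of benchmark-dose modelling.

# weighted pool-adjacent-violators: isotonic (nondecreasing) fit of means
# with weights w; returns fitted values
pava <- function(means, w) {
  k <- length(means)
  val <- means; wt <- w
  blocks <- as.list(seq_len(k))
  i <- 1
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-12) {
      neww <- wt[i] + wt[i + 1]
      newv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / neww
      val <- c(val[seq_len(i - 1)], newv, val[-seq_len(i + 1)])
      wt <- c(wt[seq_len(i - 1)], neww, wt[-seq_len(i + 1)])
      blocks <- c(blocks[seq_len(i - 1)],
                  list(c(blocks[[i]], blocks[[i + 1]])),
                  blocks[-seq_len(i + 1)])
      i <- max(i - 1, 1)
    } else i <- i + 1
  }
  out <- numeric(k)
  for (b in seq_along(val)) out[blocks[[b]]] <- val[b]
  out
}

# Williams t-type statistic for an increasing trend: isotonic estimate of
# the top-dose mean against the control mean, studentized with the pooled
# within-group variance.
williams_stat <- function(y, g, k) {
  ns <- tabulate(g, k)
  means <- vapply(seq_len(k), function(i) mean(y[g == i]), 0)
  iso <- pava(means[-1], ns[-1])          # isotonic over dose groups only
  s2 <- sum((y - means[g])^2) / (length(y) - k)
  if (s2 <= 0) s2 <- 1e-12
  (iso[k - 1] - means[1]) / sqrt(s2 * (1 / ns[k] + 1 / ns[1]))
}

#' Williams-type trend test by permutation
#'
#' Tests for a monotone concentration-related trend against a control
#' group. The statistic is Williams' isotonic contrast: the pool-adjacent-
#' violators (amalgamated) estimate of the highest-dose mean minus the
#' control mean, studentized by the pooled within-group variance. The null
#' distribution is obtained by permuting group labels, which gives exact
#' small-sample behaviour without critical-value tables.
#'
#' @param groups list of numeric replicate vectors, ordered control first
#'   then ascending dose; at least 3 groups and 2 replicates in the control.
#' @param direction `"up"` tests an increasing trend, `"down"` a decreasing
#'   one, `"auto"` (default) picks the direction with the larger observed
#'   statistic and doubles the one-sided p (two-sided-by-direction).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return p-value in [0, 1].
#' @examples
#' g <- list(rnorm(3, 0), rnorm(3, 1), rnorm(3, 2), rnorm(3, 3))
#' williams_trend_p(g, direction = "up", n_perm = 500, seed = 1)
#' @export
williams_trend_p <- function(groups, direction = c("auto", "up", "down"),
                             n_perm = 10000, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(is.list(groups), length(groups) >= 3)
  if (length(groups[[1]]) < 2)
    stop("control group needs at least 2 replicates")
  k <- length(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  sgn <- switch(direction, up = 1, down = -1, auto = NA)

  obs_stat <- function(yy) {
    if (is.na(sgn)) max(williams_stat(yy, g, k), williams_stat(-yy, g, k))
    else williams_stat(sgn * yy, g, k)
  }
  t_obs <- obs_stat(y)
  if (!is.finite(t_obs)) return(1)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(length(y))]
    if (obs_stat(yp) >= t_obs - 1e-12) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

#' Trend + fold-change prefilter for one gene
#'
#' A biomarker response enters benchmark-dose modelling only when it shows
#' a significant Williams-type trend (p < `alpha`) and a maximal absolute
#' fold change vs the vehicle control of at least `fc_min`. Fold change is
#' computed on the normalized expression scale; changes below 1 are folded
#' (1/fc) so 0.5 counts as a 2-fold change.
#'
#' @param groups list of replicate vectors (control first, ascending dose)
#'   of normalized expression (control-relative fold scale).
#' @param alpha significance threshold (default 0.05).
#' @param fc_min minimum absolute fold change (default 1.5).
#' @param ... passed to [williams_trend_p()].
#' @return list with `pass`, `p`, `max_fold_change`.
#' @export
prefilter_gene <- function(groups, alpha = 0.05, fc_min = 1.5, ...) {
  p <- williams_trend_p(groups, ...)
  ctrl <- mean(groups[[1]])
  if (ctrl <= 0) stop("control mean must be positive on the fold scale")
  fcs <- vapply(groups[-1], function(gr) mean(gr) / ctrl, 0)
  afc <- max(pmax(fcs, 1 / fcs))
  list(pass = (p < alpha) && (afc >= fc_min), p = p, max_fold_change = afc)
}

#' Efficiency-corrected relative expression (Pfaffl method)
#'
#' Ratio of target-gene to reference-gene expression change between a
#' treated and a control sample, correcting each gene for its qPCR
#' amplification efficiency:
#' \deqn{R = E_{target}^{\Delta Ct_{target}} / E_{ref}^{\Delta Ct_{ref}}}
#' with \eqn{\Delta Ct = Ct_{control} - Ct_{treated}}.
#'
#' @param ct_target_treated,ct_target_control Ct values of the biomarker.
#' @param ct_ref_treated,ct_ref_control Ct values of the housekeeping gene.
#' @param e_target,e_ref amplification efficiencies in (1, 2] (2 = perfect
#'   doubling per cycle).
#' @return fold change (1 = unchanged).
#' @examples
#' pfaffl_relative_expression(19, 20, 20, 20, 2, 2)  # 2-fold up
#' @export
pfaffl_relative_expression <- function(ct_target_treated, ct_target_control,
                                       ct_ref_treated, ct_ref_control,
                                       e_target = 2, e_ref = 2) {
  if (e_target <= 1 || e_ref <= 1 || e_target > 2 || e_ref > 2)
    stop("amplification efficiencies must lie in (1, 2]")
  d_t <- ct_target_control - ct_target_treated
  d_r <- ct_ref_control - ct_ref_treated
  e_target^d_t / e_ref^d_r
}
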