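# LOEC calling for the receptor-activation pre-screens and the
# steroidogenesis assay, with carry-over interpretation of the latter.

#' Lowest observed effect concentration by Dunnett comparison
#'
#' Compares every tested concentration against the vehicle control with
#' Dunnett's many-to-one procedure (single-step, via \pkg{multcomp}) and
#' returns the lowest concentration whose adjusted p-value falls below
#' `alpha`. The LOEC is always one of the tested concentrations; when no
#' concentration is significant it is absent.
#'
#' @param concentrations tested concentrations (uM), strictly positive.
#' @param responses list of replicate vectors aligned with
#'   `concentrations`.
#' @param vehicle replicate responses of the vehicle control (>= 2 values).
#' @param alpha significance level (default 0.05).
#' @return object of class `loec_result`: list with `loec` (uM or `NA`),
#'   `direction` (`"up"`/`"down"` at the LOEC, `NA` if absent),
#'   `p_values` (adjusted, per concentration),
#'   `confounded_by_carryover` (`FALSE` here; see [h295r_interpret()]).
#' @export
loec <- function(concentrations, responses, vehicle, alpha = 0.05) {
  conc <- as.numeric(concentrations)
  stopifnot(all(conc > 0), is.list(responses),
            length(responses) == length(conc))
  if (length(vehicle) < 2)
    stop("at least 2 vehicle control replicates required")
  ord <- order(conc)
  conc <- conc[ord]; responses <- responses[ord]

  y <- c(vehicle, unlist(responses, use.names = FALSE))
  grp <- factor(rep(c("vehicle", paste0("c", seq_along(conc))),
                    c(length(vehicle), lengths(responses))),
                levels = c("vehicle", paste0("c", seq_along(conc))))
  fit <- stats::aov(y ~ grp)
  cmp <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
  sm <- summary(cmp)
  padj <- as.numeric(sm$test$pvalues)
  est <- as.numeric(sm$test$coefficients)

  sig <- which(padj < alpha)
  if (length(sig) == 0L) {
    return(structure(list(loec = NA_real_, direction = NA_character_,
                          p_values = padj, confounded_by_carryover = FALSE),
                     class = "loec_result"))
  }
  i <- min(sig)   # ties broken by lower concentration
  structure(list(loec = conc[i],
                 direction = if (est[i] > 0) "up" else "down",
                 p_values = padj, confounded_by_carryover = FALSE),
            class = "loec_result")
}

#' @export
print.loec_result <- function(x, ...) {
  if (is.na(x$loec)) cat("LOEC: none (no significant concentration)\n")
  else cat(sprintf("LOEC: %.4g uM (%s)%s\n", x$loec, x$direction,
                   if (isTRUE(x$confounded_by_carryover))
                     " [confounded by receptor carry-over]" else ""))
  invisible(x)
}

#' Interpret a steroidogenesis LOEC against the receptor pre-screen
#'
#' The steroidogenesis assay quantifies hormone changes by applying diluted
#' assay medium to reporter cells; a compound that itself activates the
#' reporter can therefore mimic a hormone change if it is carried over in
#' the medium. The pre-screen rules this out: when the pre-screen shows
#' direct receptor activity at or below the carried-over concentration
#' (steroidogenesis LOEC divided by the dilution factor), the
#' steroidogenesis LOEC is retained but flagged as confounded.
#'
#' @param steroid_loec `loec_result` from the steroidogenesis assay.
#' @param prescreen_loec `loec_result` from the receptor pre-screen of the
#'   same chemical and receptor.
#' @param dilution_factor dilution of the assay medium onto the reporter
#'   cells (> 1 means the carried-over concentration is lower).
#' @return the steroid `loec_result` with `confounded_by_carryover` set.
#' @export
h295r_interpret <- function(steroid_loec, prescreen_loec, dilution_factor) {
  stopifnot(inherits(steroid_loec, "loec_result"),
            inherits(prescreen_loec, "loec_result"),
            dilution_factor > 0)
  confounded <- FALSE
  if (!is.na(steroid_loec$loec) && !is.na(prescreen_loec$loec)) {
    carried_over <- steroid_loec$loec / dilution_factor
    confounded <- prescreen_loec$loec <= carried_over
  }
  steroid_loec$confounded_by_carryover <- confounded
  steroid_loec
}
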