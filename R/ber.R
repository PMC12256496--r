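# BER aggregation: minimum PoD per chemical, bioactivity:exposure ratio per
# scenario, and protectiveness/utility scoring against benchmark labels.

# platform precedence for tie-breaking, in the order the PoD sources are
# enumerated in the framework
.platform_order <- c("ipp", "csp", "httr_hepg2", "httr_heparg", "httr_mcf7",
                     "reprotracker", "devtox_qp", "h295r", "calux")

#' Minimum platform PoD for a chemical
#'
#' Selects the record with the smallest PoD from the available platform
#' PoDs. Ties are broken by platform precedence (profiling panel, cell
#' stress panel, the transcriptomics cell lines, then the DART-targeted
#' assays) and then by endpoint id; ties are recorded on the result.
#'
#' @param pods data.frame with columns `chemical_id`, `platform` (one of
#'   the framework platforms), `endpoint`, `pod_uM` (> 0) and optionally
#'   `category` (`"dart_targeted"` or `"broad"`).
#' @param subset optional category filter (`"dart_targeted"` or `"broad"`),
#'   used to contrast targeted and broad screening tools.
#' @return one-row data.frame (the winning record) with an extra `tied`
#'   logical column.
#' @export
min_pod <- function(pods, subset = NULL) {
  stopifnot(is.data.frame(pods),
            all(c("platform", "endpoint", "pod_uM") %in% names(pods)))
  if (!is.null(subset)) {
    stopifnot("category" %in% names(pods))
    pods <- pods[pods$category == subset, , drop = FALSE]
  }
  if (nrow(pods) == 0L) stop("no PoD records after filtering")
  if (any(pods$pod_uM <= 0)) stop("PoDs must be positive")
  if (!all(pods$platform %in% .platform_order))
    stop("unknown platform(s): ",
         paste(setdiff(pods$platform, .platform_order), collapse = ", "))
  rank_platform <- match(pods$platform, .platform_order)
  ord <- order(pods$pod_uM, rank_platform, pods$endpoint)
  win <- pods[ord[1], , drop = FALSE]
  win$tied <- sum(pods$pod_uM == win$pod_uM) > 1
  win
}

#' Bioactivity:exposure ratio and risk call for one scenario
#'
#' `BER = min PoD / Cmax`. A BER at or below the threshold (default 1)
#' flags the scenario as uncertain risk - bioactivity is expected at the
#' estimated exposure - while a BER above it is called low risk. A missing
#' Cmax yields no call (the scenario is flagged instead of silently
#' substituted).
#'
#' @param min_pod_uM minimum platform PoD (uM, > 0).
#' @param cmax_uM estimated plasma Cmax for the scenario (uM, > 0), or `NA`.
#' @param threshold decision boundary (default 1; `<=` is uncertain).
#' @return list with `ber`, `call` (`"low_risk"`, `"uncertain_risk"` or
#'   `"no_call"`), `cmax_missing`.
#' @examples
#' ber(10, 1)    # low risk
#' ber(1, 1)     # boundary: uncertain risk
#' @export
ber <- function(min_pod_uM, cmax_uM, threshold = 1) {
  stopifnot(min_pod_uM > 0)
  if (is.na(cmax_uM))
    return(list(ber = NA_real_, call = "no_call", cmax_missing = TRUE))
  stopifnot(cmax_uM > 0)
  b <- min_pod_uM / cmax_uM
  list(ber = b,
       call = if (b <= threshold) "uncertain_risk" else "low_risk",
       cmax_missing = FALSE)
}

#' Protectiveness and utility of a set of BER calls
#'
#' Protectiveness is the percentage of high-risk benchmark scenarios
#' correctly called uncertain risk; utility is the percentage of low-risk
#' scenarios correctly called low risk. Scenarios whose benchmark label is
#' uncertain are reported separately and enter neither metric.
#'
#' @param calls character vector of BER calls (`"uncertain_risk"`,
#'   `"low_risk"`, `"no_call"`).
#' @param risk_truth character vector of benchmark labels (`"high"`,
#'   `"low"`, `"uncertain"`), same length.
#' @return object of class `framework_metrics`: list with `protectiveness`,
#'   `utility` (percent, `NA` when the class is absent) and `counts`
#'   (table of truth x call).
#' @examples
#' framework_metrics(c("uncertain_risk", "low_risk"), c("high", "low"))
#' @export
framework_metrics <- function(calls, risk_truth) {
  stopifnot(length(calls) == length(risk_truth),
            all(calls %in% c("uncertain_risk", "low_risk", "no_call")),
            all(risk_truth %in% c("high", "low", "uncertain")))
  high <- risk_truth == "high"; low <- risk_truth == "low"
  prot <- if (any(high)) 100 * sum(calls[high] == "uncertain_risk") /
    sum(high) else NA_real_
  util <- if (any(low)) 100 * sum(calls[low] == "low_risk") /
    sum(low) else NA_real_
  structure(list(protectiveness = prot, utility = util,
                 counts = table(truth = risk_truth, call = calls)),
            class = "framework_metrics")
}

#' @export
print.framework_metrics <- function(x, ...) {
  cat(sprintf("Protectiveness %.1f%%  Utility %.1f%%\n",
              x$protectiveness, x$utility))
  print(x$counts)
  invisible(x)
}

#' Score a PoD table against a scenario table
#'
#' Joins per-chemical minimum PoDs to exposure scenarios, computes a BER
#' and call per scenario, and summarizes protectiveness/utility.
#'
#' @param pods PoD data.frame (see [min_pod()]).
#' @param scenarios data.frame with columns `chemical_id`,
#'   `scenario_label`, `cmax_uM`, `risk_truth`.
#' @param subset optional PoD category filter passed to [min_pod()].
#' @param threshold BER decision boundary.
#' @return list with `per_scenario` (data.frame: scenario, truth, min PoD,
#'   ber, call) and `metrics` (a `framework_metrics`).
#' @export
evaluate_ber <- function(pods, scenarios, subset = NULL, threshold = 1) {
  stopifnot(is.data.frame(scenarios),
            all(c("chemical_id", "cmax_uM", "risk_truth") %in%
                  names(scenarios)))
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    ch_pods <- pods[pods$chemical_id == sc$chemical_id, , drop = FALSE]
    if (nrow(ch_pods) == 0L)
      return(data.frame(chemical_id = sc$chemical_id,
                        scenario_label = sc$scenario_label,
                        risk_truth = sc$risk_truth, min_pod_uM = NA_real_,
                        min_pod_platform = NA_character_, ber = NA_real_,
                        call = "no_call"))
    mp <- min_pod(ch_pods, subset = subset)
    b <- ber(mp$pod_uM, sc$cmax_uM, threshold = threshold)
    data.frame(chemical_id = sc$chemical_id,
               scenario_label = sc$scenario_label,
               risk_truth = sc$risk_truth, min_pod_uM = mp$pod_uM,
               min_pod_platform = mp$platform, ber = b$ber, call = b$call)
  })
  per_scenario <- do.call(rbind, rows)
  list(per_scenario = per_scenario,
       metrics = framework_metrics(per_scenario$call,
                                   per_scenario$risk_truth))
}
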