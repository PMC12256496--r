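#' Impute a study's concentration mean and SD from whatever was reported
#'
#' Pharmacokinetic literature reports internal concentrations in
#' heterogeneous form: mean with SD, mean with SEM, or only a range. This
#' harmonizes one study record to a (mean, sd) pair with a documented
#' precedence: a reported SD wins over SEM-derived SD (`SEM * sqrt(N)`),
#' which wins over the range rule `SD ~ range/6` (99.7% of a normal lies
#' within three SDs of the mean). A missing mean is filled from the range.
#'
#' @param record a list or one-row data.frame with (some of) fields
#'   `conc_mean`, `conc_sd`, `conc_sem`, `conc_min`, `conc_max`, `n`.
#' @param mean_from_range `"midpoint"` (default) uses
#'   `(max + min)/2`; `"compat_half_range"` reproduces the literal
#'   `(max - min)/2` rule some workflows print, kept as a compatibility
#'   mode only (it can fall below the range minimum).
#' @return list with `mean`, `sd` (`NA` if unavailable), `sd_source` (one of
#'   `"reported"`, `"sem"`, `"range"`, `"missing"`), `mean_source`
#'   (`"reported"` or `"range"`) and `sd_missing` flag.
#' @examples
#' impute_summary(list(conc_min = 2, conc_max = 8))      # sd = 1
#' impute_summary(list(conc_mean = 4, conc_sem = 2, n = 25))  # sd = 10
#' @export
impute_summary <- function(record,
                           mean_from_range = c("midpoint",
                                               "compat_half_range")) {
  mean_from_range <- match.arg(mean_from_range)
  g <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  m <- g("conc_mean"); sd <- g("conc_sd"); sem <- g("conc_sem")
  lo <- g("conc_min"); hi <- g("conc_max"); n <- g("n")
  has_range <- !is.na(lo) && !is.na(hi)
  if (has_range && lo > hi) stop("conc_min must not exceed conc_max")
  if (is.na(m) && !has_range) stop("record has neither a mean nor a range")

  if (is.na(m)) {
    m <- if (mean_from_range == "midpoint") (hi + lo) / 2 else (hi - lo) / 2
    mean_source <- "range"
  } else mean_source <- "reported"

  if (!is.na(sd)) {
    sd_source <- "reported"
  } else if (!is.na(sem)) {
    if (is.na(n)) stop("SEM given without study N")
    sd <- sem * sqrt(n); sd_source <- "sem"
  } else if (has_range) {
    sd <- (hi - lo) / 6; sd_source <- "range"
  } else {
    sd <- NA_real_; sd_source <- "missing"
  }
  list(mean = m, sd = sd, sd_source = sd_source, mean_source = mean_source,
       sd_missing = is.na(sd))
}

#' External dose in mg/day
#'
#' Converts a dosing regimen to an external daily dose. Body-weight doses
#' assume a 70 kg adult; body-surface-area doses assume 1.7 m2.
#'
#' @param amount dose amount per administration (>= 0).
#' @param unit one of `"mg"`, `"mg_per_kg"`, `"mg_per_m2"`.
#' @param doses_per_day administrations per day (> 0).
#' @return dose in mg/day.
#' @export
external_dose_mg_per_day <- function(amount, unit, doses_per_day = 1) {
  stopifnot(amount >= 0, doses_per_day > 0)
  scale <- switch(unit,
                  mg = 1, mg_per_kg = 70, mg_per_m2 = 1.7,
                  stop("unknown dose unit: ", unit))
  amount * scale * doses_per_day
}

#' Internal concentration in micromolar
#'
#' Converts a reported systemic concentration to uM using the molecular
#' weight of the undissociated, desalted species for mass-based units.
#'
#' @param value concentration in `unit`.
#' @param unit one of `"ug_per_mL"`, `"mg_per_L"`, `"ng_per_mL"`, `"uM"`,
#'   `"nM"`.
#' @param mw molecular weight in g/mol (required for mass units).
#' @return concentration in uM.
#' @export
internal_conc_uM <- function(value, unit, mw = NULL) {
  to_mg_per_L <- c(ug_per_mL = 1, mg_per_L = 1, ng_per_mL = 1e-3)
  if (unit %in% names(to_mg_per_L)) {
    if (is.null(mw) || is.na(mw)) stop("molecular weight required for ", unit)
    stopifnot(mw > 0)
    # (mg/L) / (g/mol) = mmol/m3 = umol/L * 1e-3, hence the 1000
    return(value * to_mg_per_L[[unit]] / mw * 1000)
  }
  switch(unit, uM = value, nM = value / 1000,
         stop("unknown concentration unit: ", unit))
}

#' Inverse of [internal_conc_uM()] for mass units (round-trip checks)
#' @param value_uM concentration in uM.
#' @param unit target unit.
#' @param mw molecular weight in g/mol.
#' @return concentration in `unit`.
#' @export
uM_to_unit <- function(value_uM, unit, mw = NULL) {
  switch(unit,
         uM = value_uM,
         nM = value_uM * 1000,
         ug_per_mL = value_uM * mw / 1000,
         mg_per_L = value_uM * mw / 1000,
         ng_per_mL = value_uM * mw,
         stop("unknown concentration unit: ", unit))
}

#' Concentration-dose ratio (CDR) for one study
#'
#' Divides the internal concentration summary by the external daily dose,
#' yielding uM per mg/day. The SD scales linearly with the same factor.
#'
#' @param conc_mean_uM,conc_sd_uM internal concentration mean and SD (uM);
#'   `conc_sd_uM` may be `NA`.
#' @param dose_mg_per_day external dose (> 0); records without a defined
#'   dose (e.g. biomonitoring) must be excluded upstream.
#' @param n study population size.
#' @return list with `cdr_mean`, `cdr_sd`, `n`.
#' @export
cdr <- function(conc_mean_uM, dose_mg_per_day, conc_sd_uM = NA_real_, n = 1L) {
  if (dose_mg_per_day <= 0)
    stop("dose must be positive; doseless records are excluded upstream")
  list(cdr_mean = conc_mean_uM / dose_mg_per_day,
       cdr_sd = conc_sd_uM / dose_mg_per_day,
       n = as.integer(n))
}

#' N-weighted population summary of study-level CDRs
#'
#' Pools study-level means and SDs into a population mean and SD, weighting
#' by study size. The pooled SD combines the within-study variance and the
#' between-study spread of means:
#' \deqn{SD^2_{tot} = \frac{\sum (N_i-1) SD_i^2 + \sum N_i(\bar x_i - \bar
#' x_{tot})^2}{N_{tot}-1}}
#' which equals the SD of the raw pooled sample reconstructed to have
#' exactly those per-study means and SDs. Studies with missing SD
#' contribute to the mean (with their N) but are excluded from the SD sum;
#' `n_sd` reports the size actually behind the SD.
#'
#' The summary also carries the 95th-percentile individual
#' (`p95 = mean + z * sd`, z = 1.64 by default) and the toxicokinetic
#' variability factor `tkvf95 = p95 / mean`.
#'
#' @param records list of CDR records (each with `cdr_mean`, `cdr_sd`, `n`)
#'   or a data.frame with those columns.
#' @param z z-score for the sensitive individual (default 1.64 for p95).
#' @return object of class `population_summary` with fields `weighted_mean`,
#'   `weighted_sd`, `n_total`, `n_sd`, `p95`, `tkvf95`.
#' @export
weighted_population_summary <- function(records, z = 1.64) {
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  if (length(records) == 0L) stop("at least one CDR record required")
  m <- vapply(records, function(r) as.numeric(r$cdr_mean), 0)
  s <- vapply(records, function(r) {
    v <- r$cdr_sd; if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  n <- vapply(records, function(r) as.numeric(r$n), 0)
  stopifnot(all(n >= 1))

  n_total <- sum(n)
  wmean <- sum(m * n) / n_total

  has_sd <- !is.na(s)
  if (any(has_sd) && sum(n[has_sd]) > 1) {
    ns <- n[has_sd]; ms <- m[has_sd]; ss <- s[has_sd]
    n_sd <- sum(ns)
    wsd <- sqrt((sum((ns - 1) * ss^2) + sum(ns * (ms - wmean)^2)) /
                  (n_sd - 1))
  } else {
    n_sd <- 0; wsd <- NA_real_
  }
  p95 <- if (is.na(wsd)) NA_real_ else wmean + z * wsd
  tkvf95 <- if (is.na(p95) || wmean <= 0) NA_real_ else p95 / wmean
  structure(list(weighted_mean = wmean, weighted_sd = wsd,
                 n_total = as.integer(n_total), n_sd = as.integer(n_sd),
                 p95 = p95, tkvf95 = tkvf95, z = z),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "CDR population summary: mean %.4g, SD %.4g (N=%d), p95 %.4g, TKVF95 %.3g\n",
    x$weighted_mean, x$weighted_sd, x$n_total, x$p95, x$tkvf95))
  invisible(x)
}

#' Toxicokinetic variability factor from a population summary
#'
#' `TKVF95 = p95 / mean = 1 + z * CV`, the fold by which a sensitive
#' (95th-percentile) individual's internal dose exceeds the typical (mean)
#' individual's.
#'
#' @param summary a `population_summary`.
#' @param z z-score (default 1.64).
#' @return dimensionless factor (>= 1 when SD >= 0).
#' @export
tkvf <- function(summary, z = 1.64) {
  stopifnot(inherits(summary, "population_summary"))
  if (summary$weighted_mean <= 0) stop("weighted mean must be positive")
  if (is.na(summary$weighted_sd)) return(NA_real_)
  1 + z * summary$weighted_sd / summary$weighted_mean
}

#' Compare a population's CDR to a reference population
#'
#' Fold difference of means (comparator / reference) with a Welch-style
#' two-sample z test built from the weighted summaries. When either group
#' has fewer than 10 subjects the p-value is suppressed (`small_n_flag`),
#' mirroring the reporting convention for sparse pregnancy/fetal data.
#'
#' @param reference,comparator `population_summary` objects.
#' @param small_n below this N the comparison is flagged and p suppressed.
#' @return list with `fold_difference`, `p_value` (`NA` when suppressed or
#'   SDs unavailable), `small_n_flag`.
#' @export
compare_populations <- function(reference, comparator, small_n = 10) {
  stopifnot(inherits(reference, "population_summary"),
            inherits(comparator, "population_summary"))
  if (reference$weighted_mean <= 0)
    stop("reference mean must be positive")
  fold <- comparator$weighted_mean / reference$weighted_mean
  flag <- reference$n_total < small_n || comparator$n_total < small_n
  p <- NA_real_
  if (!flag && !is.na(reference$weighted_sd) &&
      !is.na(comparator$weighted_sd)) {
    sed <- sqrt(reference$weighted_sd^2 / reference$n_total +
                  comparator$weighted_sd^2 / comparator$n_total)
    if (sed == 0) {
      p <- if (comparator$weighted_mean == reference$weighted_mean) 1 else 0
    } else {
      zstat <- (comparator$weighted_mean - reference$weighted_mean) / sed
      p <- 2 * stats::pnorm(-abs(zstat))
    }
  }
  list(fold_difference = fold, p_value = p, small_n_flag = flag)
}

#' Full PK pipeline: study records to population summaries
#'
#' Convenience wrapper: imputes missing summary statistics, converts units,
#' forms CDRs and pools them per chemical and population. Records without a
#' usable dose are excluded with a reason code rather than silently dropped.
#'
#' @param pk data.frame of study records with columns `chemical_id`,
#'   `population`, `dose_amount`, `dose_unit`, `doses_per_day`, `n`,
#'   `conc_mean`, `conc_unit`, and optionally `conc_sd`, `conc_sem`,
#'   `conc_min`, `conc_max`, `mw`.
#' @param mw named vector of molecular weights (g/mol) by chemical, used
#'   when the table has no `mw` column.
#' @return list with `summaries` (data.frame, one row per
#'   chemical x population) and `excluded` (data.frame of dropped records
#'   with `reason`).
#' @export
pk_population_summaries <- function(pk, mw = NULL) {
  stopifnot(is.data.frame(pk))
  excluded <- list(); rows <- list()
  key <- interaction(pk$chemical_id, pk$population, drop = TRUE)
  for (k in levels(key)) {
    sub <- pk[key == k, , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(sub))) {
      r <- as.list(sub[i, ])
      dose <- tryCatch(
        external_dose_mg_per_day(r$dose_amount, r$dose_unit, r$doses_per_day),
        error = function(e) NA_real_)
      if (is.na(dose) || dose <= 0) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(chemical_id = r$chemical_id, population = r$population,
                     reason = "no_defined_dose")
        next
      }
      imp <- impute_summary(r)
      mwi <- if (!is.null(r$mw) && !is.na(r$mw)) r$mw else mw[[r$chemical_id]]
      cm <- internal_conc_uM(imp$mean, r$conc_unit, mwi)
      cs <- if (imp$sd_missing) NA_real_ else
        internal_conc_uM(imp$sd, r$conc_unit, mwi)
      recs[[length(recs) + 1L]] <- cdr(cm, dose, cs, r$n)
    }
    if (length(recs) == 0L) next
    s <- weighted_population_summary(recs)
    rows[[length(rows) + 1L]] <- data.frame(
      chemical_id = sub$chemical_id[1], population = sub$population[1],
      weighted_mean = s$weighted_mean, weighted_sd = s$weighted_sd,
      n_total = s$n_total, p95 = s$p95, tkvf95 = s$tkvf95)
  }
  list(summaries = if (length(rows)) do.call(rbind, rows) else
    data.frame(),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame())
}
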