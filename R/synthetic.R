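# Seeded generators for every input the pipeline consumes: PK study sets
# with known population parameters, concentration-response curves with
# known PoDs, prediction sets with known confusion structure, and benchmark
# scenario suites with known risk separation. Each generator returns the
# generating truth alongside the data; nothing downstream reads the truth.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Generate synthetic PK study records
#'
#' Emulates a multi-study PK literature set for one chemical and
#' population: between-subject concentration-dose ratios are lognormal
#' (positive, right-skewed), each study reports the mean and SD of its own
#' N subjects, and reporting units are randomized across the supported
#' concentration units to exercise the conversion paths. Doses are drawn
#' per study; concentrations are `CDR * dose` so the generating CDR
#' distribution is recoverable.
#'
#' @param n_studies number of studies (>= 1).
#' @param cdr_mean,cdr_cv mean and coefficient of variation of the true
#'   between-subject CDR distribution (uM per mg/day).
#' @param n_range integer range of per-study subject counts.
#' @param mw molecular weight used for mass-unit reporting (g/mol).
#' @param fixed_unit optionally force one reporting unit (debugging aid).
#' @param seed integer seed.
#' @return list with `records` (data.frame in the PK study schema,
#'   including `mw`) and `truth` (list: `cdr_mean`, `cdr_cv`, `cdr_sd`,
#'   `p95_lognormal` - the exact 95th percentile of the generating
#'   lognormal).
#' @export
gen_pk_studies <- function(n_studies = 10, cdr_mean = 0.05, cdr_cv = 0.5,
                           n_range = c(10, 200), mw = 200,
                           fixed_unit = NULL, seed = 1L) {
  if (n_studies < 1) stop("n_studies must be >= 1")
  stopifnot(cdr_mean > 0, cdr_cv >= 0)
  sdlog <- sqrt(log(1 + cdr_cv^2))
  meanlog <- log(cdr_mean) - sdlog^2 / 2
  units <- c("ug_per_mL", "mg_per_L", "ng_per_mL", "uM", "nM")
  with_seed(seed, {
    rows <- lapply(seq_len(n_studies), function(i) {
      n <- sample(seq(n_range[1], n_range[2]), 1)
      dose <- stats::runif(1, 50, 500)                      # mg/day
      cdr_i <- if (cdr_cv == 0) rep(cdr_mean, n) else
        stats::rlnorm(n, meanlog, sdlog)
      conc_uM <- cdr_i * dose
      unit <- if (is.null(fixed_unit)) sample(units, 1) else fixed_unit
      m_rep <- uM_to_unit(mean(conc_uM), unit, mw)
      s_rep <- uM_to_unit(stats::sd(conc_uM), unit, mw)
      data.frame(chemical_id = "synth", population = "non_pregnant",
                 study_type = "clinical", dose_amount = dose,
                 dose_unit = "mg", doses_per_day = 1, n = n,
                 conc_mean = m_rep, conc_unit = unit, conc_sd = s_rep,
                 conc_sem = NA_real_, conc_min = NA_real_,
                 conc_max = NA_real_, mw = mw)
    })
    truth_p95 <- if (cdr_cv == 0) cdr_mean else
      stats::qlnorm(0.95, meanlog, sdlog)
    list(records = do.call(rbind, rows),
         truth = list(cdr_mean = cdr_mean, cdr_cv = cdr_cv,
                      cdr_sd = cdr_mean * cdr_cv,
                      p95_lognormal = truth_p95))
  })
}

#' Generate a synthetic concentration-response data set
#'
#' Emits replicate/plate-row structured responses from a known curve family
#' plus Gaussian noise, together with the generating truth (IC50, BMD at
#' 10%, or threshold crossing, as applicable to the family).
#'
#' @param family `"hill"` (0-100% activation, carries true `ic50`),
#'   `"exp3"` (exponential decline, carries the analytic 10% `bmd`),
#'   `"fourPL"` (ratio curve around 1, carries the analytic `dtt` crossing
#'   `c_star`), or `"flat"`.
#' @param concentrations tested concentrations (uM).
#' @param n_replicates replicate columns (plate rows for the hierarchical
#'   model).
#' @param noise_sd Gaussian noise SD on the response scale (>= 0).
#' @param par named list of family parameters; defaults:
#'   hill `list(ic50 = 1, slope = 1, low = 0, high = 100)`;
#'   exp3 `list(a = 100, b = 0.2)`; fourPL `list(top = 1, bottom = 0.5,
#'   mid = 2, hill = 1)`.
#' @param row_effect_sd SD of multiplicative log-normal row offsets
#'   (default 0, i.e. none).
#' @param seed integer seed.
#' @return list with `concentrations`, `responses` (matrix, columns =
#'   replicates/rows), `row_labels`, `family`, `truth`.
#' @export
gen_concresp <- function(family = c("hill", "exp3", "fourPL", "flat"),
                         concentrations = 10^seq(-2, 2, length.out = 8),
                         n_replicates = 2, noise_sd = 0, par = list(),
                         row_effect_sd = 0, seed = 1L) {
  family <- match.arg(family)
  if (noise_sd < 0) stop("noise SD must be >= 0")
  conc <- sort(as.numeric(concentrations))
  defaults <- switch(family,
    hill = list(ic50 = 1, slope = 1, low = 0, high = 100),
    exp3 = list(a = 100, b = 0.2),
    fourPL = list(top = 1, bottom = 0.5, mid = 2, hill = 1),
    flat = list(level = 100))
  par <- utils::modifyList(defaults, par)
  mu <- switch(family,
    hill = par$low + (par$high - par$low) * conc^par$slope /
      (par$ic50^par$slope + conc^par$slope),
    exp3 = par$a * exp(-par$b * conc),
    fourPL = par$bottom + (par$top - par$bottom) /
      (1 + (conc / par$mid)^par$hill),
    flat = rep(par$level, length(conc)))
  truth <- switch(family,
    hill = list(ic50 = par$ic50),
    exp3 = list(bmd = log(1 / 0.9) / par$b),
    fourPL = {
      num <- par$top - 0.85; den <- 0.85 - par$bottom
      list(c_star = if (num / den > 0)
        par$mid * (num / den)^(1 / par$hill) else NA_real_)
    },
    flat = list())
  with_seed(seed, {
    rows <- exp(stats::rnorm(n_replicates, 0, row_effect_sd))
    resp <- vapply(seq_len(n_replicates), function(r)
      mu * rows[r] + stats::rnorm(length(mu), 0, noise_sd),
      numeric(length(mu)))
    list(concentrations = conc, responses = resp,
         row_labels = paste0("row", seq_len(n_replicates)),
         family = family, truth = c(truth, list(par = par)))
  })
}

#' Generate a benchmark suite with known risk separation
#'
#' Builds a PoD table and an exposure-scenario table in which high-risk
#' scenarios have Cmax at or above the chemical's minimum PoD (BER <= 1)
#' and low-risk scenarios have Cmax at most `min PoD / separation`
#' (BER >= separation). With separation > 1 and no noise the framework
#' metrics are 100/100 by construction.
#'
#' @param n_chemicals number of chemicals (one high- and one low-risk
#'   scenario each).
#' @param separation ratio between the low-risk BER and the boundary
#'   (must be > 1 for guaranteed separation; 1 allows boundary noise).
#' @param noise_sd lognormal jitter (sdlog) applied to the scenario Cmax.
#' @param pods_per_chemical PoD records drawn per chemical.
#' @param seed integer seed.
#' @return list with `pods` (data.frame) and `scenarios` (data.frame with
#'   `risk_truth` labels).
#' @export
gen_benchmark_suite <- function(n_chemicals = 20, separation = 10,
                                noise_sd = 0, pods_per_chemical = 5,
                                seed = 1L) {
  stopifnot(separation >= 1, n_chemicals >= 1)
  platforms <- c("ipp", "csp", "httr_hepg2", "httr_heparg", "httr_mcf7",
                 "reprotracker", "devtox_qp", "h295r", "calux")
  with_seed(seed, {
    pods <- do.call(rbind, lapply(seq_len(n_chemicals), function(i) {
      data.frame(
        chemical_id = sprintf("chem%02d", i),
        platform = sample(platforms, pods_per_chemical, replace = TRUE),
        endpoint = sprintf("ep%d", seq_len(pods_per_chemical)),
        pod_uM = stats::rlnorm(pods_per_chemical, log(10), 1),
        category = sample(c("dart_targeted", "broad"), pods_per_chemical,
                          replace = TRUE))
    }))
    scenarios <- do.call(rbind, lapply(seq_len(n_chemicals), function(i) {
      id <- sprintf("chem%02d", i)
      mp <- min(pods$pod_uM[pods$chemical_id == id])
      jitter <- function() exp(stats::rnorm(1, 0, noise_sd))
      rbind(
        data.frame(chemical_id = id,
                   scenario_label = paste0(id, "_high"),
                   cmax_uM = mp * 1.5 * jitter(), risk_truth = "high"),
        data.frame(chemical_id = id,
                   scenario_label = paste0(id, "_low"),
                   cmax_uM = mp / separation / 1.5 * jitter(),
                   risk_truth = "low"))
    }))
    list(pods = pods, scenarios = scenarios)
  })
}

#' Generate prediction records with a planted confusion structure
#'
#' Produces per-chemical binary hazard calls for one synthetic model with
#' known sensitivity/specificity error rates, for exercising the
#' confusion-matrix tally.
#'
#' @param n_chemicals total chemicals; a fraction `prev` are truly toxic.
#' @param prev prevalence of true toxicants.
#' @param fn_rate,fp_rate probability of flipping a toxic call to nontoxic
#'   and vice versa.
#' @param np_rate probability a chemical is not predicted.
#' @param unknown_rate fraction of chemicals with unknown truth.
#' @param seed integer seed.
#' @return data.frame in the prediction-record schema (`model_id`
#'   `"synthetic"`).
#' @export
gen_prediction_records <- function(n_chemicals = 50, prev = 0.5,
                                   fn_rate = 0.1, fp_rate = 0.1,
                                   np_rate = 0.05, unknown_rate = 0,
                                   seed = 1L) {
  with_seed(seed, {
    truth <- ifelse(stats::runif(n_chemicals) < prev, "toxic", "nontoxic")
    unknown <- stats::runif(n_chemicals) < unknown_rate
    truth[unknown] <- "unknown"
    flipped <- ifelse(truth == "toxic",
                      ifelse(stats::runif(n_chemicals) < fn_rate,
                             "nontoxic", "toxic"),
                      ifelse(stats::runif(n_chemicals) < fp_rate,
                             "toxic", "nontoxic"))
    call <- ifelse(stats::runif(n_chemicals) < np_rate, "not_predicted",
                   flipped)
    data.frame(chemical_id = sprintf("chem%03d", seq_len(n_chemicals)),
               model_id = "synthetic", call = call, truth = truth)
  })
}
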