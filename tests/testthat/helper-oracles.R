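# Independent oracles used across the suite.

# a raw sample of size n with exactly the given mean and sd
exact_sample <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# brute-force confusion tally, written independently of tally_confusion()
brute_confusion <- function(records, model) {
  r <- records[records$model_id == model & records$truth != "unknown", ]
  tp <- fn <- tn <- fp <- 0
  for (i in seq_len(nrow(r))) {
    if (r$truth[i] == "toxic") {
      if (r$call[i] == "toxic") tp <- tp + 1
      if (r$call[i] == "nontoxic") fn <- fn + 1
    } else {
      if (r$call[i] == "nontoxic") tn <- tn + 1
      if (r$call[i] == "toxic") fp <- fp + 1
    }
  }
  c(tp = tp, fn = fn, tn = tn, fp = fp, total = nrow(r))
}

# 4PL evaluated directly (for threshold-crossing oracles)
fourPL_curve <- function(c, top, bottom, mid, hill)
  bottom + (top - bottom) / (1 + (c / mid)^hill)
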