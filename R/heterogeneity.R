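#' Scaled median absolute deviation
#'
#' `1.4826 * median(|x - median(x)|)`, the consistency-scaled MAD whose
#' expectation under a normal sample equals the standard deviation. The
#' median of an even-length vector is the mean of the two central order
#' statistics.
#'
#' @param values non-empty numeric vector (no NAs).
#' @return non-negative scalar.
#' @export
mad_scaled <- function(values) {
  if (length(values) == 0L) stop("mad_scaled: empty vector")
  if (anyNA(values)) stop("mad_scaled: NA values not allowed")
  1.4826 * stats::median(abs(values - stats::median(values)))
}

.math_qc_levels <- c("ok", "too_few_variants", "zero_median")

#' MATH score of one VAF profile
#'
#' MATH (mutant-allele tumor heterogeneity) summarizes the dispersion of a
#' tumor's variant allele fractions:
#' `MATH = 100 * mad_scaled(vafs) / median(vafs)`.
#' Degenerate inputs are flagged, never errors: fewer than `min_variants`
#' VAFs give `qc_flag = "too_few_variants"`, a zero median gives
#' `"zero_median"`; in both cases `math` is NA.
#'
#' @param vafs numeric vector of variant allele fractions.
#' @param min_variants minimum profile size for a usable score (default 5;
#'   the MAD of fewer points is too unstable to rank tumors by).
#' @return one-row data.frame: `n_variants`, `median_vaf`, `mad_scaled`,
#'   `math`, `qc_flag`.
#' @export
math_score <- function(vafs, min_variants = 5) {
  n <- length(vafs)
  if (n < min_variants) {
    return(data.frame(n_variants = n, median_vaf = NA_real_,
                      mad_scaled = NA_real_, math = NA_real_,
                      qc_flag = "too_few_variants",
                      stringsAsFactors = FALSE))
  }
  med <- stats::median(vafs)
  md <- mad_scaled(vafs)
  if (med == 0) {
    return(data.frame(n_variants = n, median_vaf = med, mad_scaled = md,
                      math = NA_real_, qc_flag = "zero_median",
                      stringsAsFactors = FALSE))
  }
  data.frame(n_variants = n, median_vaf = med, mad_scaled = md,
             math = 100 * md / med, qc_flag = "ok",
             stringsAsFactors = FALSE)
}

#' MATH scores for a cohort of VAF profiles
#'
#' @param profiles named list, sample_id -> VAF vector (e.g. from
#'   [vaf_profiles()]).
#' @param min_variants passed to [math_score()].
#' @return data.frame with one row per sample (`sample_id` first), in input
#'   order; `attr(, "summary")` holds the cohort median and range of MATH
#'   over qc-ok samples (all NA when no sample is usable).
#' @export
cohort_math <- function(profiles, min_variants = 5) {
  if (length(profiles) == 0L) stop("cohort_math: empty profile mapping")
  rows <- lapply(profiles, math_score, min_variants = min_variants)
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(sample_id = names(profiles),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  ok <- out$math[out$qc_flag == "ok"]
  smry <- if (length(ok)) {
    list(median = stats::median(ok), range = range(ok), n_ok = length(ok))
  } else {
    list(median = NA_real_, range = c(NA_real_, NA_real_), n_ok = 0L)
  }
  structure(out, summary = smry)
}
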