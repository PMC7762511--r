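#' Assign MATH tertile groups
#'
#' Samples with a usable MATH score are sorted ascending (ties broken by
#' sample_id, so assignment is deterministic across platforms) and split at
#' ranks `k1 = floor(n/3)` and `k2 = floor(2n/3)`: ranks 1..k1 are "low",
#' k1+1..k2 "intermediate", and the remainder "high". When n is not a
#' multiple of 3 the extra sample(s) therefore land in the high group
#' (385 -> 128/128/129). Samples whose `qc_flag` is not "ok" keep an NA
#' group.
#'
#' @param math_table output of [cohort_math()] (needs `sample_id`, `math`,
#'   `qc_flag`).
#' @return the table with a `math_group` factor column
#'   (low < intermediate < high); `attr(, "group_medians")` holds the
#'   per-group median MATH, `attr(, "group_sizes")` the counts.
#' @export
assign_tertiles <- function(math_table) {
  usable <- which(math_table$qc_flag == "ok" & !is.na(math_table$math))
  n <- length(usable)
  if (n < 3L) stop("assign_tertiles: need at least 3 qc-ok samples, have ", n)
  ord <- usable[order(math_table$math[usable], math_table$sample_id[usable])]
  k1 <- floor(n / 3)
  k2 <- floor(2 * n / 3)
  lab <- rep("high", n)
  lab[seq_len(k1)] <- "low"
  if (k2 > k1) lab[(k1 + 1):k2] <- "intermediate"
  grp <- rep(NA_character_, nrow(math_table))
  grp[ord] <- lab
  math_table$math_group <- factor(grp, levels = c("low", "intermediate", "high"))
  med <- tapply(math_table$math[usable], math_table$math_group[usable],
                stats::median)
  structure(math_table,
            group_medians = med,
            group_sizes = table(math_table$math_group))
}

#' Format a count as "n(p%)" with round-half-up percentages
#'
#' @param count,total non-negative counts.
#' @return character, e.g. `count_pct(252, 385)` is `"252(65.5%)"`.
#' @export
count_pct <- function(count, total) {
  pct <- 100 * count / total
  # round half up to one decimal (floating-point guard on the .x5 boundary)
  r <- floor(pct * 10 + 0.5 + 1e-9) / 10
  sprintf("%d(%.1f%%)", count, r)
}

#' One-way ANOVA F test of a numeric variable across groups
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return list with `f`, `df1`, `df2`, `p_value`.
#' @export
group_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  g <- factor(groups[keep])
  if (nlevels(g) < 2L) return(list(f = NA_real_, df1 = NA, df2 = NA,
                                   p_value = NA_real_))
  fit <- stats::aov(values[keep] ~ g)
  tab <- summary(fit)[[1]]
  list(f = tab[["F value"]][1], df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
       p_value = tab[["Pr(>F)"]][1])
}

#' Baseline-characteristics table with univariate survival p-values
#'
#' For each categorical characteristic: the count and percentage of the
#' cohort at every level (percentages round-half-up to one decimal), plus a
#' univariate p-value from the k-group log-rank test across the levels
#' (records with an NA level are counted in the table but excluded from the
#' test). Numeric characteristics are instead compared across MATH groups
#' by a one-way ANOVA F test.
#'
#' @param cohort data.frame with `os_time`, `os_event`, `math_group` and the
#'   requested characteristic columns.
#' @param characteristics character vector of column names to summarize.
#' @return data.frame: `characteristic`, `level`, `n`, `label`, `p_value`
#'   (the p is carried on the first row of each characteristic).
#' @export
baseline_table <- function(cohort, characteristics) {
  if (nrow(cohort) == 0L) stop("baseline_table: empty cohort")
  total <- nrow(cohort)
  out <- list()
  for (ch in characteristics) {
    if (!ch %in% names(cohort)) stop("characteristic '", ch, "' not in cohort")
    v <- cohort[[ch]]
    if (is.numeric(v)) {
      a <- group_anova(v, cohort$math_group)
      out[[ch]] <- data.frame(
        characteristic = ch, level = "(continuous)", n = sum(!is.na(v)),
        label = sprintf("mean %.2f", mean(v, na.rm = TRUE)),
        p_value = a$p_value, stringsAsFactors = FALSE)
      next
    }
    f <- if (is.factor(v)) v else factor(v)
    lev <- levels(f)
    if (anyNA(f)) lev <- c(lev, "NA")
    counts <- vapply(lev, function(l) {
      if (l == "NA") sum(is.na(f)) else sum(!is.na(f) & f == l)
    }, integer(1))
    # log-rank across non-NA levels that actually occur
    test_keep <- !is.na(f)
    used <- droplevels(f[test_keep])
    p <- NA_real_
    if (nlevels(used) >= 2L && sum(cohort$os_event[test_keep], na.rm = TRUE) > 0) {
      lr <- logrank_test(cohort$os_time[test_keep],
                         cohort$os_event[test_keep], used)
      p <- lr$p_value
    }
    out[[ch]] <- data.frame(
      characteristic = ch, level = lev, n = unname(counts),
      label = vapply(counts, count_pct, character(1), total = total),
      p_value = c(p, rep(NA_real_, length(lev) - 1L)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ordinal numeric coding of clinical covariates for Cox models
#'
#' Mirrors single-hazard-ratio-per-covariate reporting: stage I-IV -> 1-4,
#' grade G1-G3 -> 1-3 (Gx -> NA), age group >=60 -> 1 / <60 -> 0, male -> 1,
#' radiation yes -> 1, histology Diffuse/Intestinal/SignetRing -> 1/2/3,
#' MATH group low/intermediate/high -> 0/1/2. Unknown levels and NAs stay NA
#' (downstream fits drop rows listwise).
#'
#' @param cohort data.frame with (any of) `age_group`, `sex`, `stage`,
#'   `grade`, `radiation`, `histology`, `math_group`.
#' @return numeric matrix, one column per available covariate.
#' @export
encode_clinical <- function(cohort) {
  code <- function(x, map) unname(map[as.character(x)])
  cols <- list()
  if ("age_group" %in% names(cohort)) {
    cols$age <- code(cohort$age_group, c(">=60" = 1, "<60" = 0))
  }
  if ("sex" %in% names(cohort)) {
    cols$sex <- code(cohort$sex, c(Male = 1, Female = 0))
  }
  if ("math_group" %in% names(cohort)) {
    cols$MATH <- code(cohort$math_group,
                      c(low = 0, intermediate = 1, high = 2))
  }
  if ("stage" %in% names(cohort)) {
    cols$stage <- code(cohort$stage, c(I = 1, II = 2, III = 3, IV = 4))
  }
  if ("grade" %in% names(cohort)) {
    cols$grade <- code(cohort$grade, c(G1 = 1, G2 = 2, G3 = 3))
  }
  if ("radiation" %in% names(cohort)) {
    cols$radiation <- code(cohort$radiation, c(Yes = 1, No = 0))
  }
  if ("histology" %in% names(cohort)) {
    cols$histology <- code(cohort$histology,
                           c(Diffuse = 1, Intestinal = 2, SignetRing = 3))
  }
  do.call(cbind, cols)
}
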