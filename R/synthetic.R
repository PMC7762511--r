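#' The 20 immune cell types shifted by default in synthetic expression
#'
#' Default ground truth for the expression generator: these cell-type sets
#' receive the planted mean shift in the low/intermediate-heterogeneity
#' group, mirroring the design in which most immune populations are more
#' infiltrated in less heterogeneous tumors. The remaining 8 of the 28
#' packaged sets stay exchangeable between groups.
#' @export
default_shifted_sets <- c(
  "Activated_CD4_T_cell", "Activated_CD8_T_cell",
  "Central_memory_CD4_T_cell", "Central_memory_CD8_T_cell",
  "Effector_memory_CD4_T_cell", "Effector_memory_CD8_T_cell",
  "Type_1_T_helper_cell", "Activated_dendritic_cell",
  "Natural_killer_cell", "Regulatory_T_cell", "Type_2_T_helper_cell",
  "Gamma_delta_T_cell", "Activated_B_cell", "Immature_B_cell",
  "T_follicular_helper_cell", "Mast_cell", "MDSC", "Macrophage",
  "Eosinophil", "Monocyte"
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline targets: a 385-patient
#' gastrectomy cohort of which ~44% carry adjuvant-chemotherapy information,
#' whole-exome read counts at ~150x mean coverage, a median of ~63 somatic
#' variants per sample, survival under proportional hazards with one
#' log-hazard step per MATH tertile (default step HR 1.433), and log-scale
#' expression with a planted 1-pooled-SD shift on 20 of the 28 packaged
#' immune-cell sets in the low/intermediate group.
#'
#' @param seed integer seed (mandatory); every random draw in the generator
#'   flows from it through per-component sub-streams.
#' @param n_samples cohort size (default 385).
#' @param variant_mean,variant_size negative-binomial mean and size of the
#'   per-sample variant count (default mean 63, size 10).
#' @param depth_mean Poisson mean sequencing depth (default 150).
#' @param purity_range uniform tumor-purity interval (default 0.4-0.9).
#' @param subclone_range integer range of subclone counts per tumor
#'   (default 1-3).
#' @param theta subclonal dispersion: subclone cancer-cell fractions are
#'   `1 - Exp(mean = theta)` truncated to [0.05, 1]; `theta = 0` makes every
#'   variant clonal so MATH reflects read-sampling noise only (default 0.1).
#' @param clonal_fraction probability a variant is clonal (default 0.6).
#' @param weibull_shape,weibull_scale baseline event-time distribution
#'   (default shape 1.2, scale 36 months).
#' @param group_hr hazard ratio per MATH-tertile step (default 1.433).
#' @param censoring target fraction of censored observations (default 0.5).
#' @param chemo_fraction probability a sample carries the adjuvant
#'   chemotherapy flag (default 0.444, i.e. 171/385).
#' @param n_genes expression matrix size (default 1000; set-member genes are
#'   always included).
#' @param delta planted expression shift in pooled-SD units (default 1).
#' @param shifted_sets names of sets receiving the shift (default
#'   [default_shifted_sets]).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_samples = 385,
                             variant_mean = 63, variant_size = 10,
                             depth_mean = 150,
                             purity_range = c(0.4, 0.9),
                             subclone_range = c(1, 3),
                             theta = 0.1,
                             clonal_fraction = 0.6,
                             weibull_shape = 1.2, weibull_scale = 36,
                             group_hr = 1.433,
                             censoring = 0.5,
                             chemo_fraction = 0.444,
                             n_genes = 1000,
                             delta = 1,
                             shifted_sets = default_shifted_sets) {
  if (missing(seed)) stop("synthetic_config: a seed is mandatory")
  stopifnot(n_samples >= 1, variant_mean > 0, variant_size > 0,
            depth_mean > 0, theta >= 0,
            length(purity_range) == 2, purity_range[1] >= 0,
            purity_range[2] <= 1, purity_range[1] <= purity_range[2],
            subclone_range[1] >= 1, subclone_range[1] <= subclone_range[2],
            clonal_fraction >= 0, clonal_fraction <= 1,
            weibull_shape > 0, weibull_scale > 0, group_hr > 0,
            censoring >= 0, censoring < 1,
            chemo_fraction >= 0, chemo_fraction <= 1,
            n_genes >= 1, delta >= 0)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 variant_mean = variant_mean, variant_size = variant_size,
                 depth_mean = depth_mean, purity_range = purity_range,
                 subclone_range = as.integer(subclone_range), theta = theta,
                 clonal_fraction = clonal_fraction,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 group_hr = group_hr, censoring = censoring,
                 chemo_fraction = chemo_fraction,
                 n_genes = as.integer(n_genes), delta = delta,
                 shifted_sets = shifted_sets),
            class = "synthetic_config")
}

# per-component sub-seeds derived from the master seed, so each simulate_*
# call is reproducible on its own. Restores the caller's RNG state.
.sub_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  sample.int(2147483000L, 4)
}

# default mutated-gene pool: recurrently mutated gastric-cancer genes get
# the largest weights, a zipf tail of background genes the rest.
.default_gene_pool <- function() {
  top <- c("TTN", "TP53", "MUC16", "LRP1B", "FAT4", "CSMD1", "SYNE1",
           "OBSCN", "FLG", "PIK3CA")
  bg <- sprintf("GENE%04d", seq_len(400))
  w <- c(seq(12, 3, length.out = length(top)), 1 / seq_along(bg)^0.5)
  list(genes = c(top, bg), weights = w / sum(w))
}

.classification_probs <- c(
  Missense_Mutation = 0.55, Silent = 0.14, Nonsense_Mutation = 0.05,
  Frame_Shift_Del = 0.05, Frame_Shift_Ins = 0.04, Splice_Site = 0.05,
  In_Frame_Del = 0.03, In_Frame_Ins = 0.02, Nonstop_Mutation = 0.01,
  "3'UTR" = 0.03, Intron = 0.03
)

#' Simulate a somatic-mutation cohort (MAF) with known ground truth
#'
#' Per sample: purity is uniform on the configured range; the tumor carries
#' one clonal population (cancer-cell fraction 1) plus subclones whose CCFs
#' spread below 1 by an exponential amount with mean `theta`. Each variant
#' is clonal with probability `clonal_fraction`, otherwise assigned to a
#' random subclone; its true allele fraction is `purity * CCF / 2` (diploid
#' heterozygous variants, no copy-number events so the ground truth stays
#' clean). Read depth is Poisson (zero draws are redrawn and counted) and
#' alt reads binomial at the true VAF.
#'
#' @param config a [synthetic_config()].
#' @param gene_pool optional list(genes, weights) for mutated-gene labels.
#' @return list: `maf` (a `maf_table`), `truth` (per-sample purity and
#'   subclone CCFs, theta, redraw count).
#' @export
simulate_maf <- function(config, gene_pool = .default_gene_pool()) {
  sub <- .sub_seeds(config$seed)
  set.seed(sub[1])
  n <- config$n_samples
  ids <- sprintf("SYN%04d", seq_len(n))
  truth_samples <- vector("list", n)
  names(truth_samples) <- ids
  rows <- vector("list", n)
  n_redrawn <- 0L
  for (i in seq_len(n)) {
    nv <- max(1L, stats::rnbinom(1, size = config$variant_size,
                                 mu = config$variant_mean))
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    nsub <- sample(seq(config$subclone_range[1], config$subclone_range[2]), 1)
    ccf_sub <- if (config$theta > 0) {
      pmin(1, pmax(0.05, 1 - stats::rexp(nsub, rate = 1 / config$theta)))
    } else rep(1, nsub)
    clonal <- stats::runif(nv) < config$clonal_fraction
    clone_of <- ifelse(clonal, 0L, sample.int(nsub, nv, replace = TRUE))
    ccf <- ifelse(clone_of == 0L, 1, ccf_sub[pmax(clone_of, 1L)])
    true_vaf <- purity * ccf / 2
    depth <- stats::rpois(nv, config$depth_mean)
    while (any(depth == 0L)) {
      z <- depth == 0L
      n_redrawn <- n_redrawn + sum(z)
      depth[z] <- stats::rpois(sum(z), config$depth_mean)
    }
    alt <- stats::rbinom(nv, depth, true_vaf)
    rows[[i]] <- data.frame(
      sample_id = ids[i],
      gene = sample(gene_pool$genes, nv, replace = TRUE,
                    prob = gene_pool$weights),
      chromosome = sample(c(as.character(1:22), "X"), nv, replace = TRUE),
      start_position = sample.int(2e8, nv, replace = TRUE),
      variant_classification = sample(names(.classification_probs), nv,
                                      replace = TRUE,
                                      prob = .classification_probs),
      t_ref_count = depth - alt,
      t_alt_count = alt,
      vaf = ifelse(depth > 0, alt / depth, NA_real_),
      stringsAsFactors = FALSE)
    truth_samples[[i]] <- list(purity = purity, subclone_ccf = ccf_sub)
  }
  maf <- do.call(rbind, rows)
  rownames(maf) <- NULL
  maf <- structure(maf, source = "synthetic", dialect = maf_dialect(),
                   n_flagged = 0L, n_skipped = 0L,
                   class = c("maf_table", "data.frame"))
  list(maf = maf,
       truth = list(theta = config$theta, n_depth_redrawn = n_redrawn,
                    samples = truth_samples))
}

#' Simulate survival and clinical covariates for given MATH groups
#'
#' Event times are Weibull under proportional hazards with one log-hazard
#' step `log(group_hr)` per tertile (low = 0, intermediate = 1, high = 2).
#' Censoring times are uniform on (0, u) with u calibrated to the target
#' censoring fraction (independent of covariates, keeping the Cox recovery
#' assumptions clean). Clinical covariates are drawn with level frequencies
#' matching a surgically treated gastric-cancer cohort, independently of
#' survival.
#'
#' @param config a [synthetic_config()].
#' @param math_groups named factor (names = sample ids) with levels
#'   low/intermediate/high.
#' @return clinical data.frame: `sample_id`, `os_time`, `os_event`,
#'   `age_group`, `sex`, `stage`, `grade`, `radiation`, `histology`,
#'   `adjuvant_chemo`; `attr(, "truth")` records the true log-hazard step
#'   and the achieved censoring fraction.
#' @export
simulate_survival <- function(config, math_groups) {
  sub <- .sub_seeds(config$seed)
  set.seed(sub[2])
  n <- length(math_groups)
  code <- c(low = 0, intermediate = 1, high = 2)[as.character(math_groups)]
  beta <- log(config$group_hr)
  E <- stats::rexp(n)
  T_event <- config$weibull_scale *
    (E / exp(beta * code))^(1 / config$weibull_shape)
  U <- stats::runif(n)
  target <- config$censoring
  if (target > 0) {
    f <- function(u) mean(u * U < T_event) - target
    u_star <- stats::uniroot(f, lower = 1e-9, upper = 1e9 * max(T_event),
                             tol = 1e-10)$root
    C <- u_star * U
  } else {
    C <- rep(Inf, n)
  }
  os_event <- as.integer(T_event <= C)
  achieved <- 1 - mean(os_event)
  if (abs(achieved - target) > 0.05) {
    warning(sprintf("censoring target %.2f not attained; achieved %.3f",
                    target, achieved))
  }
  draw <- function(levels, probs) {
    sample(levels, n, replace = TRUE, prob = probs)
  }
  clin <- data.frame(
    sample_id = names(math_groups),
    os_time = pmin(T_event, C),
    os_event = os_event,
    age_group = draw(c(">=60", "<60"), c(0.688, 0.312)),
    sex = draw(c("Male", "Female"), c(0.655, 0.345)),
    stage = draw(c("I", "II", "III", "IV", NA), c(0.127, 0.317, 0.421, 0.094, 0.041)),
    grade = draw(c("Gx", "G1", "G2", "G3"), c(0.023, 0.026, 0.374, 0.577)),
    radiation = draw(c("Yes", "No", NA), c(0.114, 0.405, 0.481)),
    histology = draw(c("Diffuse", "Intestinal", "SignetRing", NA),
                     c(0.138, 0.478, 0.031, 0.353)),
    adjuvant_chemo = stats::rbinom(n, 1, config$chemo_fraction),
    stringsAsFactors = FALSE)
  structure(clin, truth = list(log_hr_per_step = beta,
                               achieved_censoring = achieved))
}

#' Simulate a log-scale expression matrix with planted gene-set shifts
#'
#' Baseline expression is Gaussian on the log scale (per-gene mean ~ N(6,1),
#' within-gene noise SD 1, so a shift of `delta` is `delta` pooled SDs).
#' Every gene of a shifted set gains `+delta` in the low/intermediate-group
#' samples; genes in several shifted sets accumulate the shifts (warned).
#' All set-member genes are always included; background genes pad the
#' matrix to `n_genes`.
#'
#' @param config a [synthetic_config()].
#' @param math_groups named factor as in [simulate_survival()].
#' @param sets a `gene_set_collection`; `config$shifted_sets` must be a
#'   subset of its names.
#' @return genes x samples matrix; `attr(, "truth")` records shifted sets
#'   and delta.
#' @export
simulate_expression <- function(config, math_groups, sets) {
  sub <- .sub_seeds(config$seed)
  set.seed(sub[3])
  shifted <- config$shifted_sets
  if (!all(shifted %in% names(sets))) {
    stop("shifted_sets not in the collection: ",
         paste(setdiff(shifted, names(sets)), collapse = ", "))
  }
  set_genes <- unique(unlist(sets))
  n_bg <- max(0L, config$n_genes - length(set_genes))
  genes <- c(set_genes, sprintf("BG%05d", seq_len(n_bg)))
  G <- length(genes)
  n <- length(math_groups)
  mu <- stats::rnorm(G, 6, 1)
  X <- mu + matrix(stats::rnorm(G * n), G, n)
  dimnames(X) <- list(genes, names(math_groups))
  shift_count <- table(unlist(sets[shifted]))
  if (any(shift_count > 1)) {
    warning("gene(s) in multiple shifted sets; shifts add: ",
            paste(utils::head(names(shift_count)[shift_count > 1], 5),
                  collapse = ", "))
  }
  low_int <- math_groups != "high"
  if (config$delta > 0 && any(low_int) && length(shifted)) {
    idx <- match(names(shift_count), genes)
    X[idx, low_int] <- X[idx, low_int] +
      config$delta * as.numeric(shift_count)
  }
  structure(X, truth = list(shifted_sets = shifted, delta = config$delta))
}

#' Simulate a complete cohort: mutations, MATH groups, survival, expression
#'
#' Convenience wrapper running the full generator: MAF, per-sample VAF
#' profiles, MATH scores, tertile groups, clinical/survival table, and an
#' expression matrix with the configured planted shifts.
#'
#' @param config a [synthetic_config()].
#' @param sets gene sets for the expression generator (default the packaged
#'   28 immune-cell sets).
#' @param vaf_max,min_variants MATH filtering settings (defaults 0.75, 5).
#' @return list: `maf`, `math_table` (with `math_group`), `clinical`,
#'   `expression`, `truth`.
#' @export
simulate_cohort <- function(config, sets = immune_cell_sets(),
                            vaf_max = 0.75, min_variants = 5) {
  sim <- simulate_maf(config)
  prof <- vaf_profiles(sim$maf, vaf_max = vaf_max)
  mt <- cohort_math(prof, min_variants = min_variants)
  mt <- assign_tertiles(mt)
  groups <- stats::setNames(mt$math_group, mt$sample_id)
  groups <- groups[!is.na(groups)]
  clinical <- simulate_survival(config, groups)
  expression <- simulate_expression(config, groups, sets)
  list(maf = sim$maf, math_table = mt, clinical = clinical,
       expression = expression,
       truth = list(maf = sim$truth,
                    survival = attr(clinical, "truth"),
                    expression = attr(expression, "truth")))
}
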