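#' Build a pipeline run configuration
#'
#' Exactly one data source: a synthetic generator config, or input file
#' paths (MAF + clinical required; expression and GMT optional — stages
#' without their inputs are skipped with a logged notice).
#'
#' @param seed master seed for every stochastic stage (mandatory). When a
#'   synthetic config is supplied its seed is overridden by this one, so a
#'   single integer reproduces the whole run.
#' @param outdir output directory.
#' @param synthetic optional [synthetic_config()].
#' @param maf,clinical,expression,gmt optional input paths (tab-delimited;
#'   clinical needs `sample_id`, `os_time`, `os_event` columns; expression
#'   is genes x samples with the gene symbol in the first column).
#' @param include,vaf_max,min_variants variant filtering and MATH QC.
#' @param n_perm,weight_p GSEA settings.
#' @param ssgsea_alpha,mw_continuity immune-scoring settings.
#' @param tie_method Cox tie handling.
#' @param top_k co-occurrence scan size.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, outdir, synthetic = NULL,
                       maf = NULL, clinical = NULL, expression = NULL,
                       gmt = NULL,
                       include = NULL, vaf_max = 0.75, min_variants = 5,
                       n_perm = 1000, weight_p = 1,
                       ssgsea_alpha = 0.25, mw_continuity = FALSE,
                       tie_method = "efron", top_k = 25) {
  if (missing(seed)) stop("run_config: a seed is mandatory")
  has_files <- !is.null(maf) || !is.null(clinical)
  if (is.null(synthetic) == !has_files) {
    stop("supply exactly one of: a synthetic config, or maf+clinical paths")
  }
  if (has_files && (is.null(maf) || is.null(clinical))) {
    stop("file input needs both maf and clinical paths")
  }
  if (!is.null(synthetic)) synthetic$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 synthetic = synthetic, maf = maf, clinical = clinical,
                 expression = expression, gmt = gmt,
                 include = include, vaf_max = vaf_max,
                 min_variants = min_variants, n_perm = n_perm,
                 weight_p = weight_p, ssgsea_alpha = ssgsea_alpha,
                 mw_continuity = mw_continuity, tie_method = tie_method,
                 top_k = top_k),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

.stage <- function(name, code) {
  message("[stage] ", name)
  tryCatch(code, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full heterogeneity-prognosis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' input), per-sample MATH scoring, tertile stratification with the
#' baseline-characteristics table (full cohort and, when an adjuvant
#' chemotherapy flag is present, the chemotherapy subset with its own
#' re-derived tertiles), Kaplan-Meier / log-rank / multivariate Cox
#' survival analysis, GSEA between the high and low/intermediate groups,
#' single-sample immune-cell scoring with group comparison and per-cell-type
#' Cox fits, and somatic-mutation summaries with the pairwise co-occurrence
#' scan. Every table is written as TSV under `config$outdir` and listed in
#' `manifest.json` together with its MD5 and the config hash, so a rerun
#' with the same seed can be verified byte-for-byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_all <- function(config) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  # ---- data ----
  dat <- .stage("data", {
    if (!is.null(config$synthetic)) {
      sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else immune_cell_sets()
      cohort <- simulate_cohort(config$synthetic, sets = sets,
                                vaf_max = config$vaf_max,
                                min_variants = config$min_variants)
      add(write_maf(cohort$maf, file.path(out, "maf.tsv")))
      add(.write_tsv(cohort$clinical, file.path(out, "clinical.tsv")))
      expr_df <- data.frame(gene = rownames(cohort$expression),
                            cohort$expression, check.names = FALSE,
                            stringsAsFactors = FALSE)
      add(.write_tsv(expr_df, file.path(out, "expression.tsv")))
      jsonlite::write_json(
        list(theta = cohort$truth$maf$theta,
             log_hr_per_step = cohort$truth$survival$log_hr_per_step,
             achieved_censoring = cohort$truth$survival$achieved_censoring,
             shifted_sets = cohort$truth$expression$shifted_sets,
             delta = cohort$truth$expression$delta),
        file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
      add(file.path(out, "ground_truth.json"))
      list(maf = cohort$maf, clinical = cohort$clinical,
           expression = cohort$expression, sets = sets,
           math_table = cohort$math_table)
    } else {
      maf <- read_maf(config$maf)
      clinical <- utils::read.delim(config$clinical, sep = "\t",
                                    stringsAsFactors = FALSE)
      expression <- NULL
      if (!is.null(config$expression)) {
        e <- utils::read.delim(config$expression, sep = "\t",
                               check.names = FALSE, stringsAsFactors = FALSE)
        expression <- as.matrix(e[, -1, drop = FALSE])
        rownames(expression) <- e[[1]]
      }
      sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else immune_cell_sets()
      list(maf = maf, clinical = clinical, expression = expression,
           sets = sets, math_table = NULL)
    }
  })

  # ---- MATH ----
  math_table <- .stage("math", {
    mt <- if (!is.null(dat$math_table)) dat$math_table else {
      assign_tertiles(cohort_math(
        vaf_profiles(dat$maf, include = config$include,
                     vaf_max = config$vaf_max),
        min_variants = config$min_variants))
    }
    add(.write_tsv(mt, file.path(out, "math_table.tsv")))
    smry <- attr(mt, "summary")
    med <- attr(mt, "group_medians")
    add(.write_tsv(data.frame(
      statistic = c("cohort_median", "cohort_min", "cohort_max",
                    paste0("median_", names(med))),
      value = c(smry$median, smry$range, as.numeric(med))),
      file.path(out, "math_summary.tsv")))
    mt
  })

  # ---- stratify / baseline ----
  chars <- c("sex", "age_group", "stage", "grade", "radiation",
             "histology", "math_group")
  strat <- .stage("stratify", {
    cohort <- merge(dat$clinical,
                    math_table[, c("sample_id", "n_variants", "math",
                                   "qc_flag", "math_group")],
                    by = "sample_id", sort = TRUE)
    add(.write_tsv(cohort, file.path(out, "cohort.tsv")))
    bl <- baseline_table(cohort, intersect(chars, names(cohort)))
    add(.write_tsv(bl, file.path(out, "baseline_table.tsv")))
    chemo <- NULL
    if ("adjuvant_chemo" %in% names(cohort)) {
      sub_ids <- cohort$sample_id[!is.na(cohort$adjuvant_chemo) &
                                    cohort$adjuvant_chemo == 1]
      if (length(sub_ids) >= 9) {
        # the chemotherapy subset re-derives its own tertiles
        mt_sub <- math_table[math_table$sample_id %in% sub_ids, , drop = FALSE]
        mt_sub$math_group <- NULL
        mt_sub <- assign_tertiles(mt_sub)
        chemo <- merge(dat$clinical[dat$clinical$sample_id %in% sub_ids, ],
                       mt_sub[, c("sample_id", "n_variants", "math",
                                  "qc_flag", "math_group")],
                       by = "sample_id", sort = TRUE)
        add(.write_tsv(chemo, file.path(out, "cohort_chemo.tsv")))
        add(.write_tsv(baseline_table(chemo, intersect(chars, names(chemo))),
                       file.path(out, "baseline_table_chemo.tsv")))
      } else {
        message("[stage] stratify: chemotherapy subset too small; skipped")
      }
    }
    list(cohort = cohort, chemo = chemo)
  })

  # ---- survival ----
  .stage("survival", {
    run_surv <- function(cohort, tag) {
      cc <- cohort[!is.na(cohort$math_group), , drop = FALSE]
      km <- lapply(levels(factor(cc$math_group)), function(g) {
        sub <- cc[cc$math_group == g, ]
        cv <- km_estimate(sub$os_time, sub$os_event)
        if (nrow(cv)) cbind(group = g, cv) else NULL
      })
      km <- do.call(rbind, km)
      if (!is.null(km)) add(.write_tsv(km, file.path(out, paste0("km_", tag, ".tsv"))))
      lr <- logrank_test(cc$os_time, cc$os_event, cc$math_group)
      add(.write_tsv(data.frame(chi_square = lr$chi_square, df = lr$df,
                                p_value = lr$p_value),
                     file.path(out, paste0("logrank_", tag, ".tsv"))))
      X <- encode_clinical(cc)
      fit <- cox_fit(cc$os_time, cc$os_event, X,
                     tie_method = config$tie_method)
      tab <- fit$table
      tab$converged <- fit$converged
      tab$flag <- fit$flag
      add(.write_tsv(tab, file.path(out, paste0("cox_", tag, ".tsv"))))
      invisible(NULL)
    }
    run_surv(strat$cohort, "full")
    if (!is.null(strat$chemo)) run_surv(strat$chemo, "chemo")
  })

  # analysis cohort for the expression stages: the chemotherapy subset when
  # present, otherwise the full cohort
  expr_cohort <- if (!is.null(strat$chemo)) strat$chemo else strat$cohort

  # ---- enrichment ----
  gsea <- NULL
  if (is.null(dat$expression)) {
    message("[stage] enrichment skipped: no expression data")
  } else {
    gsea <- .stage("enrichment", {
      cc <- expr_cohort[!is.na(expr_cohort$math_group), ]
      ids <- intersect(colnames(dat$expression), cc$sample_id)
      ph <- ifelse(cc$math_group[match(ids, cc$sample_id)] == "high",
                   "high", "low_intermediate")
      ph <- factor(ph, levels = c("low_intermediate", "high"))
      res <- gsea_significance(dat$expression[, ids, drop = FALSE], ph,
                               dat$sets, n_perm = config$n_perm,
                               seed = config$seed + 7L,
                               weight_p = config$weight_p)
      add(.write_tsv(res, file.path(out, "gsea_results.tsv")))
      res
    })
  }

  # ---- immune ----
  immune <- NULL
  if (is.null(dat$expression)) {
    message("[stage] immune skipped: no expression data")
  } else {
    immune <- .stage("immune", {
      cc <- expr_cohort[!is.na(expr_cohort$math_group), ]
      ids <- intersect(colnames(dat$expression), cc$sample_id)
      scores <- ssgsea_matrix(dat$expression[, ids, drop = FALSE],
                              dat$sets, alpha = config$ssgsea_alpha)
      sc_df <- data.frame(cell_type = rownames(scores), scores,
                          check.names = FALSE, stringsAsFactors = FALSE)
      add(.write_tsv(sc_df, file.path(out, "immune_scores.tsv")))
      grp <- as.character(cc$math_group[match(ids, cc$sample_id)])
      diff <- immune_diff_table(scores, grp,
                                continuity = config$mw_continuity)
      add(.write_tsv(diff, file.path(out, "immune_diff.tsv")))
      icox <- per_celltype_cox(scores, cc, tie_method = config$tie_method)
      add(.write_tsv(icox, file.path(out, "immune_cox.tsv")))
      list(scores = scores, diff = diff, cox = icox)
    })
  }

  # ---- mutation summary ----
  mut <- .stage("mutsummary", {
    maf <- dat$maf
    if (!is.null(strat$chemo)) {
      maf <- maf[maf$sample_id %in% strat$chemo$sample_id, , drop = FALSE]
      class(maf) <- c("maf_table", "data.frame")
    }
    s <- summarize_maf(maf)
    add(.write_tsv(data.frame(classification = names(s$classification_counts),
                              n = s$classification_counts),
                   file.path(out, "classification_counts.tsv")))
    add(.write_tsv(s$sample_load, file.path(out, "sample_load.tsv")))
    add(.write_tsv(s$gene_ranking, file.path(out, "gene_ranking.tsv")))
    gm <- gene_sample_matrix(maf)
    scan <- cooccurrence_scan(gm, top_k = min(config$top_k, nrow(gm)))
    add(.write_tsv(scan, file.path(out, "cooccurrence.tsv")))
    list(summary = s, scan = scan)
  })

  # ---- manifest ----
  .stage("manifest", {
    cfg <- config
    cfg$outdir <- NULL          # not part of the scientific configuration
    cfg$synthetic <- unclass(cfg$synthetic)
    cfg_path <- file.path(out, "config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    manifest <- list(
      config_hash = unname(tools::md5sum(cfg_path)),
      outputs = lapply(sort(unique(files)), function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      }))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(outdir = out, files = sort(unique(files)),
                 math_table = math_table, cohort = strat$cohort,
                 chemo = strat$chemo, gsea = gsea, immune = immune,
                 mutsummary = mut))
}
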