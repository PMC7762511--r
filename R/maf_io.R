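#' Default MAF column dialect
#'
#' Maps the canonical internal field names onto the column headers found in
#' the file. The defaults are the TCGA MAF conventions; count-column names
#' vary between callers, so the mapping is user-overridable.
#'
#' @param ... named overrides, e.g. `t_ref_count = "ref_reads"`.
#' @return named character vector: internal field -> file column name.
#' @export
maf_dialect <- function(...) {
  d <- c(
    sample_id              = "Tumor_Sample_Barcode",
    gene                   = "Hugo_Symbol",
    chromosome             = "Chromosome",
    start_position         = "Start_Position",
    variant_classification = "Variant_Classification",
    t_ref_count            = "t_ref_count",
    t_alt_count            = "t_alt_count"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

# columns that must be present in any MAF we accept
.maf_required <- c("gene", "sample_id", "variant_classification")

#' Read a Mutation Annotation Format (MAF) file
#'
#' Tab-delimited with a header row; lines starting with `#` (e.g.
#' `#version 2.4`) are skipped. Each data row becomes one variant record
#' with a derived variant allele fraction
#' VAF = t_alt_count / (t_alt_count + t_ref_count).
#' Rows whose read counts are absent or unparseable keep `vaf = NA` and are
#' counted in `attr(, "n_flagged")`; rows with an empty gene or sample
#' barcode are dropped and counted in `attr(, "n_skipped")`.
#'
#' @param path path to a tab-delimited MAF file.
#' @param dialect column mapping from [maf_dialect()].
#' @return a `maf_table`: data.frame with columns `sample_id`, `gene`,
#'   `chromosome`, `start_position`, `variant_classification`,
#'   `t_ref_count`, `t_alt_count`, `vaf` (input row order preserved).
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           quote = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  for (f in .maf_required) {
    if (!dialect[[f]] %in% names(raw)) {
      stop("MAF is missing required column '", dialect[[f]], "'")
    }
  }
  pick <- function(f, default = NA_character_) {
    col <- dialect[[f]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  maf <- data.frame(
    sample_id              = pick("sample_id"),
    gene                   = pick("gene"),
    chromosome             = pick("chromosome"),
    start_position         = num(pick("start_position")),
    variant_classification = pick("variant_classification"),
    t_ref_count            = num(pick("t_ref_count")),
    t_alt_count            = num(pick("t_alt_count")),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(maf$sample_id) & nzchar(maf$sample_id) &
        !is.na(maf$gene) & nzchar(maf$gene)
  n_skipped <- sum(!ok)
  maf <- maf[ok, , drop = FALSE]

  tot <- maf$t_ref_count + maf$t_alt_count
  maf$vaf <- ifelse(!is.na(tot) & tot > 0, maf$t_alt_count / tot, NA_real_)
  n_flagged <- sum(is.na(maf$vaf))
  rownames(maf) <- NULL

  structure(maf,
            source = path, dialect = dialect,
            n_flagged = n_flagged, n_skipped = n_skipped,
            class = c("maf_table", "data.frame"))
}

#' Write a `maf_table` back to a MAF file
#'
#' Columns are emitted under the dialect's file names; re-reading the file
#' with [read_maf()] reproduces the records.
#'
#' @param maf a `maf_table`.
#' @param path output path.
#' @param dialect column mapping used for the header names.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path, dialect = maf_dialect()) {
  out <- maf[, names(dialect), drop = FALSE]
  names(out) <- unname(dialect[names(out)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Per-sample VAF profiles
#'
#' Groups retained variant allele fractions by sample. A variant is retained
#' when its classification is in `include` (NULL = all classifications), its
#' VAF is present, and `vaf <= vaf_max`. The upper trim damps allele
#' fractions inflated by copy-number gain or loss of heterozygosity.
#' Samples present in the table but with no retained variant appear as
#' zero-length vectors, so downstream QC can flag rather than lose them.
#'
#' @param maf a `maf_table`.
#' @param include character vector of classifications to keep, or NULL for
#'   all. An explicitly empty include-list is an error.
#' @param vaf_max upper VAF trim (default 0.75).
#' @return named list, sample_id -> numeric vector of VAFs (input order).
#' @export
vaf_profiles <- function(maf, include = NULL, vaf_max = 0.75) {
  if (nrow(maf) == 0L) stop("empty MAF table")
  if (!is.null(include) && length(include) == 0L) {
    stop("classification include-list must be NULL (all) or non-empty")
  }
  keep <- !is.na(maf$vaf) & maf$vaf <= vaf_max
  if (!is.null(include)) keep <- keep & maf$variant_classification %in% include
  samples <- unique(maf$sample_id)
  kept <- maf[keep, c("sample_id", "vaf"), drop = FALSE]
  prof <- split(kept$vaf, factor(kept$sample_id, levels = samples))
  structure(lapply(prof, as.numeric), n_retained = nrow(kept))
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then one or more gene symbols,
#' tab-separated. Duplicate symbols within a set are deduplicated (first
#' occurrence kept); duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `description` attribute (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(parts))
  desc <- character(length(parts))
  nm <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    genes <- p[-(1:2)]
    genes <- unique(genes[nzchar(genes)])
    if (length(p) < 3L || length(genes) == 0L) {
      stop("GMT line ", i, " ('", p[1], "') lists no genes")
    }
    nm[i] <- p[1]
    desc[i] <- if (length(p) >= 2) p[2] else ""
    sets[[i]] <- genes
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (or `gene_set_collection`).
#' @param path output path.
#' @param description optional named descriptions; defaults to the
#'   collection's own, else the set name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = attr(sets, "description")) {
  nm <- names(sets)
  if (is.null(description)) description <- stats::setNames(nm, nm)
  lines <- vapply(nm, function(s) {
    paste(c(s, description[[s]], sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged 28 immune-cell gene sets (synthetic membership)
#'
#' Set names are 28 immune cell types; the gene memberships are synthetic
#' placeholders shipped so the single-sample scoring and group-comparison
#' machinery is runnable and testable end to end. For real analyses supply
#' your own GMT of published immune-cell signatures via [read_gmt()].
#'
#' @return a `gene_set_collection` of 28 sets.
#' @export
immune_cell_sets <- function() {
  read_gmt(system.file("extdata", "immune28_synthetic.gmt",
                       package = "mathsurv", mustWork = TRUE))
}
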