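.PHENO_NUMERIC <- c("age", "full_iq", "mean_fd", "ados_comm",
                    "ados_social", "ados_rrb", "ados_total")

#' Load a phenotype table
#'
#' Reads a comma-separated phenotype file with one row per subject.
#' Mandatory columns: `subject_id`, `site`, `diagnosis`.  Numeric
#' columns (`age`, `full_iq`, `mean_fd`, the three ADOS subscales and
#' `ados_total`) are parsed with empty cells becoming `NA`.  Row order
#' is preserved.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame with typed columns.
#' @export
loadPhenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  mandatory <- c("subject_id", "site", "diagnosis")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("duplicated subject_id: ", paste(dup, collapse = ", "))
  for (nm in intersect(.PHENO_NUMERIC, names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Recompute the ADOS total score
#'
#' The total is defined as Communication + Social Interaction, the
#' instrument's recommended diagnostic total; the Restricted/Stereotyped
#' Behaviors subscale never enters.  The total is missing whenever
#' either constituent subscale is missing.
#'
#' @param comm,social ADOS Communication and Social Interaction
#'   subscale scores (non-negative, may be `NA`); vectorized.
#' @return numeric vector of totals with `NA` where undefined.
#' @export
computeAdosTotal <- function(comm, social) {
  if (any(comm < 0, na.rm = TRUE) || any(social < 0, na.rm = TRUE))
    stop("ADOS subscale scores cannot be negative")
  comm + social
}

#' Apply the cohort inclusion filters
#'
#' Sets a `group_assignment` column on a phenotype table following the
#' study inclusion rules, applied in this order:
#' \enumerate{
#'   \item individual bounds: `full_iq >= iq_min`, `mean_fd <=
#'     fd_threshold`, `age` within `age_range` (all rows);
#'   \item ASD severity: recomputed `ados_total > ados_min_exclusive`
#'     (strict), applied only to ASD rows with a defined total; ASD rows
#'     with no total at all are excluded;
#'   \item site size: ASD rows surviving the individual rules are kept
#'     only from sites with at least `min_asd_per_site` surviving ASD
#'     subjects;
#'   \item grouping: surviving ASD rows with all three subscales present
#'     become `discovery`; those with a total but at least one subscale
#'     missing become `validation`; controls are kept (as `control`)
#'     only from sites contributing discovery subjects.
#' }
#' When `cfg$validation_site_disjoint` is `TRUE` (default) validation
#' subjects are additionally required to come from sites contributing
#' neither discovery nor control subjects.
#'
#' @param pheno phenotype data.frame from [loadPhenotypes()].
#' @param cfg pipeline configuration, see [pipelineConfig()].
#' @return the table with `group_assignment` in
#'   `{discovery, validation, control, excluded}` and an attached
#'   `"filter_report"` attribute counting removals per rule.
#' @export
applyInclusionFilters <- function(pheno, cfg = pipelineConfig()) {
  n <- nrow(pheno)
  pheno$ados_total <- computeAdosTotal(pheno$ados_comm, pheno$ados_social)
  asd <- pheno$diagnosis == "ASD"
  report <- c()

  ok_iq <- !is.na(pheno$full_iq) & pheno$full_iq >= cfg$iq_min
  ok_fd <- !is.na(pheno$mean_fd) & pheno$mean_fd <= cfg$fd_threshold
  ok_age <- !is.na(pheno$age) & pheno$age >= cfg$age_range[1] &
    pheno$age <= cfg$age_range[2]
  report["iq"] <- sum(!ok_iq)
  report["fd"] <- sum(ok_iq & !ok_fd)
  report["age"] <- sum(ok_iq & ok_fd & !ok_age)
  keep <- ok_iq & ok_fd & ok_age

  # ADOS severity: strict "> threshold", ASD only
  ok_ados <- !asd | (!is.na(pheno$ados_total) &
                     pheno$ados_total > cfg$ados_min_exclusive)
  report["ados"] <- sum(keep & !ok_ados)
  keep <- keep & ok_ados

  # site rule after the individual rules
  asd_by_site <- table(pheno$site[keep & asd])
  small <- names(asd_by_site)[asd_by_site < cfg$min_asd_per_site]
  drop_site <- keep & asd & pheno$site %in% small
  report["site"] <- sum(drop_site)
  keep <- keep & !drop_site

  assign <- rep("excluded", n)
  subsc <- cbind(pheno$ados_comm, pheno$ados_social, pheno$ados_rrb)
  complete <- stats::complete.cases(subsc)
  assign[keep & asd & complete] <- "discovery"
  assign[keep & asd & !complete & !is.na(pheno$ados_total)] <- "validation"

  disc_sites <- unique(pheno$site[assign == "discovery"])
  is_ctrl <- keep & !asd
  report["control_site"] <- sum(is_ctrl & !pheno$site %in% disc_sites)
  assign[is_ctrl & pheno$site %in% disc_sites] <- "control"

  if (isTRUE(cfg$validation_site_disjoint)) {
    used <- unique(pheno$site[assign %in% c("discovery", "control")])
    bad <- assign == "validation" & pheno$site %in% used
    report["validation_site_overlap"] <- sum(bad)
    assign[bad] <- "excluded"
  }

  pheno$group_assignment <- assign
  for (g in c("discovery", "validation", "control"))
    if (!any(assign == g))
      warning("empty ", g, " group after filtering")
  attr(pheno, "filter_report") <- report
  pheno
}

#' Pipeline configuration
#'
#' Collects every tunable of the stratification/prediction pipeline
#' with the study defaults.  All thresholds must be strictly positive
#' and `cutoff_range` a contiguous integer interval.
#'
#' @param ... overrides of the defaults listed below.
#' @return a validated named list of class `fcstrat_config`.
#' @section Defaults:
#' \describe{
#'   \item{screening_p_threshold 0.005}{Spearman screening p cut.}
#'   \item{screening_k 100}{top-k size for permutation re-screens (and
#'     for the observed screen under `screening_mode = "top_k"`).}
#'   \item{screening_mode "threshold"}{observed-data screening rule;
#'     `"top_k"` fixes the feature-to-sample ratio instead.}
#'   \item{n_permutations 10000}{whole-pipeline permutation count.}
#'   \item{fdr_q 0.05}{BH-FDR level.}
#'   \item{cutoff_range 9:17}{ADOS cutoffs for the agreement sweep.}
#'   \item{n_folds 10}{cross-validation folds.}
#'   \item{prediction_feature_cap 20}{edges entering the SVM.}
#'   \item{fd_threshold 0.5}{mean framewise displacement cap (mm).}
#'   \item{age_range c(6, 30)}{age window (years).}
#'   \item{iq_min 70}{full-IQ floor.}
#'   \item{ados_min_exclusive 7}{ASD kept only with total > 7.}
#'   \item{min_asd_per_site 3}{minimum surviving ASD subjects per site.}
#'   \item{svm_mode "classification"}{or `"regression"`.}
#'   \item{standardize_mode "within_subject"}{see
#'     [standardizeSubjects()].}
#'   \item{cca_on_residualized TRUE}{feed residualized values to CCA.}
#'   \item{validation_site_disjoint TRUE}{see
#'     [applyInclusionFilters()].}
#'   \item{components_for_clustering "significant"}{or `"all"`.}
#'   \item{rng_seed 1}{base seed.}
#' }
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    screening_p_threshold = 0.005, screening_k = 100,
    n_permutations = 10000, rng_seed = 1,
    fdr_q = 0.05, cutoff_range = 9:17,
    n_folds = 10, prediction_feature_cap = 20,
    fd_threshold = 0.5, age_range = c(6, 30), iq_min = 70,
    ados_min_exclusive = 7, min_asd_per_site = 3,
    svm_mode = "classification",
    screening_mode = "threshold",
    standardize_mode = "within_subject",
    cca_on_residualized = TRUE,
    validation_site_disjoint = TRUE,
    components_for_clustering = "significant"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validateConfig(cfg)
}

#' @rdname pipelineConfig
#' @param cfg a configuration list to validate.
#' @export
validateConfig <- function(cfg) {
  pos <- c("screening_p_threshold", "screening_k", "n_permutations",
           "fdr_q", "n_folds", "prediction_feature_cap", "fd_threshold",
           "iq_min", "min_asd_per_site")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("config: ", nm, " must be strictly positive")
  cr <- cfg$cutoff_range
  if (!is.numeric(cr) || any(cr != round(cr)) ||
      !all(diff(sort(cr)) == 1))
    stop("config: cutoff_range must be a contiguous integer interval")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0)
    stop("config: age_range must be an increasing pair")
  if (!cfg$svm_mode %in% c("classification", "regression"))
    stop("config: svm_mode must be classification or regression")
  if (!cfg$screening_mode %in% c("threshold", "top_k"))
    stop("config: screening_mode must be threshold or top_k")
  structure(cfg, class = "fcstrat_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys error, absent keys take the
#' defaults of [pipelineConfig()].
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$age_range)) vals$age_range <- as.numeric(vals$age_range)
  if (!is.null(vals$cutoff_range) && length(vals$cutoff_range) == 2)
    vals$cutoff_range <- seq(vals$cutoff_range[1], vals$cutoff_range[2])
  do.call(pipelineConfig, vals)
}

#' Write an FCExperiment to a TSV file
#'
#' Header = `subject_id` followed by edge labels (`"ROIa--ROIb"`), one
#' row per subject.
#'
#' @param x an [FCExperiment-class].
#' @param path output TSV path.
#' @export
writeFCTable <- function(x, path) {
  m <- fcMatrix(x)
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an FCExperiment from a TSV file
#'
#' @param path TSV written by [writeFCTable()].
#' @param phenotype optional phenotype table matched on `subject_id`.
#' @param stage stage flag of the stored values (default `fisher_z`).
#' @return an [FCExperiment-class].
#' @export
readFCTable <- function(path, phenotype = NULL, stage = "fisher_z") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df$subject_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  labs <- colnames(m)
  parts <- strsplit(labs, "--", fixed = TRUE)
  rois <- unique(unlist(parts))
  idx <- S4Vectors::DataFrame(
    roi_a = match(vapply(parts, `[`, "", 1), rois),
    roi_b = match(vapply(parts, `[`, "", 2), rois),
    label = labs
  )
  if (!is.null(phenotype)) {
    ord <- match(ids, phenotype$subject_id)
    if (anyNA(ord)) stop("FC subjects missing from phenotype table")
    phenotype <- phenotype[ord, , drop = FALSE]
  }
  FCExperiment(m, idx, phenotype, stage = stage)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits `phenotypes.csv`, `fc.tsv` and `ground_truth.json` into
#' `out_dir`; the tables round-trip losslessly through
#' [loadPhenotypes()] and [readFCTable()].
#'
#' @param cohort list from [simulateCohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  pp <- file.path(out_dir, "phenotypes.csv")
  utils::write.csv(phenotypes(cohort$fc), pp, row.names = FALSE, na = "")
  fp <- file.path(out_dir, "fc.tsv")
  writeFCTable(cohort$fc, fp)
  gp <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(cohort$truth, gp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(phenotypes = pp, fc = fp, truth = gp))
}
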