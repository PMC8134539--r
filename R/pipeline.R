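.stage <- function(name, verbose, expr) {
  if (verbose) message("[fcstrat] stage ", name, " ...")
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full stratification and prediction pipeline
#'
#' Executes, in order: cohort simulation (when no data are supplied),
#' inclusion filtering, per-subject standardization, covariate
#' residualization, Spearman screening, CCA with whole-pipeline
#' permutation inference, Ward clustering into severity subgroups,
#' the ADOS-cutoff agreement sweep, subgroup-vs-control biomarker
#' tests with the graded-change composite, and SVM severity
#' prediction with external validation.  Each analysis residualizes
#' covariates on the union of subjects entering that comparison.
#'
#' @param fc an [FCExperiment-class] (stage `raw_r` or `fisher_z`)
#'   with phenotypes in `colData`, or `NULL` to simulate a cohort.
#' @param cfg a [pipelineConfig()].
#' @param seed integer seed governing every random draw of the run.
#' @param simulation a [simParams()] object used when `fc` is `NULL`.
#' @param outDir optional directory; when given, a JSON summary and
#'   TSV tables (agreement curve, biomarker tables, predictions) are
#'   written there.
#' @param verbose log stage progress and counts.
#' @return list with elements `filter_report`, `screen`, `cca`,
#'   `partition`, `agreement`, `biomarkers`, `graded`, `prediction`,
#'   `config`, `seed`, `truth` (simulated runs only).
#' @export
runPipeline <- function(fc = NULL, cfg = pipelineConfig(),
                        seed = cfg$rng_seed, simulation = NULL,
                        outDir = NULL, verbose = TRUE) {
  cfg <- validateConfig(cfg)
  set.seed(seed)
  truth <- NULL
  if (is.null(fc)) {
    if (is.null(simulation)) simulation <- simParams()
    sim <- .stage("simulate", verbose,
                  simulateCohort(simulation, seed = seed))
    fc <- sim$fc; truth <- sim$truth
  }

  ph <- .stage("filter", verbose, {
    p <- applyInclusionFilters(phenotypes(fc), cfg)
    SummarizedExperiment::colData(fc) <- S4Vectors::DataFrame(
      p, row.names = p$subject_id)
    p
  })
  report <- attr(ph, "filter_report")
  if (verbose)
    message("[fcstrat] groups: ",
            paste(names(table(ph$group_assignment)),
                  table(ph$group_assignment), sep = "=", collapse = " "))

  std <- .stage("fc", verbose,
                standardizeSubjects(fc, mode = cfg$standardize_mode))

  covCols <- c("age", "sex", "full_iq", "mean_fd", "site")
  disc <- std[, ph$group_assignment == "discovery"]
  ctrl <- std[, ph$group_assignment == "control"]
  vald <- std[, ph$group_assignment == "validation"]

  discR <- .stage("residualize", verbose, residualizeFC(disc))
  discIn <- if (cfg$cca_on_residualized) discR else disc
  phD <- phenotypes(disc)

  suite <- .stage("screen/cca/cluster", verbose,
                  permutationSuite(discIn, cfg = cfg,
                                   observedMode = cfg$screening_mode))
  part <- suite$partition
  labels <- severityLabels(part)
  if (verbose)
    message("[fcstrat] screened k=", suite$screen$k,
            "; severe n=", sum(labels == "severe"),
            ", mild n=", sum(labels == "mild"))

  agree <- .stage("agree", verbose,
                  cutoffSweep(labels, phD$ados_total,
                              cutoff_range = cfg$cutoff_range))

  bio <- .stage("biomarkers", verbose, {
    dc <- std[, ph$group_assignment %in% c("discovery", "control")]
    dcR <- residualizeFC(dc)
    phDC <- phenotypes(dc)
    isD <- phDC$group_assignment == "discovery"
    lab3 <- ifelse(!isD, "control",
                   as.character(labels)[match(phDC$subject_id,
                                              phD$subject_id)])
    sevT <- groupwiseTests(dcR, which(lab3 == "severe"),
                           which(lab3 == "control"), q = cfg$fdr_q,
                           comparison = "severe_vs_control")
    mldT <- groupwiseTests(dcR, which(lab3 == "mild"),
                           which(lab3 == "control"), q = cfg$fdr_q,
                           comparison = "mild_vs_control")
    graded <- list()
    for (nm in c("severe", "mild")) {
      tb <- if (nm == "severe") sevT else mldT
      sigtb <- tb[tb$significant, ]
      if (nrow(sigtb)) {
        comp <- alignAndComposite(dcR, sigtb$edge, sigtb$direction)
        graded[[paste0(nm, "_set")]] <-
          gradedChangeTest(comp, lab3, alpha = 0.05)
      }
    }
    list(severe_vs_control = sevT, mild_vs_control = mldT,
         graded = graded)
  })

  predres <- .stage("predict", verbose, {
    feats <- selectTopFeatures(discR, suite$screen$selected_labels,
                               labels, q = cfg$fdr_q,
                               cap = cfg$prediction_feature_cap)
    Xd <- fcMatrix(discR)[, feats, drop = FALSE]
    cv <- cvPredict(Xd, phD$ados_total, nFolds = cfg$n_folds,
                    mode = cfg$svm_mode)
    ext <- NULL
    if (ncol(vald) >= 3) {
      dv <- std[, ph$group_assignment %in% c("discovery", "validation")]
      dvR <- residualizeFC(dv)
      phDV <- phenotypes(dv)
      isD <- phDV$group_assignment == "discovery"
      M <- fcMatrix(dvR)[, feats, drop = FALSE]
      ext <- externalValidate(M[isD, , drop = FALSE],
                              phDV$ados_total[isD],
                              M[!isD, , drop = FALSE],
                              phDV$ados_total[!isD],
                              mode = cfg$svm_mode)
    }
    list(features = feats, cv = cv, external = ext)
  })

  out <- list(filter_report = report, screen = suite$screen,
              cca = suite$cca, partition = part, agreement = agree,
              biomarkers = bio, prediction = predres,
              config = cfg, seed = seed, truth = truth)
  if (!is.null(outDir)) .stage("write", verbose,
                               writePipelineReport(out, outDir))
  out
}

#' Write the pipeline report bundle
#'
#' Emits `summary.json` plus TSV tables (`agreement.tsv`,
#' `biomarkers_severe_vs_control.tsv`, `biomarkers_mild_vs_control.tsv`,
#' `predictions_cv.tsv`, `predictions_external.tsv`) into `outDir`.
#'
#' @param res result list of [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the summary path.
#' @export
writePipelineReport <- function(res, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create ", outDir)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wtsv(res$agreement, "agreement.tsv")
  wtsv(res$biomarkers$severe_vs_control, "biomarkers_severe_vs_control.tsv")
  wtsv(res$biomarkers$mild_vs_control, "biomarkers_mild_vs_control.tsv")
  cv <- res$prediction$cv
  wtsv(data.frame(fold = cv@fold, observed = cv@observed,
                  predicted = cv@predicted), "predictions_cv.tsv")
  if (!is.null(res$prediction$external)) {
    ex <- res$prediction$external
    wtsv(data.frame(observed = ex@observed, predicted = ex@predicted),
         "predictions_external.tsv")
  }
  cca <- res$cca
  summary <- list(
    seed = res$seed,
    filter_report = as.list(res$filter_report),
    screened_k = res$screen$k,
    canonical_correlations = cca@canCor,
    wilks_lambda = cca@wilksLambda,
    eta_sq = cca@etaSq, adj_eta_sq = cca@adjEtaSq,
    permutation_p = as.list(cca@permP),
    subgroup_sizes = as.list(table(severityLabels(res$partition))),
    cluster_contrast_t = res$partition@adosContrast$t,
    cluster_contrast_p_perm = res$partition@permP,
    silhouette_chosen_k = res$partition@chosenK,
    cv_r = res$prediction$cv@r,
    cv_p_one_tailed = res$prediction$cv@pOneTailed,
    external_r = if (is.null(res$prediction$external)) NULL
                 else res$prediction$external@r,
    config = unclass(res$config)
  )
  path <- file.path(outDir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
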