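#' @import methods
#' @importFrom stats cor sd pt setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData "assay<-" "colData<-"
#' @importFrom S4Vectors DataFrame
NULL

.FC_STAGES <- c("raw_r", "fisher_z", "standardized", "residualized")

#' Subject-by-edge functional connectivity container
#'
#' `FCExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold edge-wise
#' functional connectivity (FC) values for a cohort.  Rows are edges
#' (unordered ROI pairs, indexed in `rowData` by `roi_a < roi_b` and a
#' `"ROIa--ROIb"` label), columns are subjects, and `colData` carries the
#' phenotype table.  A `stage` flag records how far the values have been
#' processed; transitions are only allowed forward through
#' `raw_r -> fisher_z -> standardized -> residualized`.
#'
#' @slot stage character(1), one of `"raw_r"`, `"fisher_z"`,
#'   `"standardized"`, `"residualized"`.
#'
#' @seealso [FCExperiment()] for construction, [fcMatrix()],
#'   [edgeIndex()], [fcStage()], [standardizeSubjects()], [residualizeFC()]
#' @export
setClass("FCExperiment",
  contains = "SummarizedExperiment",
  slots = c(stage = "character")
)

setValidity("FCExperiment", function(object) {
  msg <- NULL
  if (length(object@stage) != 1L || !object@stage %in% .FC_STAGES)
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.FC_STAGES, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  need <- c("roi_a", "roi_b", "label")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain roi_a, roi_b, label")
  else if (nrow(rd) > 0 && any(rd$roi_a >= rd$roi_b))
    msg <- c(msg, "edge index must satisfy roi_a < roi_b")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated subject ids")
  if (is.null(msg)) TRUE else msg
})

#' Canonical correlation analysis result
#'
#' Holds canonical weights, canonical correlations, Wilks' lambda and the
#' derived eta-squared, subject-level canonical scores on the edge side,
#' and (after [permutationSuite()]) permutation null distributions,
#' permutation p-values and the null-adjusted eta-squared.
#'
#' @slot xWeights k x d matrix of edge-side canonical weights.
#' @slot yWeights q x d matrix of subscale-side canonical weights.
#' @slot canCor numeric(d), canonical correlations, non-increasing.
#' @slot wilksLambda numeric(1), `prod(1 - canCor^2)`.
#' @slot etaSq numeric(1), `1 - wilksLambda`.
#' @slot adjEtaSq numeric(1), null-mean-shrunk eta-squared (`NA` before
#'   permutation).
#' @slot scores n x d matrix of edge-side canonical variates.
#' @slot screenedEdges character vector of screened edge labels.
#' @slot nulls list of permutation null vectors (`eta_sq`, `R1..Rd`,
#'   `cluster_t`).
#' @slot permP named numeric of permutation p-values.
#' @slot naiveP numeric(1), Bartlett chi-squared p-value for Wilks'
#'   lambda, which ignores the edge-selection step.
#' @export
setClass("CCAResult",
  slots = c(
    xWeights = "matrix", yWeights = "matrix",
    canCor = "numeric", wilksLambda = "numeric", etaSq = "numeric",
    adjEtaSq = "numeric", scores = "matrix",
    screenedEdges = "character",
    nulls = "list", permP = "numeric", naiveP = "numeric"
  )
)

setValidity("CCAResult", function(object) {
  r <- object@canCor
  msg <- NULL
  if (any(r < -1e-8) || any(r > 1 + 1e-8))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (is.unsorted(rev(r), strictly = FALSE))
    msg <- c(msg, "canonical correlations must be non-increasing")
  if (abs(object@wilksLambda - prod(1 - r^2)) > 1e-8)
    msg <- c(msg, "wilksLambda must equal prod(1 - R_i^2)")
  if (abs(object@etaSq - (1 - object@wilksLambda)) > 1e-8)
    msg <- c(msg, "etaSq must equal 1 - wilksLambda")
  if (is.null(msg)) TRUE else msg
})

#' Severity partition of a discovery cohort
#'
#' Result of Ward clustering of canonical scores: per-subject
#' severe/mild labels, the linkage tree, the silhouette scan over
#' candidate cluster counts, and the ADOS-total contrast between the two
#' subgroups with its whole-pipeline permutation p-value.
#'
#' @slot labels factor with levels `severe`, `mild`, one per subject.
#' @slot tree the `hclust` linkage record.
#' @slot silhouetteByK named numeric, mean silhouette width per k.
#' @slot chosenK integer(1), argmax of the silhouette scan.
#' @slot adosContrast list, the two-sample t-test of ADOS totals between
#'   subgroups (see [twoSampleT()]).
#' @slot permP numeric(1), permutation p for the contrast (`NA` if no
#'   permutation null was supplied).
#' @export
setClass("PartitionResult",
  slots = c(
    labels = "factor", tree = "ANY", silhouetteByK = "numeric",
    chosenK = "integer", adosContrast = "list", permP = "numeric"
  )
)

setValidity("PartitionResult", function(object) {
  msg <- NULL
  if (!all(levels(object@labels) %in% c("severe", "mild")))
    msg <- c(msg, "labels must use levels severe/mild")
  s <- object@silhouetteByK
  if (length(s) && (any(s < -1 - 1e-8) || any(s > 1 + 1e-8)))
    msg <- c(msg, "silhouette values must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Severity prediction result
#'
#' Per-subject predicted and observed ADOS totals, fold assignment (for
#' cross-validated runs), the Pearson correlation between predicted and
#' observed scores with its one-tailed significance, and a snapshot of
#' the model configuration.
#'
#' @slot predicted numeric, predicted ADOS totals.
#' @slot observed numeric, observed ADOS totals.
#' @slot fold integer, fold of each subject (0 for external validation).
#' @slot r numeric(1), Pearson correlation.
#' @slot t numeric(1), t statistic for `r` on `n - 2` df.
#' @slot pOneTailed numeric(1), one-tailed p-value.
#' @slot config list, model configuration snapshot.
#' @export
setClass("PredictionResult",
  slots = c(
    predicted = "numeric", observed = "numeric", fold = "integer",
    r = "numeric", t = "numeric", pOneTailed = "numeric", config = "list"
  )
)

setValidity("PredictionResult", function(object) {
  msg <- NULL
  if (length(object@predicted) != length(object@observed))
    msg <- c(msg, "predicted and observed lengths differ")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-8)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})
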