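#' Build the edge index for an ROI parcellation
#'
#' Enumerates all unordered ROI pairs `(i, j)` with `i < j` in
#' column-by-column upper-triangle order, the same order
#' [vectorizeUpper()] uses.  A 94-region parcellation (AAL-2) yields
#' `94 * 93 / 2 = 4371` edges.
#'
#' @param roiLabels character vector of ROI names; `length(roiLabels)`
#'   determines the number of regions.
#' @return a [S4Vectors::DataFrame] with integer columns `roi_a`,
#'   `roi_b` (1-based, `roi_a < roi_b`) and a character `label` column
#'   `"ROIa--ROIb"`.
#' @examples
#' idx <- makeEdgeIndex(c("A", "B", "C"))
#' idx$label  # "A--B" "A--C" "B--C"
#' @export
makeEdgeIndex <- function(roiLabels) {
  r <- length(roiLabels)
  if (r < 2) stop("need at least two ROIs")
  if (anyDuplicated(roiLabels)) stop("ROI labels must be unique")
  ut <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  ord <- order(ut[, "col"], ut[, "row"])
  ut <- ut[ord, , drop = FALSE]
  S4Vectors::DataFrame(
    roi_a = as.integer(ut[, "row"]),
    roi_b = as.integer(ut[, "col"]),
    label = paste0(roiLabels[ut[, "row"]], "--", roiLabels[ut[, "col"]])
  )
}

#' Construct an FCExperiment
#'
#' @param fc numeric matrix, subjects x edges (row per subject).  Edge
#'   columns must follow the order of `edgeIdx`.
#' @param edgeIdx edge index from [makeEdgeIndex()]; if `NULL`, inferred
#'   from `ncol(fc)` assuming a complete upper triangle with numeric ROI
#'   labels.
#' @param phenotype data.frame with one row per subject (in `fc` row
#'   order), used as `colData`; must contain `subject_id` if `fc` has no
#'   rownames.
#' @param stage processing stage of the values, see
#'   [FCExperiment-class].
#' @return an [FCExperiment-class] object.
#' @export
FCExperiment <- function(fc, edgeIdx = NULL, phenotype = NULL,
                         stage = c("fisher_z", "raw_r", "standardized",
                                   "residualized")) {
  stage <- match.arg(stage)
  fc <- as.matrix(fc)
  if (is.null(edgeIdx)) {
    r <- (1 + sqrt(1 + 8 * ncol(fc))) / 2
    if (abs(r - round(r)) > 1e-9)
      stop("ncol(fc) is not R(R-1)/2 for integer R; supply edgeIdx")
    edgeIdx <- makeEdgeIndex(as.character(seq_len(round(r))))
  }
  if (nrow(edgeIdx) != ncol(fc))
    stop("edge index length (", nrow(edgeIdx),
         ") does not match number of edge columns (", ncol(fc), ")")
  ids <- rownames(fc)
  if (is.null(ids)) {
    if (!is.null(phenotype) && "subject_id" %in% names(phenotype))
      ids <- as.character(phenotype$subject_id)
    else ids <- sprintf("S%04d", seq_len(nrow(fc)))
  }
  cd <- if (is.null(phenotype)) S4Vectors::DataFrame(row.names = ids)
        else S4Vectors::DataFrame(phenotype, row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fc = t(fc)),
    rowData = edgeIdx, colData = cd
  )
  rownames(se) <- edgeIdx$label
  colnames(se) <- ids
  new("FCExperiment", se, stage = stage)
}

#' FCExperiment accessors
#'
#' `fcMatrix` returns the subjects x edges value matrix; `fcStage` the
#' processing stage; `edgeIndex` the edge table; `subjectIds` the
#' subject identifiers; `phenotypes` the colData as a plain data.frame.
#'
#' @param x an [FCExperiment-class].
#' @name FCExperiment-accessors
#' @aliases fcMatrix fcStage edgeIndex subjectIds phenotypes
NULL

#' @rdname FCExperiment-accessors
#' @export
setMethod("fcMatrix", "FCExperiment", function(x)
  t(SummarizedExperiment::assay(x, "fc")))

#' @rdname FCExperiment-accessors
#' @export
setMethod("fcStage", "FCExperiment", function(x) x@stage)

#' @rdname FCExperiment-accessors
#' @export
setMethod("edgeIndex", "FCExperiment", function(x)
  SummarizedExperiment::rowData(x))

#' @rdname FCExperiment-accessors
#' @export
setMethod("subjectIds", "FCExperiment", function(x) colnames(x))

#' @rdname FCExperiment-accessors
#' @export
setMethod("phenotypes", "FCExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "FCExperiment", function(object) {
  cat("FCExperiment:", ncol(object), "subjects x", nrow(object),
      "edges; stage:", object@stage, "\n")
  callNextMethod()
})

# stage transitions only move forward; used by the processing verbs
.advanceStage <- function(x, to) {
  from <- match(x@stage, .FC_STAGES)
  dest <- match(to, .FC_STAGES)
  if (dest <= from)
    stop("cannot move stage backwards (", x@stage, " -> ", to, ")")
  x@stage <- to
  x
}

#' @rdname CCAResult-accessors
#' @name CCAResult-accessors
#' @param x a [CCAResult-class].
#' @export
setMethod("canonicalCorrelations", "CCAResult", function(x) x@canCor)

#' @rdname CCAResult-accessors
#' @export
setMethod("etaSquared", "CCAResult", function(x) x@etaSq)

#' @rdname CCAResult-accessors
#' @export
setMethod("adjEtaSquared", "CCAResult", function(x) x@adjEtaSq)

#' @rdname CCAResult-accessors
#' @export
setMethod("subjectScores", "CCAResult", function(x) x@scores)

setMethod("show", "CCAResult", function(object) {
  cat("CCAResult:", length(object@canCor), "components on",
      nrow(object@scores), "subjects x", nrow(object@xWeights),
      "screened edges\n")
  cat("  R:", paste(sprintf("%.3f", object@canCor), collapse = ", "), "\n")
  cat(sprintf("  Wilks' lambda = %.4f, eta^2 = %.2f%%",
              object@wilksLambda, 100 * object@etaSq))
  if (!is.na(object@adjEtaSq))
    cat(sprintf(", adj-eta^2 = %.2f%%", 100 * object@adjEtaSq))
  cat("\n")
  if (length(object@permP))
    cat("  permutation p:",
        paste(names(object@permP),
              sprintf("%.4g", object@permP), collapse = ", "), "\n")
})

#' @rdname PartitionResult-accessors
#' @name PartitionResult-accessors
#' @param x a [PartitionResult-class].
#' @export
setMethod("severityLabels", "PartitionResult", function(x) x@labels)

setMethod("show", "PartitionResult", function(object) {
  tab <- table(object@labels)
  cat("PartitionResult:", paste(names(tab), tab, sep = " = ",
                                collapse = ", "), "\n")
  cat("  silhouette-chosen k:", object@chosenK, "\n")
  if (length(object@adosContrast))
    cat(sprintf("  ADOS contrast: t = %.2f, D = %.2f",
                object@adosContrast$t, object@adosContrast$cohens_d),
        if (!is.na(object@permP))
          sprintf(", p_perm = %.4g", object@permP) else "", "\n")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", length(object@observed), "subjects")
  if (any(object@fold > 0))
    cat(",", max(object@fold), "folds")
  cat(sprintf("\n  r = %.3f, t = %.2f, p_one_tailed = %.4g\n",
              object@r, object@t, object@pOneTailed))
})
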