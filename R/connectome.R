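#' Pearson correlation matrix of an ROI time series
#'
#' @param ts numeric T x R matrix, one column per ROI, one row per
#'   timepoint; `T >= 3`, no missing values, no constant column.
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
pearsonFC <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  if (anyNA(ts)) stop("time series contains missing values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant ROI time series: ", paste(bad, collapse = ", "))
  }
  stats::cor(ts)
}

#' Fisher z-transformation
#'
#' `arctanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform for correlations.  `|r| >= 1` errors: unit correlations
#' only arise from the (excluded) diagonal, so they signal a bookkeeping
#' leak upstream.
#'
#' @param r correlations with `|r| < 1`.
#' @return transformed values, same shape as `r`.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| >= 1: diagonal or degenerate correlation")
  atanh(r)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Maps an R x R symmetric matrix to the length `R(R-1)/2` edge vector
#' in the order of `idx` (column-wise upper triangle, see
#' [makeEdgeIndex()]).
#'
#' @param mat symmetric matrix.
#' @param idx edge index; defaults to the full upper triangle of `mat`.
#' @return named numeric edge vector.
#' @export
vectorizeUpper <- function(mat, idx = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8) stop("matrix must be symmetric")
  if (is.null(idx)) {
    labs <- rownames(mat)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(mat)))
    idx <- makeEdgeIndex(labs)
  }
  if (max(idx$roi_b) > nrow(mat)) stop("edge index exceeds matrix dimension")
  stats::setNames(mat[cbind(idx$roi_a, idx$roi_b)], idx$label)
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorizeUpper()] given the same edge index; the diagonal
#' is filled with `diag`.
#'
#' @param vec edge vector.
#' @param idx edge index used to produce `vec`.
#' @param diag diagonal value (default `NA`).
#' @return symmetric matrix.
#' @export
devectorizeUpper <- function(vec, idx, diag = NA_real_) {
  r <- max(idx$roi_b)
  m <- matrix(diag, r, r)
  m[cbind(idx$roi_a, idx$roi_b)] <- vec
  m[cbind(idx$roi_b, idx$roi_a)] <- vec
  m
}

#' Within-subject standardization of an edge vector
#'
#' Centers and scales one subject's edge vector to mean 0, SD 1 over its
#' own edges, making FC profiles comparable across subjects and sites.
#' The population SD (divisor `n`) is used.
#'
#' @param vec numeric edge vector with positive spread.
#' @return standardized vector.
#' @export
standardizeSubject <- function(vec) {
  m <- mean(vec)
  s <- sqrt(mean((vec - m)^2))
  if (s == 0) stop("zero variance edge vector cannot be standardized")
  (vec - m) / s
}

#' Standardize every subject of an FCExperiment
#'
#' The default (`mode = "within_subject"`) applies
#' [standardizeSubject()] to each subject's edge vector.  The
#' alternative reading, per-edge standardization across subjects within
#' each site (`mode = "per_edge_within_site"`), is provided behind this
#' switch.
#'
#' @param x an [FCExperiment-class] at stage `raw_r` or `fisher_z`.
#' @param mode standardization population, see Details.
#' @return an [FCExperiment-class] at stage `standardized`.
#' @export
standardizeSubjects <- function(x,
                                mode = c("within_subject",
                                         "per_edge_within_site")) {
  mode <- match.arg(mode)
  m <- fcMatrix(x)  # subjects x edges
  if (mode == "within_subject") {
    m <- t(apply(m, 1, standardizeSubject))
  } else {
    site <- phenotypes(x)$site
    if (is.null(site)) stop("per_edge_within_site needs a site column")
    for (s in unique(site)) {
      rows <- which(site == s)
      sub <- m[rows, , drop = FALSE]
      mu <- colMeans(sub)
      sdv <- sqrt(pmax(colMeans(sub^2) - mu^2, 0))
      sdv[sdv == 0] <- 1
      m[rows, ] <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
    }
  }
  out <- x
  SummarizedExperiment::assay(out, "fc") <- t(m)
  .advanceStage(out, "standardized")
}

#' Regress nuisance covariates out of every edge
#'
#' Per edge, ordinary-least-squares residuals after regressing the edge
#' values on intercept + covariates (+ drop-first site indicators).
#' Residuals are exactly orthogonal to every design column.  The design
#' is fit on the subjects of `x`, i.e. on the union of subjects entering
#' the comparison at hand.
#'
#' @param x an [FCExperiment-class] at stage `standardized` (or
#'   earlier).
#' @param covariates data.frame of per-subject covariates in subject
#'   order; defaults to `age`, `sex`, `full_iq`, `mean_fd`, `site`
#'   pulled from `phenotypes(x)`.
#' @return an [FCExperiment-class] at stage `residualized`.
#' @export
residualizeFC <- function(x, covariates = NULL) {
  if (is.null(covariates)) {
    ph <- phenotypes(x)
    want <- intersect(c("age", "sex", "full_iq", "mean_fd", "site"),
                      names(ph))
    if (!length(want)) stop("no covariate columns found in phenotypes")
    covariates <- ph[, want, drop = FALSE]
  }
  X <- covariateDesign(covariates)
  if (nrow(X) != ncol(x)) stop("covariates must have one row per subject")
  if ("site" %in% names(as.data.frame(covariates))) {
    sz <- table(as.data.frame(covariates)$site)
    if (any(sz == 1))
      warning("site(s) with a single subject: ",
              paste(names(sz)[sz == 1], collapse = ", "))
  }
  m <- fcMatrix(x)                       # subjects x edges
  Q <- qr.Q(qr(X))
  res <- m - Q %*% crossprod(Q, m)       # OLS residuals, all edges at once
  out <- x
  SummarizedExperiment::assay(out, "fc") <- t(res)
  .advanceStage(out, "residualized")
}

#' Build an FCExperiment from per-subject ROI time series
#'
#' Runs [pearsonFC()], [fisherZ()] and [vectorizeUpper()] per subject
#' and assembles the subject x edge matrix.
#'
#' @param tsList named list of T x R time-series matrices, one per
#'   subject, all sharing the same ROI columns.
#' @param phenotype optional phenotype data.frame matched by
#'   `subject_id` to `names(tsList)`.
#' @return an [FCExperiment-class] at stage `fisher_z`.
#' @export
timeseriesToFC <- function(tsList, phenotype = NULL) {
  if (!length(tsList)) stop("empty time-series list")
  labs <- colnames(tsList[[1]])
  if (is.null(labs)) labs <- as.character(seq_len(ncol(tsList[[1]])))
  idx <- makeEdgeIndex(labs)
  fc <- t(vapply(tsList, function(ts) {
    fisherZ(vectorizeUpper(pearsonFC(ts), idx))
  }, numeric(nrow(idx))))
  rownames(fc) <- names(tsList)
  if (!is.null(phenotype)) {
    ord <- match(names(tsList), phenotype$subject_id)
    if (anyNA(ord)) stop("time-series subjects missing from phenotype table")
    phenotype <- phenotype[ord, , drop = FALSE]
  }
  FCExperiment(fc, idx, phenotype, stage = "fisher_z")
}
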