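# rank-transform columns and scale to zero mean / unit population SD so
# that Spearman rho = crossprod(Zx, Zy) / n (average ranks for ties)
.rankStandardize <- function(m) {
  rk <- apply(m, 2, rank)
  mu <- colMeans(rk)
  sdv <- sqrt(colMeans(rk^2) - mu^2)
  if (any(sdv == 0)) {
    bad <- colnames(m)[sdv == 0]
    stop("constant column(s): ",
         paste(if (is.null(bad)) which(sdv == 0) else bad, collapse = ", "))
  }
  sweep(sweep(rk, 2, mu), 2, sdv, "/")
}

# two-sided p for Spearman rho via the t-approximation on n - 2 df
.spearmanP <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Screen edges by Spearman association with the ADOS subscales
#'
#' For every edge, computes Spearman's rank correlation (average-rank
#' ties, two-sided p via the t-approximation) against each of the three
#' ADOS subscales and takes the minimum p across subscales ("associated
#' with at least one subscale").  In `"threshold"` mode all edges with
#' `min_p < threshold` are selected; in `"top_k"` mode exactly the `k`
#' smallest-`min_p` edges are selected (ties broken by edge position,
#' ascending), the form used inside permutation re-screens to keep the
#' feature-to-sample ratio fixed.
#'
#' @param x an [FCExperiment-class] restricted to discovery subjects,
#'   or a subjects x edges numeric matrix.
#' @param subscales n x 3 matrix/data.frame of complete ADOS subscale
#'   scores in subject order.
#' @param threshold screening p threshold (default 0.005).
#' @param k_mode `"threshold"` or `"top_k"`.
#' @param k selection size for `"top_k"` mode.
#' @return list of class `ScreenResult`: `rho` (edges x 3), `p`
#'   (edges x 3), `min_p`, `selected` (integer edge positions),
#'   `selected_labels`, `k`, `threshold`, `mode`.
#' @export
spearmanScreen <- function(x, subscales, threshold = 0.005,
                           k_mode = c("threshold", "top_k"), k = NULL) {
  k_mode <- match.arg(k_mode)
  m <- if (is(x, "FCExperiment")) fcMatrix(x) else as.matrix(x)
  Y <- as.matrix(subscales)
  n <- nrow(m)
  if (n < 10) stop("need at least 10 subjects for the t-approximation")
  if (nrow(Y) != n) stop("subscale rows must match subjects")
  if (anyNA(Y)) stop("subscales must be complete")
  if (k_mode == "top_k") {
    if (is.null(k)) stop("top_k mode needs k")
    if (k > ncol(m)) stop("k exceeds the number of edges")
  }
  Zx <- .rankStandardize(m)
  Zy <- .rankStandardize(Y)
  rho <- crossprod(Zx, Zy) / n
  p <- .spearmanP(rho, n)
  min_p <- apply(p, 1, min)
  sel <- if (k_mode == "threshold") which(min_p < threshold)
         else order(min_p, seq_along(min_p))[seq_len(k)]
  labs <- colnames(m)
  structure(list(
    rho = rho, p = p, min_p = min_p,
    selected = sort(sel),
    selected_labels = if (is.null(labs)) NULL else labs[sort(sel)],
    k = length(sel), threshold = threshold, mode = k_mode
  ), class = "ScreenResult")
}

# fast path used by the permutation engine: Zx fixed, Zy permuted
.screenTopK <- function(Zx, Zy, n, k) {
  rho <- crossprod(Zx, Zy) / n
  min_p <- apply(.spearmanP(rho, n), 1, min)
  order(min_p, seq_along(min_p))[seq_len(k)]
}
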