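#' Canonical correlation analysis between screened edges and subscales
#'
#' Solves CCA on centered data through the SVD-based formulation
#' (orthonormal bases of the two column spaces, then the SVD of their
#' cross-product), which acts as a ridge-free pseudo-inverse and is
#' well defined even when the number of edges approaches or exceeds the
#' sample size.  Returns the leading `ncol(Y)` components.
#'
#' @param X n x k matrix of screened edge values.
#' @param Y n x q matrix of ADOS subscales (q = 3 in the study design).
#' @return a [CCAResult-class] with empty permutation slots.  `naiveP`
#'   carries the Bartlett chi-squared p-value for Wilks' lambda, which
#'   ignores the edge-selection step and is therefore anticonservative
#'   whenever screening preceded the fit.
#' @export
fitCCA <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (ncol(X) < q) stop("need at least ", q, " edge columns")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sx <- svd(Xc); sy <- svd(Yc)
  tol <- function(s) max(s$d) * max(dim(s$u)) * .Machine$double.eps
  rx <- sum(sx$d > tol(sx)); ry <- sum(sy$d > tol(sy))
  if (ry < q) stop("rank(Y) = ", ry, " < ", q,
                   "; subscales are collinear")
  if (rx < q) stop("rank(X) = ", rx, " < ", q)
  Ux <- sx$u[, seq_len(rx), drop = FALSE]
  Uy <- sy$u[, seq_len(ry), drop = FALSE]
  sm <- svd(crossprod(Ux, Uy))
  d <- q
  r <- pmin(pmax(sm$d[seq_len(d)], 0), 1)
  xw <- sx$v[, seq_len(rx), drop = FALSE] %*%
    (sm$u[, seq_len(d), drop = FALSE] / sx$d[seq_len(rx)])
  yw <- sy$v[, seq_len(ry), drop = FALSE] %*%
    (sm$v[, seq_len(d), drop = FALSE] / sy$d[seq_len(ry)])
  scores <- Ux %*% sm$u[, seq_len(d), drop = FALSE]
  lambda <- prod(1 - r^2)
  # Bartlett's chi-squared approximation, selection-unaware
  chi <- -(n - 1 - (ncol(X) + q + 1) / 2) * log(max(lambda, 1e-300))
  naive_p <- stats::pchisq(chi, df = ncol(X) * q, lower.tail = FALSE)
  new("CCAResult",
      xWeights = xw, yWeights = yw, canCor = r,
      wilksLambda = lambda, etaSq = 1 - lambda,
      adjEtaSq = NA_real_, scores = scores,
      screenedEdges = if (is.null(colnames(X))) character(0)
                      else colnames(X),
      nulls = list(), permP = numeric(0), naiveP = naive_p)
}

#' Ward hierarchical clustering of canonical scores
#'
#' Agglomerative clustering with Euclidean distance and Ward's
#' minimum-variance criterion (`hclust(method = "ward.D2")`, which
#' squares the distances internally).  Deterministic given the input
#' order; `hclust` breaks exact merge ties by element order.
#'
#' @param scores n x d numeric matrix.
#' @param k number of clusters to cut (2 for the severity partition).
#' @return integer cluster labels of length n.
#' @export
wardCluster <- function(scores, k = 2) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 2 || k > n) stop("need n >= k >= 2")
  tree <- stats::hclust(stats::dist(scores), method = "ward.D2")
  stats::cutree(tree, k = k)
}

#' Silhouette scan over candidate cluster counts
#'
#' Cuts the Ward tree at each `k` and records the mean silhouette width
#' (Euclidean distance; singleton clusters contribute width 0, the
#' `cluster::silhouette` convention).  The chosen `k` is the argmax,
#' ties resolved toward the smaller `k`.
#'
#' @param scores n x d numeric matrix.
#' @param kRange candidate cluster counts (default 2:10).
#' @return list with `silhouette_by_k` (named numeric), `chosen_k` and
#'   the linkage `tree`.
#' @export
silhouetteScan <- function(scores, kRange = 2:10) {
  scores <- as.matrix(scores)
  if (nrow(scores) <= max(kRange)) stop("need n > max(kRange)")
  dd <- stats::dist(scores)
  tree <- stats::hclust(dd, method = "ward.D2")
  sil <- vapply(kRange, function(k) {
    lab <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(lab, dd)[, "sil_width"])
  }, numeric(1))
  names(sil) <- kRange
  list(silhouette_by_k = sil,
       chosen_k = kRange[which.max(sil)],
       tree = tree)
}

#' Name the severe subgroup and test its ADOS contrast
#'
#' The cluster with the higher mean ADOS total is labeled `severe`.
#' The subgroup contrast is a pooled two-sample t-test of the totals
#' (optionally covariate-controlled through [twoSampleT()]); when a
#' whole-pipeline permutation null of cluster-contrast t statistics is
#' supplied, a two-sided permutation p-value is attached.
#'
#' @param clusters integer labels from a 2-cluster cut.
#' @param ados_total per-subject ADOS totals.
#' @param covariates optional covariate table, see [twoSampleT()].
#' @param tNull optional numeric vector of null t statistics.
#' @param silhouette optional result of [silhouetteScan()].
#' @return a [PartitionResult-class].
#' @export
labelSeverity <- function(clusters, ados_total, covariates = NULL,
                          tNull = NULL, silhouette = NULL) {
  u <- sort(unique(clusters))
  if (length(u) != 2) stop("expected exactly two clusters")
  m1 <- mean(ados_total[clusters == u[1]])
  m2 <- mean(ados_total[clusters == u[2]])
  if (m1 == m2) {
    warning("equal mean ADOS totals; labeling the smaller cluster severe")
    severe <- u[order(tabulate(factor(clusters, u)))][1]
  } else severe <- if (m1 > m2) u[1] else u[2]
  lab <- factor(ifelse(clusters == severe, "severe", "mild"),
                levels = c("severe", "mild"))
  tt <- tryCatch(
    twoSampleT(ados_total[lab == "severe"],
               ados_total[lab == "mild"],
               covariates = if (is.null(covariates)) NULL else
                 rbind(covariates[lab == "severe", , drop = FALSE],
                       covariates[lab == "mild", , drop = FALSE])),
    error = function(e) {
      warning("ADOS contrast undefined: ", conditionMessage(e))
      list(t = NA_real_, df = NA_real_, p_two_tailed = NA_real_,
           p_one_tailed = NA_real_, cohens_d = NA_real_,
           n1 = sum(lab == "severe"), n2 = sum(lab == "mild"), q = 0L)
    })
  pp <- if (is.null(tNull) || is.na(tt$t)) NA_real_
        else permutationP(tt$t, tNull, tail = "two_sided")
  new("PartitionResult",
      labels = lab,
      tree = if (is.null(silhouette)) NULL else silhouette$tree,
      silhouetteByK = if (is.null(silhouette)) numeric(0)
                      else silhouette$silhouette_by_k,
      chosenK = if (is.null(silhouette)) 2L
                else as.integer(silhouette$chosen_k),
      adosContrast = tt, permP = pp)
}

#' Whole-pipeline permutation inference and stratification
#'
#' Runs the observed screening -> CCA -> Ward-clustering chain on a
#' discovery cohort and builds selection-aware permutation nulls: at
#' each iteration the ADOS subscale rows (with their totals) are
#' jointly shuffled across subjects and the *entire* chain — top-k
#' re-screening at the observed selection size, CCA refit, 2-cluster
#' Ward cut, cluster contrast of the permuted totals — is re-run.  The
#' permutation p-values therefore absorb the overfitting of both the
#' edge selection and the CCA; the null-adjusted effect size is
#' `adj_eta^2 = (eta^2_obs - mean(eta^2_null)) / (1 - mean(eta^2_null))`.
#'
#' @param x an [FCExperiment-class] restricted to discovery subjects
#'   (normally at stage `residualized`).
#' @param subscales n x 3 complete subscale matrix; defaults to the
#'   `ados_comm`, `ados_social`, `ados_rrb` phenotype columns.
#' @param totals ADOS totals; default `ados_total` phenotype column.
#' @param cfg [pipelineConfig()]; `n_permutations`, screening settings
#'   and `components_for_clustering` are honoured.
#' @param covariates optional covariates for the cluster contrast.
#' @param observedMode `"threshold"` (screen at
#'   `screening_p_threshold`, the observed-data rule) or `"top_k"`
#'   (fixed selection size `screening_k`, used e.g. for calibration
#'   experiments where the threshold rule would select too few edges).
#' @return list with `cca` (a [CCAResult-class] carrying nulls,
#'   permutation p-values and `adjEtaSq`), `partition` (a
#'   [PartitionResult-class] with the permutation p of the ADOS
#'   contrast), `screen` (the observed [spearmanScreen()] result) and
#'   `n_failed` (resampled iterations).
#' @export
permutationSuite <- function(x, subscales = NULL, totals = NULL,
                             cfg = pipelineConfig(), covariates = NULL,
                             observedMode = c("threshold", "top_k")) {
  observedMode <- match.arg(observedMode)
  B <- cfg$n_permutations
  if (B < 1) stop("n_permutations must be at least 1")
  m <- fcMatrix(x)
  ph <- phenotypes(x)
  if (is.null(subscales)) {
    subscales <- as.matrix(ph[, c("ados_comm", "ados_social", "ados_rrb")])
    if (anyNA(subscales))
      stop("incomplete subscales; restrict to discovery subjects")
  }
  subscales <- as.matrix(subscales)
  if (is.null(totals)) totals <- ph$ados_total
  n <- nrow(m)

  screen <- spearmanScreen(m, subscales,
                           threshold = cfg$screening_p_threshold,
                           k_mode = observedMode, k = cfg$screening_k)
  k <- screen$k
  if (k < ncol(subscales))
    stop("screening selected only ", k,
         " edges; lower the threshold or use top_k mode")
  obs <- fitCCA(m[, screen$selected, drop = FALSE], subscales)

  Zx <- .rankStandardize(m)
  nulls <- list(eta_sq = numeric(B), cluster_t = numeric(B))
  Rnull <- matrix(NA_real_, B, length(obs@canCor))
  n_failed <- 0L
  max_fail <- ceiling(0.01 * B) + 1L
  b <- 1L
  while (b <= B) {
    perm <- sample.int(n)
    res <- tryCatch({
      Yp <- subscales[perm, , drop = FALSE]
      sel <- .screenTopK(Zx, .rankStandardize(Yp), n, k)
      fit <- fitCCA(m[, sel, drop = FALSE], Yp)
      cl <- wardCluster(fit@scores, 2)
      tp <- totals[perm]
      g1 <- tp[cl == 1]; g2 <- tp[cl == 2]
      tstat <- twoSampleT(g1, g2, covariates =
        if (is.null(covariates)) NULL else
          rbind(covariates[perm, , drop = FALSE][cl == 1, , drop = FALSE],
                covariates[perm, , drop = FALSE][cl == 2, , drop = FALSE]))$t
      list(eta = fit@etaSq, r = fit@canCor, t = tstat)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      if (n_failed > max_fail)
        stop("more than 1% of permutation iterations failed")
      next
    }
    nulls$eta_sq[b] <- res$eta
    Rnull[b, ] <- res$r
    nulls$cluster_t[b] <- res$t
    b <- b + 1L
  }
  for (i in seq_len(ncol(Rnull)))
    nulls[[paste0("R", i)]] <- Rnull[, i]

  permP <- c(
    eta_sq = permutationP(obs@etaSq, nulls$eta_sq, "upper"),
    stats::setNames(
      vapply(seq_len(ncol(Rnull)), function(i)
        permutationP(obs@canCor[i], Rnull[, i], "upper"), numeric(1)),
      paste0("R", seq_len(ncol(Rnull))))
  )
  obs@nulls <- nulls
  obs@permP <- permP
  obs@adjEtaSq <- (obs@etaSq - mean(nulls$eta_sq)) /
    (1 - mean(nulls$eta_sq))

  comp <- seq_along(obs@canCor)
  if (identical(cfg$components_for_clustering, "significant")) {
    sig <- which(permP[-1] < 0.05)
    if (length(sig) >= 1) comp <- sig
    else warning("no significant components; clustering on all")
  }
  sil <- silhouetteScan(obs@scores[, comp, drop = FALSE],
                        kRange = 2:min(10, n - 1))
  cl <- stats::cutree(sil$tree, k = 2)
  part <- labelSeverity(cl, totals, covariates = covariates,
                        tNull = nulls$cluster_t, silhouette = sil)
  list(cca = obs, partition = part, screen = screen, n_failed = n_failed)
}
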