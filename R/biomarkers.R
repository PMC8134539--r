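#' Edge-wise group comparison with FDR control
#'
#' Runs a pooled two-sample t-test on every edge between two subject
#' groups, optionally controlling covariates by joint residualization
#' (one shared design; degrees of freedom reduced accordingly, as in
#' [twoSampleT()]), and applies Benjamini-Hochberg FDR correction over
#' the tested edge universe.
#'
#' @param x an [FCExperiment-class].
#' @param idsA,idsB subject ids (or logical/integer selections) of the
#'   two groups; A is the first-named group, so `t > 0` means A > B.
#' @param covariates optional data.frame of per-subject covariates for
#'   the combined `c(A, B)` subjects, or column names to pull from
#'   `phenotypes(x)`.
#' @param q FDR level (default 0.05).
#' @param edges optional subset of edge labels/positions forming the
#'   FDR universe (default: all edges).
#' @param comparison character tag stored with the table.
#' @return `BiomarkerTable`: data.frame sorted by p ascending with
#'   columns `edge`, `roi_a`, `roi_b`, `t`, `cohens_d`,
#'   `p_two_tailed`, `p_adjusted`, `significant`, `direction`,
#'   `comparison`.
#' @export
groupwiseTests <- function(x, idsA, idsB, covariates = NULL, q = 0.05,
                           edges = NULL, comparison = "A_vs_B") {
  m <- fcMatrix(x)
  idx <- edgeIndex(x)
  sel <- if (is.null(edges)) seq_len(ncol(m))
         else if (is.character(edges)) match(edges, colnames(m))
         else edges
  if (anyNA(sel)) stop("unknown edge labels")
  rowsA <- .resolveSubjects(x, idsA); rowsB <- .resolveSubjects(x, idsB)
  n1 <- length(rowsA); n2 <- length(rowsB)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 subjects")
  Y <- m[c(rowsA, rowsB), sel, drop = FALSE]
  qn <- 0L
  if (!is.null(covariates)) {
    if (is.character(covariates))
      covariates <- phenotypes(x)[c(rowsA, rowsB), covariates,
                                  drop = FALSE]
    X <- covariateDesign(covariates)
    if (nrow(X) != n1 + n2) stop("covariates must cover both groups")
    qn <- ncol(X) - 1L
    Q <- qr.Q(qr(X))
    Y <- Y - Q %*% crossprod(Q, Y)
  }
  A <- Y[seq_len(n1), , drop = FALSE]
  B <- Y[n1 + seq_len(n2), , drop = FALSE]
  df <- n1 + n2 - 2L - qn
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  diff <- colMeans(A) - colMeans(B)
  t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  p2 <- 2 * stats::pt(-abs(t), df)
  fdr <- bhFDR(p2, q)
  out <- data.frame(
    edge = idx$label[sel], roi_a = idx$roi_a[sel], roi_b = idx$roi_b[sel],
    t = t, cohens_d = diff / sqrt(sp2), p_two_tailed = p2,
    p_adjusted = fdr$p_adjusted, significant = fdr$reject,
    direction = sign(t), comparison = comparison,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p_two_tailed, seq_len(nrow(out))), ]
}

.resolveSubjects <- function(x, ids) {
  if (is.logical(ids)) return(which(ids))
  if (is.numeric(ids)) return(as.integer(ids))
  r <- match(ids, subjectIds(x))
  if (anyNA(r)) stop("unknown subject id(s): ",
                     paste(ids[is.na(r)], collapse = ", "))
  r
}

#' Sign-aligned composite score over an edge set
#'
#' Flips each edge by the sign of its defining t statistic (so every
#' edge points in the hypothesized "increases with severity" direction)
#' and sums: per-subject score `sum_e s_e * value_e`.  The score is
#' invariant under simultaneous negation of any edge column and its
#' sign.
#'
#' @param x an [FCExperiment-class].
#' @param edges edge labels or positions (non-empty).
#' @param signs +1/-1 per edge, from the defining comparison
#'   ([groupwiseTests()] `direction` column).
#' @return named numeric vector, one composite score per subject.
#' @export
alignAndComposite <- function(x, edges, signs) {
  if (!length(edges)) stop("empty edge set")
  if (length(signs) != length(edges))
    stop("signs must match edges")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  m <- fcMatrix(x)
  sel <- if (is.character(edges)) match(edges, colnames(m)) else edges
  if (anyNA(sel)) stop("unknown edge labels")
  drop(m[, sel, drop = FALSE] %*% signs)
}

#' Graded-change test of a composite across severity groups
#'
#' Tests the hypothesis of a graded increase of the sign-aligned
#' composite from controls, through the mild subgroup, to the severe
#' subgroup: pooled t-tests of severe-vs-mild and mild-vs-control,
#' each one-tailed in the hypothesized (positive) direction.  The
#' graded-change verdict requires both one-tailed tests significant at
#' `alpha`.
#'
#' @param composite per-subject scores from [alignAndComposite()].
#' @param labels per-subject group labels in
#'   `{severe, mild, control}`.
#' @param covariates optional covariate table (full sample, subject
#'   order of `composite`).
#' @param alpha verdict level (default 0.05).
#' @return list with `severe_vs_mild`, `mild_vs_control` (each a
#'   [twoSampleT()] result plus `p_directional`) and logical `graded`.
#' @export
gradedChangeTest <- function(composite, labels, covariates = NULL,
                             alpha = 0.05) {
  labels <- as.character(labels)
  if (!all(c("severe", "mild", "control") %in% labels))
    stop("all three groups must be non-empty")
  pair <- function(a, b) {
    ia <- labels == a; ib <- labels == b
    cv <- if (is.null(covariates)) NULL else
      rbind(covariates[ia, , drop = FALSE],
            covariates[ib, , drop = FALSE])
    tt <- twoSampleT(composite[ia], composite[ib], covariates = cv)
    # one-tailed p for the hypothesized direction a > b
    tt$p_directional <- stats::pt(tt$t, tt$df, lower.tail = FALSE)
    tt
  }
  sm <- pair("severe", "mild")
  mc <- pair("mild", "control")
  list(severe_vs_mild = sm, mild_vs_control = mc,
       graded = sm$p_directional < alpha && mc$p_directional < alpha)
}

#' Assign ages to developmental bands
#'
#' Children (6-12\], adolescents (12-18\], adults (18-30\]; boundary
#' ages (exactly 12 or 18) fall in the younger band.
#'
#' @param age numeric ages in years.
#' @param breaks band boundaries (default `c(6, 12, 18, 30)`).
#' @return factor of band labels.
#' @export
ageBands <- function(age, breaks = c(6, 12, 18, 30)) {
  cut(age, breaks = breaks, include.lowest = TRUE, right = TRUE,
      labels = c("children", "adolescents", "adults"))
}

#' Re-run edge-wise comparisons within strata
#'
#' Repeats [groupwiseTests()] inside each level of a stratifying factor
#' (e.g. age bands, sex, or a motion-filtered subset encoded as a
#' factor), so per-stratum effect sizes can be compared side by side.
#' Strata with fewer than 2 subjects in either group are skipped with a
#' warning.
#'
#' @param x an [FCExperiment-class].
#' @param idsA,idsB the two groups, as in [groupwiseTests()].
#' @param strata factor (or vector) over all subjects of `x` defining
#'   the strata.
#' @param ... passed to [groupwiseTests()].
#' @return named list of `BiomarkerTable`s, one per usable stratum,
#'   with a `cohens_d_by_stratum` attribute (edges x strata matrix).
#' @export
stratifiedRerun <- function(x, idsA, idsB, strata, ...) {
  rowsA <- .resolveSubjects(x, idsA); rowsB <- .resolveSubjects(x, idsB)
  strata <- as.factor(strata)
  if (length(strata) != ncol(x))
    stop("strata must cover every subject of x")
  out <- list()
  for (lev in levels(strata)) {
    inl <- which(strata == lev)
    a <- intersect(rowsA, inl); b <- intersect(rowsB, inl)
    if (length(a) < 2 || length(b) < 2) {
      warning("stratum ", lev, " skipped: fewer than 2 per group")
      next
    }
    out[[lev]] <- groupwiseTests(x, a, b, comparison = lev, ...)
  }
  if (length(out)) {
    first <- out[[1]][order(out[[1]]$edge), ]
    dmat <- vapply(out, function(tb) tb$cohens_d[order(tb$edge)],
                   numeric(nrow(first)))
    rownames(dmat) <- first$edge
    attr(out, "cohens_d_by_stratum") <- dmat
  }
  out
}
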