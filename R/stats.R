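#' Pooled-variance two-sample t-test with optional covariate control
#'
#' Computes the Student (pooled-variance) two-sample t statistic and
#' Cohen's D.  When covariates are supplied, both groups are first
#' jointly residualized against the covariate design (intercept +
#' covariates), and the pooled t is then computed on the residuals with
#' the degrees of freedom reduced by the number of covariate columns
#' `q`: `df = n1 + n2 - 2 - q`.  Cohen's D uses the pooled SD of the
#' (residualized) values, so `D = t * sqrt(1/n1 + 1/n2)`.
#'
#' @param x1,x2 numeric vectors, the two groups.
#' @param covariates optional data.frame (or matrix) with
#'   `length(x1) + length(x2)` rows, group 1 first; factors/characters
#'   (e.g. site, sex) are expanded to drop-first indicators.
#' @return a list with `t`, `df`, `p_two_tailed`, `p_one_tailed`
#'   (tail matching the sign of `t`), `cohens_d`, `n1`, `n2`, `q`.
#' @examples
#' twoSampleT(rnorm(20), rnorm(20, 1))
#' @export
twoSampleT <- function(x1, x2, covariates = NULL) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 observations")
  y <- c(x1, x2)
  q <- 0L
  if (!is.null(covariates)) {
    X <- covariateDesign(covariates)
    if (nrow(X) != n1 + n2)
      stop("covariates must have n1 + n2 rows")
    q <- ncol(X) - 1L  # intercept does not count
    y <- stats::lm.fit(X, y)$residuals
    x1 <- y[seq_len(n1)]; x2 <- y[n1 + seq_len(n2)]
  }
  df <- n1 + n2 - 2L - q
  if (df < 1) stop("non-positive degrees of freedom")
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(x1) - mean(x2)) / se
  d <- (mean(x1) - mean(x2)) / sqrt(sp2)
  list(t = t, df = df,
       p_two_tailed = 2 * stats::pt(-abs(t), df),
       p_one_tailed = stats::pt(-abs(t), df),
       cohens_d = d, n1 = n1, n2 = n2, q = q)
}

#' Pooled two-sample t from sufficient statistics
#'
#' Same statistic as [twoSampleT()] but computed from group means, SDs
#' and sizes, for checking consistency of reported summary tables.
#'
#' @param m1,m2 group means. @param s1,s2 group SDs. @param n1,n2 sizes.
#' @return list as in [twoSampleT()] (no covariates, `q = 0`).
#' @export
twoSampleTFromStats <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  list(t = t, df = df,
       p_two_tailed = 2 * stats::pt(-abs(t), df),
       p_one_tailed = stats::pt(-abs(t), df),
       cohens_d = (m1 - m2) / sqrt(sp2), n1 = n1, n2 = n2, q = 0L)
}

#' Cohen's D from a pooled t statistic
#'
#' Inverts the pooled-variance relationship `t = D / sqrt(1/n1 + 1/n2)`.
#'
#' @param t pooled two-sample t statistic.
#' @param n1,n2 group sizes (each at least 2).
#' @return Cohen's D.
#' @export
dFromT <- function(t, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Significance of a Pearson correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param r correlation, `|r| < 1`.
#' @param n sample size, at least 3.
#' @return list with `t`, `df`, `p_two_tailed`, `p_one_tailed` (upper
#'   tail of the observed sign).
#' @examples
#' corrSignificance(0.35, 29)$p_one_tailed  # ~0.031
#' @export
corrSignificance <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 3) stop("n must be at least 3")
  df <- n - 2
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(t = t, df = df,
       p_two_tailed = 2 * stats::pt(-abs(t), df),
       p_one_tailed = stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Thin wrapper over `p.adjust(method = "BH")` returning both the
#' rejection flags at level `q` and the adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with logical `reject` and numeric `p_adjusted`.
#' @export
bhFDR <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Permutation p-value with the add-one rule
#'
#' `p = (1 + #\{null >= observed\}) / (1 + B)` for the upper tail;
#' the two-sided version compares absolute values.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of null statistics (length B >= 1).
#' @param tail `"upper"`, `"lower"` or `"two_sided"`.
#' @return the permutation p-value.
#' @export
permutationP <- function(observed, nulls,
                         tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  if (!length(nulls)) stop("need at least one null value")
  hits <- switch(tail,
    upper = sum(nulls >= observed),
    lower = sum(nulls <= observed),
    two_sided = sum(abs(nulls) >= abs(observed))
  )
  (1 + hits) / (1 + length(nulls))
}

#' Build a covariate design matrix
#'
#' Expands a covariate table to a numeric design with intercept;
#' character/factor columns (site, sex) become drop-first indicator
#' columns.  Columns that are constant are dropped (they are absorbed by
#' the intercept).  Errors on rank deficiency, naming the collinear
#' columns.
#'
#' @param covariates data.frame or matrix of per-subject covariates.
#' @return numeric design matrix with an `(Intercept)` column.
#' @export
covariateDesign <- function(covariates) {
  df <- as.data.frame(covariates)
  keep <- vapply(df, function(col) length(unique(col)) > 1, logical(1))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0)
    return(matrix(1, nrow(as.data.frame(covariates)), 1,
                  dimnames = list(NULL, "(Intercept)")))
  for (nm in names(df))
    if (is.character(df[[nm]]) || is.logical(df[[nm]]))
      df[[nm]] <- factor(df[[nm]])
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}
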