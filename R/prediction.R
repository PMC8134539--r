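#' Select the top severity-discriminating edges
#'
#' Tests severe-vs-mild differences on the screened edge set (the FDR
#' universe is the screened set, not all edges), keeps the BH-FDR
#' survivors at level `q`, and returns at most `cap` of them, smallest
#' p first (ties broken by edge position).
#'
#' @param x an [FCExperiment-class] covering the discovery subjects.
#' @param screenedEdges edge labels from the screening stage.
#' @param labels severe/mild factor over the discovery subjects of `x`.
#' @param q FDR level (default 0.05).
#' @param cap maximum number of edges returned (default 20).
#' @param covariates optional, see [groupwiseTests()].
#' @return character vector of selected edge labels.
#' @export
selectTopFeatures <- function(x, screenedEdges, labels, q = 0.05,
                              cap = 20, covariates = NULL) {
  labels <- as.character(labels)
  tb <- groupwiseTests(x, which(labels == "severe"),
                       which(labels == "mild"),
                       covariates = covariates, q = q,
                       edges = screenedEdges,
                       comparison = "severe_vs_mild")
  surv <- tb[tb$significant, ]
  if (!nrow(surv))
    stop("no edges survive FDR at q = ", q,
         "; consider raising q or enlarging the screened set")
  utils::head(surv$edge, cap)
}

.svmDefaults <- function(m, mode) {
  list(mode = mode, kernel = "radial", cost = 1, gamma = 1 / m)
}

.fitSvm <- function(X, y, mode) {
  if (mode == "classification") {
    yf <- factor(y)
    if (nlevels(yf) < 2)
      stop("training fold contains a single class; ",
           "use svm_mode = \"regression\"")
    e1071::svm(X, yf, type = "C-classification", kernel = "radial",
               cost = 1, gamma = 1 / ncol(X))
  } else {
    e1071::svm(X, y, type = "eps-regression", kernel = "radial",
               cost = 1, gamma = 1 / ncol(X))
  }
}

.predictSvm <- function(fit, X, mode) {
  p <- stats::predict(fit, X)
  if (mode == "classification") as.numeric(as.character(p))
  else as.numeric(p)
}

# correlation significance that tolerates degenerate perfect fits
.corStats <- function(r, n) {
  if (is.na(r)) return(list(t = NA_real_, p_one_tailed = NA_real_))
  if (abs(r) >= 1 - 1e-12)
    return(list(t = sign(r) * Inf,
                p_one_tailed = if (r > 0) 0 else 1))
  cs <- corrSignificance(r, n)
  list(t = cs$t, p_one_tailed = cs$p_one_tailed)
}

#' Cross-validated SVM prediction of ADOS totals
#'
#' Radial-basis-function SVM with the library defaults (cost 1, kernel
#' width `1/m`; no hyperparameter tuning, which avoids an extra
#' selection layer).  `"classification"` mode treats the integer
#' totals as class labels (multi-class C-classification);
#' `"regression"` mode is epsilon-regression.  Subjects are shuffled
#' once (seeded upstream) into folds as equal as possible; each
#' subject is predicted exactly once by a model that never saw it.
#' Accuracy is the Pearson correlation between pooled predictions and
#' observed totals, with one-tailed significance from
#' [corrSignificance()].
#'
#' @param X n x m feature matrix (typically residualized FC values of
#'   the selected edges).
#' @param y integer ADOS totals.
#' @param nFolds number of folds (default 10; 260 subjects give
#'   234-train / 26-test splits).
#' @param mode `"classification"` or `"regression"`.
#' @return a [PredictionResult-class].
#' @export
cvPredict <- function(X, y, nFolds = 10,
                      mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must match rows of X")
  if (nFolds < 2 || nFolds > n) stop("need 2 <= nFolds <= n")
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(nFolds), length.out = n)
  pred <- numeric(n)
  for (f in seq_len(nFolds)) {
    te <- fold == f
    fit <- .fitSvm(X[!te, , drop = FALSE], y[!te], mode)
    pred[te] <- .predictSvm(fit, X[te, , drop = FALSE], mode)
  }
  r <- stats::cor(pred, y)
  cs <- .corStats(r, n)
  new("PredictionResult",
      predicted = pred, observed = as.numeric(y), fold = fold,
      r = r, t = cs$t, pOneTailed = cs$p_one_tailed,
      config = c(.svmDefaults(ncol(X), mode), n_folds = nFolds))
}

#' Validate a trained SVM on an independent group
#'
#' Fits the default-parameter SVM on all training subjects and
#' evaluates the predicted-vs-observed correlation on the held-out
#' validation group.
#'
#' @param Xtrain,ytrain discovery features and totals.
#' @param Xtest,ytest validation features (same edges, same order) and
#'   totals.
#' @param mode `"classification"` or `"regression"`.
#' @return a [PredictionResult-class] (fold 0 marks external subjects).
#' @export
externalValidate <- function(Xtrain, ytrain, Xtest, ytest,
                             mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  if (ncol(Xtrain) != ncol(Xtest) ||
      !identical(colnames(Xtrain), colnames(Xtest)))
    stop("training and test features do not match")
  if (nrow(Xtest) < 3)
    stop("validation group too small for a correlation (n < 3)")
  fit <- .fitSvm(Xtrain, ytrain, mode)
  pred <- .predictSvm(fit, Xtest, mode)
  r <- stats::cor(pred, ytest)
  cs <- .corStats(r, nrow(Xtest))
  new("PredictionResult",
      predicted = pred, observed = as.numeric(ytest),
      fold = rep(0L, nrow(Xtest)),
      r = r, t = cs$t, pOneTailed = cs$p_one_tailed,
      config = .svmDefaults(ncol(Xtrain), mode))
}
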