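test_that("pearsonFC flags duplicated, negated and constant columns", {
  set.seed(1)
  ts <- matrix(rnorm(200 * 4), 200, 4,
               dimnames = list(NULL, paste0("R", 1:4)))
  ts[, 2] <- ts[, 1]
  ts[, 3] <- -ts[, 1]
  cm <- pearsonFC(ts)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_true(isSymmetric(cm))
  expect_equal(diag(cm), setNames(rep(1, 4), colnames(ts)))

  ts[, 4] <- 5
  expect_error(pearsonFC(ts), "R4")
  expect_error(pearsonFC(ts[1:2, 1:3]), "3 timepoints")
})

test_that("sample correlation recovers a planted 0.6 at T = 10000", {
  cov <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  ts <- simulateTimeSeriesFromCov(cov, 10000, seed = 42)
  expect_equal(pearsonFC(ts)["a", "b"], 0.6, tolerance = 0.03)
})

test_that("identity covariance gives near-zero off-diagonals", {
  ts <- simulateTimeSeriesFromCov(diag(4), 10000, seed = 7)
  cm <- pearsonFC(ts)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("time-series generator rejects degenerate inputs", {
  expect_error(simulateTimeSeriesFromCov(diag(3), 1), "3 timepoints")
  bad <- diag(2); bad[1, 2] <- 0.5                 # asymmetric
  expect_error(simulateTimeSeriesFromCov(bad, 10), "symmetric")
  npd <- matrix(c(1, 2, 2, 1), 2, 2)               # eigenvalue -1
  expect_error(simulateTimeSeriesFromCov(npd, 10), "positive semi-definite")
})

test_that("Fisher z is arctanh with guarded domain", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log((1 + 0.5) / (1 - 0.5)))
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.15)
  expect_equal(fisherZ(-r), -fisherZ(r))           # odd function
  expect_error(fisherZ(1), ">= 1")
})

test_that("upper-triangle vectorization is ordered and invertible", {
  idx3 <- makeEdgeIndex(c("A", "B", "C"))
  expect_equal(idx3$label, c("A--B", "A--C", "B--C"))
  m <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  v <- vectorizeUpper(m, idx3)
  expect_equal(unname(v), c(.1, .2, .3))
  back <- devectorizeUpper(v, idx3, diag = 1)
  expect_equal(back, m)

  idx94 <- makeEdgeIndex(sprintf("r%02d", 1:94))
  expect_equal(nrow(idx94), 4371)
  expect_error(vectorizeUpper(m[, 1:2]), "square")
})

test_that("within-subject standardization uses the population SD", {
  v <- c(1, 2, 3)
  expect_equal(standardizeSubject(v),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  expect_equal(standardizeSubject(v)[1], -1.2247, tolerance = 1e-4)
  set.seed(2)
  x <- rnorm(50)
  expect_lt(abs(mean(standardizeSubject(x))), 1e-10)
  expect_equal(standardizeSubject(3 * x + 7), standardizeSubject(x))
  expect_error(standardizeSubject(rep(2, 5)), "zero variance")
})

test_that("FCExperiment standardization hits row moments and stage rules", {
  co <- smallCohort()
  std <- standardizeSubjects(co$fc)
  m <- fcMatrix(std)
  expect_lt(max(abs(rowMeans(m))), 1e-10)
  popsd <- sqrt(rowMeans(m^2) - rowMeans(m)^2)
  expect_equal(unname(popsd), rep(1, nrow(m)), tolerance = 1e-10)
  expect_equal(fcStage(std), "standardized")
  # stages only move forward
  expect_error(standardizeSubjects(std), "backwards")
})

test_that("residualization orthogonalizes every covariate and site", {
  co <- smallCohort()
  std <- standardizeSubjects(co$fc)
  res <- residualizeFC(std)
  expect_equal(fcStage(res), "residualized")
  m <- fcMatrix(res)
  ph <- phenotypes(res)
  X <- covariateDesign(ph[, c("age", "sex", "full_iq", "mean_fd", "site")])
  cors <- abs(cor(m[, sample.int(ncol(m), 50)], X[, -1]))
  expect_lt(max(cors), 1e-8)
  for (s in unique(ph$site))
    expect_lt(max(abs(colMeans(m[ph$site == s, 1:20, drop = FALSE]))), 1e-8)
})

test_that("a planted covariate effect is removed by residualization", {
  set.seed(5)
  n <- 150
  age <- runif(n, 6, 30)
  beta <- 0.08
  fc <- matrix(rnorm(n * 10), n, 10)
  fc[, 3] <- fc[, 3] + beta * age
  x <- FCExperiment(fc, makeEdgeIndex(as.character(1:5)),
                    data.frame(subject_id = paste0("S", 1:n), age = age),
                    stage = "fisher_z")
  pre <- coef(lm(fcMatrix(x)[, 3] ~ age))["age"]
  expect_lt(abs(unname(pre) - beta), 0.03)
  res <- residualizeFC(x, covariates = data.frame(age = age))
  post <- coef(lm(fcMatrix(res)[, 3] ~ age))["age"]
  expect_lt(abs(post), 1e-10)
})

test_that("rank-deficient designs and single-subject sites are reported", {
  df <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(covariateDesign(df), "collinear")
  co <- smallCohort()
  std <- standardizeSubjects(co$fc)
  ph <- phenotypes(std)
  cov <- ph[, c("age", "site")]
  cov$site[1] <- "lonely_site"
  expect_warning(residualizeFC(std, covariates = cov), "single subject")
})

test_that("time series and direct FC emission agree on screening", {
  # same underlying structure through both paths: estimated Fisher-z
  # converges to a linear rescaling of the direct values, so the
  # screened sets coincide for large T
  p <- simParams(n_discovery = 40, n_control = 5, n_validation = 5,
                 n_sites = 2, n_roi = 10, n_signal_edges = 10,
                 n_severe_marker_edges = 3, n_mild_marker_edges = 3)
  co <- simulateCohort(p, seed = 3)
  ph <- phenotypes(co$fc)
  keep <- ph$group_assignment == "discovery"
  disc <- co$fc[, keep]
  ts <- simulateTimeSeriesCohort(list(fc = disc), T = 4000, seed = 4)
  est <- timeseriesToFC(ts, phenotype = phenotypes(disc))
  Y <- phenotypes(disc)[, c("ados_comm", "ados_social", "ados_rrb")]
  sel_direct <- spearmanScreen(disc, Y, k_mode = "top_k", k = 10)$selected
  sel_ts <- spearmanScreen(est, Y, k_mode = "top_k", k = 10)$selected
  jac <- length(intersect(sel_direct, sel_ts)) /
    length(union(sel_direct, sel_ts))
  expect_gte(jac, 0.6)
})
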