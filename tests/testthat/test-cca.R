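test_that("canonical correlations match the eigendecomposition oracle", {
  set.seed(9)
  for (case in list(c(n = 30, k = 5), c(n = 50, k = 10), c(n = 20, k = 3))) {
    X <- matrix(rnorm(case["n"] * case["k"]), case["n"])
    Y <- matrix(rnorm(case["n"] * 3), case["n"])
    fit <- fitCCA(X, Y)
    expect_equal(fit@canCor, bruteCCA(X, Y), tolerance = 1e-8)
  }
  # independent library cross-check on one full-rank instance
  X <- matrix(rnorm(40 * 6), 40)
  Y <- matrix(rnorm(40 * 3), 40)
  expect_equal(fitCCA(X, Y)@canCor, cancor(X, Y)$cor, tolerance = 1e-8)
})

test_that("Y inside the span of X gives perfect correlations", {
  set.seed(10)
  X <- matrix(rnorm(60 * 8), 60)
  M <- matrix(c(1, 2, 0, 0, 1, 1, 1, 0, 1), 3, 3)   # invertible mixing
  Y <- X[, 1:3] %*% M
  fit <- fitCCA(X, Y)
  expect_equal(fit@canCor, c(1, 1, 1), tolerance = 1e-8)
  expect_equal(fit@wilksLambda, 0, tolerance = 1e-8)
})

test_that("CCAResult invariants hold and scores are uncorrelated", {
  set.seed(11)
  X <- matrix(rnorm(80 * 12), 80)
  Y <- matrix(rnorm(80 * 3), 80)
  fit <- fitCCA(X, Y)
  r <- fit@canCor
  expect_true(all(diff(r) <= 1e-12))            # non-increasing
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(fit@wilksLambda, prod(1 - r^2))
  expect_equal(fit@etaSq, 1 - fit@wilksLambda)
  cc <- cor(fit@scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_lt(max(abs(colMeans(fit@scores))), 1e-10)
})

test_that("degenerate CCA inputs error informatively", {
  set.seed(12)
  X <- matrix(rnorm(30 * 5), 30)
  Ybad <- cbind(1:30, 2 * (1:30), rnorm(30))      # rank 2
  expect_error(fitCCA(X, Ybad), "collinear")
  expect_error(fitCCA(X[, 1:2], matrix(rnorm(90), 30)), "at least 3")
})

test_that("Ward separates distant blobs and respects merge monotonicity", {
  set.seed(13)
  blob <- rbind(matrix(rnorm(40 * 2), 40), matrix(rnorm(30 * 2, 10), 30))
  lab <- wardCluster(blob, 2)
  expect_equal(adjustedRand(lab, rep(1:2, c(40, 30))), 1)
  # n = k: every point its own cluster
  pts <- matrix(rnorm(10), 5)
  expect_equal(sort(unique(wardCluster(pts, 5))), 1:5)
  tree <- hclust(dist(blob), method = "ward.D2")
  expect_true(all(diff(tree$height) >= -1e-10))
  expect_error(wardCluster(pts, 1), "k >= 2")
})

test_that("silhouette scan picks the planted number of blobs", {
  set.seed(14)
  two <- rbind(matrix(rnorm(60 * 2, sd = 0.3), 60),
               matrix(rnorm(60 * 2, mean = 8, sd = 0.3), 60))
  s2 <- silhouetteScan(two)
  expect_equal(s2$chosen_k, 2)
  expect_gt(max(s2$silhouette_by_k), 0.8)

  three <- rbind(matrix(rnorm(40 * 2, sd = 0.3), 40),
                 cbind(rnorm(40, 8, 0.3), rnorm(40, 0, 0.3)),
                 cbind(rnorm(40, 4, 0.3), rnorm(40, 7, 0.3)))
  expect_equal(silhouetteScan(three)$chosen_k, 3)

  # 3 columns, matching the canonical-score use case
  blobless <- matrix(rnorm(150 * 3), 150)
  expect_lt(max(silhouetteScan(blobless)$silhouette_by_k), 0.3)
})

test_that("severity labeling follows the higher mean and is stable", {
  totals <- c(14, 14, 11, 11)
  # degenerate within-cluster variance: labels still assigned, the
  # contrast t is NA (warned)
  pr <- suppressWarnings(labelSeverity(c(1, 1, 2, 2), totals))
  expect_equal(as.character(pr@labels), c("severe", "severe", "mild", "mild"))
  expect_true(is.na(pr@adosContrast$t))
  # invariant to cluster id relabeling
  pr2 <- suppressWarnings(labelSeverity(c(2, 2, 1, 1), totals))
  expect_equal(pr2@labels, pr@labels)
  # tie: smaller cluster labeled severe, with a warning
  warns <- capture_warnings(pr3 <- labelSeverity(c(1, 1, 1, 2), rep(10, 4)))
  expect_true(any(grepl("equal", warns)))
  expect_equal(as.character(pr3@labels[4]), "severe")
})

test_that("permutation suite returns calibrated machinery on planted data", {
  suite <- smallSuite()
  cca <- suite$cca
  B <- 60
  expect_length(cca@nulls$eta_sq, B)
  expect_length(cca@nulls$cluster_t, B)
  expect_true(all(cca@permP >= 1 / (B + 1) & cca@permP <= 1))
  expect_lte(cca@adjEtaSq, cca@etaSq)
  # strong planted structure: eta^2 beats every permutation
  expect_equal(unname(cca@permP["eta_sq"]), 1 / (B + 1))
  part <- suite$partition
  expect_s4_class(part, "PartitionResult")
  expect_true(part@permP >= 0 && part@permP <= 1)
  expect_gt(part@adosContrast$t, 0)   # severe has higher totals
})

test_that("permutation suite is reproducible under a fixed seed", {
  co <- smallCohort()
  ph <- phenotypes(co$fc)
  disc <- co$fc[, ph$group_assignment == "discovery"]
  discR <- residualizeFC(standardizeSubjects(disc))
  cfg <- pipelineConfig(n_permutations = 20, screening_k = 30)
  set.seed(42)
  a <- suppressWarnings(permutationSuite(discR, cfg = cfg,
                                         observedMode = "top_k"))
  set.seed(42)
  b <- suppressWarnings(permutationSuite(discR, cfg = cfg,
                                         observedMode = "top_k"))
  expect_identical(a$cca@nulls, b$cca@nulls)
  expect_identical(a$partition@labels, b$partition@labels)
})

test_that("zero permutations are rejected at config construction", {
  expect_error(pipelineConfig(n_permutations = 0), "strictly positive")
})
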