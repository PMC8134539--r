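test_that("edge-wise tests agree with the scalar kernel, with covariates", {
  co <- smallCohort()
  std <- standardizeSubjects(co$fc)
  ph <- phenotypes(std)
  idsA <- which(ph$group_assignment == "discovery")[1:20]
  idsB <- which(ph$group_assignment == "control")[1:25]
  cov <- ph[c(idsA, idsB), c("age", "sex")]
  tb <- groupwiseTests(std, idsA, idsB, covariates = cov)
  m <- fcMatrix(std)
  e <- tb$edge[5]
  ref <- twoSampleT(m[idsA, e], m[idsB, e], covariates = cov)
  row <- tb[tb$edge == e, ]
  expect_equal(row$t, ref$t, tolerance = 1e-10)
  expect_equal(row$cohens_d, ref$cohens_d, tolerance = 1e-10)
  expect_equal(row$p_two_tailed, ref$p_two_tailed, tolerance = 1e-10)
  expect_equal(row$direction, sign(row$t))
  expect_true(!is.unsorted(tb$p_two_tailed))
})

test_that("null comparisons yield (almost) no FDR discoveries", {
  set.seed(17)
  nsig <- replicate(8, {
    fc <- matrix(rnorm(60 * 120), 60, 120)
    x <- FCExperiment(fc, makeEdgeIndex(as.character(1:16)), stage = "fisher_z")
    sum(groupwiseTests(x, 1:30, 31:60, q = 0.05)$significant)
  })
  expect_lte(mean(nsig), 1)
})

test_that("planted severe-marker edges are recovered against controls", {
  rec <- vapply(1:5, function(s) {
    co <- smallCohort(30 + s)
    ph <- phenotypes(co$fc)
    std <- standardizeSubjects(co$fc)
    dc <- std[, ph$group_assignment %in% c("discovery", "control")]
    dcR <- residualizeFC(dc)
    phDC <- phenotypes(dcR)
    tl <- co$truth$true_subgroup_label[phDC$subject_id]
    sev <- which(!is.na(tl) & tl == "severe")
    ctl <- which(phDC$group_assignment == "control")
    tb <- groupwiseTests(dcR, sev, ctl, q = 0.05,
                         comparison = "severe_vs_control")
    hits <- tb$edge[tb$significant]
    mean(co$truth$severe_marker_edge_ids %in% hits)
  }, numeric(1))
  expect_gte(median(rec), 0.9)
})

test_that("splitting one population keeps the empirical FDR at the level", {
  set.seed(18)
  fdp <- replicate(30, {
    fc <- matrix(rnorm(50 * 100), 50, 100)
    x <- FCExperiment(fc, makeEdgeIndex(as.character(1:15))[1:100, ],
                      stage = "fisher_z")
    rej <- groupwiseTests(x, 1:25, 26:50, q = 0.05)$significant
    if (!any(rej)) 0 else 1     # all discoveries are false here
  })
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})

test_that("sign-aligned composites behave like signed row sums", {
  fc <- matrix(c(1, -2, 3, 0.5, 1, -1), 2, 3)
  x <- FCExperiment(fc, makeEdgeIndex(c("A", "B", "C")), stage = "fisher_z")
  expect_equal(unname(alignAndComposite(x, 1:3, c(1, 1, 1))), rowSums(fc))
  # single edge, sign -1, values (1, -2) -> (-1, 2)
  expect_equal(unname(alignAndComposite(x, 1, -1)), c(-1, 2))
  # negating an edge column and its sign leaves scores unchanged
  fc2 <- fc; fc2[, 2] <- -fc2[, 2]
  x2 <- FCExperiment(fc2, makeEdgeIndex(c("A", "B", "C")), stage = "fisher_z")
  expect_equal(alignAndComposite(x, 1:3, c(1, 1, -1)),
               alignAndComposite(x2, 1:3, c(1, -1, -1)))
  expect_error(alignAndComposite(x, integer(0), numeric(0)), "empty")
  expect_error(alignAndComposite(x, 1:2, c(1, 0.5)), "\\+1 or -1")
})

test_that("graded ordering is detected and absent under shuffles", {
  set.seed(19)
  n <- 60
  labels <- rep(c("severe", "mild", "control"), each = n)
  comp <- c(rnorm(n, 2), rnorm(n, 1), rnorm(n, 0))
  g <- gradedChangeTest(comp, labels)
  expect_true(g$graded)
  expect_gt(g$severe_vs_mild$t, 0)
  expect_gt(g$mild_vs_control$t, 0)

  hits <- sum(replicate(50, {
    gradedChangeTest(comp, sample(labels))$graded
  }))
  expect_lte(hits, 2)   # verdict rate ~ alpha^2 under independence

  # identical severe and mild composites: t exactly 0
  comp2 <- c(rep(c(1, 2, 3), n / 3 * 2), rnorm(n))
  g2 <- gradedChangeTest(comp2, labels)
  expect_equal(g2$severe_vs_mild$t, 0)
})

test_that("age bands partition with boundaries in the younger band", {
  age <- c(6, 11.9, 12, 12.1, 18, 18.5, 30)
  b <- ageBands(age)
  expect_equal(as.character(b),
               c("children", "children", "children", "adolescents",
                 "adolescents", "adults", "adults"))
  expect_false(anyNA(ageBands(runif(100, 6, 30))))
})

test_that("stratified reruns give comparable effects, skip tiny strata", {
  co <- smallCohort()
  ph <- phenotypes(co$fc)
  std <- standardizeSubjects(co$fc)
  tl <- co$truth$true_subgroup_label[ph$subject_id]
  sev <- which(!is.na(tl) & tl == "severe")
  ctl <- which(ph$group_assignment == "control")
  # median split on age: a homogeneous planted effect appears in both
  strata <- factor(ifelse(ph$age <= median(ph$age), "younger", "older"))
  out <- stratifiedRerun(std, sev, ctl, strata, q = 0.05)
  expect_setequal(names(out), c("younger", "older"))
  dmat <- attr(out, "cohens_d_by_stratum")
  marker <- co$truth$severe_marker_edge_ids
  expect_lt(mean(abs(dmat[marker, "younger"] - dmat[marker, "older"])), 0.8)
  expect_gt(mean(dmat[marker, "younger"]), 0)

  # low-motion filter expressed as a stratum: only low-FD subjects used
  lowfd <- factor(ifelse(ph$mean_fd <= 0.2, "low", "high"))
  out2 <- stratifiedRerun(std, sev, ctl, lowfd, q = 0.05)
  expect_true("low" %in% names(out2))

  tiny <- factor(c("rare", rep("common", ncol(std) - 1)))
  expect_warning(stratifiedRerun(std, sev, ctl, tiny, q = 0.05), "skipped")
})
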