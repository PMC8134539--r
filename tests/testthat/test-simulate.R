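test_that("cohort bookkeeping: group sizes, ADOS ranges, missingness", {
  co <- smallCohort()
  ph <- phenotypes(co$fc)
  expect_equal(as.integer(table(ph$group_assignment)[c("discovery",
                                                       "control",
                                                       "validation")]),
               c(120L, 140L, 12L))
  pat <- ph$diagnosis == "ASD"
  expect_true(all(ph$ados_comm[pat] >= 0 & ph$ados_comm[pat] <= 10))
  expect_true(all(ph$ados_social[pat] >= 0 & ph$ados_social[pat] <= 14))
  expect_true(all(ph$ados_total[pat] > 7))    # forced above threshold
  expect_true(all(is.na(ph$ados_comm[!pat]))) # controls carry no ADOS
  expect_true(all(is.na(ph$ados_rrb[ph$group_assignment == "validation"])))
  expect_true(all(!is.na(ph$ados_total[ph$group_assignment == "validation"])))
  expect_true(all(ph$age >= 6 & ph$age <= 30))
  expect_true(all(ph$full_iq >= 70))
  expect_true(all(ph$mean_fd <= 0.5))
})

test_that("ground truth is structured: disjoint edge sets, labels, latent", {
  co <- smallCohort()
  tr <- co$truth
  expect_length(tr$signal_edge_ids, co$params$n_signal_edges)
  expect_length(intersect(tr$signal_edge_ids, tr$severe_marker_edge_ids), 0)
  expect_length(intersect(tr$severe_marker_edge_ids,
                          tr$mild_marker_edge_ids), 0)
  expect_setequal(unique(tr$true_subgroup_label), c("severe", "mild"))
  expect_length(tr$true_subgroup_label, 120)
  expect_equal(dim(tr$true_latent_scores), c(272, 3))
  expect_equal(tr$implied_canonical_correlations,
               impliedCanCor(co$params))
  expect_true(all(diff(tr$implied_canonical_correlations) <= 0))
  # without a severity mixture the implied values are the per-dimension
  # trait reliabilities themselves
  p0 <- simParams(subgroup_separation = 0)
  expect_equal(impliedCanCor(p0),
               sort(p0$canonical_strength, decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  p <- simParams(n_discovery = 30, n_control = 20, n_validation = 5,
                 n_roi = 10, n_signal_edges = 8,
                 n_severe_marker_edges = 3, n_mild_marker_edges = 3)
  a <- simulateCohort(p, seed = 5)
  b <- simulateCohort(p, seed = 5)
  c <- simulateCohort(p, seed = 6)
  expect_identical(fcMatrix(a$fc), fcMatrix(b$fc))
  expect_identical(phenotypes(a$fc), phenotypes(b$fc))
  expect_false(identical(fcMatrix(a$fc), fcMatrix(c$fc)))
})

test_that("parameter validation catches impossible requests", {
  expect_error(simParams(n_discovery = 0), "positive")
  expect_error(simParams(canonical_strength = c(1, 0.8, 0.7)), "\\[0, 1\\)")
  expect_error(simParams(canonical_strength = c(0.8, 0.7)), "latent_dim")
  expect_error(simParams(n_roi = 5, n_signal_edges = 100), "exceed")
  expect_error(simParams(mild_marker_pattern = c(mild = 0.2, severe = 0.5)),
               "mild >= severe")
})

test_that("null cohorts select about 0.5% of edges at threshold 0.005", {
  # zero planted effects: the screening count is Binomial(E, ~0.005)
  p <- simParams(n_discovery = 120, n_control = 5, n_validation = 5,
                 n_sites = 2, n_roi = 40, n_signal_edges = 1,
                 n_severe_marker_edges = 1, n_mild_marker_edges = 1,
                 canonical_strength = c(0, 0, 0), subgroup_separation = 0,
                 edge_signal = 0, mild_marker_pattern = c(mild = 0, severe = 0),
                 site_sd = 0,
                 covariate_effects = c(age = 0, iq = 0, sex = 0, fd = 0))
  counts <- vapply(1:10, function(s) {
    co <- simulateCohort(p, seed = 100 + s)
    ph <- phenotypes(co$fc)
    disc <- co$fc[, ph$group_assignment == "discovery"]
    Y <- phenotypes(disc)[, c("ados_comm", "ados_social", "ados_rrb")]
    spearmanScreen(disc, Y, threshold = 0.005)$k
  }, numeric(1))
  E <- 40 * 39 / 2
  # min-p over 3 correlated subscales: per-edge rate is below 3*0.005;
  # check the mean count against the binomial band around 0.005*E per
  # subscale-adjusted expectation, within 3 SDs of the 10-seed mean
  expect_gt(mean(counts), 0)
  p_eff <- mean(counts) / E
  expect_lt(p_eff, 3 * 0.005)
  se <- sqrt(p_eff * (1 - p_eff) * E / 10) # SD of the mean count
  expect_lt(abs(mean(counts) - p_eff * E), 3 * se + 1e-9)
  # and each subscale's own rejection rate is near the nominal 0.005
  co <- simulateCohort(p, seed = 200)
  ph <- phenotypes(co$fc)
  disc <- co$fc[, ph$group_assignment == "discovery"]
  Y <- phenotypes(disc)[, c("ados_comm", "ados_social", "ados_rrb")]
  scr <- spearmanScreen(disc, Y, threshold = 0.005)
  rate <- mean(scr$p < 0.005)
  expect_lt(abs(rate - 0.005), 3 * sqrt(0.005 * 0.995 / (3 * E)))
})

test_that("implied canonical correlations are recovered by the CCA stage", {
  # study-sized cohorts; the in-sample canonical correlations are
  # inflated by roughly (1 - R^2) k/n, so recovery is assessed on the
  # null-adjusted scale: R_adj^2 = (R^2 - mean R_null^2)/(1 - mean
  # R_null^2) with a fixed-selection permutation null, mirroring the
  # adjusted eta^2.  Per-component medians over seeds must sit within
  # 0.1 of the closed-form implied values.
  imp <- impliedCanCor(simParams())
  adj <- vapply(1:8, function(s) {
    co <- simulateCohort(simParams(), seed = 40 + s)
    ph <- phenotypes(co$fc)
    disc <- co$fc[, ph$group_assignment == "discovery"]
    discR <- residualizeFC(standardizeSubjects(disc))
    m <- fcMatrix(discR)
    Y <- as.matrix(phenotypes(discR)[, c("ados_comm", "ados_social",
                                         "ados_rrb")])
    X <- m[, spearmanScreen(m, Y, k_mode = "top_k", k = 100)$selected]
    fit <- fitCCA(X, Y)
    set.seed(140 + s)
    nullR2 <- replicate(50, fitCCA(X, Y[sample.int(nrow(Y)), ])@canCor^2)
    mn <- rowMeans(nullR2)
    sqrt(pmax(0, (fit@canCor^2 - mn) / (1 - mn)))
  }, numeric(3))
  expect_lt(max(abs(apply(adj, 1, median) - imp)), 0.1)
})

test_that("the latent severity mixture orders ADOS totals by subgroup", {
  co <- smallCohort()
  ph <- phenotypes(co$fc)
  disc <- ph$group_assignment == "discovery"
  lab <- co$truth$true_subgroup_label[ph$subject_id[disc]]
  tot <- ph$ados_total[disc]
  expect_gt(mean(tot[lab == "severe"]), mean(tot[lab == "mild"]))
})
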