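# shared helpers: adjusted Rand index, a brute-force CCA oracle, toy
# phenotype tables and cached scaled-down cohorts

adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# independent CCA oracle: direct eigendecomposition of the canonical
# correlation matrix Sxx^-1 Sxy Syy^-1 Syx (full-rank instances only)
bruteCCA <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  Sxx <- crossprod(X); Syy <- crossprod(Y)
  Sxy <- crossprod(X, Y)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev[seq_len(ncol(Y))], 1), 0))
}

toyPheno <- function() {
  data.frame(
    subject_id = paste0("S", 1:6),
    site = rep("siteA", 6),
    diagnosis = c(rep("ASD", 4), "control", "control"),
    age = c(10, 12, 20, 25, 15, 8),
    sex = c("male", "male", "female", "male", "male", "female"),
    full_iq = c(100, 110, 95, 120, 105, 99),
    mean_fd = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.1),
    ados_comm = c(4, 5, 3, 6, NA, NA),
    ados_social = c(7, 8, 6, 9, NA, NA),
    ados_rrb = c(2, 3, 1, 4, NA, NA),
    stringsAsFactors = FALSE
  )
}

# small planted cohort reused across test files (cached per session)
.fcstrat_cache <- new.env(parent = emptyenv())

smallCohort <- function(seed = 11) {
  key <- paste0("cohort", seed)
  if (is.null(.fcstrat_cache[[key]])) {
    p <- simParams(n_discovery = 120, n_control = 140, n_validation = 12,
                   n_sites = 4, n_roi = 24, n_signal_edges = 40,
                   n_severe_marker_edges = 12, n_mild_marker_edges = 12)
    .fcstrat_cache[[key]] <- simulateCohort(p, seed = seed)
  }
  .fcstrat_cache[[key]]
}

smallSuite <- function(seed = 11, B = 60) {
  key <- paste0("suite", seed, "_", B)
  if (is.null(.fcstrat_cache[[key]])) {
    co <- smallCohort(seed)
    ph <- phenotypes(co$fc)
    disc <- co$fc[, ph$group_assignment == "discovery"]
    discR <- residualizeFC(standardizeSubjects(disc))
    cfg <- pipelineConfig(n_permutations = B, screening_k = 30)
    set.seed(seed + 1)
    .fcstrat_cache[[key]] <- suppressWarnings(
      permutationSuite(discR, cfg = cfg, observedMode = "top_k"))
  }
  .fcstrat_cache[[key]]
}
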