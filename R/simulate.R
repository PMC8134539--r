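#' Simulation parameters for a synthetic multi-site cohort
#'
#' Defaults emulate the structure of the multi-site resting-state
#' cohort the pipeline targets: group sizes 260 / 574 / 29
#' (discovery / control / validation), a 94-region parcellation (4,371
#' edges), a 3-dimensional latent clinical trait driving both a subset
#' of edges and the three ADOS subscales, two planted severity
#' subgroups among discovery patients, additive site offsets, and
#' linear covariate effects of age, IQ, sex and head motion on edges.
#'
#' @param n_discovery,n_control,n_validation group sizes.
#' @param n_sites number of acquisition sites for discovery/control
#'   subjects; validation subjects are drawn from
#'   `n_validation_sites` additional, disjoint sites.
#' @param n_validation_sites sites reserved for the validation group.
#' @param n_roi number of ROIs; edges = `n_roi (n_roi - 1) / 2`.
#' @param n_timepoints nominal time-series length (used only when time
#'   series are emitted).
#' @param latent_dim latent trait dimension (3: one per ADOS subscale).
#' @param n_signal_edges edges loading on the latent trait.
#' @param canonical_strength per-dimension latent-to-subscale loading
#'   in `[0, 1)`; equals the implied canonical correlation when the
#'   edge side recovers the latent scores well.
#' @param subgroup_separation Euclidean gap between the severe and
#'   mild subgroup centers in latent space (the centers lie along the
#'   equi-loading severity direction), and the standardized shift
#'   applied to severe subjects on the severe-marker edges (SD units
#'   of the edge noise).
#' @param latent_within_sd within-subgroup SD of each latent
#'   dimension (isotropic mixture-component spread).
#' @param severe_frac fraction of discovery patients planted severe.
#' @param n_severe_marker_edges,n_mild_marker_edges marker-set sizes.
#' @param mild_marker_pattern named shifts (`mild`, `severe`) on
#'   mild-marker edges realizing mild > severe > control.
#' @param edge_signal loading magnitude of the latent trait on signal
#'   edges.
#' @param site_sd SD of the additive per-site, per-edge offsets.
#' @param noise_sd SD of the edge-level Gaussian noise.
#' @param covariate_effects named scales (`age`, `iq`, `sex`, `fd`) of
#'   the linear covariate loadings on edges.
#' @param male_frac_asd,male_frac_control male fractions.
#' @return validated list of class `SimParams`.
#' @export
simParams <- function(n_discovery = 260, n_control = 574,
                      n_validation = 29,
                      n_sites = 8, n_validation_sites = 2,
                      n_roi = 94, n_timepoints = 200, latent_dim = 3,
                      n_signal_edges = 100,
                      canonical_strength = c(0.8, 0.8, 0.7),
                      subgroup_separation = 3, latent_within_sd = 0.3,
                      severe_frac = 0.35,
                      n_severe_marker_edges = 20,
                      n_mild_marker_edges = 20,
                      mild_marker_pattern = c(mild = 0.8, severe = 0.4),
                      edge_signal = 0.7, site_sd = 0.3, noise_sd = 1,
                      covariate_effects = c(age = 0.02, iq = 0.005,
                                            sex = 0.2, fd = 0.8),
                      male_frac_asd = 0.9, male_frac_control = 0.7) {
  p <- as.list(environment())
  counts <- c(p$n_discovery, p$n_control, p$n_validation, p$n_sites,
              p$n_roi, p$latent_dim, p$n_signal_edges)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (any(p$canonical_strength < 0) || any(p$canonical_strength >= 1))
    stop("canonical_strength entries must lie in [0, 1)")
  if (length(p$canonical_strength) != p$latent_dim)
    stop("canonical_strength must have latent_dim entries")
  n_edges <- p$n_roi * (p$n_roi - 1) / 2
  if (p$n_signal_edges + p$n_severe_marker_edges +
      p$n_mild_marker_edges > n_edges)
    stop("edge sets exceed the number of available edges")
  if (p$mild_marker_pattern["mild"] < p$mild_marker_pattern["severe"])
    stop("mild_marker_pattern must satisfy mild >= severe")
  structure(p, class = "SimParams")
}

# latent -> noisy trait with target correlation a; a = 0 gives pure noise
.traitWithCor <- function(z, a) {
  if (a <= 0) return(stats::rnorm(length(z)))
  z + stats::sd(z) * sqrt(1 - a^2) / a * stats::rnorm(length(z))
}

.subscale <- function(raw, center, slope, lo, hi) {
  round(pmin(pmax(center + slope * as.numeric(scale(raw)), lo), hi))
}

#' Simulate a multi-site cohort with planted structure
#'
#' Draws covariates within the inclusion bounds, latent clinical trait
#' scores, ADOS subscales as rounded/clipped monotone functions of the
#' latent trait (total = Communication + Social forced above 7 for
#' patients by redrawing the subscale noise), and Fisher-z-scale edge
#' values
#' `baseline + latent loadings (signal edges) + subgroup/marker shifts +
#' site offset + covariate effects + Gaussian noise`.
#' Controls receive neither ADOS scores nor patient shifts.
#'
#' @param params a [simParams()] object.
#' @param seed integer RNG seed (one seed determines the whole cohort).
#' @return list with `fc` (an [FCExperiment-class] at stage
#'   `fisher_z`, phenotypes in `colData`) and `truth` (signal /
#'   severe-marker / mild-marker edge labels, per-discovery-subject
#'   subgroup labels, latent scores, implied canonical correlations).
#' @export
simulateCohort <- function(params = simParams(), seed = 1) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(seed)
  p <- params
  nD <- p$n_discovery; nC <- p$n_control; nV <- p$n_validation
  n <- nD + nC + nV
  grp <- rep(c("discovery", "control", "validation"), c(nD, nC, nV))
  asd <- grp != "control"
  ids <- sprintf("S%04d", seq_len(n))

  main_sites <- sprintf("site%02d", seq_len(p$n_sites))
  val_sites <- sprintf("vsite%02d", seq_len(p$n_validation_sites))
  site <- character(n)
  site[grp != "validation"] <- sample(main_sites, nD + nC, replace = TRUE)
  site[grp == "validation"] <- sample(val_sites, nV, replace = TRUE)

  age <- pmin(pmax(stats::rnorm(n, 15, 5), 6), 30)
  full_iq <- pmin(pmax(stats::rnorm(n, ifelse(asd, 105, 114),
                                    ifelse(asd, 16, 13)), 70), 160)
  male_p <- ifelse(asd, p$male_frac_asd, p$male_frac_control)
  sex <- ifelse(stats::rbinom(n, 1, male_p) == 1, "male", "female")
  mean_fd <- 0.5 * stats::rbeta(n, 2, 5)

  # latent clinical trait; zero for controls.  Patients form a
  # two-component severity mixture: subgroup centers lie
  # subgroup_separation apart along the equi-loading direction of the
  # latent space (severe patients are higher on every trait
  # dimension), with isotropic within-subgroup spread latent_within_sd
  # per dimension.  Centers are mean-zero over patients.
  subgroup <- rep(NA_character_, n)
  subgroup[asd] <- ifelse(stats::runif(sum(asd)) < p$severe_frac,
                          "severe", "mild")
  sev <- !is.na(subgroup) & subgroup == "severe"
  mld <- !is.na(subgroup) & subgroup == "mild"
  gap_d <- p$subgroup_separation / sqrt(p$latent_dim)
  ctr <- gap_d * c(severe = 1 - p$severe_frac, mild = -p$severe_frac)
  z <- matrix(0, n, p$latent_dim)
  z[asd, ] <- stats::rnorm(sum(asd) * p$latent_dim,
                           sd = p$latent_within_sd) +
    ifelse(sev[asd], ctr["severe"], ctr["mild"])

  # ADOS subscales from the latent trait, patients only
  pat <- which(asd)
  a <- p$canonical_strength
  comm <- social <- rrb <- rep(NA_real_, n)
  draw <- function() {
    t1 <- .traitWithCor(z[pat, 1], a[1])
    t2 <- .traitWithCor(z[pat, 2], a[2])
    t3 <- .traitWithCor(z[pat, 3], a[3])
    list(comm = .subscale(t1, 4.5, 2, 0, 10),
         social = .subscale(t2, 7.5, 2.5, 0, 14),
         rrb = .subscale(t3, 3, 1.5, 0, 8))
  }
  s <- draw()
  for (i in seq_len(200)) {
    low <- s$comm + s$social <= 7
    if (!any(low)) break
    s2 <- draw()
    s$comm[low] <- s2$comm[low]; s$social[low] <- s2$social[low]
    s$rrb[low] <- s2$rrb[low]
  }
  if (any(s$comm + s$social <= 7))
    stop("could not realize ADOS totals > 7; increase effect scale")
  comm[pat] <- s$comm; social[pat] <- s$social; rrb[pat] <- s$rrb

  # edge machinery
  n_edges <- p$n_roi * (p$n_roi - 1) / 2
  idx <- makeEdgeIndex(sprintf("ROI%03d", seq_len(p$n_roi)))
  picks <- sample.int(n_edges,
                      p$n_signal_edges + p$n_severe_marker_edges +
                        p$n_mild_marker_edges)
  sig <- picks[seq_len(p$n_signal_edges)]
  sevm <- picks[p$n_signal_edges + seq_len(p$n_severe_marker_edges)]
  mldm <- picks[p$n_signal_edges + p$n_severe_marker_edges +
                  seq_len(p$n_mild_marker_edges)]

  fc <- matrix(stats::rnorm(n * n_edges, sd = p$noise_sd), n, n_edges)
  fc <- sweep(fc, 2, stats::rnorm(n_edges, 0, 0.6), "+")  # edge baselines

  # latent loadings on signal edges: dimension cycled, sign alternating
  dim_of <- rep_len(seq_len(p$latent_dim), p$n_signal_edges)
  sgn <- rep_len(c(1, -1), p$n_signal_edges)
  fc[, sig] <- fc[, sig] +
    z[, dim_of, drop = FALSE] * rep(sgn * p$edge_signal, each = n)

  fc[sev, sevm] <- fc[sev, sevm] + p$subgroup_separation
  fc[mld, mldm] <- fc[mld, mldm] + p$mild_marker_pattern[["mild"]]
  fc[sev, mldm] <- fc[sev, mldm] + p$mild_marker_pattern[["severe"]]

  all_sites <- c(main_sites, val_sites)
  site_off <- matrix(stats::rnorm(length(all_sites) * n_edges,
                                  sd = p$site_sd),
                     length(all_sites), n_edges)
  fc <- fc + site_off[match(site, all_sites), , drop = FALSE]

  covs <- cbind(age = age, iq = full_iq, sex = as.numeric(sex == "male"),
                fd = mean_fd)
  covs <- scale(covs)
  eff <- p$covariate_effects[colnames(covs)]
  U <- matrix(stats::rnorm(ncol(covs) * n_edges), ncol(covs), n_edges)
  fc <- fc + covs %*% (U * eff)

  pheno <- data.frame(
    subject_id = ids, site = site,
    diagnosis = ifelse(asd, "ASD", "control"),
    age = age, sex = sex, full_iq = full_iq, mean_fd = mean_fd,
    ados_comm = comm, ados_social = social, ados_rrb = rrb,
    ados_total = computeAdosTotal(comm, social),
    group_assignment = grp,
    stringsAsFactors = FALSE
  )
  # the validation group is defined by a missing subscale (total known)
  vsel <- grp == "validation"
  pheno$ados_rrb[vsel] <- NA

  rownames(fc) <- ids
  x <- FCExperiment(fc, idx, pheno, stage = "fisher_z")
  truth <- list(
    implied_canonical_correlations = impliedCanCor(p),
    signal_edge_ids = idx$label[sig],
    severe_marker_edge_ids = idx$label[sevm],
    mild_marker_edge_ids = idx$label[mldm],
    true_subgroup_label = stats::setNames(subgroup[grp == "discovery"],
                                          ids[grp == "discovery"]),
    true_latent_scores = z
  )
  list(fc = x, truth = truth, params = p, seed = seed)
}

#' Population canonical correlations implied by simulation parameters
#'
#' Closed-form canonical correlations between the latent trait space
#' and the three ADOS subscale variables under the generative model,
#' assuming the edge side recovers the latent scores (accurate once
#' enough signal edges load on each dimension).  The severity mixture
#' makes the latent dimensions correlated, so these differ from
#' `canonical_strength` whenever `subgroup_separation > 0`: the leading
#' correlation rises (severity is shared variance) and the trailing
#' ones fall.  Subscale rounding is ignored.
#'
#' @param params a [simParams()] object.
#' @return numeric vector of implied canonical correlations,
#'   non-increasing.
#' @export
impliedCanCor <- function(params) {
  p <- params
  a <- p$canonical_strength
  if (all(a <= 0)) return(rep(0, p$latent_dim))
  f <- p$severe_frac
  gap_d <- p$subgroup_separation / sqrt(p$latent_dim)
  between <- f * (1 - f) * gap_d^2
  Sz <- matrix(between, p$latent_dim, p$latent_dim)
  diag(Sz) <- between + p$latent_within_sd^2
  # y_d = a_d z_d + sd(z_d) sqrt(1 - a_d^2)/a_d * eps_d
  Da <- diag(a, p$latent_dim)
  s2 <- ifelse(a > 0, diag(Sz) * (1 - a^2), 1)
  Szy <- Sz %*% Da
  Sy <- Da %*% Sz %*% Da + diag(s2, p$latent_dim)
  M <- solve(Sz, Szy) %*% solve(Sy, t(Szy))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev, 1), 0))
}

#' Simulate an ROI time series with a prescribed covariance
#'
#' Draws `T` i.i.d. multivariate normal timepoints whose population
#' covariance equals `cov`, via the symmetric eigenvalue square root.
#'
#' @param cov symmetric positive-semidefinite R x R covariance matrix.
#' @param T number of timepoints (at least 3; the downstream Pearson
#'   correlation is undefined below that).
#' @param seed optional RNG seed.
#' @return T x R matrix, columns named after `cov` rows.
#' @export
simulateTimeSeriesFromCov <- function(cov, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) > 1e-8)
    stop("covariance must be symmetric")
  if (T < 3) stop("need at least 3 timepoints for a correlation")
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("covariance is not positive semi-definite")
  sq <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  ts <- matrix(stats::rnorm(T * nrow(cov)), T) %*% sq
  colnames(ts) <- rownames(cov)
  ts
}

#' Emit per-subject time series consistent with a cohort's FC values
#'
#' Maps each subject's Fisher-z edge vector to a correlation matrix via
#' `tanh(scale * fc)`, projects to the nearest positive-definite
#' correlation matrix, and draws `T` timepoints from it.  As `T` grows
#' the re-estimated Fisher-z values converge to `scale * fc`, a linear
#' rescaling, so rank-based screening on the re-estimated values
#' converges to screening on the direct values.
#'
#' @param cohort list from [simulateCohort()] (keep `n_roi` small; the
#'   nearest-PD projection is per subject).
#' @param T timepoints per subject.
#' @param scale shrink factor keeping `tanh` correlations away from
#'   +/-1.
#' @param seed RNG seed.
#' @return named list of T x R time-series matrices.
#' @export
simulateTimeSeriesCohort <- function(cohort, T = 200, scale = 0.25,
                                     seed = 1) {
  set.seed(seed)
  m <- fcMatrix(cohort$fc)
  idx <- edgeIndex(cohort$fc)
  r <- max(idx$roi_b)
  labs <- sprintf("ROI%03d", seq_len(r))
  out <- vector("list", nrow(m))
  names(out) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    cm <- devectorizeUpper(tanh(scale * m[i, ]), idx, diag = 1)
    dimnames(cm) <- list(labs, labs)
    pd <- as.matrix(Matrix::nearPD(cm, corr = TRUE)$mat)
    out[[i]] <- simulateTimeSeriesFromCov(pd, T)
  }
  out
}
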