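#' Simulate a random rooted feature phylogeny
#'
#' A stand-in reference tree for phylogenetic diversity metrics: a random
#' rooted bifurcating topology over all features with i.i.d. exponential
#' branch lengths (mean 0.1).
#'
#' @param n_features number of leaves (>= 2); labels are `feature_ids(n)`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A rooted `phylo` object with `n_features` leaves.
#' @export
simulate_tree <- function(n_features, seed) {
  if (n_features < 2) stop("n_features must be >= 2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tr <- ape::rtree(n_features, br = function(n) stats::rexp(n, rate = 10))
  tr$tip.label <- feature_ids(n_features)[sample.int(n_features)]
  validate_tree(tr)
}

#' Feature identifiers used by the simulators
#' @param n number of features.
#' @return character vector `F001 ... Fn`.
#' @export
feature_ids <- function(n) sprintf("F%03d", seq_len(n))

#' Configuration for the paired intervention simulator
#'
#' Defaults define the package's reference recovery scenario, mirroring the
#' geometry of a seven-cohort resistant-starch meta-analysis: 7 studies of 30
#' subjects, 200 features, a planted 22-feature module depleted by
#' `delta = -0.8` on the log scale at the endpoint.
#'
#' @param n_studies number of paired cohorts.
#' @param subjects_per_study integer vector of length `n_studies`.
#' @param n_features number of features.
#' @param module_features indices (into `1:n_features`) of the planted
#'   depleted module.
#' @param delta log-scale intervention effect applied to module features at
#'   the endpoint (negative = depletion); scalar or one value per module
#'   feature.
#' @param sigma_study SD of study-level per-feature log-abundance offsets.
#' @param sigma_subject SD of subject-level offsets, shared across the
#'   subject's two timepoints (so strict pairing removes them).
#' @param sigma_noise residual per-sample log-scale SD.
#' @param sigma_beta SD of the baseline per-feature log-abundances (spread of
#'   the community's rank-abundance curve).
#' @param depth_range integer (min, max) sequencing depth, sampled uniformly.
#' @param seed integer seed.
#' @return A `paired_sim_config` list.
#' @export
paired_sim_config <- function(n_studies = 7,
                              subjects_per_study = rep(30, n_studies),
                              n_features = 200,
                              module_features = 1:22,
                              delta = -0.8,
                              sigma_study = 0.5,
                              sigma_subject = 1.0,
                              sigma_noise = 0.5,
                              sigma_beta = 1.0,
                              depth_range = c(5000, 20000),
                              seed = 1) {
  stopifnot(length(subjects_per_study) == n_studies,
            all(module_features >= 1), all(module_features <= n_features),
            sigma_study >= 0, sigma_subject >= 0, sigma_noise >= 0,
            depth_range[1] >= 1, depth_range[1] <= depth_range[2])
  if (length(delta) == 1) delta <- rep(delta, length(module_features))
  stopifnot(length(delta) == length(module_features))
  structure(list(n_studies = n_studies,
                 subjects_per_study = as.integer(subjects_per_study),
                 n_features = as.integer(n_features),
                 module_features = as.integer(module_features),
                 delta = delta, sigma_study = sigma_study,
                 sigma_subject = sigma_subject, sigma_noise = sigma_noise,
                 sigma_beta = sigma_beta,
                 depth_range = as.integer(depth_range), seed = as.integer(seed)),
            class = "paired_sim_config")
}

# multinomial draw from softmax(eta) at the given depth
.softmax_multinom <- function(eta, depth) {
  w <- exp(eta - max(eta))
  as.numeric(stats::rmultinom(1, size = depth, prob = w / sum(w)))
}

#' Simulate multi-cohort paired intervention data with known ground truth
#'
#' Logistic-normal multinomial generator. For subject j of study i, feature k,
#' timepoint t in {0 = baseline, 1 = endpoint} the latent log-weight is
#' `eta = beta_k + u_ik + s_ijk + t * delta_k + eps` with
#' `u ~ N(0, sigma_study^2)` (per study x feature, shared across timepoints),
#' `s ~ N(0, sigma_subject^2)` (per subject x feature, shared across the
#' subject's two samples) and `eps ~ N(0, sigma_noise^2)` independent per
#' sample. Counts are multinomial at a uniformly drawn depth. The CLR of the
#' latent weights is exactly the additive structure the downstream
#' random-intercept model assumes, so parameter recovery is meaningful.
#'
#' @param cfg a [paired_sim_config()].
#' @return list with `cohorts` (a [cohort_set()], paired metadata) and
#'   `truth` (module feature ids, per-feature true delta, realized per-study
#'   offsets).
#' @export
simulate_paired_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "paired_sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  p <- cfg$n_features
  fid <- feature_ids(p)
  delta_full <- stats::setNames(numeric(p), fid)
  delta_full[cfg$module_features] <- cfg$delta
  beta <- stats::rnorm(p, 0, cfg$sigma_beta)
  tables <- list(); metadata <- list(); offsets <- list()
  for (i in seq_len(cfg$n_studies)) {
    sid <- sprintf("study%02d", i)
    u <- stats::rnorm(p, 0, cfg$sigma_study)
    offsets[[sid]] <- stats::setNames(u, fid)
    nsub <- cfg$subjects_per_study[i]
    counts <- matrix(0, 2 * nsub, p,
                     dimnames = list(character(2 * nsub), fid))
    md <- vector("list", 2 * nsub)
    for (j in seq_len(nsub)) {
      s <- stats::rnorm(p, 0, cfg$sigma_subject)
      subj <- sprintf("%s_subj%03d", sid, j)
      for (t in 0:1) {
        eta <- beta + u + s + t * delta_full +
          stats::rnorm(p, 0, cfg$sigma_noise)
        depth <- sample(cfg$depth_range[1]:cfg$depth_range[2], 1)
        row <- 2 * (j - 1) + t + 1
        counts[row, ] <- .softmax_multinom(eta, depth)
        samp <- sprintf("%s_t%d", subj, t)
        rownames(counts)[row] <- samp
        md[[row]] <- data.frame(sample_id = samp, study_id = sid,
                                subject_id = subj,
                                timepoint = if (t == 0) "baseline" else "endpoint",
                                stringsAsFactors = FALSE)
      }
    }
    tables[[sid]] <- feature_table(counts)
    metadata[[sid]] <- sample_metadata(do.call(rbind, md), "paired")
  }
  truth <- list(module_features = fid[cfg$module_features],
                delta = delta_full, beta = stats::setNames(beta, fid),
                study_offsets = offsets)
  list(cohorts = cohort_set(tables, metadata), truth = truth)
}

#' Configuration for the cross-sectional disease-cohort simulator
#'
#' Defaults emulate a multi-study HC/CD/UC validation panel with
#' diagnosis-dependent enrichment of the planted module
#' (CD +1.0 > UC +0.4 > HC 0 on the latent log scale).
#'
#' @param n_studies number of cross-sectional cohorts.
#' @param group_sizes integer matrix `n_studies x 3` (columns HC, CD, UC);
#'   zeros allowed (a study may lack a diagnosis group).
#' @param n_features,module_features,sigma_study,sigma_noise,sigma_beta,depth_range,seed
#'   as in [paired_sim_config()].
#' @param diagnosis_shift named numeric: latent log-scale enrichment of module
#'   features per diagnosis.
#' @return A `cross_sectional_sim_config` list.
#' @export
cross_sectional_sim_config <- function(n_studies = 4,
                                       group_sizes = matrix(50, n_studies, 3,
                                         dimnames = list(NULL, c("HC", "CD", "UC"))),
                                       n_features = 200,
                                       module_features = 1:22,
                                       diagnosis_shift = c(HC = 0, CD = 1.0, UC = 0.4),
                                       sigma_study = 0.5,
                                       sigma_noise = 0.5,
                                       sigma_beta = 1.0,
                                       depth_range = c(5000, 20000),
                                       seed = 1) {
  group_sizes <- as.matrix(group_sizes)
  colnames(group_sizes) <- c("HC", "CD", "UC")
  stopifnot(nrow(group_sizes) == n_studies, all(group_sizes >= 0),
            all(is.finite(diagnosis_shift)),
            all(c("HC", "CD", "UC") %in% names(diagnosis_shift)))
  structure(list(n_studies = n_studies, group_sizes = group_sizes,
                 n_features = as.integer(n_features),
                 module_features = as.integer(module_features),
                 diagnosis_shift = diagnosis_shift[c("HC", "CD", "UC")],
                 sigma_study = sigma_study, sigma_noise = sigma_noise,
                 sigma_beta = sigma_beta,
                 depth_range = as.integer(depth_range), seed = as.integer(seed)),
            class = "cross_sectional_sim_config")
}

#' Simulate cross-sectional disease cohorts with a planted enriched module
#'
#' Same logistic-normal multinomial scheme as [simulate_paired_cohorts()],
#' with the per-diagnosis shift added to module features; study offsets are
#' shared across diagnosis groups within a study.
#'
#' @param cfg a [cross_sectional_sim_config()].
#' @return list with `cohorts` (cross-sectional [cohort_set()]) and `truth`.
#' @export
simulate_ibd_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "cross_sectional_sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  p <- cfg$n_features
  fid <- feature_ids(p)
  is_mod <- seq_len(p) %in% cfg$module_features
  beta <- stats::rnorm(p, 0, cfg$sigma_beta)
  tables <- list(); metadata <- list(); offsets <- list()
  for (i in seq_len(cfg$n_studies)) {
    sid <- sprintf("ibd%02d", i)
    u <- stats::rnorm(p, 0, cfg$sigma_study)
    offsets[[sid]] <- stats::setNames(u, fid)
    rows <- list(); md <- list(); n_done <- 0
    for (dg in c("HC", "CD", "UC")) {
      ng <- cfg$group_sizes[i, dg]
      if (ng == 0) next
      shift <- cfg$diagnosis_shift[[dg]] * is_mod
      for (j in seq_len(ng)) {
        eta <- beta + u + shift + stats::rnorm(p, 0, cfg$sigma_noise)
        depth <- sample(cfg$depth_range[1]:cfg$depth_range[2], 1)
        n_done <- n_done + 1
        samp <- sprintf("%s_%s_%03d", sid, dg, j)
        rows[[n_done]] <- .softmax_multinom(eta, depth)
        names(rows)[n_done] <- samp
        md[[n_done]] <- data.frame(sample_id = samp, study_id = sid,
                                   subject_id = samp, diagnosis = dg,
                                   stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- fid
    tables[[sid]] <- feature_table(counts)
    metadata[[sid]] <- sample_metadata(do.call(rbind, md), "cross_sectional")
  }
  truth <- list(module_features = fid[cfg$module_features],
                diagnosis_shift = cfg$diagnosis_shift,
                beta = stats::setNames(beta, fid), study_offsets = offsets)
  list(cohorts = cohort_set(tables, metadata), truth = truth)
}
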