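# one SparCC pass: variation matrix -> basis variances -> correlations,
# with iterative exclusion of the strongest pair
.sparcc_once <- function(frac, n_exclusion_iters, exclusion_threshold) {
  L <- log(frac)
  C <- stats::cov(L)
  D <- ncol(C)
  vv <- diag(C)
  Tmat <- outer(vv, vv, "+") - 2 * C       # t_ij = var(log x_i/x_j)
  incl <- matrix(TRUE, D, D); diag(incl) <- FALSE
  solve_r <- function() {
    A <- incl * 1
    diag(A) <- rowSums(incl)
    Ti <- rowSums(Tmat * incl)
    omega2 <- tryCatch(solve(A, Ti), error = function(e) rep(NA_real_, D))
    bad <- !is.finite(omega2) | omega2 <= 0
    if (any(bad))
      warning(sum(bad), " feature(s) with non-positive basis variance; ",
              "their correlations set to NA")
    omega <- sqrt(ifelse(bad, NA_real_, omega2))
    r <- (outer(omega2, omega2, "+") - Tmat) / (2 * outer(omega, omega))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  r <- solve_r()
  for (it in seq_len(n_exclusion_iters)) {
    cand <- abs(r)
    cand[!incl | !is.finite(cand)] <- -Inf
    m <- which.max(cand)
    if (!is.finite(cand[m]) || cand[m] < exclusion_threshold) break
    ij <- arrayInd(m, dim(cand))
    incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
    r <- solve_r()
  }
  r
}

#' SparCC compositional correlation inference
#'
#' Estimates basis correlations from compositional counts: per resample,
#' per-sample fractions are drawn from a Dirichlet with parameters
#' `counts + 1`; log-ratio variances `t_ab = var(log x_a/x_b)` are computed
#' and the basis variances solved for under the sparsity assumption; the most
#' strongly correlated pair is iteratively excluded and the system re-solved
#' (up to `n_exclusion_iters` times or until the strongest remaining
#' candidate falls below `exclusion_threshold`). The final correlation matrix
#' is the elementwise median over resamples, clipped to \[-1, 1\].
#'
#' Features detected in fewer than 10% of samples are excluded before
#' estimation (pairwise correlations are only meaningful for reasonably
#' prevalent features).
#'
#' @param t `feature_table` with >= 4 features and >= 10 samples.
#' @param n_resamples Dirichlet resamples (default 20).
#' @param n_exclusion_iters maximum strong-pair exclusions per resample.
#' @param exclusion_threshold stop excluding when max candidate |r| is below
#'   this.
#' @param seed integer seed.
#' @param min_prevalence prevalence floor for included features.
#' @return A `correlation_network`: `r` (symmetric, unit diagonal), `p`
#'   (NULL until [permutation_pvalues()]), `feature_ids`.
#' @export
sparcc <- function(t, n_resamples = 20, n_exclusion_iters = 10,
                   exclusion_threshold = 0.1, seed = 1,
                   min_prevalence = 0.10) {
  counts <- unclass(t)
  keep <- colMeans(counts > 0) >= min_prevalence
  if (sum(keep) < ncol(counts))
    message(sum(!keep), " low-prevalence feature(s) excluded from network")
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 4)
    stop("sparcc needs at least 4 features (basis correlations ",
         "unidentifiable below)")
  if (nrow(counts) < 10) stop("sparcc needs at least 10 samples")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rs <- lapply(seq_len(n_resamples), function(b) {
    gam <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                  nrow(counts), ncol(counts))
    frac <- gam / rowSums(gam)
    .sparcc_once(frac, n_exclusion_iters, exclusion_threshold)
  })
  r <- apply(simplify2array(rs), c(1, 2), stats::median)
  dimnames(r) <- list(colnames(counts), colnames(counts))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, p = NULL, feature_ids = colnames(counts)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d features%s\n", length(x$feature_ids),
              if (is.null(x$p)) "" else ", with permutation p-values"))
  invisible(x)
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation independently shuffles every feature's counts across
#' samples (destroying all pairwise association while preserving marginals)
#' and recomputes the SparCC point estimate with a single resample.
#' Two-sided `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`; the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param t the `feature_table` the network was built from.
#' @param net the observed [sparcc()] `correlation_network`.
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed.
#' @param n_resamples Dirichlet resamples per permutation (1 by default for
#'   speed; raise for a slower, smoother null).
#' @return The network with its `p` matrix filled in.
#' @export
permutation_pvalues <- function(t, net, n_perm = 100, seed = 1,
                                n_resamples = 1) {
  stopifnot(n_perm >= 20)
  counts <- unclass(t)[, net$feature_ids, drop = FALSE]
  n <- nrow(counts)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  robs <- abs(net$r)
  exceed <- matrix(0, nrow(robs), ncol(robs))
  for (b in seq_len(n_perm)) {
    perm <- apply(counts, 2, function(col) col[sample.int(n)])
    rps <- lapply(seq_len(n_resamples), function(i) {
      gam <- matrix(stats::rgamma(length(perm), shape = perm + 1),
                    n, ncol(perm))
      suppressWarnings(.sparcc_once(gam / rowSums(gam), 0, Inf))
    })
    rp <- if (n_resamples == 1) rps[[1]] else
      apply(simplify2array(rps), c(1, 2), stats::median)
    exceed <- exceed + (abs(rp) >= robs - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  dimnames(p) <- dimnames(net$r)
  diag(p) <- 0
  net$p <- p
  net
}

#' Filter network edges by effect size and significance
#'
#' Retains edges with `|r| >= min_abs_r` (inclusive) and `p < max_p`
#' (strict); positive and negative correlations are kept as separate classes.
#'
#' @param net a `correlation_network` with p-values.
#' @param min_abs_r minimum absolute correlation (default 0.1).
#' @param max_p significance ceiling (default 0.05).
#' @return data.frame edge list: `feature_a`, `feature_b`, `r`, `p`,
#'   `sign_class`.
#' @export
filter_edges <- function(net, min_abs_r = 0.1, max_p = 0.05) {
  if (is.null(net$p)) stop("network has no p-values; run permutation_pvalues()")
  idx <- which(upper.tri(net$r) & abs(net$r) >= min_abs_r & net$p < max_p,
               arr.ind = TRUE)
  data.frame(
    feature_a = net$feature_ids[idx[, 1]],
    feature_b = net$feature_ids[idx[, 2]],
    r = net$r[idx], p = net$p[idx],
    sign_class = ifelse(net$r[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
}

#' Detect network modules by greedy modularity maximization
#'
#' Greedy agglomerative modularity optimization on absolute edge weights
#' (deterministic for a fixed node order); features without edges form
#' singleton modules.
#'
#' @param edges an edge list from [filter_edges()].
#' @param features feature universe; defaults to the edge endpoints.
#' @return Named integer vector: module id per feature (a partition).
#' @export
detect_modules <- function(edges, features = NULL) {
  if (is.null(features))
    features <- sort(unique(c(edges$feature_a, edges$feature_b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$feature_a, to = edges$feature_b,
               weight = abs(edges$r)),
    directed = FALSE, vertices = data.frame(name = features))
  g <- igraph::simplify(g, edge.attr.comb = "max")
  memb <- igraph::membership(igraph::cluster_fast_greedy(g))
  out <- as.integer(memb)
  names(out) <- names(memb)
  out[features]
}

#' Node rewiring score between two networks
#'
#' For feature i with within-module absolute strength `s_A(i)` (sum of |r|
#' over retained edges to same-module partners) in network A and `s_B(i)` in
#' network B, the rewiring score is `|s_B - s_A| / (s_A + s_B + 1e-9)`,
#' bounded in \[0, 1): 0 when connectivity is unchanged, near 1 when a node
#' gains or loses essentially all its within-module strength.
#'
#' @param netA,netB edge lists ([filter_edges()]) on a shared feature
#'   universe (e.g. baseline and endpoint networks of one cohort).
#' @param partition module membership from [detect_modules()] on the union
#'   graph.
#' @return Named numeric vector of scores over `names(partition)`.
#' @export
rewiring_score <- function(netA, netB, partition) {
  strength <- function(e) {
    s <- stats::setNames(numeric(length(partition)), names(partition))
    if (nrow(e) == 0) return(s)
    same <- partition[e$feature_a] == partition[e$feature_b]
    e <- e[same, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      s[e$feature_a[i]] <- s[e$feature_a[i]] + abs(e$r[i])
      s[e$feature_b[i]] <- s[e$feature_b[i]] + abs(e$r[i])
    }
    s
  }
  sA <- strength(netA); sB <- strength(netB)
  abs(sB - sA) / (sA + sB + 1e-9)
}

#' Combine per-cohort rewiring scores
#'
#' Sample-size-weighted mean of cohort scores per feature; features whose
#' combined score exceeds `high_threshold` (default 0.12) are flagged as
#' strongly rewired. The combined score is a convex combination, so it is
#' bounded by the per-cohort extremes.
#'
#' @param per_cohort_scores named list of per-feature score vectors (shared
#'   names) from [rewiring_score()].
#' @param cohort_sizes numeric vector of per-cohort sample sizes, same order.
#' @param high_threshold flag threshold on the combined score.
#' @return A `rewiring_scores` data.frame: `feature`, per-cohort columns,
#'   `combined`, `high_flag`, sorted by descending combined score.
#' @export
combine_rewiring <- function(per_cohort_scores, cohort_sizes,
                             high_threshold = 0.12) {
  stopifnot(length(per_cohort_scores) >= 1,
            length(cohort_sizes) == length(per_cohort_scores))
  feats <- names(per_cohort_scores[[1]])
  mat <- vapply(per_cohort_scores, function(s) s[feats], numeric(length(feats)))
  mat <- matrix(mat, nrow = length(feats),
                dimnames = list(feats, names(per_cohort_scores)))
  w <- cohort_sizes / sum(cohort_sizes)
  combined <- as.numeric(mat %*% w)
  out <- data.frame(feature = feats, mat, combined = combined,
                    high_flag = combined > high_threshold,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  out <- out[order(-out$combined, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("rewiring_scores", "data.frame")
  out
}

#' Core-periphery subnetwork around driver and depleted taxa
#'
#' Node set = the top `n_core` features by mean relative abundance among
#' those with the maximal combined rewiring score ("driver" nodes; ties in
#' score fall back to abundance order), plus the supplied depleted feature
#' set; edges are the induced subset of the full edge list.
#'
#' @param edges full edge list ([filter_edges()]).
#' @param abundances named mean relative abundances per feature.
#' @param rewiring a [combine_rewiring()] result.
#' @param depleted feature ids of the depleted module.
#' @param n_core number of driver nodes (default 10).
#' @return list with `nodes` (feature, role in driver/depleted/both) and
#'   `edges` (induced edge list).
#' @export
core_subnetwork <- function(edges, abundances, rewiring, depleted,
                            n_core = 10) {
  top_score <- max(rewiring$combined)
  cand <- rewiring$feature[rewiring$combined == top_score]
  cand <- cand[order(-abundances[cand], cand)]
  if (length(cand) < n_core) {
    warning("only ", length(cand), " feature(s) at the maximal rewiring ",
            "score; taking all")
    drivers <- cand
  } else drivers <- cand[seq_len(n_core)]
  nodes <- union(drivers, depleted)
  role <- ifelse(nodes %in% drivers & nodes %in% depleted, "both",
                 ifelse(nodes %in% drivers, "driver", "depleted"))
  sub <- edges[edges$feature_a %in% nodes & edges$feature_b %in% nodes, ,
               drop = FALSE]
  rownames(sub) <- NULL
  list(nodes = data.frame(feature = nodes, role = role,
                          stringsAsFactors = FALSE),
       edges = sub)
}
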