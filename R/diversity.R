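#' Shannon diversity (bits)
#'
#' `-sum(p * log2(p))` over nonzero proportions. Reported in bits (log base
#' 2, the q2-diversity convention); downstream standardized effect sizes are
#' base-invariant.
#'
#' @param counts non-negative vector with positive sum.
#' @return Shannon entropy in bits.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Number of observed features
#' @param counts non-negative vector.
#' @return Count of strictly positive entries.
#' @export
observed_features <- function(counts) sum(counts > 0)

# edge x tip incidence: inc[e, t] = 1 if tip t descends from edge e
.edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  inc <- matrix(FALSE, ne, nt, dimnames = list(NULL, tree$tip.label))
  # process edges child-first (postorder) accumulating descendant tip sets
  below <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) below[[t]] <- t
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    child <- ord[r, 2]; parent <- ord[r, 1]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  for (e in seq_len(ne)) inc[e, below[[tree$edge[e, 2]]]] <- TRUE
  inc
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting every observed
#' feature to the root (the root connection is included, following the QIIME
#' convention).
#'
#' @param counts named non-negative vector; names are tree leaves.
#' @param tree rooted `phylo` with branch lengths covering all observed
#'   features.
#' @return Faith's PD in branch-length units.
#' @export
faith_pd <- function(counts, tree) {
  obs <- names(counts)[counts > 0]
  if (length(obs) == 0) return(0)
  missing_tips <- setdiff(obs, tree$tip.label)
  if (length(missing_tips) > 0)
    stop("observed feature(s) absent from tree: ",
         paste(utils::head(missing_tips, 10), collapse = ", "))
  inc <- .edge_tip_incidence(tree)
  on_path <- rowSums(inc[, obs, drop = FALSE]) > 0
  sum(tree$edge.length[on_path])
}

#' Per-sample alpha diversity table
#'
#' @param t a `feature_table` (typically rarefied).
#' @param tree optional rooted `phylo`; required for Faith's PD.
#' @return data.frame with `sample_id`, `shannon`, `observed_features` and,
#'   if a tree is given, `faith_pd`.
#' @export
alpha_diversity <- function(t, tree = NULL) {
  counts <- unclass(t)
  out <- data.frame(sample_id = rownames(counts),
                    shannon = apply(counts, 1, shannon),
                    observed_features = apply(counts, 1, observed_features),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree)) {
    inc <- .edge_tip_incidence(tree)
    missing_tips <- setdiff(colnames(counts)[colSums(counts) > 0],
                            tree$tip.label)
    if (length(missing_tips) > 0)
      stop("observed feature(s) absent from tree: ",
           paste(utils::head(missing_tips, 10), collapse = ", "))
    pres <- counts[, colnames(inc), drop = FALSE] > 0
    onpath <- inc %*% t(pres) > 0          # edges x samples
    out$faith_pd <- as.numeric(crossprod(onpath, tree$edge.length))
  }
  out
}

#' Beta diversity distance matrix
#'
#' Four metrics: `bray_curtis` (`sum|x-y| / sum(x+y)`), `jaccard`
#' (presence/absence, `1 - shared/union`), `unweighted_unifrac` (unshared
#' branch length over total branch length of the root-connected union
#' subtree) and `weighted_unifrac` (`sum_b b * |p_x(b) - p_y(b)|` with `p` the
#' fraction of the sample's reads descending from branch `b`; unnormalized,
#' the q2-diversity default -- pass `normalized = TRUE` for the variant
#' divided by `sum_b b * (p_x + p_y)`).
#'
#' @param t a `feature_table` (typically rarefied).
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param tree rooted `phylo` covering all features; required for UniFrac.
#' @param normalized normalize weighted UniFrac to \[0, 1\] (not used by the
#'   pipeline; exposed for sensitivity analysis).
#' @return A square symmetric matrix with zero diagonal and sample dimnames;
#'   attribute `metric` records the metric.
#' @export
beta_distance <- function(t, metric = c("bray_curtis", "jaccard",
                                        "unweighted_unifrac",
                                        "weighted_unifrac"),
                          tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  counts <- unclass(t)
  if (metric %in% c("bray_curtis", "jaccard")) {
    d <- if (metric == "bray_curtis")
      vegan::vegdist(counts, method = "bray")
    else vegan::vegdist(counts, method = "jaccard", binary = TRUE)
    d <- as.matrix(d)
  } else {
    if (is.null(tree)) stop(metric, " requires a tree")
    missing_tips <- setdiff(colnames(counts), tree$tip.label)
    if (length(missing_tips) > 0)
      stop("feature(s) absent from tree: ",
           paste(utils::head(missing_tips, 10), collapse = ", "))
    inc <- .edge_tip_incidence(tree)[, colnames(counts), drop = FALSE]
    bl <- tree$edge.length
    n <- nrow(counts)
    d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
    if (metric == "unweighted_unifrac") {
      pres <- inc %*% t(counts > 0) > 0     # edges x samples
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        un <- pres[, i] | pres[, j]
        sh <- pres[, i] & pres[, j]
        tot <- sum(bl[un])
        d[i, j] <- d[j, i] <- if (tot == 0) 0 else sum(bl[un & !sh]) / tot
      }
    } else {
      prop <- inc %*% t(counts / rowSums(counts))  # edges x samples
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        num <- sum(bl * abs(prop[, i] - prop[, j]))
        d[i, j] <- d[j, i] <- if (normalized)
          num / sum(bl * (prop[, i] + prop[, j])) else num
      }
    }
  }
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

#' Intra-individual (baseline vs endpoint) beta-diversity distances
#'
#' Extracts each complete pair's baseline-to-endpoint distance -- a direct
#' per-subject proxy for the magnitude of microbiome restructuring, used for
#' contrasts across intervention classes.
#'
#' @param t `feature_table` holding both samples of each pair.
#' @param m paired-mode `sample_metadata`.
#' @inheritParams beta_distance
#' @return data.frame: `study_id`, `subject_id`, `distance`.
#' @export
paired_beta_distance <- function(t, m, metric = "bray_curtis", tree = NULL) {
  pairs <- pair_samples(m)
  keep <- pairs$baseline %in% rownames(t) & pairs$endpoint %in% rownames(t)
  pairs <- pairs[keep, , drop = FALSE]
  D <- beta_distance(t, metric, tree)
  data.frame(study_id = pairs$study_id, subject_id = pairs$subject_id,
             distance = D[cbind(pairs$baseline, pairs$endpoint)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Principal coordinate analysis
#'
#' Classical (Torgerson) scaling of the Gower-centered squared-distance
#' matrix. Negative eigenvalues (non-Euclidean distances) are reported, never
#' silently dropped.
#'
#' @param D square distance matrix (e.g. from [beta_distance()]).
#' @param k number of coordinate axes (>= 1).
#' @return list with `coordinates` (samples x k, ordered by descending
#'   eigenvalue) and `eigenvalues` (all n - 1 of them, signed).
#' @export
pcoa <- function(D, k = 2) {
  stopifnot(k >= 1)
  res <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  coords <- res$points
  if (!is.null(rownames(D))) rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = res$eig)
}
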