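#' Module abundance score
#'
#' Per-sample sum of relative abundances over a fixed feature set (the
#' depleted-taxon module). Module members absent from the table contribute 0
#' (feature sets can differ across cohorts); a warning lists them.
#'
#' @param rel_abund samples x features matrix of relative abundances (rows
#'   sum to ~1, e.g. from [relative_abundance()]).
#' @param module character vector of module feature ids.
#' @return Named numeric vector of per-sample scores in \[0, 1\].
#' @export
module_score <- function(rel_abund, module) {
  stopifnot(length(module) > 0, !anyDuplicated(module))
  present <- intersect(module, colnames(rel_abund))
  missing_feats <- setdiff(module, colnames(rel_abund))
  if (length(missing_feats) > 0)
    warning(length(missing_feats), " module feature(s) absent from table, ",
            "scored as 0: ", paste(utils::head(missing_feats, 5),
                                   collapse = ", "))
  if (length(present) == 0)
    return(stats::setNames(numeric(nrow(rel_abund)), rownames(rel_abund)))
  rowSums(rel_abund[, present, drop = FALSE])
}

# REML profile for y = X beta + Zb + e with study random intercept,
# via per-study sufficient statistics; returns criterion and GLS pieces
.lmm_gls <- function(lambda, Xs, ys, ni) {
  p <- ncol(Xs[[1]])
  XtWX <- matrix(0, p, p); XtWy <- numeric(p); yWy <- 0
  for (i in seq_along(Xs)) {
    X <- Xs[[i]]; y <- ys[[i]]; n <- ni[i]
    a <- lambda / (1 + lambda * n)
    cx <- colSums(X); sy <- sum(y)
    XtWX <- XtWX + crossprod(X) - a * tcrossprod(cx)
    XtWy <- XtWy + crossprod(X, y) - a * cx * sy
    yWy <- yWy + sum(y^2) - a * sy^2
  }
  beta <- solve(XtWX, XtWy)
  Q <- yWy - sum(beta * XtWy)
  list(beta = beta, XtWX = XtWX, Q = max(Q, 0))
}

.lmm_criterion <- function(lambda, Xs, ys, ni, N) {
  g <- .lmm_gls(lambda, Xs, ys, ni)
  p <- ncol(Xs[[1]])
  (N - p) * log(max(g$Q, 1e-300)) + sum(log(1 + lambda * ni)) +
    determinant(g$XtWX, logarithm = TRUE)$modulus[1]
}

#' Diagnosis mixed model for module scores
#'
#' Fits `score ~ diagnosis + (1 | study)` by profiled REML (the same
#' variance-ratio profiling engine as the differential abundance stage,
#' generalized to a fixed-effects design), then reports per-diagnosis
#' marginal means (model-predicted means at random effect 0) and all
#' pairwise Wald contrasts with Benjamini-Hochberg adjustment. With a single
#' study the fit collapses to an ordinary fixed-effects linear model
#' (`tau2 = 0`).
#'
#' @param scores numeric module scores (proportion scale).
#' @param diagnosis labels (HC/CD/UC); levels with zero samples are dropped
#'   with a warning.
#' @param study study labels.
#' @param logit analyze logit-transformed scores instead of raw proportions
#'   (sensitivity analysis; marginal means are then on the logit scale).
#' @return A `diagnosis_lmm`: `marginal_means` (named), `contrasts`
#'   data.frame (`pair`, `estimate`, `se`, `stat`, `p`, `q`), `tau2`,
#'   `sigma2`, `n`.
#' @export
fit_diagnosis_lmm <- function(scores, diagnosis, study, logit = FALSE) {
  if (logit) {
    eps <- 1e-6
    scores <- stats::qlogis(pmin(pmax(scores, eps), 1 - eps))
  }
  stopifnot(length(scores) == length(diagnosis),
            length(scores) == length(study))
  diagnosis <- as.character(diagnosis); study <- as.character(study)
  lv <- intersect(c("HC", "CD", "UC"), unique(diagnosis))
  if (length(lv) < length(unique(diagnosis)))
    lv <- unique(diagnosis)
  empty <- setdiff(lv, unique(diagnosis))
  if (length(empty) > 0) {
    warning("diagnosis level(s) with no samples dropped: ",
            paste(empty, collapse = ", "))
    lv <- setdiff(lv, empty)
  }
  if (length(lv) < 2) stop("need at least 2 diagnosis levels")
  dg <- factor(diagnosis, levels = lv)
  X <- stats::model.matrix(~dg)
  N <- length(scores)
  sp <- split(seq_len(N), study)
  Xs <- lapply(sp, function(ix) X[ix, , drop = FALSE])
  ys <- lapply(sp, function(ix) scores[ix])
  ni <- vapply(sp, length, 0L)
  if (length(sp) == 1) {
    lambda <- 0
  } else {
    grid <- c(0, 10^seq(-6, 4, by = 0.25))
    crit <- vapply(grid, .lmm_criterion, 0, Xs = Xs, ys = ys, ni = ni, N = N)
    i <- which.min(crit)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(.lmm_criterion, c(lo, hi), Xs = Xs, ys = ys,
                           ni = ni, N = N, tol = 1e-10)
    lambda <- if (.lmm_criterion(0, Xs, ys, ni, N) <= opt$objective) 0
              else opt$minimum
  }
  g <- .lmm_gls(lambda, Xs, ys, ni)
  p <- ncol(X)
  sigma2 <- g$Q / (N - p)
  tau2 <- lambda * sigma2
  vc <- sigma2 * solve(g$XtWX)
  beta <- as.numeric(g$beta)
  # marginal means at random effect 0: L beta with L the level design
  L <- stats::model.matrix(~dg2, data.frame(dg2 = factor(lv, levels = lv)))
  mm <- stats::setNames(as.numeric(L %*% beta), lv)
  prs <- utils::combn(lv, 2, simplify = FALSE)
  ct <- lapply(prs, function(pr) {
    l <- L[lv == pr[2], ] - L[lv == pr[1], ]
    est <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% vc %*% l))
    z <- est / se
    data.frame(pair = paste(pr[2], "-", pr[1]), estimate = est, se = se,
               stat = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  ct <- do.call(rbind, c(ct, list(make.row.names = FALSE)))
  ct$q <- bh_fdr(ct$p)
  structure(list(marginal_means = mm, contrasts = ct, tau2 = tau2,
                 sigma2 = sigma2, n = N, k_studies = length(sp)),
            class = "diagnosis_lmm")
}

#' @export
print.diagnosis_lmm <- function(x, ...) {
  cat(sprintf("Diagnosis LMM (n = %d, %d studies; tau2 = %.3g, sigma2 = %.3g)\n",
              x$n, x$k_studies, x$tau2, x$sigma2))
  cat("Marginal means:\n")
  print(round(x$marginal_means, 4))
  cat("Pairwise contrasts (BH-adjusted):\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return `(mean(a) - mean(b)) / pooled SD`.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Leave-one-study-out disease classification: full table vs module
#'
#' For a two-group diagnosis contrast, trains 500-tree probability random
#' forests in a leave-one-study-out loop using either the full feature table
#' or only the module features, on relative abundances. Cohorts lacking
#' either contrast group are excluded (logged). Per-cohort AUC differences
#' between the two feature sets are compared by a paired Wilcoxon signed-rank
#' test.
#'
#' @param c cross-sectional [cohort_set()].
#' @param contrast `"HC_vs_CD"` or `"HC_vs_UC"`; the disease class is the
#'   positive class.
#' @param module module feature ids.
#' @param seed integer seed.
#' @param n_trees trees per forest.
#' @return list: `per_cohort` (study, auc_full, auc_module, n_test),
#'   `wilcoxon_p`, `excluded` (study ids lacking a contrast group).
#' @export
loso_disease_classifier <- function(c, contrast = c("HC_vs_CD", "HC_vs_UC"),
                                    module, seed = 1, n_trees = 500) {
  contrast <- match.arg(contrast)
  disease <- sub("HC_vs_", "", contrast)
  groups <- c("HC", disease)
  keep <- vapply(study_ids(c), function(sid)
    all(groups %in% c$metadata[[sid]]$diagnosis), logical(1))
  excluded <- study_ids(c)[!keep]
  if (length(excluded) > 0)
    message(length(excluded), " cohort(s) lacking a ", contrast,
            " group excluded: ", paste(excluded, collapse = ", "))
  sids <- study_ids(c)[keep]
  if (length(sids) < 2) stop("need at least 2 cohorts with both groups")
  shared <- Reduce(intersect, lapply(c$tables[sids], colnames))
  mod_feats <- intersect(module, shared)
  if (length(mod_feats) == 0) stop("no module features in the shared set")
  Xs <- lapply(c$tables[sids], function(t) {
    relative_abundance(t)[, shared, drop = FALSE]
  })
  md <- lapply(c$metadata[sids], function(m) m[m$diagnosis %in% groups, ])
  out <- list()
  for (ho in sids) {
    tr <- setdiff(sids, ho)
    ytr <- unlist(lapply(tr, function(s)
      stats::setNames(md[[s]]$diagnosis, md[[s]]$sample_id)))
    Xtr <- do.call(rbind, lapply(tr, function(s)
      Xs[[s]][md[[s]]$sample_id, , drop = FALSE]))
    Xte <- Xs[[ho]][md[[ho]]$sample_id, , drop = FALSE]
    yte <- md[[ho]]$diagnosis
    aucs <- vapply(list(full = shared, module = mod_feats), function(fs) {
      fit <- .fit_rf(Xtr[, fs, drop = FALSE], ytr, n_trees, seed)
      sc <- .predict_rf(fit, Xte[, fs, drop = FALSE], disease)
      auroc(sc, yte == disease)
    }, 0)
    out[[ho]] <- data.frame(study_id = ho, auc_full = aucs[["full"]],
                            auc_module = aucs[["module"]],
                            n_test = nrow(Xte), stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  d <- per$auc_full - per$auc_module
  wp <- if (all(d == 0)) 1 else wilcoxon_signed_rank(d)$p
  list(per_cohort = per, wilcoxon_p = wp, excluded = excluded)
}
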