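#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `AUC = (R1 - n1(n1+1)/2) / (n1 * n0)` where `R1` is the rank sum of the
#' positive-class scores.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or a 2-level factor whose
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Subject-level cross-validation folds
#'
#' Subjects are shuffled (seeded) and dealt round-robin into `k` folds, so
#' fold sizes differ by at most one subject and both samples of a subject
#' always share a fold -- the leakage guard for paired designs.
#'
#' @param m `sample_metadata`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` fold specs, each with `fold`, `train` and `test`
#'   sample ids.
#' @export
subject_folds <- function(m, k = 5, seed = 1) {
  subs <- unique(m$subject_id)
  if (length(subs) < k) stop("need at least k = ", k, " subjects")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subs <- sample(subs)
  assign_fold <- rep_len(seq_len(k), length(subs))
  lapply(seq_len(k), function(f) {
    test_subs <- subs[assign_fold == f]
    test <- m$sample_id[m$subject_id %in% test_subs]
    list(fold = f, train = setdiff(m$sample_id, test), test = test)
  })
}

# per-study design matrices on the shared feature set
.design_matrices <- function(c, transform = c("clr", "relative")) {
  transform <- match.arg(transform)
  shared <- Reduce(intersect, lapply(c$tables, colnames))
  lapply(c$tables, function(t) {
    tt <- unclass(t)[, shared, drop = FALSE]
    if (transform == "clr") clr_transform(tt) else tt / rowSums(tt)
  })
}

.fit_rf <- function(X, y, n_trees, seed) {
  ranger::ranger(x = X, y = factor(y), probability = TRUE,
                 num.trees = n_trees, seed = seed, num.threads = 1)
}

.predict_rf <- function(fit, X, positive) {
  predict(fit, data = X, num.threads = 1)$predictions[, positive]
}

#' Within-study cross-validated intervention-state classification
#'
#' Per study: a 500-tree probability random forest discriminating baseline
#' from endpoint samples, evaluated by subject-level k-fold CV; held-out
#' probability scores are pooled into a single per-study AUC.
#'
#' @param c paired-mode [cohort_set()].
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param transform feature transform: `"clr"` (default, consistent with the
#'   differential abundance stage) or `"relative"`.
#' @param n_trees trees in the ensemble (default 500).
#' @return data.frame: `scheme`, `train_scope`, `test_scope`, `auc`,
#'   `n_test`.
#' @export
within_study_cv <- function(c, k = 5, seed = 1, transform = "clr",
                            n_trees = 500) {
  Xs <- .design_matrices(c, transform)
  out <- list()
  for (sid in study_ids(c)) {
    m <- c$metadata[[sid]]
    X <- Xs[[sid]]
    y <- stats::setNames(m$timepoint, m$sample_id)[rownames(X)]
    folds <- subject_folds(m, k, seed)
    scores <- numeric(0); truth <- character(0)
    for (f in folds) {
      stopifnot(length(intersect(f$train, f$test)) == 0)
      fit <- .fit_rf(X[f$train, , drop = FALSE], y[f$train], n_trees, seed)
      scores <- c(scores, .predict_rf(fit, X[f$test, , drop = FALSE],
                                      "endpoint"))
      truth <- c(truth, y[f$test])
    }
    out[[sid]] <- data.frame(scheme = "cv", train_scope = sid,
                             test_scope = sid,
                             auc = auroc(scores, truth == "endpoint"),
                             n_test = length(truth), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cross-study validation (train on one study, test on every other)
#'
#' One model per training study (fit once on the whole study), evaluated on
#' every other study; the diagonal is excluded. Depressed off-diagonal AUCs
#' relative to within-study CV indicate batch effects / limited
#' transferability.
#'
#' @inheritParams within_study_cv
#' @return data.frame with `S * (S - 1)` rows.
#' @export
cross_study_validation <- function(c, seed = 1, transform = "clr",
                                   n_trees = 500) {
  sids <- study_ids(c)
  if (length(sids) < 2) stop("need at least 2 studies")
  Xs <- .design_matrices(c, transform)
  ys <- lapply(c$metadata, function(m)
    stats::setNames(m$timepoint, m$sample_id))
  out <- list()
  for (tr in sids) {
    fit <- .fit_rf(Xs[[tr]], ys[[tr]][rownames(Xs[[tr]])], n_trees, seed)
    for (te in setdiff(sids, tr)) {
      sc <- .predict_rf(fit, Xs[[te]], "endpoint")
      yy <- ys[[te]][rownames(Xs[[te]])]
      out[[paste(tr, te)]] <- data.frame(
        scheme = "csv", train_scope = tr, test_scope = te,
        auc = auroc(sc, yy == "endpoint"), n_test = length(yy),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Leave-one-study-out validation
#'
#' Trains on all studies but one (pooled) and tests on the held-out study;
#' repeated for every study. Held-out subjects are asserted never to appear
#' in training.
#'
#' @inheritParams within_study_cv
#' @return data.frame with one row per held-out study.
#' @export
loso <- function(c, seed = 1, transform = "clr", n_trees = 500) {
  sids <- study_ids(c)
  if (length(sids) < 2) stop("need at least 2 studies")
  Xs <- .design_matrices(c, transform)
  ys <- lapply(c$metadata, function(m)
    stats::setNames(m$timepoint, m$sample_id))
  out <- list()
  for (ho in sids) {
    tr <- setdiff(sids, ho)
    Xtr <- do.call(rbind, Xs[tr])
    ytr <- unlist(lapply(tr, function(s) ys[[s]][rownames(Xs[[s]])]),
                  use.names = FALSE)
    held_subj <- c$metadata[[ho]]$subject_id
    train_subj <- unlist(lapply(tr, function(s) c$metadata[[s]]$subject_id))
    stopifnot(length(intersect(held_subj, train_subj)) == 0)
    fit <- .fit_rf(Xtr, ytr, n_trees, seed)
    sc <- .predict_rf(fit, Xs[[ho]], "endpoint")
    yy <- ys[[ho]][rownames(Xs[[ho]])]
    out[[ho]] <- data.frame(scheme = "loso",
                            train_scope = paste(tr, collapse = "+"),
                            test_scope = ho,
                            auc = auroc(sc, yy == "endpoint"),
                            n_test = length(yy), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize leave-one-study-out results by intervention class
#'
#' Groups per-study hold-out AUCs by an intervention-class map (e.g.
#' resistant starch structural classes RS1/RS2/RS4); classes represented by a
#' single study are flagged `excluded` and not summarized, since a one-study
#' class mean is not a cross-study statement.
#'
#' @param results a [loso()] data.frame.
#' @param class_map named character vector: study id -> class.
#' @return data.frame: `class`, `n_studies`, `mean_auc` (NA when excluded),
#'   `excluded`.
#' @export
stratify_by_class <- function(results, class_map) {
  miss <- setdiff(results$test_scope, names(class_map))
  if (length(miss) > 0)
    stop("class_map missing studies: ", paste(miss, collapse = ", "))
  cls <- class_map[results$test_scope]
  out <- lapply(sort(unique(cls)), function(cc) {
    sub <- results[cls == cc, , drop = FALSE]
    excl <- nrow(sub) < 2
    data.frame(class = cc, n_studies = nrow(sub),
               mean_auc = if (excl) NA_real_ else mean(sub$auc),
               excluded = excl, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
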