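#' Pseudo-F and R-squared of a grouping on a distance matrix
#'
#' One-factor distance-based ANOVA decomposition:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = (SS_between / (a-1)) / (SS_within / (n-a))`,
#' `R2 = SS_between / SS_total`.
#'
#' @param D square symmetric distance matrix.
#' @param groups label vector aligned with rows of `D`; >= 2 groups.
#' @return list with `F` and `R2`.
#' @export
pseudo_f <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(groups) == n)
  groups <- as.character(groups)
  lv <- unique(groups)
  a <- length(lv)
  if (a < 2) stop("need at least 2 groups")
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  if (ss_total == 0) stop("degenerate distance matrix: total sum of squares is 0")
  ss_within <- 0
  for (g in lv) {
    idx <- groups == g
    ss_within <- ss_within + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / sum(idx)
  }
  ss_between <- ss_total - ss_within
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total)
}

# vectorized pseudo-F for many 2-group indicator columns at once
.pseudo_f_many2 <- function(D2, Z, ss_total, n) {
  n1 <- colSums(Z)
  q1 <- colSums(Z * (D2 %*% Z)) / 2
  Zc <- 1 - Z
  q2 <- colSums(Zc * (D2 %*% Zc)) / 2
  ss_within <- q1 / n1 + q2 / (n - n1)
  ss_between <- ss_total - ss_within
  (ss_between / 1) / (ss_within / (n - 2))
}

#' Repeated-measures PERMANOVA with subject-restricted permutations
#'
#' Tests a two-level within-subject factor (baseline vs endpoint) on a
#' distance matrix while preserving the paired design: the null distribution
#' is generated by independently swapping the two labels within each subject
#' block -- the only permutations that respect blocks of size two. When the
#' number of distinct sign-flip patterns `2^S` does not exceed `n_perm` they
#' are enumerated exhaustively and the p-value is exact; otherwise `n_perm`
#' random patterns are drawn and `p = (1 + #{F_perm >= F_obs}) / (1 +
#' n_perm)`.
#'
#' @param D square symmetric distance matrix.
#' @param groups two-level label vector (e.g. timepoints).
#' @param subjects block labels; each block must contain exactly 2 samples
#'   with distinct group labels.
#' @param n_perm number of permutations for the Monte-Carlo branch.
#' @param seed integer seed for the Monte-Carlo branch.
#' @return A `permanova_result`: `pseudo_F`, `R2`, `p`, `n_perm`, `scheme`,
#'   `exact`.
#' @export
rm_permanova <- function(D, groups, subjects, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  subjects <- as.character(subjects)
  stopifnot(length(groups) == n, length(subjects) == n)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("rm_permanova requires exactly 2 group levels")
  blocks <- split(seq_len(n), subjects)
  for (b in blocks) {
    if (length(b) != 2 || groups[b[1]] == groups[b[2]])
      stop("every subject block must hold exactly 2 samples with distinct ",
           "group labels")
  }
  S <- length(blocks)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  if (ss_total == 0) stop("degenerate distance matrix: total sum of squares is 0")
  z_obs <- as.numeric(groups == lv[2])
  f_obs <- .pseudo_f_many2(D2, matrix(z_obs, ncol = 1), ss_total, n)
  r2 <- pseudo_f(D, groups)$R2
  # index of the lv[2] sample within each block, and its partner
  pos2 <- vapply(blocks, function(b) b[which(groups[b] == lv[2])], 0L)
  pos1 <- vapply(blocks, function(b) b[which(groups[b] == lv[1])], 0L)
  build_Z <- function(flip) {           # flip: S x P logical, TRUE = swap
    P <- ncol(flip)
    Z <- matrix(0, n, P)
    for (s in seq_len(S)) {
      Z[pos2[s], ] <- ifelse(flip[s, ], 0, 1)
      Z[pos1[s], ] <- ifelse(flip[s, ], 1, 0)
    }
    Z
  }
  exact <- 2^S <= n_perm
  if (exact) {
    P <- 2^S
    flip <- vapply(seq_len(P) - 1,
                   function(i) as.logical(bitwAnd(i, 2^(seq_len(S) - 1))),
                   logical(S))
    f_all <- .pseudo_f_many2(D2, build_Z(matrix(flip, nrow = S)), ss_total, n)
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- P
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    flip <- matrix(stats::runif(S * n_perm) < 0.5, S, n_perm)
    f_perm <- .pseudo_f_many2(D2, build_Z(flip), ss_total, n)
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, R2 = r2, p = p, n_perm = n_used,
                 scheme = "within_subject", exact = exact),
            class = "permanova_result")
}

#' PERMANOVA for variance explained by study (unrestricted permutations)
#'
#' Free permutation of study labels; quantifies study-level clustering of
#' baseline communities as the fraction of distance variance explained by
#' cohort identity.
#'
#' @param D square symmetric distance matrix.
#' @param study_labels label vector (>= 2 studies).
#' @inheritParams rm_permanova
#' @return A `permanova_result` with `scheme = "unrestricted"`.
#' @export
study_variance <- function(D, study_labels, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  study_labels <- as.character(study_labels)
  stopifnot(length(study_labels) == n)
  lv <- unique(study_labels)
  if (length(lv) < 2) stop("need at least 2 studies")
  obs <- pseudo_f(D, study_labels)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  a <- length(lv)
  ss_within <- numeric(n_perm)
  for (g in lv) {
    base <- as.numeric(study_labels == g)
    Z <- matrix(base[perm_idx], n, n_perm)
    ss_within <- ss_within + colSums(Z * (D2 %*% Z)) / 2 / sum(base)
  }
  f_perm <- ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  p <- (1 + sum(f_perm >= obs$F - 1e-12)) / (1 + n_perm)
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p = p, n_perm = n_perm,
                 scheme = "unrestricted", exact = FALSE),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s%s): pseudo-F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$scheme, if (x$exact) ", exact" else "", x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}
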