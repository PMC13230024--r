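# shared fixture builders and independent brute-force oracles

random_feature_table <- function(n_samples, n_features, lambda = 20,
                                 seed = 1) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_samples * n_features, lambda),
                   n_samples, n_features,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   feature_ids(n_features)))
  feature_table(counts)
}

# tiny paired metadata: n subjects, 2 timepoints, one study
tiny_paired_metadata <- function(n, study = "st1") {
  subj <- sprintf("%s_sub%02d", study, seq_len(n))
  sample_metadata(data.frame(
    sample_id = c(paste0(subj, "_b"), paste0(subj, "_e")),
    study_id = study, subject_id = rep(subj, 2),
    timepoint = rep(c("baseline", "endpoint"), each = n)), "paired")
}

# exhaustive rank-sum oracle: two-sided p by enumerating all C(n,m) group
# assignments of the pooled sample (no ties assumed handled by midranks)
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mu <- m * (n - m) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# exhaustive signed-rank oracle over all 2^n sign patterns
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# pairwise-comparison AUC oracle
enum_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force restricted-likelihood grid search for the meta-analytic tau2
grid_reml_meta <- function(g, v, upper = 5, coarse = 1e-3, fine = 1e-6) {
  ll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * g) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (g - mu)^2))
  }
  grid <- seq(0, upper, by = coarse)
  vals <- vapply(grid, ll, 0)
  t0 <- grid[which.max(vals)]
  grid2 <- seq(max(0, t0 - coarse), t0 + coarse, by = fine)
  t2 <- grid2[which.max(vapply(grid2, ll, 0))]
  w <- 1 / (v + t2)
  list(tau2 = t2, mu = sum(w * g) / sum(w))
}

# brute-force profiled grid search for the random-intercept LMM: dense grid
# on the variance ratio, direct (dense-matrix) GLS at each point
grid_reml_lmm <- function(y, studies) {
  st <- as.character(studies)
  N <- length(y)
  Z <- stats::model.matrix(~ 0 + factor(st))
  X <- matrix(1, N, 1)
  crit <- function(lambda) {
    V <- diag(N) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    Q <- drop(t(r) %*% Vi %*% r)
    (N - 1) * log(Q) + determinant(V, logarithm = TRUE)$modulus[1] +
      log(XtVX[1, 1])
  }
  lams <- c(0, 10^seq(-5, 3, by = 0.01))
  vals <- vapply(lams, crit, 0)
  lam <- lams[which.min(vals)]
  if (lam > 0) {
    l2 <- seq(lam / 1.03, lam * 1.03, length.out = 200)
    lam <- l2[which.min(vapply(l2, crit, 0))]
  }
  V <- diag(N) + lam * tcrossprod(Z)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  mu <- drop(solve(XtVX, t(X) %*% Vi %*% y))
  r <- y - mu
  Q <- drop(t(r) %*% Vi %*% r)
  sigma2 <- Q / (N - 1)
  list(mu = mu, tau2 = lam * sigma2, sigma2 = sigma2,
       se_mu = sqrt(sigma2 / XtVX[1, 1]))
}
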