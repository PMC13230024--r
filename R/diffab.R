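#' Per-subject paired CLR differences across cohorts
#'
#' Applies the centered log-ratio transform within each cohort separately (on
#' that cohort's post-filter feature set), then takes each complete pair's
#' endpoint-minus-baseline difference, restricted to the feature set shared
#' by all cohorts. One row per paired subject.
#'
#' @param c paired-mode [cohort_set()] (prevalence filtering should already
#'   have been applied to each table).
#' @param pseudocount pseudocount for the CLR (default 1).
#' @return A `delta_table`: list with `delta` (subjects x shared features
#'   matrix of delta-CLR values), `study_id`, `subject_id`.
#' @export
delta_clr <- function(c, pseudocount = 1) {
  shared <- Reduce(intersect, lapply(c$tables, colnames))
  if (length(shared) == 0) stop("no features shared by all cohorts")
  rows <- list(); study <- character(); subject <- character()
  for (sid in study_ids(c)) {
    clr <- clr_transform(c$tables[[sid]], pseudocount)
    pairs <- suppressMessages(pair_samples(c$metadata[[sid]]))
    if (nrow(pairs) == 0) next
    d <- clr[pairs$endpoint, shared, drop = FALSE] -
      clr[pairs$baseline, shared, drop = FALSE]
    rownames(d) <- pairs$subject_id
    rows[[sid]] <- d
    study <- c(study, rep(sid, nrow(pairs)))
    subject <- c(subject, pairs$subject_id)
  }
  delta <- do.call(rbind, rows)
  stopifnot(all(is.finite(delta)))
  structure(list(delta = delta, study_id = study, subject_id = subject),
            class = "delta_table")
}

#' @export
print.delta_table <- function(x, ...) {
  cat(sprintf("delta_table: %d paired subjects x %d features, %d studies\n",
              nrow(x$delta), ncol(x$delta), length(unique(x$study_id))))
  invisible(x)
}

# profiled REML criterion pieces for y_ij = mu + b_i + e_ij at ratio
# lambda = tau2 / sigma2; returns -2 * restricted log-likelihood (profiled
# over mu and sigma2, up to a constant)
.ri_profile <- function(lambda, ybar, ni, ssw, N) {
  w <- ni / (1 + lambda * ni)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(w * (ybar - mu)^2)
  (N - 1) * log(Q) + sum(log(1 + lambda * ni)) + log(sum(w))
}

#' Random-intercept REML fit of a mean with study heterogeneity
#'
#' Fits `y_ij = mu + b_i + e_ij`, `b_i ~ N(0, tau2)` (study), `e_ij ~ N(0,
#' sigma2)`, by restricted maximum likelihood: the variance ratio
#' `lambda = tau2/sigma2` is profiled on a log grid and refined by bounded
#' 1-D optimization; `mu` is the generalized least squares estimate at the
#' optimum. Inference on `mu` is a Wald z test. A boundary fit (`tau2 = 0`)
#' is legitimate and reported as such.
#'
#' @param y numeric response vector (>= 2 observations).
#' @param studies grouping labels aligned with `y`.
#' @return An `ri_fit`: `mu`, `se_mu`, `tau2`, `sigma2`, `stat` (z), `p`,
#'   `per_study_means`, `n`.
#' @export
fit_random_intercept <- function(y, studies) {
  stopifnot(length(y) == length(studies))
  N <- length(y)
  if (N < 2) stop("need at least 2 observations")
  studies <- as.character(studies)
  sp <- split(y, studies)
  ni <- vapply(sp, length, 0L)
  ybar <- vapply(sp, mean, 0)
  ssw <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0))
  k <- length(sp)
  if (stats::var(y) == 0) {
    warning("all observations identical: degenerate fit")
    return(structure(list(mu = y[1], se_mu = 0, tau2 = 0, sigma2 = 0,
                          stat = NaN, p = NaN, per_study_means = ybar, n = N),
                     class = "ri_fit"))
  }
  if (k == 1) {
    lambda <- 0
  } else {
    grid <- c(0, 10^seq(-6, 4, by = 0.25))
    crit <- vapply(grid, .ri_profile, 0, ybar = ybar, ni = ni, ssw = ssw, N = N)
    i <- which.min(crit)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    if (lo == hi) {
      lambda <- grid[i]
    } else {
      opt <- stats::optimize(.ri_profile, c(lo, hi), ybar = ybar, ni = ni,
                             ssw = ssw, N = N, tol = 1e-10)
      lambda <- if (.ri_profile(0, ybar, ni, ssw, N) <= opt$objective) 0
                else opt$minimum
    }
  }
  w <- ni / (1 + lambda * ni)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(w * (ybar - mu)^2)
  sigma2 <- Q / (N - 1)
  tau2 <- lambda * sigma2
  se <- sqrt(sigma2 / sum(w))
  z <- mu / se
  structure(list(mu = mu, se_mu = se, tau2 = tau2, sigma2 = sigma2,
                 stat = z, p = 2 * stats::pnorm(-abs(z)),
                 per_study_means = ybar, n = N),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept REML fit (n = %d, %d studies):\n  mu = %.4f (se %.4f), z = %.3f, p = %.3g\n  tau2 = %.4f, sigma2 = %.4f\n",
    x$n, length(x$per_study_means), x$mu, x$se_mu, x$stat, x$p,
    x$tau2, x$sigma2))
  invisible(x)
}

#' @export
coef.ri_fit <- function(object, ...) c(mu = object$mu)

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-cohort paired differential abundance
#'
#' Fits the intercept-only study-random-intercept REML model to every
#' feature's delta-CLR values, adjusts the Wald p-values by
#' Benjamini-Hochberg across all tested features, and flags features with
#' `q < alpha` as significant. Results are sorted by `(q, -|mu_hat|,
#' feature)` for reproducible output.
#'
#' @param d a [delta_clr()] `delta_table`.
#' @param alpha FDR threshold for the significant set (default 0.05).
#' @return A `diffab_result`: `results` data.frame (feature, mu_hat, se,
#'   stat, p, q, tau2, sigma2), `per_study_means` (feature x study matrix),
#'   `significant` (feature ids), `alpha`.
#' @export
run_differential_abundance <- function(d, alpha = 0.05) {
  stopifnot(inherits(d, "delta_table"), nrow(d$delta) > 0)
  feats <- colnames(d$delta)
  fits <- lapply(feats, function(f) {
    tryCatch(fit_random_intercept(d$delta[, f], d$study_id),
             error = function(e) stop("feature '", f, "': ",
                                      conditionMessage(e)))
  })
  res <- data.frame(
    feature = feats,
    mu_hat = vapply(fits, function(x) x$mu, 0),
    se = vapply(fits, function(x) x$se_mu, 0),
    stat = vapply(fits, function(x) x$stat, 0),
    p = vapply(fits, function(x) x$p, 0),
    tau2 = vapply(fits, function(x) x$tau2, 0),
    sigma2 = vapply(fits, function(x) x$sigma2, 0),
    stringsAsFactors = FALSE)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, -abs(res$mu_hat), res$feature),
             c("feature", "mu_hat", "se", "stat", "p", "q", "tau2", "sigma2")]
  rownames(res) <- NULL
  studies <- sort(unique(d$study_id))
  psm <- vapply(studies, function(s)
    colMeans(d$delta[d$study_id == s, , drop = FALSE]),
    numeric(ncol(d$delta)))
  structure(list(results = res,
                 per_study_means = psm,
                 significant = res$feature[!is.na(res$q) & res$q < alpha],
                 alpha = alpha),
            class = "diffab_result")
}

#' @export
print.diffab_result <- function(x, ...) {
  cat(sprintf(
    "Paired differential abundance: %d features tested, %d significant at FDR < %g\n",
    nrow(x$results), length(x$significant), x$alpha))
  if (length(x$significant) > 0)
    print(utils::head(x$results, min(10, length(x$significant))))
  invisible(x)
}

#' @export
summary.diffab_result <- function(object, ...) {
  sig <- object$results[object$results$feature %in% object$significant, ]
  cat(sprintf("%d/%d features significant at FDR < %g; %d depleted, %d enriched\n",
              nrow(sig), nrow(object$results), object$alpha,
              sum(sig$mu_hat < 0), sum(sig$mu_hat > 0)))
  invisible(sig)
}

#' Per-cohort consistency of significant features
#'
#' Long table of mean delta-CLR per (significant feature, study), with a
#' per-feature `unidirectional` flag set when every study mean shares the
#' sign of the pooled estimate -- the cross-cohort consistency display of the
#' depleted module.
#'
#' @param results a `diffab_result`.
#' @param d the `delta_table` the results came from.
#' @return data.frame: `feature`, `study_id`, `mean_dclr`, `unidirectional`.
#' @export
consistency_table <- function(results, d) {
  sig <- results$significant
  if (length(sig) == 0)
    return(data.frame(feature = character(), study_id = character(),
                      mean_dclr = numeric(), unidirectional = logical()))
  studies <- sort(unique(d$study_id))
  out <- list()
  mu <- stats::setNames(results$results$mu_hat, results$results$feature)
  for (f in sig) {
    m <- vapply(studies, function(s) mean(d$delta[d$study_id == s, f]), 0)
    out[[f]] <- data.frame(feature = f, study_id = studies, mean_dclr = m,
                           unidirectional = all(sign(m) == sign(mu[[f]])),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
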