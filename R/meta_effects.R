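#' Paired standardized mean difference (Hedges' g) for one study
#'
#' Change-score standardized mean difference: `d = mean(endpoint - baseline) /
#' sd(endpoint - baseline)` (n - 1 denominator), corrected for small-sample
#' bias by `J = 1 - 3 / (4(n - 1) - 1)`, with sampling variance
#' `var_g = 1/n + g^2 / (2n)`.
#'
#' @param baseline,endpoint numeric vectors of equal length (one value per
#'   paired subject), n >= 2.
#' @param study_id optional label carried into the result.
#' @return A `study_effect` list: `study_id`, `g`, `var_g`, `n`.
#' @export
paired_hedges_g <- function(baseline, endpoint, study_id = NA_character_) {
  stopifnot(length(baseline) == length(endpoint))
  n <- length(baseline)
  if (n < 2) stop("need at least 2 pairs")
  d <- endpoint - baseline
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance paired differences: effect size undefined")
  J <- 1 - 3 / (4 * (n - 1) - 1)
  g <- J * mean(d) / s
  structure(list(study_id = study_id, g = g,
                 var_g = 1 / n + g^2 / (2 * n), n = n),
            class = "study_effect")
}

#' @export
print.study_effect <- function(x, ...) {
  cat(sprintf("study_effect%s: g = %.4f (var %.4f, n = %d)\n",
              if (is.na(x$study_id)) "" else paste0(" [", x$study_id, "]"),
              x$g, x$var_g, x$n), sep = "")
  invisible(x)
}

#' Paired Student's t-test
#'
#' @inheritParams paired_hedges_g
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
paired_ttest <- function(baseline, endpoint) {
  stopifnot(length(baseline) == length(endpoint), length(baseline) >= 2)
  if (stats::sd(endpoint - baseline) == 0)
    stop("zero-variance paired differences")
  tt <- stats::t.test(endpoint, baseline, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

# restricted log-likelihood of the normal-normal meta-analytic model at tau2
.reml_loglik_meta <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * g) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (g - mu)^2))
}

#' Pool study effects with a REML random-effects model
#'
#' Fits `g_i ~ N(mu, v_i + tau2)` by restricted maximum likelihood: `tau2`
#' maximizes the restricted log-likelihood (bounded 1-D optimization, with
#' the `tau2 = 0` boundary checked explicitly), `mu` is the inverse-variance
#' weighted mean at the optimum, and inference uses the normal (z)
#' approximation.
#'
#' @param effects list of `study_effect` objects (or a data.frame with
#'   columns `g` and `var_g`), k >= 1.
#' @return A `pooled_effect` list: `mu`, `se_mu`, `ci95`, `z`, `p`, `tau2`,
#'   `Q` (Cochran heterogeneity statistic at tau2 = 0 weights), `k`.
#' @export
reml_pool <- function(effects) {
  if (inherits(effects, "study_effect")) effects <- list(effects)
  if (is.data.frame(effects)) {
    g <- effects$g; v <- effects$var_g
  } else {
    g <- vapply(effects, function(e) e$g, 0)
    v <- vapply(effects, function(e) e$var_g, 0)
  }
  k <- length(g)
  if (k == 0) stop("no study effects to pool")
  stopifnot(all(v > 0))
  if (k == 1) {
    tau2 <- 0
  } else {
    upper <- max(10 * stats::var(g), 10 * max(v), 1)
    opt <- stats::optimize(.reml_loglik_meta, c(0, upper), g = g, v = v,
                           maximum = TRUE, tol = 1e-12)
    tau2 <- if (.reml_loglik_meta(0, g, v) >= opt$objective) 0
            else opt$maximum
  }
  w <- 1 / (v + tau2)
  mu <- sum(w * g) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- mu / se
  w0 <- 1 / v
  mu0 <- sum(w0 * g) / sum(w0)
  structure(list(mu = mu, se_mu = se,
                 ci95 = c(mu - 1.959963984540054 * se,
                          mu + 1.959963984540054 * se),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2, Q = sum(w0 * (g - mu0)^2), k = k),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "Random-effects pooled estimate (REML, k = %d):\n  mu = %.4f  (95%% CI %.4f to %.4f)\n  z = %.3f, p = %.3g, tau2 = %.4f\n",
    x$k, x$mu, x$ci95[1], x$ci95[2], x$z, x$p, x$tau2))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midrank tie handling; exact null enumeration for small untied samples,
#' normal approximation with tie and continuity correction otherwise (the
#' base-R switchover).
#'
#' @param x,y numeric vectors, both nonempty.
#' @return list with `statistic` (W) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped before ranking; exact for small untied
#' inputs, normal approximation with corrections otherwise.
#'
#' @param differences numeric vector with at least one nonzero entry.
#' @return list with `statistic` (V) and `p` (two-sided).
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[differences != 0]
  if (length(d) == 0) stop("all differences are zero")
  wt <- suppressWarnings(stats::wilcox.test(d))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Meta-analysis of paired alpha-diversity change across cohorts
#'
#' Computes per-sample alpha diversity within each study, the per-study
#' paired Hedges' g (endpoint minus baseline) with a paired t-test, and the
#' REML-pooled effect across studies.
#'
#' @param c paired-mode [cohort_set()] (tables already depth-filtered and
#'   rarefied as desired).
#' @param metric `"shannon"`, `"observed_features"` or `"faith_pd"`.
#' @param tree rooted `phylo`; required for `faith_pd` (defaults to the
#'   cohort set's tree).
#' @return list with `per_study` (data.frame: study_id, metric, g, var_g, n,
#'   t, p) and `pooled` (a `pooled_effect`).
#' @export
pool_alpha_diversity <- function(c, metric = c("shannon", "observed_features",
                                               "faith_pd"), tree = c$tree) {
  metric <- match.arg(metric)
  if (metric == "faith_pd" && is.null(tree))
    stop("faith_pd requires a tree")
  effects <- list(); rows <- list()
  for (sid in study_ids(c)) {
    alpha <- alpha_diversity(c$tables[[sid]],
                             tree = if (metric == "faith_pd") tree else NULL)
    vals <- stats::setNames(alpha[[metric]], alpha$sample_id)
    pairs <- suppressMessages(pair_samples(c$metadata[[sid]]))
    eff <- paired_hedges_g(vals[pairs$baseline], vals[pairs$endpoint], sid)
    tt <- paired_ttest(vals[pairs$baseline], vals[pairs$endpoint])
    effects[[sid]] <- eff
    rows[[sid]] <- data.frame(study_id = sid, metric = metric, g = eff$g,
                              var_g = eff$var_g, n = eff$n, t = tt$t,
                              p = tt$p, stringsAsFactors = FALSE)
  }
  list(per_study = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pooled = reml_pool(effects))
}
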