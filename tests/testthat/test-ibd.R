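test_that("module scores are set sums on the proportion scale", {
  ra <- rbind(s1 = c(0.25, 0.25, 0.5), s2 = c(0.07, 0.9, 0.03))
  colnames(ra) <- feature_ids(3)
  expect_equal(unname(module_score(ra, feature_ids(3))), c(1, 1))
  expect_equal(unname(module_score(ra, "F001")), c(0.25, 0.07))
  expect_warning(sc <- module_score(ra, c("F001", "F099")), "absent")
  expect_equal(unname(sc), c(0.25, 0.07))
  # additivity over disjoint modules, set-sum oracle on random fixtures
  set.seed(39)
  ra2 <- relative_abundance(random_feature_table(6, 12, seed = 40))
  m1 <- feature_ids(12)[1:4]; m2 <- feature_ids(12)[5:7]
  expect_equal(module_score(ra2, c(m1, m2)),
               module_score(ra2, m1) + module_score(ra2, m2))
  expect_equal(unname(module_score(ra2, m1)),
               unname(rowSums(ra2[, m1])))
  expect_true(all(module_score(ra2, m1) >= 0 & module_score(ra2, m1) <= 1))
})

test_that("cohen's d matches the pooled-SD hand value and is antisymmetric", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 5), c(2, 8)), -cohens_d(c(2, 8), c(1, 5)))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("diagnosis mixed model recovers planted ordering and collapses", {
  cfg <- cross_sectional_sim_config(n_studies = 4,
                                    group_sizes = matrix(50, 4, 3),
                                    n_features = 100, module_features = 1:10,
                                    seed = 41)
  sim <- simulate_ibd_cohorts(cfg)
  ra <- do.call(rbind, lapply(sim$cohorts$tables, relative_abundance))
  md <- do.call(rbind, lapply(sim$cohorts$metadata, as.data.frame))
  sc <- module_score(ra[md$sample_id, , drop = FALSE],
                     sim$truth$module_features)
  fit <- fit_diagnosis_lmm(sc, md$diagnosis, md$study_id)
  mm <- fit$marginal_means
  expect_true(mm[["CD"]] > mm[["UC"]] && mm[["UC"]] > mm[["HC"]])
  expect_lt(fit$contrasts$q[fit$contrasts$pair == "CD - HC"], 0.01)
  expect_true(all(fit$contrasts$q >= fit$contrasts$p))
  expect_gte(fit$tau2, 0)

  # reference-level invariance: means equal, contrasts flip sign only
  fit2 <- fit_diagnosis_lmm(sc, factor(md$diagnosis,
                                       levels = c("CD", "HC", "UC")),
                            md$study_id)
  expect_equal(sort(fit2$marginal_means), sort(mm), tolerance = 1e-8)
  hc_cd_1 <- fit$contrasts$estimate[fit$contrasts$pair == "CD - HC"]
  hc_cd_2 <- fit2$contrasts$estimate[grepl("HC", fit2$contrasts$pair) &
                                     grepl("CD", fit2$contrasts$pair)]
  expect_equal(abs(hc_cd_2), abs(hc_cd_1), tolerance = 1e-8)

  # single study collapses to OLS with two-sample Wald contrasts
  md1 <- sim$cohorts$metadata[[1]]
  ra1 <- relative_abundance(sim$cohorts$tables[[1]])
  sc1 <- module_score(ra1[md1$sample_id, , drop = FALSE],
                      sim$truth$module_features)
  f1 <- fit_diagnosis_lmm(sc1, md1$diagnosis, md1$study_id)
  expect_equal(f1$tau2, 0)
  ols <- lm(sc1 ~ factor(md1$diagnosis, levels = c("HC", "CD", "UC")))
  expect_equal(unname(f1$marginal_means["HC"]), unname(coef(ols)[1]),
               tolerance = 1e-8)
  expect_equal(unname(f1$marginal_means["CD"]),
               unname(coef(ols)[1] + coef(ols)[2]), tolerance = 1e-8)

  # dropped empty level
  expect_warning(
    f2 <- fit_diagnosis_lmm(sc1[md1$diagnosis != "UC"],
                            factor(md1$diagnosis[md1$diagnosis != "UC"],
                                   levels = c("HC", "CD", "UC")),
                            md1$study_id[md1$diagnosis != "UC"]),
    NA)
  expect_setequal(names(f2$marginal_means), c("HC", "CD"))
})

test_that("diagnosis mixed model agrees with lme4 on a planted fixture", {
  skip_if_not_installed("lme4")
  set.seed(42)
  st <- rep(paste0("s", 1:5), each = 45)
  dg <- rep(rep(c("HC", "CD", "UC"), each = 15), 5)
  y <- 0.05 + 0.02 * (dg == "CD") + 0.008 * (dg == "UC") +
    rep(rnorm(5, 0, 0.012), each = 45) + rnorm(225, 0, 0.02)
  mine <- fit_diagnosis_lmm(y, dg, st)
  lm4 <- lme4::lmer(y ~ factor(dg, levels = c("HC", "CD", "UC")) + (1 | st),
                    REML = TRUE)
  fe <- lme4::fixef(lm4)
  expect_equal(unname(mine$marginal_means[c("HC", "CD", "UC")]),
               unname(c(fe[1], fe[1] + fe[2], fe[1] + fe[3])),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(mine$tau2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(mine$sigma2, vc$vcov[2], tolerance = 1e-6)
  V <- as.matrix(lme4::vcov.merMod(lm4))
  se_cd <- sqrt(V[2, 2])
  expect_equal(mine$contrasts$se[mine$contrasts$pair == "CD - HC"], se_cd,
               tolerance = 1e-5)
})

test_that("hc-cd contrast estimation is nearly unbiased with good coverage", {
  set.seed(43)
  true_contrast <- 0.02
  est <- numeric(0); cover <- 0; n_rep <- 200
  for (r in 1:n_rep) {
    st <- rep(paste0("s", 1:5), each = 40)
    dg <- rep(rep(c("HC", "CD"), each = 20), 5)
    y <- 0.05 + true_contrast * (dg == "CD") +
      rep(rnorm(5, 0, 0.01), each = 40) + rnorm(200, 0, 0.025)
    fit <- fit_diagnosis_lmm(y, dg, st)
    ct <- fit$contrasts[fit$contrasts$pair == "CD - HC", ]
    est <- c(est, ct$estimate)
    ci <- ct$estimate + c(-1, 1) * 1.959963984540054 * ct$se
    if (ci[1] <= true_contrast && true_contrast <= ci[2]) cover <- cover + 1
  }
  expect_lt(abs(mean(est) - true_contrast), 0.05 * true_contrast)
  expect_gte(cover / n_rep, 0.93)
  expect_lte(cover / n_rep, 0.97)
})

test_that("loso disease classifiers compare full vs module feature sets", {
  cfg <- cross_sectional_sim_config(n_studies = 3,
                                    group_sizes = rbind(c(25, 25, 25),
                                                        c(25, 25, 25),
                                                        c(25, 25, 0)),
                                    n_features = 60, module_features = 1:8,
                                    diagnosis_shift = c(HC = 0, CD = 1.2,
                                                        UC = 0.5),
                                    seed = 44)
  sim <- simulate_ibd_cohorts(cfg)
  # module carries the entire signal: full vs module indistinguishable
  res <- suppressMessages(
    loso_disease_classifier(sim$cohorts, "HC_vs_CD",
                            sim$truth$module_features, seed = 1,
                            n_trees = 150))
  expect_equal(nrow(res$per_cohort), 3)
  expect_gt(min(res$per_cohort$auc_module), 0.7)
  expect_gt(res$wilcoxon_p, 0.1)
  # cohort without UC excluded from the UC contrast
  expect_message(
    res_uc <- loso_disease_classifier(sim$cohorts, "HC_vs_UC",
                                      sim$truth$module_features, seed = 1,
                                      n_trees = 150),
    "excluded")
  expect_equal(res_uc$excluded, "ibd03")
  expect_equal(nrow(res_uc$per_cohort), 2)

  # signal split between module and many non-module features: the full
  # table should dominate the module subset in every cohort
  p <- 80
  extra <- 9:58
  shift_feats <- c(1:8, extra)
  cfg2 <- cross_sectional_sim_config(n_studies = 3,
                                     group_sizes = matrix(30, 3, 3),
                                     n_features = p,
                                     module_features = shift_feats,
                                     diagnosis_shift = c(HC = 0, CD = 1.0,
                                                         UC = 0.4),
                                     seed = 45)
  sim2 <- simulate_ibd_cohorts(cfg2)
  res2 <- loso_disease_classifier(sim2$cohorts, "HC_vs_CD",
                                  feature_ids(p)[1:8], seed = 1,
                                  n_trees = 150)
  expect_true(all(res2$per_cohort$auc_full >= res2$per_cohort$auc_module))
  expect_lt(res2$wilcoxon_p, 0.3)
})
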