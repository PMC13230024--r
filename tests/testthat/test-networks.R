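# shared latent-lognormal composition sampler for network fixtures
lognormal_counts <- function(n, p, latent_cor_pair = NULL, rho = 0.8,
                             depth = 10000, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  if (!is.null(latent_cor_pair)) {
    i <- latent_cor_pair[1]; j <- latent_cor_pair[2]
    z[, j] <- rho * z[, i] + sqrt(1 - rho^2) * z[, j]
  }
  w <- exp(z)
  counts <- t(apply(w, 1, function(row) rmultinom(1, depth, row / sum(row))))
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n)), feature_ids(p))
  feature_table(counts)
}

test_that("sparcc is symmetric, seeded, and near zero for independence", {
  ft <- lognormal_counts(200, 30, seed = 32)
  net <- sparcc(ft, n_resamples = 10, seed = 1)
  expect_equal(net$r, t(net$r))
  expect_true(all(diag(net$r) == 1))
  expect_true(all(abs(net$r) <= 1))
  off <- net$r[upper.tri(net$r)]
  expect_lt(median(abs(off)), 0.1)
  net2 <- sparcc(ft, n_resamples = 10, seed = 1)
  expect_identical(net$r, net2$r)
  expect_error(sparcc(lognormal_counts(20, 3, seed = 1)), "4 features")
})

test_that("sparcc recovers a planted correlated pair and beats naive pearson", {
  ft <- lognormal_counts(250, 30, latent_cor_pair = c(1, 2), rho = 0.85,
                         seed = 33)
  net <- sparcc(ft, n_resamples = 10, seed = 2)
  r12 <- net$r["F001", "F002"]
  expect_gt(r12, 0)
  row1 <- abs(net$r["F001", setdiff(colnames(net$r), "F001")])
  expect_equal(names(which.max(row1)), "F002")
  # compositional-bias check: on independent data sparcc's background is
  # tighter than pearson on relative abundances
  ft0 <- lognormal_counts(250, 30, seed = 34)
  net0 <- sparcc(ft0, n_resamples = 10, seed = 3)
  pear <- cor(relative_abundance(ft0))
  expect_lt(median(abs(net0$r[upper.tri(net0$r)])),
            median(abs(pear[upper.tri(pear)])) + 0.02)
})

test_that("permutation p-values are calibrated with an add-one floor", {
  ft <- lognormal_counts(120, 12, latent_cor_pair = c(1, 2), rho = 0.9,
                         seed = 35)
  net <- sparcc(ft, n_resamples = 10, seed = 4)
  net <- permutation_pvalues(ft, net, n_perm = 99, seed = 5)
  expect_true(all(net$p[upper.tri(net$p)] > 0))
  expect_equal(net$p["F001", "F002"], 1 / 100)   # permutation floor
  # null features: roughly nominal fraction below 0.05
  pnull <- net$p[upper.tri(net$p)][-1]
  expect_lt(mean(pnull < 0.05), 0.25)
})

test_that("edge filtering applies inclusive r and strict p thresholds", {
  r <- diag(4); r[1, 2] <- r[2, 1] <- 0.1; r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- -0.4; r[1, 4] <- r[4, 1] <- 0.09
  p <- matrix(0.01, 4, 4); diag(p) <- 0
  p[2, 3] <- p[3, 2] <- 0.05                     # exactly at the boundary
  net <- structure(list(r = r, p = p, feature_ids = feature_ids(4)),
                   class = "correlation_network")
  e <- filter_edges(net)
  key <- paste(e$feature_a, e$feature_b)
  expect_true("F001 F002" %in% key)              # r = 0.1 retained (>=)
  expect_false("F002 F003" %in% key)             # p = 0.05 dropped (<)
  expect_false("F001 F004" %in% key)             # |r| below 0.1
  expect_equal(e$sign_class[key == "F001 F003"], "positive")
  net$p[] <- 0.5
  expect_equal(nrow(filter_edges(net)), 0)
})

test_that("module detection recovers planted cliques with singletons", {
  clique <- function(ids, r) {
    prs <- utils::combn(ids, 2)
    data.frame(feature_a = prs[1, ], feature_b = prs[2, ], r = r, p = 0.001,
               sign_class = "positive", stringsAsFactors = FALSE)
  }
  e <- rbind(clique(feature_ids(5), 0.8),
             clique(sprintf("F%03d", 6:10), 0.8),
             data.frame(feature_a = "F001", feature_b = "F006", r = 0.11,
                        p = 0.01, sign_class = "positive"))
  part <- detect_modules(e, features = feature_ids(11))  # F011 edgeless
  expect_equal(length(unique(part[feature_ids(5)])), 1)
  expect_equal(length(unique(part[sprintf("F%03d", 6:10)])), 1)
  expect_false(part[["F001"]] == part[["F006"]])
  expect_false(part[["F011"]] %in% part[setdiff(names(part), "F011")])
  # a partition: every feature assigned exactly once
  expect_setequal(names(part), feature_ids(11))
})

test_that("rewiring scores measure within-module strength change", {
  part <- stats::setNames(c(1, 1, 1, 2), feature_ids(4))
  eA <- data.frame(feature_a = c("F001", "F001"), feature_b = c("F002", "F003"),
                   r = c(0.4, 0.2), p = 0.01, sign_class = "positive")
  expect_equal(max(rewiring_score(eA, eA, part)), 0)
  # feature loses all edges -> score ~ 1
  eB <- eA[0, ]
  expect_gt(rewiring_score(eA, eB, part)[["F001"]], 0.999)
  # hand-worked: s_A = 0.6, s_B = 0.2 -> 0.4 / 0.8 = 0.5
  eB2 <- data.frame(feature_a = "F001", feature_b = "F002", r = 0.2, p = 0.01,
                    sign_class = "positive")
  expect_equal(rewiring_score(eA, eB2, part)[["F001"]], 0.5, tolerance = 1e-6)
  # symmetry under swapping networks
  expect_equal(rewiring_score(eA, eB2, part), rewiring_score(eB2, eA, part))
  # cross-module edges do not count
  eX <- data.frame(feature_a = "F001", feature_b = "F004", r = 0.9, p = 0.01,
                   sign_class = "positive")
  expect_equal(rewiring_score(eA, rbind(eB2, eX), part)[["F001"]], 0.5,
               tolerance = 1e-6)
})

test_that("combined rewiring is a weighted convex combination with a flag", {
  sA <- stats::setNames(c(0.2, 0.05), c("F001", "F002"))
  sB <- stats::setNames(c(0.4, 0.15), c("F001", "F002"))
  cw <- combine_rewiring(list(a = sA, b = sB), c(10, 10))
  expect_equal(cw$combined[cw$feature == "F001"], 0.3)
  expect_equal(cw$combined[cw$feature == "F002"], 0.1)
  expect_equal(cw$high_flag, c(TRUE, FALSE))     # threshold 0.12
  # single cohort passes through
  one <- combine_rewiring(list(a = sA), 5)
  expect_equal(stats::setNames(one$combined, one$feature)[names(sA)], sA)
  # unequal weights stay inside the per-cohort envelope
  cw2 <- combine_rewiring(list(a = sA, b = sB), c(1, 99))
  for (f in c("F001", "F002")) {
    v <- cw2$combined[cw2$feature == f]
    expect_gte(v, min(sA[f], sB[f])); expect_lte(v, max(sA[f], sB[f]))
  }
})

test_that("core subnetwork selects drivers by abundance among top scorers", {
  feats <- feature_ids(6)
  rw <- data.frame(feature = feats,
                   combined = c(1, 1, 1, 0.3, 0.1, 0),
                   high_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  ab <- stats::setNames(c(0.05, 0.30, 0.10, 0.4, 0.1, 0.05), feats)
  e <- data.frame(feature_a = c("F002", "F002", "F005"),
                  feature_b = c("F003", "F004", "F006"),
                  r = c(0.5, -0.3, 0.2), p = 0.01,
                  sign_class = c("positive", "negative", "positive"))
  sub <- core_subnetwork(e, ab, rw, depleted = c("F005"), n_core = 2)
  expect_setequal(sub$nodes$feature, c("F002", "F003", "F005"))
  expect_equal(sub$nodes$role[sub$nodes$feature == "F005"], "depleted")
  # induced edges = brute-force membership filter
  keep <- e$feature_a %in% sub$nodes$feature &
    e$feature_b %in% sub$nodes$feature
  expect_equal(sub$edges$feature_a, e$feature_a[keep])
  # fewer top scorers than requested: warn and take all
  rw2 <- rw; rw2$combined <- c(1, rep(0, 5))
  expect_warning(sub2 <- core_subnetwork(e, ab, rw2, character(0), n_core = 3),
                 "taking all")
  expect_equal(sub2$nodes$feature, "F001")
})

test_that("depleted-but-unrewired features score low when correlations hold", {
  # abundance depletion with untouched latent correlation structure:
  # same latent draw, endpoint scaled down on module features
  set.seed(36)
  n <- 150; p <- 16
  z <- matrix(rnorm(n * p), n, p)
  z[, 2] <- 0.8 * z[, 1] + 0.6 * z[, 2]
  z[, 4] <- 0.8 * z[, 3] + 0.6 * z[, 4]
  mk <- function(shift) {
    w <- exp(sweep(z, 2, shift, "+"))
    counts <- t(apply(w, 1, function(row) rmultinom(1, 8000, row / sum(row))))
    dimnames(counts) <- list(sprintf("s%03d", 1:n), feature_ids(p))
    feature_table(counts)
  }
  shift <- rep(0, p); shift[9:12] <- -1          # depleted, uncorrelated
  netA <- permutation_pvalues(mk(rep(0, p)), sparcc(mk(rep(0, p)),
                                                    n_resamples = 5, seed = 1),
                              n_perm = 40, seed = 2)
  netB <- permutation_pvalues(mk(shift), sparcc(mk(shift),
                                                n_resamples = 5, seed = 1),
                              n_perm = 40, seed = 2)
  eA <- filter_edges(netA); eB <- filter_edges(netB)
  part <- detect_modules(unique(rbind(eA, eB)), feature_ids(p))
  sc <- rewiring_score(eA, eB, part)
  depl <- sc[feature_ids(p)[9:12]]
  expect_lte(median(depl), quantile(sc, 0.75))
})
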