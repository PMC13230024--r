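test_that("feature table round-trips through TSV and rejects bad input", {
  ft <- feature_table(matrix(c(5, 1, 0, 3), 2, 2,
                             dimnames = list(c("s1", "s2"), c("fA", "fB"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(unclass(back), unclass(ft))

  bad <- ft; bad[1, 1] <- -1
  writeLines(c("sample_id\tfA\tfB", "s1\t-1\t0", "s2\t1\t3"), path)
  expect_error(read_feature_table(path), "negative or non-integral")
  expect_error(feature_table(matrix(1.5, 1, 1,
                                    dimnames = list("s", "f"))),
               "non-integral")
  expect_error(
    feature_table(matrix(1, 2, 1, dimnames = list(c("s", "s"), "f"))),
    "duplicate sample")
})

test_that("metadata validates condition labels and pairing uniqueness", {
  df <- data.frame(sample_id = c("a", "b", "c", "d"), study_id = "st",
                   subject_id = c("u1", "u1", "u2", "u2"),
                   timepoint = c("baseline", "endpoint",
                                 "baseline", "endpoint"))
  m <- sample_metadata(df, "paired")
  expect_equal(nrow(pair_samples(m)), 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(m, path)
  expect_equal(as.data.frame(read_metadata(path, "paired")),
               as.data.frame(m))

  df2 <- df; df2$timepoint[2] <- "baseline"
  expect_error(sample_metadata(df2, "paired"), "duplicated")
  dfx <- data.frame(sample_id = "a", study_id = "st", subject_id = "u",
                    diagnosis = "UC")
  expect_s3_class(sample_metadata(dfx, "cross_sectional"), "sample_metadata")
  dfx$diagnosis <- "ibd"
  expect_error(sample_metadata(dfx, "cross_sectional"), "unknown diagnosis")
})

test_that("tree reading enforces rootedness and branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2):0;", path)
  tr <- read_tree(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sum(tr$edge.length), 5)
  writeLines("((A,B),C);", path)
  expect_error(read_tree(path), "branch lengths")
  writeLines("(A:1,B:1,C:2);", path)
  expect_error(read_tree(path), "unrooted")
  # round trip
  tr2 <- simulate_tree(8, 11)
  write_tree(tr2, path)
  back <- read_tree(path)
  expect_setequal(back$tip.label, tr2$tip.label)
  expect_equal(sum(back$edge.length), sum(tr2$edge.length), tolerance = 1e-9)
})

test_that("depth filter keeps exactly the samples at or above threshold", {
  counts <- rbind(s1 = c(999, 0), s2 = c(500, 500), s3 = c(2000, 500))
  colnames(counts) <- c("f1", "f2")
  ft <- feature_table(counts)
  out <- filter_min_depth(ft, 1000)
  expect_equal(rownames(out), c("s2", "s3"))
  expect_identical(unclass(filter_min_depth(ft, 0)), unclass(ft))
  expect_warning(empty <- filter_min_depth(ft, 1e7), "no sample")
  expect_equal(nrow(empty), 0)
  # idempotence
  expect_identical(unclass(filter_min_depth(out, 1000)), unclass(out))
})

test_that("prevalence filter uses ceiling with detection = count > 0", {
  set.seed(2)
  counts <- matrix(rpois(20 * 6, 3), 20, 6,
                   dimnames = list(sprintf("s%02d", 1:20), feature_ids(6)))
  counts[, 1] <- 0; counts[1, 1] <- 7     # present in 1/20 -> needs >= 2
  ft <- feature_table(counts)
  expect_false("F001" %in% colnames(filter_prevalence(ft, 0.10)))
  expect_identical(colnames(filter_prevalence(ft, 0)), colnames(ft))
  # 10 samples, feature in exactly 1 sample, ceil(0.1*10) = 1 -> kept
  c10 <- counts[1:10, , drop = FALSE]
  c10[, 2] <- 0; c10[3, 2] <- 5
  expect_true("F002" %in% colnames(filter_prevalence(feature_table(c10), 0.10)))
  # never increases feature count
  expect_lte(ncol(filter_prevalence(ft, 0.5)), ncol(ft))
})

test_that("rarefaction is seeded, exact-depth, and hypergeometric in mean", {
  ft <- feature_table(matrix(c(10, 0), 1, 2,
                             dimnames = list("s1", c("f1", "f2"))))
  expect_equal(as.numeric(unclass(rarefy(ft, 5, seed = 1))), c(5, 0))
  # whole-sample subsample returned unchanged
  expect_equal(as.numeric(unclass(rarefy(ft, 10, seed = 1))), c(10, 0))
  ft2 <- random_feature_table(5, 8, lambda = 300, seed = 3)
  r1 <- rarefy(ft2, 1000, seed = 9)
  r2 <- rarefy(ft2, 1000, seed = 9)
  expect_identical(unclass(r1), unclass(r2))
  expect_true(all(rowSums(r1) == 1000))
  expect_error(rarefy(ft2, 10^7, seed = 1), "filter_min_depth")
  # mean of repeated draws matches the hypergeometric expectation
  ft3 <- feature_table(matrix(c(500, 500), 1, 2,
                              dimnames = list("s", c("a", "b"))))
  draws <- vapply(1:2000, function(s) unclass(rarefy(ft3, 100, seed = s))[1, 1], 0)
  se <- sqrt(100 * 0.5 * 0.5 * (1000 - 100) / (1000 - 1)) / sqrt(2000)
  expect_lt(abs(mean(draws) - 50), 3 * se)
})

test_that("pairing drops incomplete subjects and respects study boundaries", {
  m <- tiny_paired_metadata(3)
  m2 <- sample_metadata(as.data.frame(m)[-2, ], "paired")  # drop an endpoint
  expect_message(pr <- pair_samples(m2), "1 subject")
  expect_equal(nrow(pr), 2)
  expect_equal(attr(pr, "n_dropped"), 1L)
  empty <- sample_metadata(
    data.frame(sample_id = character(), study_id = character(),
               subject_id = character(), timepoint = character()), "paired")
  expect_equal(nrow(pair_samples(empty)), 0)
  # same subject id in two studies pairs within study only
  df <- data.frame(sample_id = c("a", "b", "c", "d"),
                   study_id = c("s1", "s1", "s2", "s2"),
                   subject_id = "u1",
                   timepoint = c("baseline", "endpoint",
                                 "baseline", "endpoint"))
  pr2 <- pair_samples(sample_metadata(df, "paired"))
  expect_equal(nrow(pr2), 2)
  expect_setequal(pr2$study_id, c("s1", "s2"))
  # brute-force count check on random fixtures
  set.seed(5)
  for (rep in 1:5) {
    n <- 12
    df <- data.frame(sample_id = sprintf("x%02d", 1:n), study_id = "st",
                     subject_id = sample(sprintf("u%d", 1:6), n, TRUE),
                     timepoint = sample(c("baseline", "endpoint"), n, TRUE))
    df <- df[!duplicated(df[c("subject_id", "timepoint")]), ]
    expected <- sum(vapply(split(df$timepoint, df$subject_id), function(tp)
      sum(tp == "baseline") == 1 && sum(tp == "endpoint") == 1, logical(1)))
    got <- suppressMessages(pair_samples(sample_metadata(df, "paired")))
    expect_equal(nrow(got), expected)
  }
})

test_that("compositional transforms satisfy their closure identities", {
  ra <- relative_abundance(feature_table(matrix(c(2, 2, 4), 1, 3,
    dimnames = list("s", c("a", "b", "c")))))
  expect_equal(as.numeric(ra), c(0.25, 0.25, 0.5))
  ft <- random_feature_table(10, 7, seed = 4)
  expect_true(all(abs(rowSums(relative_abundance(ft)) - 1) < 1e-12))
  expect_error(relative_abundance(feature_table(matrix(0, 1, 1,
    dimnames = list("s", "f")))), "zero-sum")

  expect_equal(as.numeric(clr_transform(matrix(c(1, 1, 1), 1, 3))),
               c(0, 0, 0))
  got <- clr_transform(matrix(c(9, 0), 1, 2))
  expect_equal(as.numeric(got), c(log(10) / 2, -log(10) / 2),
               tolerance = 1e-9)
  expect_true(all(abs(rowSums(clr_transform(ft))) < 1e-9))
})

test_that("cohort summaries reproduce per-study and total bookkeeping", {
  co <- intervention_cohort_fixture()
  cs <- cohort_summary(co)
  expect_equal(nrow(cs), 8)              # 7 cohorts + total
  tot <- cs[cs$study_id == "Total", ]
  expect_equal(tot$n_subjects, sum(cs$n_subjects[cs$study_id != "Total"]))
  ibd <- ibd_cohort_fixture()
  ics <- cohort_summary(ibd)
  expect_equal(nrow(ics), 9)             # 8 cohorts + total
  per <- ics[ics$study_id != "Total", ]
  tot <- ics[ics$study_id == "Total", ]
  expect_equal(tot$n_HC, sum(per$n_HC))
  expect_equal(tot$n_samples, tot$n_HC + tot$n_CD + tot$n_UC)
  empty <- cohort_set(list(), list())
  expect_equal(cohort_summary(empty)$n_samples, 0)
})
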