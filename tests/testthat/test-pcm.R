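test_that("activity labelling uses the 6.5 cutoff inclusively", {
  expect_true(label_activity(7.0))
  expect_false(label_activity(6.49))
  expect_true(label_activity(6.5))
  expect_error(label_activity(NA_real_), "pChEMBL")
})

test_that("random splits are exact seeded 80:20 partitions", {
  dat <- synth_bioactivity(4, 25, seed = 2)
  sp <- split_random(dat, 77)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$test), seq_len(100))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_random(dat, 77), sp)
  expect_false(identical(split_random(dat, 78), sp))
  expect_error(split_random(dat[1:3, ], 1), "few")
})

test_that("temporal splits put pre-cutoff years in training", {
  dat <- data.frame(target_id = "T", SMILES = letters[1:4],
                    pchembl_value = 5, year = c(2010, 2012, 2013, 2015))
  sp <- split_temporal(dat, 2013)
  expect_equal(sp$train, 1:2)
  expect_equal(sp$test, 3:4)
  old <- dat
  old$year <- 2001:2004
  expect_error(split_temporal(old, 2013), "empty")
})

test_that("feature tables concatenate compound and protein blocks", {
  dat <- synth_bioactivity(3, 8, seed = 5)
  fpm <- ecfp6_matrix(unique(dat$SMILES))
  tid <- unique(dat$target_id)
  ps <- lapply(stats::setNames(tid, tid), function(t) {
    stats::setNames(rep(seq_along(tid)[tid == t], 30), paste0("PC", 1:30))
  })
  x <- build_feature_table(dat, ps, fpm)
  expect_equal(ncol(x), 1024 + 30)
  expect_equal(nrow(x), nrow(dat))
  rs <- lapply(stats::setNames(tid, tid), function(t) {
    stats::setNames(numeric(3785), paste0("f", 1:3785))
  })
  expect_equal(ncol(build_feature_table(dat, rs, fpm)), 1024 + 3785)
  # combination mode: widths add
  both <- build_feature_table(dat, list(ps, rs), fpm)
  expect_equal(ncol(both), 1024 + 30 + 3785)
  expect_error(build_feature_table(dat, ps[-1], fpm), "missing protein")
  expect_error(build_feature_table(dat, ps, fpm[-1, ]), "missing compound")
})

test_that("MCC follows the formula with the degenerate-zero convention", {
  expect_equal(metric_mcc(8, 7, 2, 3),
               (8 * 7 - 2 * 3) / sqrt(10 * 11 * 9 * 10))
  expect_equal(metric_mcc(10, 12, 0, 0), 1)
  expect_equal(metric_mcc(0, 0, 0, 7), 0) # all-negative predictions
  expect_equal(metric_mcc(5, 0, 7, 0), 0) # all-positive predictions
  expect_equal(metric_mcc(0, 0, 5, 7), -1) # perfectly anti-correlated
})

test_that("random-forest models learn additive signal and are reproducible", {
  dat <- synth_bioactivity(8, 50, target_scale = 1, compound_scale = 1,
                           noise_sd = 0.3, seed = 3)
  fpm <- ecfp6_matrix(unique(dat$SMILES))
  tid <- unique(dat$target_id)
  prot <- lapply(stats::setNames(seq_along(tid), tid), function(i) {
    ddpd3:::withr_seed(1000 + i,
                       stats::setNames(stats::rnorm(20), paste0("p", 1:20)))
  })
  x <- build_feature_table(dat, prot, fpm)
  y <- dat$pchembl_value
  sp <- split_random(dat, 1)
  run <- train_eval_rf(x, y, "regression", 1, sp, num_trees = 200)
  expect_gt(run$metrics[["pearson_r"]], 0.5)
  expect_lt(run$metrics[["rmse"]], stats::sd(y[sp$test]))
  expect_equal(nrow(run$cv), 5)
  # identical seed and data give identical metrics and importances
  rerun <- train_eval_rf(x, y, "regression", 1, sp, num_trees = 200)
  expect_identical(run$metrics, rerun$metrics)
  expect_identical(run$importance, rerun$importance)
  # label-shuffled control learns nothing
  ys <- ddpd3:::withr_seed(99, sample(y))
  shuf <- train_eval_rf(x, ys, "regression", 1, sp, num_trees = 200)
  expect_lt(abs(shuf$metrics[["pearson_r"]]), 0.25)
  # classification path with both classes
  cls <- train_eval_rf(x, label_activity(y), "classification", 2, sp,
                       num_trees = 200)
  expect_gt(cls$metrics[["mcc"]], 0.2)
  expect_lte(cls$metrics[["mcc"]], 1)
  expect_error(train_eval_rf(x, rep(TRUE, nrow(x)), "classification", 1, sp),
               "single class")
})

test_that("PCM with informative protein descriptors beats the QSAR average", {
  dat <- synth_bioactivity(6, 40, target_scale = 1.5, compound_scale = 1,
                           noise_sd = 0.3, seed = 11)
  fpm <- ecfp6_matrix(unique(dat$SMILES))
  tid <- unique(dat$target_id)
  prot <- lapply(stats::setNames(seq_along(tid), tid), function(i) {
    v <- numeric(length(tid))
    v[i] <- 1
    stats::setNames(v, paste0("t", seq_along(tid)))
  })
  x <- build_feature_table(dat, prot, fpm)
  pcm_r <- qsar_r <- numeric(3)
  for (i in 1:3) {
    sp <- split_random(dat, i)
    pcm_r[i] <- train_eval_rf(x, dat$pchembl_value, "regression", i, sp,
                              num_trees = 200)$metrics[["pearson_r"]]
    qsar_r[i] <- qsar_baseline(dat, fpm, "regression", i, "random",
                               num_trees = 200)$mean[["pearson_r"]]
  }
  expect_gte(mean(pcm_r), mean(qsar_r))
  # two identical targets: the average equals the single-target metric
  one <- synth_bioactivity(1, 30, seed = 9)
  two <- rbind(one, transform(one, target_id = "T002"))
  q2 <- qsar_baseline(two, ecfp6_matrix(unique(two$SMILES)), "regression",
                      1, "random", num_trees = 100)
  expect_equal(q2$mean[["pearson_r"]],
               mean(q2$per_target$pearson_r))
  expect_equal(q2$per_target$pearson_r[1], q2$per_target$pearson_r[2])
})

test_that("AVE bias is near zero for exchangeable splits and positive for clustered ones", {
  set.seed(9)
  fp <- matrix(stats::rbinom(1000 * 512, 1, 0.1), 1000, 512)
  act <- stats::rbinom(1000, 1, 0.5) == 1
  idx <- sample(1000, 500)
  expect_lt(abs(ave_bias(fp[idx, ], act[idx], fp[-idx, ], act[-idx])), 0.05)
  # test actives duplicated from train actives, inactives disjoint
  tr_act <- fp[1:250, ]
  tr_inact <- matrix(stats::rbinom(150 * 512, 1, 0.5), 150, 512)
  te <- rbind(fp[1:100, ], matrix(stats::rbinom(100 * 512, 1, 0.5), 100, 512))
  bias <- ave_bias(rbind(tr_act, tr_inact),
                   c(rep(TRUE, 250), rep(FALSE, 150)),
                   te, c(rep(TRUE, 100), rep(FALSE, 100)))
  expect_gt(bias, 0.2)
  # swapping active/inactive labels everywhere leaves AVE unchanged
  a1 <- ave_bias(fp[idx, ], act[idx], fp[-idx, ], act[-idx])
  a2 <- ave_bias(fp[idx, ], !act[idx], fp[-idx, ], !act[-idx])
  expect_equal(a1, a2)
  expect_error(ave_bias(fp[idx, ], rep(TRUE, 500), fp[-idx, ], act[-idx]),
               "train_active")
})

test_that("descriptor comparison reproduces the star thresholds", {
  same <- rep(0.4, 10)
  res <- compare_descriptors(same, same)
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "ns")
  a <- 0.40 + c(-1, 1, 0, -1, 1, 0, -1, 1, 0, 0) * 0.001
  b <- 0.45 + c(1, -1, 0, 1, -1, 0, 1, -1, 0, 0) * 0.001
  res2 <- compare_descriptors(a, b)
  expect_equal(res2$stars, "***")
  # dual route: p from the pooled-variance t statistic and t distribution
  sp2 <- ((9 * var(a)) + (9 * var(b))) / 18
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 10))
  expect_equal(res2$p_value, 2 * stats::pt(-abs(tstat), df = 18))
  mid <- compare_descriptors(rnorm(10, 0, 1) + 100, rnorm(10, 0, 1) + 100.1)
  expect_true(mid$stars %in% c("ns", "*", "**", "***"))
  expect_error(compare_descriptors(1, c(1, 2)), "at least 2")
})

test_that("feature ranking recovers a planted feature with deterministic ties", {
  set.seed(6)
  n <- 300
  x <- matrix(stats::rbinom(n * 30, 1, 0.5), n, 30)
  colnames(x) <- sprintf("f%02d", 1:30)
  y <- 3 * x[, 5] + stats::rnorm(n, 0, 0.5)
  sp <- split_random(data.frame(seq_len(n)), 1)
  runs <- lapply(1:3, function(s) {
    train_eval_rf(x, y, "regression", s, sp, num_trees = 100)
  })
  ranked <- top_features(runs, k = 10)
  expect_equal(ranked$feature[1], "f05")
  expect_equal(nrow(ranked), 10)
  expect_true(all(diff(ranked$mean_importance) <= 0))
  full <- top_features(runs, k = 999)
  expect_equal(nrow(full), 30)
  # ties broken lexicographically
  fake <- list(list(importance = c(b = 1, a = 1, c = 2)),
               list(importance = c(a = 1, b = 1, c = 2)))
  tf <- top_features(fake, k = 3)
  expect_equal(tf$feature, c("c", "a", "b"))
  bad <- list(list(importance = c(a = 1)), list(importance = c(b = 1)))
  expect_error(top_features(bad, 1), "mismatched")
})

test_that("the multi-seed benchmark loop is reproducible end to end", {
  dat <- synth_bioactivity(4, 30, seed = 21)
  fpm <- ecfp6_matrix(unique(dat$SMILES))
  tid <- unique(dat$target_id)
  prot <- list(onehot = lapply(stats::setNames(seq_along(tid), tid),
                               function(i) {
    v <- numeric(4)
    v[i] <- 1
    stats::setNames(v, paste0("t", 1:4))
  }))
  b1 <- benchmark_pcm(dat, prot, fpm, "regression", "random",
                      seeds = c(1234L, 2345L), num_trees = 100)
  b2 <- benchmark_pcm(dat, prot, fpm, "regression", "random",
                      seeds = c(1234L, 2345L), num_trees = 100)
  expect_identical(b1$results, b2$results)
  expect_setequal(unique(b1$results$metric), c("pearson_r", "rmse"))
  expect_equal(ddpd_seeds(),
               c(1234L, 2345L, 3456L, 4567L, 5678L, 6879L, 7890L, 8901L,
                 9012L, 9999L))
})
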