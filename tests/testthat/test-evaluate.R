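test_that("confusion metrics evaluate their definitions", {
  lab <- c(rep("movement", 10), rep("noise", 10))
  pred <- c(rep("movement", 9), "noise", rep("noise", 8), "movement", "movement")
  cm <- confusion_metrics(pred, lab)
  expect_equal(cm[c("tp", "fn", "tn", "fp")], list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(cm$error, 0.15)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.8)
  all_mov <- confusion_metrics(rep("movement", 20), lab)
  expect_equal(all_mov$sensitivity, 1)
  expect_equal(all_mov$specificity, 0)
  perfect <- confusion_metrics(lab, lab)
  expect_equal(perfect$error, 0)
  expect_error(confusion_metrics(character(), character()), "empty")
})

test_that("the five-fold test is stratified, exact in its means, and leak-free", {
  x <- withr::with_seed(20, rbind(matrix(rnorm(200 * 2), 200, 2),
                                  matrix(rnorm(200 * 2, 10), 200, 2)))
  y <- rep(c("noise", "movement"), each = 200)
  r <- five_fold_test(x, y, "lda", seed = 3)
  # perfectly separable clouds
  expect_equal(r$mean_error, 0)
  expect_equal(r$mean_sensitivity, 1)
  expect_equal(r$mean_specificity, 1)
  # each part holds 40 movement + 40 noise epochs
  parts <- table(r$part_assignment, y)
  expect_true(all(parts == 40))
  # reported means are the fold means exactly
  expect_identical(r$mean_error, mean(r$folds$error))
  expect_identical(r$mean_sensitivity, mean(r$folds$sensitivity))
  # the test part never appears among the chosen training parts
  for (i in seq_len(5)) {
    chosen <- as.integer(strsplit(r$folds$chosen_training_parts[i], ",")[[1]])
    expect_length(chosen, 3)
    expect_false(i %in% chosen)
  }
  expect_error(five_fold_test(x[1:8, ], y[c(1:4, 201:204)], "lda"), "at least")
})

test_that("permuted labels drive the five-fold test to chance", {
  x <- withr::with_seed(21, matrix(rnorm(200 * 3), 200, 3))
  y <- withr::with_seed(22, sample(rep(c("noise", "movement"), each = 100)))
  r <- five_fold_test(x, y, "lda", seed = 5)
  expect_gte(r$mean_error, 0.4)
  expect_lte(r$mean_error, 0.6)
})

test_that("the template route runs through the same nested protocol", {
  tpl <- sin(2 * pi * 3 * (0:499) / 500)
  mk <- function(n, sig) t(replicate(n, sig * tpl + rnorm(500, 0, 0.3)))
  x <- withr::with_seed(23, rbind(mk(50, 1), mk(50, 0)))
  y <- rep(c("movement", "noise"), each = 50)
  r <- five_fold_test(x, y, "template", seed = 2)
  expect_lt(r$mean_error, 0.1)
  # degrading the template raises the error
  rj <- five_fold_test(x, y, "template", seed = 2, template_jitter_sd = 5)
  expect_gt(rj$mean_error, r$mean_error)
})

test_that("Friedman comparison matches rank algebra and exact enumeration", {
  same <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  f0 <- friedman_compare(cbind(a = same[, 1], b = same[, 1]))
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # k = 2, one method strictly better for all 6 subjects: the maximum stat
  m2 <- cbind(a = 1:6, b = (1:6) + 0.5)
  f2 <- friedman_compare(m2)
  expect_equal(f2$statistic, 6)
  # hand rank algebra on a 4 x 3 table without within-row ties
  m3 <- matrix(c(1, 2, 3,
                 2, 3, 1,
                 1, 3, 2,
                 1, 2, 3), 4, 3, byrow = TRUE)
  ranks <- t(apply(m3, 1, rank))
  n <- 4; k <- 3
  hand <- 12 * sum((colSums(ranks) - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  f3 <- friedman_compare(m3)
  expect_equal(f3$statistic, hand)
  expect_equal(f3$df, k - 1)
  expect_lt(abs(f3$p_value - friedman_exact_p(m3)), 0.02)
  expect_error(friedman_compare(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  # invariance to a monotone per-subject transformation
  f3t <- friedman_compare(exp(m3))
  expect_equal(f3t$statistic, f3$statistic)
})

test_that("Fisher projection separates known clusters and honours its contract", {
  gen <- function(mu) cbind(rnorm(60, mu[1], 0.2), rnorm(60, mu[2], 0.2),
                            rnorm(60, 0, 0.2))
  x <- withr::with_seed(24, rbind(gen(c(0, 0)), gen(c(5, 0)), gen(c(0, 5))))
  lab <- rep(c("noise", "s20", "f60"), each = 60)
  z <- fisher_projection(x, lab)
  expect_identical(dim(z), c(180L, 2L))
  expect_equal(apply(z, 2, range), matrix(c(-1, 1, -1, 1), 2, 2))
  # projected class means pairwise separated by > 5x within-class spread
  mus <- rowsum(z, lab) / 60
  spread <- mean(sapply(unique(lab), function(g) {
    mean(apply(z[lab == g, ], 2, sd))
  }))
  d <- as.matrix(dist(mus))
  expect_gt(min(d[d > 0]), 5 * spread)
  # shuffled labels: projection still defined, output still in range
  zs <- fisher_projection(x, withr::with_seed(25, sample(lab)))
  expect_true(all(zs >= -1 & zs <= 1))
  expect_error(fisher_projection(x, lab, out_dim = 3), "out_dim")
})

test_that("run_study aggregates per-method metrics with standard errors", {
  recs <- lapply(1:3, function(i) {
    generate_recording(sim_config(n_trials_per_task = 8, seed = 30 + i), "real")
  })
  rep_ <- run_study(recs, seed = 9)
  expect_s3_class(rep_, "study_report")
  expect_equal(nrow(rep_$aggregate), 3)
  expect_identical(dim(rep_$errors), c(3L, 3L))
  m <- "lda_temporal"
  errs <- rep_$errors[, m]
  agg <- rep_$aggregate[rep_$aggregate$method == m, ]
  expect_equal(agg$mean_error, mean(errs))
  expect_equal(agg$se_error, sd(errs) / sqrt(3))
  expect_named(rep_$friedman, c("temporal_vs_spectral", "best_vs_template"))
  # imagery cohorts run with the 5-feature temporal mode
  irecs <- lapply(1:2, function(i) {
    generate_recording(sim_config(n_trials_per_task = 8, seed = 40 + i),
                       "imaginary")
  })
  irep <- run_study(irecs, seed = 9, methods = c("lda_temporal", "lda_spectral"))
  expect_equal(irep$group, "imaginary")
  expect_equal(nrow(irep$aggregate), 2)
})
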