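test_that("LDA places the boundary between symmetric classes and mirrors under label swap", {
  x <- withr::with_seed(1, matrix(c(rnorm(50, -1, 0.05), rnorm(50, 1, 0.05))))
  y <- rep(c("noise", "movement"), each = 50)
  m <- train_lda(x, y)
  # boundary at x = -bias/weight, near 0 for symmetric classes
  expect_lt(abs(-m$bias / m$weights), 0.1)
  expect_equal(unname(lda_classify(m, x)), y) # separable: training error 0
  m2 <- train_lda(x, rev(y))
  expect_equal(m2$weights, -m$weights)
  expect_equal(abs(m2$bias), abs(m$bias))
})

test_that("LDA test error approaches the Gaussian Bayes risk at 3-sigma separation", {
  gen <- function(n) {
    x <- rbind(cbind(rnorm(n), rnorm(n)), cbind(rnorm(n, 3), rnorm(n)))
    list(x = x, y = rep(c("noise", "movement"), each = n))
  }
  tr <- withr::with_seed(10, gen(2000))
  te <- withr::with_seed(11, gen(2000))
  m <- train_lda(tr$x, tr$y)
  err <- mean(lda_classify(m, te$x) != te$y)
  bayes <- stats::pnorm(-1.5) # means 3 sigma apart, identity covariance
  expect_lt(abs(err - bayes), 0.02)
  # independent oracle: MASS::lda with equal priors agrees on predictions
  mm <- MASS::lda(tr$x, grouping = tr$y, prior = c(0.5, 0.5))
  agree <- mean(as.character(stats::predict(mm, te$x)$class) ==
                  lda_classify(m, te$x))
  expect_gt(agree, 0.995)
})

test_that("LDA decisions are invariant to affine feature transforms", {
  tr <- withr::with_seed(12, list(
    x = rbind(cbind(rnorm(200), rnorm(200)), cbind(rnorm(200, 2), rnorm(200, 1))),
    y = rep(c("noise", "movement"), each = 200)))
  a <- matrix(c(2, 0.5, -1, 3), 2, 2) # invertible
  b <- c(5, -7)
  xt <- sweep(tr$x %*% a, 2, b, "+")
  m1 <- train_lda(tr$x, tr$y)
  m2 <- train_lda(xt, tr$y)
  expect_equal(lda_classify(m1, tr$x), lda_classify(m2, xt))
})

test_that("degenerate LDA inputs follow the documented rules", {
  expect_error(train_lda(matrix(rnorm(10)), rep("noise", 10)), "two values")
  m <- structure(list(weights = c(0, 0), bias = -1,
                      class_order = c("noise", "movement")),
                 class = "lda_model")
  expect_equal(unname(lda_classify(m, matrix(rnorm(20), 10, 2))),
               rep("noise", 10))
  m$bias <- 0 # exact boundary -> negative class
  expect_equal(unname(lda_classify(m, matrix(1, 1, 2))), "noise")
  expect_error(lda_score(m, matrix(1, 1, 3)), "mismatch")
  # constant feature: regularisation keeps the solve finite
  x <- cbind(rnorm(40), 1)
  y <- rep(c("noise", "movement"), 20)
  expect_true(all(is.finite(train_lda(x, y)$weights)))
})

test_that("the template is the ensemble average and correlation is gain/offset invariant", {
  e <- sin(2 * pi * (0:999) / 500)
  m <- rbind(e, e, e)
  expect_equal(build_template(m), e, ignore_attr = TRUE)
  expect_error(build_template(m[0, , drop = FALSE]), "2 epochs")
  expect_equal(build_template(rbind(e, -e)), rep(0, 1000), ignore_attr = TRUE)
  expect_equal(template_correlation(e, e), 1)
  expect_equal(template_correlation(e, -e), -1)
  expect_equal(template_correlation(e, 3.2 * e + 10), 1)
  expect_error(template_correlation(e, rep(1, 1000)), "constant")
  # at default SNR the trained template's minimum sits in the final part of
  # the window (the half-cosine is nearly flat over its last 300 ms, so the
  # residual noise of a 50-epoch average can move the argmin within it)
  cfg <- sim_config(n_trials_per_task = 25, seed = 6)
  rec <- generate_recording(cfg, "real")
  ep <- extract_epochs(surrogate_channels(rec), rec$true_onsets,
                       rec$task_labels, "temporal")
  tpl <- build_template(epoch_matrix(ep, "movement"))
  expect_gte(which.min(tpl), 0.85 * length(tpl))
  expect_lt(min(tpl), -4)
})

test_that("threshold fitting minimises error with ties toward sensitivity", {
  r <- c(rep(0.9, 10), rep(0.1, 10))
  y <- rep(c("movement", "noise"), each = 10)
  th <- fit_threshold(r, y)
  errs <- mean((r > th) != (y == "movement"))
  expect_equal(errs, 0)
  # the grid's lowest zero-error threshold: noise at 0.1 is not > 0.1
  expect_equal(th, 0.10)
  # permuted labels leave only chance performance
  yp <- withr::with_seed(13, sample(y))
  thp <- fit_threshold(r, yp)
  expect_gte(mean((r > thp) != (yp == "movement")), 0.4)
  # indistinguishable singletons: error 0.5 at best
  th1 <- fit_threshold(c(0.5, 0.5), c("movement", "noise"))
  expect_equal(mean((c(0.5, 0.5) > th1) != c(TRUE, FALSE)), 0.5)
})

test_that("template classification applies the strict-greater rule", {
  tpl <- sin(2 * pi * (0:999) / 500)
  m <- template_model(tpl, 0.5)
  x <- rbind(tpl, -tpl, 0.9 * tpl + withr::with_seed(14, rnorm(1000, 0, 2)))
  got <- unname(template_classify(m, x))
  expect_equal(got[1], "movement")
  expect_equal(got[2], "noise")
  expect_error(template_model(rep(1, 10), 0.5), "constant")
})

test_that("both detectors succeed at high SNR and sit at chance for a null generator", {
  run_one <- function(amp, pink_sd, seed) {
    cfg <- sim_config(mrcp_peak_amplitude = amp, background_pink_sd = pink_sd,
                      seed = seed)
    rec <- generate_recording(cfg, "real")
    surr <- surrogate_channels(rec)
    ons <- resolve_onsets(rec)
    ep_t <- extract_epochs(surr, ons$onset, ons$task, "temporal")
    ep_s <- extract_epochs(surr, ons$onset, ons$task, "spectral")
    fsp <- extract_features(ep_s, "spectral")
    c(lda = five_fold_test(as.matrix(fsp[, -(1:4)]), fsp$label, "lda",
                           seed = 3)$mean_error,
      template = five_fold_test(ep_t$samples, ep_t$meta$label, "template",
                                seed = 3)$mean_error)
  }
  # high SNR: peak -10 uV over pink sd 1 uV, 200 epochs
  expect_true(all(run_one(-10, 1, 81) <= 0.05))
  # null generator: expected error at chance within 5 points (a single
  # 200-epoch realisation scatters with a Monte-Carlo sd of ~5 points, so
  # the expectation is estimated over four seeds)
  nul <- rowMeans(sapply(82:85, function(s) run_one(0, 1, s)))
  expect_true(all(nul >= 0.45 & nul <= 0.55))
})
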