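#' Confusion counts and detection metrics
#'
#' Detection error is the fraction of false positives plus false negatives;
#' sensitivity is the true-positive rate over movements; specificity the
#' true-negative rate over noise.
#'
#' @param predictions,labels equal-length label vectors.
#' @param positive the positive-class label (default `"movement"`).
#' @return list with `tp`, `tn`, `fp`, `fn`, `error`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(predictions, labels, positive = "movement") {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(labels)) stop("length mismatch")
  p <- as.character(predictions) == positive
  a <- as.character(labels) == positive
  tp <- sum(p & a); tn <- sum(!p & !a); fp <- sum(p & !a); fn <- sum(!p & a)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       error = (fp + fn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Class-stratified assignment of epochs to parts: shuffle within each class
# (seeded) and deal cyclically, so part sizes per class differ by at most 1.
stratified_parts <- function(y, k, seed) {
  part <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(as.character(y))) {
      idx <- sample(which(as.character(y) == cls))
      part[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  part
}

fit_detector <- function(x, y, method, template_jitter_sd = 0) {
  if (method == "lda") {
    train_lda(x, y)
  } else {
    cls <- class_order(y)
    tpl <- build_template(x[as.character(y) == cls[2], , drop = FALSE])
    if (template_jitter_sd > 0) {
      tpl <- tpl + stats::rnorm(length(tpl), 0, template_jitter_sd)
    }
    r <- apply(x, 1, template_correlation, template = tpl)
    template_model(tpl, fit_threshold(r, y))
  }
}

predict_detector <- function(model, x) {
  if (inherits(model, "lda_model")) lda_classify(model, x)
  else template_classify(model, x)
}

#' Nested five-fold test procedure
#'
#' Splits the epochs into five class-stratified parts (seeded shuffle). For
#' each choice of test part, a four-fold validation runs on the remaining
#' parts: train on three, validate on one, rotating the validation part.
#' The trained detector with the lowest validation error (ties broken by the
#' lowest validation-part index) is applied unchanged to the held-out test
#' part. The validation step selects among already-trained models; no model
#' ever sees its test part.
#'
#' @param x feature matrix (for `method = "lda"`) or matrix of temporal-path
#'   epoch samples (for `method = "template"`), one epoch per row.
#' @param y movement/noise labels per row.
#' @param method `"lda"` or `"template"`.
#' @param seed integer seed for the part assignment.
#' @param n_folds number of parts (default 5).
#' @param template_jitter_sd standard deviation of Gaussian noise added to
#'   each trained template (microvolts), modelling a degraded template
#'   (default 0: none).
#' @return An object of class `subject_result`: list with `folds` (one row
#'   per fold: confusion counts, error, sensitivity, specificity,
#'   `chosen_training_parts` as a comma-joined string), `mean_error`,
#'   `mean_sensitivity`, `mean_specificity`, `method`, `part_assignment`.
#' @export
five_fold_test <- function(x, y, method = c("lda", "template"), seed = 1,
                           n_folds = 5, template_jitter_sd = 0) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  if (min(table(y)) < n_folds) {
    stop("need at least ", n_folds, " epochs per class")
  }
  part <- stratified_parts(y, n_folds, seed)
  folds <- vector("list", n_folds)
  for (test_part in seq_len(n_folds)) {
    rest <- setdiff(seq_len(n_folds), test_part)
    best <- NULL
    for (val_part in rest) { # increasing order: ties go to the lowest index
      tr <- part %in% setdiff(rest, val_part)
      va <- part == val_part
      model <- withr::with_seed(seed + 1000L * test_part + val_part,
                                fit_detector(x[tr, , drop = FALSE], y[tr],
                                             method, template_jitter_sd))
      verr <- confusion_metrics(predict_detector(model, x[va, , drop = FALSE]),
                                y[va])$error
      if (is.null(best) || verr < best$verr) {
        best <- list(model = model, verr = verr,
                     train_parts = setdiff(rest, val_part))
      }
    }
    te <- part == test_part
    cm <- confusion_metrics(predict_detector(best$model, x[te, , drop = FALSE]),
                            y[te])
    folds[[test_part]] <- data.frame(
      fold = test_part, tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
      error = cm$error, sensitivity = cm$sensitivity,
      specificity = cm$specificity,
      chosen_training_parts = paste(best$train_parts, collapse = ","),
      stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  structure(list(folds = folds,
                 mean_error = mean(folds$error),
                 mean_sensitivity = mean(folds$sensitivity),
                 mean_specificity = mean(folds$specificity),
                 method = method,
                 part_assignment = part),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s: error %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$method, 100 * x$mean_error, 100 * x$mean_sensitivity,
              100 * x$mean_specificity))
  invisible(x)
}

#' Friedman test across methods
#'
#' Ranks the methods within each subject (mean ranks for ties) and computes
#' the Friedman chi-square statistic with `k - 1` degrees of freedom via
#' [stats::friedman.test()]. For small untied tables (at most 8 subjects, 4
#' methods) the p-value comes from the exact permutation null distribution
#' of the statistic instead of the chi-square approximation, which is poor
#' at such sizes. A table whose every row is completely tied carries no
#' information: statistic 0, p-value 1.
#'
#' @param scores numeric matrix, subjects in rows, methods in columns; no
#'   missing cells.
#' @return list with `statistic`, `df`, `p_value`, `exact` (logical).
#' @export
friedman_compare <- function(scores) {
  m <- as.matrix(scores)
  if (anyNA(m)) stop("missing cells are not allowed")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 methods")
  n <- nrow(m); k <- ncol(m)
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    return(list(statistic = 0, df = k - 1, p_value = 1, exact = FALSE))
  }
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  untied <- all(apply(m, 1, function(r) length(unique(r)) == k))
  if (untied && n <= 8 && k <= 3) {
    p <- friedman_exact_pvalue(stat, n, k)
    return(list(statistic = stat, df = k - 1, p_value = p, exact = TRUE))
  }
  list(statistic = stat, df = unname(ft$parameter), p_value = ft$p.value,
       exact = FALSE)
}

# Exact permutation null of the Friedman statistic for untied data: each
# subject contributes a uniform random permutation of ranks 1..k. The joint
# distribution of the column rank sums is built by dynamic programming over
# subjects; the p-value is P(T >= observed).
friedman_exact_pvalue <- function(stat, n, k) {
  perms <- all_permutations(k)
  # state: rank sums of the first k-1 columns (the last is determined)
  dist <- list()
  key <- function(v) paste(v, collapse = ",")
  dist[[key(rep(0, k - 1))]] <- 1
  for (s in seq_len(n)) {
    nxt <- list()
    for (ky in names(dist)) {
      base <- as.integer(strsplit(ky, ",", fixed = TRUE)[[1]])
      for (i in seq_len(nrow(perms))) {
        v <- base + perms[i, seq_len(k - 1)]
        kv <- key(v)
        nxt[[kv]] <- (nxt[[kv]] %||% 0) + dist[[ky]]
      }
    }
    dist <- nxt
  }
  total <- factorial(k)^n
  p <- 0
  for (ky in names(dist)) {
    rs <- as.integer(strsplit(ky, ",", fixed = TRUE)[[1]])
    rs <- c(rs, n * k * (k + 1) / 2 - sum(rs))
    t_ <- 12 * sum((rs - n * (k + 1) / 2)^2) / (n * k * (k + 1))
    if (t_ >= stat - 1e-9) p <- p + dist[[ky]]
  }
  p / total
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(sub, k)[, append(seq_len(k - 1), k, after = pos - 1), drop = FALSE]
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-class Fisher discriminant projection
#'
#' Solves the generalised eigenproblem of between-class versus within-class
#' scatter and projects the features onto the top discriminant directions,
#' then rescales each output dimension linearly to `[-1, 1]` (for plotting).
#' A singular within-class scatter is ridge-regularised with a warning.
#'
#' @param x numeric feature matrix.
#' @param labels class labels (e.g. f60 / s20 / noise).
#' @param out_dim output dimensionality, at most `nlevels - 1`.
#' @return matrix with `out_dim` columns, each scaled to `[-1, 1]`.
#' @export
fisher_projection <- function(x, labels, out_dim = 2) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (out_dim > length(classes) - 1) {
    stop("out_dim must be <= number of classes - 1")
  }
  d <- ncol(x)
  mu <- colMeans(x)
  sw <- matrix(0, d, d); sb <- matrix(0, d, d)
  for (cls in classes) {
    xi <- x[labels == cls, , drop = FALSE]
    mui <- colMeans(xi)
    sw <- sw + crossprod(sweep(xi, 2, mui))
    sb <- sb + nrow(xi) * tcrossprod(mui - mu)
  }
  if (rcond(sw) < 1e-10) {
    warning("within-class scatter is ill-conditioned; regularising")
    sw <- sw + diag(1e-6 * max(sum(diag(sw)), .Machine$double.eps) / d, d)
  }
  e <- eigen(solve(sw, sb))
  v <- Re(e$vectors[, order(-Re(e$values))[seq_len(out_dim)], drop = FALSE])
  z <- x %*% v
  apply(z, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) return(rep(0, length(col)))
    2 * (col - rng[1]) / diff(rng) - 1
  })
}

#' Run the full cohort study
#'
#' For every recording: preprocess to the surrogate pair, resolve onsets,
#' cut epochs on both paths, extract features, and evaluate each requested
#' method with the nested five-fold test. Aggregates mean and standard error
#' (sd/sqrt(n)) across subjects per method and compares methods with the
#' Friedman test, first temporal versus spectral features and then the
#' better of the two versus template matching.
#'
#' @param recordings list of `mrcp_recording` objects (one cohort/group).
#' @param seed integer; per-subject fold seeds are derived from it.
#' @param methods subset of `c("lda_temporal", "lda_spectral", "template")`.
#' @param template_jitter_sd passed to [five_fold_test()] for the template
#'   method.
#' @param regression_end passed to [temporal_features()].
#' @return An object of class `study_report`: list with `subjects` (per
#'   subject per method: mean metrics), `errors` (subjects x methods
#'   matrix), `aggregate` (per method: mean and SE of each metric),
#'   `friedman` (the two comparisons), `log` (dropped trials and imagery
#'   flags), `group`, `n_subjects`.
#' @export
run_study <- function(recordings, seed = 1,
                      methods = c("lda_temporal", "lda_spectral", "template"),
                      template_jitter_sd = 0,
                      regression_end = "epoch_end") {
  stopifnot(length(recordings) >= 2)
  methods <- match.arg(methods, several.ok = TRUE)
  group <- recordings[[1]]$group
  mode <- if (group == "imaginary") "imagery" else "executed"
  n_sub <- length(recordings)
  res <- list(); logs <- list()
  for (i in seq_len(n_sub)) {
    rec <- recordings[[i]]
    surr <- surrogate_channels(rec)
    ons <- resolve_onsets(rec)
    keep <- !is.na(ons$onset)
    ep_t <- extract_epochs(surr, ons$onset[keep], ons$task[keep], "temporal")
    ep_s <- extract_epochs(surr, ons$onset[keep], ons$task[keep], "spectral")
    if (nrow(ep_t$dropped) || any(!keep) || any(ons$flagged)) {
      logs[[length(logs) + 1]] <- data.frame(
        subject = i,
        trial = c(ons$trial[!keep], ons$trial[ons$flagged], ep_t$dropped$trial),
        reason = c(rep("onset not found", sum(!keep)),
                   rep("imagery force guard", sum(ons$flagged)),
                   ep_t$dropped$reason))
    }
    sub <- list()
    subj_seed <- (seed + 7919L * i) %% .Machine$integer.max
    for (m in methods) {
      sub[[m]] <- switch(
        m,
        lda_temporal = {
          ft <- extract_features(ep_t, "temporal", mode = mode,
                                 regression_end = regression_end)
          five_fold_test(as.matrix(ft[, -(1:4)]), ft$label, "lda", subj_seed)
        },
        lda_spectral = {
          fs <- extract_features(ep_s, "spectral")
          five_fold_test(as.matrix(fs[, -(1:4)]), fs$label, "lda", subj_seed)
        },
        template = five_fold_test(ep_t$samples, ep_t$meta$label, "template",
                                  subj_seed,
                                  template_jitter_sd = template_jitter_sd))
    }
    res[[i]] <- sub
  }
  metric <- function(m, what) {
    vapply(res, function(s) s[[m]][[what]], numeric(1))
  }
  errors <- sapply(methods, metric, what = "mean_error")
  if (is.null(dim(errors))) errors <- matrix(errors, nrow = 1,
                                             dimnames = list(NULL, methods))
  aggregate <- do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m,
               mean_error = mean(metric(m, "mean_error")),
               se_error = stats::sd(metric(m, "mean_error")) / sqrt(n_sub),
               mean_sensitivity = mean(metric(m, "mean_sensitivity")),
               se_sensitivity = stats::sd(metric(m, "mean_sensitivity")) / sqrt(n_sub),
               mean_specificity = mean(metric(m, "mean_specificity")),
               se_specificity = stats::sd(metric(m, "mean_specificity")) / sqrt(n_sub),
               stringsAsFactors = FALSE)
  }))
  friedman <- list()
  if (all(c("lda_temporal", "lda_spectral") %in% methods) && n_sub >= 2) {
    friedman$temporal_vs_spectral <-
      friedman_compare(errors[, c("lda_temporal", "lda_spectral")])
    if ("template" %in% methods) {
      best <- if (mean(errors[, "lda_spectral"]) <= mean(errors[, "lda_temporal"]))
        "lda_spectral" else "lda_temporal"
      friedman$best_vs_template <-
        c(list(best_feature_method = best),
          friedman_compare(errors[, c(best, "template")]))
    }
  }
  structure(list(subjects = res, errors = errors, aggregate = aggregate,
                 friedman = friedman,
                 log = if (length(logs)) do.call(rbind, logs) else
                   data.frame(subject = integer(), trial = integer(),
                              reason = character()),
                 group = group, n_subjects = n_sub, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$n_subjects, "subjects,", x$group, "movements\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-13s error %5.1f +/- %.1f%%  sens %5.1f +/- %.1f%%  spec %5.1f +/- %.1f%%\n",
                a$method[i], 100 * a$mean_error[i], 100 * a$se_error[i],
                100 * a$mean_sensitivity[i], 100 * a$se_sensitivity[i],
                100 * a$mean_specificity[i], 100 * a$se_specificity[i]))
  }
  for (nm in names(x$friedman)) {
    f <- x$friedman[[nm]]
    cat(sprintf("  Friedman %s: chi2 = %.3g, p = %.3g\n", nm, f$statistic,
                f$p_value))
  }
  if (nrow(x$log)) cat("  logged trials:", nrow(x$log), "\n")
  invisible(x)
}
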