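#' Train a linear discriminant (movement vs noise)
#'
#' Fisher/Gaussian LDA in closed form: pooled within-class covariance, equal
#' priors (the epoch classes are balanced by design). The weight vector is
#' `solve(S, mu_pos - mu_neg)` and the bias places the boundary at the
#' midpoint of the class means. When the pooled covariance is
#' ill-conditioned it is regularised by adding `1e-6 * trace(S)/d` to the
#' diagonal. Decision rule: movement iff the discriminant score is strictly
#' positive (ties go to noise).
#'
#' @param x numeric feature matrix, epochs in rows.
#' @param y labels with exactly two distinct values; `"movement"` (or
#'   logical `TRUE`) is the positive class when present, otherwise the
#'   lexicographically later label.
#' @return An object of class `lda_model`: list with `weights`, `bias`,
#'   `class_order` (negative, positive) and `feature_names`.
#' @export
train_lda <- function(x, y) {
  x <- as.matrix(x)
  cls <- class_order(y)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  neg <- x[y == cls[1], , drop = FALSE]
  pos <- x[y == cls[2], , drop = FALSE]
  if (nrow(neg) < 2 || nrow(pos) < 2) stop("need >= 2 epochs per class")
  mu0 <- colMeans(neg); mu1 <- colMeans(pos)
  d <- ncol(x)
  s <- ((nrow(neg) - 1) * stats::cov(neg) + (nrow(pos) - 1) * stats::cov(pos)) /
    (nrow(neg) + nrow(pos) - 2)
  if (d == 1) s <- matrix(s, 1, 1)
  if (!all(is.finite(s)) || rcond(s) < 1e-10) {
    s <- s + diag(1e-6 * max(sum(diag(s)), .Machine$double.eps) / d, d)
  }
  w <- drop(solve(s, mu1 - mu0))
  b <- -sum(w * (mu0 + mu1)) / 2
  structure(list(weights = w, bias = b, class_order = cls,
                 feature_names = colnames(x)),
            class = "lda_model")
}

class_order <- function(y) {
  u <- sort(unique(as.character(y)))
  if (length(u) != 2) stop("labels must take exactly two values")
  if ("movement" %in% u) c(setdiff(u, "movement"), "movement") else u
}

#' Discriminant score
#'
#' @param model an `lda_model`.
#' @param x feature matrix (or vector for a single epoch).
#' @return numeric score per row; positive means the positive class.
#' @export
lda_score <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$weights)) {
    stop("feature count mismatch: model has ", length(model$weights),
         ", input has ", ncol(x))
  }
  drop(as.matrix(x) %*% model$weights) + model$bias
}

#' Classify epochs with a trained discriminant
#'
#' @inheritParams lda_score
#' @return character vector of class labels; a score of exactly zero is
#'   assigned to the negative (noise) class.
#' @export
lda_classify <- function(model, x) {
  ifelse(lda_score(model, x) > 0, model$class_order[2], model$class_order[1])
}

#' Build an MRCP template
#'
#' The pointwise mean (ensemble average) of the training movement epochs on
#' the temporal path.
#'
#' @param train_epochs matrix of movement epochs (rows) by samples.
#' @return numeric template, one value per sample.
#' @export
build_template <- function(train_epochs) {
  train_epochs <- as.matrix(train_epochs)
  if (nrow(train_epochs) < 2) stop("need at least 2 epochs to average")
  colMeans(train_epochs)
}

#' Correlation between a template and an epoch
#'
#' Pearson correlation coefficient, so the match is invariant to per-epoch
#' gain and offset.
#'
#' @param template,epoch numeric series of equal length; neither constant.
#' @return scalar in `[-1, 1]`.
#' @export
template_correlation <- function(template, epoch) {
  if (length(template) != length(epoch)) stop("length mismatch")
  if (stats::sd(template) == 0 || stats::sd(epoch) == 0) {
    stop("correlation undefined for a constant series")
  }
  stats::cor(template, epoch)
}

#' Fit a correlation threshold
#'
#' Scans thresholds on a fixed grid from -1 to 1 in steps of 0.01 and
#' returns the value minimising the detection error under the rule
#' "movement iff r > threshold"; ties are broken toward the lower threshold
#' (favouring sensitivity).
#'
#' @param correlations numeric vector of template correlations.
#' @param labels class labels aligned with `correlations`.
#' @param grid candidate thresholds.
#' @return the selected threshold.
#' @export
fit_threshold <- function(correlations, labels,
                          grid = (-100:100) / 100) {
  cls <- class_order(labels)
  is_pos <- as.character(labels) == cls[2]
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present")
  err <- vapply(grid, function(th) {
    mean((correlations > th) != is_pos)
  }, numeric(1))
  grid[which.min(err)] # which.min takes the first, i.e. lowest, threshold
}

#' Template-matching detector
#'
#' Bundles a template, its correlation threshold, and the class order.
#'
#' @param template numeric template series (not constant).
#' @param threshold correlation threshold in `[-1, 1]`.
#' @return An object of class `template_model`.
#' @export
template_model <- function(template, threshold) {
  if (stats::sd(template) == 0) stop("template must not be constant")
  stopifnot(threshold >= -1, threshold <= 1)
  structure(list(template = template, threshold = threshold,
                 class_order = c("noise", "movement")),
            class = "template_model")
}

#' Classify epochs by template correlation
#'
#' @param model a `template_model`.
#' @param x matrix of epochs (rows) by samples.
#' @return character vector of labels: movement iff the Pearson correlation
#'   with the template strictly exceeds the threshold.
#' @export
template_classify <- function(model, x) {
  r <- apply(as.matrix(x), 1, template_correlation, template = model$template)
  ifelse(r > model$threshold, model$class_order[2], model$class_order[1])
}
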