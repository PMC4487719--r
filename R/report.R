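#' Write a study report to disk
#'
#' Emits a machine-readable `report.json` (per-subject fold metrics, the
#' aggregate table, Friedman statistics, the trial log) and a plain-text
#' `summary.txt` with the aggregate table. Output is fully determined by the
#' report object, so two runs with the same configuration and seed produce
#' byte-identical files.
#'
#' @param report a `study_report` from [run_study()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(seq_along(report$subjects), function(i) {
    lapply(report$subjects[[i]], function(sr) {
      list(folds = sr$folds, mean_error = sr$mean_error,
           mean_sensitivity = sr$mean_sensitivity,
           mean_specificity = sr$mean_specificity, method = sr$method)
    })
  })
  payload <- list(group = report$group, n_subjects = report$n_subjects,
                  seed = report$seed, aggregate = report$aggregate,
                  friedman = report$friedman, subjects = subjects,
                  log = report$log)
  jsonlite::write_json(payload, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(path, "summary.txt"))
  invisible(path)
}

#' Write a feature table or projection as delimited text
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' Serialise a detector model to flat text
#'
#' LDA models are written as `feature,name = coefficient` lines plus the
#' bias; template models as the threshold followed by the template samples.
#' For audit and reuse, not for exchange with other software.
#'
#' @param model an `lda_model` or `template_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "lda_model")) {
    nm <- model$feature_names
    if (is.null(nm)) nm <- paste0("f", seq_along(model$weights))
    lines <- c("type = lda",
               paste0("class_order = ", paste(model$class_order, collapse = ",")),
               sprintf("bias = %.17g", model$bias),
               sprintf("weight %s = %.17g", nm, model$weights))
  } else if (inherits(model, "template_model")) {
    lines <- c("type = template",
               sprintf("threshold = %.17g", model$threshold),
               sprintf("template = %s",
                       paste(sprintf("%.17g", model$template), collapse = ",")))
  } else {
    stop("unsupported model class")
  }
  writeLines(lines, path)
  invisible(path)
}
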