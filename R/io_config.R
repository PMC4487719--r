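#' Study configuration
#'
#' All tunables of the pipeline in one validated list: the simulation
#' settings (see [sim_config()]), the filter corners, the epoch windows, the
#' Welch settings, the band edges, the temporal-feature switches, the
#' threshold grid, and the fold structure. Every default is the value the
#' analysis is defined with; only override what an experiment varies.
#'
#' @param ... named overrides of any default field.
#' @return An object of class `study_config`.
#' @export
study_config <- function(...) {
  sim <- sim_config()
  defaults <- c(unclass(sim)[setdiff(names(sim), "channel_gains")],
                list(
                  channel_gains = sim$channel_gains,
                  bp_low = 0.05, bp_high = 10, hp_cutoff = 0.05,
                  filter_order = 2,
                  signal_window = c(-2, 0), noise_window = c(-5, -3),
                  welch_seg_len_s = 1, welch_overlap = 0.5,
                  band_lo = c(0, 4, 8, 13, 30),
                  band_hi = c(4, 8, 13, 30, 100),
                  temporal_mode = "executed",
                  regression_end = "epoch_end",
                  threshold_grid_step = 0.01,
                  n_folds = 5, n_validation_folds = 4,
                  n_subjects = 12,
                  group = "real",
                  template_jitter_sd = 0,
                  out_dir = "."))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  if (any(cfg$band_hi <= cfg$band_lo)) {
    stop("every band must satisfy lo < hi")
  }
  stopifnot(cfg$bp_low < cfg$bp_high, cfg$hp_cutoff > 0,
            cfg$n_folds >= 2, cfg$n_validation_folds == cfg$n_folds - 1,
            cfg$welch_overlap >= 0, cfg$welch_overlap < 1,
            cfg$group %in% c("real", "imaginary", "attempted"),
            cfg$temporal_mode %in% c("executed", "imagery"),
            cfg$regression_end %in% c("epoch_end", "max_negativity"))
  validate_sim_config(as_sim_config(cfg))
  invisible(cfg)
}

#' Extract the simulation part of a study configuration
#'
#' @param cfg a `study_config`.
#' @return a [sim_config()].
#' @export
as_sim_config <- function(cfg) {
  fields <- names(formals(sim_config))
  fields <- setdiff(fields, "channel_gains")
  do.call(sim_config, c(cfg[fields], list(channel_gains = cfg$channel_gains)))
}

#' Save a study configuration as flat key-value text
#'
#' One `key = value` line per field; vectors are comma-joined; numbers are
#' written with full precision so [load_config()] round-trips losslessly.
#'
#' @param cfg a `study_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  keys <- names(unclass(cfg))
  lines <- vapply(keys, function(k) {
    v <- cfg[[k]]
    if (k == "channel_gains") {
      paste0(k, " = ", paste(names(v), sprintf("%.17g", v), sep = ":",
                             collapse = ","))
    } else if (is.null(v)) {
      paste0(k, " = ")
    } else {
      paste0(k, " = ", fmt(v))
    }
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load a study configuration from flat key-value text
#'
#' Absent keys keep their defaults; unknown keys raise an error naming them.
#'
#' @param path file written by [save_config()] (or by hand).
#' @return a `study_config`.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  template <- study_config()
  over <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(unclass(template))) {
      stop("unknown config key: ", key)
    }
    over[[key]] <- parse_config_value(key, val, template[[key]])
  }
  do.call(study_config, over)
}

parse_config_value <- function(key, val, ref) {
  if (val == "") return(NULL)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  if (key == "channel_gains") {
    kv <- strsplit(parts, ":", fixed = TRUE)
    out <- vapply(kv, function(p) as.numeric(p[2]), 0)
    names(out) <- vapply(kv, `[`, "", 1)
    return(out)
  }
  if (is.numeric(ref) || is.null(ref)) {
    out <- suppressWarnings(as.numeric(parts))
    if (anyNA(out)) stop("invalid numeric value for key '", key, "': ", val)
    return(out)
  }
  trimws(parts)
}
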