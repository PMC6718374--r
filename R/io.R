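#' Read and write curve CSV files
#'
#' Curves are exchanged as plain CSV with `#`-prefixed header comments
#' carrying metadata (`unit`, optionally `seed`, `config_hash`,
#' `decay_corrected`, `reference_time`). Sampled curves use columns
#' `time_s,value`; framed TACs use
#' `frame_start_s,frame_duration_s,mean_activity`. `read_curve_csv()`
#' dispatches on the header columns and returns the matching class,
#' validating its invariants (strictly increasing times, contiguous
#' frames) with the offending row named on failure.
#'
#' @param x A [sampled_curve()] or [framed_tac()].
#' @param path File path.
#' @param extra Named character vector of extra `# key=value` header
#'   comments to write.
#' @return `read_curve_csv()`: a [sampled_curve()] or [framed_tac()];
#'   `write_curve_csv()`: `path`, invisibly.
#' @export
write_curve_csv <- function(x, path, extra = NULL) {
  meta <- character()
  if (inherits(x, "sampled_curve")) {
    meta["unit"] <- curve_unit(x)
    df <- data.frame(time_s = x$time, value = x$value)
  } else if (inherits(x, "framed_tac")) {
    meta["decay_corrected"] <- as.character(is_decay_corrected(x))
    meta["reference_time"] <- format(attr(x, "reference_time"), digits = 15)
    df <- data.frame(frame_start_s = x$start, frame_duration_s = x$duration,
                     mean_activity = x$activity)
  } else {
    abort("`x` must be a sampled_curve or framed_tac.")
  }
  meta <- c(meta, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  writeLines(paste(names(df), collapse = ","), con)
  write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in sub("^#\\s*", "", hdr)) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- tryCatch(
    read.csv(text = lines[!grepl("^#", lines)], strip.white = TRUE),
    error = function(e) abort(sprintf("malformed CSV in %s: %s", path, conditionMessage(e))))
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    abort(sprintf("malformed rows in %s: column `%s` is not numeric.",
                  path, names(df)[bad]))
  }
  if (all(c("time_s", "value") %in% names(df))) {
    sampled_curve(df$time_s, df$value,
                  unit = meta$unit %||% "unitless")
  } else if (all(c("frame_start_s", "frame_duration_s", "mean_activity") %in% names(df))) {
    framed_tac(frame_scheme(df$frame_start_s, df$frame_duration_s),
               df$mean_activity,
               decay_corrected = isTRUE(as.logical(meta$decay_corrected %||% FALSE)),
               reference_time = as.numeric(meta$reference_time %||% df$frame_start_s[1]))
  } else {
    abort(sprintf("unrecognized columns in %s: expected time_s,value or frame_start_s,frame_duration_s,mean_activity.",
                  path))
  }
}

#' Read a pipeline configuration file
#'
#' JSON (via jsonlite) or YAML (via yaml, if installed) keyed as in
#' [run_pipeline()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    rlang::check_installed("yaml")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
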