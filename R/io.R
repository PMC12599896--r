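# Record and scenario files. Records are plain CSV with a one-line metadata
# header (sampling rate, provenance) standing in for the device's flash log;
# scenarios are YAML.

#' Write a triaxial record to CSV
#'
#' Column layout: `sample_index` (0-based), `ax_g`, `ay_g`, `az_g`, plus
#' truth columns when present. A leading metadata line carries the sampling
#' rate and any provenance string. Values use the shortest decimal
#' representation that round-trips, so write-then-read reproduces the
#' record exactly.
#'
#' @param record A `tremor_record`.
#' @param path Destination file.
#' @param provenance Optional string recorded in the metadata line (e.g.
#'   the generating config and seed).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, provenance = NULL) {
  check_that(inherits(record, "tremor_record"), "`record` must be a tremor_record")
  fs <- attr(record, "fs")
  sc <- attr(record, "scenario")
  if (is.null(provenance) && !is.null(sc))
    provenance <- sprintf("scenario seed=%d noise=%s", sc$seed, sc$noise_kind)
  meta <- sprintf("# tremortrack record fs_hz=%s%s", format(fs, digits = 15),
                  if (is.null(provenance)) "" else paste0(" | ", provenance))
  cols <- intersect(c("sample_index", "ax_g", "ay_g", "az_g",
                      "phase_true_deg", "axis_true", "fc_true_hz"),
                    names(record))
  writeLines(meta, path)
  readr::write_csv(record[cols], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a triaxial record from CSV
#'
#' Validates the layout written by [write_record()]: the metadata line must
#' name the sampling rate, `sample_index` must increase strictly by 1 from
#' 0, and all acceleration values must be finite; violations are rejected
#' naming the first offending line.
#'
#' @param path File to read.
#' @return A `tremor_record` tibble.
#' @export
read_record <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  meta <- readLines(path, n = 1)
  m <- regmatches(meta, regexec("fs_hz=([0-9.eE+-]+)", meta))[[1]]
  check_that(length(m) == 2,
             "missing metadata line ('# tremortrack record fs_hz=...')")
  fs <- as.numeric(m[2])
  # base read.csv: correctly-rounded double parsing, so the shortest
  # round-trip decimals written by write_record() reproduce bits exactly
  df <- utils::read.csv(path, skip = 1, header = TRUE)
  need <- c("sample_index", "ax_g", "ay_g", "az_g")
  miss <- setdiff(need, names(df))
  check_that(length(miss) == 0,
             sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  idx <- df$sample_index
  bad <- which(idx != seq_along(idx) - 1)[1]
  check_that(is.na(bad),
             sprintf("sample_index must increase by 1 from 0; first bad line: %d",
                     bad + 2L))  # +1 metadata, +1 header
  for (col in c("ax_g", "ay_g", "az_g")) {
    nf <- which(!is.finite(df[[col]]))[1]
    check_that(is.na(nf),
               sprintf("non-finite value in %s at line %d", col, nf + 2L))
  }
  truth_cols <- intersect(c("phase_true_deg", "axis_true", "fc_true_hz"), names(df))
  truth <- if (length(truth_cols)) df[truth_cols] else NULL
  tremor_record(df$ax_g, df$ay_g, df$az_g, fs = fs, truth = truth)
}

#' Write / read a tremor scenario as YAML
#'
#' Data-frame envelopes and frequency trajectories are serialized as
#' column lists; function-valued fields cannot be written to file.
#'
#' @param scenario A [tremor_scenario()].
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `tremor_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  check_that(inherits(scenario, "tremor_scenario"), "`scenario` must be a tremor_scenario")
  ser <- unclass(scenario)
  ser$envelope <- lapply(ser$envelope, function(e) {
    check_that(!is.function(e), "function-valued envelopes cannot be serialized")
    if (is.data.frame(e)) as.list(e) else e
  })
  check_that(!is.function(ser$freq), "function-valued frequency trajectories cannot be serialized")
  if (is.data.frame(ser$freq)) ser$freq <- as.list(ser$freq)
  if (is.data.frame(ser$cessation)) ser$cessation <- as.list(ser$cessation)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  # hand-written files with an unquoted axis key `y:` hit YAML 1.1 implicit
  # boolean typing; map it back
  if (!is.null(raw$envelope))
    names(raw$envelope) <- sub("^TRUE$", "y", names(raw$envelope))
  delist <- function(x, cols) {
    if (is.list(x) && all(cols %in% names(x))) as.data.frame(x) else x
  }
  tremor_scenario(
    duration_s = raw$duration_s, fs = raw$fs,
    envelope = lapply(raw$envelope, delist, cols = c("time_s", "value")),
    freq = delist(raw$freq, c("time_s", "f_hz")),
    cessation = if (is.null(raw$cessation)) NULL
                else as.data.frame(raw$cessation),
    dc_offset = raw$dc_offset %||% c(0, 0, 0),
    noise_kind = raw$noise_kind %||% "none",
    noise_scale = raw$noise_scale %||% 0,
    phase0 = raw$phase0 %||% 0,
    envelope_method = raw$envelope_method %||% "linear",
    seed = raw$seed %||% 1L
  )
}
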