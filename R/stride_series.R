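#' Construct a stride series
#'
#' A stride series holds the per-stride observations of a single treadmill
#' trial: stride times `T` (seconds) and stride lengths `L` (meters), one
#' entry per stride, together with the belt speed `v` (m/s). Stride speeds
#' `S = L/T` are always derived on demand (see [stride_speeds()]) and never
#' stored, so they cannot fall out of sync with `T` and `L`.
#'
#' @param T Numeric vector of stride times in seconds, all `> 0`.
#' @param L Numeric vector of stride lengths in meters, same length as `T`,
#'   all `> 0`.
#' @param v Belt speed in m/s, `> 0`.
#' @param trial_id Character label for the trial.
#' @param condition Character label for the condition (e.g. `"100%PWS"`,
#'   `"OVC"`, `"surrogate/shuffle"`).
#' @return An object of class `stride_series`: a list with elements `T`,
#'   `L`, `v`, `trial_id`, `condition`.
#' @examples
#' s <- stride_series(T = c(1.1, 1.12, 1.09), L = c(1.33, 1.35, 1.32))
#' stride_speeds(s)
#' @export
stride_series <- function(T, L, v = 1.21, trial_id = "trial",
                          condition = "unspecified") {
  T <- as.numeric(T)
  L <- as.numeric(L)
  out <- structure(
    list(T = T, L = L, v = as.numeric(v)[1],
         trial_id = as.character(trial_id)[1],
         condition = as.character(condition)[1]),
    class = "stride_series")
  validate_stride_series(out)
  out
}

#' Validate a stride series
#'
#' Checks the class invariants: equal lengths, strictly positive stride
#' times, lengths and belt speed, no missing values. Nonpositive values are
#' a hard error because every downstream quantity divides by `T` or assumes
#' forward progress.
#'
#' @param series Object to validate.
#' @return `series`, invisibly, if valid; otherwise signals a condition of
#'   class `stridegem_invalid_series`.
#' @export
validate_stride_series <- function(series) {
  if (!inherits(series, "stride_series"))
    stop_stridegem("not a stride_series object", "invalid_series")
  T <- series$T; L <- series$L; v <- series$v
  if (!is.numeric(T) || !is.numeric(L))
    stop_stridegem("T and L must be numeric", "invalid_series")
  if (length(T) != length(L))
    stop_stridegem("T and L must have equal length", "invalid_series")
  if (length(T) < 1L)
    stop_stridegem("series must contain at least one stride", "invalid_series")
  if (anyNA(T) || anyNA(L) || is.na(v))
    stop_stridegem("missing values are not allowed", "invalid_series")
  if (any(T <= 0))
    stop_stridegem("all stride times must be > 0", "invalid_series")
  if (any(L <= 0))
    stop_stridegem("all stride lengths must be > 0", "invalid_series")
  if (!is.numeric(v) || v <= 0)
    stop_stridegem("belt speed v must be > 0", "invalid_series")
  invisible(series)
}

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf("<stride_series> %s (%s)\n", x$trial_id, x$condition))
  cat(sprintf("  %d strides at belt speed v = %g m/s\n", length(x$T), x$v))
  cat(sprintf("  mean T = %.4f s, mean L = %.4f m, mean S = %.4f m/s\n",
              mean(x$T), mean(x$L), mean(stride_speeds(x))))
  invisible(x)
}

#' @export
length.stride_series <- function(x) length(x$T)

#' @export
as.data.frame.stride_series <- function(x, ...) {
  data.frame(stride = seq_along(x$T), T_s = x$T, L_m = x$L)
}

#' Per-stride speeds
#'
#' Computes the stride speed of each stride, `S_n = L_n / T_n` (m/s).
#' Note that `mean(S)` is in general *not* `sum(L)/sum(T)`; the per-stride
#' definition is the one used throughout the analysis.
#'
#' @param series A [stride_series()].
#' @return Numeric vector of stride speeds, same length as the series.
#' @export
stride_speeds <- function(series) {
  validate_stride_series(series)
  series$L / series$T
}

#' Net cumulative displacement on the belt
#'
#' On a belt moving at speed `v`, a stride of length `L_n` taking `T_n`
#' seconds displaces the walker by `L_n - v * T_n` in the laboratory frame.
#' The net cumulative displacement after stride `n` is
#' `d_net(n) = sum_{i<=n} (L_i - v * T_i)`, with `d = 0` at the belt
#' center (the starting position). Walking "on speed" (`L_i = v * T_i`)
#' keeps `d_net` at zero.
#'
#' @param series A [stride_series()].
#' @return Numeric vector `d_net(1), ..., d_net(N)` in meters.
#' @export
dnet <- function(series) {
  validate_stride_series(series)
  cumsum(series$L - series$v * series$T)
}

#' Check the treadmill belt constraint
#'
#' A trial is physically realizable only if the walker never reaches either
#' end of the belt: `-d_max <= min(d_net)` and `max(d_net) <= d_max`, where
#' `d_max` is half the belt length (0.864 m for the treadmill modelled
#' here). Used both to screen surrogates and to verify simulations.
#'
#' @param series A [stride_series()].
#' @param d_max Half belt length in meters (`> 0`), default `0.864`.
#' @return A list with elements `ok` (logical), `max_d`, `min_d` (meters).
#' @export
check_belt_constraint <- function(series, d_max = 0.864) {
  if (!is.numeric(d_max) || d_max <= 0)
    stop_stridegem("d_max must be > 0", "invalid_series")
  d <- dnet(series)
  list(ok = (min(d) >= -d_max) && (max(d) <= d_max),
       max_d = max(d), min_d = min(d))
}

#' Read / write stride series CSV files
#'
#' The on-disk format is a plain comma-separated file with `#`-prefixed
#' `key=value` metadata lines (`v`, `trial_id`, `condition`) followed by a
#' header row `stride,T_s,L_m`. Values are written with 17 significant
#' digits, so a write/read cycle reproduces the series exactly. Malformed
#' files (missing columns, non-numeric or
#' nonpositive values, missing `v`) signal `stridegem_malformed_file`.
#'
#' @param path File path.
#' @return `read_stride_csv()` returns a [stride_series()];
#'   `write_stride_csv()` returns `path` invisibly.
#' @export
read_stride_csv <- function(path) {
  if (!file.exists(path))
    stop_stridegem(sprintf("file not found: %s", path), "malformed_file")
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      meta[[key]] <- trimws(substr(kv, eq + 1, nchar(kv)))
    }
  }
  if (is.null(meta$v))
    stop_stridegem("missing '# v=<belt speed>' metadata line", "malformed_file")
  v <- suppressWarnings(as.numeric(meta$v))
  if (is.na(v))
    stop_stridegem("non-numeric belt speed in metadata", "malformed_file")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop_stridegem("no data rows", "malformed_file")
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    colClasses = "numeric"),
    error = function(e) stop_stridegem(
      sprintf("cannot parse CSV body: %s", conditionMessage(e)),
      "malformed_file"))
  need <- c("stride", "T_s", "L_m")
  if (!all(need %in% names(df)))
    stop_stridegem(
      sprintf("missing required columns: %s",
              paste(setdiff(need, names(df)), collapse = ", ")),
      "malformed_file")
  if (anyNA(df$T_s) || anyNA(df$L_m))
    stop_stridegem("non-numeric or missing stride values", "malformed_file")
  if (any(df$T_s <= 0) || any(df$L_m <= 0))
    stop_stridegem("nonpositive stride time or length", "malformed_file")
  stride_series(T = df$T_s, L = df$L_m, v = v,
                trial_id = if (is.null(meta$trial_id)) "trial" else meta$trial_id,
                condition = if (is.null(meta$condition)) "unspecified" else meta$condition)
}

#' @rdname read_stride_csv
#' @param series A [stride_series()] to write.
#' @export
write_stride_csv <- function(series, path) {
  validate_stride_series(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# v=%.12g", series$v),
    sprintf("# trial_id=%s", series$trial_id),
    sprintf("# condition=%s", series$condition),
    "stride,T_s,L_m",
    sprintf("%d,%.17g,%.17g", seq_along(series$T), series$T, series$L)
  ), con)
  invisible(path)
}
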