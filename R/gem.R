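#' Fit a GEM frame for a trial
#'
#' The goal equivalent manifold (GEM) for constant-speed treadmill walking
#' is the set of stride time/length pairs that hit the belt speed exactly:
#' `L = v * T`. This function builds the coordinate frame used to decompose
#' strides into deviations along and perpendicular to that line.
#'
#' Stride times and lengths are first normalized to unit variance by
#' dividing each series by its own standard deviation (`normalization =
#' "per-series-SD"`; `"none"` keeps physical units). In normalized
#' coordinates the GEM is a line of slope `m_hat = v * sigma_T / sigma_L`.
#' The frame's orthonormal basis is the unit tangent
#' `e_T = (1, m_hat)/sqrt(1 + m_hat^2)` (both components positive: along
#' the GEM toward longer, slower strides) and unit normal
#' `e_P = (-m_hat, 1)/sqrt(1 + m_hat^2)`, oriented so that positive
#' perpendicular deviations correspond to stride speeds above the belt
#' speed.
#'
#' The operating point is either the sample mean of the trial
#' (`"sample-mean"`, the default) or its projection onto the GEM
#' (`"projected-to-GEM"`, which sets `Lstar = v * Tstar`). The choice only
#' shifts the perpendicular deviations by an additive constant, so
#' dispersion and scaling-exponent statistics are unaffected.
#'
#' @param series A [stride_series()] with at least 3 strides.
#' @param normalization `"per-series-SD"` (default) or `"none"`.
#' @param operating_point `"sample-mean"` (default) or `"projected-to-GEM"`.
#' @return An object of class `gem_frame`: list with `sigma_T`, `sigma_L`,
#'   `v`, `Tstar`, `Lstar`, `m_hat`, `e_T`, `e_P`, `normalization`,
#'   `operating_point`.
#' @export
fit_gem_frame <- function(series,
                          normalization = c("per-series-SD", "none"),
                          operating_point = c("sample-mean",
                                              "projected-to-GEM")) {
  validate_stride_series(series)
  normalization <- match.arg(normalization)
  operating_point <- match.arg(operating_point)
  if (length(series$T) < 3L)
    stop_stridegem("need at least 3 strides to fit a GEM frame",
                   "invalid_series")
  if (normalization == "per-series-SD") {
    sigma_T <- stats::sd(series$T)
    sigma_L <- stats::sd(series$L)
    if (sigma_T == 0 || sigma_L == 0)
      stop_stridegem(
        "zero-variance series cannot be normalized to unit variance",
        "degenerate_series")
  } else {
    sigma_T <- 1
    sigma_L <- 1
  }
  Tstar <- mean(series$T)
  Lstar <- if (operating_point == "projected-to-GEM")
    series$v * Tstar else mean(series$L)
  m_hat <- series$v * sigma_T / sigma_L
  nrm <- sqrt(1 + m_hat^2)
  structure(
    list(sigma_T = sigma_T, sigma_L = sigma_L, v = series$v,
         Tstar = Tstar, Lstar = Lstar, m_hat = m_hat,
         e_T = c(1, m_hat) / nrm, e_P = c(-m_hat, 1) / nrm,
         normalization = normalization, operating_point = operating_point),
    class = "gem_frame")
}

#' @export
print.gem_frame <- function(x, ...) {
  cat("<gem_frame>\n")
  cat(sprintf("  v = %g m/s, operating point (T*, L*) = (%.4f s, %.4f m)\n",
              x$v, x$Tstar, x$Lstar))
  cat(sprintf("  sigma_T = %.5g s, sigma_L = %.5g m, m_hat = %.5g\n",
              x$sigma_T, x$sigma_L, x$m_hat))
  cat(sprintf("  e_T = (%.5f, %.5f), e_P = (%.5f, %.5f)\n",
              x$e_T[1], x$e_T[2], x$e_P[1], x$e_P[2]))
  invisible(x)
}

#' Decompose strides into GEM deviations
#'
#' Transforms each stride into dimensionless deviations tangent to the GEM
#' (`delta_T`, goal-equivalent: changes that leave stride speed at the belt
#' speed) and perpendicular to it (`delta_P`, goal-relevant: changes in
#' stride speed). With normalized centered coordinates
#' `T' = (T_n - Tstar)/sigma_T`, `L' = (L_n - Lstar)/sigma_L`,
#' `delta_T = e_T . (T', L')` and `delta_P = e_P . (T', L')`.
#' `delta_P > 0` means the stride was faster than the belt.
#'
#' @param series A [stride_series()].
#' @param frame A [fit_gem_frame()] result fitted at the same belt speed.
#' @return An object of class `gem_deviations`: list with numeric vectors
#'   `delta_T`, `delta_P` and the `frame`.
#' @export
gem_decompose <- function(series, frame) {
  validate_stride_series(series)
  if (!inherits(frame, "gem_frame"))
    stop_stridegem("frame must be a gem_frame", "invalid_series")
  if (!isTRUE(all.equal(frame$v, series$v)))
    stop_stridegem("frame and series belt speeds differ", "invalid_series")
  Tp <- series$T / frame$sigma_T - frame$Tstar / frame$sigma_T
  Lp <- series$L / frame$sigma_L - frame$Lstar / frame$sigma_L
  structure(
    list(delta_T = frame$e_T[1] * Tp + frame$e_T[2] * Lp,
         delta_P = frame$e_P[1] * Tp + frame$e_P[2] * Lp,
         frame = frame),
    class = "gem_deviations")
}

#' @export
print.gem_deviations <- function(x, ...) {
  cat(sprintf("<gem_deviations> %d strides\n", length(x$delta_T)))
  cat(sprintf("  SD(delta_T) = %.4g, SD(delta_P) = %.4g\n",
              stats::sd(x$delta_T), stats::sd(x$delta_P)))
  invisible(x)
}

#' @export
as.data.frame.gem_deviations <- function(x, ...) {
  data.frame(stride = seq_along(x$delta_T),
             delta_T = x$delta_T, delta_P = x$delta_P)
}

#' Reconstruct physical strides from GEM deviations
#'
#' Inverts [gem_decompose()]: maps `(delta_T, delta_P)` pairs back to
#' stride times and lengths in physical units using the frame's basis,
#' scales and operating point. `gem_decompose()` after `gem_reconstruct()`
#' is the identity to machine precision, as is the reverse composition.
#'
#' @param dev A `gem_deviations` object (with its frame).
#' @param trial_id,condition Labels for the reconstructed series.
#' @return A [stride_series()].
#' @export
gem_reconstruct <- function(dev, trial_id = "reconstructed",
                            condition = "reconstructed") {
  if (!inherits(dev, "gem_deviations"))
    stop_stridegem("dev must be a gem_deviations", "invalid_series")
  f <- dev$frame
  # inverse rotation: basis matrix [e_T e_P] is orthonormal
  Tp <- f$e_T[1] * dev$delta_T + f$e_P[1] * dev$delta_P
  Lp <- f$e_T[2] * dev$delta_T + f$e_P[2] * dev$delta_P
  stride_series(T = (Tp + f$Tstar / f$sigma_T) * f$sigma_T,
                L = (Lp + f$Lstar / f$sigma_L) * f$sigma_L,
                v = f$v, trial_id = trial_id, condition = condition)
}

#' Export GEM deviations to CSV (frame as JSON sidecar)
#'
#' Writes a `stride,delta_T,delta_P` CSV and, optionally, the frame
#' serialized as JSON next to it.
#'
#' @param dev A `gem_deviations` object.
#' @param path Output CSV path.
#' @param frame_json Optional path for the frame JSON (default: `path` with
#'   a `.frame.json` extension; `NA` suppresses it).
#' @return `path`, invisibly.
#' @export
write_gem_csv <- function(dev, path, frame_json = NULL) {
  if (!inherits(dev, "gem_deviations"))
    stop_stridegem("dev must be a gem_deviations", "invalid_series")
  utils::write.csv(as.data.frame(dev), path, row.names = FALSE)
  if (is.null(frame_json))
    frame_json <- sub("\\.csv$", "", path)
  if (!is.na(frame_json)) {
    f <- dev$frame
    jsonlite::write_json(
      list(sigma_T = f$sigma_T, sigma_L = f$sigma_L, v = f$v,
           Tstar = f$Tstar, Lstar = f$Lstar, m_hat = f$m_hat,
           e_T = f$e_T, e_P = f$e_P, normalization = f$normalization,
           operating_point = f$operating_point),
      paste0(frame_json, ".frame.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
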