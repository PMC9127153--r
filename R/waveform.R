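#' Construct a single-cycle velocity waveform
#'
#' A `velocity_waveform` holds one cardiac cycle of uniformly sampled
#' centerline blood velocity. The sample grid must cover exactly one period
#' on the half-open interval `[0, T)`, i.e. `t[k] = (k-1) * T / n`.
#'
#' @param v numeric vector of centerline velocity samples (m/s).
#' @param period cardiac cycle length T in seconds (> 0).
#' @param t optional explicit time grid (s); defaults to the canonical
#'   uniform grid `seq(0, period, length.out = n + 1)[1:n]`. If supplied it
#'   must be uniform (relative jitter below 1e-9) and span `[0, T)`.
#'
#' @return An object of class `velocity_waveform` with fields `t`, `v`,
#'   `period`.
#' @examples
#' w <- velocity_waveform(rep(0.4, 64), period = 1)
#' mean(w$v)
#' @export
velocity_waveform <- function(v, period, t = NULL) {
  if (!is.numeric(v) || anyNA(v)) stop("velocity samples must be numeric and non-missing")
  n <- length(v)
  if (n < 32L) stop("a velocity waveform needs at least 32 samples per cycle, got ", n)
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0)
    stop("period must be a single positive number (seconds)")
  dt <- period / n
  if (is.null(t)) {
    t <- dt * (seq_len(n) - 1L)
  } else {
    if (length(t) != n) stop("time and velocity vectors differ in length")
    steps <- diff(t)
    if (any(steps <= 0)) stop("time samples must be strictly increasing")
    if (max(abs(steps - dt)) > 1e-9 * dt)
      stop("non-uniform sampling: waveform samples must lie on a uniform grid spanning [0, T)")
    if (abs(t[1L]) > 1e-9 * period)
      stop("waveform samples must start at t = 0 and span the half-open interval [0, T)")
  }
  structure(list(t = as.numeric(t), v = as.numeric(v), period = period),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> %d samples, T = %.4g s (%.0f bpm)\n",
              length(x$v), x$period, 60 / x$period))
  cat(sprintf("  mean %.3f m/s, range [%.3f, %.3f] m/s\n",
              mean(x$v), min(x$v), max(x$v)))
  invisible(x)
}

#' Vessel geometry (straight rigid tube)
#'
#' @param diameter lumen diameter D in metres. Values outside the
#'   physiological common-carotid range (2-12 mm) trigger a warning, not an
#'   error, so that sensitivity analyses remain possible.
#' @return Object of class `vessel_geometry` with `diameter` and derived
#'   `radius`.
#' @examples
#' vessel_geometry(0.0063)$radius
#' @export
vessel_geometry <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) || diameter <= 0)
    stop("diameter must be a single positive number (metres)")
  if (diameter < 2e-3 || diameter > 12e-3)
    warning(sprintf("diameter %.3g m is outside the 2-12 mm physiological carotid range", diameter))
  structure(list(diameter = diameter, radius = diameter / 2), class = "vessel_geometry")
}

#' Blood viscosity from hematocrit
#'
#' Quadratic constitutive relation for whole-blood dynamic viscosity,
#' `mu = mu_p * (1 + 2.5 * Hct + 7.35 * Hct^2)` with plasma viscosity
#' `mu_p = 1.2e-3` Pa s. When hematocrit is unavailable a population default
#' of 3.5e-3 Pa s is returned.
#'
#' @param hct hematocrit as a fraction in `[0, 0.65]`, or `NULL`/`NA` for the
#'   default.
#' @return dynamic viscosity in Pa s.
#' @examples
#' viscosity_from_hematocrit(0.45)
#' viscosity_from_hematocrit(NULL)
#' @export
viscosity_from_hematocrit <- function(hct = NULL) {
  if (is.null(hct) || (length(hct) == 1L && is.na(hct))) return(3.5e-3)
  if (!is.numeric(hct) || any(hct < 0) || any(hct > 0.65))
    stop("hematocrit must lie in [0, 0.65] (fraction, not percent)")
  1.2e-3 * (1 + 2.5 * hct + 7.35 * hct^2)
}

#' Blood physical properties
#'
#' @param density blood density rho in kg/m^3 (default 1060).
#' @param viscosity dynamic viscosity mu in Pa s; if omitted it is derived
#'   from `hematocrit` via [viscosity_from_hematocrit()]. Supplying both a
#'   viscosity and a hematocrit that disagree with the constitutive relation
#'   is an error.
#' @param hematocrit optional hematocrit fraction in `[0, 0.65]`.
#' @return Object of class `blood_properties` with `density`, `viscosity`,
#'   `hematocrit`.
#' @examples
#' blood_properties(hematocrit = 0.42)
#' @export
blood_properties <- function(density = 1060, viscosity = NULL, hematocrit = NULL) {
  if (!is.numeric(density) || length(density) != 1L || density < 1000 || density > 1125)
    stop("blood density must lie in [1000, 1125] kg/m^3")
  if (length(hematocrit) == 1L && is.na(hematocrit)) hematocrit <- NULL
  mu_hct <- if (!is.null(hematocrit)) viscosity_from_hematocrit(hematocrit) else NULL
  if (is.null(viscosity)) {
    viscosity <- if (!is.null(mu_hct)) mu_hct else viscosity_from_hematocrit(NULL)
  } else if (!is.null(mu_hct) && abs(viscosity - mu_hct) > 1e-12) {
    stop("supplied viscosity contradicts the hematocrit-derived value; provide one or the other")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity < 1e-3 || viscosity > 1e-2)
    stop("dynamic viscosity must lie in [1e-3, 1e-2] Pa s")
  structure(list(density = density, viscosity = viscosity,
                 hematocrit = if (is.null(hematocrit)) NA_real_ else hematocrit),
            class = "blood_properties")
}
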