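#' Reynolds number
#'
#' `Re = rho * V * D / mu`. In the pipeline `V` is the cycle-averaged
#' centerline (Doppler envelope) velocity; see the package vignette for why
#' the envelope velocity, rather than the parabolic-profile spatial mean
#' `V/2`, is the convention this analysis uses.
#'
#' @param v_mean characteristic velocity (m/s), non-negative.
#' @param diameter lumen diameter (m).
#' @param density blood density (kg/m^3).
#' @param viscosity dynamic viscosity (Pa s).
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(1.1, 0.006, 1060, 3.5e-3)  # ~1999
#' @export
reynolds_number <- function(v_mean, diameter, density, viscosity) {
  if (any(c(diameter, density, viscosity) <= 0) || anyNA(c(diameter, density, viscosity)))
    stop("diameter, density and viscosity must be positive")
  if (any(v_mean < 0) || anyNA(v_mean)) stop("characteristic velocity must be non-negative")
  density * v_mean * diameter / viscosity
}

#' Classify flow regime by Reynolds number
#'
#' Thresholds for arterial flow: `Re < 200` undisturbed laminar,
#' `200 <= Re <= 1800` disturbed, `Re > 2000` turbulent. The band
#' `1800 < Re <= 2000` falls between the published ranges and is labelled
#' `indeterminate` rather than silently merged into a neighbour.
#'
#' @param re Reynolds number(s), non-negative.
#' @return Object of class `flow_classification` (single value) or a
#'   character vector of regimes (vector input): one of
#'   `"undisturbed_laminar"`, `"disturbed"`, `"indeterminate"`,
#'   `"turbulent"`.
#' @examples
#' classify_flow(150)$regime
#' classify_flow(c(100, 500, 1900, 2500))
#' @export
classify_flow <- function(re) {
  if (any(re < 0) || anyNA(re)) stop("Reynolds number must be non-negative")
  regime <- ifelse(re < 200, "undisturbed_laminar",
            ifelse(re <= 1800, "disturbed",
            ifelse(re <= 2000, "indeterminate", "turbulent")))
  if (length(re) == 1L)
    return(structure(list(re = re, regime = regime), class = "flow_classification"))
  regime
}

#' @export
print.flow_classification <- function(x, ...) {
  cat(sprintf("<flow_classification> Re = %.0f: %s\n", x$re, x$regime))
  invisible(x)
}
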