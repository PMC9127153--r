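#' Discrete Fourier decomposition of a velocity waveform
#'
#' Decomposes one sampled cardiac cycle into its harmonic content:
#' `v(t) ~ C_0 + sum_{n=1..N} Re(2 * C_n * exp(1i * n * omega * t))` with
#' fundamental angular frequency `omega = 2*pi/T`. `C_0` is the (real)
#' sample mean; `C_n` are one-sided complex Fourier coefficients.
#'
#' @param w a [velocity_waveform()].
#' @param n_harmonics number of harmonics N to retain; must satisfy
#'   `N <= floor(samples/2) - 1` so the Nyquist bin is never folded in.
#' @return Object of class `harmonic_spectrum`: `omega` (rad/s), `c0`,
#'   complex vector `cn` of length N, and `period`.
#' @examples
#' w <- velocity_waveform(0.4 + 0.1 * cos(2 * pi * (0:63) / 64), period = 1)
#' fourier_decompose(w, 2)$cn[1]   # 0.05 + 0i
#' @export
fourier_decompose <- function(w, n_harmonics = 8L) {
  stopifnot(inherits(w, "velocity_waveform"))
  n <- length(w$v)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("need at least one harmonic")
  if (n_harmonics > n %/% 2L - 1L)
    stop("n_harmonics = ", n_harmonics, " exceeds floor(samples/2) - 1 = ", n %/% 2L - 1L)
  a <- stats::fft(w$v) / n
  structure(list(omega = 2 * pi / w$period,
                 c0 = Re(a[1L]),
                 cn = a[seq_len(n_harmonics) + 1L],
                 period = w$period),
            class = "harmonic_spectrum")
}

#' Reconstruct samples from a harmonic spectrum
#'
#' Inverse of [fourier_decompose()] on an arbitrary time grid; used for
#' truncation-error checks.
#' @param spec a `harmonic_spectrum`.
#' @param t time points (s).
#' @return numeric velocity samples (m/s).
#' @export
harmonic_reconstruct <- function(spec, t) {
  stopifnot(inherits(spec, "harmonic_spectrum"))
  v <- rep(spec$c0, length(t))
  for (n in seq_along(spec$cn))
    v <- v + Re(2 * spec$cn[n] * exp(1i * n * spec$omega * t))
  v
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega * rho / mu)`: the ratio of unsteady inertial to
#' viscous forces, which controls how blunt the oscillatory velocity profile
#' is and how wall shear leads centerline velocity in phase.
#'
#' @param radius vessel radius R (m).
#' @param omega angular frequency of the harmonic (rad/s). May be a vector.
#' @param density blood density (kg/m^3).
#' @param viscosity dynamic viscosity (Pa s).
#' @return dimensionless Womersley number(s).
#' @examples
#' womersley_number(0.003, 2 * pi * 70 / 60, 1060, 3.5e-3)  # ~4.47
#' @export
womersley_number <- function(radius, omega, density, viscosity) {
  if (any(c(radius, omega, density, viscosity) <= 0) ||
      anyNA(c(radius, omega, density, viscosity)))
    stop("all Womersley-number arguments must be positive")
  radius * sqrt(omega * density / viscosity)
}

#' Per-harmonic wall shear from a centerline velocity harmonic
#'
#' Transfer function from the n-th complex centerline-velocity coefficient
#' `C_n` to the complex wall-shear coefficient `tau_n`, derived from the
#' Womersley profile `u(r) = A * (1 - J0(Lambda r/R) / J0(Lambda))` with
#' `Lambda = i^{3/2} alpha_n` and the centerline condition `u(0) = C_n`:
#'
#' `tau_n = mu * C_n * Lambda * J1(Lambda) / (R * (1 - J0(Lambda)))`
#'
#' using the fluid-side convention `tau = -mu du/dr` at `r = R`, which makes
#' the steady limit `tau -> +2 mu C_n / R` (Poiseuille with centerline
#' velocity).
#'
#' @param cn complex centerline velocity coefficient (m/s).
#' @param alpha_n Womersley number of the harmonic (> 0).
#' @param radius vessel radius (m).
#' @param viscosity dynamic viscosity (Pa s).
#' @return complex wall shear coefficient (Pa).
#' @export
harmonic_wall_shear <- function(cn, alpha_n, radius, viscosity) {
  if (!is.finite(alpha_n) || alpha_n <= 0) stop("alpha_n must be positive for oscillatory harmonics")
  if (radius <= 0 || viscosity <= 0) stop("radius and viscosity must be positive")
  lam <- alpha_n * exp(1i * 3 * pi / 4)  # i^{3/2} * alpha
  b <- besselJ01_complex(lam)
  denom <- 1 - b$j0
  if (Mod(denom) < 1e-14)
    stop("Womersley transfer numerically degenerate: |J0(Lambda) - 1| < 1e-14 (alpha too small)")
  viscosity * cn * lam * b$j1 / (radius * denom)
}

#' Endothelial shear stress over one cardiac cycle (Womersley estimation)
#'
#' Computes the wall (endothelial) shear-stress time series implied by a
#' centerline velocity waveform in a straight rigid tube: the waveform is
#' Fourier-decomposed, the steady component is mapped by Poiseuille
#' (`tau_0 = 2 mu C_0 / R`), each oscillatory harmonic by the Womersley
#' transfer function, and the series is resynthesised on the waveform's own
#' grid. All internal computation is in SI; the returned stresses are in
#' dyn/cm^2 (1 Pa = 10 dyn/cm^2), the unit conventional in vascular
#' physiology.
#'
#' @param w a [velocity_waveform()] of centerline (peak-envelope) velocity.
#' @param geometry a [vessel_geometry()].
#' @param blood a [blood_properties()].
#' @param n_harmonics harmonics retained (default 8; carotid waveform energy
#'   above the 8th harmonic is negligible).
#' @return Object of class `shear_result`: `tau` (dyn/cm^2, on `w$t`),
#'   `mean_ess`, `peak_ess` (dyn/cm^2), `alpha` (per-harmonic Womersley
#'   numbers), plus the inputs' summary fields.
#' @examples
#' w <- velocity_waveform(rep(0.4, 64), period = 1)
#' ess_waveform(w, vessel_geometry(0.006), blood_properties())$mean_ess  # 9.33
#' @export
ess_waveform <- function(w, geometry, blood, n_harmonics = 8L) {
  stopifnot(inherits(w, "velocity_waveform"), inherits(geometry, "vessel_geometry"),
            inherits(blood, "blood_properties"))
  spec <- fourier_decompose(w, n_harmonics)
  mu <- blood$viscosity
  R <- geometry$radius
  tau0 <- 2 * mu * spec$c0 / R               # steady Poiseuille term, Pa
  nh <- length(spec$cn)
  alpha <- womersley_number(R, spec$omega * seq_len(nh), blood$density, mu)
  tau_t <- rep(tau0, length(w$t))
  for (n in seq_len(nh)) {
    if (Mod(spec$cn[n]) == 0) next           # linearity: zero harmonic contributes nothing
    tn <- harmonic_wall_shear(spec$cn[n], alpha[n], R, mu)
    tau_t <- tau_t + Re(2 * tn * exp(1i * n * spec$omega * w$t))
  }
  tau_t <- tau_t * 10                        # Pa -> dyn/cm^2
  structure(list(tau = tau_t,
                 mean_ess = mean(tau_t),
                 peak_ess = max(tau_t),
                 alpha = alpha,
                 n_harmonics = nh,
                 omega = spec$omega),
            class = "shear_result")
}

#' @export
print.shear_result <- function(x, ...) {
  cat(sprintf("<shear_result> mean ESS %.2f dyn/cm2, peak %.2f dyn/cm2, alpha_1 = %.2f (%d harmonics)\n",
              x$mean_ess, x$peak_ess, x$alpha[1L], x$n_harmonics))
  invisible(x)
}
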