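# Independent oracles: deliberately naive implementations that never share
# code with the package internals they check.

# Brute-force O(n^2) discrete Fourier coefficients, C_k = (1/n) sum v_j w^-jk.
dft_oracle <- function(v) {
  n <- length(v)
  vapply(0:(n - 1), function(k) {
    sum(v * exp(-2i * pi * k * (0:(n - 1)) / n)) / n
  }, complex(1))
}

# J0 for complex argument via the integral representation
# J0(z) = (1/pi) * integral_0^pi cos(z sin(theta)) dtheta (Simpson's rule).
j0_quad <- function(z, n = 4000L) {
  th <- seq(0, pi, length.out = n + 1L)
  f <- cos(z * sin(th))
  wts <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(wts * f) * (pi / (3 * n)) / pi
}

# Wall-shear oracle: numerically differentiate the Womersley velocity
# profile u(r) = C * (1 - J0(L r/R)/J0(L)) / (1 - 1/J0(L)) at the wall and
# apply tau = -mu du/dr|_{r=R}, with Richardson extrapolation.
womersley_shear_oracle <- function(cn, alpha, radius, viscosity) {
  lam <- alpha * exp(1i * 3 * pi / 4)
  j0l <- j0_quad(lam)
  u <- function(r) cn * (1 - j0_quad(lam * r / radius) / j0l) / (1 - 1 / j0l)
  dd <- function(h) (u(radius + h) - u(radius - h)) / (2 * h)
  h <- 1e-4 * radius
  dudr <- (4 * dd(h / 2) - dd(h)) / 3
  -viscosity * dudr
}

# Small helpers used across test files ---------------------------------------

default_geometry <- function() vessel_geometry(6.3e-3)
default_blood <- function() blood_properties(hematocrit = 0.42)

# Fast per-record truth table for statistical Monte-Carlo runs.
truth_long <- function(seed, calibration = default_calibration(), icc = 0.5,
                       n_participants = 14L) {
  tt <- truth_table(generate_study(design = study_design(n_participants),
                                   calibration = calibration, icc = icc,
                                   seed = seed, build_waveforms = FALSE))
  names(tt)[names(tt) == "true_ess_dyn_cm2"] <- "ess_mean_dyn_cm2"
  as.data.frame(tt)
}

# Exercise-only calibration with every condition at the same mean/SD.
null_calibration <- function(mean = 50, sd = 12) {
  cal <- default_calibration()
  ex <- cal$intensity != "rest"
  cal$ess_mean[ex] <- mean
  cal$ess_sd[ex] <- sd
  cal
}
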