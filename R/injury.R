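#' SAE J211-1 channel-frequency-class filtering
#'
#' Phaseless 4-pole Butterworth realized as a 2-pole filter run forward and
#' then backward (with reflected-edge padding), per SAE J211-1 practice.
#' CFC 600 uses a 1000 Hz -3 dB (single-pass) cutoff, CFC 1000 uses
#' 1650 Hz. Tibial force channels are rated CFC 600, pelvis acceleration
#' CFC 1000.
#'
#' @param signal A [transient_signal()].
#' @param cfc_class `"CFC600"` or `"CFC1000"`.
#' @return The filtered signal (same length, same metadata).
#' @export
cfc_filter <- function(signal, cfc_class = c("CFC600", "CFC1000")) {
  stopifnot(inherits(signal, "transient_signal"))
  cfc_class <- match.arg(cfc_class)
  cls <- c(CFC600 = 600, CFC1000 = 1000)[cfc_class]
  cutoff <- c(CFC600 = 1000, CFC1000 = 1650)[cfc_class]
  fs <- 1 / signal$dt
  if (fs < 10 * cls)
    stop(sprintf("sample rate %.4g Hz too low for %s (need >= %g Hz)",
                 fs, cfc_class, 10 * cls))
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  signal$samples <- filtfilt_reflect(bf$b, bf$a, signal$samples)
  signal
}

#' Peak tibial compression assessment
#'
#' Compressive axial force is positive by the package's sign convention.
#' The injury metric `Fzp` is the peak of the compressive part only
#' (tension is ignored); the channel passes when `Fzp` is strictly below
#' the AEP-55 lower-limb tolerance of 5.4 kN and fails at or above it.
#'
#' @param force A `tibial_force` [transient_signal()] in kN.
#' @param filtered Set `TRUE` if the signal is already CFC600-filtered;
#'   otherwise the filter is applied internally.
#' @param Fzc Tolerance in kN (default 5.4).
#' @return List with `Fzp` (kN) and `pass` (logical).
#' @export
tibial_assessment <- function(force, filtered = FALSE, Fzc = 5.4) {
  stopifnot(inherits(force, "transient_signal"))
  if (force$channel != "tibial_force")
    stop("tibial_assessment expects a tibial_force channel")
  if (!filtered) force <- cfc_filter(force, "CFC600")
  comp <- force$samples[force$samples > 0]
  if (!length(comp)) {
    warning("signal contains no compressive phase; Fzp = 0")
    return(list(Fzp = 0, pass = TRUE))
  }
  Fzp <- max(comp)
  list(Fzp = Fzp, pass = Fzp < Fzc)
}

#' Dynamic Response Index model parameters
#'
#' The DRIz single-degree-of-freedom spinal model: damping ratio 0.224,
#' natural circular frequency 52.9 rad/s, gravity 9.81 m/s^2.
#'
#' @param zeta Damping ratio.
#' @param omega_n Natural circular frequency (rad/s).
#' @param gravity Gravitational acceleration (m/s^2).
#' @return A list of class `dri_params`.
#' @export
dri_params <- function(zeta = 0.224, omega_n = 52.9, gravity = 9.81) {
  stopifnot(zeta > 0, zeta < 1, omega_n > 0, gravity > 0)
  structure(list(zeta = zeta, omega_n = omega_n, gravity = gravity),
            class = "dri_params")
}

# Exact zero-order-hold discretization of the underdamped oscillator
# state [delta, delta_dot]' driven by the base acceleration u:
#   delta_dd + 2 zeta wn delta_d + wn^2 delta = u(t).
dri_discretize <- function(zeta, wn, dt) {
  wd <- wn * sqrt(1 - zeta^2)
  e <- exp(-zeta * wn * dt)
  cwd <- cos(wd * dt); swd <- sin(wd * dt)
  Ad <- matrix(c(e * (cwd + zeta * wn / wd * swd), e * swd / wd,
                 -e * wn^2 / wd * swd, e * (cwd - zeta * wn / wd * swd)),
               2, 2, byrow = TRUE)
  Ainv <- matrix(c(-2 * zeta / wn, -1 / wn^2, 1, 0), 2, 2, byrow = TRUE)
  Bd <- Ainv %*% (Ad - diag(2)) %*% c(0, 1)
  list(Ad = Ad, Bd = as.numeric(Bd))
}

#' Spinal Dynamic Response Index (DRIz)
#'
#' Integrates the spinal mass-spring-damper model from rest over the full
#' record using the exact zero-order-hold discretization at the signal's
#' sample step, and reads out `DRIz = omega_n^2 * max(delta) / g` over the
#' compressive (positive-deflection) phase only. Input acceleration in g is
#' converted to m/s^2 internally; the input is taken as the measured
#' (gravity-free) transient. Positive acceleration is the compressive
#' (downward-seat) direction.
#'
#' @param pelvis_accel A `pelvis_accel` [transient_signal()] in g or
#'   m_s2.
#' @param params A [dri_params()].
#' @param filtered Set `TRUE` if already CFC1000-filtered.
#' @return Non-negative DRIz (dimensionless).
#' @export
dri_z <- function(pelvis_accel, params = dri_params(), filtered = FALSE) {
  stopifnot(inherits(pelvis_accel, "transient_signal"),
            inherits(params, "dri_params"))
  if (pelvis_accel$channel != "pelvis_accel")
    stop("dri_z expects a pelvis_accel channel")
  if (!filtered) pelvis_accel <- cfc_filter(pelvis_accel, "CFC1000")
  u <- pelvis_accel$samples
  if (pelvis_accel$units == "g") u <- u * params$gravity
  dsc <- dri_discretize(params$zeta, params$omega_n, pelvis_accel$dt)
  s <- c(0, 0)
  dmax <- 0
  for (k in seq_along(u)) {
    s <- dsc$Ad %*% s + dsc$Bd * u[k]
    if (s[1L] > dmax) dmax <- s[1L]
  }
  params$omega_n^2 * dmax / params$gravity
}

#' Combined injury assessment
#'
#' Computes both AEP-55 indices: peak tibial compression `Fzp` against the
#' 5.4 kN tolerance and `DRIz` against 17.7. Each index passes strictly
#' below its tolerance and fails at or above it.
#'
#' @param tibial_force A `tibial_force` signal (kN), or `NULL`.
#' @param pelvis_accel A `pelvis_accel` signal (g), or `NULL`.
#' @param Fzc,DRIz_c Tolerances.
#' @param filtered Signals already CFC-filtered?
#' @return A list of class `injury_indices` with `Fzp`, `Fz_pass`, `DRIz`,
#'   `DRIz_pass` (NA for channels not supplied) and the tolerances.
#' @export
injury_indices <- function(tibial_force = NULL, pelvis_accel = NULL,
                           Fzc = 5.4, DRIz_c = 17.7, filtered = FALSE) {
  Fzp <- NA_real_; Fz_pass <- NA
  DRIz <- NA_real_; DRIz_pass <- NA
  if (!is.null(tibial_force)) {
    ta <- tibial_assessment(tibial_force, filtered = filtered, Fzc = Fzc)
    Fzp <- ta$Fzp; Fz_pass <- ta$pass
  }
  if (!is.null(pelvis_accel)) {
    DRIz <- dri_z(pelvis_accel, filtered = filtered)
    DRIz_pass <- DRIz < DRIz_c
  }
  structure(list(Fzp = Fzp, Fz_pass = Fz_pass, DRIz = DRIz,
                 DRIz_pass = DRIz_pass, Fzc = Fzc, DRIz_c = DRIz_c),
            class = "injury_indices")
}

#' @export
print.injury_indices <- function(x, ...) {
  cat(sprintf("<injury_indices> Fzp = %.3g kN (tolerance %.3g, %s); DRIz = %.3g (tolerance %.3g, %s)\n",
              x$Fzp, x$Fzc,
              if (isTRUE(x$Fz_pass)) "pass" else if (isFALSE(x$Fz_pass)) "FAIL" else "n/a",
              x$DRIz, x$DRIz_c,
              if (isTRUE(x$DRIz_pass)) "pass" else if (isFALSE(x$DRIz_pass)) "FAIL" else "n/a"))
  invisible(x)
}
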