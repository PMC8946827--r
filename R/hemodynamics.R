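#' @keywords internal
"_PACKAGE"

# Pressure unit conversion: 1 mmHg in pascal.
MMHG_PA <- 133.322

#' Hemodynamic parameters of the measured arterial segment
#'
#' Bundle of subject constants that couple arterial pressure to the
#' bio-impedance seen by a tetrapolar electrode pair across a short artery
#' segment. Pressure changes alter the arterial cross-sectional area
#' (Bramwell-Hill relation) and the area sets the segment impedance through
#' Ohm's law for a cylindrical conductor, `Z = L / (sigma * A)`.
#'
#' Defaults are order-of-magnitude carotid values: blood density
#' 1060 kg/m^3, a 15 cm pulse path travelled in 25 ms (pulse-wave velocity
#' 6 m/s), a 2 cm sensed segment, blood conductivity 0.6 S/m and a reference
#' lumen area of 3e-5 m^2 (about a 6 mm diameter vessel) at 90 mmHg. The
#' absolute ohm scale of real neck IPG also includes tissue shunting that is
#' not modelled here, so these defaults set a convenient, not a calibrated,
#' impedance scale.
#'
#' @param rho Blood density, kg/m^3.
#' @param D Distance between the two pulse measurement locations, m.
#' @param PTT Pulse transit time over `D`, s.
#' @param L Length of the sensed arterial segment, m.
#' @param sigma Blood electrical conductivity, S/m.
#' @param A0 Reference cross-sectional area at pressure `P0`, m^2.
#' @param P0 Reference transmural pressure, mmHg.
#' @return An object of class `hemo_params` (named list).
#' @examples
#' h <- hemo_params()
#' # impedance at the reference state:
#' h$L / (h$sigma * h$A0)
#' @export
hemo_params <- function(rho = 1060, D = 0.15, PTT = 0.025,
                        L = 0.02, sigma = 0.6, A0 = 3e-5, P0 = 90) {
  p <- list(rho = rho, D = D, PTT = PTT, L = L, sigma = sigma, A0 = A0, P0 = P0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("hemodynamic parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "hemo_params")
}

#' @export
print.hemo_params <- function(x, ...) {
  cat("Hemodynamic parameters (arterial segment)\n")
  cat(sprintf("  rho = %g kg/m^3, D = %g m, PTT = %g s (PWV %.2f m/s)\n",
              x$rho, x$D, x$PTT, x$D / x$PTT))
  cat(sprintf("  L = %g m, sigma = %g S/m, A0 = %g m^2 @ P0 = %g mmHg\n",
              x$L, x$sigma, x$A0, x$P0))
  cat(sprintf("  reference impedance L/(sigma*A0) = %.1f ohm\n",
              x$L / (x$sigma * x$A0)))
  invisible(x)
}

# Area sensitivity to pressure, 1/Pa: dA/A = beta * dP.
pressure_area_beta <- function(hemo) {
  hemo$PTT^2 / (hemo$rho * hemo$D^2)
}

#' Arterial cross-sectional area at a given pressure
#'
#' Closed-form integral of the Bramwell-Hill relation
#' `dP = rho * (D/PTT)^2 * dA/A` with `rho`, `D`, `PTT` held constant over
#' the pulse: `A(P) = A0 * exp((P - P0) * PTT^2 / (rho * D^2))` with
#' pressures converted to pascal internally.
#'
#' @param P Pressure waveform or scalar, mmHg.
#' @param hemo A [hemo_params()] object.
#' @param P0 Reference pressure, mmHg (defaults to `hemo$P0`).
#' @return Area in m^2, same length as `P`.
#' @export
pressure_to_area <- function(P, hemo, P0 = hemo$P0) {
  stopifnot(inherits(hemo, "hemo_params"))
  if (any(!is.finite(P))) stop("pressure waveform must be finite", call. = FALSE)
  hemo$A0 * exp((P - P0) * MMHG_PA * pressure_area_beta(hemo))
}

#' Convert an arterial pressure waveform to a segment impedance waveform
#'
#' Composes the closed-form area response [pressure_to_area()] with the
#' cylindrical-conductor impedance `Z = L / (sigma * A)`. Impedance is
#' strictly decreasing in pressure: a pressure rise dilates the artery and
#' the larger conducting cross-section lowers the segment impedance.
#'
#' @inheritParams pressure_to_area
#' @return Impedance in ohm, same length as `P`.
#' @examples
#' h <- hemo_params()
#' Z <- pressure_to_impedance(c(80, 120), h)
#' Z[1] > Z[2]  # higher pressure -> lower impedance
#' @export
pressure_to_impedance <- function(P, hemo, P0 = hemo$P0) {
  A <- pressure_to_area(P, hemo, P0 = P0)
  hemo$L / (hemo$sigma * A)
}

#' Invert the impedance model back to pressure
#'
#' Exact inverse of [pressure_to_impedance()]; used to check that, with all
#' noise sources off, per-beat impedance extrema map back onto the simulated
#' systolic and diastolic pressures.
#'
#' @param Z Impedance waveform, ohm.
#' @inheritParams pressure_to_area
#' @return Pressure in mmHg.
#' @export
impedance_to_pressure <- function(Z, hemo, P0 = hemo$P0) {
  stopifnot(inherits(hemo, "hemo_params"))
  if (any(!is.finite(Z)) || any(Z <= 0)) {
    stop("impedance waveform must be finite and positive", call. = FALSE)
  }
  A <- hemo$L / (hemo$sigma * Z)
  P0 + log(A / hemo$A0) / (pressure_area_beta(hemo) * MMHG_PA)
}
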