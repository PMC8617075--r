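## Seawater density: EOS-80 (UNESCO 1983) one-atmosphere polynomial plus
## secant bulk modulus pressure term; linearized above 40 degC where the
## polynomial leaves its fitted range (hot end-member fluids).

#' @keywords internal
.rho_eos80 <- function(T, S, p) {
  rw <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  r0 <- rw +
    S * (0.824493 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
           8.2467e-7 * T^3 + 5.3875e-9 * T^4) +
    S^1.5 * (-5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2) +
    4.8314e-4 * S^2
  if (all(p == 0)) return(r0)
  Kw <- 19652.21 + 148.4206 * T - 2.327105 * T^2 +
    1.360477e-2 * T^3 - 5.155288e-5 * T^4
  K0 <- Kw +
    S * (54.6746 - 0.603459 * T + 1.09987e-2 * T^2 - 6.1670e-5 * T^3) +
    S^1.5 * (7.944e-2 + 1.6483e-2 * T - 5.3009e-4 * T^2)
  Aw <- 3.239908 + 1.43713e-3 * T + 1.16092e-4 * T^2 - 5.77905e-7 * T^3
  A <- Aw + S * (2.2838e-3 - 1.0981e-5 * T - 1.6078e-6 * T^2) +
    1.91075e-4 * S^1.5
  Bw <- 8.50935e-5 - 6.12293e-6 * T + 5.2787e-8 * T^2
  B <- Bw + S * (-9.9348e-7 + 2.0816e-8 * T + 9.1697e-10 * T^2)
  K <- K0 + A * p + B * p^2
  r0 / (1 - p / K)
}

#' Seawater density
#'
#' International equation of state of seawater (EOS-80) for temperatures up
#' to 40 degC. Hot hydrothermal end-member fluids fall far outside the
#' fitted range of the polynomial, so above 40 degC the density is
#' extrapolated linearly with the local temperature slope at 40 degC. The
#' extrapolation under-represents the expansion of a 350 degC fluid; this
#' only shifts the first few metres of rise because entrainment rapidly
#' restores near-ambient temperatures.
#'
#' @param T_C temperature, degC (-2 to 400).
#' @param S practical salinity, per mille (0 to 45).
#' @param p_bar gauge pressure, bar (default 0: potential-density
#'   convention, matching the ambient density inputs of the plume model).
#' @return density, kg m^-3.
#' @export
seawater_density <- function(T_C, S, p_bar = 0) {
  if (any(T_C < -2 | T_C > 400)) stop("temperature out of range [-2, 400] degC")
  if (any(S < 0 | S > 45)) stop("salinity out of range [0, 45]")
  if (any(p_bar < 0)) stop("pressure must be >= 0")
  n <- max(length(T_C), length(S), length(p_bar))
  T_C <- rep_len(T_C, n); S <- rep_len(S, n); p_bar <- rep_len(p_bar, n)
  out <- numeric(n)
  cold <- T_C <= 40
  if (any(cold)) out[cold] <- .rho_eos80(T_C[cold], S[cold], p_bar[cold])
  if (any(!cold)) {
    dT <- 0.01
    r40 <- .rho_eos80(40, S[!cold], p_bar[!cold])
    slope <- (.rho_eos80(40 + dT, S[!cold], p_bar[!cold]) - r40) / dT
    out[!cold] <- r40 + slope * (T_C[!cold] - 40)
  }
  out
}
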