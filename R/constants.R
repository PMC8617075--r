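## Physical constants (SI unless noted)

#' @keywords internal
.const <- list(
  kB    = 1.380649e-23,    # Boltzmann, J K^-1
  hP    = 6.62607015e-34,  # Planck, J s
  R     = 8.314462618e-3,  # gas constant, kJ mol^-1 K^-1
  g     = 9.81,            # gravitational acceleration, m s^-2
  Tref  = 298.15,          # reference temperature, K
  A_DH  = 0.509,           # Debye-Hueckel A parameter (25 C, water)
  MC    = 12.011           # molar mass of carbon, g mol^-1
)

## mol m^-3 -> mol (kg solvent)^-1: 1 m^3 of dilute seawater ~ 1e3 kg solvent
.MOLALITY_PER_MOLM3 <- 1e-3

## molC m^-3 s^-1 -> ugC L^-1 d^-1
.MOLC_S_TO_UGC_L_D <- 12.011 * 86400 * 1e3
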