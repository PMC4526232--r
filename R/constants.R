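# Internal unit system: nm, amu, kJ/mol, ps, K.
# In these units 1 amu nm^2 ps^-2 == 1 kJ/mol, so frequencies from
# sqrt((kJ/mol/nm^2)/amu) come out directly in rad/ps.

.kB <- 0.008314462618      # kJ mol^-1 K^-1
.hbar <- 0.0635077993      # kJ mol^-1 ps (hbar * NA, expressed per mole)
.PN_PER_KJ_MOL_NM <- 1.66053906892  # pN per kJ mol^-1 nm^-1
.KCAL <- 4.184             # kJ per kcal
.F_ELEC <- 138.935458      # kJ mol^-1 nm e^-2, Coulomb prefactor 1/(4 pi eps0)

#' Convert forces from internal units to piconewtons
#'
#' @param x force(s) in kJ mol^-1 nm^-1
#' @return force(s) in pN
#' @export
kj_nm_to_pn <- function(x) x * .PN_PER_KJ_MOL_NM

#' Quantum harmonic-oscillator entropy per mode
#'
#' Entropy of a quantum harmonic oscillator of angular frequency `omega`
#' at temperature `temperature`, per mode:
#' \deqn{s(\omega) = k_B [ x/(e^x - 1) - \ln(1 - e^{-x}) ], \quad x = \hbar\omega/k_B T}
#'
#' @param omega angular frequency, rad/ps (vectorised)
#' @param temperature temperature in K
#' @return per-mode entropy in kJ mol^-1 K^-1
#' @export
qho_entropy <- function(omega, temperature) {
  stopifnot(temperature > 0)
  x <- .hbar * omega / (.kB * temperature)
  s <- .kB * (x / expm1(x) - log1p(-exp(-x)))
  # omega -> 0 diverges; omega exactly 0 must be excluded by callers
  s[omega == 0] <- Inf
  s
}
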