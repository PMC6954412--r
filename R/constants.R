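#' Physical constants used throughout the package
#'
#' CODATA 2018 values. `MU_B_OVER_H_MHZ_PER_T` is the Bohr magneton divided
#' by the Planck constant, i.e. the electron Zeeman conversion factor
#' (13996.245 MHz/T); `DIPOLAR_PREFACTOR_MHZ_NM3` is
#' mu0 * muB^2 / (4 pi h) expressed in MHz nm^3, so that the full dipolar
#' constant for a pair of electrons is `gA * gB * DIPOLAR_PREFACTOR_MHZ_NM3`
#' (about 52 MHz nm^3 for nitroxides).
#' @name peldor-constants
#' @keywords internal
NULL

MU_B_JT <- 9.2740100783e-24    # Bohr magneton, J/T
H_JS <- 6.62607015e-34         # Planck constant, J s
MU0_OVER_4PI <- 1e-7           # T m / A

MU_B_OVER_H_MHZ_PER_T <- MU_B_JT / H_JS * 1e-6           # 13996.245 MHz/T

# mu0 muB^2 / (4 pi h), in MHz nm^3 (1 m^3 Hz = 1e27 nm^3 Hz = 1e21 nm^3 MHz)
DIPOLAR_PREFACTOR_MHZ_NM3 <- MU0_OVER_4PI * MU_B_JT^2 / H_JS * 1e21

#' Dipolar coupling constant for a pair of electron spins
#'
#' Returns D = mu0 muB^2 gA gB / (4 pi h) in MHz nm^3, the prefactor of the
#' secular dipolar frequency nu(r, theta) = D / r^3 * (1 - 3 cos^2 theta).
#'
#' @param g_A,g_B effective g values of the two spins (defaults: free
#'   electron-like isotropic nitroxide value).
#' @return dipolar constant in MHz nm^3 (about 52 for nitroxides).
#' @examples
#' dipolar_constant()          # ~52.2 MHz nm^3 for g = 2.006
#' @export
dipolar_constant <- function(g_A = 2.006, g_B = g_A) {
  DIPOLAR_PREFACTOR_MHZ_NM3 * g_A * g_B
}
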