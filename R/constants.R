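#' Physical constants and material properties
#'
#' Returns the set of physical constants used throughout the solvers, in SI
#' units, together with the relative permittivities of the materials that make
#' up the supported pores.
#'
#' @param temperature Temperature in K (default 293 K).
#' @return A list of class `physical_constants` with elements `k` (Boltzmann
#'   constant, J/K), `T` (K), `q` (elementary charge, C), `N_A` (1/mol),
#'   `C_F` (Faraday constant, C/mol), `eps0` (vacuum permittivity, C/(V m)),
#'   `eta` (water viscosity, Pa s), `kT` (J) and `eps_r` (named vector of
#'   relative permittivities).
#' @export
physical_constants <- function(temperature = 293) {
  stopifnot(temperature > 0)
  k <- 1.3806e-23
  q <- 1.602e-19
  N_A <- 6.022e23
  out <- list(
    k = k, T = temperature, q = q, N_A = N_A,
    C_F = q * N_A,
    eps0 = 8.854e-12,
    eta = 1e-3,
    kT = k * temperature,
    eps_r = c(
      water = 80.2, protein = 2, dna = 12, lipid = 2,
      sin = 7, gold = 6.9, sam = 2.7
    )
  )
  class(out) <- "physical_constants"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit helpers: user-facing lengths are nm, voltages mV, currents pA,
# surface charges q/nm^2; everything internal is SI
.nm <- 1e-9
.qnm2_to_Cm2 <- function(sigma_qnm2) sigma_qnm2 * 1.602e-19 / 1e-18

#' @exportS3Method base::print
print.physical_constants <- function(x, ...) {
  cat("Physical constants (SI): T =", x$T, "K, kT =", format(x$kT, digits = 5),
      "J, eta =", x$eta, "Pa s\n")
  invisible(x)
}
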