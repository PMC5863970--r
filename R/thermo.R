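#' Thermodynamic configuration
#'
#' Bundles the absolute temperature and gas constant used for every
#' free-energy / inhibition-constant conversion in the package.
#'
#' @param temperature_k Absolute temperature in kelvin. Default 298.15 K,
#'   the temperature at which docking scores are customarily reported.
#' @param gas_constant_kcal Gas constant in kcal mol^-1 K^-1 (CODATA value).
#'
#' @return An object of class `"thermo_config"`: a list with elements
#'   `temperature_k`, `gas_constant_kcal` and the derived product `rt_kcal`.
#' @examples
#' cfg <- thermo_config()
#' cfg$rt_kcal # about 0.5925 kcal/mol at 298.15 K
#' @export
thermo_config <- function(temperature_k = 298.15,
                          gas_constant_kcal = 1.98720425864083e-3) {
  if (!is.numeric(temperature_k) || length(temperature_k) != 1L ||
      !is.finite(temperature_k) || temperature_k <= 0) {
    stop("`temperature_k` must be a single positive, finite number", call. = FALSE)
  }
  if (!is.numeric(gas_constant_kcal) || length(gas_constant_kcal) != 1L ||
      !is.finite(gas_constant_kcal) || gas_constant_kcal <= 0) {
    stop("`gas_constant_kcal` must be a single positive, finite number", call. = FALSE)
  }
  structure(
    list(temperature_k = temperature_k,
         gas_constant_kcal = gas_constant_kcal,
         rt_kcal = gas_constant_kcal * temperature_k),
    class = "thermo_config"
  )
}

#' @export
print.thermo_config <- function(x, ...) {
  cat("Thermodynamic configuration\n")
  cat(sprintf("  T  = %g K\n  R  = %g kcal/(mol K)\n  RT = %g kcal/mol\n",
              x$temperature_k, x$gas_constant_kcal, x$rt_kcal))
  invisible(x)
}

#' Convert binding free energy to an inhibition constant
#'
#' Applies the equilibrium relation Ki = exp(dG / RT), returning Ki in
#' nanomolar. More negative free energies give smaller (tighter) inhibition
#' constants.
#'
#' @param delta_g_kcal Binding free energy in kcal/mol (vectorized).
#' @param config A [thermo_config()].
#'
#' @return Inhibition constant(s) in nM.
#' @examples
#' ki_from_energy(-8.41)  # ~ 685 nM
#' ki_from_energy(0)      # 1 M = 1e9 nM
#' @seealso [energy_from_ki()], [pki_from_ki()]
#' @export
ki_from_energy <- function(delta_g_kcal, config = thermo_config()) {
  stopifnot(inherits(config, "thermo_config"))
  if (!is.numeric(delta_g_kcal) || any(!is.finite(delta_g_kcal))) {
    stop("`delta_g_kcal` must be finite numeric", call. = FALSE)
  }
  exp(delta_g_kcal / config$rt_kcal) * 1e9
}

#' Convert an inhibition constant back to binding free energy
#'
#' Exact inverse of [ki_from_energy()]: dG = RT * ln(Ki in molar).
#'
#' @param ki_nm Inhibition constant(s) in nM; must be positive.
#' @inheritParams ki_from_energy
#' @return Free energy in kcal/mol.
#' @examples
#' energy_from_ki(684.74) # ~ -8.41 kcal/mol
#' @export
energy_from_ki <- function(ki_nm, config = thermo_config()) {
  stopifnot(inherits(config, "thermo_config"))
  if (!is.numeric(ki_nm) || any(!is.finite(ki_nm)) || any(ki_nm <= 0)) {
    stop("`ki_nm` must be positive, finite numeric", call. = FALSE)
  }
  config$rt_kcal * log(ki_nm * 1e-9)
}

#' pKi from an inhibition constant in nM
#'
#' pKi = -log10(Ki in molar); the nM input is converted to molar internally.
#' Higher pKi means a more potent ligand.
#'
#' @param ki_nm Inhibition constant(s) in nM; must be positive.
#' @return Dimensionless pKi value(s).
#' @examples
#' pki_from_ki(832)  # 6.08
#' pki_from_ki(1000) # 6.00 (1 uM)
#' @export
pki_from_ki <- function(ki_nm) {
  if (!is.numeric(ki_nm) || any(!is.finite(ki_nm)) || any(ki_nm <= 0)) {
    stop("`ki_nm` must be positive, finite numeric", call. = FALSE)
  }
  -log10(ki_nm * 1e-9)
}

#' Inhibition constant in nM from pKi
#'
#' @param pki Dimensionless pKi value(s).
#' @return Ki in nM.
#' @export
ki_from_pki <- function(pki) {
  if (!is.numeric(pki) || any(!is.finite(pki))) {
    stop("`pki` must be finite numeric", call. = FALSE)
  }
  10^(-pki) * 1e9
}

#' Check a docking free-energy decomposition
#'
#' A docking score decomposes as
#' total = intermolecular (vdW + H-bond + desolvation + electrostatic)
#' + torsional penalty. This verifies the decomposition within a tolerance.
#'
#' @param intermolecular_kcal Intermolecular energy term, kcal/mol.
#' @param torsional_kcal Torsional free-energy penalty, kcal/mol (>= 0).
#' @param total_kcal Total estimated binding free energy, kcal/mol.
#' @param tol Absolute tolerance in kcal/mol (default 0.01, the reporting
#'   precision of docking tables).
#' @return Logical vector: does each triplet satisfy the decomposition?
#' @examples
#' check_decomposition(-9.01, 0.60, -8.41) # TRUE
#' @export
check_decomposition <- function(intermolecular_kcal, torsional_kcal,
                                total_kcal, tol = 0.01) {
  vals <- c(intermolecular_kcal, torsional_kcal, total_kcal)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("all energy terms must be finite numeric", call. = FALSE)
  }
  abs(total_kcal - (intermolecular_kcal + torsional_kcal)) <= tol
}
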