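#' Physical constants used throughout the package
#'
#' Fixed constants: the classical electron radius, Avogadro's number, the
#' product hc expressed in keV*m (so lambda\[m\] = hcKeVm / E\[keV\]), and the
#' molar mass per electron ratio of 1.86 g/mol adopted for hydrated
#' biological matter (a water/lipid/protein/chromatin mixture).
#'
#' @return named list with elements `electronRadiusM`, `avogadro`, `hcKeVm`,
#'   `molarMassPerElectron`.
#' @examples
#' physicalConstants()$electronRadiusM
#' @export
physicalConstants <- function() {
  list(
    electronRadiusM = 2.8179403e-15,
    avogadro = 6.02214076e23,
    hcKeVm = 1.23984193e-9,
    molarMassPerElectron = 1.86
  )
}

.const <- physicalConstants()
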