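# Unit conventions, used everywhere:
#   length um, time s, pressure Pa, volumetric species nM,
#   surface species molecules/um^2, volumetric flow um^3/s internally.

#' Physical constants and unit conversions
#'
#' Centralized conversion constants. Volumetric concentrations are carried
#' in nM, lengths in micrometres, times in seconds. One nM corresponds to
#' ~0.602 molecules per cubic micrometre.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{molec_per_um3_per_nM}{molecules per um^3 in a 1 nM solution.}
#'   \item{um3_per_L}{cubic micrometres per litre.}
#'   \item{pa_to_dyn_cm2}{dyn/cm^2 per Pa.}
#' }
#' @export
ln_units <- list(
  avogadro             = 6.02214076e23,
  molec_per_um3_per_nM = 6.02214076e23 * 1e-9 / 1e15,  # 0.6022...
  um3_per_L            = 1e15,
  pa_to_dyn_cm2        = 10
)

# microlitres/hour -> um^3/s
ul_per_h_to_um3_per_s <- function(q) q * 1e9 / 3600

# molecules -> nanomoles... helpers kept internal
molecules_to_mol <- function(n) n / ln_units$avogadro

# moles in a volume given in um^3 -> nM
mol_in_um3_to_nM <- function(mol, vol_um3) {
  mol / (vol_um3 / ln_units$um3_per_L) * 1e9
}

# surface flux molecules/um^2/s -> nM * um / s (for Robin boundary terms)
molec_flux_to_nM_um <- function(f) f / ln_units$molec_per_um3_per_nM
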