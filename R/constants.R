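# Physical constants and element tables shared across the package.
# Internal length unit is nm everywhere; PDB I/O converts A <-> nm at the
# file boundary.

#' Bondi van der Waals radii (nm)
#'
#' Default van der Waals radii assigned to atoms on construction and on PDB
#' import.  The table can be overridden per call in the functions that
#' consume it (e.g. [sasa()]).
#'
#' @format Named numeric vector, element symbol -> radius in nm.
#' @export
vdw_radii_nm <- c(
  H = 0.110, C = 0.170, N = 0.155, O = 0.152, P = 0.180,
  S = 0.180, F = 0.147, Cl = 0.175, Br = 0.185, I = 0.198,
  Na = 0.227, K = 0.275, Mg = 0.173, Ca = 0.231, Zn = 0.139,
  Fe = 0.194, Mn = 0.197
)

# Periodic-table symbols accepted in AtomRecord validation.
.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te",
  "I", "Xe", "Cs", "Ba", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

# Effective carbon vdW diameter (nm) added to atom-centre extents when
# reporting carbon-dot heights/diameters.
.carbon_vdw_diameter <- 0.34

.lookup_vdw <- function(element, table = vdw_radii_nm) {
  r <- unname(table[element])
  r[is.na(r)] <- 0.17  # fall back to carbon-like radius for exotic elements
  r
}
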