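#' Physical constants used throughout the package
#'
#' Centralised so every module converts units the same way.
#'
#' \describe{
#'   \item{COULOMB_K}{Coulomb constant, 332.0636 kcal Å mol^-1 e^-2, the
#'     value conventional in biomolecular force fields.}
#'   \item{EA_TO_DEBYE}{1 e·Å = 4.8032 Debye; dipole moments computed from
#'     partial charges in e and coordinates in Å are multiplied by this.}
#'   \item{EV_TO_KCAL}{1 e·V = 23.060548 kcal/mol; used when converting a
#'     dipole-field product (Debye × V/Å) into kcal/mol.}
#'   \item{AVOGADRO}{Avogadro's number, mol^-1.}
#' }
#' @name samscan-constants
#' @keywords internal
NULL

COULOMB_K <- 332.0636
EA_TO_DEBYE <- 4.8032
EV_TO_KCAL <- 23.060548
AVOGADRO <- 6.02214076e23

# 1 Debye * (1 V/Å) in kcal/mol: Debye -> e*Å -> e*V -> kcal/mol
DEBYE_VA_TO_KCAL <- EV_TO_KCAL / EA_TO_DEBYE
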