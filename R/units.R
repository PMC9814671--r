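# Unit conventions: all internal dynamics in atomic units (hbar = 1);
# user-facing energies in cm^-1 (and kcal/mol for config), times in ps,
# lengths in bohr, actions in units of hbar.

KCAL_CM <- 349.755            # 1 kcal/mol in cm^-1
HARTREE_CM <- 219474.6313632  # 1 hartree in cm^-1
PS_AU <- 41341.37             # 1 ps in atomic units of time
AMU_AU <- 1822.888486         # 1 unified amu in electron masses

#' Energy and time unit conversions
#'
#' Helpers for the unit conventions used throughout the package: energies are
#' exchanged with the user in cm^-1 (kcal/mol in configuration files), times
#' in picoseconds, while all propagation happens in atomic units.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
kcal_to_cm <- function(x) x * KCAL_CM

#' @rdname units
#' @export
cm_to_kcal <- function(x) x / KCAL_CM

#' @rdname units
#' @export
cm_to_hartree <- function(x) x / HARTREE_CM

#' @rdname units
#' @export
hartree_to_cm <- function(x) x * HARTREE_CM

#' @rdname units
#' @export
ps_to_au <- function(x) x * PS_AU

#' @rdname units
#' @export
au_to_ps <- function(x) x / PS_AU
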