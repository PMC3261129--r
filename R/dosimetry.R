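# Dosimetry: absorbed dose <-> particle fluence per nucleus area.
#
# For a particle beam of linear energy transfer LET (keV/um) traversing
# unit-density water, the absorbed dose deposited by a fluence Phi
# (particles/um^2) is
#
#   dose [Gy] = Phi * LET * k / rho_um3
#
# with k = 1.602e-16 J/keV and rho_um3 = density * 1e-15 kg/um^3, i.e.
# dose = 0.1602 * LET * Phi at density 1 g/cm^3.  Fluence is conventionally
# reported per nucleus cross-section (default 100 um^2).

#' Conversion constant from keV/um fluence-LET product to Gray
#'
#' @param kev_to_joule Joule per keV (default 1.602e-16).
#' @param density target specific gravity in g/cm^3 (default 1, water).
#' @return Gy per (keV/um * particles/um^2), numeric scalar.
#' @keywords internal
#' @noRd
gy_per_kev_um <- function(kev_to_joule = 1.602e-16, density = 1) {
  check_scalar_number(kev_to_joule, "kev_to_joule", positive = TRUE)
  check_scalar_number(density, "density", positive = TRUE)
  kev_to_joule / (density * 1e-15)
}

#' Particle fluence per nucleus area from absorbed dose
#'
#' Computes the number of particles crossing a reference nucleus
#' cross-section (default 100 um^2 of unit-density water) that deposits a
#' given absorbed dose at a given LET.
#'
#' @param dose absorbed dose in Gy (vectorised, >= 0).
#' @param let linear energy transfer in keV/um (> 0).
#' @param density specific gravity of the target, g/cm^3 (default 1).
#' @param nucleus_area reference area in um^2 (default 100).
#' @param kev_to_joule energy conversion constant, J/keV.
#' @return particles per `nucleus_area`, unrounded.
#' @examples
#' fluence_from_dose(400, 30.0)   # ~ 8.32e3 per 100 um^2
#' @seealso [dose_from_fluence()], [condition_table()]
#' @export
fluence_from_dose <- function(dose, let, density = 1, nucleus_area = 100,
                              kev_to_joule = 1.602e-16) {
  check_scalar_number(dose, "dose", nonnegative = TRUE)
  check_scalar_number(let, "let", positive = TRUE)
  check_scalar_number(nucleus_area, "nucleus_area", positive = TRUE)
  k <- gy_per_kev_um(kev_to_joule, density)
  nucleus_area * dose / (let * k)
}

#' Absorbed dose from particle fluence per nucleus area
#'
#' Exact inverse of [fluence_from_dose()].
#'
#' @param fluence particles per `nucleus_area` (>= 0).
#' @inheritParams fluence_from_dose
#' @return absorbed dose in Gy.
#' @examples
#' dose_from_fluence(8320, 30.0)  # ~ 400 Gy
#' @export
dose_from_fluence <- function(fluence, let, density = 1, nucleus_area = 100,
                              kev_to_joule = 1.602e-16) {
  check_scalar_number(fluence, "fluence", nonnegative = TRUE)
  check_scalar_number(let, "let", positive = TRUE)
  check_scalar_number(nucleus_area, "nucleus_area", positive = TRUE)
  k <- gy_per_kev_um(kev_to_joule, density)
  fluence * let * k / nucleus_area
}

#' Tabulate irradiation conditions with derived fluence
#'
#' @param conditions a data.frame with columns `let` and `dose`, or a list
#'   of `c(let, dose)` pairs.
#' @param ion_label free-text ion description recycled over rows.
#' @inheritParams fluence_from_dose
#' @return a data.frame with one row per condition: `ion_label`, `let`,
#'   `dose`, `density`, `nucleus_area`, `fluence` (unrounded particles per
#'   `nucleus_area`) and `fluence_rounded` (nearest integer, the reporting
#'   convention).
#' @examples
#' condition_table(list(c(22.5, 250), c(22.5, 450), c(30.0, 400)))
#' @export
condition_table <- function(conditions, ion_label = "12C6+", density = 1,
                            nucleus_area = 100, kev_to_joule = 1.602e-16) {
  if (is.data.frame(conditions)) {
    if (!all(c("let", "dose") %in% names(conditions))) {
      ionmut_error("conditions data.frame needs columns 'let' and 'dose'",
                   "ionmut_domain_error")
    }
    let <- conditions$let
    dose <- conditions$dose
  } else {
    let <- vapply(conditions, `[`, numeric(1), 1L)
    dose <- vapply(conditions, `[`, numeric(1), 2L)
  }
  n <- length(let)
  out <- data.frame(
    ion_label = rep_len(ion_label, n),
    let = let, dose = dose,
    density = rep_len(density, n),
    nucleus_area = rep_len(nucleus_area, n),
    stringsAsFactors = FALSE
  )
  out$fluence <- vapply(seq_len(n), function(i) {
    tryCatch(
      fluence_from_dose(dose[i], let[i], density, nucleus_area,
                        kev_to_joule),
      ionmut_error = function(e) {
        ionmut_error(sprintf("condition %d: %s", i, conditionMessage(e)),
                     "ionmut_domain_error")
      }
    )
  }, numeric(1))
  out$fluence_rounded <- round_half_away(out$fluence)
  out
}
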