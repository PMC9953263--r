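# Dose arithmetic: from a per-body-surface-area chemotherapy dose to the
# expected drug concentration in whole blood and in a washed RBC
# suspension, plus the suspension hematocrit sanity check.

#' Convert a per-BSA drug dose to blood and suspension concentrations
#'
#' The whole-blood concentration of a dose prescribed per body surface
#' area is `dose * S / V` (mg/m^2 * m^2 / L = mg/L = ug/mL) for a
#' reference patient of surface area `S` and circulating blood volume
#' `V`. Because the drug acts on a finite number of cells, the working
#' concentration for a washed suspension is scaled by the ratio of the
#' suspension cell concentration to the whole-blood cell concentration,
#' keeping the drug-per-cell load equal. Both values are returned; note
#' that published protocols sometimes state final suspension
#' concentrations that do not follow from this arithmetic, so no
#' equality with any externally stated value is implied.
#'
#' @param dose_per_bsa Dose (mg/m^2).
#' @param body_surface_area Reference body surface area (m^2, default
#'   1.81).
#' @param blood_volume Circulating blood volume (L, default 4.5).
#' @param suspension_cell_conc RBC concentration of the working
#'   suspension (cells/mL, default 5e8).
#' @param whole_blood_cell_conc RBC concentration of whole blood
#'   (cells/mL, default 5e9).
#' @return List with `blood_ug_ml` and `suspension_ug_ml`.
#' @examples
#' dose_to_concentration(175)  # paclitaxel at the maximum dose
#' @export
dose_to_concentration <- function(dose_per_bsa,
                                  body_surface_area = 1.81,
                                  blood_volume = 4.5,
                                  suspension_cell_conc = 5e8,
                                  whole_blood_cell_conc = 5e9) {
  if (dose_per_bsa < 0)
    stop("`dose_per_bsa` must be nonnegative", call. = FALSE)
  if (body_surface_area <= 0 || blood_volume <= 0 ||
      suspension_cell_conc <= 0 || whole_blood_cell_conc <= 0)
    stop("surface area, volume and cell concentrations must be positive",
         call. = FALSE)
  blood <- dose_per_bsa * body_surface_area / blood_volume
  list(blood_ug_ml = blood,
       suspension_ug_ml = blood *
         suspension_cell_conc / whole_blood_cell_conc)
}

#' Hematocrit of an RBC suspension
#'
#' Volume fraction occupied by cells: `cell concentration * MCV`,
#' expressed in percent. A washed suspension of 5e8 cells/mL at a
#' typical MCV sits at about 4-4.5%.
#'
#' @param cell_conc Cell concentration (cells/mL).
#' @param mcv Mean cell volume (fL).
#' @return Hematocrit (%).
#' @examples
#' suspension_hematocrit(5e8, 84.6)  # 4.23
#' @export
suspension_hematocrit <- function(cell_conc, mcv) {
  if (cell_conc < 0 || mcv < 0)
    stop("`cell_conc` and `mcv` must be nonnegative", call. = FALSE)
  # cells/mL * fL = 1e-15 L per 1e-3 L; *100 for percent
  100 * cell_conc * mcv * 1e-15 / 1e-3
}
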