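#' Sugar specification
#'
#' Formulation bookkeeping is done in monosaccharide units: disaccharides
#' (trehalose, sucrose, maltose, lactose) count 2 units per molecule and the
#' trisaccharide raffinose counts 3. Molar masses are anhydrous.
#'
#' @param name Sugar name (one of [wab_sugars()] except `"none"`), or a
#'   custom name if `units_per_molecule` and `molar_mass` are supplied.
#' @param units_per_molecule Integer, 2 or 3.
#' @param molar_mass Molar mass in g/mol.
#' @return A list of class `"wab_sugar"`.
#' @export
sugar_spec <- function(name, units_per_molecule = NULL, molar_mass = NULL) {
  known <- list(
    trehalose = list(units = 2L, mass = 342.30),
    sucrose   = list(units = 2L, mass = 342.30),
    maltose   = list(units = 2L, mass = 342.30),
    lactose   = list(units = 2L, mass = 342.30),
    raffinose = list(units = 3L, mass = 504.42)
  )
  if (is.null(units_per_molecule) || is.null(molar_mass)) {
    if (!name %in% names(known)) {
      stop("unknown sugar '", name,
           "'; supply units_per_molecule and molar_mass", call. = FALSE)
    }
    units_per_molecule <- known[[name]]$units
    molar_mass <- known[[name]]$mass
  }
  units_per_molecule <- as.integer(units_per_molecule)
  if (!units_per_molecule %in% c(2L, 3L)) {
    stop("units_per_molecule must be 2 (disaccharide) or 3 (trisaccharide)",
         call. = FALSE)
  }
  stopifnot(is.numeric(molar_mass), molar_mass > 0)
  structure(list(name = name, units_per_molecule = units_per_molecule,
                 molar_mass = molar_mass),
            class = "wab_sugar")
}

water_molar_mass <- 18.015

#' Monosaccharide-units-per-protein ratio (S/P)
#'
#' @param sugar_molarity Sugar concentration in mol/L.
#' @param protein_molarity Protein concentration in mol/L; 0 means a
#'   protein-free (binary) sample and yields the sentinel `Inf`.
#' @param sugar A [sugar_spec()].
#' @return S/P in monosaccharide units per protein molecule (`Inf` when
#'   protein-free).
#' @export
sp_ratio <- function(sugar_molarity, protein_molarity, sugar) {
  stopifnot(inherits(sugar, "wab_sugar"),
            sugar_molarity >= 0, protein_molarity >= 0)
  if (protein_molarity == 0) return(Inf)
  sugar_molarity * sugar$units_per_molecule / protein_molarity
}

#' Sugar molarity realizing a total monosaccharide-unit molarity
#'
#' Solutions are prepared at equal monosaccharide-unit concentration rather
#' than equal nominal molarity, so that di- and trisaccharides are
#' comparable: e.g. 0.8 M units correspond to 0.40 M disaccharide and
#' 0.27 M raffinose.
#'
#' @param total_unit_molarity Monosaccharide-unit concentration in mol/L.
#' @param sugar A [sugar_spec()].
#' @return Sugar molarity in mol/L.
#' @export
sugar_molarity_from_units <- function(total_unit_molarity, sugar) {
  stopifnot(inherits(sugar, "wab_sugar"), total_unit_molarity >= 0)
  total_unit_molarity / sugar$units_per_molecule
}

#' Convert a molar water/sugar ratio to a mass ratio
#'
#' @param ws_molar Water molecules per sugar molecule (>= 0).
#' @param sugar A [sugar_spec()].
#' @return g water per g sugar. E.g. a 2:1 water:trehalose stoichiometry is
#'   0.105 g/g (0.11 at two decimals).
#' @export
ws_mass_ratio <- function(ws_molar, sugar) {
  stopifnot(inherits(sugar, "wab_sugar"), ws_molar >= 0)
  ws_molar * water_molar_mass / sugar$molar_mass
}

#' @rdname ws_mass_ratio
#' @param mass_ratio g water per g sugar.
#' @return `ws_molar_from_mass`: water molecules per sugar molecule.
#' @export
ws_molar_from_mass <- function(mass_ratio, sugar) {
  stopifnot(inherits(sugar, "wab_sugar"), mass_ratio >= 0)
  mass_ratio * sugar$molar_mass / water_molar_mass
}

#' Protein:sugar mass ratio at a given S/P
#'
#' @param sp S/P in monosaccharide units per protein.
#' @param sugar A [sugar_spec()].
#' @param protein_molar_mass Protein molar mass in g/mol; default 16950
#'   (horse myoglobin, configurable).
#' @return Grams of protein per gram of sugar.
#' @export
protein_sugar_mass_ratio <- function(sp, sugar, protein_molar_mass = 16950) {
  stopifnot(inherits(sugar, "wab_sugar"), sp > 0, protein_molar_mass > 0)
  sugar_per_protein <- sp / sugar$units_per_molecule
  protein_molar_mass / (sugar_per_protein * sugar$molar_mass)
}

#' Location of the residual-water minimum across S/P
#'
#' Given residual water content (W/S, water molecules per sugar molecule)
#' measured at several finite S/P ratios, returns the S/P with the smallest
#' W/S; ties break toward the smaller S/P.
#'
#' @param ws_by_sp Named numeric vector: names are finite S/P values,
#'   values are W/S ratios.
#' @return The S/P value (numeric) at the W/S minimum.
#' @export
ws_minimum <- function(ws_by_sp) {
  if (length(ws_by_sp) == 0L) stop("empty W/S map", call. = FALSE)
  sp <- as.numeric(names(ws_by_sp))
  if (anyNA(sp) || any(!is.finite(sp))) {
    stop("S/P keys must be finite numbers", call. = FALSE)
  }
  ws <- as.numeric(ws_by_sp)
  best <- which(ws == min(ws))
  min(sp[best])
}

#' Residual water content reference data
#'
#' Measured water/saccharide molar ratios (W/S) of dried myoglobin-sugar
#' films at each S/P ratio, for the five sugars studied; `Inf` marks the
#' protein-free samples. For every sugar the residual water passes through a
#' minimum at S/P = 80. Bundled as the worked-example input for
#' [ws_minimum()].
#'
#' @return Data.frame with columns `sp`, `trehalose`, `sucrose`, `maltose`,
#'   `lactose`, `raffinose` (NA where a composition was not prepared).
#' @export
ws_reference <- function() {
  data.frame(
    sp        = c(20, 40, 80, 160, 320, 640, Inf),
    trehalose = c(3.8, 1.8, 0.3, 1.4, 2.0, 2.5, 3.0),
    sucrose   = c(0.8, 0.4, 0.3, 2.2, 3.3, 1.1, 0.8),
    maltose   = c(1.2, 0.5, 0.3, 1.2, 2.4, NA, 4.0),
    lactose   = c(2.0, 0.4, 0.2, 2.1, 3.2, NA, 5.3),
    raffinose = c(1.2, 1.0, 0.3, 2.1, 5.6, NA, 6.8)
  )
}

#' Sample formulation reference: molar concentrations
#'
#' Sugar and myoglobin concentrations used to prepare the amorphous films at
#' each nominal S/P, for disaccharides and for raffinose. The disaccharide
#' rows reproduce their S/P label exactly under [sp_ratio()]; the raffinose
#' concentrations imply slightly different ratios than their nominal labels
#' (e.g. 130 mM x 3 / 5 mM = 78 for the row labeled 80), and are kept as
#' printed without reconciliation.
#'
#' @return Data.frame with columns `sp_label`, `family`
#'   (`"disaccharide"`/`"raffinose"`), `sugar_mM`, `protein_mM` (NA for the
#'   protein-free row).
#' @export
formulation_reference <- function() {
  rbind(
    data.frame(sp_label = c(20, 40, 80, 160, 320, 640, Inf),
               family = "disaccharide",
               sugar_mM = c(80, 140, 200, 240, 320, 320, 400),
               protein_mM = c(8, 7, 5, 3, 2, 1, NA)),
    data.frame(sp_label = c(20, 40, 80, 160, 320, Inf),
               family = "raffinose",
               sugar_mM = c(50, 90, 130, 160, 210, 270),
               protein_mM = c(8, 7, 5, 3, 2, NA))
  )
}
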