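# Cmol stoichiometry: elemental formulas normalised per carbon, Cmol masses,
# degree of reduction, and the unit conversions used throughout the package.

# IUPAC 2021 standard atomic weights
.atomic_weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' Elemental formula normalised per carbon atom
#'
#' Represents the composition of an organic compound on a carbon-mole (Cmol)
#' basis, i.e. scaled so the carbon coefficient is exactly 1. For example
#' PHB monomer C4H6O2 becomes CH1.5O0.5.
#'
#' @param C,H,O,N stoichiometric coefficients (non-negative; `C` > 0).
#' @return An object of class `elemental_formula`: a named numeric vector
#'   with components C (always 1), H, O, N.
#' @examples
#' elemental_formula(C = 4, H = 6, O = 2)  # PHB monomer -> CH1.5O0.5
#' elemental_formula(H = 1.8, O = 0.5, N = 0.2)  # standard biomass
#' @export
elemental_formula <- function(C = 1, H = 0, O = 0, N = 0) {
  x <- c(C = C, H = H, O = O, N = N)
  if (any(!is.finite(x))) stop("formula coefficients must be finite numbers")
  if (any(x < 0)) stop("invalid formula: negative stoichiometric coefficient")
  if (C <= 0) stop("invalid formula: carbon coefficient must be positive")
  structure(x / C, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  sub <- function(el) {
    v <- unname(x[el])
    if (v == 0) "" else if (el == "C" && v == 1) "C" else paste0(el, format(v, digits = 4))
  }
  cat("<elemental_formula> C", paste0(vapply(c("H", "O", "N"), sub, ""), collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Reference formulas: biomass, PHB and acetate
#'
#' Standard compositions on a per-carbon basis: active biomass CH1.8O0.5N0.2
#' (24.6 g/Cmol), PHB monomer C4H6O2 i.e. CH1.5O0.5 (21.5 g/Cmol), and
#' acetate C2H4O2 i.e. CH2O (degree of reduction exactly 4).
#'
#' @return An `elemental_formula`.
#' @export
biomass_formula <- function() elemental_formula(C = 1, H = 1.8, O = 0.5, N = 0.2)

#' @rdname biomass_formula
#' @export
phb_formula <- function() elemental_formula(C = 4, H = 6, O = 2)

#' @rdname biomass_formula
#' @export
acetate_formula <- function() elemental_formula(C = 2, H = 4, O = 2)

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.numeric(f) && all(c("C", "H", "O", "N") %in% names(f)))
    return(elemental_formula(f[["C"]], f[["H"]], f[["O"]], f[["N"]]))
  stop("expected an 'elemental_formula'")
}

#' Mass of one carbon-mole
#'
#' Sum of coefficient times standard atomic weight over C, H, O, N for a
#' formula normalised to one carbon. Biomass CH1.8O0.5N0.2 gives 24.63
#' (24.6 to one decimal) and PHB CH1.5O0.5 gives 21.52 g/Cmol.
#'
#' @param formula an [elemental_formula()].
#' @return Mass in g/Cmol.
#' @export
cmol_mass <- function(formula) {
  f <- as_formula(formula)
  sum(unclass(f) * .atomic_weights[names(unclass(f))])
}

#' Degree of reduction per Cmol
#'
#' Available electron equivalents per carbon mole, gamma = 4 C + 1 H - 2 O - 3 N,
#' with ammonia as the nitrogen reference. Acetate gives exactly 4; PHB
#' (CH1.5O0.5) gives 4.5; biomass (CH1.8O0.5N0.2) gives 4.2. Used to close
#' the oxygen (electron) balance: one mol O2 accepts 4 electron equivalents.
#'
#' @param formula an [elemental_formula()].
#' @param nitrogen_source reference state for nitrogen; only `"ammonia"` is
#'   supported.
#' @return Electron equivalents per Cmol.
#' @export
degree_of_reduction <- function(formula, nitrogen_source = "ammonia") {
  nitrogen_source <- match.arg(nitrogen_source, "ammonia")
  f <- unclass(as_formula(formula))
  4 * f[["C"]] + 1 * f[["H"]] - 2 * f[["O"]] - 3 * f[["N"]]
}

#' Convert between mass and carbon-mole concentrations
#'
#' `mass_to_cmol()` converts g/L to Cmmol/L given a Cmol mass (g/Cmol);
#' `cmol_to_mass()` is the exact inverse. Internally the package carries all
#' organic concentrations in Cmmol/L; grams appear only at I/O boundaries.
#'
#' @param g_per_l concentration in g/L (non-negative).
#' @param cmmol_per_l concentration in Cmmol/L (non-negative).
#' @param mass Cmol mass in g/Cmol (strictly positive), e.g. from
#'   [cmol_mass()].
#' @return Concentration in Cmmol/L (or g/L for the inverse).
#' @export
mass_to_cmol <- function(g_per_l, mass) {
  check_cmol_mass(mass)
  if (any(g_per_l < 0)) stop("concentration must be non-negative")
  1000 * g_per_l / mass
}

#' @rdname mass_to_cmol
#' @export
cmol_to_mass <- function(cmmol_per_l, mass) {
  check_cmol_mass(mass)
  if (any(cmmol_per_l < 0)) stop("concentration must be non-negative")
  cmmol_per_l * mass / 1000
}

check_cmol_mass <- function(mass) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("Cmol mass must be a single positive number (g/Cmol)")
  invisible(mass)
}

#' Active biomass from solids measurements
#'
#' Active biomass is estimated as volatile suspended solids minus the stored
#' polymer, X = VSS - PHB (all g/L). Alternatively the polymer can be given
#' as a weight fraction of VSS, in which case PHB = VSS x PHB%.
#'
#' @param vss volatile suspended solids, g/L.
#' @param phb PHB concentration, g/L. Ignored if `phb_fraction` is given.
#' @param phb_fraction PHB weight fraction of VSS in [0, 1] (optional).
#' @return Active biomass X in g/L.
#' @export
active_biomass <- function(vss, phb = 0, phb_fraction = NULL) {
  if (any(vss < 0)) stop("VSS must be non-negative")
  if (!is.null(phb_fraction)) {
    if (any(phb_fraction < 0 | phb_fraction > 1))
      stop("phb_fraction must lie in [0, 1]")
    phb <- vss * phb_fraction
  }
  if (any(phb < 0)) stop("PHB must be non-negative")
  if (any(phb > vss + 1e-12))
    stop("inconsistent measurement: PHB exceeds VSS")
  vss - phb
}

#' PHB content as weight percent of total solids
#'
#' Computes 100 * m_PHB / (m_PHB + m_X) from carbon-mole concentrations,
#' using 21.5 g/Cmol for PHB and 24.6 g/Cmol for active biomass.
#'
#' @param phb_cmmol PHB, Cmmol/L.
#' @param x_cmmol active biomass, Cmmol/L.
#' @return Weight percent in [0, 100].
#' @export
phb_weight_percent <- function(phb_cmmol, x_cmmol) {
  mp <- cmol_to_mass(phb_cmmol, cmol_mass(phb_formula()))
  mx <- cmol_to_mass(x_cmmol, cmol_mass(biomass_formula()))
  tot <- mp + mx
  ifelse(tot > 0, 100 * mp / tot, 0)
}
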