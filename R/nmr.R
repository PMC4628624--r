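# Conversion of NMR observables into conformational restraints and
# classifications: 3J(HN-HA) couplings to phi intervals (chirality-aware),
# NOE volumes to distance bounds, amide temperature coefficients to
# hydrogen-bond classes, proline Cb/Cg shifts to cis/trans isomer calls.

# J -> phi interval rules for l-residues, left-closed bins on J (a boundary
# coupling falls into the higher-J rule).
.j_phi_rules <- data.frame(
  j_lo = c(0, 6, 8, 9),
  j_hi = c(6, 8, 9, Inf),
  phi_lo = c(-90, -120, -160, -140),
  phi_hi = c(-30, -60, -80, -100)
)

#' Convert a 3J(HN-HA) coupling into a phi torsion restraint interval
#'
#' l-residues: J < 6 Hz gives phi in \[-90, -30\]; 6 <= J < 8 gives
#' \[-120, -60\]; 8 <= J < 9 gives \[-160, -80\]; J >= 9 gives \[-140, -100\]
#' (degrees).  d-residues occupy the mirror region of the Ramachandran map
#' (phi, psi -> -phi, -psi), so the l interval is negated and its endpoints
#' swapped.
#'
#' @param J coupling constant, Hz (>= 0).
#' @param chirality `"L"` or `"D"`.
#' @param residue_index optional 1-based residue number carried into the label.
#' @param force_constant restraint force constant, kcal/(mol rad^2), default 2.
#' @return a one-row data.frame (class `dihedral_restraint`): `residue`,
#'   `angle`, `lo`, `hi` (degrees), `force_constant`, `label`.
#' @export
j_to_phi_interval <- function(J, chirality = "L", residue_index = NA_integer_,
                              force_constant = 2) {
  if (length(J) != 1L || !is.finite(J) || J < 0) stop("J must be a finite non-negative scalar")
  chirality <- toupper(chirality)
  if (!chirality %in% c("L", "D")) stop("chirality must be 'L' or 'D'")
  r <- .j_phi_rules[J >= .j_phi_rules$j_lo & J < .j_phi_rules$j_hi, ]
  lo <- r$phi_lo; hi <- r$phi_hi
  if (chirality == "D") { tmp <- lo; lo <- -hi; hi <- -tmp }
  out <- data.frame(residue = residue_index, angle = "phi", lo = lo, hi = hi,
                    force_constant = force_constant,
                    label = sprintf("phi%s J=%.1fHz %s",
                                    ifelse(is.na(residue_index), "",
                                           residue_index), J, chirality),
                    stringsAsFactors = FALSE)
  class(out) <- c("dihedral_restraint", class(out))
  out
}

#' Calibrate NOE volumes into interproton distance bounds
#'
#' Isolated-spin-pair calibration: d = d_ref * (V_ref / V)^(1/6), anchored on
#' one reference pair of known distance.  Upper bounds for pseudo-atoms are
#' padded (+1.0 A for methyl groups, +0.9 A for degenerate aromatic ring
#' pairs) and clipped at 6.0 A.  The output is flagged as stand-in calibrated:
#' no NOE distance-class curves are fitted.
#'
#' @param peaks data.frame with columns `atom1`, `atom2`, `volume` (> 0) and
#'   optionally `type` (`""`, `"methyl"`, `"aromatic"`).
#' @param ref_volume volume of the reference pair (> 0).
#' @param ref_distance known reference distance, A, inside (1.7, 6.0); default
#'   1.78 A, a geminal Hb pair.
#' @param force_constant force constant attached to every distance restraint,
#'   kcal/(mol rad^2), default 20.
#' @return data.frame (class `distance_restraint_set`): `atom1`, `atom2`,
#'   `distance`, `upper` (padded/clipped bound), `force_constant`;
#'   attribute `calibration = "ISPA stand-in"`.
#' @export
calibrate_noe <- function(peaks, ref_volume, ref_distance = 1.78,
                          force_constant = 20) {
  if (!all(c("atom1", "atom2", "volume") %in% names(peaks)))
    stop("peaks need columns atom1, atom2, volume")
  if (any(peaks$volume <= 0)) stop("NOE volumes must be positive")
  if (ref_volume <= 0) stop("reference volume must be positive")
  if (ref_distance <= 1.7 || ref_distance >= 6.0)
    stop("reference distance must lie in (1.7, 6.0) A")
  d <- ref_distance * (ref_volume / peaks$volume)^(1 / 6)
  pad <- rep(0, nrow(peaks))
  if (!is.null(peaks$type)) {
    pad[peaks$type == "methyl"] <- 1.0
    pad[peaks$type == "aromatic"] <- 0.9
  }
  out <- data.frame(atom1 = peaks$atom1, atom2 = peaks$atom2,
                    distance = d, upper = pmin(d + pad, 6.0),
                    force_constant = force_constant,
                    stringsAsFactors = FALSE)
  attr(out, "calibration") <- "ISPA stand-in"
  class(out) <- c("distance_restraint_set", class(out))
  out
}

#' Amide proton temperature coefficient
#'
#' Ordinary least-squares slope of the amide 1H chemical shift (in ppb)
#' against temperature (in K).
#'
#' @param temperature temperatures; Celsius by default (converted to K), or
#'   Kelvin with `units = "K"`.
#' @param shift_ppm amide proton shifts, ppm.
#' @param units `"C"` or `"K"`.
#' @return slope in ppb/K.
#' @export
temp_coefficient <- function(temperature, shift_ppm, units = c("C", "K")) {
  units <- match.arg(units)
  if (length(temperature) < 2L || length(unique(temperature)) < 2L)
    stop("at least two distinct temperatures are required")
  if (length(temperature) != length(shift_ppm))
    stop("temperature and shift vectors must have equal length")
  TK <- if (units == "C") temperature + 273.15 else temperature
  unname(stats::coef(stats::lm(I(shift_ppm * 1000) ~ TK))[2])
}

#' Classify a temperature coefficient into a hydrogen-bond class
#'
#' Coefficients in (-3, 0\] ppb/K indicate strong intramolecular hydrogen
#' bonds (solvent-shielded amides); (-5, -3\] indicates weak intramolecular
#' and/or solute-solvent bonds; values at or below -5 exclude a stable bond.
#' Boundary values fall into the weaker class.  Positive coefficients are
#' outside the usual rules and are mapped to `"strong"` (shielded) with a
#' warning.
#'
#' @param coef temperature coefficient, ppb/K.
#' @return one of `"strong"`, `"weak"`, `"none"`.
#' @export
classify_hbond <- function(coef) {
  if (!is.finite(coef)) stop("temperature coefficient must be finite")
  if (coef > 0) {
    warning("positive temperature coefficient; treating the amide as shielded")
    return("strong")
  }
  if (coef > -3) "strong" else if (coef > -5) "weak" else "none"
}

#' Proline cis/trans isomer from Cb/Cg chemical shifts
#'
#' The shift difference delta(Cb) - delta(Cg) separates the isomers: small
#' differences (around 4.5 ppm) indicate trans X-Pro peptide bonds, large ones
#' (around 9.6 ppm) cis.  The decision threshold is 7.0 ppm, midway between
#' the literature anchors.
#'
#' @param shift_table data.frame with columns `residue`, `atom`, `ppm`
#'   (13C shifts; see [read_shift_table()]).
#' @param residue_index 1-based index of the proline.
#' @return list with `isomer` (`"trans"`, `"cis"` or `"undetermined"`) and
#'   `delta_ppm` (NA when a shift is missing).
#' @export
proline_isomer <- function(shift_table, residue_index) {
  get <- function(atom) {
    v <- shift_table$ppm[shift_table$residue == residue_index &
                           shift_table$atom == atom]
    if (length(v) == 1L && is.finite(v)) v else NA_real_
  }
  cb <- get("CB"); cg <- get("CG")
  if (is.na(cb) || is.na(cg))
    return(list(isomer = "undetermined", delta_ppm = NA_real_))
  d <- cb - cg
  list(isomer = if (d < 7.0) "trans" else "cis", delta_ppm = d)
}

#' Carbon zero-point frequency from the proton zero-point frequency
#'
#' Indirect 13C referencing against DSS via the frequency ratio
#' Xi = 0.251449530.
#'
#' @param proton_zero_freq proton reference frequency (Hz, or any unit).
#' @return carbon reference frequency in the same unit.
#' @export
reference_carbon <- function(proton_zero_freq) {
  if (any(proton_zero_freq < 0)) stop("frequency must be non-negative")
  proton_zero_freq * 0.251449530
}

#' Aggregate couplings and NOE peaks into a restraint set
#'
#' Builds phi dihedral restraints from couplings (Gly couplings are skipped by
#' default: with two degenerate HA protons the coupling does not identify
#' phi), distance restraints from calibrated NOE volumes, and, when
#' `omega_trans` is set, trans peptide-bond restraints on every omega torsion
#' (180 +/- `omega_tol` degrees) at force constant 50 kcal/(mol rad^2).
#' Duplicate distance restraints on one atom pair keep the tighter bound.
#'
#' @param couplings data.frame with `residue`, `J`, `chirality` (see
#'   [read_couplings()]); may be `NULL`.
#' @param peaks NOE peak data.frame (see [calibrate_noe()]); may be `NULL`.
#' @param ref_volume,ref_distance NOE calibration anchor.
#' @param n_residues residue count (needed for omega restraints).
#' @param omega_trans logical; add trans omega restraints.
#' @param omega_tol half-width of the omega interval, degrees (default 10).
#' @param include_gly logical, default `FALSE`.
#' @return list of class `restraint_set`: `distance` (data.frame), `dihedral`
#'   (data.frame), `counts`, `meta` (calibration flag, dropped duplicates).
#' @export
build_restraint_set <- function(couplings = NULL, peaks = NULL,
                                ref_volume = NULL, ref_distance = 1.78,
                                n_residues = NULL, omega_trans = FALSE,
                                omega_tol = 10, include_gly = FALSE) {
  dihedral <- NULL
  if (!is.null(couplings) && nrow(couplings)) {
    keep <- rep(TRUE, nrow(couplings))
    if (!include_gly && !is.null(couplings$residue_name))
      keep <- toupper(couplings$residue_name) != "GLY"
    rows <- lapply(which(keep), function(k)
      j_to_phi_interval(couplings$J[k], couplings$chirality[k],
                        couplings$residue[k]))
    dihedral <- do.call(rbind, rows)
  }
  if (omega_trans) {
    if (is.null(n_residues)) stop("omega restraints need n_residues")
    om <- data.frame(residue = seq(2L, n_residues), angle = "omega",
                     lo = 180 - omega_tol, hi = 180 + omega_tol,
                     force_constant = 50,
                     label = sprintf("omega%d trans", seq(2L, n_residues)),
                     stringsAsFactors = FALSE)
    dihedral <- rbind(dihedral, om)
  }
  distance <- NULL
  dropped <- 0L
  if (!is.null(peaks) && nrow(peaks)) {
    if (is.null(ref_volume)) stop("NOE calibration needs ref_volume")
    distance <- calibrate_noe(peaks, ref_volume, ref_distance)
    key <- paste(pmin(distance$atom1, distance$atom2),
                 pmax(distance$atom1, distance$atom2))
    if (anyDuplicated(key)) {
      ord <- order(key, distance$upper)
      distance <- distance[ord, ][!duplicated(key[ord]), ]
      dropped <- length(key) - nrow(distance)
      message(dropped, " duplicate distance restraint(s) dropped, ",
              "keeping the tighter bound")
    }
    rownames(distance) <- NULL
  }
  structure(list(
    distance = distance, dihedral = dihedral,
    counts = c(distance = if (is.null(distance)) 0L else nrow(distance),
               dihedral = if (is.null(dihedral)) 0L else nrow(dihedral)),
    meta = list(calibration = if (is.null(distance)) NULL else "ISPA stand-in",
                duplicates_dropped = dropped)),
    class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("restraint_set:", x$counts["distance"], "distance,",
      x$counts["dihedral"], "dihedral restraint(s)\n")
  if (!is.null(x$meta$calibration))
    cat("  distance calibration:", x$meta$calibration, "\n")
  invisible(x)
}
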