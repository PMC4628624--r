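# Peptide topology: residues with l/d chirality, atoms, bonds and disulfides.
# Atom naming follows PDB v3; residue numbering is 1-based throughout.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

# Side-chain heavy-atom templates (PDB v3 names), in build order.  The first
# atom of every non-Gly side chain is CB, bonded to CA.
.sidechain_atoms <- list(
  GLY = character(0),
  CYS = c("CB", "SG"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  PRO = c("CB", "CG", "CD"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")
)

.one_to_three <- c(C = "CYS", Y = "TYR", F = "PHE", Q = "GLN", N = "ASN",
                   P = "PRO", R = "ARG", G = "GLY")

.atom_element <- function(name) substr(sub("^[0-9]", "", name), 1, 1)

#' Construct a peptide topology
#'
#' Defines the frame of reference for all per-residue analyses: residue
#' identities with l/d chirality, atoms with elements and masses, covalent
#' bonds, disulfide bridges and an optional C-terminal amide.
#'
#' Each residue carries backbone atoms N, (H), CA, C, O plus the standard
#' side-chain heavy atoms; amide H is present for every residue except the
#' first (free amine) and prolines.  When `c_terminal_amide` is set the final
#' residue gains an NT nitrogen capping the C-terminus.
#'
#' @param sequence character vector of 3-letter residue codes (or a single
#'   string of 1-letter codes).
#' @param chirality per-residue `"L"` or `"D"`; Gly is recorded as achiral
#'   regardless.  Default all-L.
#' @param disulfides 2-column matrix (or length-2 vector) of residue index
#'   pairs; both residues must be Cys.
#' @param c_terminal_amide logical, default `TRUE` (hormone-like CONH2 tail).
#' @return an object of class `pep_topology` with elements `residues`
#'   (data.frame: name, chirality), `atoms` (data.frame: residue, atom_name,
#'   element, mass), `bonds` (2-column index matrix), `disulfides`,
#'   `c_terminal_amide`.
#' @export
pep_topology <- function(sequence, chirality = NULL, disulfides = NULL,
                         c_terminal_amide = TRUE) {
  if (length(sequence) == 1L && !sequence %in% names(.sidechain_atoms)) {
    sequence <- .one_to_three[strsplit(toupper(sequence), "")[[1]]]
    if (anyNA(sequence)) stop("unknown 1-letter residue code")
  }
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(.sidechain_atoms))
  if (length(bad)) stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  n <- length(sequence)
  if (n < 1L) stop("a topology needs at least one residue")
  if (is.null(chirality)) chirality <- rep("L", n)
  chirality <- toupper(rep_len(chirality, n))
  if (!all(chirality %in% c("L", "D"))) stop("chirality must be 'L' or 'D'")
  chirality[sequence == "GLY"] <- "achiral"

  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    res <- sequence[i]
    nm <- c("N",
            if (i > 1L && res != "PRO") "H",
            "CA", "HA", "C", "O",
            .sidechain_atoms[[res]],
            if (c_terminal_amide && i == n) "NT")
    data.frame(residue = i, atom_name = nm,
               element = vapply(nm, .atom_element, ""),
               stringsAsFactors = FALSE)
  }))
  atoms$element[atoms$atom_name == "NT"] <- "N"
  atoms$mass <- .element_masses[atoms$element]
  rownames(atoms) <- NULL

  idx <- function(i, name) which(atoms$residue == i & atoms$atom_name == name)
  bonds <- list()
  add_bond <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)
  for (i in seq_len(n)) {
    add_bond(idx(i, "N"), idx(i, "CA"))
    add_bond(idx(i, "CA"), idx(i, "C"))
    add_bond(idx(i, "C"), idx(i, "O"))
    add_bond(idx(i, "CA"), idx(i, "HA"))
    if (length(idx(i, "H"))) add_bond(idx(i, "N"), idx(i, "H"))
    if (i < n) add_bond(idx(i, "C"), idx(i + 1L, "N"))
    sc <- .sidechain_atoms[[sequence[i]]]
    if (length(sc)) {
      add_bond(idx(i, "CA"), idx(i, "CB"))
      # chain bonds in template order; ring closures for aromatics
      for (k in seq_along(sc)[-1]) add_bond(idx(i, sc[k - 1]), idx(i, sc[k]))
      if (sequence[i] %in% c("TYR", "PHE")) {
        add_bond(idx(i, "CD1"), idx(i, "CE1"))
        add_bond(idx(i, "CD2"), idx(i, "CE2"))
        add_bond(idx(i, "CE1"), idx(i, "CZ"))
      }
      if (sequence[i] == "PRO") add_bond(idx(i, "CD"), idx(i, "N"))
    }
    if (c_terminal_amide && i == n) add_bond(idx(i, "C"), idx(i, "NT"))
  }
  bonds <- do.call(rbind, bonds)

  if (!is.null(disulfides)) {
    disulfides <- matrix(as.integer(disulfides), ncol = 2)
    for (r in seq_len(nrow(disulfides))) {
      pr <- disulfides[r, ]
      if (any(pr < 1L | pr > n) || any(sequence[pr] != "CYS"))
        stop("disulfide pair must reference two Cys residues")
      bonds <- rbind(bonds, c(idx(pr[1], "SG"), idx(pr[2], "SG")))
    }
  }

  structure(list(
    residues = data.frame(name = sequence, chirality = chirality,
                          stringsAsFactors = FALSE),
    atoms = atoms, bonds = bonds, disulfides = disulfides,
    c_terminal_amide = c_terminal_amide), class = "pep_topology")
}

#' @export
print.pep_topology <- function(x, ...) {
  tag <- ifelse(x$residues$chirality == "D", "d-", "")
  cat("pep_topology:", nrow(x$residues), "residues,", nrow(x$atoms), "atoms\n")
  cat(" ", paste0(tag, x$residues$name, seq_len(nrow(x$residues)),
                  collapse = "-"),
      if (isTRUE(x$c_terminal_amide)) "-NH2", "\n")
  if (!is.null(x$disulfides))
    cat("  disulfide:", paste(apply(x$disulfides, 1, paste, collapse = "-"),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Vasopressin-family topologies
#'
#' Convenience constructor for arginine-vasopressin (CYFQNCPRG-NH2, 1-6
#' disulfide) and its chirality variants: `DAVP` carries d-Arg8, `iAVP` is the
#' all-d inverso peptide, and `iDAVP` is the inverso of DAVP (all-d except
#' l-Arg8).
#'
#' @param variant one of `"AVP"`, `"DAVP"`, `"iAVP"`, `"iDAVP"`.
#' @return a `pep_topology`.
#' @export
avp_topology <- function(variant = c("AVP", "DAVP", "iAVP", "iDAVP")) {
  variant <- match.arg(variant)
  chir <- switch(variant,
    AVP   = rep("L", 9),
    DAVP  = c(rep("L", 7), "D", "L"),
    iAVP  = rep("D", 9),
    iDAVP = c(rep("D", 7), "L", "D"))
  pep_topology("CYFQNCPRG", chirality = chir, disulfides = c(1L, 6L),
               c_terminal_amide = TRUE)
}

#' Select atoms by rule string
#'
#' Selection grammar (1-based residue ranges): `"all"`, `"heavy"`,
#' `"backbone"` (N, CA, C), `"sidechain:i"` (side-chain heavy atoms),
#' `"carbonylO:i"`, `"ring:i"` (the three ring mass-centre carbons CG, CE1,
#' CE2), `"name:CA"`.  A residue range may follow any keyword after a colon,
#' e.g. `"backbone:1-6"` or `"heavy:1-6"`.
#'
#' @param topology a `pep_topology`.
#' @param rule selection string, or an integer vector of atom indices.
#' @return integer atom indices with a `tag` attribute, class `atom_selection`.
#' @export
select_atoms <- function(topology, rule) {
  atoms <- topology$atoms
  if (is.numeric(rule)) {
    idx <- as.integer(rule)
    if (anyDuplicated(idx) || any(idx < 1L | idx > nrow(atoms)))
      stop("atom indices must be unique and in range")
    return(structure(idx, tag = "explicit", class = "atom_selection"))
  }
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  key <- parts[1]
  if (key == "name") {
    if (length(parts) < 2L) stop("'name:' selection needs an atom name")
    idx <- which(atoms$atom_name == parts[2])
  } else {
    resrange <- if (length(parts) > 1L) {
      rr <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      if (anyNA(rr)) stop("malformed residue range in selection '", rule, "'")
      seq(rr[1], rr[length(rr)])
    } else seq_len(max(atoms$residue))
    keep <- atoms$residue %in% resrange
    idx <- switch(key,
      all = which(keep),
      heavy = which(keep & atoms$element != "H"),
      backbone = which(keep & atoms$atom_name %in% c("N", "CA", "C")),
      sidechain = which(keep & atoms$element != "H" &
                          !atoms$atom_name %in% c("N", "CA", "C", "O", "NT")),
      carbonylO = which(keep & atoms$atom_name == "O"),
      ring = which(keep & atoms$atom_name %in% c("CG", "CE1", "CE2")),
      stop("unknown selection keyword: ", key))
  }
  if (!length(idx)) stop("selection '", rule, "' matches no atoms")
  structure(as.integer(idx), tag = rule, class = "atom_selection")
}

.atom_index <- function(topology, residue, name) {
  i <- which(topology$atoms$residue == residue &
               topology$atoms$atom_name == name)
  if (length(i) != 1L) return(NA_integer_)
  i
}
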