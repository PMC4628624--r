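# File formats: multi-model PDB (MODEL/ENDMDL, CRYST1 cubic box), XYZ with a
# box record on the comment line, tabular readers for NMR observables, and
# restraint writers (neutral TSV plus an AMBER-flavoured &rst block).
# PDB cannot express l/d chirality, so ensembles with d-residues carry a
# two-column sidecar (residue_index, L|D).

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens a `pep_ensemble`.
#' @param path output file.
#' @param sidecar optional path for the chirality sidecar; written
#'   automatically (next to `path`, extension `.chir`) when the topology
#'   contains d-residues and `sidecar` is `NULL`.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path, sidecar = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ens$box_edge))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      ens$box_edge, ens$box_edge, ens$box_edge, 90, 90, 90), con)
  atoms <- ens$atoms
  resno <- if (!is.null(atoms$residue)) atoms$residue else rep(1L, nrow(atoms))
  resno[is.na(resno)] <- 0L
  resnm <- rep("UNK", nrow(atoms))
  if (!is.null(ens$topology)) {
    pep <- !is.na(atoms$residue) & atoms$residue > 0
    resnm[pep] <- ens$topology$residues$name[atoms$residue[pep]]
  }
  if (!is.null(atoms$group)) {
    resnm[atoms$group == "water"] <- "HOH"
    resnm[atoms$group == "headgroups"] <- "DHG"
    resnm[atoms$group == "core"] <- "DCR"
  }
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- ens$frames[[f]]
    nm <- atoms$atom_name
    nm4 <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), sprintf("%-4s", nm))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(X)) %% 100000, nm4, substr(resnm, 1, 3), resno %% 10000,
      X[, 1], X[, 2], X[, 3], 1, 0, atoms$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(ens$topology)) {
    chir <- ens$topology$residues$chirality
    if (any(chir == "D")) {
      if (is.null(sidecar)) sidecar <- paste0(sub("\\.pdb$", "", path), ".chir")
      utils::write.table(
        data.frame(residue = seq_along(chir),
                   chirality = ifelse(chir == "D", "D", "L")),
        sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' MODEL/ENDMDL blocks become frames, a CRYST1 record with three equal edges
#' becomes the cubic box.  PDB cannot express l/d chirality, so it is supplied
#' through `chirality` (a vector, or the path of a two-column sidecar file
#' `residue_index  L|D`).  Inconsistent atom counts across models and
#' malformed ATOM records are reported with line numbers.
#'
#' @param path PDB file.
#' @param chirality `NULL` (all-L), a per-residue character vector, or a
#'   sidecar file path.
#' @param topology optional `pep_topology` to attach (checked against the atom
#'   count); when `NULL` a topology is rebuilt from the residue names if they
#'   are all standard.
#' @return a `pep_ensemble`.
#' @export
read_pdb_ensemble <- function(path, chirality = NULL, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  ic <- which(rec == "CRYST1")
  if (length(ic)) {
    abc <- suppressWarnings(as.numeric(c(substr(lines[ic[1]], 7, 15),
                                         substr(lines[ic[1]], 16, 24),
                                         substr(lines[ic[1]], 25, 33))))
    if (anyNA(abc)) stop("malformed CRYST1 record at line ", ic[1])
    if (max(abc) - min(abc) > 1e-3)
      stop("only cubic boxes are supported (CRYST1 line ", ic[1], ")")
    box <- abc[1]
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(rec == "MODEL ")
  frames <- list()
  parse_block <- function(ln_idx) {
    ln <- lines[ln_idx]
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop("malformed ATOM record at line ", ln_idx[bad[1]],
           " (columns 31-54 must hold three coordinates); last good record ",
           "at line ", if (bad[1] > 1) ln_idx[bad[1] - 1] else NA)
    cbind(x, y, z)
  }
  if (!length(model_starts)) {
    if (!any(is_atom)) stop("no ATOM records found in ", path)
    frames[[1]] <- parse_block(which(is_atom))
    meta_idx <- which(is_atom)
  } else {
    ends <- which(rec == "ENDMDL")
    if (length(ends) < length(model_starts))
      stop("truncated file: MODEL at line ",
           model_starts[length(model_starts)], " has no ENDMDL; last ",
           "complete model ends at line ",
           if (length(ends)) ends[length(ends)] else NA)
    for (m in seq_along(model_starts)) {
      sel <- which(is_atom & seq_along(rec) > model_starts[m] &
                     seq_along(rec) < ends[m])
      frames[[m]] <- parse_block(sel)
      if (m == 1L) meta_idx <- sel
    }
    nat <- vapply(frames, nrow, 0L)
    if (length(unique(nat)) != 1L)
      stop("inconsistent atom counts across models: ",
           paste(unique(nat), collapse = ", "))
  }
  first <- lines[meta_idx]
  atom_name <- trimws(substr(first, 13, 16))
  res_name <- trimws(substr(first, 18, 20))
  res_no <- suppressWarnings(as.integer(substr(first, 23, 26)))
  element <- trimws(substr(first, 77, 78))
  element[element == ""] <- vapply(atom_name[element == ""], .atom_element, "")
  atoms <- data.frame(residue = res_no, atom_name = atom_name,
                      element = element,
                      mass = .element_masses[element],
                      stringsAsFactors = FALSE)
  atoms$group <- ifelse(res_name == "HOH", "water",
                        ifelse(res_name == "DHG", "headgroups",
                               ifelse(res_name == "DCR", "core", "peptide")))
  if (is.null(topology)) {
    pep <- atoms$group == "peptide" & !is.na(res_no) & res_no > 0
    if (any(pep)) {
      resseq <- tapply(res_name[pep], res_no[pep], `[`, 1)
      resseq <- resseq[order(as.integer(names(resseq)))]
      if (all(resseq %in% names(.sidechain_atoms))) {
        chir <- NULL
        if (!is.null(chirality)) {
          chir <- if (length(chirality) == 1L && file.exists(chirality)) {
            sc <- utils::read.table(chirality, header = TRUE,
                                    stringsAsFactors = FALSE)
            sc$chirality[order(sc$residue)]
          } else chirality
        }
        topology <- try(pep_topology(unname(resseq), chirality = chir,
                                     c_terminal_amide = "NT" %in% atom_name),
                        silent = TRUE)
        if (inherits(topology, "try-error") ||
            nrow(topology$atoms) != sum(pep)) topology <- NULL
      }
    }
  }
  ens <- pep_ensemble(topology = topology, frames = frames, box_edge = box,
                      atoms = atoms)
  ens$meta$peptide_offset <- 0L
  ens
}

#' Write an ensemble in XYZ format (box on the comment line)
#'
#' @param ens a `pep_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- ens$atoms$element
  for (f in seq_len(n_frames(ens))) {
    X <- ens$frames[[f]]
    writeLines(as.character(nrow(X)), con)
    writeLines(if (!is.null(ens$box_edge))
      sprintf("frame %d box= %.6f", f, ens$box_edge)
      else sprintf("frame %d", f), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el, X[, 1], X[, 2],
                       X[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_xyz_ensemble()]
#'
#' @param path XYZ file.
#' @return list with `frames` (coordinate matrices), `elements`, `box_edge`.
#' @export
read_xyz_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); elements <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed atom count at line ", i)
    cm <- lines[i + 1L]
    bm <- regmatches(cm, regexpr("box= *[0-9.eE+-]+", cm))
    if (length(bm)) box <- as.numeric(sub("box= *", "", bm))
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed coordinate block starting at line ", i + 2L)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  list(frames = frames, elements = elements, box_edge = box)
}

#' Expected frame count from simulation bookkeeping
#'
#' How many saved frames the analysis window contains:
#' floor(analyze_last_ns x 10^6 / (dt_fs x save_every)).
#'
#' @param total_ns total simulated time, ns.
#' @param dt_fs integration time step, fs.
#' @param save_every coordinates saved every this many steps.
#' @param analyze_last_ns analysed trailing window, ns.
#' @return integer frame count.
#' @export
frame_bookkeeping <- function(total_ns, dt_fs, save_every, analyze_last_ns) {
  if (dt_fs <= 0 || save_every <= 0) stop("time step and save interval must be positive")
  if (total_ns <= 0) stop("total simulated time must be positive")
  if (analyze_last_ns < 0) stop("analysis window must be non-negative")
  if (analyze_last_ns > total_ns)
    stop("analysis window exceeds the simulated time")
  as.integer(floor(analyze_last_ns * 1e6 / (dt_fs * save_every)))
}

# ---- tabular readers -------------------------------------------------------

.read_table <- function(path, required) {
  x <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                         stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(basename(path), " lacks column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read a coupling-constant table (residue, J, chirality)
#' @param path whitespace- or tab-separated file with a header.
#' @return data.frame with columns `residue`, `J`, `chirality` (and any
#'   extras, e.g. `residue_name`).
#' @export
read_couplings <- function(path) .read_table(path, c("residue", "J", "chirality"))

#' Read a NOE peak list (atom1, atom2, volume)
#' @param path whitespace- or tab-separated file with a header.
#' @return data.frame; an optional `type` column flags methyl/aromatic pairs.
#' @export
read_peaks <- function(path) .read_table(path, c("atom1", "atom2", "volume"))

#' Read a chemical-shift table (residue, atom, ppm)
#' @param path whitespace- or tab-separated file with a header.
#' @return data.frame.
#' @export
read_shift_table <- function(path) .read_table(path, c("residue", "atom", "ppm"))

#' Read an amide-proton temperature series (residue, temperature_C, shift_ppm)
#' @param path whitespace- or tab-separated file with a header.
#' @return data.frame.
#' @export
read_temp_series <- function(path)
  .read_table(path, c("residue", "temperature_C", "shift_ppm"))

# ---- restraint writers -----------------------------------------------------

#' Write a restraint set as neutral TSV tables
#'
#' The format of record: one TSV with columns `type` (distance|dihedral),
#' `atoms` (comma-joined identifiers), `lo`, `hi`, `force_constant`, `label`.
#' Distance restraints use lo = 1.8 (van der Waals floor) and hi = the
#' calibrated upper bound.
#'
#' @param rs a `restraint_set` from [build_restraint_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_restraints_tsv <- function(rs, path) {
  rows <- list()
  if (!is.null(rs$distance) && nrow(rs$distance))
    rows[[1]] <- data.frame(
      type = "distance",
      atoms = paste(rs$distance$atom1, rs$distance$atom2, sep = ","),
      lo = 1.8, hi = rs$distance$upper,
      force_constant = rs$distance$force_constant,
      label = "", stringsAsFactors = FALSE)
  if (!is.null(rs$dihedral) && nrow(rs$dihedral))
    rows[[2]] <- data.frame(
      type = "dihedral",
      atoms = paste(rs$dihedral$angle, rs$dihedral$residue, sep = ","),
      lo = rs$dihedral$lo, hi = rs$dihedral$hi,
      force_constant = rs$dihedral$force_constant,
      label = rs$dihedral$label, stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a restraint set as AMBER-flavoured &rst blocks
#'
#' Distance restraints become flat-bottomed wells (r1 = lo - 0.5, r2 = lo,
#' r3 = hi, r4 = hi + 0.5) with rk2 = rk3 = the force constant; dihedral
#' restraints carry their interval in r2/r3.  Atom identifiers are written
#' as-is in an `iat` comment-compatible form.
#'
#' @param rs a `restraint_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_restraints_amber <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(rs$distance)) for (k in seq_len(nrow(rs$distance))) {
    d <- rs$distance[k, ]
    writeLines(sprintf(
      " &rst iat=%s,%s, r1=%.2f, r2=%.2f, r3=%.2f, r4=%.2f, rk2=%.1f, rk3=%.1f, &end",
      d$atom1, d$atom2, 1.3, 1.8, d$upper, d$upper + 0.5,
      d$force_constant, d$force_constant), con)
  }
  if (!is.null(rs$dihedral)) for (k in seq_len(nrow(rs$dihedral))) {
    d <- rs$dihedral[k, ]
    writeLines(sprintf(
      " &rst iat=%s:%s, r1=%.1f, r2=%.1f, r3=%.1f, r4=%.1f, rk2=%.1f, rk3=%.1f, &end",
      d$angle, d$residue, d$lo - 10, d$lo, d$hi, d$hi + 10,
      d$force_constant, d$force_constant), con)
  }
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

.config_defaults <- function() list(
  input = "", selection = "backbone", tol_main = 30, tol_one = 45,
  dmax = 7.0, hbond_dmax = 3.5, hbond_angle = 120, hydration_radius = 3.8,
  dr = 0.1, r_max = 12, seed = 1, outdir = ".")

#' Read a plain-text run configuration (`key = value` lines)
#'
#' Unknown keys are rejected; missing keys take documented defaults.  Numeric
#' values are converted; `#` starts a comment.
#'
#' @param path config file.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  defaults <- .config_defaults()
  out <- defaults
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE) ||
        length(strsplit(ln, "=", fixed = TRUE)[[1]]) > 2L)
      stop("malformed config line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) stop("unknown config key: '", key, "'")
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) && is.numeric(defaults[[key]])) num else val
  }
  for (k in c("tol_main", "tol_one", "dmax", "hbond_dmax", "hbond_angle",
              "hydration_radius", "dr", "r_max"))
    if (out[[k]] <= 0) stop("config threshold '", k, "' must be positive")
  out
}

#' Write a run configuration
#' @param config named list (see [read_run_config()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}
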