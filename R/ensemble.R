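# Conformations and ensembles.  An ensemble is an ordered set of frames over
# one topology (or one generic atom table for mixed peptide/detergent/water
# scenes), with an optional cubic periodic box.

#' Construct a single conformation
#'
#' @param xyz numeric matrix, one row per atom (Angstrom).
#' @param box_edge optional cubic box edge length, Angstrom.
#' @return object of class `conformation`.
#' @export
conformation <- function(xyz, box_edge = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("coordinates must be an n x 3 matrix")
  if (!is.null(box_edge) && box_edge <= 0) stop("box_edge must be positive")
  structure(list(xyz = xyz, box_edge = box_edge), class = "conformation")
}

#' Construct a conformational ensemble
#'
#' @param topology a `pep_topology`, or `NULL` for generic scenes built with
#'   [make_box()] (which supply their own atom table).
#' @param frames list of coordinate matrices (or `conformation` objects), all
#'   with the same atom count.
#' @param box_edge optional cubic box edge, Angstrom, shared by all frames.
#' @param times optional frame times (ps), strictly increasing.
#' @param atoms atom table (data.frame with at least `atom_name`, `element`,
#'   `mass`, optionally `group`); derived from `topology` when omitted.
#' @return object of class `pep_ensemble` with elements `topology`, `atoms`,
#'   `frames` (list of matrices), `box_edge`, `times`, `meta`.
#' @export
pep_ensemble <- function(topology = NULL, frames, box_edge = NULL,
                         times = NULL, atoms = NULL) {
  frames <- lapply(frames, function(f) {
    if (inherits(f, "conformation")) f$xyz else as.matrix(f)
  })
  if (!length(frames)) stop("an ensemble needs at least one frame")
  nat <- vapply(frames, nrow, 0L)
  if (length(unique(nat)) != 1L)
    stop("all frames must share the same atom count")
  if (is.null(atoms)) {
    if (is.null(topology)) stop("either topology or an atom table is required")
    atoms <- topology$atoms
  }
  if (nrow(atoms) != nat[1])
    stop("frame atom count (", nat[1], ") does not match the atom table (",
         nrow(atoms), ")")
  if (!is.null(times)) {
    if (length(times) != length(frames) || any(diff(times) <= 0))
      stop("frame times must match the frame count and increase strictly")
  }
  if (!is.null(box_edge) && box_edge <= 0) stop("box_edge must be positive")
  structure(list(topology = topology, atoms = atoms, frames = frames,
                 box_edge = box_edge, times = times, meta = list()),
            class = "pep_ensemble")
}

#' @export
print.pep_ensemble <- function(x, ...) {
  cat("pep_ensemble:", length(x$frames), "frame(s),", nrow(x$atoms),
      "atoms", if (!is.null(x$box_edge))
        sprintf("| cubic box %.2f A", x$box_edge), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `pep_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Radius of gyration of a selection
#'
#' Rg = sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i)) with rbar the (mass-weighted)
#' centre of the selection.
#'
#' @param frame coordinate matrix or `conformation`.
#' @param sel atom indices (e.g. from [select_atoms()]).
#' @param masses per-atom masses for the full frame; equal masses when `NULL`
#'   or `mass_weighted = FALSE`.
#' @param mass_weighted logical, default `TRUE`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, sel = NULL, masses = NULL,
                               mass_weighted = TRUE) {
  xyz <- if (inherits(frame, "conformation")) frame$xyz else as.matrix(frame)
  if (is.null(sel)) sel <- seq_len(nrow(xyz))
  if (!length(sel)) stop("empty selection")
  X <- xyz[sel, , drop = FALSE]
  w <- if (mass_weighted && !is.null(masses)) masses[sel] else rep(1, length(sel))
  ctr <- colSums(X * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)) / sum(w))
}

#' Ensemble-average radius of gyration
#'
#' @param ens a `pep_ensemble`.
#' @param sel selection rule string or atom indices (default all atoms).
#' @param mass_weighted logical.
#' @return mean Rg over frames, Angstrom.
#' @export
ensemble_rg <- function(ens, sel = "heavy", mass_weighted = TRUE) {
  idx <- if (is.character(sel)) select_atoms(ens$topology, sel) else sel
  mean(vapply(ens$frames, radius_of_gyration, 0, sel = idx,
              masses = ens$atoms$mass, mass_weighted = mass_weighted))
}

#' Ensemble RMSD statistic
#'
#' Spread of an ensemble about its mean structure: every frame is
#' least-squares superposed on the running mean structure over the selection,
#' and the reported statistic is the mean RMSD of the superposed frames to
#' that mean.  The alternative `"pairwise"` convention averages the fitted
#' RMSD over all frame pairs.
#'
#' @param ens a `pep_ensemble` with at least 2 frames.
#' @param sel selection rule string or atom indices.
#' @param method `"mean_structure"` (default) or `"pairwise"`.
#' @return RMSD in Angstrom.
#' @export
ensemble_rmsd <- function(ens, sel = "backbone",
                          method = c("mean_structure", "pairwise")) {
  method <- match.arg(method)
  if (n_frames(ens) < 2L) stop("ensemble RMSD needs at least 2 frames")
  idx <- if (is.character(sel)) select_atoms(ens$topology, sel) else sel
  frames <- ens$frames
  if (method == "pairwise") {
    nf <- length(frames)
    tot <- 0; np <- 0L
    for (i in seq_len(nf - 1L)) for (j in seq(i + 1L, nf)) {
      tot <- tot + superpose(frames[[j]], frames[[i]], idx)$rmsd
      np <- np + 1L
    }
    return(tot / np)
  }
  # two rounds: fit to frame 1, average, re-fit to the mean, re-average
  ref <- frames[[1]]
  for (round in 1:2) {
    fitted <- lapply(frames, function(f) superpose(f, ref, idx)$xyz)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  mean(vapply(frames, function(f) superpose(f, ref, idx)$rmsd, 0))
}
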