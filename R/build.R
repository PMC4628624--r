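# Geometry-only synthetic structure generation: ideal peptides with planted
# backbone torsions, jittered ensembles, and toy micelle/water boxes with
# exactly known ground truth.  No force field and no sterics -- the point is
# analytic ground truth for validating the analysis stages, not physics.

.bb_geom <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.8)

# Tetrahedral branch directions at CA: bisector of the two backbone bonds
# opened by +/- beta; the sign of the out-of-plane component fixes chirality.
.ca_branch <- function(X, iN, iCA, iC, sign_out, bond, beta = 54.75) {
  uN <- .unit3(X[iN, ] - X[iCA, ])
  uC <- .unit3(X[iC, ] - X[iCA, ])
  w1 <- .unit3(-(uN + uC))
  w2 <- .unit3(.cross3(uN, uC))
  b <- beta * pi / 180
  X[iCA, ] + bond * (w1 * cos(b) + sign_out * w2 * sin(b))
}

#' Build an ideal-geometry peptide conformation with planted torsions
#'
#' Constructs backbone coordinates from fixed internal coordinates (N-CA
#' 1.458, CA-C' 1.525, C'-N 1.329 A, standard valence angles) so that
#' [backbone_angles()] round-trips the requested phi/psi/omega essentially
#' exactly.  d-residues receive the inverted Cbeta placement (the all-d build
#' of a sign-negated angle set is the exact mirror image of the l build);
#' aromatic rings are placed as ideal hexagons whose C1/C3/C5 centroid is the
#' hexagon centre.  No steric checking is performed: an impossible torsion
#' request is built literally.
#'
#' @param topology a `pep_topology`.
#' @param phi,psi per-residue torsions, degrees (`phi[1]` is ignored; `psi` of
#'   the last residue orients the terminal carbonyl/amide).
#' @param omega per-residue peptide-bond torsion preceding each residue,
#'   degrees; default all trans (180).
#' @return a `conformation` whose rows follow `topology$atoms`.
#' @export
build_peptide <- function(topology, phi, psi, omega = NULL) {
  n <- nrow(topology$residues)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- if (is.null(omega)) rep(180, n) else rep_len(omega, n)
  atoms <- topology$atoms
  X <- matrix(NA_real_, nrow(atoms), 3)
  idx <- function(i, nm) .atom_index(topology, i, nm)
  g <- .bb_geom

  # backbone chain
  X[idx(1, "N"), ] <- c(0, 0, 0)
  X[idx(1, "CA"), ] <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  X[idx(1, "C"), ] <- X[idx(1, "CA"), ] + g$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    iN <- idx(i, "N"); iCA <- idx(i, "CA"); iC <- idx(i, "C")
    jN <- idx(i + 1, "N"); jCA <- idx(i + 1, "CA"); jC <- idx(i + 1, "C")
    X[jN, ] <- .place_atom(X[iN, ], X[iCA, ], X[iC, ], g$c_n, g$ang_ca_c_n,
                           psi[i])
    X[jCA, ] <- .place_atom(X[iCA, ], X[iC, ], X[jN, ], g$n_ca, g$ang_c_n_ca,
                            omega[i + 1])
    X[jC, ] <- .place_atom(X[iC, ], X[jN, ], X[jCA, ], g$ca_c, g$ang_n_ca_c,
                           phi[i + 1])
  }
  # carbonyl O (anti to the following N) and the C-terminal amide N
  if (isTRUE(topology$c_terminal_amide)) {
    X[idx(n, "NT"), ] <- .place_atom(X[idx(n, "N"), ], X[idx(n, "CA"), ],
                                     X[idx(n, "C"), ], g$c_n, g$ang_ca_c_n,
                                     psi[n])
  }
  for (i in seq_len(n)) {
    X[idx(i, "O"), ] <- .place_atom(X[idx(i, "N"), ], X[idx(i, "CA"), ],
                                    X[idx(i, "C"), ], g$c_o, g$ang_ca_c_o,
                                    wrap_angle(psi[i] + 180))
  }
  # amide hydrogens (bisector convention) and HA
  for (i in seq_len(n)) {
    ih <- idx(i, "H")
    if (length(ih) && !is.na(ih) && i > 1)
      X[ih, ] <- .rebuild_amide_h(X, idx(i, "N"), idx(i - 1, "C"), idx(i, "CA"))
    # side chain
    res <- topology$residues$name[i]
    chir <- topology$residues$chirality[i]
    iN <- idx(i, "N"); iCA <- idx(i, "CA"); iC <- idx(i, "C")
    if (res == "GLY") {
      uN <- .unit3(X[iN, ] - X[iCA, ]); uC <- .unit3(X[iC, ] - X[iCA, ])
      X[idx(i, "HA"), ] <- X[iCA, ] + 1.09 * .unit3(-(uN + uC))
      next
    }
    # fix the CB out-of-plane sign so that the improper dihedral
    # CA-N-C-CB is positive for L and negative for D
    s <- +1
    cb_try <- .ca_branch(X, iN, iCA, iC, s, 1.53)
    imp <- dihedral_angle(X[iCA, ], X[iN, ], X[iC, ], cb_try)
    want <- if (chir == "D") -1 else 1
    if (sign(imp) != want) { s <- -1; cb_try <- .ca_branch(X, iN, iCA, iC, s, 1.53) }
    iCB <- idx(i, "CB")
    X[iCB, ] <- cb_try
    X[idx(i, "HA"), ] <- .ca_branch(X, iN, iCA, iC, -s, 1.09)
    cs <- if (chir == "D") -1 else 1
    X <- .build_sidechain(X, topology, i, cs)
  }
  conformation(X)
}

# Place side-chain atoms beyond CB.  Chain torsions are all-anti (mirror
# invariant) except the proline ring curl, which is scaled by the chirality
# sign so that d-residues build as exact mirror images.
.build_sidechain <- function(X, top, i, cs) {
  res <- top$residues$name[i]
  idx <- function(nm) .atom_index(top, i, nm)
  iN <- idx("N"); iCA <- idx("CA"); iCB <- idx("CB")
  chain_place <- function(a, b, c, nm, bond = 1.52, angle = 113,
                          torsion = 180)
    X[idx(nm), ] <<- .place_atom(X[a, ], X[b, ], X[c, ], bond, angle, torsion)
  switch(res,
    CYS = chain_place(iN, iCA, iCB, "SG", bond = 1.81, angle = 114),
    PRO = {
      chain_place(iN, iCA, iCB, "CG", torsion = 30 * cs)
      chain_place(iCA, iCB, idx("CG"), "CD", torsion = -35 * cs)
    },
    GLN = {
      chain_place(iN, iCA, iCB, "CG")
      chain_place(iCA, iCB, idx("CG"), "CD")
      chain_place(iCB, idx("CG"), idx("CD"), "OE1", bond = 1.23, angle = 121,
                  torsion = 0)
      chain_place(iCB, idx("CG"), idx("CD"), "NE2", bond = 1.33, angle = 117,
                  torsion = 180)
    },
    ASN = {
      chain_place(iN, iCA, iCB, "CG")
      chain_place(iCA, iCB, idx("CG"), "OD1", bond = 1.23, angle = 121,
                  torsion = 0)
      chain_place(iCA, iCB, idx("CG"), "ND2", bond = 1.33, angle = 117,
                  torsion = 180)
    },
    ARG = {
      chain_place(iN, iCA, iCB, "CG")
      chain_place(iCA, iCB, idx("CG"), "CD")
      chain_place(iCB, idx("CG"), idx("CD"), "NE", bond = 1.46, angle = 112)
      chain_place(idx("CG"), idx("CD"), idx("NE"), "CZ", bond = 1.33,
                  angle = 124)
      chain_place(idx("CD"), idx("NE"), idx("CZ"), "NH1", bond = 1.33,
                  angle = 120, torsion = 0)
      chain_place(idx("CD"), idx("NE"), idx("CZ"), "NH2", bond = 1.33,
                  angle = 120, torsion = 180)
    },
    TYR = ,
    PHE = {
      chain_place(iN, iCA, iCB, "CG", bond = 1.51, angle = 114)
      iCG <- idx("CG")
      e1 <- .unit3(X[iCG, ] - X[iCB, ])
      p <- X[iCB, ] - X[iCA, ]
      e2 <- .unit3(p - sum(p * e1) * e1)
      ctr <- X[iCG, ] + 1.39 * e1
      verts <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (k in seq_along(verts)) {
        thk <- (k - 1) * 60 * pi / 180
        X[idx(verts[k]), ] <- ctr + 1.39 * (-cos(thk) * e1 + sin(thk) * e2)
      }
      if (res == "TYR")
        X[idx("OH"), ] <- X[idx("CZ"), ] + 1.36 * .unit3(X[idx("CZ"), ] - ctr)
    },
    GLY = NULL)
  X
}

#' Jittered copies of a conformation as an ensemble
#'
#' Adds iid Gaussian noise (per coordinate) to every atom of every frame --
#' the standard synthetic ensemble for testing spread statistics, whose mean
#' RMSD about the mean structure is known in closed form.
#'
#' @param conf a `conformation` or coordinate matrix.
#' @param topology the matching `pep_topology`.
#' @param n_frames number of frames.
#' @param sd Gaussian sigma per coordinate, Angstrom (0 = identical copies).
#' @param seed RNG seed.
#' @return a `pep_ensemble`.
#' @export
jitter_ensemble <- function(conf, topology, n_frames = 50, sd = 0.1,
                            seed = 1) {
  X <- if (inherits(conf, "conformation")) conf$xyz else as.matrix(conf)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f)
    X + matrix(stats::rnorm(length(X), sd = sd), nrow(X), 3))
  pep_ensemble(topology, frames)
}

#' Generate a toy peptide/micelle/water periodic box
#'
#' Emulates the mixed anionic-zwitterionic micelle system used for
#' membrane-mimetic NMR work: head-group sites on a spherical shell (one
#' sulfur site per SDS, phosphorus + choline nitrogen per DPC), core sites
#' (terminal methyl plus last three tail carbons per detergent) uniform inside
#' the shell, and water oxygens uniform in the remaining box volume.  Geometry
#' only -- placements are random, not packed, so every density is exactly
#' known.  With `micelle = NULL` the box is a pure uniform gas of water
#' oxygens, the analytic reference for RDF normalisation.
#'
#' @param edge cubic box edge, Angstrom (default 85, the simulation-box scale
#'   for this peptide/micelle system).
#' @param water_density water number density in the water-accessible volume,
#'   A^-3.  The default 0.02325 puts about 13,500 waters in the default box.
#' @param micelle list(`shell_radius`, `n_sds`, `n_dpc`, `tail_sites`) or
#'   `NULL`; defaults 20 A, 10 SDS, 50 DPC, 3 tail carbons (plus the terminal
#'   methyl) per detergent.
#' @param peptide optional list(`topology`, `conformation`, `placement`) with
#'   placement `"surface"`, `"buried"` or `"bulk"`.
#' @param n_frames frames to generate; water is resampled each frame, peptide
#'   and micelle sites are jittered by `jitter_sd`.
#' @param jitter_sd Gaussian jitter for non-water sites across frames, A.
#' @param seed RNG seed (required for reproducibility).
#' @return a `pep_ensemble` with groups `peptide`, `headgroups`, `core`,
#'   `water`; `meta$micelle` records the planted geometry, `meta$counts` the
#'   composition.
#' @export
make_box <- function(edge = 85, water_density = 0.02325,
                     micelle = list(shell_radius = 20, n_sds = 10,
                                    n_dpc = 50, tail_sites = 3),
                     peptide = NULL, n_frames = 1, jitter_sd = 0,
                     seed = 1) {
  stopifnot(edge > 0, water_density >= 0)
  set.seed(seed)
  center <- rep(edge / 2, 3)
  if (!is.null(micelle) && micelle$shell_radius >= edge / 2)
    stop("micelle shell radius must be below half the box edge")

  unit_sphere <- function(n) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  atoms <- list(); base <- list()
  add <- function(nm, el, grp, xyz, residue = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      residue = residue, atom_name = nm, element = el,
      mass = .element_masses[el], group = grp, stringsAsFactors = FALSE)
    base[[length(base) + 1L]] <<- xyz
  }

  top <- NULL
  if (!is.null(peptide)) {
    top <- peptide$topology
    Xp <- if (inherits(peptide$conformation, "conformation"))
      peptide$conformation$xyz else as.matrix(peptide$conformation)
    placement <- if (is.null(peptide$placement)) "surface" else peptide$placement
    target <- switch(placement,
      buried = center,
      surface = center + c(if (is.null(micelle)) 0 else micelle$shell_radius,
                           0, 0),
      bulk = center + rep(0.45 * edge / sqrt(3), 3),
      stop("unknown peptide placement: ", placement))
    Xp <- sweep(Xp, 2, colMeans(Xp)) + rep(target, each = nrow(Xp))
    for (k in seq_len(nrow(Xp)))
      add(top$atoms$atom_name[k], top$atoms$element[k], "peptide",
          Xp[k, ], top$atoms$residue[k])
  }

  mic_sphere_r <- 0
  if (!is.null(micelle)) {
    rs <- micelle$shell_radius
    mic_sphere_r <- rs
    heads <- unit_sphere(micelle$n_sds + micelle$n_dpc) * rs
    for (k in seq_len(micelle$n_sds))
      add("S", "S", "headgroups", center + heads[k, ])
    if (micelle$n_dpc > 0) for (k in seq_len(micelle$n_dpc)) {
      u <- heads[micelle$n_sds + k, ]
      add("P", "P", "headgroups", center + u)
      add("N", "N", "headgroups", center + u * (rs + 3) / rs)
    }
    n_core <- (micelle$tail_sites + 1L) * (micelle$n_sds + micelle$n_dpc)
    rr <- rs * 0.85 * stats::runif(n_core)^(1 / 3)
    core <- unit_sphere(n_core) * rr
    for (k in seq_len(n_core)) add("C", "C", "core", center + core[k, ])
  }

  v_free <- edge^3 - 4 / 3 * pi * mic_sphere_r^3
  n_water <- if (water_density > 0) stats::rpois(1, water_density * v_free) else 0L
  sample_water <- function(n) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      cand <- matrix(stats::runif(3 * 2 * n, 0, edge), ncol = 3)
      if (mic_sphere_r > 0) {
        d2 <- rowSums(sweep(cand, 2, center)^2)
        cand <- cand[d2 > mic_sphere_r^2, , drop = FALSE]
      }
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  }
  W0 <- sample_water(n_water)
  for (k in seq_len(n_water)) add("O", "O", "water", W0[k, ])

  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  Xbase <- do.call(rbind, base)
  is_water <- atoms$group == "water"
  frames <- lapply(seq_len(n_frames), function(f) {
    X <- Xbase
    if (f > 1L && n_water > 0) X[is_water, ] <- sample_water(n_water)
    if (jitter_sd > 0 && any(!is_water))
      X[!is_water, ] <- X[!is_water, ] +
        matrix(stats::rnorm(3 * sum(!is_water), sd = jitter_sd),
               sum(!is_water), 3)
    X
  })
  ens <- pep_ensemble(topology = top, frames = frames, box_edge = edge,
                      atoms = atoms)
  ens$meta$peptide_offset <- 0L
  ens$meta$micelle <- if (is.null(micelle)) NULL else
    list(center = center, shell_radius = micelle$shell_radius)
  ens$meta$counts <- c(SDS = if (is.null(micelle)) 0L else micelle$n_sds,
                       DPC = if (is.null(micelle)) 0L else micelle$n_dpc,
                       peptide = as.integer(!is.null(peptide)),
                       water = n_water)
  ens
}

#' Box composition report: counts, molarities and mole ratios
#'
#' Converts particle counts in a cubic box into molar concentrations
#' (count / (N_A V)) and reports the detergent mole ratios the field quotes:
#' DPC:SDS and total detergent:peptide.  Explicit sample concentrations (mM)
#' may be supplied instead of, or in addition to, counts.
#'
#' @param counts named vector with entries `SDS`, `DPC`, `peptide`.
#' @param box_edge cubic box edge, Angstrom (required with `counts`).
#' @param concentrations optional named vector of mM concentrations (`SDS`,
#'   `DPC`, `peptide`) taking precedence for the ratio computations.
#' @param digits rounding for the reported ratios (default 1).
#' @return list: `mM` (from counts), `dpc_to_sds`, `detergent_to_peptide`.
#' @export
composition_report <- function(counts = NULL, box_edge = NULL,
                               concentrations = NULL, digits = 1) {
  NA_avogadro <- 6.02214076e23
  mM <- NULL
  if (!is.null(counts)) {
    if (is.null(box_edge) || box_edge <= 0)
      stop("counts need a positive box_edge")
    v_l <- box_edge^3 * 1e-27
    mM <- counts / (NA_avogadro * v_l) * 1000
  }
  src <- if (!is.null(concentrations)) concentrations else mM
  if (is.null(src)) stop("provide counts or concentrations")
  ratio <- function(num, den) {
    if (!all(c(num, den) %in% names(src)) || src[den] == 0) return(NA_real_)
    round(unname(sum(src[num]) / src[den]), digits)
  }
  list(mM = mM,
       dpc_to_sds = ratio("DPC", "SDS"),
       detergent_to_peptide = ratio(c("SDS", "DPC"), "peptide"))
}

#' Synthesise NMR observables from an ensemble with known ground truth
#'
#' Closes the validation loop for the restraint stage: couplings follow a
#' Karplus curve on the ensemble-mean phi (chirality-aware, coefficients for
#' 3J(HN-HA)), NOE volumes are proportional to the ensemble average of
#' r^-6 over chosen proton pairs, and amide-proton temperature series are
#' linear with chosen slopes.  The exact generating parameters are returned
#' alongside so recovery can be asserted.
#'
#' @param ens a `pep_ensemble` with a peptide topology.
#' @param karplus Karplus coefficients (A, B, C) in J = A cos^2(theta) +
#'   B cos(theta) + C with theta = phi - 60 for l-residues (mirrored for d);
#'   default c(6.51, -1.76, 1.60).  Used for synthesis only -- restraint
#'   inversion uses the interval rules, not this curve.
#' @param j_noise_sd Gaussian noise on J, Hz.
#' @param noe_pairs data.frame with `atom1`, `atom2` (labels `"res:ATOM"`), or
#'   `NULL` for the default backbone HN/HA pair set.
#' @param noe_scale volume of a 1 A pair (arbitrary units).
#' @param temp_slopes per-residue amide temperature coefficients, ppb/K
#'   (named by residue index); default -4.5 for all amide-bearing residues.
#' @param temperatures series temperatures, Celsius.
#' @param temp_noise_sd Gaussian noise on the series shifts, ppm.
#' @param seed RNG seed for the noise.
#' @return list: `couplings`, `peaks`, `temp_series` (data.frames) and
#'   `truth` (phi means, NOE distances, slopes).
#' @export
synth_observables <- function(ens, karplus = c(6.51, -1.76, 1.60),
                              j_noise_sd = 0, noe_pairs = NULL,
                              noe_scale = 1e6, temp_slopes = NULL,
                              temperatures = c(5, 10, 20, 32, 40, 50),
                              temp_noise_sd = 0, seed = 1) {
  set.seed(seed)
  top <- ens$topology
  n <- nrow(top$residues)
  ang <- backbone_angles(ens)
  circ_mean <- function(x) {
    x <- x[is.finite(x)] * pi / 180
    wrap_angle(atan2(mean(sin(x)), mean(cos(x))) * 180 / pi)
  }
  phi_mean <- vapply(seq_len(n), function(i) circ_mean(ang$phi[, i]), 0)

  has_hn <- !is.na(vapply(seq_len(n), .atom_index, 0L, topology = top,
                          name = "H"))
  jres <- which(has_hn)
  chir <- ifelse(top$residues$chirality == "D", "D", "L")
  theta <- ifelse(chir[jres] == "D", phi_mean[jres] + 60, phi_mean[jres] - 60)
  ct <- cos(theta * pi / 180)
  J <- karplus[1] * ct^2 + karplus[2] * ct + karplus[3]
  J <- pmax(0, J + stats::rnorm(length(J), sd = j_noise_sd))
  couplings <- data.frame(residue = jres,
                          residue_name = top$residues$name[jres],
                          J = J, chirality = chir[jres],
                          stringsAsFactors = FALSE)

  if (is.null(noe_pairs)) {
    lab <- function(i, a) sprintf("%d:%s", i, a)
    prs <- list()
    for (i in seq_len(n)) {
      if (has_hn[i]) prs[[length(prs) + 1L]] <- c(lab(i, "H"), lab(i, "HA"))
      if (i < n && has_hn[i + 1])
        prs[[length(prs) + 1L]] <- c(lab(i, "HA"), lab(i + 1, "H"))
      if (i < n && has_hn[i] && has_hn[i + 1])
        prs[[length(prs) + 1L]] <- c(lab(i, "H"), lab(i + 1, "H"))
    }
    noe_pairs <- as.data.frame(do.call(rbind, prs), stringsAsFactors = FALSE)
    names(noe_pairs) <- c("atom1", "atom2")
  }
  lab_index <- function(lab) {
    p <- strsplit(lab, ":", fixed = TRUE)[[1]]
    .atom_index(top, as.integer(p[1]), p[2])
  }
  i1 <- vapply(noe_pairs$atom1, lab_index, 0L)
  i2 <- vapply(noe_pairs$atom2, lab_index, 0L)
  r6 <- vapply(seq_along(i1), function(k)
    mean(vapply(ens$frames, function(X)
      .norm3(X[i1[k], ] - X[i2[k], ])^(-6), 0)), 0)
  peaks <- data.frame(atom1 = noe_pairs$atom1, atom2 = noe_pairs$atom2,
                      volume = noe_scale * r6, type = "",
                      stringsAsFactors = FALSE)
  noe_truth <- data.frame(atom1 = peaks$atom1, atom2 = peaks$atom2,
                          distance = r6^(-1 / 6), stringsAsFactors = FALSE)

  if (is.null(temp_slopes)) {
    temp_slopes <- stats::setNames(rep(-4.5, length(jres)), jres)
  }
  ts <- do.call(rbind, lapply(names(temp_slopes), function(rs) {
    sl <- temp_slopes[[rs]]
    shifts <- 8.5 + sl * 1e-3 * (temperatures - 32) +
      stats::rnorm(length(temperatures), sd = temp_noise_sd)
    data.frame(residue = as.integer(rs), temperature_C = temperatures,
               shift_ppm = shifts)
  }))
  list(couplings = couplings, peaks = peaks, temp_series = ts,
       truth = list(phi_mean = phi_mean, noe = noe_truth,
                    slopes = temp_slopes, karplus = karplus))
}
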