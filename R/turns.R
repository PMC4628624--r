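# Backbone torsions and beta-turn detection/typing.  Primed Lewis types are
# the sign-negated (mirror) partners of the unprimed ones and are the turns
# favoured by d-residues at position i+1 (II') or i+2 (II).

#' Canonical beta-turn templates
#'
#' Ideal (phi, psi) of residues i+1 and i+2 for the Lewis turn types.  Primed
#' templates are the sign-negated unprimed ones.  Type VII (the "kink") has no
#' 4-angle template and is handled separately; type IV is the fallback class
#' for chain reversals matching no template.
#'
#' @return data.frame with columns `type`, `phi1`, `psi1`, `phi2`, `psi2`,
#'   `primed_partner`.
#' @export
turn_templates <- function() {
  data.frame(
    type  = c("I", "I'", "II", "II'", "III", "III'", "VIII", "VIII'"),
    phi1  = c(-60, 60, -60, 60, -60, 60, -60, 60),
    psi1  = c(-30, 30, 120, -120, -30, 30, -30, 30),
    phi2  = c(-90, 90, 80, -80, -60, 60, -120, 120),
    psi2  = c(0, 0, 0, 0, -30, 30, 120, -120),
    primed_partner = c("I'", "I", "II'", "II", "III'", "III", "VIII'", "VIII"),
    stringsAsFactors = FALSE
  )
}

#' Backbone torsion angles of an ensemble
#'
#' phi(i) = C'(i-1)-N(i)-CA(i)-C'(i); psi(i) = N(i)-CA(i)-C'(i)-N(i+1) (the
#' C-terminal amide nitrogen serves for the last residue when present);
#' omega(i) = CA(i-1)-C'(i-1)-N(i)-CA(i), the peptide bond preceding residue
#' i.  Angles of d-residues are reported as-is, with no sign normalisation.
#'
#' @param ens a `pep_ensemble` whose topology has backbone atoms N, CA, C.
#' @return object of class `backbone_angles`: list of matrices `phi`, `psi`,
#'   `omega` (frames x residues, degrees, NA where undefined).
#' @export
backbone_angles <- function(ens) {
  top <- ens$topology
  if (is.null(top)) stop("backbone angles need a peptide topology")
  n <- nrow(top$residues)
  iN  <- vapply(seq_len(n), .atom_index, 0L, topology = top, name = "N")
  iCA <- vapply(seq_len(n), .atom_index, 0L, topology = top, name = "CA")
  iC  <- vapply(seq_len(n), .atom_index, 0L, topology = top, name = "C")
  iNT <- if (isTRUE(top$c_terminal_amide)) .atom_index(top, n, "NT") else NA_integer_
  nf <- n_frames(ens)
  phi <- psi <- omega <- matrix(NA_real_, nf, n)
  for (f in seq_len(nf)) {
    X <- ens$frames[[f]]
    for (i in seq_len(n)) {
      if (anyNA(c(iN[i], iCA[i], iC[i]))) next
      if (i > 1L && !anyNA(c(iC[i - 1], iCA[i - 1])))
        phi[f, i] <- dihedral_angle(X[iC[i - 1], ], X[iN[i], ],
                                    X[iCA[i], ], X[iC[i], ])
      nxt <- if (i < n) iN[i + 1] else iNT
      if (!is.na(nxt))
        psi[f, i] <- dihedral_angle(X[iN[i], ], X[iCA[i], ],
                                    X[iC[i], ], X[nxt, ])
      if (i > 1L && !anyNA(c(iCA[i - 1], iC[i - 1])))
        omega[f, i] <- dihedral_angle(X[iCA[i - 1], ], X[iC[i - 1], ],
                                      X[iN[i], ], X[iCA[i], ])
    }
  }
  structure(list(phi = phi, psi = psi, omega = omega,
                 n_residues = n, n_frames = nf),
            class = "backbone_angles")
}

# Classify one 4-angle tuple (phi1, psi1, phi2, psi2) against the templates.
# Returns list(type, maxdev) or NULL when nothing matches.
.classify_turn_frame <- function(ang, templates, tol_main, tol_one) {
  if (anyNA(ang)) return(NULL)
  best_type <- NULL
  best_dev <- Inf
  for (k in seq_len(nrow(templates))) {
    dev <- angle_diff(ang, unlist(templates[k, c("phi1", "psi1", "phi2", "psi2")]))
    n_over <- sum(dev > tol_main)
    ok <- n_over == 0L || (n_over == 1L && max(dev) <= tol_one)
    if (ok && max(dev) < best_dev) {
      best_dev <- max(dev)
      best_type <- templates$type[k]
    }
  }
  # type VII kink: only psi(i+1) and phi(i+2) are constrained
  dev_a <- max(angle_diff(ang[2], 180), abs(ang[3]))
  dev_b <- max(abs(ang[2]), angle_diff(ang[3], 180))
  kink_a <- angle_diff(ang[2], 180) <= tol_main && abs(ang[3]) < 60
  kink_b <- abs(ang[2]) < 60 && angle_diff(ang[3], 180) <= tol_main
  if (kink_a || kink_b) {
    dev <- if (kink_a && (!kink_b || dev_a <= dev_b)) dev_a else dev_b
    if (dev < best_dev) { best_dev <- dev; best_type <- "VII" }
  }
  if (is.null(best_type)) NULL else list(type = best_type, maxdev = best_dev)
}

#' Detect and type beta-turns across an ensemble
#'
#' A frame contains a turn at start residue i when the CA(i)-CA(i+3) distance
#' is below `dmax` and the four torsions (phi, psi of residues i+1, i+2) match
#' a template with at most three deviations within `tol_main` and at most one
#' within `tol_one`; the template with the smallest maximum deviation wins.
#' Chain reversals (distance criterion met) matching no template are typed IV.
#' Type VII is scored on the constrained angle pair only (see
#' [turn_templates()]).
#'
#' @param ens a `pep_ensemble`.
#' @param tol_main main angular tolerance, degrees (default 30).
#' @param tol_one relaxed tolerance allowed for one angle, degrees (default 45).
#' @param dmax CA(i)-CA(i+3) distance cutoff, Angstrom (default 7).
#' @param angles optional precomputed [backbone_angles()].
#' @return data.frame of class `turn_assignment`: `start` (residue i), `type`,
#'   `occupancy` (fraction of frames), `mean_maxdev` (degrees), `mean_ca_dist`
#'   (A).  Attribute `per_frame` holds the frame-level assignments.
#' @export
detect_turns <- function(ens, tol_main = 30, tol_one = 45, dmax = 7.0,
                         angles = NULL) {
  top <- ens$topology
  n <- nrow(top$residues)
  if (n < 4L) stop("turn detection needs at least 4 residues")
  if (is.null(angles)) angles <- backbone_angles(ens)
  iCA <- vapply(seq_len(n), .atom_index, 0L, topology = top, name = "CA")
  tmpl <- turn_templates()
  recs <- list()
  for (f in seq_len(n_frames(ens))) {
    X <- ens$frames[[f]]
    for (i in seq_len(n - 3L)) {
      dca <- sqrt(sum((X[iCA[i], ] - X[iCA[i + 3], ])^2))
      if (dca >= dmax) next
      ang <- c(angles$phi[f, i + 1], angles$psi[f, i + 1],
               angles$phi[f, i + 2], angles$psi[f, i + 2])
      hit <- .classify_turn_frame(ang, tmpl, tol_main, tol_one)
      if (is.null(hit)) hit <- list(type = "IV", maxdev = NA_real_)
      recs[[length(recs) + 1L]] <- data.frame(
        frame = f, start = i, type = hit$type, maxdev = hit$maxdev,
        ca_dist = dca, stringsAsFactors = FALSE)
    }
  }
  nf <- n_frames(ens)
  if (!length(recs)) {
    out <- data.frame(start = integer(0), type = character(0),
                      occupancy = numeric(0), mean_maxdev = numeric(0),
                      mean_ca_dist = numeric(0))
    attr(out, "per_frame") <- NULL
    class(out) <- c("turn_assignment", class(out))
    return(out)
  }
  per_frame <- do.call(rbind, recs)
  agg <- split(per_frame, list(per_frame$start, per_frame$type), drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(g) data.frame(
    start = g$start[1], type = g$type[1], occupancy = nrow(g) / nf,
    mean_maxdev = mean(g$maxdev), mean_ca_dist = mean(g$ca_dist),
    stringsAsFactors = FALSE)))
  out <- out[order(out$start, -out$occupancy), ]
  rownames(out) <- NULL
  attr(out, "per_frame") <- per_frame
  class(out) <- c("turn_assignment", class(out))
  out
}

#' Aromatic ring-pair descriptors
#'
#' Two measures of the mutual arrangement of two aromatic side chains
#' (canonically Tyr2 and Phe3): `Dis`, the distance between the ring mass
#' centres, and `Ang`, the dihedral angle over (ring centre a, CA of a, CA of
#' b, ring centre b).  Ring mass centres use the three carbons C1, C3, C5 of
#' the IUPAC ring numbering, i.e. PDB atoms CG, CE1, CE2; with equal carbon
#' masses the mass-weighted and geometric centres coincide.
#'
#' @param ens a `pep_ensemble`.
#' @param res_a,res_b 1-based indices of the two aromatic residues (defaults
#'   2 and 3).
#' @return list of class `ring_descriptor`: `per_frame` (data.frame with
#'   `dis`, `ang`), `dis_mean`, `dis_sd`, `ang_mean` (circular mean, degrees),
#'   `ang_R` (mean resultant length, 1 = no dispersion).
#' @export
ring_descriptors <- function(ens, res_a = 2L, res_b = 3L) {
  top <- ens$topology
  ring <- function(i) {
    idx <- vapply(c("CG", "CE1", "CE2"), .atom_index, 0L,
                  topology = top, residue = i)
    if (anyNA(idx)) stop("residue ", i, " lacks aromatic ring atoms CG/CE1/CE2")
    idx
  }
  ra <- ring(res_a); rb <- ring(res_b)
  ca_a <- .atom_index(top, res_a, "CA"); ca_b <- .atom_index(top, res_b, "CA")
  masses <- top$atoms$mass
  pf <- t(vapply(ens$frames, function(X) {
    coma <- center_of_mass(X[ra, ], masses[ra])
    comb <- center_of_mass(X[rb, ], masses[rb])
    c(dis = .norm3(coma - comb),
      ang = dihedral_angle(coma, X[ca_a, ], X[ca_b, ], comb))
  }, c(dis = 0, ang = 0)))
  ang_rad <- pf[, "ang"] * pi / 180
  S <- mean(sin(ang_rad)); C <- mean(cos(ang_rad))
  structure(list(per_frame = as.data.frame(pf),
                 dis_mean = mean(pf[, "dis"]), dis_sd = stats::sd(pf[, "dis"]),
                 ang_mean = wrap_angle(atan2(S, C) * 180 / pi),
                 ang_R = sqrt(S^2 + C^2)),
            class = "ring_descriptor")
}

#' @export
print.ring_descriptor <- function(x, ...) {
  cat(sprintf(
    "ring_descriptor: Dis = %.2f +/- %.2f A | Ang = %.1f deg (R = %.2f)\n",
    x$dis_mean, if (is.na(x$dis_sd)) 0 else x$dis_sd, x$ang_mean, x$ang_R))
  invisible(x)
}
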