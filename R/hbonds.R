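# Hydrogen-bond occupancy over an ensemble.  Geometric criterion: donor
# heavy atom to acceptor heavy atom distance <= d_max and D-H...A angle >=
# angle_min.  Missing polar hydrogens are rebuilt at idealised positions.

# Rebuild the amide H of residue i: 1.01 A from N along the negated bisector
# of the two N bonds (previous C' and own CA).
.rebuild_amide_h <- function(X, iN, iC_prev, iCA) {
  u <- .unit3(X[iC_prev, ] - X[iN, ])
  v <- .unit3(X[iCA, ] - X[iN, ])
  X[iN, ] + 1.01 * .unit3(-(u + v))
}

# Donor table: backbone amide NH of residues 2..n (except Pro), the
# C-terminal amide NT, and simple side-chain N/O donors.  Virtual H for
# side-chain donors and NT points along the antecedent->donor extension.
.donor_table <- function(top) {
  n <- nrow(top$residues)
  out <- list()
  add <- function(res, atom, antecedent, label, bisector = FALSE)
    out[[length(out) + 1L]] <<- data.frame(
      residue = res, atom = atom, antecedent = antecedent, label = label,
      bisector = bisector, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (i > 1L && top$residues$name[i] != "PRO")
      add(i, "N", "C", sprintf("HN%d", i), bisector = TRUE)
    sc <- switch(top$residues$name[i],
      GLN = list(c("NE2", "CD")),
      ASN = list(c("ND2", "CG")),
      ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
      TYR = list(c("OH", "CZ")),
      NULL)
    for (p in sc) add(i, p[1], p[2], sprintf("sc%d", i))
    if (isTRUE(top$c_terminal_amide) && i == n)
      add(i, "NT", "C", "HNT")
  }
  do.call(rbind, out)
}

# Acceptor table: backbone carbonyl O plus side-chain carbonyl/hydroxyl O.
.acceptor_table <- function(top) {
  n <- nrow(top$residues)
  out <- list()
  add <- function(res, atom, label)
    out[[length(out) + 1L]] <<- data.frame(residue = res, atom = atom,
                                           label = label,
                                           stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    add(i, "O", sprintf("CO%d", i))
    sc <- switch(top$residues$name[i],
      GLN = "OE1", ASN = "OD1", TYR = "OH", NULL)
    if (!is.null(sc)) add(i, sc, sprintf("sc%d", i))
  }
  do.call(rbind, out)
}

#' Hydrogen-bond occupancies over an ensemble
#'
#' Counts a donor/acceptor pair as bonded in a frame when the donor-heavy to
#' acceptor-heavy distance is at most `d_max` and the D-H...A angle is at
#' least `angle_min`.  Backbone amide hydrogens missing from the coordinates
#' are rebuilt 1.01 A from N along the bisector convention; side-chain and
#' C-terminal amide donors use a virtual H along the antecedent->donor bond
#' extension.  Pairs whose donor and acceptor are covalently adjacent (the
#' amide N against its own preceding carbonyl, or within one residue) are
#' excluded.
#'
#' @param ens a `pep_ensemble` with a peptide topology.
#' @param d_max heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum D-H...A angle, degrees (default 120).
#' @param min_occupancy report only bonds at or above this occupancy
#'   (default 0, i.e. all observed bonds).
#' @return data.frame of class `hbond_table`, sorted by occupancy: `donor`,
#'   `acceptor`, `occupancy`, `mean_distance`.
#' @export
hbond_occupancy <- function(ens, d_max = 3.5, angle_min = 120,
                            min_occupancy = 0) {
  top <- ens$topology
  if (is.null(top)) stop("hydrogen-bond analysis needs a peptide topology")
  don <- .donor_table(top)
  acc <- .acceptor_table(top)
  don$idx <- mapply(.atom_index, don$residue, don$atom,
                    MoreArgs = list(topology = top))
  don$h_idx <- mapply(.atom_index, don$residue,
                      ifelse(don$atom == "N", "H", NA_character_),
                      MoreArgs = list(topology = top))
  don$ante_idx <- mapply(.atom_index,
                         ifelse(don$bisector & don$atom == "N",
                                don$residue - 1L, don$residue),
                         don$antecedent, MoreArgs = list(topology = top))
  acc$idx <- mapply(.atom_index, acc$residue, acc$atom,
                    MoreArgs = list(topology = top))
  don <- don[!is.na(don$idx) & !is.na(don$ante_idx), ]
  acc <- acc[!is.na(acc$idx), ]
  acc_C <- mapply(.atom_index, acc$residue,
                  ifelse(acc$atom == "O", "C", acc$atom),
                  MoreArgs = list(topology = top))

  nf <- n_frames(ens)
  nd <- nrow(don); na_ <- nrow(acc)
  hits <- matrix(0L, nd, na_)
  dsum <- matrix(0, nd, na_)
  iCA <- vapply(seq_len(nrow(top$residues)), .atom_index, 0L,
                topology = top, name = "CA")
  for (f in seq_len(nf)) {
    X <- ens$frames[[f]]
    for (di in seq_len(nd)) {
      iN <- don$idx[di]
      H <- if (!is.na(don$h_idx[di])) {
        X[don$h_idx[di], ]
      } else if (don$bisector[di]) {
        .rebuild_amide_h(X, iN, don$ante_idx[di], iCA[don$residue[di]])
      } else {
        X[iN, ] + 1.01 * .unit3(X[iN, ] - X[don$ante_idx[di], ])
      }
      for (ai in seq_len(na_)) {
        if (acc$idx[ai] == iN) next
        # exclude the donor's own preceding carbonyl (covalent N-C bond)
        if (don$atom[di] %in% c("N", "NT") && acc$atom[ai] == "O" &&
            acc$residue[ai] == don$residue[di] - don$bisector[di]) next
        if (don$residue[di] == acc$residue[ai] &&
            don$atom[di] != "N") next
        d <- .norm3(X[iN, ] - X[acc$idx[ai], ])
        if (d > d_max) next
        hv <- .unit3(H - X[iN, ])  # not used directly; angle below
        v1 <- X[iN, ] - H
        v2 <- X[acc$idx[ai], ] - H
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (.norm3(v1) * .norm3(v2))))) * 180 / pi
        if (ang < angle_min) next
        hits[di, ai] <- hits[di, ai] + 1L
        dsum[di, ai] <- dsum[di, ai] + d
      }
    }
  }
  found <- which(hits > 0L, arr.ind = TRUE)
  if (!nrow(found)) {
    out <- data.frame(donor = character(0), acceptor = character(0),
                      occupancy = numeric(0), mean_distance = numeric(0))
  } else {
    out <- data.frame(
      donor = don$label[found[, 1]],
      acceptor = acc$label[found[, 2]],
      occupancy = hits[found] / nf,
      mean_distance = dsum[found] / hits[found],
      stringsAsFactors = FALSE)
  }
  out <- out[out$occupancy >= min_occupancy, ]
  out <- out[order(-out$occupancy), ]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", class(out))
  out
}
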