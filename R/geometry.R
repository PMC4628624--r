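# Geometric primitives shared by all analysis stages.  Coordinates are in
# Angstrom, angles in degrees on the canonical interval (-180, 180].

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Wrap an angle onto (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped to the canonical interval `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Smallest circular difference between two angles
#'
#' @param a,b angles in degrees.
#' @return non-negative circular distance, at most 180 degrees.
#' @export
angle_diff <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}

#' Dihedral (torsion) angle of four points
#'
#' Signed torsion about the p2--p3 axis following the IUPAC convention:
#' looking from p2 towards p3, a clockwise rotation of the far bond relative
#' to the near bond is positive.  A cis arrangement gives 0, trans gives 180.
#' Mirror-reflecting all four points negates the result.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees on `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.norm3(b1) < 1e-8 || .norm3(b2) < 1e-8 || .norm3(b3) < 1e-8)
    stop("degenerate dihedral: consecutive points coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-8 || .norm3(n2) < 1e-8)
    stop("degenerate dihedral: three consecutive points are collinear")
  m <- .cross3(n1, .unit3(b2))
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Centre of mass (or geometric centroid) of selected atoms
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param masses atomic masses, recycled against the selection; ignored for
#'   `weighting = "geometric"`.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return numeric 3-vector.
#' @export
center_of_mass <- function(coords, masses = NULL,
                           weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty selection")
  if (weighting == "geometric" || is.null(masses)) {
    w <- rep(1, nrow(coords))
  } else {
    w <- rep_len(masses, nrow(coords))
  }
  colSums(coords * w) / sum(w)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' selected atoms of `mobile` and `reference`.
#'
#' @param mobile,reference coordinate matrices with identical row counts.
#' @param sel integer atom indices used for the fit (default: all rows).
#' @return a list with `rotation` (3x3, applied on the right of row vectors),
#'   `translation` (3-vector), `rmsd` (Angstrom, over `sel` after fitting) and
#'   `xyz`, the fully transformed `mobile` coordinates.
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  sel <- as.integer(sel)
  if (length(sel) < 3L) stop("superposition needs at least 3 selected atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  # collinearity check: rank of the centred selection must be >= 2
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L)
    stop("degenerate selection: selected atoms are collinear")
  C <- crossprod(Pc, Qc)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted_sel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Qc)^2)))
  xyz <- sweep(sweep(mobile, 2, cp) %*% R, 2, cq, `+`)
  list(rotation = R, translation = cq - cp %*% R, rmsd = rmsd, xyz = xyz)
}

#' Root-mean-square deviation without fitting
#'
#' @param a,b coordinate matrices of equal dimension.
#' @param sel optional integer row selection.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(a, b, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(a))
  sqrt(mean(rowSums((a[sel, , drop = FALSE] - b[sel, , drop = FALSE])^2)))
}

# Place a new atom D from three predecessors a-b-c using internal coordinates
# (NeRF construction).  `torsion` follows the same sign convention as
# dihedral_angle(a, b, c, D).
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit3(c - b)
  n <- .unit3(.cross3(b - a, bc))
  p <- .cross3(n, bc)
  c + bond * (-cos(th) * bc + sin(th) * (cos(ph) * p - sin(ph) * n))
}
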