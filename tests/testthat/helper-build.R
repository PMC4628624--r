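# Shared builders for the test suite.  Everything is generated in code; no
# binary fixtures.

# random rigid rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# AVP-like peptide with a planted turn template at start residue `start`
# (angles at start+1, start+2); background extended chain.
turn_peptide <- function(type, start = 6, variant = "AVP") {
  top <- avp_topology(variant)
  sgn <- ifelse(top$residues$chirality == "D", -1, 1)
  phi <- sgn * -120
  psi <- sgn * 130
  tm <- turn_templates()
  row <- tm[tm$type == type, ]
  stopifnot(nrow(row) == 1)
  phi[start + 1] <- row$phi1; psi[start + 1] <- row$psi1
  phi[start + 2] <- row$phi2; psi[start + 2] <- row$psi2
  list(topology = top,
       conformation = build_peptide(top, phi, psi),
       phi = phi, psi = psi)
}

# single-residue probe peptide for solvation tests
probe_peptide <- function(res = "F") {
  top <- pep_topology(res, c_terminal_amide = FALSE)
  list(topology = top, conformation = build_peptide(top, 0, 0))
}

# coarse grid-search oracle for the optimal-superposition RMSD
grid_search_rmsd <- function(mobile, reference, step_deg = 30) {
  angs <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  rot <- function(a, b, g) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rz2
  }
  Pc <- sweep(mobile, 2, colMeans(mobile))
  Qc <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  for (a in angs) for (b in angs[angs < pi + 1e-9]) for (g in angs) {
    r <- sqrt(mean(rowSums((Pc %*% rot(a, b, g) - Qc)^2)))
    if (r < best) best <- r
  }
  best
}
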