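test_that("backbone angles recover helical torsions and flip under mirror", {
  top <- pep_topology("CYFQNCPRG", disulfides = c(1, 6))
  cf <- build_peptide(top, -57, -47)
  ens <- pep_ensemble(top, list(cf$xyz))
  ang <- backbone_angles(ens)
  expect_equal(ang$phi[1, 2:9], rep(-57, 8), tolerance = 0.5)
  expect_equal(ang$psi[1, 1:8], rep(-47, 8), tolerance = 0.5)
  expect_true(is.na(ang$phi[1, 1]))
  # mirror image: all angles negated
  M <- cf$xyz; M[, 1] <- -M[, 1]
  angM <- backbone_angles(pep_ensemble(top, list(M)))
  expect_equal(angM$phi[1, 2:9], -ang$phi[1, 2:9], tolerance = 1e-8)
  expect_equal(angM$psi[1, ], -ang$psi[1, ], tolerance = 1e-8)
})

test_that("psi of the last residue is undefined without a terminal amide", {
  top <- pep_topology("CYFQNCPRG", disulfides = c(1, 6),
                      c_terminal_amide = FALSE)
  cf <- build_peptide(top, -70, 140)
  ang <- backbone_angles(pep_ensemble(top, list(cf$xyz)))
  expect_true(is.na(ang$psi[1, 9]))
})

test_that("turn templates have primed mirror partners and type II geometry", {
  tm <- turn_templates()
  expect_equal(tm$phi2[tm$type == "II"], 80)
  expect_equal(unlist(tm[tm$type == "II'", c("phi1", "psi1", "phi2", "psi2")]),
               c(phi1 = 60, psi1 = -120, phi2 = -80, psi2 = 0))
  for (k in seq_len(nrow(tm))) {
    p <- tm[tm$type == tm$primed_partner[k], ]
    expect_equal(unlist(p[, c("phi1", "psi1", "phi2", "psi2")]),
                 -unlist(tm[k, c("phi1", "psi1", "phi2", "psi2")]),
                 ignore_attr = TRUE)
  }
})

test_that("planted template turns are detected with zero deviation", {
  for (ty in c("I", "II", "II'", "III", "VIII'")) {
    tp <- turn_peptide(ty, start = 6)
    tt <- detect_turns(pep_ensemble(tp$topology, list(tp$conformation$xyz)))
    hit <- tt[tt$start == 6, ]
    expect_equal(hit$type, ty)
    expect_lt(hit$mean_maxdev, 1e-6)
    expect_equal(hit$occupancy, 1)
    expect_lt(hit$mean_ca_dist, 7)
  }
})

test_that("turn typing commutes with mirror symmetry", {
  tm <- turn_templates()
  top <- pep_topology("CYFQNCPRG", disulfides = c(1, 6))
  set.seed(41)
  for (ty in tm$type) {
    phi <- rep(-120, 9); psi <- rep(130, 9)
    row <- tm[tm$type == ty, ]
    jit <- runif(4, -8, 8)   # off-ideal but inside tolerance
    phi[7] <- row$phi1 + jit[1]; psi[7] <- row$psi1 + jit[2]
    phi[8] <- row$phi2 + jit[3]; psi[8] <- row$psi2 + jit[4]
    cf <- build_peptide(top, phi, psi)
    t1 <- detect_turns(pep_ensemble(top, list(cf$xyz)))
    M <- cf$xyz; M[, 1] <- -M[, 1]
    t2 <- detect_turns(pep_ensemble(top, list(M)))
    ty1 <- t1$type[t1$start == 6]
    ty2 <- t2$type[t2$start == 6]
    expect_equal(ty2, tm$primed_partner[tm$type == ty1])
  }
})

test_that("extended chains contain no turns and tight tolerance rejects", {
  top <- avp_topology("AVP")
  cf <- build_peptide(top, -120, 130)
  ens <- pep_ensemble(top, list(cf$xyz))
  expect_equal(nrow(detect_turns(ens)), 0)
  # near-ideal but not exact turn: rejected as IV when tolerances -> 0
  tp <- turn_peptide("II'", start = 6)
  phi <- tp$phi; phi[7] <- phi[7] + 5
  cf2 <- build_peptide(tp$topology, phi, tp$psi)
  strict <- detect_turns(pep_ensemble(tp$topology, list(cf2$xyz)),
                         tol_main = 0.5, tol_one = 0.5)
  expect_equal(strict$type[strict$start == 6], "IV")
})

test_that("chain reversals matching no template are typed IV", {
  top <- avp_topology("AVP")
  phi <- rep(-120, 9); psi <- rep(130, 9)
  phi[7] <- -142.2; psi[7] <- 41.3; phi[8] <- 131.2; psi[8] <- 20.6
  cf <- build_peptide(top, phi, psi)
  tt <- detect_turns(pep_ensemble(top, list(cf$xyz)))
  expect_true(any(tt$start == 6 & tt$type == "IV"))
  expect_true(all(tt$type == "IV"))
})

test_that("per-start turn occupancies sum to at most 1", {
  # half the frames carry a II' turn, half are extended
  tp <- turn_peptide("II'", start = 6)
  ext <- build_peptide(tp$topology, rep(-120, 9), rep(130, 9))
  frames <- c(replicate(5, tp$conformation$xyz, simplify = FALSE),
              replicate(5, ext$xyz, simplify = FALSE))
  tt <- detect_turns(pep_ensemble(tp$topology, frames))
  occ <- tapply(tt$occupancy, tt$start, sum)
  expect_true(all(occ <= 1 + 1e-12))
  expect_equal(tt$occupancy[tt$start == 6 & tt$type == "II'"], 0.5)
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(rbind(c(1, 2, 3))), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  a <- 3.7
  cube <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  expect_equal(radius_of_gyration(cube), a * sqrt(3) / 2)
  expect_error(radius_of_gyration(two, integer(0)), "empty")
  # rigid-transform invariance
  set.seed(43)
  X <- matrix(rnorm(30), 10, 3)
  R <- random_rotation()
  expect_equal(radius_of_gyration(X %*% R + rep(c(4, 5, 6), each = 10)),
               radius_of_gyration(X), tolerance = 1e-10)
})

test_that("ring descriptors hit the planar limits and flip under mirror", {
  top <- avp_topology("AVP")
  cf <- build_peptide(top, -100, 120)
  ens <- pep_ensemble(top, list(cf$xyz))
  rd <- ring_descriptors(ens)
  expect_gt(rd$dis_mean, 0)
  expect_true(rd$ang_mean > -180 && rd$ang_mean <= 180)
  # mirror: Dis invariant, Ang negated
  M <- cf$xyz; M[, 1] <- -M[, 1]
  rdM <- ring_descriptors(pep_ensemble(top, list(M)))
  expect_equal(rdM$dis_mean, rd$dis_mean, tolerance = 1e-9)
  expect_equal(rdM$ang_mean, -rd$ang_mean, tolerance = 1e-9)
  # rigid transforms leave both unchanged
  R <- random_rotation()
  X2 <- cf$xyz %*% R + rep(c(3, -1, 2), each = nrow(cf$xyz))
  rd2 <- ring_descriptors(pep_ensemble(top, list(X2)))
  expect_equal(rd2$dis_mean, rd$dis_mean, tolerance = 1e-9)
  expect_equal(rd2$ang_mean, rd$ang_mean, tolerance = 1e-9)
})

test_that("ring descriptor circular mean recovers a planted orientation", {
  top <- avp_topology("AVP")
  cf <- build_peptide(top, -100, 120)
  base <- ring_descriptors(pep_ensemble(top, list(cf$xyz)))
  ens <- jitter_ensemble(cf, top, n_frames = 200, sd = 0.08, seed = 8)
  rd <- ring_descriptors(ens)
  expect_equal(rd$ang_mean, base$ang_mean, tolerance = 5)
  expect_equal(rd$dis_mean, base$dis_mean, tolerance = 0.2)
  expect_gt(rd$ang_R, 0.9)
})

test_that("ensemble RMSD is zero for rigid copies and recovers jitter", {
  top <- avp_topology("AVP")
  cf <- build_peptide(top, -100, 120)
  # identical frames
  ens0 <- pep_ensemble(top, replicate(4, cf$xyz, simplify = FALSE))
  expect_lt(ensemble_rmsd(ens0, "backbone"), 1e-10)
  # two frames differing by a rigid rotation only
  R <- random_rotation()
  ens1 <- pep_ensemble(top, list(cf$xyz, cf$xyz %*% R))
  expect_lt(ensemble_rmsd(ens1, "backbone"), 1e-10)
  expect_lt(ensemble_rmsd(ens1, "backbone", method = "pairwise"), 1e-10)
  # isotropic Gaussian jitter sigma: mean RMSD to the mean structure is
  # sigma * sqrt(3) * sqrt((F-1)/F), mildly reduced by the 6 fitted dof
  sig <- 0.1; F <- 100
  ens2 <- jitter_ensemble(cf, top, n_frames = F, sd = sig, seed = 12)
  expected <- sig * sqrt(3) * sqrt((F - 1) / F)
  expect_equal(ensemble_rmsd(ens2, "all"), expected, tolerance = 0.05)
})

test_that("hydrogen bonds obey the geometric cutoffs", {
  # ideal turn geometry: HN9-CO6 present at ~2.8 A
  tp <- turn_peptide("I", start = 6)
  hb <- hbond_occupancy(pep_ensemble(tp$topology, list(tp$conformation$xyz)))
  expect_true("HN9" %in% hb$donor && "CO6" %in% hb$acceptor)
  i <- which(hb$donor == "HN9" & hb$acceptor == "CO6")
  expect_lt(hb$mean_distance[i], 3.5)
  # tightening the distance cutoff below the observed distance removes it
  hb2 <- hbond_occupancy(pep_ensemble(tp$topology,
                                      list(tp$conformation$xyz)),
                         d_max = hb$mean_distance[i] - 0.1)
  expect_false(any(hb2$donor == "HN9" & hb2$acceptor == "CO6"))
})

test_that("planted hydrogen-bond occupancy is recovered", {
  tp <- turn_peptide("I", start = 6)
  ext <- build_peptide(tp$topology, rep(-120, 9), rep(130, 9))
  set.seed(19)
  q <- 0.8; F <- 100
  pick <- rbinom(F, 1, q)
  frames <- lapply(pick, function(p) if (p) tp$conformation$xyz else ext$xyz)
  hb <- hbond_occupancy(pep_ensemble(tp$topology, frames),
                        min_occupancy = 0.3)
  occ <- hb$occupancy[hb$donor == "HN9" & hb$acceptor == "CO6"]
  expect_equal(occ, mean(pick))                    # exact by construction
  expect_lt(abs(occ - q), 3 * sqrt(q * (1 - q) / F))  # binomial error
})
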