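test_that("J-to-phi intervals follow the rule set with left-closed bins", {
  expect_equal(unlist(j_to_phi_interval(5.0, "L")[c("lo", "hi")]),
               c(lo = -90, hi = -30))
  expect_equal(unlist(j_to_phi_interval(7.0, "L")[c("lo", "hi")]),
               c(lo = -120, hi = -60))
  expect_equal(unlist(j_to_phi_interval(8.5, "L")[c("lo", "hi")]),
               c(lo = -160, hi = -80))
  expect_equal(unlist(j_to_phi_interval(11.8, "L")[c("lo", "hi")]),
               c(lo = -140, hi = -100))
  # boundary couplings fall into the higher-J rule
  expect_equal(j_to_phi_interval(6, "L")$lo, -120)
  expect_equal(j_to_phi_interval(8, "L")$lo, -160)
  expect_equal(j_to_phi_interval(9, "L")$lo, -140)
  # d-residues: negated, endpoint-swapped
  expect_equal(unlist(j_to_phi_interval(10.2, "D")[c("lo", "hi")]),
               c(lo = 100, hi = 140))
  expect_equal(unlist(j_to_phi_interval(5.0, "D")[c("lo", "hi")]),
               c(lo = 30, hi = 90))
  expect_error(j_to_phi_interval(-1, "L"), "non-negative")
})

test_that("d-intervals mirror l-intervals for all couplings", {
  for (J in seq(0, 14, by = 0.25)) {
    l <- j_to_phi_interval(J, "L")
    d <- j_to_phi_interval(J, "D")
    expect_equal(d$lo, -l$hi)
    expect_equal(d$hi, -l$lo)
    expect_equal(d$hi - d$lo, l$hi - l$lo)
  }
})

test_that("NOE calibration inverts the r^-6 relation and pads pseudo-atoms", {
  pk <- data.frame(atom1 = c("a", "b", "c"), atom2 = c("x", "y", "z"),
                   volume = c(100, 100 / 64, 100),
                   type = c("", "", "methyl"))
  d <- calibrate_noe(pk, ref_volume = 100, ref_distance = 2.0)
  expect_equal(d$distance[1], 2.0)           # V = V_ref  ->  d = d_ref
  expect_equal(d$distance[2], 4.0)           # 64^(1/6) = 2 exactly
  expect_equal(d$upper[3], 3.0)              # +1.0 A methyl padding
  expect_identical(attr(d, "calibration"), "ISPA stand-in")
  expect_error(calibrate_noe(data.frame(atom1 = "a", atom2 = "b",
                                        volume = -1), 100), "positive")
  expect_error(calibrate_noe(pk, 100, ref_distance = 1.5), "1.7")
})

test_that("calibrated distances are monotone in volume and scale-invariant", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(3:30, 1)
    pk <- data.frame(atom1 = paste0("a", 1:n), atom2 = paste0("b", 1:n),
                     volume = runif(n, 0.01, 50))
    d1 <- calibrate_noe(pk, ref_volume = 2, ref_distance = 2.5)
    expect_equal(order(d1$distance), order(-pk$volume))
    expect_true(all(d1$upper <= 6.0))
    pk2 <- pk; pk2$volume <- pk2$volume * 17.3
    d2 <- calibrate_noe(pk2, ref_volume = 2 * 17.3, ref_distance = 2.5)
    expect_equal(d2$distance, d1$distance, tolerance = 1e-12)
  }
})

test_that("temperature coefficients are OLS slopes in ppb/K", {
  expect_equal(temp_coefficient(c(300, 310), c(8.0, 8.0), units = "K"), 0)
  expect_equal(temp_coefficient(c(300, 310), c(8.000, 7.990), units = "K"),
               -1.0, tolerance = 1e-10)
  # exact linear data at arbitrary slope recovered to 1e-10
  Tc <- c(5, 10, 20, 32, 40, 50)
  for (sl in c(-6.3, -2.7, 1.4)) {
    sh <- 8.2 + sl * 1e-3 * Tc
    expect_equal(temp_coefficient(Tc, sh), sl, tolerance = 1e-10)
  }
  expect_error(temp_coefficient(c(300, 300), c(8, 8.1), units = "K"),
               "distinct")
})

test_that("noisy temperature series recover the planted slope", {
  set.seed(9)
  Tc <- c(5, 10, 20, 32, 40, 50)
  slopes <- replicate(200, {
    sh <- 8.3 - 4.2e-3 * Tc + rnorm(6, sd = 0.004)
    temp_coefficient(Tc, sh)
  })
  expect_equal(mean(slopes), -4.2, tolerance = 0.05)
})

test_that("temperature coefficients classify into hydrogen-bond classes", {
  expect_equal(classify_hbond(-2.7), "strong")
  expect_equal(classify_hbond(-3.5), "weak")
  expect_equal(classify_hbond(-6.1), "none")
  # boundaries fall into the weaker class
  expect_equal(classify_hbond(-3), "weak")
  expect_equal(classify_hbond(-5), "none")
  expect_warning(res <- classify_hbond(0.4), "shielded")
  expect_equal(res, "strong")
  # adding a constant to all shifts does not change the class
  Tc <- c(5, 20, 40); sh <- 8.1 - 2.5e-3 * Tc
  expect_equal(classify_hbond(temp_coefficient(Tc, sh)),
               classify_hbond(temp_coefficient(Tc, sh + 0.7)))
})

test_that("proline isomer calls follow the Cb-Cg shift difference", {
  st <- data.frame(residue = c(7, 7), atom = c("CB", "CG"),
                   ppm = c(29.46, 25.17))
  r <- proline_isomer(st, 7)
  expect_equal(r$delta_ppm, 4.29)
  expect_equal(r$isomer, "trans")
  st$ppm <- c(34.0, 24.4)   # delta 9.6
  expect_equal(proline_isomer(st, 7)$isomer, "cis")
  expect_equal(proline_isomer(st[1, ], 7)$isomer, "undetermined")
})

test_that("indirect carbon referencing is the exact DSS frequency ratio", {
  expect_equal(reference_carbon(500e6), 0.251449530 * 500e6)
  expect_equal(reference_carbon(0), 0)
  expect_equal(reference_carbon(600e6) / reference_carbon(500e6), 600 / 500)
})

test_that("restraint sets aggregate, deduplicate and count", {
  cp <- data.frame(residue = c(2, 8), residue_name = c("TYR", "ARG"),
                   J = c(7.1, 10.2), chirality = c("L", "D"))
  pk <- data.frame(atom1 = c("2:H", "2:H", "3:H"),
                   atom2 = c("3:H", "3:H", "4:H"),
                   volume = c(10, 30, 20))
  expect_message(
    rs <- build_restraint_set(cp, pk, ref_volume = 20, n_residues = 9,
                              omega_trans = TRUE),
    "duplicate")
  expect_equal(unname(rs$counts["distance"]), 2L)
  # duplicate pair keeps the tighter (higher-volume, shorter) bound
  dup <- rs$distance[rs$distance$atom1 == "2:H", ]
  expect_equal(dup$upper,
               calibrate_noe(pk[2, ], 20)$upper)
  # 2 phi + 8 omega restraints
  expect_equal(unname(rs$counts["dihedral"]), 10L)
  expect_true(all(rs$dihedral$force_constant[rs$dihedral$angle == "omega"] == 50))
  expect_true(all(rs$dihedral$force_constant[rs$dihedral$angle == "phi"] == 2))
  # empty inputs give an empty set
  e <- build_restraint_set()
  expect_equal(sum(e$counts), 0L)
  # one restraint per peak when all pairs are distinct
  pk75 <- data.frame(atom1 = sprintf("a%d", 1:75), atom2 = sprintf("b%d", 1:75),
                     volume = runif(75, 1, 40))
  expect_equal(unname(build_restraint_set(peaks = pk75,
                                          ref_volume = 5)$counts["distance"]),
               75L)
})

test_that("Gly couplings are excluded from phi restraints by default", {
  cp <- data.frame(residue = c(8, 9), residue_name = c("ARG", "GLY"),
                   J = c(8.9, 6.0), chirality = c("L", "L"))
  rs <- build_restraint_set(cp)
  expect_equal(nrow(rs$dihedral), 1L)
  rs2 <- build_restraint_set(cp, include_gly = TRUE)
  expect_equal(nrow(rs2$dihedral), 2L)
})
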