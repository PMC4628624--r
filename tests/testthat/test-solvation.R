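# A uniform gas in a periodic box is the analytic reference for g(r); a fixed
# shell of points gives exact running integrals; union counting and analytic
# sphere volumes pin the hydration numbers.

make_shell_scene <- function(k = 12, r0 = 5.13, edge = 30) {
  center <- rep(edge / 2, 3)
  u <- matrix(rnorm(3 * k), k, 3)
  u <- u / sqrt(rowSums(u^2))
  atoms <- data.frame(residue = NA_integer_,
                      atom_name = c("X", rep("O", k)),
                      element = c("C", rep("O", k)),
                      mass = c(12.011, rep(15.999, k)),
                      group = c("probe", rep("shell", k)))
  X <- rbind(center, sweep(u * r0, 2, center, `+`))
  pep_ensemble(topology = NULL, frames = list(X), box_edge = edge,
               atoms = atoms)
}

test_that("RDF of a uniform gas is 1 in every bin beyond the first", {
  box <- make_box(edge = 30, water_density = 0.02, micelle = NULL,
                  n_frames = 10, seed = 21)
  g <- rdf(box, "water", "water", r_max = 10, dr = 0.5)
  keep <- g$r > 1.5   # tiny bins carry too few counts for a tight bound
  expect_true(all(abs(g$g[keep] - 1) < 0.1))
  expect_lt(abs(mean(g$g[keep]) - 1), 0.02)
  # n(r) is non-decreasing and g >= 0
  expect_true(all(diff(g$n) >= 0))
  expect_true(all(g$g >= 0))
})

test_that("running integral counts a fixed shell exactly", {
  set.seed(23)
  sc <- make_shell_scene(k = 12, r0 = 5.13)
  g <- rdf(sc, "probe", "shell", r_max = 10, dr = 0.25)
  expect_equal(g$n[which.min(abs(g$r - 7))], 12)
  expect_equal(max(g$n), 12)
  expect_equal(g$n[which.min(abs(g$r - 3))], 0)
})

test_that("n(r) at shared grid points is stable under bin-width doubling", {
  box <- make_box(edge = 24, water_density = 0.03, micelle = NULL,
                  n_frames = 3, seed = 29)
  g1 <- rdf(box, "water", "water", r_max = 8, dr = 0.1)
  g2 <- rdf(box, "water", "water", r_max = 8, dr = 0.2)
  # cumulative counts at r = 2, 4, 6, 8 must agree exactly
  at <- function(g, r) g$n[which.min(abs((g$r + (g$r[2] - g$r[1]) / 2) - r))]
  for (r in c(2, 4, 6, 8)) expect_equal(at(g1, r), at(g2, r), tolerance = 1e-12)
})

test_that("g(r) integrates back to n(r) (internal consistency)", {
  box <- make_box(edge = 24, water_density = 0.03, micelle = NULL,
                  n_frames = 2, seed = 31)
  g <- rdf(box, "water", "water", r_max = 8, dr = 0.2)
  dr <- 0.2
  shell <- 4 / 3 * pi * ((g$r + dr / 2)^3 - (g$r - dr / 2)^3)
  n_rec <- cumsum(g$g * shell * g$density_B)
  expect_equal(n_rec, g$n, tolerance = 1e-9)
})

test_that("RDF is symmetric under group exchange and translation", {
  set.seed(33)
  sc <- make_shell_scene(k = 20, r0 = 6.17)
  gab <- rdf(sc, "probe", "shell", r_max = 10, dr = 0.5)
  gba <- rdf(sc, "shell", "probe", r_max = 10, dr = 0.5)
  expect_equal(gab$g, gba$g, tolerance = 1e-12)
  # translating everything (with wrapping) leaves g unchanged
  sc2 <- sc
  sc2$frames[[1]] <- (sc$frames[[1]] + rep(c(11, 4, 7), each = nrow(sc$frames[[1]]))) %% sc$box_edge
  g2 <- rdf(sc2, "probe", "shell", r_max = 10, dr = 0.5)
  expect_equal(g2$g, gab$g, tolerance = 1e-9)
})

test_that("r_max beyond half the box edge is rejected", {
  box <- make_box(edge = 20, water_density = 0.01, micelle = NULL, seed = 1)
  expect_error(rdf(box, "water", "water", r_max = 11), "half the box")
  expect_error(hydration_number(box, "water", radius = 10.5), "half the box")
})

test_that("hydration number matches the analytic sphere-volume expectation", {
  pp <- probe_peptide("G")
  box <- make_box(edge = 30, water_density = 0.0334, micelle = NULL,
                  peptide = list(topology = pp$topology,
                                 conformation = pp$conformation,
                                 placement = "bulk"),
                  n_frames = 60, seed = 7)
  hn <- hydration_number(box, "name:CA", radius = 3.8)
  expected <- 4 / 3 * pi * 3.8^3 * 0.0334    # 7.68 waters
  # MC error: ~sqrt(lambda/frames) per-frame sampling plus the Poisson
  # fluctuation of the box water count (~3%)
  expect_equal(hn, expected, tolerance = 0.15)
  # no water -> 0
  dry <- make_box(edge = 30, water_density = 0, micelle = NULL,
                  peptide = list(topology = pp$topology,
                                 conformation = pp$conformation,
                                 placement = "bulk"),
                  n_frames = 1, seed = 7)
  expect_equal(hydration_number(dry, "name:CA"), 0)
})

test_that("union counting never exceeds the sum of per-atom counts", {
  pp <- probe_peptide("C")   # CB and SG about 1.8 A apart
  box <- make_box(edge = 26, water_density = 0.0334, micelle = NULL,
                  peptide = list(topology = pp$topology,
                                 conformation = pp$conformation,
                                 placement = "bulk"),
                  n_frames = 10, seed = 13)
  u <- hydration_number(box, "sidechain:1", radius = 3.8)
  parts <- sum(vapply(select_atoms(pp$topology, "sidechain:1"),
                      function(i) hydration_number(box, i, radius = 3.8), 0))
  expect_lt(u, parts)
  expect_gt(u, parts / 2)
})

test_that("per-residue hydration report covers both probe sets", {
  top <- avp_topology("AVP")
  cf <- build_peptide(top, -100, 120)
  box <- make_box(edge = 40, water_density = 0.02, micelle = NULL,
                  peptide = list(topology = top, conformation = cf,
                                 placement = "buried"),
                  n_frames = 3, seed = 17)
  hr <- hydration_report(box)
  expect_equal(nrow(hr), 9)
  expect_true(is.na(hr$sidechain[9]))   # Gly has no side chain
  expect_true(all(hr$carbonyl_O >= 0))
})

test_that("contact profiles recover the planted environments", {
  pp <- probe_peptide("F")
  mk <- function(pl, seed) make_box(
    edge = 44, water_density = 0.0334,
    micelle = list(shell_radius = 12, n_sds = 5, n_dpc = 10, tail_sites = 3),
    peptide = list(topology = pp$topology, conformation = pp$conformation,
                   placement = pl),
    n_frames = 5, seed = seed)
  expect_equal(contact_profile(mk("buried", 3), 1)$class, "buried_in_core")
  expect_equal(contact_profile(mk("surface", 3), 1)$class, "interfacial")
  expect_equal(contact_profile(mk("bulk", 3), 1)$class, "solvent_exposed")
})
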