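test_that("nonpolar solvation term evaluates the linear SASA model", {
  expect_equal(gsa_from_sasa(0), 0.92)
  expect_equal(gsa_from_sasa(1000), 0.00542 * 1000 + 0.92)
  expect_equal(gsa_from_sasa(1000), 6.34)
  expect_equal(gsa_from_sasa(123, gamma = 0, b = 0), 0)
  expect_error(gsa_from_sasa(-1), "sasa")
})

test_that("per-frame species free energy sums its components", {
  fr <- data.frame(species = "ligand", replica = 1, time_ns = 1,
                   e_int = 1, e_vdw = 2, e_ele = 3, g_pb = 4, g_sa = 5)
  expect_equal(species_free_energy(fr), 15)
  fr0 <- transform(fr, e_int = 0, e_vdw = 0, e_ele = 0, g_pb = 0, g_sa = 0)
  expect_equal(species_free_energy(fr0), 0)
  # entropy shifts the result by exactly -T*S
  ts <- -310.15 * 0.01
  expect_equal(species_free_energy(fr, minus_ts = ts), 15 + ts)
  # missing component is named
  expect_error(species_free_energy(fr[, setdiff(names(fr), "g_pb")]), "g_pb")
  # sasa column resolves through the surface-area model
  fr2 <- transform(fr, g_sa = NULL, sasa = 1000)
  expect_equal(species_free_energy(fr2), 1 + 2 + 3 + 4 + 6.34)
})

test_that("frame selection is endpoint-anchored and uniform", {
  t1 <- select_frames(40)
  expect_length(t1, 50)
  expect_true(all(t1 > 30 & t1 <= 40))
  expect_equal(max(t1), 40)
  expect_equal(unique(round(diff(t1), 12)), 10 / 50)

  expect_equal(select_frames(40, n_frames = 1), 40)  # final frame
  expect_equal(select_frames(10, 10, 5), c(2, 4, 6, 8, 10))
  expect_error(select_frames(5, 10), "exceeds")
})

test_that("null binding and constant ensembles give exact results", {
  g <- gen_energy_frames(seed = 1, n_replicas = 4, n_frames = 6)
  # receptor + ligand constructed to equal the complex exactly
  half <- function(s, f) {
    s$e_int <- f * s$e_int; s$e_vdw <- f * s$e_vdw; s$e_ele <- f * s$e_ele
    s$g_pb <- f * s$g_pb; s$g_sa <- f * s$g_sa
    s
  }
  rec <- half(g$complex, 0.7); rec$species <- "receptor"
  lig <- half(g$complex, 0.3); lig$species <- "ligand"
  r <- esmacs_binding_free_energy(g$complex, energy_frames(rec),
                                  energy_frames(lig), mode = "one_traj",
                                  n_boot = 2000, seed = 3)
  expect_equal(r$delta_g, 0, tolerance = 1e-10)
  expect_equal(r$sem, 0, tolerance = 1e-10)

  # constant ensembles: dG is the difference of constants, SEM = 0
  gc <- gen_energy_frames(means = c(complex = -100, receptor = -60,
                                    ligand = -30),
                          sd = 0, seed = 2, n_replicas = 25, n_frames = 10)
  r2 <- esmacs_binding_free_energy(gc$complex, gc$receptor, gc$ligand,
                                   n_boot = 1000, seed = 4)
  expect_equal(r2$delta_g, -10, tolerance = 1e-10)
  expect_equal(r2$sem, 0, tolerance = 1e-10)
})

test_that("linearity: scaling all components scales dG", {
  g <- gen_energy_frames(seed = 5, n_replicas = 5, n_frames = 8)
  scale_set <- function(s, c) {
    for (cn in c("e_int", "e_vdw", "e_ele", "g_pb", "g_sa")) {
      s[[cn]] <- c * s[[cn]]
    }
    energy_frames(as.data.frame(s))
  }
  r1 <- esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                                   n_boot = 1, seed = 1)
  r3 <- esmacs_binding_free_energy(scale_set(g$complex, 3),
                                   scale_set(g$receptor, 3),
                                   scale_set(g$ligand, 3),
                                   n_boot = 1, seed = 1)
  expect_equal(r3$delta_g, 3 * r1$delta_g, tolerance = 1e-10)
})

test_that("component breakdown sums to dG and modes agree on point estimates", {
  g <- gen_energy_frames(seed = 8, n_replicas = 6, n_frames = 10)
  r1 <- esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                                   mode = "one_traj", n_boot = 500, seed = 2)
  r3 <- esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                                   mode = "three_traj", n_boot = 500,
                                   seed = 2)
  expect_equal(sum(r1$components), r1$delta_g, tolerance = 1e-10)
  expect_identical(r1$delta_g, r3$delta_g)
  expect_identical(r1$components, r3$components)
})

test_that("one_traj mode rejects mismatched replica/frame keys", {
  g <- gen_energy_frames(seed = 9, n_replicas = 3, n_frames = 4)
  rec <- as.data.frame(g$receptor)
  rec <- rec[rec$replica != 3, ]
  expect_error(esmacs_binding_free_energy(g$complex, energy_frames(rec),
                                          g$ligand, mode = "one_traj"),
               "identical replica/time keys")
})

test_that("bootstrap SEM vanishes as inter-replica variance vanishes", {
  sems <- vapply(c(2, 0.5, 0.05), function(sdv) {
    g <- gen_energy_frames(sd = sdv, seed = 11, n_replicas = 10,
                           n_frames = 20)
    esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                               n_boot = 2000, seed = 1)$sem
  }, numeric(1))
  expect_true(all(diff(sems) < 0))
  expect_lt(sems[3], 0.01)
})

test_that("tail-window selection picks the protocol frames", {
  g <- gen_energy_frames(seed = 12, n_replicas = 2, n_frames = 40,
                         window_ns = 20)  # times 30.5 .. 50
  r <- esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                                  window_ns = 10, n_frames = 10,
                                  n_boot = 10, seed = 1)
  expect_equal(r$delta_g,
               esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                                          window_ns = 10, n_frames = 10,
                                          n_boot = 10, seed = 99)$delta_g)
})

test_that("running-average diagnostic tracks the full estimate", {
  g <- gen_energy_frames(seed = 13, n_replicas = 3, n_frames = 10)
  ra <- esmacs_running_average(g$complex, g$receptor, g$ligand, n_points = 5)
  expect_true(nrow(ra) >= 2)
  full <- esmacs_binding_free_energy(g$complex, g$receptor, g$ligand,
                                     n_boot = 1, seed = 1)$delta_g
  expect_equal(ra$delta_g[nrow(ra)], full, tolerance = 1e-10)
})
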