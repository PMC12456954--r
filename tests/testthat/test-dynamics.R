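# Potential terms, forces, the Brownian propagator, and the virial tensor.

test_that("scalar energy terms evaluate their closed forms", {
  expect_equal(harmonic_bond_energy(2, 2, 10), 0)
  expect_equal(harmonic_bond_energy(3, 2, 10), 5)
  expect_error(harmonic_bond_energy(1, 1, -1), "non-negative")

  expect_equal(gaussian_linker_energy(0, 60), 0)
  k60 <- linker_spring_constant(60, 0.38, 300)
  expect_equal(k60, 3 * kB * 300 / (60 * 0.38^2))
  expect_equal(round(k60, 3), 0.864)
  expect_equal(linker_spring_constant(120), k60 / 2)

  expect_equal(excluded_volume_energy(5, 2, 3, 10), 0)     # at contact
  expect_equal(excluded_volume_energy(6, 2, 3, 10), 0)     # beyond
  e1 <- excluded_volume_energy(4.5, 2, 3, 10)
  e2 <- excluded_volume_energy(4.0, 2, 3, 10)
  expect_gt(e1, 0)
  expect_gt(e2, e1)                                        # monotone inward

  expect_equal(membrane_potential(0, "membrane"), 0)
  expect_equal(membrane_potential(3.5, "membrane", 10, 2.5), 5)
  expect_equal(membrane_potential(-3.5, "membrane", 10, 2.5), 5)
  expect_equal(membrane_potential(0, "cytoplasm", 10, 2.5), 31.25)
  expect_equal(membrane_potential(-3, "cytoplasm", 10, 2.5), 0)
  expect_error(membrane_potential(0, "nucleus"), "compartment")
})

test_that("energy decomposition sums exactly and matches the R oracle", {
  st <- small_mixed_state(seed = 3)
  r <- bd_run(st, 1500, seed = 8)        # generic configuration with bonds
  st <- r$state
  e <- total_energy(st)
  expect_identical(unname(e["V_total"]),
                   unname(sum(e[c("V_bond", "V_angle", "V_dihedral",
                                  "V_spe", "V_nonspe", "V_system")])))
  orc <- oracle_energy(st)
  expect_equal(unname(e["V_bond"]), unname(orc["bond"]), tolerance = 1e-10)
  expect_equal(unname(e["V_spe"]), unname(orc["spe"]), tolerance = 1e-10)
  expect_equal(unname(e["V_nonspe"]), unname(orc["ev"]), tolerance = 1e-10)
  expect_equal(unname(e["V_total"]), unname(orc["total"]), tolerance = 1e-10)
  # empty state has zero everything
  e0 <- total_energy(build_system(
    system_composition(c(PSD95 = 0L), rep(10, 3)), 1))
  expect_true(all(e0 == 0))
})

test_that("forces are the negative gradient (central differences)", {
  st <- small_mixed_state(seed = 4)
  st <- bd_run(st, 1500, seed = 2)$state
  F <- forces(st)
  h <- 1e-5
  set.seed(42)
  for (i in sample(nrow(st$pos), 8)) {
    for (a in 1:3) {
      sp <- st; sp$pos[i, a] <- sp$pos[i, a] + h
      sm <- st; sm$pos[i, a] <- sm$pos[i, a] - h
      fnum <- -(total_energy(sp)[["V_total"]] -
                  total_energy(sm)[["V_total"]]) / (2 * h)
      expect_equal(F[i, a], fnum, tolerance = 1e-5)
    }
  }
})

test_that("free diffusion has the analytic displacement statistics", {
  st <- make_fixture("ideal_gas", list(n = 400L, box = c(200, 200, 200),
                                       diffusion = 0.25))
  run <- bd_run(st, 600, seed = 31, traj_stride = 100)
  frames <- run$trajectory$frames
  # per-axis increment variance over lag 100 steps = 2 D dt nlag
  incs <- c()
  for (k in 2:length(frames)) {
    d <- frames[[k]]$pos - frames[[k - 1]]$pos
    d <- d - 200 * round(d / 200)
    incs <- c(incs, as.vector(d))
  }
  v <- var(incs)
  expected <- 2 * 0.25 * 0.25 * 100
  se <- expected * sqrt(2 / (length(incs) - 1))
  expect_lt(abs(v - expected), 4 * se)
  # 3D MSD slope = 6 D t (lag of 100 steps, minimum-image increments)
  d1 <- frames[[2]]$pos - frames[[1]]$pos
  d1 <- d1 - 200 * round(d1 / 200)
  msd <- mean(rowSums(d1^2))
  expect_equal(msd / (100 * 0.25), 6 * 0.25, tolerance = 0.15)
  # zero-force drift is zero on average
  expect_lt(abs(mean(incs)), 4 * sqrt(v / length(incs)))
})

test_that("constant force produces the mobility drift", {
  # two particles joined by a stretched stiff bond relax at D F / kB T
  st <- make_fixture("bonded_dimer", list(rest = 2, stretch = 1, k = 10,
                                          box = c(50, 50, 50)))
  F <- forces(st)
  expect_equal(F[1, 3], 10)        # k (d - rest) toward the partner
  expect_equal(F[2, 3], -10)
  expect_equal(F[1, 1:2], c(0, 0))
  # drift per step for D = 0.25, F = 10: D F dt / kBT = 0.2506 nm
  expect_equal(0.25 * 10 * 0.25 / (kB * 300), 0.2506, tolerance = 1e-3)
})

test_that("single particle under the membrane potential samples Boltzmann", {
  st <- make_fixture("ideal_gas", list(n = 48L, box = c(20, 20, 40)))
  st$mode <- "membrane_2d"
  set.seed(9)
  st$pos[, 3] <- runif(48, 23, 37)     # wrapped z in (-17, -3)
  run <- bd_run(st, 8e5, seed = 17, traj_stride = 2000)
  z <- unlist(lapply(run$trajectory$frames[-(1:80)], function(f) {
    zz <- f$pos[, 3]; zz - 40 * round(zz / 40)
  }))
  kT <- kB * 300; k <- 10; d <- 2.5; zf <- -20 + 2.5
  dens <- function(zz) ifelse(zz < zf, exp(-0.5 * k * (zz - zf)^2 / kT),
                       ifelse(zz < -d, 1, exp(-0.5 * k * (zz + d)^2 / kT)))
  zs <- seq(-20, 0, length.out = 8001)
  cdf <- cumsum(dens(zs)); cdf <- cdf / max(cdf)
  Fz <- approxfun(zs, cdf, yleft = 0, yright = 1)
  idx <- seq(1, length(z), by = 13)    # thin to decorrelate
  ks <- suppressWarnings(stats::ks.test(z[idx], Fz))
  expect_gt(ks$p.value, 0.01)
})

test_that("virial pressure matches the ideal gas and a hand virial", {
  stg <- make_fixture("ideal_gas", list(n = 200L, box = c(40, 40, 40)))
  p <- accumulate_pressure(stg)
  ideal <- 200 * kB * 300 / 40^3
  expect_equal(unname(p$components[c("Pxx", "Pyy", "Pzz")]),
               rep(ideal, 3), tolerance = 1e-12)
  expect_equal(unname(p$components[c("Pxy", "Pxz", "Pyz")]), rep(0, 3))
  expect_true(isSymmetric(p$tensor))
  # single dimer stretched along z: P_zz - P_xx = r_z F_z / V
  std <- make_fixture("bonded_dimer", list(rest = 2, stretch = 1, k = 10,
                                           box = c(30, 30, 30)))
  pd <- accumulate_pressure(std)
  # bond force on the far particle is -k*stretch along +z at separation 3
  expect_equal(unname(pd$components["Pzz"] - pd$components["Pxx"]),
               3 * (-10) / 30^3, tolerance = 1e-12)
})

test_that("runs are bit-reproducible and frames carry live bonds", {
  st <- small_mixed_state(seed = 6)
  r1 <- bd_run(st, 800, seed = 21, traj_stride = 400)
  r2 <- bd_run(st, 800, seed = 21, traj_stride = 400)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$spec_bonds, r2$state$spec_bonds)
  r3 <- bd_run(st, 800, seed = 22)
  expect_false(identical(r1$state$pos, r3$state$pos))
})
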