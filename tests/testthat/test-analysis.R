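# Trajectory observables: clustering vs the union-find oracle, profiles,
# interaction counts, effective valency, ring orientation, tension, and
# morphology classification.

test_that("cluster detection matches the brute-force union-find oracle", {
  # constructed fixture with a known partition
  st <- make_fixture("toy_cluster", list(n_cluster = 5L, n_free = 3L),
                     seed = 2)
  cl <- detect_clusters(state_frame(st)$frames[[1]], st)
  expect_identical(max(cl$sizes), 5L)
  expect_identical(sort(cl$sizes), sort(c(5L, 1L, 1L, 1L)))
  # random mixed systems, several seeds: identical partitions
  for (seed in 1:4) {
    stm <- small_mixed_state(seed = seed, box = 40)
    run <- bd_run(stm, 8000, seed = seed + 50, traj_stride = 8000)
    f <- run$trajectory$frames[[length(run$trajectory$frames)]]
    cl <- detect_clusters(f, stm)
    orc <- oracle_clusters(f, stm)
    # same partition up to label permutation
    expect_identical(length(unique(cl$membership)), length(unique(orc)))
    tab <- table(cl$membership, orc)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  # all-singleton case
  stg <- make_fixture("ideal_gas", list(n = 20L, radius = 0.1))
  clg <- detect_clusters(state_frame(stg)$frames[[1]], stg)
  expect_true(all(clg$sizes == 1L))
})

test_that("largest-cluster composition counts the constructed cluster", {
  st <- make_fixture("toy_cluster", list(n_cluster = 6L, n_free = 2L),
                     seed = 3)
  comp <- largest_cluster_composition(state_frame(st), st, window = 1)
  expect_equal(unname(comp["cluster_size"]), 6)
  expect_error(largest_cluster_composition(
    structure(list(frames = list(), box = st$box, mode = st$mode),
              class = "psd_trajectory"), st), "empty")
})

test_that("radial distribution conserves counts and sees uniform shells", {
  # spherical shell of molecules at fixed radius from the center
  st <- make_fixture("ideal_gas", list(n = 400L, box = c(60, 60, 60),
                                       radius = 1.2))
  set.seed(4)
  u <- matrix(rnorm(1200), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  st$pos <- sweep(u * 10, 2, c(30, 30, 30), "+")
  f <- state_frame(st)$frames[[1]]
  cl <- detect_clusters(f, st)         # shell at r=10: all one cluster
  rd <- radial_distribution(f, st, cl, breaks = seq(0, 14, by = 1))
  expect_equal(sum(rd$count), 400)
  expect_true(all(rd$count[rd$r < 8] == 0))
  expect_gt(sum(rd$count[rd$r > 9 & rd$r < 11]), 350)
  # normalization by the radius of gyration
  rdn <- radial_distribution(f, st, cl, normalize_rg = TRUE,
                             breaks = seq(0, 1.4, by = 0.1))
  expect_equal(attr(rdn, "rg"), 10, tolerance = 0.01)
  expect_gt(sum(rdn$count[rdn$r > 0.9 & rdn$r < 1.1]), 350)
})

test_that("axial profiles integrate to N and resolve a two-slab step", {
  st <- make_fixture("two_slab", list(n_lo = 120L, n_hi = 40L,
                                      box = c(30, 30, 60)), seed = 5)
  f <- state_frame(st)$frames[[1]]
  pr <- axial_profile(f, st, axis = "z", breaks = seq(-30, 30, by = 5))
  expect_equal(sum(pr$count), 160)
  lo <- sum(pr$count[pr$coord > 0 | pr$coord < -29])  # z in (0, 30) half
  # fixture places n_lo in stored z (0, 30) -> wrapped (0,30); n_hi in (30,60) -> (-30, 0)
  dens_lo <- mean(pr$density[pr$coord > 0])
  dens_hi <- mean(pr$density[pr$coord < 0])
  expect_equal(dens_lo / dens_hi, 3, tolerance = 0.35)
  # flat profile for an ideal gas
  stg <- make_fixture("ideal_gas", list(n = 600L, box = c(30, 30, 60)))
  prg <- axial_profile(state_frame(stg)$frames[[1]], stg, axis = "z")
  expect_equal(sum(prg$count), 600)
  expect_lt(sd(prg$density) / mean(prg$density), 0.5)
})

test_that("interaction counts match a brute-force pair scan", {
  stm <- small_mixed_state(seed = 7, box = 38)
  run <- bd_run(stm, 20000, seed = 70, traj_stride = 20000)
  f <- run$trajectory$frames[[length(run$trajectory$frames)]]
  ic <- interaction_counts(f, stm)
  # brute-force non-specific contact count
  pos <- f$pos; box <- stm$box; r <- stm$particles$radius
  mol <- stm$particles$molecule
  for (a in 1:3) {
    d <- outer(pos[, a], pos[, a], "-")
    d <- d - box[a] * round(d / box[a])
    if (a == 1) d2 <- d^2 else d2 <- d2 + d^2
  }
  cut <- (outer(r, r, "+") + 0.5)^2
  hit <- which(d2 <= cut & upper.tri(d2), arr.ind = TRUE)
  hit <- hit[mol[hit[, 1]] != mol[hit[, 2]], , drop = FALSE]
  pa <- stm$sites$particle[f$bonds$site_a]
  pb <- stm$sites$particle[f$bonds$site_b]
  bonded <- paste(pmin(pa, pb), pmax(pa, pb))
  keys <- paste(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2]))
  expect_identical(unname(sum(ic$nonspecific)),
                   as.integer(sum(!keys %in% bonded)))
  expect_identical(unname(sum(ic$specific)), nrow(f$bonds))
  # specific tallies by molecule-type pair are consistent with bond rules
  if (nrow(f$bonds)) {
    expect_true(all(grepl("\\|", names(ic$specific))))
  }
  # empty frame gives all zeros
  ic0 <- interaction_counts(state_frame(small_mixed_state(8, box = 200))$frames[[1]],
                            small_mixed_state(8, box = 200))
  expect_identical(sum(ic0$specific), 0L)
})

test_that("effective valency counts distinct NMDARs once per CaMKII", {
  st <- small_mixed_state(seed = 9, box = 40)
  # construct bonds by hand: both arms of NMDAR 1 to the same CaMKII,
  # one arm of NMDAR 2 to the same CaMKII
  ck <- st$molecules$id[st$molecules$template == "CaMKII"][1]
  nm <- st$molecules$id[st$molecules$template == "NMDAR_GluN2Bc2"]
  kin_sites <- st$sites$id[st$sites$type == "kinase_active" &
    st$particles$molecule[st$sites$particle] == ck]
  arm_sites <- function(m) st$sites$id[st$sites$type == "CaMKII_site_GluN2B" &
    st$particles$molecule[st$sites$particle] == m]
  bonds <- data.frame(
    site_a = c(arm_sites(nm[1]), arm_sites(nm[2])[1]),
    site_b = kin_sites[1:3], rule = 3L, formed_step = 0L)
  f <- list(step = 0L, pos = st$pos, bonds = bonds)
  ev <- effective_valency(f, st)
  expect_identical(sort(ev, decreasing = TRUE)[1], 2L)   # two distinct NMDARs
  # no bonds -> zeros
  expect_true(all(effective_valency(state_frame(st)$frames[[1]], st) == 0L))
  # 12 bonds from 12 distinct NMDARs would count 12: simulate by relabeling
  expect_identical(length(ev),
                   sum(st$molecules$template == "CaMKII"))
})

test_that("ring orientation reads constructed angles exactly", {
  comp <- system_composition(c(CaMKII = 1L), c(60, 60, 60),
                             mode = "membrane_2d")
  st <- build_system(comp, seed = 1)
  tpl <- build_template("CaMKII", mode = "membrane_2d")
  center <- c(30, 30, 30)
  place <- function(rot) sweep(tpl$coords %*% t(rot), 2, center, "+")
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                               0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  for (ang in c(0, 45, 90)) {
    st$pos <- place(rotx(ang * pi / 180))
    out <- camkii_orientation(list(step = 0, pos = st$pos,
                                   bonds = st$spec_bonds), st)
    expect_identical(nrow(out), 2L)   # two rings
    expect_equal(out$angle, rep(ang, 2), tolerance = 1e-6)
  }
})

test_that("Kirkwood-Buff tension: zero for ideal, positive for a bonded slab", {
  # direct substitution check
  samp <- cbind(Pxx = rep(0.004, 40), Pyy = rep(0.004, 40),
                Pzz = rep(0.01, 40))
  te <- interfacial_tension(samp, L_z = 1500)
  expect_equal(te$gamma, 0.5 * 1500 * (0.01 - 0.004))
  expect_equal(te$gamma, 4.5)
  expect_equal(te$gamma_mN_m, 4.5 * 1.66054)
  expect_error(interfacial_tension(samp[1, , drop = FALSE], 10), "samples")
  # isotropic tensor gives exactly zero
  iso <- cbind(Pxx = rep(0.01, 40), Pyy = rep(0.01, 40),
               Pzz = rep(0.01, 40))
  expect_identical(interfacial_tension(iso, 100)$gamma, 0)
  # interaction-free slab simulation: zero within 2 SE
  st <- make_fixture("ideal_gas", list(n = 150L, box = c(20, 20, 80),
                                       radius = 1))
  run <- bd_run(st, 30000, seed = 5, sample_stride = 30)
  te0 <- interfacial_tension(run$samples, 80)
  expect_lt(abs(te0$gamma), 2.5 * te0$se + 1e-6)
  # a slab under lateral bond tension (cohesive layer): known positive gamma
  stb <- make_fixture("ideal_gas", list(n = 80L, box = c(16, 16, 64),
                                        radius = 0))
  set.seed(6)
  base <- cbind(runif(40, 0, 16), runif(40, 0, 16), runif(40, 24, 40))
  dirs <- cbind(rep(c(1, 0), 20), rep(c(0, 1), 20), 0)  # in-plane axes
  stb$pos <- rbind(base, base + 3 * dirs)               # stretched to d = 3
  stb$particles$molecule <- rep(1:40, 2)
  stb$molecules <- data.frame(id = 1:40, template = "fixture")
  stb$bonds <- data.frame(i = 1:40, j = 41:80, rest = 2, k = 5,
                          kind = "harmonic")
  stb$particles$diffusion <- 1e-8                       # hold the network
  runb <- bd_run(stb, 3000, seed = 7, sample_stride = 10)
  teb <- interfacial_tension(runb$samples, 64)
  # each stretched bond adds r.F = 3 * (-5) to one lateral component:
  # gamma = L_z/2 * 300/V
  expect_equal(teb$gamma, 0.5 * 64 * 300 / (16 * 16 * 64), tolerance = 0.1)
  expect_gt(teb$gamma, 2 * teb$se)
})

test_that("morphology classification reproduces the tension inequalities", {
  expect_identical(classify_morphology(3, 1, 1)$label, "core_shell_A_core")
  expect_identical(classify_morphology(1, 3, 1)$label, "core_shell_N_core")
  expect_identical(classify_morphology(1, 1, 3)$label, "segregated")
  expect_identical(classify_morphology(1.2, 1.0, 0.5)$label, "janus")
  m <- classify_morphology(3, 1, 1)
  expect_gt(m$margins["core_shell_A_core"], 0)
  expect_lt(m$margins["segregated"], 0)
  expect_error(classify_morphology(-1, 1, 1), ">= 0")
})

test_that("phase assignment conserves composition and labels known lobes", {
  # two constructed lobes: AMPAR-rich left, NMDAR-rich right, one far-away
  comp <- system_composition(
    c(AMPAR_TARP4 = 4L, NMDAR_GluN2Bc2 = 4L, PSD95 = 0L, CaMKII = 0L),
    rep(120, 3), mode = "solution_3d")
  st <- build_system(comp, seed = 3)
  # re-place molecules: AMPARs touching at x ~ 30, NMDARs at x ~ 44, one
  # NMDAR isolated
  mv <- function(m, target) {
    idx <- which(st$particles$molecule == m)
    ref <- colMeans(st$pos[idx, , drop = FALSE])
    st$pos[idx, ] <<- sweep(st$pos[idx, , drop = FALSE], 2, target - ref, "+")
  }
  am <- st$molecules$id[st$molecules$template == "AMPAR_TARP4"]
  nm <- st$molecules$id[st$molecules$template == "NMDAR_GluN2Bc2"]
  for (k in 1:4) mv(am[k], c(22 + 6 * k, 60, 60))
  for (k in 1:3) mv(nm[k], c(46 + 6 * k, 60, 60))
  mv(nm[4], c(110, 20, 20))
  f <- state_frame(st)$frames[[1]]
  lab <- phase_assignment(f, st)
  expect_identical(lab[am], rep("A_phase", 4))
  expect_identical(lab[nm[1:3]][3], "N_phase")
  expect_identical(lab[nm[4]], "dilute")
  # conservation: every molecule gets exactly one label
  expect_identical(length(lab), nrow(st$molecules))
  expect_true(all(lab %in% c("A_phase", "N_phase", "dilute")))
})
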