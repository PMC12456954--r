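# Stochastic binding reactions: rate limits, valency exclusion, mutual
# exclusion, survival statistics, and the K_d estimator.

# run a short stochastic trajectory of a small mixed system and return the
# per-frame bond tables together with the state
sampled_run <- function(seed, n_steps = 40000, rules = NULL,
                        variant = variant_spec(), stride = 2000) {
  st <- small_mixed_state(seed = seed, variant = variant, box = 35)
  run <- bd_run(st, n_steps, seed = seed + 100, rules = rules,
                traj_stride = stride)
  list(state = run$state, frames = run$trajectory$frames)
}

test_that("zero on-rate never binds; zero off-rate never unbinds", {
  rules <- default_rules()
  rules$lambda_on <- 0
  r <- sampled_run(1, 20000, rules = rules)
  expect_identical(nrow(r$state$spec_bonds), 0L)
  for (f in r$frames) expect_identical(nrow(f$bonds), 0L)

  rules <- default_rules()
  rules$lambda_off <- 0
  rules$lambda_on <- 50           # near-instant on contact
  r <- sampled_run(2, 20000, rules = rules)
  nb <- vapply(r$frames, function(f) nrow(f$bonds), integer(1))
  expect_true(all(diff(nb) >= 0))  # bonds only accumulate
  expect_gt(nrow(r$state$spec_bonds), 0)
})

test_that("large off-rate breaks every bond each step", {
  # lambda_off dt >> 1 ensures p_off ~ 1: a bond formed in one sweep is
  # gone by the next sampled frame
  rules <- default_rules()
  rules$lambda_off <- 1e3
  r <- sampled_run(3, 20000, rules = rules, stride = 997)
  nb <- vapply(r$frames, function(f) nrow(f$bonds), integer(1))
  expect_true(all(nb == 0L))
})

test_that("valency and mutual exclusion hold at every sampled frame", {
  r <- sampled_run(4, 60000)
  st <- r$state
  for (f in r$frames) {
    if (!nrow(f$bonds)) next
    # each site occupies at most one bond
    expect_false(any(duplicated(c(f$bonds$site_a, f$bonds$site_b))))
    # per-PDZ occupancy <= 1 follows; also no PDZ holds two PBM types
    pdz <- st$sites$id[st$sites$type == "PDZ"]
    occ <- c(f$bonds$site_a, f$bonds$site_b)
    expect_lte(max(table(factor(occ[occ %in% pdz], levels = pdz))), 1)
    # a CaMKII molecule carries at most 12 bonds
    pa <- st$sites$particle[f$bonds$site_a]
    pb <- st$sites$particle[f$bonds$site_b]
    mols <- c(st$particles$molecule[pa], st$particles$molecule[pb])
    ck <- st$molecules$id[st$molecules$template == "CaMKII"]
    if (length(ck)) expect_lte(max(0, table(mols[mols %in% ck])), 12)
  }
})

test_that("inactive CaMKII forms no specific bonds over a trajectory", {
  r <- sampled_run(5, 60000, variant = variant_spec("inactive"))
  st <- r$state
  ck <- st$molecules$id[st$molecules$template == "CaMKII"]
  for (f in r$frames) {
    if (!nrow(f$bonds)) next
    pa <- st$sites$particle[f$bonds$site_a]
    pb <- st$sites$particle[f$bonds$site_b]
    mols <- c(st$particles$molecule[pa], st$particles$molecule[pb])
    expect_false(any(mols %in% ck))
  }
})

test_that("a GluN2Bc arm can hold PSD-95 and CaMKII simultaneously", {
  # the two site types on one GluN2Bc particle are independent, so a frame
  # can carry both a PBM-PDZ and a CaMKII-site-kinase bond on the same arm
  r <- sampled_run(6, 150000)
  st <- r$state
  seen_both <- FALSE
  for (f in r$frames) {
    if (nrow(f$bonds) < 2) next
    typ_a <- st$sites$type[f$bonds$site_a]
    arm <- st$sites$particle[f$bonds$site_a]
    pdz_arms <- arm[typ_a == "PBM_GluN2B"]
    kin_arms <- arm[typ_a == "CaMKII_site_GluN2B"]
    if (length(intersect(pdz_arms, kin_arms))) seen_both <- TRUE
  }
  expect_true(seen_both)
})

test_that("competing PBMs split a single PDZ roughly evenly", {
  # one free PDZ particle between two TARPc peptides, all nearly immobile:
  # long-run occupancy divides ~50/50 and never doubles up
  params <- domain_params()
  st <- psdmeso:::.free_domain_state(
    list("PSD95_PDZ1", "TARPc", "TARPc"), rep(30, 3), variant_spec(), 1)
  r_pdz <- st$particles$radius[1]
  r_t <- st$particles$radius[2]
  st$pos[1, ] <- c(15, 15, 15)
  st$pos[2, ] <- c(15 + r_pdz + r_t + 0.2, 15, 15)
  st$pos[3, ] <- c(15 - r_pdz - r_t - 0.2, 15, 15)
  st$particles$diffusion <- 1e-9      # hold the geometry
  rules <- default_rules()
  rules$lambda_on <- 0.5
  rules$lambda_off <- 0.02
  run <- bd_run(st, 120000, seed = 9, rules = rules, traj_stride = 50)
  occ <- vapply(run$trajectory$frames, function(f) {
    if (!nrow(f$bonds)) return(0L)
    expect_identical(nrow(f$bonds), 1L)   # never more than one per PDZ
    p <- st$sites$particle[f$bonds$site_a]
    if (st$sites$type[f$bonds$site_a][1] == "PDZ")
      p <- st$sites$particle[f$bonds$site_b]
    as.integer(p)
  }, integer(1))
  n2 <- sum(occ == 2); n3 <- sum(occ == 3)
  expect_gt(n2 + n3, 200)
  expect_lt(abs(n2 - n3) / (n2 + n3), 0.25)
})

test_that("bond survival times are exponential with mean 1/lambda_off", {
  st <- psdmeso:::.free_domain_state(
    list("PSD95_PDZ1", "TARPc"), rep(25, 3), variant_spec(), 2)
  st$pos[1, ] <- c(12, 12, 12)
  st$pos[2, ] <- c(12 + sum(st$particles$radius) + 0.2, 12, 12)
  st$particles$diffusion <- 1e-9
  rules <- default_rules()
  rules$lambda_on <- 20               # rebinds almost immediately
  rules$lambda_off <- 0.02            # mean lifetime 50 ns = 200 steps
  run <- bd_run(st, 3e5, seed = 3, rules = rules, sample_stride = 1)
  bound <- run$samples[, "n_bonds"] > 0
  rl <- rle(bound)
  lifetimes <- rl$lengths[rl$values] * 0.25   # ns
  expect_gt(length(lifetimes), 450)
  expect_equal(mean(lifetimes), 1 / 0.02,
               tolerance = 5 / sqrt(length(lifetimes)))
  # exponential shape: CV ~ 1
  expect_equal(sd(lifetimes) / mean(lifetimes), 1, tolerance = 0.15)
})

test_that("apparent_kd reproduces its closed form and flags edge cases", {
  v100 <- 100^3
  # P_b = P_u = 0.5 in a (100 nm)^3 box: 0.25/0.5 / (N_A V) ~ 0.83 uM
  tr <- rep(c(TRUE, FALSE), 5000)
  est <- apparent_kd(tr, v100, discard = 0)
  expect_equal(est$kd, 0.5^2 / 0.5 * count_to_uM(1, v100))
  expect_equal(est$kd, 0.830, tolerance = 1e-2)
  expect_equal(count_to_uM(1, v100), 1.66, tolerance = 1e-2)
  # P_b -> 1 drives K_d -> 0; never-bound is flagged above range
  expect_lt(apparent_kd(c(FALSE, rep(TRUE, 9999)), v100, discard = 0)$kd,
            1e-3)
  never <- apparent_kd(rep(FALSE, 1000), v100, discard = 0)
  expect_true(never$above_range)
  expect_identical(never$kd, Inf)
})
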