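# Potential-energy terms, the overdamped Langevin propagator, and virial
# pressure.  Scalar energy forms are exposed directly; system-level
# evaluation and time propagation run in the compiled core.

#' Harmonic bond energy
#'
#' `V = 1/2 k (d - rest)^2`; the force is the negative gradient along the
#' pair axis.
#'
#' @param d inter-particle distance in nm
#' @param rest rest length in nm
#' @param k spring constant in kJ/mol/nm^2
#' @return energy in kJ/mol
#' @export
harmonic_bond_energy <- function(d, rest, k) {
  if (any(k < 0)) stop("k must be non-negative")
  if (any(d < 0)) stop("d must be non-negative")
  0.5 * k * (d - rest)^2
}

#' Gaussian linker energy
#'
#' Entropic-spring energy of a flexible linker, `V = 1/2 k_link d^2` with
#' `k_link = 3 kB T / (n_link b^2)`.
#'
#' @param d end-to-end distance in nm
#' @param n_link number of linker residues
#' @param b Kuhn length in nm
#' @param temperature temperature in K
#' @return energy in kJ/mol
#' @export
gaussian_linker_energy <- function(d, n_link, b = 0.38, temperature = 300) {
  0.5 * linker_spring_constant(n_link, b, temperature) * d^2
}

#' Soft excluded-volume energy
#'
#' Purely repulsive harmonic overlap penalty:
#' `V = 1/2 k_rep (d - r_i - r_j)^2` for `d < r_i + r_j`, zero beyond
#' contact.
#'
#' @param d center distance in nm
#' @param r_i,r_j particle radii in nm
#' @param k_rep repulsive spring constant in kJ/mol/nm^2
#' @return energy in kJ/mol
#' @export
excluded_volume_energy <- function(d, r_i, r_j, k_rep = 10) {
  if (any(k_rep < 0)) stop("k_rep must be non-negative")
  if (any(d < 0)) stop("d must be non-negative")
  contact <- r_i + r_j
  ifelse(d < contact, 0.5 * k_rep * (d - contact)^2, 0)
}

#' Implicit membrane potential
#'
#' Membrane-compartment domains are held inside the slab `|z| < d_mem2`
#' (flat bottom, harmonic walls); cytoplasmic domains are excluded from the
#' membrane and above, i.e. confined to `z < -d_mem2`.
#'
#' @param z z coordinate in nm (membrane center at z = 0)
#' @param compartment "membrane" or "cytoplasm"
#' @param k_mem membrane spring constant in kJ/mol/nm^2
#' @param d_mem2 half membrane thickness in nm
#' @return energy in kJ/mol
#' @export
membrane_potential <- function(z, compartment, k_mem = 10, d_mem2 = 2.5) {
  if (!all(compartment %in% c("membrane", "cytoplasm"))) {
    stop("unknown compartment")
  }
  ifelse(compartment == "membrane",
         ifelse(abs(z) < d_mem2, 0, 0.5 * k_mem * (abs(z) - d_mem2)^2),
         ifelse(z < -d_mem2, 0, 0.5 * k_mem * (z + d_mem2)^2))
}

#' Force-field parameters
#'
#' @param k_rep excluded-volume spring constant, kJ/mol/nm^2
#' @param k_mem membrane spring constant, kJ/mol/nm^2 (before any
#'   `membrane_k_scale` from the variant)
#' @param d_mem2 half membrane thickness in nm
#' @return object of class `psd_ff`
#' @export
force_field_params <- function(k_rep = 10, k_mem = 10, d_mem2 = 2.5) {
  if (k_rep < 0 || k_mem < 0) stop("spring constants must be non-negative")
  if (d_mem2 <= 0) stop("d_mem2 must be positive")
  structure(list(k_rep = k_rep, k_mem = k_mem, d_mem2 = d_mem2),
            class = "psd_ff")
}

#' Thermostat / integrator settings
#'
#' @param temperature temperature in K
#' @param viscosity_cyto cytoplasmic viscosity in mPa s
#' @param viscosity_mem membrane viscosity in mPa s (10x cytoplasmic)
#' @param dt timestep in ns
#' @return object of class `psd_thermostat`
#' @export
thermostat <- function(temperature = 300, viscosity_cyto = 0.89,
                       viscosity_mem = 8.9, dt = 0.25) {
  if (dt <= 0 || temperature <= 0) stop("dt and temperature must be positive")
  structure(list(temperature = temperature,
                 viscosity_cyto = viscosity_cyto,
                 viscosity_mem = viscosity_mem, dt = dt),
            class = "psd_thermostat")
}

# Default force field derived from a state's variant.
.ff_for_state <- function(state, ff = NULL) {
  v <- state$variant
  if (is.null(ff)) ff <- force_field_params(d_mem2 = v$membrane_half_thickness)
  ff$k_mem_eff <- ff$k_mem * v$membrane_k_scale
  ff
}

# Marshal a psd_state (+ rules) into the flat argument set of the core.
.sys_args <- function(state, ff, thermo, rules, confinement = NULL) {
  p <- state$particles
  n <- nrow(state$pos)
  memb <- state$mode == "membrane_2d"
  diff <- p$diffusion
  if (memb && n > 0) {
    fac <- thermo$viscosity_mem / thermo$viscosity_cyto
    diff[p$compartment == "membrane"] <-
      diff[p$compartment == "membrane"] / fac
  }
  sb <- state$bonds
  sites <- state$sites
  if (is.null(rules)) rules <- default_rules(state$variant, mode = state$mode)
  rl <- list(
    ta = match(rules$site_a, site_type_levels) - 1L,
    tb = match(rules$site_b, site_type_levels) - 1L,
    r_react = rules$r_react,
    lambda_on = rules$lambda_on,
    lambda_off = rules$lambda_off,
    bond_rest = rules$bond_rest,
    bond_k = rules$bond_k)
  if (anyNA(rl$ta) || anyNA(rl$tb)) stop("unknown site type in rules")
  bonds0 <- as.matrix(state$spec_bonds[c("site_a", "site_b", "rule",
                                         "formed_step")])
  storage.mode(bonds0) <- "integer"
  bonds0[, 1:3] <- bonds0[, 1:3] - 1L
  conf <- confinement
  list(
    pos = state$pos, box = state$box,
    radius = p$radius, diff = diff,
    comp = as.integer(p$compartment == "membrane"),
    mol = as.integer(p$molecule),
    sbond = {
      m <- cbind(as.integer(sb$i) - 1L, as.integer(sb$j) - 1L)
      storage.mode(m) <- "integer"; m
    },
    sbond_rest = as.numeric(sb$rest), sbond_k = as.numeric(sb$k),
    site_particle = as.integer(sites$particle) - 1L,
    site_type = match(sites$type, site_type_levels) - 1L,
    site_active = as.integer(sites$active),
    rules = rl, bonds0 = bonds0,
    membrane_on = memb,
    k_mem = ff$k_mem_eff %||% ff$k_mem,
    d_mem2 = ff$d_mem2,
    conf_on = !is.null(conf),
    conf_lo = conf$lo %||% 0, conf_hi = conf$hi %||% 0,
    conf_k = conf$k %||% 0,
    conf_release = as.integer(conf$release_step %||% -1L),
    k_rep = ff$k_rep, kT = kB * thermo$temperature, dt = thermo$dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total potential energy decomposition
#'
#' Evaluates every term of the total potential
#' `V_total = V_bond + V_angle + V_dihedral + V_spe + V_nonspe + V_system`
#' for the current state.  Angle/dihedral slots are zero (no such terms in
#' the default parameterization; the CaMKII shape is maintained by its bond
#' network).
#'
#' @param state a `psd_state`
#' @param ff a [force_field_params()] (default derived from the variant)
#' @param thermo a [thermostat()]
#' @param rules reaction-rule table (default [default_rules()])
#' @param confinement optional list(lo, hi, k, release_step) z-confinement
#' @return named numeric vector of the six terms plus `V_total`
#' @export
total_energy <- function(state, ff = NULL, thermo = thermostat(),
                         rules = NULL, confinement = NULL) {
  ff <- .ff_for_state(state, ff)
  a <- .sys_args(state, ff, thermo, rules, confinement)
  res <- cpp_energy_forces(a$pos, a$box, a$radius, a$diff, a$comp, a$mol,
                           a$sbond, a$sbond_rest, a$sbond_k,
                           a$site_particle, a$site_type, a$site_active,
                           a$rules, a$bonds0, a$membrane_on, a$k_mem,
                           a$d_mem2, a$conf_on, a$conf_lo, a$conf_hi,
                           a$conf_k, a$conf_release, a$k_rep, a$kT, a$dt,
                           TRUE)
  res$energy
}

#' Forces on all particles
#'
#' Negative gradient of the total potential; one row per particle.
#' @inheritParams total_energy
#' @return N x 3 matrix of forces in kJ/mol/nm
#' @export
forces <- function(state, ff = NULL, thermo = thermostat(), rules = NULL,
                   confinement = NULL) {
  ff <- .ff_for_state(state, ff)
  a <- .sys_args(state, ff, thermo, rules, confinement)
  res <- cpp_energy_forces(a$pos, a$box, a$radius, a$diff, a$comp, a$mol,
                           a$sbond, a$sbond_rest, a$sbond_k,
                           a$site_particle, a$site_type, a$site_active,
                           a$rules, a$bonds0, a$membrane_on, a$k_mem,
                           a$d_mem2, a$conf_on, a$conf_lo, a$conf_hi,
                           a$conf_k, a$conf_release, a$k_rep, a$kT, a$dt,
                           TRUE)
  res$forces
}

#' Instantaneous virial pressure tensor
#'
#' `P_ab = (1/V) (N kB T delta_ab + sum_pairs r_ij,a F_ij,b)` over all
#' pairwise and bonded interactions with minimum-image separations.
#' External (membrane, confinement) forces are excluded from the virial.
#'
#' @inheritParams total_energy
#' @return list with `tensor` (symmetric 3 x 3 matrix, kJ/mol/nm^3) and
#'   `components` (named vector Pxx..Pyz)
#' @export
accumulate_pressure <- function(state, ff = NULL, thermo = thermostat(),
                                rules = NULL) {
  if (prod(state$box) <= 0) stop("zero box volume")
  ff <- .ff_for_state(state, ff)
  a <- .sys_args(state, ff, thermo, rules, NULL)
  res <- cpp_energy_forces(a$pos, a$box, a$radius, a$diff, a$comp, a$mol,
                           a$sbond, a$sbond_rest, a$sbond_k,
                           a$site_particle, a$site_type, a$site_active,
                           a$rules, a$bonds0, a$membrane_on, a$k_mem,
                           a$d_mem2, a$conf_on, a$conf_lo, a$conf_hi,
                           a$conf_k, a$conf_release, a$k_rep, a$kT, a$dt,
                           FALSE)
  pc <- res$pressure
  tens <- matrix(c(pc["Pxx"], pc["Pxy"], pc["Pxz"],
                   pc["Pxy"], pc["Pyy"], pc["Pyz"],
                   pc["Pxz"], pc["Pyz"], pc["Pzz"]), 3, 3)
  list(tensor = tens, components = pc)
}

#' Run Brownian dynamics
#'
#' Advances the overdamped Langevin equation: per particle and step the
#' displacement is `(D_i/kB T) F_i dt + sqrt(2 D_i dt) xi` with standard
#' normal `xi` per axis, drawn in fixed particle order from a single
#' explicit random stream (reproducible for a given seed at one thread).
#' Binding/unbinding sweeps run every step; membrane-compartment particles
#' use the 10x membrane viscosity in membrane mode.
#'
#' @param state a `psd_state`
#' @param n_steps number of timesteps
#' @param seed integer seed for the run's random stream (ignored if
#'   `rng_state` given)
#' @param ff a [force_field_params()]
#' @param thermo a [thermostat()]
#' @param rules reaction-rule table (default [default_rules()]); pass a
#'   zero-row table to disable reactions
#' @param sample_stride record pressure/energy/bond-count samples every this
#'   many steps (0 = never)
#' @param traj_stride record trajectory frames every this many steps
#'   (0 = never)
#' @param confinement optional list(lo, hi, k, release_step): harmonic
#'   z-confinement to `[lo, hi]`, removed at `release_step` (global step)
#' @param rng_state optional packed RNG state from a previous run (resume)
#' @return list with the updated `state`, `samples` matrix, `trajectory`
#'   (class `psd_trajectory`), and `rng_state`
#' @export
bd_run <- function(state, n_steps, seed = 1L, ff = NULL,
                   thermo = thermostat(), rules = NULL,
                   sample_stride = 0L, traj_stride = 0L,
                   confinement = NULL, rng_state = NULL) {
  stopifnot(inherits(state, "psd_state"), n_steps >= 0)
  ff <- .ff_for_state(state, ff)
  if (is.null(rules)) rules <- default_rules(state$variant, mode = state$mode)
  a <- .sys_args(state, ff, thermo, rules, confinement)
  res <- cpp_run(a$pos, a$box, a$radius, a$diff, a$comp, a$mol,
                 a$sbond, a$sbond_rest, a$sbond_k,
                 a$site_particle, a$site_type, a$site_active,
                 a$rules, a$bonds0, a$membrane_on, a$k_mem, a$d_mem2,
                 a$conf_on, a$conf_lo, a$conf_hi, a$conf_k, a$conf_release,
                 a$k_rep, a$kT, a$dt,
                 as.integer(n_steps), as.integer(state$step),
                 as.integer(sample_stride), as.integer(traj_stride),
                 as.numeric(seed), rng_state)
  state$pos <- res$pos
  state$spec_bonds <- .bonds_from_cpp(res$bonds)
  state$step <- res$step
  traj <- structure(list(frames = lapply(res$frames, function(f) {
    list(step = f$step, pos = f$pos, bonds = .bonds_from_cpp(f$bonds))
  }), box = state$box, mode = state$mode), class = "psd_trajectory")
  list(state = state, samples = res$samples, trajectory = traj,
       rng_state = res$rng_state)
}

.bonds_from_cpp <- function(bm) {
  data.frame(site_a = bm[, 1] + 1L, site_b = bm[, 2] + 1L,
             rule = bm[, 3] + 1L, formed_step = bm[, 4])
}

#' Advance a single Brownian-dynamics step
#'
#' @inheritParams bd_run
#' @return the updated `psd_state`
#' @export
bd_step <- function(state, seed = 1L, ff = NULL, thermo = thermostat(),
                    rules = NULL, rng_state = NULL) {
  bd_run(state, 1L, seed = seed, ff = ff, thermo = thermo, rules = rules,
         rng_state = rng_state)$state
}
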