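# Named simulation scenarios: the 3D cubic solution system, the 2D
# membrane system, and the 3D slab systems used for interfacial-tension
# measurement.  Reference compositions: 135 AMPAR(TARP)4, 240 PSD-95,
# 90 NMDAR(GluN2Bc)2, 60 CaMKII in a 155.362 nm cubic box; PSD-95 copies
# chosen so that total PDZ domains equal the total of their binding
# clients (4 TARPc per AMPAR + 2 GluN2Bc per NMDAR).

.ref_counts <- c(AMPAR_TARP4 = 135L, NMDAR_GluN2Bc2 = 90L,
                 PSD95 = 240L, CaMKII = 60L)
.ref_box_3d <- 155.362
.ref_box_2d <- 500
.ref_steps <- 8e7

# Scale counts by scale^3, preserving the PDZ stoichiometry identity
# 3 * PSD95 = 4 * AMPAR + 2 * NMDAR by minimally incrementing AMPAR.
.scaled_counts <- function(scale) {
  a <- max(1L, as.integer(round(.ref_counts[["AMPAR_TARP4"]] * scale^3)))
  n <- max(1L, as.integer(round(.ref_counts[["NMDAR_GluN2Bc2"]] * scale^3)))
  cc <- max(1L, as.integer(round(.ref_counts[["CaMKII"]] * scale^3)))
  while ((4L * a + 2L * n) %% 3L != 0L) a <- a + 1L
  c(AMPAR_TARP4 = a, NMDAR_GluN2Bc2 = n, PSD95 = (4L * a + 2L * n) %/% 3L,
    CaMKII = cc)
}

.scenario <- function(name, composition, n_steps, replicas = 3L,
                      confinement = NULL, traj_stride = NULL,
                      sample_stride = NULL, production = NULL) {
  structure(list(name = name, composition = composition,
                 n_steps = as.double(n_steps), replicas = as.integer(replicas),
                 confinement = confinement,
                 traj_stride = traj_stride %||% max(1, round(n_steps / 100)),
                 sample_stride = sample_stride %||% max(1, round(n_steps / 2e4)),
                 production = production),
            class = "psd_scenario")
}

#' 3D cubic-box solution scenario
#'
#' Four soluble complexes in a periodic cubic box.  At `scale = 1` this is
#' the reference system (135/90/240/60 molecules, 155.362 nm box,
#' 8e7 steps); `scale < 1` shrinks the box edge linearly and the counts by
#' `scale^3` while preserving the PDZ = TARPc + GluN2Bc stoichiometry.
#'
#' @param variant a [variant_spec()]
#' @param scale linear scale factor in (0, 1]
#' @param n_steps step budget (default: reference budget times `scale^3`
#'   when scaled down, floor 1e6)
#' @return object of class `psd_scenario`
#' @export
scenario_3d <- function(variant = variant_spec(), scale = 1,
                        n_steps = NULL) {
  if (!(scale > 0 && scale <= 1)) stop("scale must be in (0, 1]")
  counts <- .scaled_counts(scale)
  if (any(counts == 0L)) stop("scale yields zero copies of a species")
  if (is.null(n_steps)) {
    n_steps <- if (scale == 1) .ref_steps else max(1e6, .ref_steps * scale^3)
  }
  comp <- system_composition(counts, rep(.ref_box_3d * scale, 3),
                             mode = "solution_3d", variant = variant)
  .scenario(paste0("3d_", variant$camkii_state), comp, n_steps)
}

#' 2D membrane scenario
#'
#' Same composition as the 3D system; receptors and the PSD-95 palmitoyl
#' particle are embedded in the membrane plane at the box center, all other
#' domains diffuse in the cytoplasm below it, and membrane potentials are
#' active.  Because counts scale with `scale^3`, the box edge scales with
#' `scale^(3/2)` so that the surface density on the membrane — the
#' intensive state of a 2D system — is preserved on scale-down.
#'
#' @inheritParams scenario_3d
#' @return object of class `psd_scenario`
#' @export
scenario_2d <- function(variant = variant_spec(), scale = 1,
                        n_steps = NULL) {
  if (!(scale > 0 && scale <= 1)) stop("scale must be in (0, 1]")
  counts <- .scaled_counts(scale)
  if (any(counts == 0L)) stop("scale yields zero copies of a species")
  if (is.null(n_steps)) {
    n_steps <- if (scale == 1) .ref_steps else max(1e6, .ref_steps * scale^3)
  }
  comp <- system_composition(counts, rep(.ref_box_2d * scale^1.5, 3),
                             mode = "membrane_2d", variant = variant)
  .scenario(paste0("2d_", variant$camkii_state), comp, n_steps)
}

#' 3D slab scenario for interfacial-tension measurement
#'
#' An elongated periodic box: molecules are first confined to a central
#' z-slab by a harmonic confinement potential for the equilibration leg,
#' then released and run in a longer box for the production leg, from whose
#' pressure-tensor samples the Kirkwood-Buff tension is estimated.  Phase
#' compositions follow the cubic-box stoichiometry: the AMPAR-containing
#' phase holds AMPAR(TARP)4 with proportional PSD-95; the NMDAR-containing
#' phase holds NMDAR, proportional PSD-95, and the dense-phase share of
#' CaMKII; the combined slab is their union.
#'
#' @param phase "A_phase", "N_phase" or "AN_combined"
#' @param variant a [variant_spec()]
#' @param scale linear scale of the cross-section and counts
#' @param camkii_dense_frac fraction of total CaMKII assigned to the
#'   NMDAR-containing phase (dense-phase share observed in the cubic run)
#' @return object of class `psd_scenario`, with `confinement` set for the
#'   equilibration leg and `production` holding the elongated-box settings
#' @export
scenario_slab <- function(phase = c("A_phase", "N_phase", "AN_combined"),
                          variant = variant_spec(), scale = 1,
                          camkii_dense_frac = 37 / 60) {
  phase <- match.arg(phase)
  base <- .scaled_counts(scale)
  a <- base[["AMPAR_TARP4"]]; n <- base[["NMDAR_GluN2Bc2"]]
  cc <- base[["CaMKII"]]
  counts <- switch(phase,
    A_phase = c(AMPAR_TARP4 = a, NMDAR_GluN2Bc2 = 0L,
                PSD95 = as.integer(ceiling(4 * a / 3)), CaMKII = 0L),
    N_phase = c(AMPAR_TARP4 = 0L, NMDAR_GluN2Bc2 = n,
                PSD95 = as.integer(ceiling(2 * n / 3)),
                CaMKII = as.integer(round(camkii_dense_frac * cc))),
    AN_combined = c(AMPAR_TARP4 = a, NMDAR_GluN2Bc2 = n,
                    PSD95 = base[["PSD95"]],
                    CaMKII = as.integer(round(camkii_dense_frac * cc))))
  box_eq <- c(50, 50, 500) * scale
  box_prod <- c(50, 50, 1500) * scale
  comp <- system_composition(counts, box_eq, mode = "slab",
                             variant = variant)
  n_eq <- if (scale == 1) 4e6 else max(2e5, 4e6 * scale^3)
  n_prod <- if (scale == 1) 2e7 else max(1e6, 2e7 * scale^3)
  conf <- list(lo = -50 * scale, hi = 50 * scale, k = 10,
               release_step = n_eq)
  sc <- .scenario(paste0("slab_", phase), comp, n_eq, replicas = 1L,
                  confinement = conf,
                  production = list(box = box_prod, n_steps = n_prod))
  sc
}

#' Run a scenario
#'
#' Builds the system, runs the step budget (confinement leg then, for slab
#' scenarios, the production leg in the elongated box), and returns the
#' final state, trajectory and samples.  Replicas differ only in the
#' random stream.
#'
#' @param scenario a `psd_scenario`
#' @param seed run seed
#' @param rules reaction-rule table (default [default_rules()] for the
#'   scenario's variant)
#' @param thermo a [thermostat()]
#' @param n_steps optional override of the scenario step budget
#' @param traj_stride,sample_stride optional overrides
#' @return list(state, trajectory, samples, production_samples, rng_state)
#' @export
run_scenario <- function(scenario, seed = 1L, rules = NULL,
                         thermo = thermostat(), n_steps = NULL,
                         traj_stride = NULL, sample_stride = NULL) {
  stopifnot(inherits(scenario, "psd_scenario"))
  comp <- scenario$composition
  if (is.null(rules)) rules <- default_rules(comp$variant, mode = comp$mode)
  st <- build_system(comp, seed)
  ns <- n_steps %||% scenario$n_steps
  run <- bd_run(st, ns, seed = seed + 7L, rules = rules, thermo = thermo,
                sample_stride = sample_stride %||% scenario$sample_stride,
                traj_stride = traj_stride %||% scenario$traj_stride,
                confinement = scenario$confinement)
  prod_samples <- NULL
  if (!is.null(scenario$production)) {
    st2 <- run$state
    st2$box <- scenario$production$box
    # re-center the slab in the elongated box; coordinates carry over
    np <- scenario$production$n_steps
    run2 <- bd_run(st2, np, rules = rules, thermo = thermo,
                   sample_stride = sample_stride %||%
                     max(1, round(np / 2e4)),
                   traj_stride = traj_stride %||% max(1, round(np / 50)),
                   rng_state = run$rng_state)
    prod_samples <- run2$samples
    run$state <- run2$state
    run$trajectory$frames <- c(run$trajectory$frames,
                               run2$trajectory$frames)
    run$trajectory$box <- st2$box
    run$rng_state <- run2$rng_state
  }
  list(state = run$state, trajectory = run$trajectory,
       samples = run$samples, production_samples = prod_samples,
       rng_state = run$rng_state, scenario = scenario, seed = seed)
}

#' @export
print.psd_scenario <- function(x, ...) {
  cat("psd_scenario", x$name, "\n")
  cat("  counts:", paste(names(x$composition$counts),
                         x$composition$counts, collapse = ", "), "\n")
  cat("  box [nm]:", paste(signif(x$composition$box, 6), collapse = " x "),
      " mode:", x$composition$mode, "\n")
  cat("  n_steps:", format(x$n_steps, scientific = TRUE),
      " replicas:", x$replicas, "\n")
  invisible(x)
}
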