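# Persistence and fixtures: a line-oriented text trajectory format,
# extended-XYZ export for visualization tools, bitwise checkpoint/resume,
# and deterministic analytic fixtures for testing.

#' Write a trajectory to a text file
#'
#' Line-oriented format: a header with particle count, box, mode and seed,
#' then per frame a `FRAME <step> <n_bonds>` record, one `x y z` line per
#' particle, and one `site_a site_b rule formed_step` line per live bond.
#'
#' @param traj a `psd_trajectory`
#' @param state originating `psd_state` (for the header)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(state$pos)
  writeLines(c(
    "psdmeso-trajectory 1",
    paste("particles", n),
    paste("box", paste(format(state$box, digits = 17), collapse = " ")),
    paste("mode", state$mode),
    paste("seed", state$seed %||% NA),
    paste("frames", length(traj$frames))), con)
  for (f in traj$frames) {
    writeLines(paste("FRAME", f$step, nrow(f$bonds)), con)
    writeLines(sprintf("%.17g %.17g %.17g",
                       f$pos[, 1], f$pos[, 2], f$pos[, 3]), con)
    if (nrow(f$bonds)) {
      writeLines(sprintf("%d %d %d %d", f$bonds$site_a, f$bonds$site_b,
                         f$bonds$rule, f$bonds$formed_step), con)
    }
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' A truncated file is recovered up to the last complete frame, with a
#' warning naming the last good frame index.
#'
#' @param path file path
#' @return a `psd_trajectory` with attributes `n_particles`, `box`,
#'   `mode`, `seed`
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !startsWith(lines[1], "psdmeso-trajectory")) {
    stop("not a psdmeso trajectory file: ", path)
  }
  field <- function(i, name) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    stopifnot(parts[1] == name)
    parts[-1]
  }
  n <- as.integer(field(2, "particles"))
  box <- as.numeric(field(3, "box"))
  mode <- field(4, "mode")
  seed <- suppressWarnings(as.integer(field(5, "seed")))
  frames <- list()
  i <- 7L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (hdr[1] != "FRAME") break
    step <- as.integer(hdr[2]); nb <- as.integer(hdr[3])
    last <- i + n + nb
    if (last > length(lines)) {
      warning("truncated trajectory; recovered ", length(frames),
              " complete frame(s)")
      break
    }
    pos <- if (n > 0) {
      matrix(scan(text = lines[(i + 1L):(i + n)], quiet = TRUE),
             ncol = 3, byrow = TRUE)
    } else matrix(numeric(0), 0, 3)
    bonds <- if (nb > 0) {
      m <- matrix(scan(text = lines[(i + n + 1L):last], quiet = TRUE),
                  ncol = 4, byrow = TRUE)
      data.frame(site_a = as.integer(m[, 1]), site_b = as.integer(m[, 2]),
                 rule = as.integer(m[, 3]), formed_step = as.integer(m[, 4]))
    } else .empty_spec_bonds()[c("site_a", "site_b", "rule", "formed_step")]
    frames[[length(frames) + 1L]] <- list(step = step, pos = pos,
                                          bonds = bonds)
    i <- last + 1L
  }
  structure(list(frames = frames, box = box, mode = mode),
            class = "psd_trajectory")
}

#' Export a trajectory as extended XYZ
#'
#' One block per frame with a `Lattice`/`Properties` comment line; columns
#' are domain label, position, and radius, readable by standard
#' visualization tools.
#'
#' @param traj a `psd_trajectory`
#' @param state originating state
#' @param path output path
#' @param selection optional particle index subset
#' @return `path`, invisibly
#' @export
export_xyz <- function(traj, state, path, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(state$pos))
  con <- file(path, "w")
  on.exit(close(con))
  lab <- state$particles$domain[selection]
  rad <- state$particles$radius[selection]
  for (f in traj$frames) {
    writeLines(as.character(length(selection)), con)
    writeLines(sprintf(
      paste0('Lattice="%g 0 0 0 %g 0 0 0 %g" ',
             'Properties=species:S:1:pos:R:3:radius:R:1 step=%d'),
      state$box[1], state$box[2], state$box[3], f$step), con)
    if (length(selection)) {
      writeLines(sprintf("%s %.8g %.8g %.8g %.6g", lab,
                         f$pos[selection, 1], f$pos[selection, 2],
                         f$pos[selection, 3], rad), con)
    }
  }
  invisible(path)
}

#' Checkpoint a run
#'
#' Saves the full state and the packed random stream so that [resume_run()]
#' continues the identical trajectory (bitwise, single thread) as an
#' unbroken run.
#'
#' @param state a `psd_state`
#' @param rng_state packed RNG state from [bd_run()]
#' @param path checkpoint file path
#' @return `path`, invisibly
#' @export
checkpoint <- function(state, rng_state, path) {
  obj <- list(format = "psdmeso-checkpoint", version = 1L,
              state = state, rng_state = rng_state)
  saveRDS(obj, path)
  invisible(path)
}

#' Resume from a checkpoint
#'
#' @param path checkpoint file path
#' @return list(state, rng_state) to pass to [bd_run()]
#' @export
resume_run <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "psdmeso-checkpoint")) {
    stop("not a psdmeso checkpoint: ", path)
  }
  if (!identical(obj$version, 1L)) {
    stop("checkpoint version mismatch: ", obj$version)
  }
  list(state = obj$state, rng_state = obj$rng_state)
}

#' Deterministic analytic fixtures
#'
#' Small constructed systems with known observables, used by the test
#' suite:
#' * `ideal_gas`: n non-interacting point-like particles (zero radius, no
#'   sites) at uniform random positions; zero potential energy.
#' * `bonded_dimer`: two particles joined by one harmonic bond, offset
#'   along z by `params$stretch` from the rest length.
#' * `two_slab`: two blocks of molecules at constructed densities in the
#'   z halves of the box (step axial profile).
#' * `toy_cluster`: `params$n_cluster` molecules packed in one contact
#'   cluster plus `params$n_free` isolated ones (known partition).
#'
#' @param name fixture name
#' @param params fixture-specific parameter list
#' @param seed RNG seed
#' @return a `psd_state`
#' @export
make_fixture <- function(name = c("ideal_gas", "bonded_dimer", "two_slab",
                                  "toy_cluster"),
                         params = list(), seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  box <- params$box %||% c(50, 50, 50)
  blank <- function(pos, radius, diffusion = 0.25, mol = seq_len(nrow(pos)),
                    bonds = NULL) {
    n <- nrow(pos)
    structure(list(
      pos = pos, box = box, mode = "solution_3d", variant = variant_spec(),
      particles = data.frame(
        id = seq_len(n), molecule = mol, template = "fixture",
        domain = "fixture", radius = radius, diffusion = diffusion,
        compartment = "cytoplasm", stringsAsFactors = FALSE),
      bonds = bonds %||% data.frame(i = integer(0), j = integer(0),
                                    rest = numeric(0), k = numeric(0),
                                    kind = character(0)),
      sites = data.frame(particle = integer(0), type = character(0),
                         active = logical(0), id = integer(0)),
      spec_bonds = .empty_spec_bonds(),
      molecules = data.frame(id = unique(mol), template = "fixture",
                             stringsAsFactors = FALSE),
      step = 0L, seed = seed), class = "psd_state")
  }
  if (name == "ideal_gas") {
    n <- params$n %||% 100L
    pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                 runif(n, 0, box[3]))
    st <- blank(pos, radius = rep(params$radius %||% 0, n),
                diffusion = params$diffusion %||% 0.25)
  } else if (name == "bonded_dimer") {
    rest <- params$rest %||% 2
    stretch <- params$stretch %||% 0
    k <- params$k %||% 10
    pos <- rbind(box / 2, box / 2 + c(0, 0, rest + stretch))
    st <- blank(pos, radius = rep(params$radius %||% 0, 2), mol = c(1L, 1L),
                bonds = data.frame(i = 1L, j = 2L, rest = rest, k = k,
                                   kind = "harmonic"))
  } else if (name == "two_slab") {
    n_lo <- params$n_lo %||% 120L
    n_hi <- params$n_hi %||% 40L
    z_lo <- runif(n_lo, 0, box[3] / 2)
    z_hi <- runif(n_hi, box[3] / 2, box[3])
    pos <- cbind(runif(n_lo + n_hi, 0, box[1]),
                 runif(n_lo + n_hi, 0, box[2]), c(z_lo, z_hi))
    st <- blank(pos, radius = rep(0, n_lo + n_hi))
  } else {  # toy_cluster
    n_cluster <- params$n_cluster %||% 5L
    n_free <- params$n_free %||% 3L
    r <- params$radius %||% 1
    # chain of touching spheres -> one connected cluster
    clus <- cbind(5 + 1.9 * r * seq_len(n_cluster), 5, 5)
    free <- cbind(runif(n_free, 0, box[1]), runif(n_free, 0, box[2]),
                  box[3] - 5 - 6 * r * seq_len(n_free))
    pos <- rbind(clus, free)
    st <- blank(pos, radius = rep(r, n_cluster + n_free))
  }
  st
}

#' Convert the final state of a run into a single-frame trajectory
#'
#' @param state a `psd_state`
#' @return a `psd_trajectory` with one frame at the state's current step
#' @export
state_frame <- function(state) {
  structure(list(frames = list(list(step = state$step, pos = state$pos,
                                    bonds = state$spec_bonds)),
                 box = state$box, mode = state$mode),
            class = "psd_trajectory")
}
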