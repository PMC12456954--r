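# Model building: domain scaling laws, protein templates, whole-system
# compositions.  Each globular domain (or segment) is one spherical particle;
# the four complexes have fixed particle counts (5, 3, 6, 13).

#' Domain radius from residue count
#'
#' Power-law estimate of the radius of a globular domain modeled as a single
#' sphere, `R_n = 0.224 N^0.392` (nm).
#'
#' @param n_residues number of residues, positive
#' @return radius in nm
#' @export
radius_from_residues <- function(n_residues) {
  if (any(!is.finite(n_residues)) || any(n_residues <= 0)) {
    stop("n_residues must be positive")
  }
  0.224 * n_residues^0.392
}

#' Hydrodynamic radius from sphere radius
#'
#' `R_h = 1.45 R_n`, accounting for the larger effective friction radius of
#' a solvated domain.
#'
#' @param radius sphere radius in nm
#' @return hydrodynamic radius in nm
#' @export
hydro_radius <- function(radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  1.45 * radius
}

#' Einstein-Stokes diffusion coefficient
#'
#' `D = kB T / (6 pi eta R_h)` in simulation units (nm^2/ns), with the
#' viscosity given in mPa s (= cP).  Callers apply the 10x membrane
#' viscosity for membrane-embedded domains in 2D mode.
#'
#' @param hydro_radius hydrodynamic radius in nm
#' @param temperature temperature in K
#' @param viscosity dynamic viscosity in mPa s (water at 300 K: 0.89)
#' @return diffusion coefficient in nm^2/ns
#' @export
diffusion_coefficient <- function(hydro_radius, temperature = 300,
                                  viscosity = 0.89) {
  if (any(hydro_radius <= 0) || any(temperature <= 0) || any(viscosity <= 0)) {
    stop("all arguments must be positive")
  }
  # k_B[J/K] * 1e21 converts J/(mPa s * nm) to nm^2/ns
  1.380649e-2 * temperature / (6 * pi * viscosity * hydro_radius)
}

#' Canonical binding-site types
#' @export
site_type_levels <- c("PDZ", "PBM_TARP", "PBM_GluN2B",
                      "CaMKII_site_GluN2B", "kinase_active")

#' Template names of the four modeled complexes
#' @export
template_names <- c("AMPAR_TARP4", "NMDAR_GluN2Bc2", "PSD95", "CaMKII")

# Fixed particle counts per complex.
.template_nparticles <- c(AMPAR_TARP4 = 5L, NMDAR_GluN2Bc2 = 3L,
                          PSD95 = 6L, CaMKII = 13L)

#' Variant settings for a simulated system
#'
#' Collects the model variants studied comparatively: CaMKII activation
#' state, CaMKII radius scaling (r = 1, 2/3, 1/2), CaMKII valency
#' (V = 12, 6, 3 active kinase domains), and the weak/thick membrane
#' variants.
#'
#' @param camkii_state "active" or "inactive"
#' @param radius_scale multiplies all CaMKII particle radii and
#'   intra-complex rest lengths; in (0, 1]
#' @param valency number of kinase domains competent to bind GluN2Bc
#'   (12, 6 or 3), arranged symmetrically
#' @param membrane_k_scale scales the membrane spring constant (1 or 1/1000)
#' @param membrane_half_thickness half membrane thickness D_mem2 in nm
#'   (2.5 default, 25 for the thick-membrane variant)
#' @return an object of class `psd_variant`
#' @export
variant_spec <- function(camkii_state = c("active", "inactive"),
                         radius_scale = 1,
                         valency = 12L,
                         membrane_k_scale = 1,
                         membrane_half_thickness = 2.5) {
  camkii_state <- match.arg(camkii_state)
  if (!(radius_scale > 0 && radius_scale <= 1)) {
    stop("radius_scale must be in (0, 1]")
  }
  valency <- as.integer(valency)
  if (!valency %in% c(12L, 6L, 3L)) stop("valency must be 12, 6 or 3")
  if (membrane_k_scale <= 0) stop("membrane_k_scale must be positive")
  if (membrane_half_thickness <= 0) {
    stop("membrane_half_thickness must be positive")
  }
  structure(list(camkii_state = camkii_state,
                 radius_scale = radius_scale,
                 valency = valency,
                 membrane_k_scale = membrane_k_scale,
                 membrane_half_thickness = membrane_half_thickness),
            class = "psd_variant")
}

#' Load the domain parameter table
#'
#' Residue counts, compartments and site types per modeled domain, shipped
#' as an editable flat text table.
#'
#' @param path optional path to an alternative table
#' @return data.frame with one row per domain
#' @export
domain_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domain_params.tsv", package = "psdmeso")
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the PSD-95 linker parameter table
#' @param path optional path to an alternative table
#' @return data.frame with one row per linker
#' @export
linker_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "linker_params.tsv", package = "psdmeso")
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Entropic spring constant of a Gaussian linker
#'
#' Ideal-chain spring constant `k = 3 kB T / (n b^2)` for a flexible linker
#' of `n_link` residues with Kuhn length `b`.
#'
#' @param n_link number of linker residues
#' @param b Kuhn length in nm (default 0.38 nm per residue)
#' @param temperature temperature in K
#' @return spring constant in kJ/mol/nm^2
#' @export
linker_spring_constant <- function(n_link, b = 0.38, temperature = 300) {
  if (any(n_link < 1) || any(b <= 0)) stop("n_link >= 1 and b > 0 required")
  3 * kB * temperature / (n_link * b^2)
}

# Active-kinase pattern for a given valency: indices (1..12) of competent
# kinase domains.  Kinases 1..6 form the upper ring (60 deg spacing),
# 7..12 the lower ring offset by 30 deg.
.valency_pattern <- function(valency) {
  switch(as.character(valency),
         "12" = 1:12,
         "6"  = c(1L, 3L, 5L, 8L, 10L, 12L),  # alternate around each ring
         "3"  = c(1L, 5L, 9L),                # every fourth kinase
         stop("valency must be 12, 6 or 3"))
}

#' Build a protein template
#'
#' Constructs the domain table, internal geometry and intra-complex bond
#' network for one of the four PSD complexes.  CaMKII is a central hub
#' particle flanked by two hexagonal rings of six kinase particles; the
#' rings are held by hub-kinase, ring-neighbor, and inter-ring bonds so that
#' each ring defines a stable plane (used by the orientation analysis).
#'
#' @param name one of `template_names`
#' @param variant a [variant_spec()]; radius/valency variants apply to
#'   CaMKII only
#' @param mode "solution_3d", "membrane_2d" or "slab"; selects the
#'   residue-count column (fluorescent-protein cores in solution) and
#'   compartment assignment
#' @param params domain parameter table from [domain_params()]
#' @param temperature temperature in K (enters linker spring constants)
#' @return an object of class `psd_template` with elements `name`,
#'   `domains` (data.frame), `coords` (local particle coordinates, nm),
#'   `bonds` (data.frame with i, j, rest, k, kind)
#' @export
build_template <- function(name, variant = variant_spec(),
                           mode = c("solution_3d", "membrane_2d", "slab"),
                           params = domain_params(),
                           temperature = 300) {
  mode <- match.arg(mode)
  if (!name %in% template_names) stop("unknown template name: ", name)
  if (!inherits(variant, "psd_variant")) stop("variant must be a psd_variant")
  if (name != "CaMKII" && variant$valency != 12L &&
      identical(attr(variant, "explicit_valency"), TRUE)) {
    stop("valency variants apply to CaMKII only")
  }

  tab <- params[params$template == name, , drop = FALSE]
  rescol <- if (mode == "membrane_2d") "n_residues_2d" else "n_residues_3d"

  build_one <- function(domname) {
    row <- tab[tab$domain == domname, , drop = FALSE]
    if (nrow(row) != 1L) stop("domain not in parameter table: ", domname)
    n <- row[[rescol]]
    r <- radius_from_residues(n)
    comp <- if (mode == "membrane_2d") row$compartment else "cytoplasm"
    sites <- if (row$site_types == "-") character(0) else
      strsplit(row$site_types, ",", fixed = TRUE)[[1]]
    list(name = domname, n_residues = n, radius = r,
         hydro_radius = hydro_radius(r),
         diffusion_3d = diffusion_coefficient(hydro_radius(r), temperature),
         compartment = comp, site_types = sites)
  }

  k_bond <- 10  # kJ/mol/nm^2, structural harmonic bonds

  if (name == "AMPAR_TARP4") {
    doms <- c("AMPAR_core", rep("TARPc", 4))
    dl <- lapply(doms, build_one)
    rc <- dl[[1]]$radius; rt <- dl[[2]]$radius
    d0 <- rc + rt
    # four TARP tails pointing downward at 45 deg below the equator
    phi <- c(0, 0.5, 1, 1.5) * pi
    s <- sqrt(0.5)
    coords <- rbind(c(0, 0, 0),
                    t(vapply(phi, function(p)
                      d0 * c(s * cos(p), s * sin(p), -s), numeric(3))))
    bonds <- data.frame(i = 1L, j = 2:5, rest = d0, k = k_bond,
                        kind = "harmonic")
  } else if (name == "NMDAR_GluN2Bc2") {
    doms <- c("NMDAR_core", rep("GluN2Bc", 2))
    dl <- lapply(doms, build_one)
    d0 <- dl[[1]]$radius + dl[[2]]$radius
    s <- sqrt(0.5)
    coords <- rbind(c(0, 0, 0),
                    d0 * c(s, 0, -s),
                    d0 * c(-s, 0, -s))
    bonds <- data.frame(i = 1L, j = 2:3, rest = d0, k = k_bond,
                        kind = "harmonic")
  } else if (name == "PSD95") {
    doms <- c("PSD95_Npalm", "PSD95_PDZ1", "PSD95_PDZ2", "PSD95_PDZ3",
              "PSD95_SH3", "PSD95_GK")
    dl <- lapply(doms, build_one)
    radii <- vapply(dl, `[[`, numeric(1), "radius")
    # straight chain along -z at contact spacing
    z <- -c(0, cumsum(radii[-length(radii)] + radii[-1]))
    coords <- cbind(0, 0, z)
    lk <- linker_params()
    idx <- function(d) match(d, doms)
    bonds <- data.frame(
      i = idx(lk$domain_i), j = idx(lk$domain_j), rest = 0,
      k = linker_spring_constant(lk$n_link, temperature = temperature),
      kind = "gaussian_linker")
  } else {  # CaMKII
    doms <- c("CaMKII_hub", rep("CaMKII_kinase", 12))
    dl <- lapply(doms, build_one)
    rs <- variant$radius_scale
    for (ii in seq_along(dl)) {
      dl[[ii]]$radius <- dl[[ii]]$radius * rs
      dl[[ii]]$hydro_radius <- dl[[ii]]$hydro_radius * rs
      dl[[ii]]$diffusion_3d <- dl[[ii]]$diffusion_3d / rs
    }
    rh <- dl[[1]]$radius; rk <- dl[[2]]$radius
    h <- rk                      # ring plane offset from hub center
    rho <- sqrt((rh + rk)^2 - h^2)  # ring radius, kinase at hub contact
    ang_a <- seq(0, 300, by = 60) * pi / 180
    ang_b <- ang_a + 30 * pi / 180
    ring_a <- cbind(rho * cos(ang_a), rho * sin(ang_a), h)
    ring_b <- cbind(rho * cos(ang_b), rho * sin(ang_b), -h)
    coords <- rbind(c(0, 0, 0), ring_a, ring_b)
    # hub-kinase bonds
    b_hub <- data.frame(i = 1L, j = 2:13, rest = rh + rk, k = k_bond,
                        kind = "harmonic")
    # ring-neighbor bonds (hexagon edges)
    d_ring <- 2 * rho * sin(pi / 6)
    nb <- function(off) data.frame(
      i = off + 1:6, j = off + c(2:6, 1L), rest = d_ring, k = k_bond,
      kind = "harmonic")
    # inter-ring bonds: each upper kinase to the two nearest lower ones
    d_x <- sqrt((2 * rho * sin(pi / 12))^2 + (2 * h)^2)
    ix <- data.frame(i = rep(2:7, each = 2),
                     j = 7 + c(rbind(1:6, c(6, 1:5))),
                     rest = d_x, k = k_bond, kind = "harmonic")
    bonds <- rbind(b_hub, nb(1L), nb(7L), ix)
  }

  domains <- data.frame(
    name = vapply(dl, `[[`, character(1), "name"),
    n_residues = vapply(dl, `[[`, numeric(1), "n_residues"),
    radius = vapply(dl, `[[`, numeric(1), "radius"),
    hydro_radius = vapply(dl, `[[`, numeric(1), "hydro_radius"),
    diffusion_3d = vapply(dl, `[[`, numeric(1), "diffusion_3d"),
    compartment = vapply(dl, `[[`, character(1), "compartment"),
    stringsAsFactors = FALSE)
  domains$site_types <- I(lapply(dl, `[[`, "site_types"))

  active <- rep(TRUE, nrow(domains))
  if (name == "CaMKII") {
    kin <- which(domains$name == "CaMKII_kinase")
    act_kin <- logical(12)
    if (variant$camkii_state == "active") {
      act_kin[.valency_pattern(variant$valency)] <- TRUE
    }
    active[kin] <- act_kin
  }
  domains$active <- active

  np <- .template_nparticles[[name]]
  stopifnot(nrow(domains) == np, nrow(coords) == np)
  structure(list(name = name, domains = domains, coords = coords,
                 bonds = bonds, variant = variant),
            class = "psd_template")
}

#' System composition
#'
#' @param counts named integer vector: copies of each template
#'   (names from `template_names`; absent templates default to zero)
#' @param box box edge lengths in nm (length-3 vector)
#' @param mode "solution_3d", "membrane_2d" or "slab"
#' @param variant a [variant_spec()]
#' @return object of class `psd_composition`
#' @export
system_composition <- function(counts, box,
                               mode = c("solution_3d", "membrane_2d", "slab"),
                               variant = variant_spec()) {
  mode <- match.arg(mode)
  full <- setNames(integer(length(template_names)), template_names)
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% template_names)) {
      stop("counts must be named by template")
    }
    if (any(counts < 0)) stop("counts must be non-negative")
    full[names(counts)] <- as.integer(counts)
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  structure(list(counts = full, box = box, mode = mode, variant = variant),
            class = "psd_composition")
}

# Random rotation matrix (uniform over SO(3)) from a quaternion.
.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Build a system state from a composition
#'
#' Places molecules at random positions and orientations, avoiding
#' inter-particle overlaps (center distance >= sum of radii, minimum-image).
#' In membrane mode, membrane-compartment particles start inside the
#' membrane slab `|z| < D_mem2` and cytoplasmic particles below it;
#' molecules without membrane anchors start in the cytoplasm near the
#' membrane.  Deterministic for a given seed.
#'
#' @param comp a [system_composition()]
#' @param seed integer RNG seed
#' @param max_retries placement attempts per molecule before failing
#' @return object of class `psd_state`
#' @export
build_system <- function(comp, seed, max_retries = 500L) {
  stopifnot(inherits(comp, "psd_composition"))
  set.seed(seed)
  mode <- comp$mode
  dm2 <- comp$variant$membrane_half_thickness
  tpls <- lapply(template_names, build_template,
                 variant = comp$variant, mode = mode)
  names(tpls) <- template_names

  # registries
  pos_list <- list(); part_rows <- list(); bond_rows <- list()
  site_rows <- list(); mol_rows <- list()
  placed <- matrix(numeric(0), 0, 3)
  placed_r <- numeric(0)
  np_off <- 0L; mol_id <- 0L
  box <- comp$box

  for (tn in template_names) {
    n_copies <- comp$counts[[tn]]
    if (n_copies == 0L) next
    tpl <- tpls[[tn]]
    radii <- tpl$domains$radius
    is_mem <- tpl$domains$compartment == "membrane"
    has_mem <- any(is_mem)
    for (cc in seq_len(n_copies)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        if (mode == "membrane_2d") {
          rot <- .rotation_z(runif(1, 0, 2 * pi))
          xy <- runif(2, 0, box[1:2])
          if (has_mem) {
            zoff <- 0
          } else {
            # anchorless molecules start in the cytosol near the membrane
            maxz <- max(abs(tpl$coords[, 3]))
            hi <- -dm2 - maxz - 1
            lo <- max(-box[3] / 2 + dm2 + maxz + 0.5, hi - 40)
            zoff <- runif(1, min(lo, hi), hi)
          }
          center <- c(xy, zoff)
        } else {
          rot <- .random_rotation()
          center <- runif(3, 0, box)
        }
        xyz <- sweep(tpl$coords %*% t(rot), 2, center, "+")
        if (mode == "membrane_2d") {
          # keep cytoplasmic particles strictly below the membrane slab
          cy <- !is_mem & xyz[, 3] > -dm2
          xyz[cy, 3] <- -dm2 - 0.05
        }
        if (nrow(placed) > 0) {
          clash <- FALSE
          for (pp in seq_len(nrow(xyz))) {
            d <- sweep(placed, 2, xyz[pp, ], "-")
            d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
            if (any(rowSums(d^2) < (placed_r + radii[pp])^2)) {
              clash <- TRUE; break
            }
          }
          if (clash) next
        }
        ok <- TRUE; break
      }
      if (!ok) {
        stop("could not place molecule of template ", tn,
             " after ", max_retries, " retries (densest species)")
      }
      mol_id <- mol_id + 1L
      pos_list[[length(pos_list) + 1L]] <- xyz
      placed <- rbind(placed, xyz)
      placed_r <- c(placed_r, radii)
      idx <- np_off + seq_len(nrow(xyz))
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        id = idx, molecule = mol_id, template = tn,
        domain = tpl$domains$name, radius = radii,
        diffusion = tpl$domains$diffusion_3d,
        compartment = tpl$domains$compartment,
        stringsAsFactors = FALSE)
      if (nrow(tpl$bonds) > 0) {
        b <- tpl$bonds
        bond_rows[[length(bond_rows) + 1L]] <- data.frame(
          i = b$i + np_off, j = b$j + np_off, rest = b$rest, k = b$k,
          kind = b$kind, stringsAsFactors = FALSE)
      }
      for (dd in seq_len(nrow(tpl$domains))) {
        st <- tpl$domains$site_types[[dd]]
        if (length(st) == 0) next
        act <- if (any(st == "kinase_active")) tpl$domains$active[dd] else TRUE
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          particle = np_off + dd, type = st, active = act,
          stringsAsFactors = FALSE)
      }
      mol_rows[[length(mol_rows) + 1L]] <- data.frame(
        id = mol_id, template = tn, stringsAsFactors = FALSE)
      np_off <- np_off + nrow(xyz)
    }
  }

  pos <- if (length(pos_list)) do.call(rbind, pos_list) else
    matrix(numeric(0), 0, 3)
  particles <- if (length(part_rows)) do.call(rbind, part_rows) else
    data.frame(id = integer(0), molecule = integer(0),
               template = character(0), domain = character(0),
               radius = numeric(0), diffusion = numeric(0),
               compartment = character(0))
  bonds <- if (length(bond_rows)) do.call(rbind, bond_rows) else
    data.frame(i = integer(0), j = integer(0), rest = numeric(0),
               k = numeric(0), kind = character(0))
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(particle = integer(0), type = character(0),
               active = logical(0))
  if (nrow(sites)) sites$id <- seq_len(nrow(sites))
  else sites$id <- integer(0)
  molecules <- if (length(mol_rows)) do.call(rbind, mol_rows) else
    data.frame(id = integer(0), template = character(0))
  rownames(pos) <- rownames(particles) <- rownames(bonds) <- NULL
  rownames(sites) <- rownames(molecules) <- NULL

  structure(list(pos = pos, box = box, mode = mode, variant = comp$variant,
                 particles = particles, bonds = bonds, sites = sites,
                 spec_bonds = .empty_spec_bonds(), molecules = molecules,
                 step = 0L, seed = seed),
            class = "psd_state")
}

.empty_spec_bonds <- function() {
  data.frame(site_a = integer(0), site_b = integer(0), rule = integer(0),
             formed_step = integer(0))
}

#' @export
print.psd_state <- function(x, ...) {
  cat("psd_state:", nrow(x$pos), "particles,", nrow(x$molecules),
      "molecules, mode", x$mode, "\n")
  cat("  box [nm]:", paste(signif(x$box, 6), collapse = " x "), "\n")
  if (nrow(x$molecules)) {
    print(table(x$molecules$template))
  }
  cat("  specific bonds:", nrow(x$spec_bonds), " step:", x$step, "\n")
  invisible(x)
}

#' Total particle count implied by a composition
#' @param comp a [system_composition()]
#' @return integer particle count
#' @export
composition_particle_count <- function(comp) {
  sum(.template_nparticles[names(comp$counts)] * comp$counts)
}
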