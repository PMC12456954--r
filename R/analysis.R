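# Trajectory-derived observables: cluster detection and composition,
# density profiles, specific/non-specific interaction counts, effective
# valency, CaMKII ring orientation, Kirkwood-Buff interfacial tension, and
# tension-inequality morphology classification.

# map each live specific bond to its molecule pair
.bond_molecules <- function(bonds, state) {
  if (nrow(bonds) == 0) {
    return(data.frame(mol_a = integer(0), mol_b = integer(0),
                      rule = integer(0)))
  }
  pa <- state$sites$particle[bonds$site_a]
  pb <- state$sites$particle[bonds$site_b]
  data.frame(mol_a = state$particles$molecule[pa],
             mol_b = state$particles$molecule[pb],
             rule = bonds$rule)
}

#' Detect molecular clusters in a frame
#'
#' Molecules are nodes; an edge joins two molecules when any specific bond
#' connects them or any inter-molecule particle pair is within contact
#' distance (sum of radii) plus `contact_margin`, under minimum-image
#' distances.  Clusters are the connected components.
#'
#' @param frame a trajectory frame: list(step, pos, bonds)
#' @param state the `psd_state` the trajectory came from (static registries)
#' @param contact_margin contact margin in nm
#' @return object of class `psd_clusters`: list(membership, sizes,
#'   largest) where `membership` is the per-molecule cluster label
#' @export
detect_clusters <- function(frame, state, contact_margin = 0.5) {
  nmol <- nrow(state$molecules)
  if (nmol == 0) {
    return(structure(list(membership = integer(0), sizes = integer(0),
                          largest = NA_integer_), class = "psd_clusters"))
  }
  cp <- cpp_contact_pairs(frame$pos, state$box, state$particles$radius,
                          as.integer(state$particles$molecule),
                          contact_margin)
  edges <- rbind(
    cbind(state$particles$molecule[cp[, 1]],
          state$particles$molecule[cp[, 2]]),
    {
      bm <- .bond_molecules(frame$bonds, state)
      cbind(bm$mol_a, bm$mol_b)
    })
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nmol)))
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  sizes <- as.integer(comp$csize)
  structure(list(membership = membership, sizes = sizes,
                 largest = which.max(sizes)),
            class = "psd_clusters")
}

# molecule centers of mass, unwrapped by minimum image within molecules
.molecule_centers <- function(pos, state) {
  molidx <- state$particles$molecule
  nmol <- nrow(state$molecules)
  box <- state$box
  out <- matrix(NA_real_, nmol, 3)
  for (m in seq_len(nmol)) {
    idx <- which(molidx == m)
    ref <- pos[idx[1], ]
    d <- sweep(pos[idx, , drop = FALSE], 2, ref, "-")
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    out[m, ] <- ref + colMeans(d)
  }
  out
}

#' Mean composition of the largest cluster over a trailing window
#'
#' @param traj a `psd_trajectory`
#' @param state the originating `psd_state`
#' @param window number of trailing frames to average (clamped to the
#'   trajectory length)
#' @param contact_margin contact margin in nm
#' @return named numeric: mean copies of each template in the largest
#'   cluster, plus `cluster_size`
#' @export
largest_cluster_composition <- function(traj, state, window = 1000L,
                                        contact_margin = 0.5) {
  frames <- traj$frames
  if (!length(frames)) stop("empty trajectory")
  window <- min(window, length(frames))
  frames <- frames[seq.int(length(frames) - window + 1L, length(frames))]
  acc <- setNames(numeric(length(template_names)), template_names)
  size <- 0
  for (f in frames) {
    cl <- detect_clusters(f, state, contact_margin)
    inlc <- which(cl$membership == cl$largest)
    tt <- table(factor(state$molecules$template[inlc],
                       levels = template_names))
    acc <- acc + as.numeric(tt)
    size <- size + length(inlc)
  }
  c(acc / length(frames), cluster_size = size / length(frames))
}

#' Radial distribution of molecules around a cluster center
#'
#' Per-type number density versus distance of the molecule center from the
#' cluster center of mass.  With `normalize_rg = TRUE` distances are
#' divided by the cluster radius of gyration (for pooling differently
#' sized clusters).
#'
#' @param frame trajectory frame
#' @param state originating state
#' @param cluster a `psd_clusters` (default: detected from the frame)
#' @param cluster_id which cluster (default: largest)
#' @param breaks histogram breaks in nm (or in Rg units)
#' @param normalize_rg normalize distances by the radius of gyration
#' @param contact_margin contact margin for cluster detection
#' @return data.frame: bin midpoint, template, count, density (per nm^3)
#' @export
radial_distribution <- function(frame, state, cluster = NULL,
                                cluster_id = NULL, breaks = NULL,
                                normalize_rg = FALSE,
                                contact_margin = 0.5) {
  if (is.null(cluster)) cluster <- detect_clusters(frame, state,
                                                   contact_margin)
  if (is.null(cluster_id)) cluster_id <- cluster$largest
  members <- which(cluster$membership == cluster_id)
  if (!length(members)) stop("empty cluster")
  centers <- .molecule_centers(frame$pos, state)
  ref <- centers[members[1], ]
  d <- sweep(centers[members, , drop = FALSE], 2, ref, "-")
  d <- d - sweep(round(sweep(d, 2, state$box, "/")), 2, state$box, "*")
  com <- ref + colMeans(d)
  rel <- sweep(centers[members, , drop = FALSE], 2, com, "-")
  rel <- rel - sweep(round(sweep(rel, 2, state$box, "/")), 2, state$box, "*")
  r <- sqrt(rowSums(rel^2))
  rg <- sqrt(mean(r^2))
  if (normalize_rg) r <- r / rg
  if (is.null(breaks)) breaks <- seq(0, max(r) * 1.05 + 1e-9,
                                     length.out = 21)
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  shell_vol <- 4 / 3 * pi * diff(breaks^3)
  types <- state$molecules$template[members]
  out <- NULL
  for (tt in unique(types)) {
    h <- hist(r[types == tt], breaks = breaks, plot = FALSE)
    out <- rbind(out, data.frame(r = mid, template = tt, count = h$counts,
                                 density = h$counts / shell_vol))
  }
  attr(out, "rg") <- rg
  out
}

#' Axial density profile
#'
#' Per-type molecule count and density binned along one axis; used to read
#' layering normal to the membrane (z) or across a slab.
#'
#' @param frame trajectory frame
#' @param state originating state
#' @param axis "x" or "z"
#' @param breaks bin breaks in nm (default 30 bins spanning the wrapped
#'   coordinate range, centered on 0)
#' @return data.frame: coordinate midpoint, template, count, density
#'   (per nm^3); counts sum to the molecule count
#' @export
axial_profile <- function(frame, state, axis = c("z", "x"), breaks = NULL) {
  axis <- match.arg(axis)
  ai <- if (axis == "x") 1L else 3L
  centers <- .molecule_centers(frame$pos, state)
  L <- state$box[ai]
  v <- centers[, ai]
  v <- v - L * round(v / L)   # wrap to [-L/2, L/2)
  if (is.null(breaks)) breaks <- seq(-L / 2, L / 2, length.out = 31)
  v <- pmin(pmax(v, breaks[1]), breaks[length(breaks)])
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  slab_vol <- diff(breaks) * prod(state$box[-ai])
  types <- state$molecules$template
  out <- NULL
  for (tt in unique(types)) {
    h <- hist(v[types == tt], breaks = breaks, plot = FALSE)
    out <- rbind(out, data.frame(coord = mid, template = tt,
                                 count = h$counts,
                                 density = h$counts / slab_vol))
  }
  out
}

#' Specific and non-specific interaction counts by molecule-type pair
#'
#' Specific interactions are live bonds tallied by the template pair of
#' their molecules; non-specific interactions are inter-molecule particle
#' pairs within contact + margin that are not joined by a specific bond.
#'
#' @param frame trajectory frame
#' @param state originating state
#' @param contact_margin contact margin in nm
#' @return list(specific, nonspecific): named counts by sorted
#'   template-pair label such as `"AMPAR_TARP4|PSD95"`
#' @export
interaction_counts <- function(frame, state, contact_margin = 0.5) {
  pair_label <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  tpl <- state$molecules$template
  bm <- .bond_molecules(frame$bonds, state)
  spec <- if (nrow(bm)) table(pair_label(tpl[bm$mol_a], tpl[bm$mol_b]))
          else table(character(0))
  cp <- cpp_contact_pairs(frame$pos, state$box, state$particles$radius,
                          as.integer(state$particles$molecule),
                          contact_margin)
  if (nrow(cp)) {
    # drop contacts whose particle pair carries a live specific bond
    pa <- state$sites$particle[frame$bonds$site_a]
    pb <- state$sites$particle[frame$bonds$site_b]
    bonded_key <- paste(pmin(pa, pb), pmax(pa, pb))
    key <- paste(pmin(cp[, 1], cp[, 2]), pmax(cp[, 1], cp[, 2]))
    cp <- cp[!(key %in% bonded_key), , drop = FALSE]
  }
  nonspec <- if (nrow(cp)) {
    ma <- state$particles$molecule[cp[, 1]]
    mb <- state$particles$molecule[cp[, 2]]
    table(pair_label(tpl[ma], tpl[mb]))
  } else table(character(0))
  list(specific = c(spec), nonspecific = c(nonspec))
}

#' Effective valency: NMDARs bound per CaMKII
#'
#' For each CaMKII molecule, the number of distinct NMDAR molecules with at
#' least one GluN2Bc-kinase bond to it; both arms of one NMDAR bound to the
#' same CaMKII count once.
#'
#' @param frame trajectory frame
#' @param state originating state
#' @return integer vector, one entry per CaMKII molecule
#' @export
effective_valency <- function(frame, state) {
  camkii <- which(state$molecules$template == "CaMKII")
  out <- setNames(integer(length(camkii)), camkii)
  bm <- .bond_molecules(frame$bonds, state)
  if (nrow(bm)) {
    tpl <- state$molecules$template
    is_kin <- (tpl[bm$mol_a] == "CaMKII" & tpl[bm$mol_b] == "NMDAR_GluN2Bc2") |
              (tpl[bm$mol_b] == "CaMKII" & tpl[bm$mol_a] == "NMDAR_GluN2Bc2")
    bm <- bm[is_kin, , drop = FALSE]
    if (nrow(bm)) {
      cm <- ifelse(tpl[bm$mol_a] == "CaMKII", bm$mol_a, bm$mol_b)
      nm <- ifelse(tpl[bm$mol_a] == "CaMKII", bm$mol_b, bm$mol_a)
      per <- tapply(nm, cm, function(x) length(unique(x)))
      out[as.character(names(per))] <- as.integer(per)
    }
  }
  unname(out)
}

#' CaMKII ring orientation relative to the membrane plane
#'
#' For each CaMKII and each hexagonal kinase ring, fits the least-squares
#' plane of the six kinase positions and reports the angle between that
#' plane and the membrane plane (folded to [0, 90] degrees; plane
#' orientation is sign-free) together with the hub distance from the
#' membrane center.
#'
#' @param frame trajectory frame (membrane-mode system)
#' @param state originating state
#' @return data.frame: molecule, ring (1 or 2), z (hub z, nm), angle (deg);
#'   degenerate rings are skipped
#' @export
camkii_orientation <- function(frame, state) {
  camkii <- which(state$molecules$template == "CaMKII")
  out <- NULL
  box <- state$box
  for (m in camkii) {
    idx <- which(state$particles$molecule == m)
    hub <- idx[state$particles$domain[idx] == "CaMKII_hub"]
    kin <- idx[state$particles$domain[idx] == "CaMKII_kinase"]
    if (length(hub) != 1L || length(kin) != 12L) next
    ref <- frame$pos[hub, ]
    rel <- sweep(frame$pos[kin, , drop = FALSE], 2, ref, "-")
    rel <- rel - sweep(round(sweep(rel, 2, box, "/")), 2, box, "*")
    for (ring in 1:2) {
      rk <- rel[(ring - 1) * 6 + 1:6, , drop = FALSE]
      cen <- sweep(rk, 2, colMeans(rk), "-")
      sv <- svd(cen)
      if (sv$d[2] < 1e-6) next  # degenerate (collinear) ring
      normal <- sv$v[, 3]
      ang <- acos(min(1, abs(normal[3]))) * 180 / pi
      out <- rbind(out, data.frame(molecule = m, ring = ring,
                                   z = ref[3] - box[3] *
                                     round(ref[3] / box[3]),
                                   angle = ang))
    }
  }
  out
}

#' Kirkwood-Buff interfacial tension from slab pressure samples
#'
#' `gamma = 1/2 L_z < P_zz - (P_xx + P_yy)/2 >` with the standard error
#' from block averaging.  The prefactor 1/2 accounts for the two
#' interfaces of a periodic slab.
#'
#' @param samples sample matrix from [bd_run()] (columns Pxx, Pyy, Pzz), or
#'   a 3-column matrix of those components
#' @param L_z box length normal to the slab in nm
#' @param n_blocks number of equal blocks for the error estimate
#' @return object of class `psd_tension`: list(gamma, gamma_mN_m, se,
#'   se_mN_m, L_z, n_samples)
#' @export
interfacial_tension <- function(samples, L_z, n_blocks = 10L) {
  if (is.matrix(samples) && all(c("Pxx", "Pyy", "Pzz") %in%
                                colnames(samples))) {
    an <- samples[, "Pzz"] - 0.5 * (samples[, "Pxx"] + samples[, "Pyy"])
  } else {
    samples <- as.matrix(samples)
    an <- samples[, 3] - 0.5 * (samples[, 1] + samples[, 2])
  }
  n <- length(an)
  if (n < 2L * n_blocks) n_blocks <- max(2L, n %/% 2L)
  if (n < 2L) stop("need at least 2 pressure samples (2 blocks)")
  gamma <- 0.5 * L_z * mean(an)
  blk <- split(an, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1)) * 0.5 * L_z
  se <- sd(bm) / sqrt(length(bm))
  # 1 kJ/mol/nm^2 = 1.6606 mN/m
  structure(list(gamma = gamma, gamma_mN_m = gamma * 1.66054,
                 se = se, se_mN_m = se * 1.66054,
                 L_z = L_z, n_samples = n),
            class = "psd_tension")
}

#' @export
print.psd_tension <- function(x, ...) {
  cat(sprintf("interfacial tension: %.4g +/- %.2g kJ/mol/nm^2 (%.4g mN/m)\n",
              x$gamma, x$se, x$gamma_mN_m))
  invisible(x)
}

#' Classify multiphase droplet morphology from interfacial tensions
#'
#' For two condensed phases A (AMPAR-containing) and N (NMDAR-containing)
#' in a dilute background: segregated droplets are stable when
#' `gamma_AN > gamma_A + gamma_N`; a core-shell droplet with A at the core
#' when `gamma_A > gamma_N + gamma_AN`; with N at the core when
#' `gamma_N > gamma_A + gamma_AN`; otherwise the Janus (partial engulfing)
#' morphology.
#'
#' @param gamma_a,gamma_n,gamma_an non-negative tensions (any common unit)
#' @return object of class `psd_morphology`: list(label, margins)
#' @export
classify_morphology <- function(gamma_a, gamma_n, gamma_an) {
  if (any(c(gamma_a, gamma_n, gamma_an) < 0)) stop("tensions must be >= 0")
  margins <- c(segregated = gamma_an - (gamma_a + gamma_n),
               core_shell_A_core = gamma_a - (gamma_n + gamma_an),
               core_shell_N_core = gamma_n - (gamma_a + gamma_an))
  label <- if (margins["segregated"] > 0) "segregated"
    else if (margins["core_shell_A_core"] > 0) "core_shell_A_core"
    else if (margins["core_shell_N_core"] > 0) "core_shell_N_core"
    else "janus"
  structure(list(label = label, margins = margins),
            class = "psd_morphology")
}

#' @export
print.psd_morphology <- function(x, ...) {
  cat("morphology:", x$label, "\n")
  print(signif(x$margins, 4))
  invisible(x)
}

#' Assign molecules to the A phase, N phase or dilute phase
#'
#' Cluster members are labeled by the local majority of receptor type
#' among neighboring molecules (within twice the contact margin):
#' AMPAR-majority neighborhoods give `A_phase`, NMDAR-majority `N_phase`,
#' with ties broken toward the receptor type among the molecule's own
#' specifically bound partners.  Molecules outside any cluster (singletons)
#' are `dilute`.
#'
#' @param frame trajectory frame
#' @param state originating state
#' @param contact_margin contact margin in nm
#' @return character vector of labels, one per molecule
#' @export
phase_assignment <- function(frame, state, contact_margin = 0.5) {
  nmol <- nrow(state$molecules)
  tpl <- state$molecules$template
  cl <- detect_clusters(frame, state, contact_margin)
  labels <- rep("dilute", nmol)
  in_cluster <- cl$sizes[cl$membership] >= 2L
  if (!any(in_cluster)) return(labels)
  cp <- cpp_contact_pairs(frame$pos, state$box, state$particles$radius,
                          as.integer(state$particles$molecule),
                          2 * contact_margin)
  nb <- vector("list", nmol)
  if (nrow(cp)) {
    ma <- state$particles$molecule[cp[, 1]]
    mb <- state$particles$molecule[cp[, 2]]
    for (k in seq_along(ma)) {
      nb[[ma[k]]] <- c(nb[[ma[k]]], mb[k])
      nb[[mb[k]]] <- c(nb[[mb[k]]], ma[k])
    }
  }
  bm <- .bond_molecules(frame$bonds, state)
  for (m in which(in_cluster)) {
    hood <- unique(c(m, nb[[m]]))
    a <- sum(tpl[hood] == "AMPAR_TARP4")
    n <- sum(tpl[hood] == "NMDAR_GluN2Bc2")
    if (a > n) labels[m] <- "A_phase"
    else if (n > a) labels[m] <- "N_phase"
    else {
      partners <- c(bm$mol_b[bm$mol_a == m], bm$mol_a[bm$mol_b == m])
      ap <- sum(tpl[partners] == "AMPAR_TARP4")
      np <- sum(tpl[partners] == "NMDAR_GluN2Bc2")
      labels[m] <- if (np > ap) "N_phase" else "A_phase"
    }
  }
  labels
}

#' Mean radial position of each receptor type in the largest cluster
#'
#' Summary used to read core-shell ordering: for each trailing-window
#' frame, the mean distance of AMPAR and NMDAR receptor-core particles
#' (the imaged fluorophore positions) from the largest cluster's center of
#' mass (in-plane xy distance for membrane systems).  `delta` =
#' mean_r(NMDAR) - mean_r(AMPAR): positive when NMDARs sit outward of
#' AMPARs (3D core-shell with A core), negative when NMDARs are inward.
#'
#' @param traj a `psd_trajectory`
#' @param state originating state
#' @param window trailing frames to average
#' @param contact_margin contact margin in nm
#' @return list(delta, mean_r_ampar, mean_r_nmdar, n_frames) with
#'   frame-wise values in `per_frame`
#' @export
receptor_radial_ordering <- function(traj, state, window = 20L,
                                     contact_margin = 0.5) {
  frames <- traj$frames
  if (!length(frames)) stop("empty trajectory")
  window <- min(window, length(frames))
  frames <- frames[seq.int(length(frames) - window + 1L, length(frames))]
  planar <- state$mode == "membrane_2d"
  core_of <- function(mols, domain) {
    vapply(mols, function(m) {
      which(state$particles$molecule == m &
              state$particles$domain == domain)[1]
    }, integer(1))
  }
  per <- NULL
  for (f in frames) {
    cl <- detect_clusters(f, state, contact_margin)
    members <- which(cl$membership == cl$largest)
    tt <- state$molecules$template[members]
    if (sum(tt == "AMPAR_TARP4") == 0 || sum(tt == "NMDAR_GluN2Bc2") == 0) {
      next
    }
    centers <- .molecule_centers(f$pos, state)
    ref <- centers[members[1], ]
    d <- sweep(centers[members, , drop = FALSE], 2, ref, "-")
    d <- d - sweep(round(sweep(d, 2, state$box, "/")), 2, state$box, "*")
    com <- ref + colMeans(d)
    # receptors are located by their core particle (the imaged fluorophore)
    core_r <- function(template, domain) {
      idx <- core_of(members[tt == template], domain)
      rel <- sweep(f$pos[idx, , drop = FALSE], 2, com, "-")
      rel <- rel - sweep(round(sweep(rel, 2, state$box, "/")), 2,
                         state$box, "*")
      if (planar) mean(sqrt(rowSums(rel[, 1:2, drop = FALSE]^2)))
      else mean(sqrt(rowSums(rel^2)))
    }
    per <- rbind(per, data.frame(
      step = f$step,
      r_ampar = core_r("AMPAR_TARP4", "AMPAR_core"),
      r_nmdar = core_r("NMDAR_GluN2Bc2", "NMDAR_core"),
      size = length(members)))
  }
  if (is.null(per)) {
    return(list(delta = NA_real_, mean_r_ampar = NA_real_,
                mean_r_nmdar = NA_real_, n_frames = 0L, per_frame = NULL))
  }
  list(delta = mean(per$r_nmdar - per$r_ampar),
       mean_r_ampar = mean(per$r_ampar),
       mean_r_nmdar = mean(per$r_nmdar),
       n_frames = nrow(per), per_frame = per)
}
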