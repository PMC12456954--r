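# Independent oracles and small constructed systems used across the suite.

# Brute-force cluster detection: O(N^2) particle pair scan + hand-rolled
# union-find over molecules (independent of the igraph path).
oracle_clusters <- function(frame, state, margin = 0.5) {
  nmol <- nrow(state$molecules)
  parent <- seq_len(nmol)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  pos <- frame$pos
  box <- state$box
  r <- state$particles$radius
  mol <- state$particles$molecule
  n <- nrow(pos)
  if (n > 1) {
    for (a in 1:3) {
      d <- outer(pos[, a], pos[, a], "-")
      d <- d - box[a] * round(d / box[a])
      if (a == 1) d2 <- d^2 else d2 <- d2 + d^2
    }
    cut <- outer(r, r, "+") + margin
    hit <- which(d2 <= cut^2, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      mi <- mol[hit[k, 1]]; mj <- mol[hit[k, 2]]
      if (mi != mj) link(mi, mj)
    }
  }
  if (nrow(frame$bonds)) {
    pa <- state$sites$particle[frame$bonds$site_a]
    pb <- state$sites$particle[frame$bonds$site_b]
    for (k in seq_along(pa)) link(mol[pa[k]], mol[pb[k]])
  }
  roots <- vapply(seq_len(nmol), find, integer(1))
  match(roots, unique(roots))
}

# Brute-force total-energy oracle in R: structural bonds + specific bonds +
# excluded volume over all non-bonded pairs + membrane/confinement terms.
oracle_energy <- function(state, k_rep = 10, k_mem = 10, d_mem2 = 2.5) {
  pos <- state$pos; box <- state$box
  mi <- function(d, L) d - L * round(d / L)
  pdist <- function(i, j) {
    d <- pos[i, ] - pos[j, ]
    sqrt(sum(mapply(mi, d, box)^2))
  }
  e_bond <- 0
  if (nrow(state$bonds)) {
    for (b in seq_len(nrow(state$bonds))) {
      d <- pdist(state$bonds$i[b], state$bonds$j[b])
      e_bond <- e_bond + 0.5 * state$bonds$k[b] * (d - state$bonds$rest[b])^2
    }
  }
  rules <- default_rules(state$variant, mode = state$mode)
  e_spe <- 0
  if (nrow(state$spec_bonds)) {
    for (b in seq_len(nrow(state$spec_bonds))) {
      ru <- state$spec_bonds$rule[b]
      i <- state$sites$particle[state$spec_bonds$site_a[b]]
      j <- state$sites$particle[state$spec_bonds$site_b[b]]
      d <- pdist(i, j)
      e_spe <- e_spe + 0.5 * rules$bond_k[ru] * (d - rules$bond_rest[ru])^2
    }
  }
  bonded <- paste(pmin(state$bonds$i, state$bonds$j),
                  pmax(state$bonds$i, state$bonds$j))
  e_ev <- 0
  n <- nrow(pos)
  r <- state$particles$radius
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq.int(i + 1, n)) {
      if (paste(i, j) %in% bonded) next
      d <- pdist(i, j)
      if (d < r[i] + r[j]) e_ev <- e_ev + 0.5 * k_rep * (d - r[i] - r[j])^2
    }
  }
  e_sys <- 0
  if (state$mode == "membrane_2d") {
    zz <- mi(pos[, 3], box[3])
    mem <- state$particles$compartment == "membrane"
    e_sys <- sum(membrane_potential(zz[mem], "membrane", k_mem, d_mem2)) +
      sum(membrane_potential(zz[!mem], "cytoplasm", k_mem, d_mem2))
    zf <- -box[3] / 2 + d_mem2
    low <- !mem & zz < zf
    e_sys <- e_sys + sum(0.5 * k_mem * (zz[low] - zf)^2)
  }
  c(bond = e_bond, spe = e_spe, ev = e_ev, sys = e_sys,
    total = e_bond + e_spe + e_ev + e_sys)
}

# Small mixed system (a few molecules of each template) for generic checks.
small_mixed_state <- function(seed = 1, mode = "solution_3d",
                              variant = variant_spec(), box = 45) {
  comp <- system_composition(
    c(AMPAR_TARP4 = 2L, NMDAR_GluN2Bc2 = 2L, PSD95 = 3L, CaMKII = 1L),
    rep(box, 3), mode = mode, variant = variant)
  build_system(comp, seed)
}
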