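# Shared fixtures (built once per test run) and independent oracles.

# small fast toy protein: 14-bead domains, target U-shape geometry
toy_small <- make_toy_protein(toy_spec(beads_per_domain = 14, d = 20, seed = 3))
chain_small <- toy_small$chain
topo_small <- build_topology(chain_small)

# default-size toy, used by the slower physics / pipeline tests
toy_default <- make_toy_protein(toy_spec())
chain_default <- toy_default$chain
topo_default <- build_topology(chain_default)

rand_coords <- function(n, scale = 5, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n), n, 3) * scale
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# ---- independent plain-R oracles -------------------------------------------

r_debye_oracle <- function(coords, f, q) {
  n <- nrow(coords)
  sapply(q, function(qk) {
    s <- 0
    for (i in 1:n) for (j in 1:n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      s <- s + f[i] * f[j] * (if (qk * r < 1e-12) 1 else sin(qk * r) / (qk * r))
    }
    s
  })
}

r_rg_oracle <- function(coords, w = rep(1, nrow(coords))) {
  w <- w / sum(w)
  com <- c(sum(coords[, 1] * w), sum(coords[, 2] * w), sum(coords[, 3] * w))
  s <- 0
  for (i in seq_len(nrow(coords))) s <- s + w[i] * sum((coords[i, ] - com)^2)
  sqrt(s)
}

# signed dihedral via projections onto the plane normal to the central bond
# (the half-plane vectors are p1 - p2 and p4 - p3, viewed along p2 -> p3)
r_dihedral_oracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- b2 / sqrt(sum(b2^2))
  w1 <- p1 - p2; w3 <- p4 - p3
  v1 <- w1 - sum(w1 * u) * u
  v3 <- w3 - sum(w3 * u) * u
  x <- sum(v1 * v3)
  cr <- c(v1[2] * v3[3] - v1[3] * v3[2], v1[3] * v3[1] - v1[1] * v3[3],
          v1[1] * v3[2] - v1[2] * v3[1])
  y <- sum(cr * u)
  atan2(y, x) * 180 / pi
}

# term-by-term re-implementation of the model energy (mirrors the published
# functional forms, written independently of the compiled kernel)
r_energy_oracle <- function(chain, topo, coords, params) {
  b <- chain$beads
  n <- nrow(coords)
  dist2 <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  e <- c(bond = 0, angle = 0, dihedral = 0, contact = 0,
         excluded_volume = 0, electrostatic = 0)
  for (r in seq_len(nrow(topo$bonds))) {
    bb <- topo$bonds[r, ]
    e["bond"] <- e["bond"] + bb$k * (dist2(bb$i, bb$j) - bb$r0)^2
  }
  ang <- function(i, j, k) {
    v1 <- coords[i, ] - coords[j, ]; v2 <- coords[k, ] - coords[j, ]
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }
  for (r in seq_len(nrow(topo$angles))) {
    aa <- topo$angles[r, ]
    e["angle"] <- e["angle"] + aa$k_theta * (ang(aa$i, aa$j, aa$k) - aa$theta0)^2
  }
  for (r in seq_len(nrow(topo$dihedrals))) {
    dd <- topo$dihedrals[r, ]
    phi <- r_dihedral_oracle(coords[dd$i, ], coords[dd$j, ],
                             coords[dd$k, ], coords[dd$l, ]) * pi / 180
    dphi <- phi - dd$phi0
    e["dihedral"] <- e["dihedral"] + dd$k_phi * (1 - cos(dphi)) +
      dd$k_phi / 2 * (1 - cos(3 * dphi))
  }
  ct_key <- paste(topo$contacts$i, topo$contacts$j)
  for (r in seq_len(nrow(topo$contacts))) {
    cc <- topo$contacts[r, ]
    s <- cc$r0 / dist2(cc$i, cc$j)
    e["contact"] <- e["contact"] + cc$eps * (5 * s^12 - 6 * s^10)
  }
  rc <- 2.5 * params$ev_sigma
  for (i in 1:(n - 1)) for (j in i:n) {
    if (j - i < 4) next
    if (paste(i, j) %in% ct_key) next
    r <- dist2(i, j)
    if (r >= rc) next
    e["excluded_volume"] <- e["excluded_volume"] +
      params$ev_eps * ((params$ev_sigma / r)^12 - (params$ev_sigma / rc)^12)
  }
  eps0 <- 8.8541878128e-12; ec <- 1.602176634e-19; kB <- 1.380649e-23
  lB <- ec^2 / (4 * pi * eps0 * params$dielectric * kB * 300) * 1e10
  lam <- sqrt(eps0 * params$dielectric * kB * params$temperature /
                (2 * 6.02214076e23 * ec^2 * params$ionic_strength * 1000)) * 1e10
  ch <- which(b$charge != 0)
  if (length(ch) >= 2) {
    for (ai in seq_along(ch)) for (bi in seq_len(ai - 1)) {
      i <- ch[bi]; j <- ch[ai]
      if (abs(i - j) < 3) next
      r <- dist2(i, j)
      if (r >= 40) next
      qq <- b$charge[i] * b$charge[j]
      e["electrostatic"] <- e["electrostatic"] +
        lB * qq * (exp(-r / lam) / r - exp(-40 / lam) / 40)
    }
  }
  e
}

# brute-force native-contact scan under the builder's rules
r_contact_oracle <- function(chain, cutoff = 6.5) {
  b <- chain$beads
  xyz <- as.matrix(b[, c("x", "y", "z")])
  out <- NULL
  n <- nrow(b)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < 4) next
    if (b$flexible[i] || b$flexible[j]) next
    if (is.na(b$unit[i]) || is.na(b$unit[j]) || b$unit[i] != b$unit[j]) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) > cutoff) next
    out <- rbind(out, c(i, j))
  }
  out
}
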