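# Synthetic inputs with known ground truth: a U-shaped four-domain toy
# protein, two-state conformational ensembles, and noisy aggregate-
# contaminated "experimental" SAXS profiles.  Everything is seeded, so the
# whole pipeline can run and be tested without any external downloads.

#' Specification of the toy four-domain protein
#'
#' Defaults emulate the architecture of a U-shaped four-domain chain: two
#' edge domains (a, a') connected through a rigid central pair (b, b') that
#' shares one folded unit, with two-bead flexible linkers at the a-b and
#' b'-a' junctions only.  The target centre-of-mass geometry uses the same
#' descriptors as the production analysis (theta1, theta2 in degrees,
#' dihedral phi in degrees, edge-domain distance d in Angstrom).
#'
#' @param beads_per_domain Beads per domain blob.
#' @param linker_length Flexible beads per hinge linker.
#' @param theta1,theta2,phi,d Target COM geometry.
#' @param min_separation Minimum inter-bead distance in a blob, Angstrom.
#' @param seed RNG seed.
#' @export
toy_spec <- function(beads_per_domain = 30, linker_length = 2,
                     theta1 = 72, theta2 = 132, phi = 62, d = 28,
                     min_separation = 3.4, seed = 1L) {
  stopifnot(beads_per_domain >= 4, linker_length >= 1,
            theta1 > 0, theta1 < 180, theta2 > 0, theta2 < 180,
            phi > -180, phi <= 180, d > 0, min_separation > 0)
  structure(as.list(environment()), class = "toy_spec")
}

# compact-blob radius heuristic for n beads (near-globular packing density,
# so the native contact network is dense enough to hold the blob folded)
.blob_radius <- function(n) 2.0 * n^(1 / 3)

# maximally collapsed self-avoiding walk: a serpentine path through a
# jittered cubic lattice at CA-CA spacing.  The dense packing gives each
# interior bead several native contacts, which is what keeps the blob folded
# at 300 K under the shallow per-contact wells.
.grow_blob <- function(n, min_sep, step = 3.8, jitter = 0.45) {
  # near-cubic box dimensions minimizing surface area
  dx <- ceiling(n^(1 / 3))
  dy <- ceiling(sqrt(n / dx))
  dz <- ceiling(n / (dx * dy))
  # boustrophedon path: every step moves to a face-adjacent cell, so all
  # backbone bonds are one lattice unit long
  pts <- matrix(0, dx * dy * dz, 3)
  k <- 0; row <- 0
  for (z in 0:(dz - 1)) {
    ys <- 0:(dy - 1)
    if (z %% 2 == 1) ys <- rev(ys)
    for (y in ys) {
      xs <- 0:(dx - 1)
      if (row %% 2 == 1) xs <- rev(xs)
      row <- row + 1
      for (x in xs) { k <- k + 1; pts[k, ] <- c(x, y, z) }
    }
  }
  base <- pts[seq_len(n), , drop = FALSE] * step
  # among admissible jitter draws keep the one with the densest contact
  # network (pairs |i-j| >= 4 within typical contact range)
  best <- NULL; best_n <- -1L
  seq_sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  for (try in 1:250) {
    xyz <- base + matrix(runif(3 * n, -jitter, jitter), n, 3)
    dm <- as.matrix(stats::dist(xyz))
    if (min(dm[seq_sep >= 2]) < min_sep * 0.95) next
    n_ct <- sum(dm <= 6.5 & seq_sep >= 4) / 2
    if (n_ct > best_n) { best_n <- n_ct; best <- xyz }
  }
  if (is.null(best))
    stop("lattice blob violates the minimum separation; lower the jitter")
  sweep(best, 2, colMeans(best))
}

# rotation best aligning unit vectors u[i,] with d[i,] (Kabsch on vectors)
.align_vectors <- function(u, d) {
  H <- t(u) %*% d
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
}

# place p4 given p1..p3, bond length r, angle theta (deg) at p3 and
# dihedral phi (deg) about p2-p3 (standard internal-coordinate construction)
.place_internal <- function(p1, p2, p3, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n <- cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  p3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

# COM positions of the four domains realizing (theta1, theta2, phi, d);
# arm length solved so that |a - a'| = d
.solve_domain_coms <- function(spec, r_bb, r_min) {
  B <- c(0, 0, 0); Bp <- c(r_bb, 0, 0)
  th1 <- spec$theta1 * pi / 180
  arm_coms <- function(r) {
    A <- B + r * c(cos(th1), sin(th1), 0)
    Ap <- .place_internal(A, B, Bp, r, spec$theta2, spec$phi)
    list(A = A, B = B, Bp = Bp, Ap = Ap)
  }
  dist_at <- function(r) {
    cm <- arm_coms(r)
    sqrt(sum((cm$A - cm$Ap)^2)) - spec$d
  }
  lo <- r_min; hi <- 60 * max(1, spec$d / 20)
  flo <- dist_at(lo); fhi <- dist_at(hi)
  if (flo * fhi > 0)
    stop("infeasible target geometry: cannot reach d = ", spec$d,
         " with these angles; try a larger (or smaller) d")
  r <- stats::uniroot(dist_at, c(lo, hi), tol = 1e-8)$root
  arm_coms(r)
}

# draw a residue sequence: domains from a generic globular composition,
# linkers from charged/flexible residues (emulating charged loops)
.draw_sequence <- function(n_domain_beads, is_linker) {
  comp <- c(A = .08, R = .05, N = .04, D = .06, C = .02, Q = .04, E = .07,
            G = .07, H = .02, I = .06, L = .09, K = .07, M = .02, F = .04,
            P = .05, S = .07, T = .05, W = .01, Y = .03, V = .06)
  res <- character(length(is_linker))
  res[!is_linker] <- sample(names(comp), sum(!is_linker), replace = TRUE,
                            prob = comp)
  res[is_linker] <- sample(c("K", "E", "G", "S"), sum(is_linker),
                           replace = TRUE, prob = c(.35, .25, .2, .2))
  res
}

#' Generate the toy four-domain protein
#'
#' Four compact self-avoiding domain blobs are placed so that their COMs
#' realize the requested (theta1, theta2, phi, d) geometry; blobs are
#' oriented so chain termini face their junction partners, hinge linkers
#' bridge a-b and b'-a', and the whole chain is energy-minimized under a
#' provisional topology with harmonic restraints pinning each domain COM.
#' The minimized structure is the native reference.  The function verifies
#' its own output: realized angles within 2 degrees and d within 2% of the
#' target, otherwise it errors.
#'
#' @param spec A [toy_spec].
#' @return List with `structure` (a `structure3d`), `chain` (a `cg_chain`
#'   with domains defined and charges assigned), `definition` (the
#'   [domain_definition]) and `realized` (named geometry actually achieved).
#' @export
make_toy_protein <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  n <- spec$beads_per_domain
  nl <- spec$linker_length
  R <- .blob_radius(n)
  r_bb <- 2.1 * R
  coms <- .solve_domain_coms(spec, r_bb, r_min = 2.05 * R)
  targets <- list(a = coms$A, b = coms$B, bp = coms$Bp, ap = coms$Ap)

  blobs <- lapply(1:4, function(i) .grow_blob(n, spec$min_separation))
  names(blobs) <- names(targets)
  # orient blobs: termini toward junction partners
  # chain order: a - L1 - b | bp - L2 - ap  (b|bp joined directly)
  dirs <- list(
    a = list(from = "last", to = targets$b),
    b = list(first = targets$a, last = targets$bp),
    bp = list(first = targets$b, last = targets$ap),
    ap = list(from = "first", to = targets$bp))
  unit <- function(v) v / sqrt(sum(v^2))
  for (dn in names(blobs)) {
    bl <- blobs[[dn]]
    tgt <- targets[[dn]]
    u <- NULL; d <- NULL
    di <- dirs[[dn]]
    if (!is.null(di$from)) {
      idx <- if (di$from == "last") n else 1L
      u <- rbind(unit(bl[idx, ]))
      d <- rbind(unit(di$to - tgt))
    } else {
      u <- rbind(unit(bl[1, ]), unit(bl[n, ]))
      d <- rbind(unit(di$first - tgt), unit(di$last - tgt))
    }
    Rm <- .align_vectors(u, d)
    blobs[[dn]] <- sweep(bl %*% t(Rm), 2, tgt, `+`)
  }

  # assemble chain with linker beads interpolated across the hinge junctions
  interp <- function(p, q, k) {
    t(vapply(seq_len(k), function(i) p + (q - p) * i / (k + 1), numeric(3)))
  }
  l1 <- interp(blobs$a[n, ], blobs$b[1, ], nl)
  l2 <- interp(blobs$bp[n, ], blobs$ap[1, ], nl)
  xyz <- rbind(blobs$a, l1, blobs$b, blobs$bp, l2, blobs$ap)
  ntot <- nrow(xyz)

  ranges <- list(a = c(1, n), linker1 = c(n + 1, n + nl),
                 b = c(n + nl + 1, 2 * n + nl),
                 bp = c(2 * n + nl + 1, 3 * n + nl),
                 linker2 = c(3 * n + nl + 1, 3 * n + 2 * nl),
                 ap = c(3 * n + 2 * nl + 1, ntot))
  definition <- domain_definition(
    ranges, flexible = c((n + 1):(n + nl), (3 * n + nl + 1):(3 * n + 2 * nl)),
    units = list(a = "a", bb = c("b", "bp"), ap = "ap"))

  is_linker <- seq_len(ntot) %in% definition$flexible
  res <- .draw_sequence(ntot, is_linker)

  chain <- structure(list(beads = data.frame(
    resno = seq_len(ntot), res = res,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = 0, domain = NA_character_, flexible = FALSE,
    unit = NA_integer_, stringsAsFactors = FALSE),
    chain_id = "A"), class = "cg_chain")
  chain <- define_domains(chain, definition)

  # provisional topology (junction/linker bonds reset to the ideal CA-CA
  # length) and COM-restrained minimization to relax clashes
  params <- sim_params(use_elec = FALSE)
  topo0 <- build_topology(chain, params = params)
  bad <- topo0$bonds$r0 < 3.0 | topo0$bonds$r0 > 4.4
  topo0$bonds$r0[bad] <- 3.8
  xyz_min <- .minimize_with_com_restraints(chain, topo0, params, xyz,
                                           targets, k_com = 50)
  chain$beads[, c("x", "y", "z")] <- xyz_min
  chain <- assign_charges(chain)

  # final native topology is built from the minimized reference by callers;
  # verify the realized geometry
  gt <- geometry_table(chain, xyz_min)
  realized <- c(theta1 = gt$theta1, theta2 = gt$theta2, phi = gt$phi, d = gt$d)
  if (abs(realized["theta1"] - spec$theta1) > 2 ||
      abs(realized["theta2"] - spec$theta2) > 2 ||
      abs(realized["d"] - spec$d) / spec$d > 0.02)
    stop("generated geometry misses the target (overlapping domains?); ",
         "try a larger d")

  atoms <- data.frame(
    elety = "CA", resid = unname(.aa1_to_3[res]), chain = "A",
    resno = seq_len(ntot), x = xyz_min[, 1], y = xyz_min[, 2],
    z = xyz_min[, 3], segid = chain$beads$domain, stringsAsFactors = FALSE)
  struct <- structure(list(atoms = atoms, title = "synthetic four-domain toy"),
                      class = "structure3d")
  list(structure = struct, chain = chain, definition = definition,
       realized = realized)
}

# L-BFGS-B minimization of model energy plus harmonic restraints pulling
# each domain COM to its target position
.minimize_with_com_restraints <- function(chain, topology, params, coords,
                                          targets, k_com = 5, maxit = 300) {
  tl <- .topo_list(chain, topology, params)
  pl <- .pars_list(params, NULL)
  n <- topology$n_beads
  b <- chain$beads
  groups <- lapply(names(targets), function(dn) which(b$domain == dn))
  names(groups) <- names(targets)
  fn <- function(x) {
    m <- matrix(x, n, 3)
    e <- cpp_energy(m, tl, pl)[["total"]]
    for (dn in names(groups)) {
      g <- groups[[dn]]
      e <- e + k_com * sum((colMeans(m[g, , drop = FALSE]) - targets[[dn]])^2)
    }
    e
  }
  gr <- function(x) {
    m <- matrix(x, n, 3)
    g_mat <- -cpp_forces(m, tl, pl)
    for (dn in names(groups)) {
      g <- groups[[dn]]
      dv <- 2 * k_com * (colMeans(m[g, , drop = FALSE]) - targets[[dn]]) / length(g)
      g_mat[g, ] <- sweep(g_mat[g, , drop = FALSE], 2, dv, `+`)
    }
    as.vector(g_mat)
  }
  opt <- optim(as.vector(coords), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  matrix(opt$par, n, 3)
}

#' Generate open/closed two-state ensembles by restrained sampling
#'
#' Runs Langevin dynamics with a harmonic restraint on the a-a' COM distance
#' at each of the two targets, discarding an equilibration stretch.  The
#' restraint metadata is recorded on the returned trajectories so tests can
#' exclude restrained data from production paths.
#'
#' @param chain A toy `cg_chain` (domains defined).
#' @param topology Its native `cg_topology`.
#' @param open_d,closed_d Target a-a' COM distances, Angstrom
#'   (`open_d > closed_d`).
#' @param n_frames Frames to keep per state.
#' @param seed RNG seed (the closed state uses `seed + 1000`).
#' @param params A [sim_params]; `save_interval` spaces the kept frames.
#' @param k_restraint Restraint stiffness, kBT/A^2.
#' @param n_equil Equilibration steps discarded before collection.
#' @return List with `open` and `closed` `cg_trajectory` objects.
#' @export
make_two_state_ensemble <- function(chain, topology, open_d, closed_d,
                                    n_frames = 100, seed = 1L,
                                    params = sim_params(save_interval = 200),
                                    k_restraint = 3, n_equil = 4000) {
  stopifnot(open_d > closed_d)
  b <- chain$beads
  grp_a <- which(b$domain == "a" & !b$flexible)
  grp_ap <- which(b$domain == "ap" & !b$flexible)
  if (!length(grp_a) || !length(grp_ap)) stop("chain lacks a/ap domains")
  one_state <- function(target_d, sd) {
    res <- list(group_a = grp_a, group_b = grp_ap, k = k_restraint,
                target = target_d)
    p <- params
    p$n_steps <- n_equil + n_frames * params$save_interval
    tr <- run_langevin(chain, topology, p, seed = sd, restraint = res)
    drop <- sum(tr$steps <= n_equil)
    tr <- subset_trajectory(tr, (drop + 1):length(tr$frames))
    tr$restraint <- res
    tr
  }
  open <- one_state(open_d, seed)
  closed <- one_state(closed_d, seed + 1000)
  list(open = open, closed = closed)
}

#' Specification of a synthetic SAXS experiment
#'
#' @param noise_a,noise_b Relative noise model `sigma(q)/I = a + b q`.
#' @param weights Weight fractions of monomer/dimer/trimer (sum 1).
#' @param q q grid, 1/Angstrom.
#' @param seed RNG seed for the noise draw.
#' @export
experiment_spec <- function(noise_a = 0.01, noise_b = 0.05,
                            weights = c(0.96, 0.03, 0.01),
                            q = seq(0.01, 0.30, length.out = 150),
                            seed = 1L) {
  stopifnot(abs(sum(weights) - 1) < 1e-6, noise_a >= 0, noise_b >= 0)
  structure(as.list(environment()), class = "experiment_spec")
}

# rigid k-mer of a frame with displacement chosen so the aggregate's
# coordinate Rg follows the density-preserving law Rg_k = Rg1 k^(1/3)
.aggregate_coords <- function(frame, k) {
  rg1 <- coordinate_rg(frame)
  ev <- eigen(stats::cov(frame))$vectors[, 1]
  if (k == 2) {
    s <- 2 * rg1 * sqrt(2^(2 / 3) - 1)
    off <- outer(c(-0.5, 0.5) * s, ev)
  } else if (k == 3) {
    t <- rg1 * sqrt(1.5 * (3^(2 / 3) - 1))
    off <- outer(c(-t, 0, t), ev)
  } else stop("only dimer and trimer aggregates are generated")
  ctr <- sweep(frame, 2, colMeans(frame))
  do.call(rbind, lapply(seq_len(k), function(i) sweep(ctr, 2, off[i, ], `+`)))
}

#' Synthesize an "observed" SAXS experiment from an ensemble
#'
#' The ground-truth monomer profile is the ensemble average of per-frame
#' Debye profiles (uniform form factors).  Dimer and trimer contaminants are
#' rigid copies of a representative frame (the frame of median Rg) displaced
#' along its principal axis so their Rg follows compact-growth scaling; the
#' observed profile is the weight-fraction mixture with multiplicative
#' Gaussian noise of relative standard deviation `sigma(q)/I = a + b q`, and
#' the sigma column equals that noise SD.
#'
#' @param ensemble A `cg_trajectory`.
#' @param spec An [experiment_spec].
#' @return List with `observed`, `truth` ([saxs_profile]s), `mixture`
#'   (the [mixture_spec] used) and `representative` (frame index used for
#'   the aggregates).
#' @export
synthesize_experiment <- function(ensemble, spec = experiment_spec()) {
  stopifnot(inherits(ensemble, "cg_trajectory"), length(ensemble$frames) > 0)
  set.seed(spec$seed)
  q <- spec$q
  n <- nrow(ensemble$frames[[1]])
  profs <- lapply(ensemble$frames, function(fr) debye_profile(fr, q = q)$I)
  truth_I <- Reduce(`+`, profs) / length(profs)
  qpos <- q[q > 0]
  truth <- saxs_profile(qpos, truth_I, label = "monomer truth")

  rgs <- vapply(ensemble$frames, coordinate_rg, 0)
  rep_idx <- which.min(abs(rgs - stats::median(rgs)))
  rep_frame <- ensemble$frames[[rep_idx]]

  w <- spec$weights
  mix <- mixture_spec(order = seq_along(w), weight_fraction = w,
                      molar_mass = seq_along(w) * n)
  comps <- list(truth)
  for (k in seq_along(w)[-1])
    comps[[k]] <- debye_profile(.aggregate_coords(rep_frame, k), q = qpos,
                                label = sprintf("%d-mer", k))
  mixed <- mixture_profile(comps, mix)

  rel <- spec$noise_a + spec$noise_b * qpos
  sigma <- rel * mixed$I
  I_obs <- mixed$I * (1 + rel * rnorm(length(qpos)))
  if (all(sigma == 0)) {
    observed <- saxs_profile(qpos, I_obs, label = "observed (synthetic)")
  } else {
    observed <- saxs_profile(qpos, I_obs, sigma = sigma,
                             label = "observed (synthetic)")
  }
  list(observed = observed, truth = truth, mixture = mix,
       representative = rep_idx)
}
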