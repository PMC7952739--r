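# Langevin sampling of the coarse-grained model.  Energies are expressed in
# units of kBT at 300 K, lengths in Angstrom, bead masses are 1 and time is
# in reduced units; temperature enters through the thermostat target only.

#' Simulation parameters
#'
#' Defaults follow the package's reference protocol: structure-based terms
#' plus screened (Debye-Hueckel) electrostatics at 150 mM ionic strength and
#' 300 K.  The optional short-range hydrophobic attraction is off by default.
#'
#' @param temperature Kelvin.
#' @param dt Integration step (reduced time units).
#' @param gamma Langevin friction (1/time unit); `gamma = 0` gives the
#'   deterministic velocity-Verlet limit used for energy-drift checks.
#' @param n_steps Steps per run.
#' @param save_interval Steps between saved snapshots.
#' @param n_runs Independent runs launched by [run_sampling()].
#' @param seed Base RNG seed (each run r uses `seed + r - 1`).
#' @param ionic_strength mol/L, sets the Debye screening length.
#' @param dielectric Relative solvent dielectric constant.
#' @param eps_contact Native-contact well depth, kBT.
#' @param k_bond,k_angle,k_dihedral Native force constants
#'   (kBT/A^2, kBT/rad^2, kBT).
#' @param k_angle_flex Generic angle constant on flexible triples, kBT/rad^2.
#' @param ev_eps,ev_sigma Excluded-volume strength (kBT) and diameter (A).
#' @param use_contacts,use_ev,use_elec,use_hydro Term toggles.
#' @param hydro_eps,hydro_r0 Hydrophobic well depth (kBT) and position (A).
#' @return A `sim_params` list.
#' @export
sim_params <- function(temperature = 300, dt = 0.005, gamma = 1,
                       n_steps = 1e6, save_interval = 500, n_runs = 8,
                       seed = 1L,
                       ionic_strength = 0.150, dielectric = 78,
                       eps_contact = 0.8, k_bond = 100, k_angle = 20,
                       k_dihedral = 1, k_angle_flex = 5,
                       ev_eps = 0.2, ev_sigma = 4.0,
                       use_contacts = TRUE, use_ev = TRUE, use_elec = TRUE,
                       use_hydro = FALSE, hydro_eps = 0.2, hydro_r0 = 6) {
  stopifnot(temperature > 0, dt > 0, n_steps >= 0, save_interval >= 1)
  if (use_elec && ionic_strength <= 0)
    stop("ionic_strength must be > 0 when electrostatics are on")
  structure(as.list(environment()), class = "sim_params")
}

#' Debye screening length
#'
#' @param ionic_strength mol/L.
#' @param dielectric Relative dielectric constant.
#' @param temperature Kelvin.
#' @return Screening length in Angstrom (about 7.9 A at 150 mM, 300 K).
#' @export
debye_length <- function(ionic_strength, dielectric = 78, temperature = 300) {
  stopifnot(ionic_strength > 0)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23; NA_ <- 6.02214076e23
  sqrt(eps0 * dielectric * kB * temperature /
         (2 * NA_ * e^2 * ionic_strength * 1000)) * 1e10
}

# Bjerrum length in A, expressed in the package's kBT(300 K) energy unit
.bjerrum_300 <- function(dielectric) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  e^2 / (4 * pi * eps0 * dielectric * kB * 300) * 1e10
}

# pack topology + chain into the list consumed by the compiled kernels
.topo_list <- function(chain, topology, params) {
  b <- chain$beads
  n <- nrow(b)
  hydro <- topology$hydro
  if (isTRUE(params$use_hydro) && nrow(hydro) == 0) {
    hyd_set <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")
    idx <- which(b$res %in% hyd_set)
    if (length(idx) >= 2) {
      prs <- t(utils::combn(idx, 2))
      prs <- prs[abs(prs[, 1] - prs[, 2]) >= 4, , drop = FALSE]
      ckey <- (pmin(topology$contacts$i, topology$contacts$j) - 1) * n +
        (pmax(topology$contacts$i, topology$contacts$j) - 1)
      pkey <- (pmin(prs[, 1], prs[, 2]) - 1) * n + (pmax(prs[, 1], prs[, 2]) - 1)
      hydro <- prs[!(pkey %in% ckey), , drop = FALSE]
    }
  }
  list(bonds = as.matrix(topology$bonds[, c("i", "j", "r0", "k")]),
       angles = as.matrix(topology$angles[, c("i", "j", "k", "theta0", "k_theta")]),
       dihedrals = as.matrix(topology$dihedrals[, c("i", "j", "k", "l", "phi0", "k_phi")]),
       contacts = as.matrix(topology$contacts[, c("i", "j", "r0", "eps")]),
       hydro = matrix(as.numeric(hydro), ncol = 2),
       charges = as.numeric(b$charge),
       excl_keys = as.numeric(topology$excl_keys))
}

.pars_list <- function(params, restraint = NULL) {
  list(kT = params$temperature / 300,
       ev_eps = params$ev_eps, ev_sigma = params$ev_sigma,
       ev_cut = 2.5 * params$ev_sigma,
       lB = .bjerrum_300(params$dielectric),
       lambdaD = debye_length(params$ionic_strength, params$dielectric,
                              params$temperature),
       elec_cut = 40,
       hydro_eps = params$hydro_eps, hydro_r0 = params$hydro_r0,
       use_contacts = isTRUE(params$use_contacts),
       use_ev = isTRUE(params$use_ev),
       use_elec = isTRUE(params$use_elec),
       use_hydro = isTRUE(params$use_hydro),
       restraint = restraint)
}

.check_coords <- function(coords, n) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n-by-3 matrix (n = ", n, ")")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  storage.mode(coords) <- "double"
  coords
}

#' Potential energy decomposition
#'
#' @param chain A `cg_chain` with charges assigned (zero charges are fine).
#' @param topology A `cg_topology` from [build_topology()].
#' @param coords Optional n-by-3 coordinates; defaults to the chain's own.
#' @param params A [sim_params].
#' @param restraint Optional centre-of-mass distance restraint (internal use
#'   by the synthetic-ensemble generator), a list
#'   `list(group_a =, group_b =, k =, target =)`.
#' @return Named vector of energy components (kBT at 300 K) plus `total`.
#' @export
potential_energy <- function(chain, topology, coords = NULL,
                             params = sim_params(), restraint = NULL) {
  coords <- .check_coords(if (is.null(coords)) chain_coords(chain) else coords,
                          topology$n_beads)
  cpp_energy(coords, .topo_list(chain, topology, params),
             .pars_list(params, restraint))
}

#' Forces (negative potential gradient)
#'
#' @inheritParams potential_energy
#' @return n-by-3 matrix of forces, kBT/A.
#' @export
forces <- function(chain, topology, coords = NULL, params = sim_params(),
                   restraint = NULL) {
  coords <- .check_coords(if (is.null(coords)) chain_coords(chain) else coords,
                          topology$n_beads)
  cpp_forces(coords, .topo_list(chain, topology, params),
             .pars_list(params, restraint))
}

#' Run one Langevin dynamics trajectory
#'
#' BAOAB discretization of underdamped Langevin dynamics.  Snapshots are
#' collected every `params$save_interval` steps, the first one after the
#' first full interval.  The random stream is fully determined by `seed`, so
#' identical inputs reproduce the trajectory bitwise.
#'
#' @inheritParams potential_energy
#' @param seed Integer RNG seed for this run.
#' @param run_id Identifier stored with every frame.
#' @return A `cg_trajectory`: list with `frames` (list of n-by-3 matrices),
#'   `steps`, `run_id`, `kinetic` (per-frame kinetic energy), `params`,
#'   `seed`, and `restraint` metadata (`NULL` for production runs).
#' @export
run_langevin <- function(chain, topology, params = sim_params(),
                         coords = NULL, seed = params$seed, run_id = 1L,
                         restraint = NULL) {
  coords <- .check_coords(if (is.null(coords)) chain_coords(chain) else coords,
                          topology$n_beads)
  res <- cpp_langevin(coords, .topo_list(chain, topology, params),
                      .pars_list(params, restraint),
                      as.integer(params$n_steps),
                      as.integer(params$save_interval),
                      params$dt, params$gamma, as.numeric(seed))
  nf <- length(res$steps)
  n <- topology$n_beads
  frames <- lapply(seq_len(nf), function(f)
    matrix(res$frames[((f - 1) * n * 3 + 1):(f * n * 3)], nrow = n, ncol = 3))
  structure(list(frames = frames, steps = as.integer(res$steps),
                 run_id = rep(as.integer(run_id), nf),
                 kinetic = as.numeric(res$kinetic),
                 final_coords = res$final_coords,
                 params = params, seed = seed, restraint = restraint),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames of %d beads (%d run%s)%s\n",
              length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0L,
              length(unique(x$run_id)),
              if (length(unique(x$run_id)) == 1) "" else "s",
              if (is.null(x$restraint)) "" else " [restrained]"))
  invisible(x)
}

#' Run several independent Langevin trajectories and pool the snapshots
#'
#' @inheritParams potential_energy
#' @param n_runs Number of runs; run r uses seed `params$seed + r - 1`.
#' @return A pooled `cg_trajectory` whose `run_id` distinguishes the runs.
#' @export
run_sampling <- function(chain, topology, params = sim_params(),
                         coords = NULL, n_runs = params$n_runs) {
  trajs <- lapply(seq_len(n_runs), function(r)
    run_langevin(chain, topology, params, coords = coords,
                 seed = params$seed + r - 1, run_id = r))
  combine_trajectories(trajs)
}

#' Concatenate trajectories over a common chain
#' @param trajs List of `cg_trajectory` objects.
#' @export
combine_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  out <- trajs[[1]]
  out$frames <- do.call(c, lapply(trajs, `[[`, "frames"))
  out$steps <- do.call(c, lapply(trajs, `[[`, "steps"))
  out$run_id <- do.call(c, lapply(trajs, `[[`, "run_id"))
  out$kinetic <- do.call(c, lapply(trajs, `[[`, "kinetic"))
  out$final_coords <- trajs[[length(trajs)]]$final_coords
  out
}

#' Mean kinetic temperature of a trajectory
#'
#' Equipartition estimate: `T = 300 K * 2 KE / (3 n)` per frame, averaged.
#' @param traj A `cg_trajectory`.
#' @return Kelvin.
#' @export
kinetic_temperature <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"), length(traj$frames) > 0)
  n <- nrow(traj$frames[[1]])
  mean(300 * 2 * traj$kinetic / (3 * n))
}

#' Energy minimization under the model potential
#'
#' L-BFGS-B on the total potential with analytic gradients; used to relax
#' generated structures before they serve as native references.
#'
#' @inheritParams potential_energy
#' @param maxit Iteration cap.
#' @return n-by-3 matrix of minimized coordinates.
#' @export
minimize_structure <- function(chain, topology, params = sim_params(),
                               coords = NULL, restraint = NULL, maxit = 400) {
  coords <- .check_coords(if (is.null(coords)) chain_coords(chain) else coords,
                          topology$n_beads)
  tl <- .topo_list(chain, topology, params)
  pl <- .pars_list(params, restraint)
  n <- topology$n_beads
  fn <- function(x) cpp_energy(matrix(x, n, 3), tl, pl)[["total"]]
  gr <- function(x) -as.vector(cpp_forces(matrix(x, n, 3), tl, pl))
  opt <- optim(as.vector(coords), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  matrix(opt$par, n, 3)
}

#' Fraction of native contacts formed
#'
#' A contact counts as formed when its distance is within `tol` Angstrom of
#' the native distance (distance < r0 + tol, the common convention for
#' C-alpha-level Q).  With `per_unit = TRUE` the fraction is reported per
#' folded unit (requires the chain).
#'
#' @param topology A `cg_topology`.
#' @param coords n-by-3 coordinates.
#' @param tol Formation margin over the native distance, Angstrom.
#' @param chain Optional `cg_chain` for per-unit output.
#' @param per_unit Report one value per folded unit.
#' @export
native_contact_fraction <- function(topology, coords, tol = 2,
                                    chain = NULL, per_unit = FALSE) {
  ct <- topology$contacts
  if (nrow(ct) == 0) return(if (per_unit) numeric(0) else NA_real_)
  d <- sqrt(rowSums((coords[ct$i, , drop = FALSE] -
                     coords[ct$j, , drop = FALSE])^2))
  formed <- d < ct$r0 + tol
  if (!per_unit) return(mean(formed))
  stopifnot(!is.null(chain))
  unit <- chain$beads$unit[ct$i]
  tapply(formed, unit, mean)
}
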