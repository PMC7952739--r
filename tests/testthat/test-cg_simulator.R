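test_that("energy components behave at the native structure and closed forms", {
  p <- sim_params()
  e <- potential_energy(chain_small, topo_small, params = p)
  expect_equal(e[["bond"]], 0, tolerance = 1e-10)
  expect_equal(e[["dihedral"]], 0, tolerance = 1e-10)
  # every native contact sits at its minimum -eps
  expect_equal(e[["contact"]], -nrow(topo_small$contacts) * p$eps_contact,
               tolerance = 1e-8)
  # native angle deviations are zero for native terms (generic linker angles
  # reference 120 deg, not the native geometry, so the component is >= 0)
  expect_gte(e[["angle"]], 0)
  expect_equal(e[["total"]], sum(e[-length(e)]), tolerance = 1e-10)

  # screened-Coulomb closed form: +1/-1 charges one Debye length apart
  lam <- debye_length(0.150, 78, 300)
  ch2 <- structure(list(beads = data.frame(
    resno = 1:5, res = "G", x = c(0, 10, 20, 30, lam), y = c(0, 10, 20, 30, 0),
    z = 0, charge = c(1, 0, 0, 0, -1), domain = "a", flexible = FALSE,
    unit = 1L), chain_id = "A"), class = "cg_chain")
  topo5 <- list(n_beads = 5L,
    bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), k_theta = numeric(0), type = character(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), k_phi = numeric(0)),
    contacts = data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                          eps = numeric(0)),
    hydro = matrix(numeric(0), ncol = 2), excl_keys = numeric(0))
  class(topo5) <- "cg_topology"
  pe <- sim_params(use_ev = FALSE, use_contacts = FALSE)
  e2 <- potential_energy(ch2, topo5, params = pe)
  lB <- cgsaxs:::.bjerrum_300(78)
  expected <- -lB * (exp(-1) / lam - exp(-40 / lam) / 40)   # cutoff-shifted
  expect_equal(e2[["electrostatic"]], expected, tolerance = 1e-10)
  expect_equal(e2[["electrostatic"]], -lB * exp(-1) / lam, tolerance = 5e-3)
})

test_that("energies match an independent term-by-term re-implementation", {
  set.seed(21)
  p <- sim_params()
  x <- chain_coords(chain_small) +
    matrix(rnorm(3 * nrow(chain_small$beads), 0, 0.4), ncol = 3)
  e <- potential_energy(chain_small, topo_small, x, p)
  eo <- r_energy_oracle(chain_small, topo_small, x, p)
  for (term in names(eo))
    expect_equal(e[[term]], eo[[term]], tolerance = 1e-10,
                 label = paste("term", term))
})

test_that("forces are the negative gradient and respect symmetry", {
  set.seed(22)
  p <- sim_params()
  n <- nrow(chain_small$beads)
  x <- chain_coords(chain_small) + matrix(rnorm(3 * n, 0, 0.4), ncol = 3)
  F <- forces(chain_small, topo_small, x, p)
  h <- 1e-5
  scale <- max(abs(F))
  for (k in seq(1, n, by = 3)) for (d in 1:3) {
    xp <- x; xm <- x
    xp[k, d] <- xp[k, d] + h
    xm[k, d] <- xm[k, d] - h
    num <- -(potential_energy(chain_small, topo_small, xp, p)[["total"]] -
               potential_energy(chain_small, topo_small, xm, p)[["total"]]) / (2 * h)
    expect_equal(F[k, d] / scale, num / scale, tolerance = 1e-6)
  }

  # native structure is a stationary point of the purely structure-based terms
  p_go <- sim_params(use_ev = FALSE, use_elec = FALSE, k_angle_flex = 0)
  topo_go <- build_topology(chain_small, params = p_go)
  F_nat <- forces(chain_small, topo_go, params = p_go)
  expect_lt(max(abs(F_nat)), 1e-8)

  # rigid translation leaves forces unchanged
  F2 <- forces(chain_small, topo_small, x + 13.7, p)
  expect_equal(F, F2, tolerance = 1e-9)
})

test_that("Langevin dynamics is deterministic, thermostatted and drift-free", {
  p0 <- sim_params(n_steps = 0)
  tr0 <- run_langevin(chain_small, topo_small, p0, seed = 9)
  expect_length(tr0$frames, 0L)

  p <- sim_params(n_steps = 3000, save_interval = 300)
  tr1 <- run_langevin(chain_small, topo_small, p, seed = 9)
  tr2 <- run_langevin(chain_small, topo_small, p, seed = 9)
  expect_identical(tr1$frames, tr2$frames)
  expect_length(tr1$frames, 10L)          # floor(n_steps / save_interval)
  expect_true(all(diff(tr1$steps) > 0))

  tr3 <- run_langevin(chain_small, topo_small, p, seed = 10)
  expect_false(identical(tr1$frames, tr3$frames))

  # kinetic temperature consistent with the 300 K thermostat
  pT <- sim_params(n_steps = 60000, save_interval = 150)
  trT <- run_langevin(chain_default, topo_default, pT, seed = 17)
  expect_equal(kinetic_temperature(trT), 300, tolerance = 0.03)
  # instantaneous temperatures fluctuate as equipartition predicts
  n <- nrow(chain_default$beads)
  t_inst <- 300 * 2 * trT$kinetic / (3 * n)
  expect_equal(sd(t_inst) / mean(t_inst), sqrt(2 / (3 * n)), tolerance = 0.25)

  # frictionless small-step limit conserves energy to < 0.1% over 1e4 steps
  pn <- sim_params(n_steps = 10000, save_interval = 200, gamma = 0, dt = 0.001)
  trn <- run_langevin(chain_small, topo_small, pn, seed = 12)
  etot <- vapply(seq_along(trn$frames), function(i)
    potential_energy(chain_small, topo_small, trn$frames[[i]], pn)[["total"]],
    0) + trn$kinetic
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("run_sampling pools runs with distinct seeds and run ids", {
  p <- sim_params(n_steps = 1000, save_interval = 250, n_runs = 3, seed = 40)
  traj <- run_sampling(chain_small, topo_small, p)
  expect_length(traj$frames, 12L)
  expect_equal(sort(unique(traj$run_id)), 1:3)
  # different runs explore different states
  expect_false(identical(traj$frames[[1]], traj$frames[[5]]))
})
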