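test_that("Debye profiles match closed forms and the double-sum oracle", {
  q <- seq(0.01, 0.3, length.out = 25)

  # single bead: flat profile of 1
  p1 <- debye_profile(matrix(0, 1, 3), q = q)
  expect_equal(p1$I, rep(1, length(q)))

  # two unit beads at distance d: I(q) = 2 + 2 sin(qd)/(qd)
  d <- 8
  p2 <- debye_profile(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE), q = q)
  expect_equal(p2$I, 2 + 2 * sin(q * d) / (q * d), tolerance = 1e-12)
  # forward limit (sum f)^2
  expect_equal(debye_profile(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE),
                             q = 1e-8)$I, 4, tolerance = 1e-10)

  # random cloud vs brute-force O(N^2) oracle
  cl <- rand_coords(10, seed = 31)
  f <- runif(10, 0.5, 2)
  got <- debye_profile(cl, f, q)$I
  expect_equal(got, r_debye_oracle(cl, f, q), tolerance = 1e-10)

  # rigid-motion invariance
  R <- random_rotation(5)
  cl2 <- sweep(cl %*% t(R), 2, c(11, -4, 2), `+`)
  expect_equal(debye_profile(cl2, f, q)$I, got, tolerance = 1e-10)
})

test_that("coordinate Rg matches its definition", {
  expect_equal(coordinate_rg(matrix(c(4, 5, 6), 1, 3)), 0)
  expect_equal(coordinate_rg(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)), 1)
  cl <- rand_coords(30, seed = 32)
  w <- runif(30, 0.2, 3)
  expect_equal(coordinate_rg(cl, w), r_rg_oracle(cl, w), tolerance = 1e-12)
  expect_equal(coordinate_rg(chain_coords(chain_small)),
               r_rg_oracle(chain_coords(chain_small)), tolerance = 1e-12)
})

test_that("Guinier fits recover Rg from ideal profiles", {
  q <- seq(0.01, 0.5, by = 0.005)
  ideal <- saxs_profile(q, exp(-q^2))
  g <- guinier_fit(ideal)
  expect_equal(g$rg, sqrt(3), tolerance = 1e-6)
  expect_equal(g$i0, 1, tolerance = 1e-6)

  # ideal Debye profile of the toy: Guinier Rg tracks coordinate Rg
  x <- chain_coords(chain_default)
  rg_c <- coordinate_rg(x)
  qf <- seq(0.002, 0.1, length.out = 80)
  prof <- debye_profile(x, q = qf)
  expect_equal(guinier_fit(prof, q_rg_max = 1.0)$rg, rg_c, tolerance = 0.02)
  expect_equal(guinier_fit(prof, q_rg_max = 0.8)$rg, rg_c, tolerance = 0.01)

  expect_error(guinier_fit(saxs_profile(c(0.01, 0.02), c(1, 0.9))), "3 points")
})

test_that("pair distance distributions normalize and bound Dmax", {
  two <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  dd <- distance_distribution(two, bin = 1)
  expect_equal(dd$dmax, 10)
  expect_equal(sum(dd$p > 0), 1L)
  expect_equal(dd$r[dd$p > 0], 10.5)   # the 10-11 A bin

  cl <- rand_coords(40, seed = 33)
  dd2 <- distance_distribution(cl, bin = 0.5)
  expect_equal(sum(dd2$p) * 0.5, 1, tolerance = 1e-9)
  expect_equal(dd2$dmax, max(dist(cl)), tolerance = 1e-10)
})

test_that("chi-square is scale-invariant with a closed-form optimal scale", {
  q <- seq(0.01, 0.25, length.out = 60)
  x <- chain_coords(chain_small)
  base <- debye_profile(x, q = q)
  target <- saxs_profile(q, base$I, sigma = rep(1, length(q)))

  same <- chi_square(base, target)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$scale, 1, tolerance = 1e-12)

  doubled <- saxs_profile(q, 2 * base$I)
  cs <- chi_square(doubled, target)
  expect_equal(cs$chi2, 0, tolerance = 1e-12)
  expect_equal(cs$scale, 0.5, tolerance = 1e-12)

  # chi2 invariant under any positive rescaling of the model
  set.seed(34)
  noisy <- saxs_profile(q, base$I * (1 + 0.05 * rnorm(length(q))),
                        sigma = 0.05 * base$I)
  for (c0 in c(0.1, 3, 42)) {
    scaled <- saxs_profile(q, c0 * base$I)
    expect_equal(chi_square(scaled, noisy)$chi2,
                 chi_square(base, noisy)$chi2, tolerance = 1e-10)
  }

  # statistical consistency: noise at the stated sigma gives chi2 ~ 1
  expect_lt(abs(chi_square(base, noisy)$chi2 - 1), 3 / sqrt(length(q)))

  # closed-form scale agrees with a grid search
  cs2 <- chi_square(base, noisy)
  grid <- seq(cs2$scale * 0.8, cs2$scale * 1.2, length.out = 4001)
  Im <- base$I
  chi_at <- vapply(grid, function(cc)
    sum(((cc * Im - noisy$I) / noisy$sigma)^2) / (length(q) - 1), 0)
  expect_equal(cs2$scale, grid[which.min(chi_at)], tolerance = 1e-3)
  expect_lte(cs2$chi2, min(chi_at) + 1e-10)
})

test_that("mixture profiles weight components by number concentration", {
  q <- seq(0.01, 0.3, length.out = 50)
  x <- chain_coords(chain_small)
  mono <- debye_profile(x, q = q)

  single <- mixture_profile(list(mono), mixture_spec(1, 1, 100))
  expect_equal(single$I, mono$I)

  # hand-computed weighted sum for a 96/3/1 monomer/dimer/trimer mixture
  dimer <- debye_profile(rbind(x, sweep(x, 2, c(30, 0, 0), `+`)), q = q)
  trimer <- debye_profile(rbind(x, sweep(x, 2, c(30, 0, 0), `+`),
                                sweep(x, 2, c(60, 0, 0), `+`)), q = q)
  spec <- mixture_spec(1:3, c(0.96, 0.03, 0.01), c(100, 200, 300))
  mix <- mixture_profile(list(mono, dimer, trimer), spec)
  expect_equal(mix$I, 0.96 * mono$I + 0.03 / 2 * dimer$I + 0.01 / 3 * trimer$I,
               tolerance = 1e-12)

  # identical components collapse to the single-component profile
  mix_id <- mixture_profile(list(mono, mono, mono),
                            mixture_spec(c(1, 1, 1), c(0.5, 0.3, 0.2),
                                         c(100, 100, 100)))
  expect_equal(mix_id$I, mono$I, tolerance = 1e-12)

  expect_error(mixture_spec(1:2, c(0.5, 0.4)), "sum to 1")
})

test_that("aggregate correction recovers the monomer and is monotone", {
  # ensemble-free check on a static structure
  q <- seq(0.005, 0.25, length.out = 120)
  x <- chain_coords(chain_default)
  truth <- debye_profile(x, q = q)
  rg_truth <- guinier_fit(truth)$rg

  # synthetic aggregates with density-preserving Rg scaling
  agg2 <- cgsaxs:::.aggregate_coords(x, 2)
  agg3 <- cgsaxs:::.aggregate_coords(x, 3)
  expect_equal(coordinate_rg(agg2), 2^(1 / 3) * coordinate_rg(x), tolerance = 1e-6)
  expect_equal(coordinate_rg(agg3), 3^(1 / 3) * coordinate_rg(x), tolerance = 1e-6)

  n <- nrow(x)
  spec <- mixture_spec(1:3, c(0.96, 0.03, 0.01), n * (1:3))
  obs <- mixture_profile(list(truth, debye_profile(agg2, q = q),
                              debye_profile(agg3, q = q)), spec)
  rg_obs <- guinier_fit(obs)$rg
  expect_gt(rg_obs, rg_truth)          # aggregates inflate the apparent Rg

  mono <- extract_monomer_profile(obs, spec)
  rg_rec <- guinier_fit(mono)$rg
  expect_lt(rg_rec, rg_obs)            # correction moves Rg downward
  expect_equal(rg_rec, rg_truth, tolerance = 0.01)

  # stating more trimer strictly lowers the recovered low-q intensity
  spec_hi <- mixture_spec(1:3, c(0.94, 0.03, 0.03), n * (1:3))
  mono_hi <- extract_monomer_profile(obs, spec_hi)
  low_q <- obs$q < 0.05
  expect_true(all(mono_hi$I[low_q] < mono$I[low_q]))

  # no aggregates: identity, with a message
  expect_message(
    out <- extract_monomer_profile(truth, mixture_spec(1, 1, n)),
    "no aggregates")
  expect_equal(out$I, truth$I)
})
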