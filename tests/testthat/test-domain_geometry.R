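test_that("domain COMs are arithmetic means of folded beads", {
  one <- chain_small
  one$beads$domain[1] <- "solo"
  one$beads$flexible[1] <- FALSE
  expect_equal(domain_com(one, label = "solo"),
               unlist(one$beads[1, c("x", "y", "z")]), ignore_attr = TRUE)

  x <- chain_coords(chain_small)
  idx <- which(chain_small$beads$domain == "a" & !chain_small$beads$flexible)
  expect_equal(domain_com(chain_small, label = "a"), colMeans(x[idx, ]),
               ignore_attr = TRUE)
  expect_error(domain_com(chain_small, label = "nope"), "empty domain")
})

test_that("COM angles and dihedrals match closed forms and the oracle", {
  expect_equal(com_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(com_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_error(com_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")

  # planar cis / trans
  expect_equal(com_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(com_dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 180)

  set.seed(41)
  for (k in 1:20) {
    p <- matrix(rnorm(12), 4, 3) * 4
    got <- com_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(got, r_dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    # mirror reflection negates the signed dihedral
    pm <- p; pm[, 3] <- -pm[, 3]
    mirrored <- com_dihedral(pm[1, ], pm[2, ], pm[3, ], pm[4, ])
    expect_equal(mirrored, -got, tolerance = 1e-9)
    # the left-handed convention is the sign flip
    expect_equal(com_dihedral(p[1, ], p[2, ], p[3, ], p[4, ], convention = "left"),
                 -got, tolerance = 1e-12)
  }
  expect_error(com_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("Kabsch superposition recovers rigid motions and is symmetric", {
  x <- chain_coords(chain_small)
  self <- kabsch_superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)

  R <- random_rotation(42)
  tvec <- c(5, -3, 11)
  moved <- sweep(x %*% t(R), 2, tvec, `+`)
  fit <- kabsch_superpose(x, moved)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(fit$transform(moved), x, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # near-degenerate case that would otherwise pick a reflection
  flat <- cbind(rnorm(10), rnorm(10), 0)
  fit2 <- kabsch_superpose(flat, flat %*% diag(c(1, 1, -1)))
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)

  # swapping roles gives the same RMSD
  set.seed(43)
  y <- x + matrix(rnorm(length(x), 0, 0.8), ncol = 3)
  expect_equal(kabsch_superpose(x, y)$rmsd, kabsch_superpose(y, x)$rmsd,
               tolerance = 1e-10)

  # independent cross-check against the field-standard implementation
  # (bio3d rounds its RMSD to three decimals)
  xyz_a <- as.vector(t(x)); xyz_b <- as.vector(t(y))
  ref_rmsd <- bio3d::rmsd(xyz_a, xyz_b, fit = TRUE)
  expect_lt(abs(kabsch_superpose(x, y)$rmsd - ref_rmsd), 1e-3)

  expect_error(kabsch_superpose(x, y, selection = 1:2), "3 points")
})

test_that("geometry tables summarize per-frame descriptors", {
  x <- chain_coords(chain_small)
  gt1 <- geometry_table(chain_small, list(x, x, x))
  expect_equal(nrow(gt1), 3L)
  summ <- attr(gt1, "summary")
  expect_equal(summ$sd, rep(0, 4))
  expect_equal(unlist(gt1[1, ]), unname(toy_small$realized), tolerance = 1e-6,
               ignore_attr = TRUE)

  # rigid motion of a frame leaves every descriptor unchanged
  R <- random_rotation(44)
  moved <- sweep(x %*% t(R), 2, c(-7, 2, 30), `+`)
  gt2 <- geometry_table(chain_small, list(x, moved))
  expect_equal(unlist(gt2[1, ]), unlist(gt2[2, ]), tolerance = 1e-8)

  # hand-computed two-frame check through the COM helpers
  coms <- lapply(c("a", "b", "bp", "ap"), function(d)
    domain_com(chain_small, moved, d))
  expect_equal(gt2$theta1[2], com_angle(coms[[1]], coms[[2]], coms[[3]]))
  expect_equal(gt2$d[2], sqrt(sum((coms[[1]] - coms[[4]])^2)))
})

test_that("averaged COM models remove rigid motion and report shifts", {
  x <- chain_coords(chain_small)
  avg1 <- averaged_com_model(chain_small, list(x, x))
  expect_equal(avg1$spread, setNames(rep(0, 4), c("a", "b", "bp", "ap")),
               tolerance = 1e-10)
  expect_equal(avg1$com[, "a"], domain_com(chain_small, x, "a"),
               ignore_attr = TRUE, tolerance = 1e-10)

  # two frames differing by a global rigid motion give the same model
  R <- random_rotation(45)
  moved <- sweep(x %*% t(R), 2, c(3, 3, 3), `+`)
  avg2 <- averaged_com_model(chain_small, list(x, moved))
  expect_equal(avg2$com, avg1$com, tolerance = 1e-8)
  expect_lt(max(avg2$spread), 1e-8)

  expect_equal(com_shift(avg1, avg2, "ap"), 0, tolerance = 1e-8)
  # hand-placed COM displacement
  avg3 <- avg1
  avg3$com[, "ap"] <- avg3$com[, "ap"] + c(3, 4, 0)
  expect_equal(com_shift(avg1, avg3, "ap"), 5)
  expect_equal(com_shift(avg1, avg3, "a"), 0)
  expect_error(com_shift(avg1, avg3, "zz"), "not present")
})

test_that("frequency maps normalize and subtract", {
  tabA <- data.frame(theta2 = c(110, 112, 131, 149, 150),
                     d = c(25, 25.4, 27, 30, 31))
  tabB <- data.frame(theta2 = c(95, 112, 131), d = c(24, 25.4, 27))
  fm <- frequency_maps(tabA, tabB, pair = c("theta2", "d"), bins = c(5, 1))
  expect_equal(sum(fm$mapA), 1, tolerance = 1e-9)
  expect_equal(sum(fm$mapB), 1, tolerance = 1e-9)
  expect_equal(fm$difference, fm$mapA - fm$mapB)

  # manual count: bin [110,115) x [25,26) holds rows 1 and 2 of A
  ix <- findInterval(112, fm$x)
  iy <- findInterval(25.5, fm$y)
  expect_equal(fm$mapA[ix, iy], 2 / 5)
  expect_equal(fm$mapB[ix, iy], 1 / 3)

  fm0 <- frequency_maps(tabA, tabA, pair = c("theta2", "d"), bins = c(5, 1))
  expect_true(all(fm0$difference == 0))
  expect_error(frequency_maps(tabA, tabB, c("theta2", "d"), c(0, 1)),
               "zero-width")
})
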