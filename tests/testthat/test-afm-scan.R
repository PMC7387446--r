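test_that("tip_overlap_count follows the strict-interior convention", {
  tip <- tip_model(apex_radius = 10)
  ac <- atom_collection(0, 0, 5)
  expect_gte(tip_overlap_count(tip, c(0, 0, 5), ac), 1)    # at sphere center
  ac0 <- atom_collection(0, 0, 0)
  expect_equal(tip_overlap_count(tip, c(0, 0, 20.001), ac0), 0)
  # lateral offset exactly R at apex-center height: tangent, not overlap
  acR <- atom_collection(10, 0, 5)
  expect_equal(tip_overlap_count(tip, c(0, 0, 5), acR), 0)
  # atom in the cone volume above the apex
  acC <- atom_collection(0, 0, 30)
  expect_equal(tip_overlap_count(tip, c(0, 0, 5), acC), 1)
  # hydrogens excluded
  acH <- atom_collection(0, 0, 5, element = "H")
  expect_equal(tip_overlap_count(tip, c(0, 0, 5), acH), 0)
})

test_that("single point atom images as the analytic spherical cap", {
  h <- 10; R <- 10
  ac <- atom_collection(0, 0, h)
  g <- scan_grid(-12, 12, -12, 12, 0.5)
  hm <- scan_topograph(ac, tip_model(apex_radius = R), g)
  rho <- sqrt(outer(g$x^2, g$y^2, `+`))
  # inside the cap footprint the profile is exact; outside, the cone skirt
  # takes over, which is below the (zero) cap value
  inside <- rho < R
  expect_equal(hm$values[inside], cap_profile(rho[inside], h, R),
               tolerance = 1e-12)
  expect_equal(hm$values[g$x == 0, g$y == 0], 10)
  expect_equal(hm$values[g$x == 6, g$y == 0], 8)  # h + sqrt(R^2-36) - R
})

test_that("overlap threshold ignores the k weakest contacts", {
  ac <- atom_collection(0, 0, 10)
  g <- scan_grid(-5, 5, -5, 5, 1)
  tip1 <- tip_model(overlap_threshold = 1)
  hm <- scan_topograph(ac, tip1, g)
  expect_true(all(hm$values == 0))   # the single atom is ignored

  # two stacked atoms, threshold 1: image equals the single-atom scan of
  # the remaining (lower) atom
  two <- atom_collection(c(0, 0), c(0, 0), c(10, 4))
  hm2 <- scan_topograph(two, tip1, g)
  ref <- scan_topograph(atom_collection(0, 0, 4), tip_model(), g)
  expect_equal(hm2$values, ref$values, tolerance = 1e-12)
})

test_that("empty regions give zero height and empty scenes warn", {
  ac <- atom_collection(0, 0, 10)
  g_far <- scan_grid(100, 110, 100, 110, 1)
  hm <- scan_topograph(ac, tip_model(z_cutoff = 15), g_far)
  expect_true(all(hm$values == 0))
  acH <- atom_collection(0, 0, 5, element = "H")
  expect_warning(hm0 <- scan_topograph(acH, tip_model(),
                                       scan_grid(-2, 2, -2, 2, 1)),
                 "empty")
  expect_true(all(hm0$values == 0))
})

test_that("scan and dilation oracle agree exactly on random scenes", {
  tip <- tip_model(apex_radius = 10, cone_half_angle = 20)
  g <- scan_grid(-15, 15, -15, 15, 0.5)
  for (seed in 1:12) {
    sc <- random_scene(sample(1:50, 1), seed)
    a <- scan_topograph(sc, tip, g)
    b <- dilation_oracle(sc, tip, g)
    expect_lt(max(abs(a$values - b$values)), 1e-9)
  }
})

test_that("recorded contact is consistent with the overlap predicate", {
  # independent check: just below the recorded tip height there must be an
  # overlap; just above, none (for unfloored nodes)
  tip <- tip_model()
  g <- scan_grid(-10, 10, -10, 10, 2.5)
  sc <- random_scene(20, seed = 99)
  hm <- scan_topograph(sc, tip, g)
  for (i in seq_along(g$x)) {
    for (j in seq_along(g$y)) {
      h <- hm$values[i, j]
      zt <- h + tip$apex_radius
      expect_equal(tip_overlap_count(tip, c(g$x[i], g$y[j], zt + 1e-7), sc), 0)
      if (h > 0) {
        expect_gt(tip_overlap_count(tip, c(g$x[i], g$y[j], zt - 1e-7), sc), 0)
      }
    }
  }
})

test_that("dilation is max-plus linear: far-apart atoms superpose", {
  tip <- tip_model()
  g <- scan_grid(-30, 30, -30, 30, 1)
  a1 <- atom_collection(-20, 0, 8)
  a2 <- atom_collection(20, 5, 12)
  both <- atom_collection(c(-20, 20), c(0, 5), c(8, 12))
  h1 <- scan_topograph(a1, tip, g)$values
  h2 <- scan_topograph(a2, tip, g)$values
  hb <- scan_topograph(both, tip, g)$values
  expect_equal(hb, pmax(h1, h2), tolerance = 1e-12)
})

test_that("scan invariants: dominance, equivariance, tip monotonicity", {
  tip <- tip_model()
  g <- scan_grid(-15, 15, -15, 15, 0.5)
  sc <- random_scene(30, seed = 7)
  hm <- scan_topograph(sc, tip, g)

  # dilation never erodes: at the node nearest each atom the image is at
  # least the atom height minus the sub-pixel cap falloff
  # (R - sqrt(R^2 - step^2/2) < 0.007 A here)
  for (k in seq_len(nrow(sc))) {
    i <- which.min(abs(g$x - sc$x[k]))
    j <- which.min(abs(g$y - sc$y[k]))
    expect_gte(hm$values[i, j], sc$z[k] - 0.007)
  }

  # translation equivariance: shift atoms one grid step -> shift image
  shifted <- sc; shifted$x <- shifted$x + g$step
  hs <- scan_topograph(shifted, tip, g)
  expect_equal(hs$values[-1, ], hm$values[-nrow(hm$values), ],
               tolerance = 1e-12)

  # enlarging the apex never decreases any height
  big <- scan_topograph(sc, tip_model(apex_radius = 14), g)
  expect_true(all(big$values - hm$values >= -1e-12))
})

test_that("average_topograph folds periodic maps onto one cell", {
  g <- scan_grid(0, 7.5, 0, 3.5, 0.5)  # 16 x 8 nodes
  base <- matrix(runif(4 * 8), 4, 8)
  per <- height_map(rbind(base, base, base, base), g)  # 4 cells along x
  avg <- average_topograph(per, cell_x = 2, cell_y = 4)
  expect_equal(avg$values, base, tolerance = 1e-12)

  # two cells with values v and v + 2 average to v + 1
  v <- matrix(3, 4, 8)
  g2 <- scan_grid(0, 3.5, 0, 3.5, 0.5)  # 8 x 8 nodes
  two <- height_map(rbind(v, v + 2), g2)
  expect_true(all(abs(average_topograph(two, 2, 4)$values - 4) < 1e-12))

  # single full-extent cell: identity
  m <- matrix(runif(16 * 8), 16, 8)
  hm <- height_map(m, g)
  expect_equal(average_topograph(hm, 8, 4)$values, m)

  expect_error(average_topograph(per, 2.3, 4), "multiple")
})

test_that("height maps round-trip through tsv and ascii-matrix", {
  g <- scan_grid(-2, 2, -1, 1, 0.5)
  hm <- height_map(matrix(abs(rnorm(9 * 5)), 9, 5), g, "test map")

  tsv <- tempfile(fileext = ".tsv")
  write_heightmap(hm, tsv, "tsv")
  back <- read_heightmap(tsv, "tsv", grid = g)
  expect_identical(back$values, hm$values)    # bit-identical

  am <- tempfile(fileext = ".txt")
  write_heightmap(hm, am, "ascii-matrix")
  lines <- readLines(am)
  expect_match(lines[2], "Width: 0.4", fixed = TRUE)  # 4 A -> 0.4 nm
  back2 <- read_heightmap(am, "ascii-matrix", grid = g)
  expect_equal(back2$values, hm$values, tolerance = 1e-12)

  # unit conversion: 10 A internal -> 1.0 nm in file
  hm10 <- height_map(matrix(10, 2, 2), scan_grid(0, 1, 0, 1, 1))
  f10 <- tempfile()
  write_heightmap(hm10, f10, "ascii-matrix")
  vals <- utils::read.table(f10, comment.char = "#")
  expect_true(all(vals == 1.0))
})

test_that("tiff export writes a constant image for a constant map", {
  skip_if_not_installed("tiff")
  hm <- height_map(matrix(5, 4, 4), scan_grid(0, 3, 0, 3, 1))
  f <- tempfile(fileext = ".tif")
  write_heightmap(hm, f, "tiff")
  img <- tiff::readTIFF(f)
  expect_equal(length(unique(as.vector(img))), 1)
  expect_true(file.exists(paste0(f, ".scale.txt")))
})
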