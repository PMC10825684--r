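toy_mask <- function(vals, dm = c(length(vals), 1, 1), spacing = c(1, 1, 1)) {
  voxel_mask(array(as.logical(vals), dm), spacing)
}

test_that("Dice follows hand-counted voxel overlap", {
  a <- toy_mask(c(1, 1, 0))
  b <- toy_mask(c(0, 1, 1))
  expect_equal(dice(a, b), 0.5)   # |A|=2, |B|=2, |A^B|=1
  expect_equal(dice(a, a), 1)
  expect_equal(dice(toy_mask(c(1, 0, 0)), toy_mask(c(0, 0, 1))), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(toy_mask(c(0, 0, 0)), toy_mask(c(0, 0, 0))), "empty")
  expect_error(dice(a, toy_mask(c(1, 1), dm = c(2, 1, 1))), "mismatch")
  expect_error(dice(a, toy_mask(c(1, 1, 0), spacing = c(2, 1, 1))),
               "mismatch")
})

test_that("surface Dice separates parallel slabs by physical distance", {
  dm <- c(20, 5, 5)
  slab <- function(x0, x1) {
    g <- array(FALSE, dm); g[x0:x1, , ] <- TRUE
    voxel_mask(g, c(1, 1, 1))
  }
  a <- slab(3, 5)
  b <- slab(8, 10)   # shifted 5 mm along x
  expect_equal(surface_dice(a, a, 3), 1)
  expect_equal(surface_dice(a, a, 0), 1)
  sd3 <- surface_dice(a, b, 3)
  expect_lt(sd3, 1)
  expect_equal(surface_dice(a, b, 6), 1)   # every face within 6 mm
  expect_equal(sd3, surface_dice(b, a, 3))  # symmetry
  # non-decreasing in tolerance
  tol_vals <- c(0, 1, 2, 3, 4, 5, 6)
  sds <- vapply(tol_vals, function(t) surface_dice(a, b, t), numeric(1))
  expect_true(all(diff(sds) >= 0))
  # tolerance 0 on non-identical masks stays below 1
  expect_lt(surface_dice(a, b, 0), 1)
  expect_error(surface_dice(a, voxel_mask(array(FALSE, dm)), 3),
               "non-empty")
})

test_that("surface Dice respects anisotropic spacing", {
  dm <- c(10, 4, 4)
  one <- function(x) {
    g <- array(FALSE, dm); g[x, 2, 2] <- TRUE
    g
  }
  # neighbouring single voxels along x; with 2 mm x-spacing their facing
  # surfaces coincide but the far faces are 4 mm apart
  a <- voxel_mask(one(4), spacing = c(2, 1, 1))
  b <- voxel_mask(one(5), spacing = c(2, 1, 1))
  expect_lt(surface_dice(a, b, 1.9), 1)
  expect_equal(surface_dice(a, b, 4), 1)
  # the same masks at 1 mm spacing need only half the tolerance
  a1 <- voxel_mask(one(4), spacing = c(1, 1, 1))
  b1 <- voxel_mask(one(5), spacing = c(1, 1, 1))
  expect_equal(surface_dice(a1, b1, 2), 1)
})

test_that("mean dose and VxGy follow their definitions", {
  dm <- c(2, 2, 1)
  msk <- voxel_mask(array(c(TRUE, TRUE, FALSE, FALSE), dm))
  dg <- dose_grid(array(c(10, 20, 99, 99), dm))
  expect_equal(mean_dose(dg, msk), 15)
  uni <- dose_grid(array(7, dm))
  expect_equal(mean_dose(uni, msk), 7)
  # V5/V10/V30 on hand-counted doses
  m4 <- voxel_mask(array(TRUE, c(4, 1, 1)))
  d4 <- dose_grid(array(c(2, 6, 11, 31), c(4, 1, 1)))
  expect_equal(vxgy(d4, m4, c(5, 10, 30)), c(75, 50, 25))
  expect_equal(vxgy(d4, m4, 0), 100)
  expect_equal(vxgy(d4, m4, 1000), 0)
  expect_equal(vxgy(d4, m4, 31), 25)  # inclusive threshold
  xs <- seq(0, 40, by = 2.5)
  expect_true(all(diff(vxgy(d4, m4, xs)) <= 0))
  expect_error(mean_dose(dg, voxel_mask(array(FALSE, dm))), "empty")
  expect_error(vxgy(dg, voxel_mask(array(FALSE, dm)), 5), "empty")
})

test_that("all four metrics agree with brute-force voxel loops", {
  set.seed(202)
  for (i in 1:12) {
    dm <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
    spacing <- runif(3, 0.5, 3)
    a <- random_mask(dm); b <- random_mask(dm)
    if (!any(a) || !any(b)) next
    dose <- array(runif(prod(dm), 0, 60), dm)
    va <- voxel_mask(a, spacing); vb <- voxel_mask(b, spacing)
    dg <- dose_grid(dose, spacing)
    expect_equal(dice(va, vb), oracle_dice(a, b), tolerance = 1e-12)
    expect_equal(mean_dose(dg, va), oracle_mean_dose(dose, a),
                 tolerance = 1e-10)
    for (x in c(10, 30))
      expect_equal(vxgy(dg, va, x), oracle_vxgy(dose, a, x),
                   tolerance = 1e-12)
    for (tol in c(1, 3))
      expect_equal(surface_dice(va, vb, tol),
                   oracle_surface_dice(a, b, spacing, tol),
                   tolerance = 1e-10)
  }
})

test_that("cohort-level metric summaries report mean and SD", {
  tab <- summarize_metrics(dice = c(0.9, 0.8, 0.85),
                           surface_dice_3mm = c(0.7, 0.6, 0.65))
  expect_equal(tab$metric, c("dice", "surface_dice_3mm"))
  expect_equal(tab$mean, c(0.85, 0.65))
  expect_equal(tab$sd, c(sd(c(0.9, 0.8, 0.85)), sd(c(0.7, 0.6, 0.65))))
  expect_equal(tab$n, c(3L, 3L))
})

test_that("NRRD round-trips masks and dose grids with geometry", {
  ph <- generate_phantom_pair(dim = c(9, 7, 5), spacing = c(1.5, 1, 2),
                              radius = 3, origin = c(-4, 0, 2.5),
                              dose_field = "gaussian")
  fm <- tempfile(fileext = ".nrrd")
  fd <- tempfile(fileext = ".nrrd")
  write_nrrd(ph$mask_a, fm)
  write_nrrd(ph$dose, fd)
  m <- read_nrrd(fm)
  d <- read_nrrd(fd)
  expect_s3_class(m, "voxel_mask")
  expect_s3_class(d, "dose_grid")
  expect_identical(m$grid, ph$mask_a$grid)
  expect_equal(m$spacing, c(1.5, 1, 2))
  expect_equal(m$origin, c(-4, 0, 2.5))
  expect_equal(d$grid, ph$dose$grid, tolerance = 1e-12)
  # metrics survive the round trip exactly
  expect_equal(mean_dose(d, m), mean_dose(ph$dose, ph$mask_a),
               tolerance = 1e-12)
})
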