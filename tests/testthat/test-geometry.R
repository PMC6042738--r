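test_that("anatomy grid enumerates 9 variants, 81 combinations, 243 normals, 1944 lesion models", {
  expect_equal(nrow(anatomy_variants()), 9)
  expect_equal(nrow(enumerate_models(heights = 1)), 81)
  expect_equal(nrow(enumerate_models(heights = 3)), 243)
  expect_equal(nrow(enumerate_models(heights = 3, with_lesions = TRUE)), 1944)
  # descriptors are unique and deterministically ordered
  m <- enumerate_models(heights = 3, with_lesions = TRUE)
  expect_equal(anyDuplicated(m$model_id), 0)
  expect_identical(m$model_id, enumerate_models(heights = 3, with_lesions = TRUE)$model_id)
})

test_that("geometry scaling is componentwise and preserves containment", {
  base <- make_head_geometry(anatomy_spec())
  expect_equal(base$head_semi_axes, c(0.095, 0.115, 0.120))
  expect_gt(base$clearance, 0)

  big_brain <- make_head_geometry(anatomy_spec(brain_scale = "xyz+"))
  vol_ratio <- prod(big_brain$brain_semi_axes) / prod(base$brain_semi_axes)
  expect_equal(vol_ratio, 1.05^3, tolerance = 1e-12)

  # the containment check trips when the required clearance is not met
  expect_error(
    make_head_geometry(anatomy_spec("xyz-", "xyz+"), min_clearance_m = 0.02),
    "clearance"
  )
})

test_that("lesion radius follows the sphere volume law", {
  expect_equal(lesion_radius(30), 0.01928, tolerance = 1e-3)
  expect_equal(lesion_radius(60), 0.02429, tolerance = 1e-3)
  # independent check against the volume integral
  r <- lesion_radius(17)
  expect_equal(4 / 3 * pi * r^3, 17e-6, tolerance = 1e-12)
  expect_error(lesion_radius(0), "positive")
  expect_error(lesion_radius(-5), "positive")
})

test_that("lesion placement sits on the cardinal axis inside the brain", {
  geom <- make_head_geometry(anatomy_spec())
  ring <- electrode_ring_spec()
  les <- place_lesion(geom, lesion_spec(30, "north"), ring)
  r <- lesion_radius(30)
  expect_equal(les$centre[1], 0)
  expect_equal(les$centre[3], geom$brain_centre[3])
  expect_equal(les$centre[2], geom$brain_semi_axes[2] - 2e-3 - r, tolerance = 1e-12)
  expect_identical(region_membership(geom, rbind(les$centre)), "brain")

  # east and west are mirror images in X
  e <- place_lesion(geom, lesion_spec(30, "east"), ring)
  w <- place_lesion(geom, lesion_spec(30, "west"), ring)
  expect_equal(e$centre * c(-1, 1, 1), w$centre)

  # oversized inset pushes the sphere across the brain centreline
  expect_error(
    place_lesion(geom, lesion_spec(60, "north", inset_mm = 45), ring),
    "centreline"
  )
})

test_that("every placed lesion sphere is wholly inside the brain region", {
  geom <- make_head_geometry(anatomy_spec())
  ring <- electrode_ring_spec()
  set.seed(11)
  for (vol in c(5, 30, 60)) {
    les <- place_lesion(geom, lesion_spec(vol, "west"), ring)
    u <- matrix(rnorm(3000), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * runif(1000)^(1 / 3) * les$radius
    pts <- sweep(u, 2, les$centre, "+")
    memb <- region_membership(geom, pts, les)
    expect_true(all(memb %in% c("brain", "lesion")))
  }
})

test_that("lesion inset is preserved under anatomy scaling", {
  ring <- electrode_ring_spec()
  for (variant in c("base", "xyz+", "xyz-")) {
    geom <- make_head_geometry(anatomy_spec(brain_scale = variant))
    les <- place_lesion(geom, lesion_spec(30, "north"), ring)
    gap <- geom$brain_semi_axes[2] - (les$centre[2] + les$radius)
    expect_equal(gap, 2e-3, tolerance = 1e-4) # within 0.1 mm
  }
})

test_that("electrode ring has 16 arc-equidistant, sagittally symmetric points", {
  geom <- make_head_geometry(anatomy_spec())
  pos <- electrode_positions(geom, electrode_ring_spec())
  expect_equal(dim(pos), c(16, 3))
  # electrodes 1 and 16 flank north: their midpoint has the maximal +Y
  mid <- (pos[1, ] + pos[16, ]) / 2
  expect_true(mid[2] > max(pos[, 2]) - 1e-9)
  # sagittal symmetry: electrode k mirrors electrode 17-k in X
  for (k in 1:8) {
    expect_equal(pos[k, 1], -pos[17 - k, 1], tolerance = 1e-6)
    expect_equal(pos[k, 2], pos[17 - k, 2], tolerance = 1e-6)
  }
  # arc-length spacing is uniform to 1%
  d <- sqrt(rowSums((pos - pos[c(2:16, 1), ])^2))
  expect_lt((max(d) - min(d)) / mean(d), 0.01)

  # the three ring heights form parallel planes 2 mm apart
  z <- vapply(c(-2, 0, 2), function(h) {
    electrode_positions(geom, electrode_ring_spec(height_offset_mm = h))[1, 3]
  }, numeric(1))
  expect_equal(diff(z), c(2e-3, 2e-3), tolerance = 1e-12)
})
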