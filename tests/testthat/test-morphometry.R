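test_that("structure volumes follow voxel arithmetic and conservation", {
  vol <- label_volume(array(4L, c(10, 10, 10)), 1)
  expect_equal(structure_volume(vol, 4L), 1.0)
  expect_equal(structure_volume(vol, 7L), 0)
  ph <- fx_phantom()
  total <- sum(ph$codes != 0L) * ph$voxel_size^3 / 1000
  by_code <- sum(vapply(setdiff(sort(unique(as.vector(ph$codes))), 0L),
                        function(cd) structure_volume(ph, cd), 0))
  expect_equal(by_code, total)
})

test_that("a voxelized sphere recovers the analytic volume within 2%", {
  vs <- 0.5; r <- 5
  n <- 24
  coords <- (seq_len(n) - 0.5) * vs
  d2 <- outer(outer((coords - 6)^2, (coords - 6)^2, "+"), (coords - 6)^2, "+")
  codes <- array(0L, c(n, n, n)); codes[d2 <= r^2] <- 4L
  vol <- label_volume(codes, vs)
  expect_equal(structure_volume(vol, 4L), 4 / 3 * pi * r^3 / 1000,
               tolerance = 0.02)
})

test_that("structure volume is invariant under axis permutation", {
  ph <- fx_phantom()
  perm <- label_volume(aperm(ph$codes, c(3, 1, 2)), ph$voxel_size,
                       ph$dictionary)
  for (cd in c(3L, 4L, 8L, 12L))
    expect_equal(structure_volume(perm, cd), structure_volume(ph, cd))
})

test_that("wall thickness is measured as ray run length", {
  # 5-voxel wall at 1 mm spanning x = 10..14, tall in y
  codes <- array(0L, c(30, 30, 3)); codes[11:15, 5:25, ] <- 4L
  codes[11:15, 26, 2] <- 14L; codes[c(10, 16), 15, 2] <- 2L  # plane tokens
  vol <- label_volume(codes, 1)
  plane <- structure(list(orientation = "short_axis", tag = "mid",
                          axis = 3L, index = 2L),
                     class = "measurement_plane")
  expect_equal(wall_thickness(vol, plane, c(5, 15.2), c(1, 0), 4L), 5,
               tolerance = 0.05)
  expect_equal(wall_thickness(vol, plane, c(5, 10.2), c(1, 1), 4L),
               5 * sqrt(2), tolerance = 0.06)
  expect_error(wall_thickness(vol, plane, c(5, 2.2), c(1, 0), 4L),
               "does not intersect")
})

test_that("chamber diameter is the widest in-plane chord", {
  # voxelized disc of radius 10 mm at 1 mm voxels
  codes <- array(0L, c(30, 30, 3))
  cx <- (1:30) - 0.5
  d2 <- outer((cx - 15)^2, (cx - 15)^2, "+")
  sl <- matrix(0L, 30, 30); sl[d2 <= 100] <- 2L
  codes[, , 2] <- sl
  vol <- label_volume(codes, 1)
  plane <- structure(list(orientation = "short_axis", tag = "mid",
                          axis = 3L, index = 2L),
                     class = "measurement_plane")
  expect_equal(chamber_diameter(vol, plane, 2L), 20, tolerance = 0.06)
  single <- vol; single$codes[, , 2] <- 0L; single$codes[4, 4, 2] <- 2L
  expect_equal(chamber_diameter(single, plane, 2L), 1)
  empty <- structure(list(orientation = "short_axis", tag = "base",
                          axis = 3L, index = 1L),
                     class = "measurement_plane")
  expect_error(chamber_diameter(vol, empty, 2L), "absent from plane")
})

test_that("standard planes are located from valve and cavity landmarks", {
  ph <- fx_phantom()
  base <- select_plane(ph, "short_axis", "base")
  valve_z <- which(apply(ph$codes == 14L, 3, any))
  expect_equal(base$index, min(valve_z) - 1L)
  apex <- select_plane(ph, "short_axis", "apex")
  mid <- select_plane(ph, "short_axis", "mid")
  expect_lt(apex$index, base$index)
  expect_equal(mid$index, (base$index + apex$index) %/% 2L)
  ant <- select_plane(ph, "long_axis", "anterior")
  post <- select_plane(ph, "long_axis", "posterior")
  midl <- select_plane(ph, "long_axis", "mid")
  expect_lt(ant$index, post$index)
  expect_equal(midl$index, (ant$index + post$index) %/% 2L)
  # both ventricular cavities visible on the apex plane
  sl <- ph$codes[, , apex$index]
  expect_gte(ccsim:::slice_components(sl == 2L), 2L)
  no_valve <- label_volume(array(c(2L, 0L), c(4, 4, 4)), 1)
  expect_error(select_plane(no_valve, "short_axis", "base"),
               "valve region absent")
})

test_that("phantom wall thickness recovers the spec within one voxel", {
  ph <- fx_phantom()
  spec <- phantom_spec()
  mid <- select_plane(ph, "short_axis", "mid")
  ws <- wall_thickness_session(ph, mid)
  central <- ws[ws$fraction == 0.5, ]  # perpendicular to the free walls
  expect_lt(abs(central$lv_free_wall - spec$lv_wall), 1 + ph$voxel_size)
  expect_lt(abs(central$rv_free_wall - spec$rv_wall), 1 + ph$voxel_size)
  expect_true(all(stats::na.omit(ws$septum) > 0))
})

test_that("downsampled structure volumes agree within 10% on the phantom", {
  ph <- fx_phantom()
  ds <- downsample_labels(ph, 4)
  for (cd in c(3L, 4L)) {
    v0 <- structure_volume(ph, cd)
    v4 <- structure_volume(ds, cd)
    expect_lt(abs(v4 - v0) / v0, 0.10)
  }
})

test_that("the morphometry table collects volumes and plane measurements", {
  ph <- fx_phantom()
  tab <- morphometry_table(ph, id = "p1")
  expect_true(all(c("id", "plane", "structure", "measurement", "value",
                    "unit") %in% names(tab)))
  expect_true(any(tab$measurement == "volume"))
  expect_true(any(tab$measurement == "thickness"))
  expect_true(all(tab$value[tab$measurement == "volume"] > 0))
})
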