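test_that("the default policy encodes the conduction-system contract", {
  pol <- default_policy()
  expect_false(policy_allows(pol, 11, 4))   # AVN insulated from ventricles
  expect_true(policy_allows(pol, 8, 8))     # same-code implicitly coupled
  expect_true(policy_allows(pol, 13, 4))    # insertions drive the ventricle
  expect_false(policy_allows(pol, 8, 3))    # SN core only via its exits
  expect_true(policy_allows(pol, 9, 3))
  expect_true(policy_allows(pol, 10, 5))
  expect_false(policy_allows(pol, 12, 4))   # bundle insulated except at 13
  expect_false(policy_allows(pol, 12, 3))
  # symmetric by construction
  expect_equal(policy_allows(pol, 11, 12), policy_allows(pol, 12, 11))
  expect_error(coupling_policy(cbind(4L, 14L)), "non-excitable")
})

test_that("region tables reject non-excitable codes", {
  expect_error(region_table(c(3, 14), D = 0.3), "non-excitable")
  tab <- default_region_table(base_upstroke = 1)
  expect_setequal(tab$code, 3:13)
  expect_equal(tab$D[tab$code == 8], 0.1)
  expect_equal(tab$upstroke[tab$code == 12], 2)
})

test_that("tissue graphs have the right edges and conductances", {
  slab <- make_slab(c(3, 3, 3), 1, 4L)
  regions <- region_table(4L, D = 0.3)
  g <- build_tissue_graph(slab, regions, default_policy())
  expect_equal(g$n, 27)
  deg <- diff(g$ptr)
  expect_equal(sort(unique(deg)), c(3L, 4L, 5L, 6L))
  center <- which(g$node_voxel == which(slab$codes == 4L &
    slice.index(slab$codes, 1) == 3 & slice.index(slab$codes, 2) == 3 &
    slice.index(slab$codes, 3) == 3))
  expect_equal(deg[center], 6L)
  expect_true(all(abs(g$w - 0.3) < 1e-12))
  # harmonic mean across a 0.3 | 0.9 interface
  codes <- array(0L, c(4, 3, 3)); codes[2, 2, 2] <- 4L; codes[3, 2, 2] <- 13L
  duo <- label_volume(codes, 2)
  g2 <- build_tissue_graph(duo, default_region_table(1), default_policy())
  expect_equal(g2$w, rep(2 * 0.3 * 0.9 / (0.3 + 0.9) / 4, 2))
  # AVN voxel next to ventricular voxel: no edge
  codes[3, 2, 2] <- 11L
  g3 <- build_tissue_graph(label_volume(codes, 2),
                           default_region_table(1), default_policy())
  expect_equal(length(g3$w), 0L)
  # a code missing from the region table is an error
  expect_error(build_tissue_graph(duo, region_table(4L, 0.3),
                                  default_policy()),
               "missing from the region table")
})

test_that("one diffusion step equals the dense Laplacian product", {
  set.seed(5)
  codes <- array(sample(c(0L, 3L, 4L, 12L, 13L), 8^3, TRUE), c(8, 8, 8))
  vol <- label_volume(codes, 0.8)
  regions <- default_region_table(1)
  g <- build_tissue_graph(vol, regions, default_policy())
  n <- g$n
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (e in seq(g$ptr[i] + 1, length.out = g$ptr[i + 1] - g$ptr[i])) {
      j <- g$idx[e] + 1
      L[i, j] <- L[i, j] + g$w[e]
      L[i, i] <- L[i, i] - g$w[e]
    }
  }
  expect_equal(L, t(L))  # symmetric edges
  v0 <- stats::runif(n, -90, 20)
  dt <- 0.01
  # all conductances zero: pure diffusion
  p0 <- cell_params(gNa = 0, gto = 0, gCaL = 0, gKr = 0, gKur = 0, gK1 = 0)
  res <- ccsim:::.simulate_tissue_cpp(g$ptr, g$idx, g$w, rep(1, n),
                                      rep(1, n), p0, v0, dt, 1L,
                                      integer(0), 0, 0, 0, 1e9, 0, 0L)
  expect_equal(res$v_final, v0 + dt * as.vector(L %*% v0), tolerance = 1e-12)
})

test_that("diffusion-only runs conserve total membrane potential", {
  set.seed(6)
  vol <- make_cable(6, 2, 0.5)
  regions <- region_table(4L, D = 0.3)
  g <- build_tissue_graph(vol, regions, default_policy())
  p0 <- cell_params(gNa = 0, gto = 0, gCaL = 0, gKr = 0, gKur = 0, gK1 = 0)
  v0 <- stats::runif(g$n, -90, 30)
  n_steps <- 200L
  res <- ccsim:::.simulate_tissue_cpp(g$ptr, g$idx, g$w, rep(1, g$n),
                                      rep(1, g$n), p0, v0, 0.01, n_steps,
                                      integer(0), 0, 0, 0, 1e9, 0, 0L)
  expect_lt(abs(sum(res$v_final) - sum(v0)), 1e-6 * n_steps)
})

test_that("an unstimulated volume never activates", {
  slab <- make_cable(8, 1.5, 0.5)
  regions <- region_table(4L, D = 0.3)
  prot <- stimulus_protocol("custom", mask = slab_face_mask(slab),
                            amplitude = 0)
  res <- simulate(slab, regions, default_policy(), prot,
                  sim_config(duration = 100, early_stop_ms = 5))
  expect_equal(res$n_activated, 0L)
  tm <- res$activation_map$times
  expect_true(all(is.infinite(tm[slab$codes == 4L])))
  expect_true(all(is.na(tm[slab$codes == 0L])))
})

test_that("excitation cannot jump between disconnected slabs", {
  codes <- array(0L, c(24, 5, 5))
  codes[2:10, 2:4, 2:4] <- 4L
  codes[14:23, 2:4, 2:4] <- 4L
  vol <- label_volume(codes, 0.5)
  mask <- array(FALSE, dim(codes)); mask[2:4, 2:4, 2:4] <- TRUE
  prot <- stimulus_protocol("custom", mask = mask)
  fx_calibration()
  res <- simulate(vol, default_region_table(), default_policy(), prot,
                  sim_config(duration = 120, early_stop_ms = 10))
  tm <- res$activation_map$times
  expect_true(all(is.finite(tm[2:10, 2:4, 2:4])))
  expect_true(all(is.infinite(tm[14:23, 2:4, 2:4])))
})

test_that("measure_cv reads a constructed linear activation map", {
  times <- array(NA_real_, c(20, 4, 4))
  for (x in 1:20) times[x, 2:3, 2:3] <- x * 1.0   # 1 ms per 1 mm voxel
  map <- structure(list(times = times, voxel_size = 1, dims = c(20L, 4L, 4L)),
                   class = "activation_map")
  expect_equal(measure_cv(map, 5, 15, axis = 1L), 1.0)
  expect_error(measure_cv(map, 1, 15, axis = 1L), "10% boundary margins")
  times[10, , ] <- Inf
  map$times <- times
  expect_error(measure_cv(map, 5, 10, axis = 1L), "unactivated probe plane")
})

test_that("the CFL margin warning fires for the fast-pathway D", {
  slab <- make_slab(c(4, 2, 2), 0.292, 4L)
  regions <- region_table(4L, D = 0.9, upstroke = fx_calibration())
  prot <- stimulus_protocol("custom", mask = slab_face_mask(slab))
  expect_warning(
    simulate(slab, regions, default_policy(), prot,
             sim_config(duration = 5, early_stop_ms = 2)),
    "margin")
})

test_that("activation maps round-trip through raw float32 with sentinels", {
  times <- array(NA_real_, c(6, 5, 4))
  times[2:5, 2:4, 2:3] <- seq(0, 1, length.out = 24) * 100
  times[3, 3, 2] <- Inf
  map <- structure(list(times = times, voxel_size = 0.5, dims = dim(times)),
                   class = "activation_map")
  path <- file.path(tempdir(), "act.raw")
  write_activation_map(map, path)
  back <- read_activation_map(path)
  expect_equal(back$voxel_size, 0.5)
  expect_identical(is.na(back$times), is.na(times))
  expect_identical(is.infinite(back$times), is.infinite(times))
  fin <- is.finite(times)
  expect_equal(back$times[fin], times[fin], tolerance = 1e-5)
})

test_that("dt refinement leaves the slab conduction velocity stable", {
  cv1 <- fx_slab_cv(dt = 0.01)
  cv2 <- fx_slab_cv(dt = 0.005)
  expect_lt(abs(cv2 - cv1) / cv1, 0.02)
})

test_that("snapshot recording returns potentials at the requested stride", {
  slab <- make_cable(4, 1, 0.5)
  regions <- region_table(4L, D = 0.3)
  prot <- stimulus_protocol("custom", mask = slab_face_mask(slab))
  fx_calibration()
  res <- simulate(slab, regions, default_policy(), prot,
                  sim_config(duration = 5, early_stop_ms = 0,
                             snapshot_stride = 100))
  expect_equal(ncol(res$snapshots), length(res$snapshot_times))
  expect_equal(nrow(res$snapshots), res$n_nodes)
  expect_equal(res$snapshot_times[1:3], c(0, 1, 2))
  # first snapshot is the uniform resting state
  expect_lt(diff(range(res$snapshots[, 1])), 1e-9)
})
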