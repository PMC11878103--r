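test_that("the sinus beat follows the conduction-system sequence", {
  res <- fx_sinus()
  m <- median_by_code(res)
  expect_lt(m["8"], m["3"])    # sinus node before working atrium
  expect_lt(m["3"], m["11"])   # atrium before AVN
  expect_lt(m["11"], m["12"])  # AVN before His-Purkinje
  expect_lt(m["12"], m["4"])   # His-Purkinje before ventricle
  # every region fully activates in a healthy sinus beat
  expect_true(all(res$summary$fraction_activated == 1))
  # delay across the AVN: ventricles start well after the atria finish first
  expect_gt(res$summary$first[res$summary$code == 4],
            res$summary$first[res$summary$code == 3])
})

test_that("the ectopic beat reverses the atrioventricular order", {
  sinus <- fx_sinus(); ect <- fx_ectopic()
  ms <- median_by_code(sinus); me <- median_by_code(ect)
  expect_lt(me["4"], me["3"])              # retrograde: ventricle first
  expect_gt(ms["4"] - ms["3"], 0)          # sinus: atrium first
  expect_lt((me["3"] - me["4"]) * (ms["3"] - ms["4"]), 0)  # sign flip
  # the two activation maps disagree on most tissue
  ts <- sinus$activation_map$times; te <- ect$activation_map$times
  tissue <- is.finite(ts) & is.finite(te)
  expect_gt(mean(abs(ts[tissue] - te[tissue]) > 1), 0.5)
})

test_that("removing the AVN isolates the atria from an ectopic beat", {
  ph <- fx_phantom()
  cut <- ph; cut$codes[cut$codes == 11L] <- 0L
  fx_calibration()
  res <- run_ectopic(cut, config = sim_config(duration = 150))
  s <- res$summary
  expect_equal(s$fraction_activated[s$code == 3], 0)
  expect_equal(s$fraction_activated[s$code == 4], 1)
})

test_that("fast atrial pathways accelerate equidistant propagation", {
  # two parallel cables from a shared stimulated block; one carries a
  # crista-terminalis segment in its middle
  fx_calibration()
  codes <- array(0L, c(44, 8, 4))
  codes[2:43, 2:3, 2:3] <- 3L          # plain atrial cable
  codes[2:43, 6:7, 2:3] <- 3L          # fast-pathway cable
  codes[12:33, 6:7, 2:3] <- 5L         # crista segment mid-cable
  codes[2:3, 4:5, 2:3] <- 3L           # bridge at the stimulated end
  vol <- label_volume(codes, 1)
  mask <- array(FALSE, dim(codes)); mask[2:3, 2:7, 2:3] <- TRUE
  prot <- stimulus_protocol("custom", mask = mask)
  res <- simulate(vol, default_region_table(), default_policy(), prot,
                  sim_config(duration = 150, early_stop_ms = 10))
  tm <- res$activation_map$times
  t_plain <- median(tm[42, 2:3, 2:3])
  t_fast <- median(tm[42, 6:7, 2:3])
  expect_true(is.finite(t_plain) && is.finite(t_fast))
  expect_lt(t_fast, t_plain)
})

test_that("per-region rescaling maps each region onto [0, 1]", {
  codes <- array(0L, c(5, 3, 3))
  codes[1:3, 2, 2] <- 3L; codes[4:5, 2, 2] <- 4L
  vol <- label_volume(codes, 1)
  times <- array(NA_real_, dim(codes))
  times[1:3, 2, 2] <- c(10, 20, 30); times[4:5, 2, 2] <- c(7, 7)
  map <- structure(list(times = times, voxel_size = 1, dims = dim(codes)),
                   class = "activation_map")
  sc <- region_scaled_map(map, vol)
  expect_equal(sc$times[1:3, 2, 2], c(0, 0.5, 1))
  expect_equal(sc$times[4:5, 2, 2], c(0, 0))  # degenerate single-time region
  expect_identical(map$times[1:3, 2, 2], c(10, 20, 30))  # input untouched
  expect_identical(region_scaled_map(sc, vol)$times, sc$times)  # idempotent
  # a never-activated region keeps its sentinel
  times[4:5, 2, 2] <- Inf
  map$times <- times
  sc2 <- region_scaled_map(map, vol)
  expect_true(all(is.infinite(sc2$times[4:5, 2, 2])))
})

test_that("latest-activation reports locate the slowest tissue", {
  slab <- make_cable(10, 1.5, 0.5)
  prot <- stimulus_protocol("custom", mask = slab_face_mask(slab))
  fx_calibration()
  res <- simulate(slab, default_region_table(), default_policy(), prot,
                  sim_config(duration = 150, early_stop_ms = 10))
  rep <- latest_activation_report(res$activation_map, slab, k = 5)
  expect_equal(nrow(rep$voxels), 5)
  nx <- slab$dims[1]
  expect_true(all(rep$voxels$x >= nx - 2))  # far face activates last
  big <- latest_activation_report(res$activation_map, slab, k = 1e6)
  expect_equal(nrow(big$voxels), res$n_activated)
})

test_that("protocol preconditions are enforced", {
  ph <- fx_phantom()
  no_sn <- ph; no_sn$codes[no_sn$codes == 8L] <- 3L
  expect_error(run_sinus(no_sn), "no sinus node")
  no_hps <- ph; no_hps$codes[no_hps$codes %in% c(12L, 13L)] <- 0L
  expect_error(run_ectopic(no_hps), "no His-Purkinje")
  expect_error(stimulus_protocol("custom"), "mask or a target voxel")
})

test_that("run manifests record configuration and volume provenance", {
  path <- file.path(tempdir(), "manifest.json")
  run_manifest(path, sim_config(), stimulus_protocol("sinus"),
               vol = fx_phantom())
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$package, "ccsim")
  expect_equal(m$protocol$name, "sinus")
  expect_equal(m$volume$dims, c(96, 96, 96))
})
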