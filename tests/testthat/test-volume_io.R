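test_that("label volumes round-trip bit-exactly through TIFF and raw", {
  set.seed(7)
  codes <- array(sample(0:16, 1000, replace = TRUE), c(10, 10, 10))
  vol <- label_volume(codes, 0.5)
  for (ext in c("tif", "raw")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_label_volume(vol, path)
    back <- read_label_volume(path)
    expect_identical(back$codes, vol$codes)
    expect_equal(back$voxel_size, vol$voxel_size)
    expect_identical(back$dictionary, vol$dictionary)
  }
})

test_that("a trivial stack of zeros reads back with the right shape", {
  vol <- label_volume(array(0L, c(2, 2, 2)), 1)
  path <- file.path(tempdir(), "zero.tif")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_equal(back$dims, c(2L, 2L, 2L))
  expect_true(all(back$codes == 0L))
})

test_that("two writes of the same volume are byte-identical", {
  vol <- label_volume(array(rep(c(0L, 4L), 500), c(10, 10, 10)), 0.292)
  p1 <- file.path(tempdir(), "a.raw"); p2 <- file.path(tempdir(), "b.raw")
  write_label_volume(vol, p1); write_label_volume(vol, p2)
  expect_identical(readBin(p1, "raw", 2000), readBin(p2, "raw", 2000))
  p3 <- file.path(tempdir(), "a.tif"); p4 <- file.path(tempdir(), "b.tif")
  write_label_volume(vol, p3); write_label_volume(vol, p4)
  expect_identical(readBin(p3, "raw", 1e6), readBin(p4, "raw", 1e6))
})

test_that("codes absent from the dictionary are registered or rejected", {
  codes <- array(0L, c(4, 4, 4)); codes[2, 2, 3] <- 255L
  vol <- label_volume(codes, 1, dictionary = c(`0` = "background",
                                               `255` = "mystery"))
  path <- file.path(tempdir(), "unk.tif")
  write_label_volume(vol, path)
  unlink(sidecar <- sub("\\.tif$", ".json", path))  # drop label semantics
  back <- read_label_volume(path, voxel_size = 1)
  expect_equal(unname(back$dictionary["255"]), "unknown_255")
  expect_error(read_label_volume(path, voxel_size = 1,
                                 unknown_codes = "error"),
               "absent from the dictionary")
})

test_that("missing files and malformed raw volumes are rejected", {
  expect_error(read_label_volume(file.path(tempdir(), "nope.tif")),
               "no such file")
  vol <- label_volume(array(1L, c(3, 3, 3)), 1)
  path <- file.path(tempdir(), "trunc.raw")
  write_label_volume(vol, path)
  writeBin(as.raw(1:10), path)  # truncate
  expect_error(read_label_volume(path), "does not match sidecar dims")
})

test_that("grid node count matches structured-grid arithmetic", {
  expect_identical(grid_node_count(c(419, 353, 263)), 38899541)
  expect_identical(grid_node_count(c(1, 1, 1)), 1)
  vol <- label_volume(array(0L, c(3, 4, 5)), 1)
  expect_identical(grid_node_count(vol), 60)
})

test_that("downsampling by 4 takes 73 um voxels to 292 um exactly", {
  vol <- label_volume(array(4L, c(8, 8, 8)), 0.073)
  out <- downsample_labels(vol, 4)
  expect_identical(out$voxel_size, 0.292)
  expect_equal(out$dims, c(2L, 2L, 2L))
})

test_that("downsampling uses majority vote with priority tie-breaks", {
  # 63 voxels of ventricle, 1 of atrium: majority wins
  codes <- array(4L, c(4, 4, 4)); codes[1, 1, 1] <- 3L
  out <- downsample_labels(label_volume(codes, 1), 4)
  expect_identical(as.vector(out$codes), 4L)
  # 32/32 tie between myocardium and His-Purkinje: conduction code wins
  codes <- array(4L, c(4, 4, 4)); codes[, , 1:2] <- 12L
  out <- downsample_labels(label_volume(codes, 1), 4)
  expect_identical(as.vector(out$codes), 12L)
  # factor 1 is the identity
  vol <- label_volume(array(sample(0:4, 27, TRUE), c(3, 3, 3)), 1)
  expect_identical(downsample_labels(vol, 1), vol)
  expect_error(downsample_labels(vol, 0), "positive integer")
})

test_that("downsampling never invents codes and keeps single-code volumes", {
  set.seed(11)
  for (i in 1:5) {
    codes <- array(sample(c(0L, 3L, 4L, 12L), 6^3, TRUE,
                          prob = c(.4, .3, .29, .01)), c(6, 6, 6))
    vol <- label_volume(codes, 0.2)
    for (f in c(2, 3, 4)) {
      out <- downsample_labels(vol, f)
      expect_true(all(unique(as.vector(out$codes)) %in%
                        unique(as.vector(codes))))
      expect_equal(out$dims, as.integer(ceiling(vol$dims / f)))
      expect_equal(out$voxel_size, vol$voxel_size * f)
    }
  }
  mono <- label_volume(array(5L, c(7, 5, 3)), 1)
  expect_identical(unique(as.vector(downsample_labels(mono, 3)$codes)), 5L)
})

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", n * 50)
  list(n = n, rec = rec)
}

test_that("STL export produces the closed-form voxel-surface triangle count", {
  vol <- label_volume(array(4L, c(1, 1, 1)), 1)
  path <- file.path(tempdir(), "cube.stl")
  expect_equal(export_stl(vol, 4L, path), 12)
  expect_equal(read_stl(path)$n, 12)
  expect_equal(file.size(path), 84 + 12 * 50)
  # 2 x 1 x 1 bar: two shared faces removed
  bar <- label_volume(array(4L, c(2, 1, 1)), 1)
  expect_equal(export_stl(bar, 4L, path), 20)
  # a x b x c solid box: 2 * 2(ab + bc + ca) triangles
  for (dims in list(c(3, 2, 4), c(5, 1, 2))) {
    box <- label_volume(array(4L, dims), 0.5)
    a <- dims[1]; b <- dims[2]; cc <- dims[3]
    expect_equal(export_stl(box, 4L, path),
                 4 * (a * b + b * cc + cc * a))
  }
  expect_error(export_stl(vol, 9L, path), "no voxel carries")
})

test_that("STL vertices span the correct bounding box in mm", {
  vol <- label_volume(array(4L, c(2, 1, 1)), 0.5)
  path <- file.path(tempdir(), "bar.stl")
  export_stl(vol, 4L, path)
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  verts <- matrix(NA_real_, n * 3, 3)
  for (i in seq_len(n)) {
    readBin(con, "numeric", 3, size = 4, endian = "little")  # normal
    for (v in 1:3)
      verts[(i - 1) * 3 + v, ] <- readBin(con, "numeric", 3, size = 4,
                                          endian = "little")
    readBin(con, "raw", 2)
  }
  expect_equal(apply(verts, 2, min), c(0, 0, 0))
  expect_equal(apply(verts, 2, max), c(1, 0.5, 0.5))
})
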