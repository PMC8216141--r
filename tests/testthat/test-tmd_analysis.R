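# voxel TMD analytics and NRRD round trip

make_cylinder <- function(nxy = 25, nz = 20, r = 9, value = 900) {
  a <- array(0, c(nxy, nxy, nz))
  cx <- (nxy + 1) / 2
  ix <- matrix(rep(seq_len(nxy), nxy), nxy, nxy)
  inside <- sqrt((ix - cx)^2 + (t(ix) - cx)^2) <= r
  for (k in seq_len(nz)) a[, , k] <- inside * value
  list(vol = voxel_volume(a, voxel_size = 10), inside = inside)
}

test_that("segmentation recovers a uniform cylinder minus a thin shell", {
  cyl <- make_cylinder(value = 900)
  m <- segment_volume(cyl$vol, sigma = 1, threshold = 490)
  inside3d <- array(rep(cyl$inside, 20), dim = dim(cyl$vol$data))
  # mask within support, eroded by at most ~2 voxels of smoothing
  mid <- m$data[, , 10]
  expect_true(all(mid[!cyl$inside] == FALSE | !any(mid[!cyl$inside])))
  expect_gt(sum(mid), 0.5 * sum(cyl$inside))
  expect_true(all(which(mid) %in% which(cyl$inside)))
  # erosion depth: every retained voxel is within the support, and the
  # masked radius is within 2 voxels of the true radius
  expect_gte(sum(mid), sum(sqrt((row(mid) - 13)^2 + (col(mid) - 13)^2) <= 7))

  # all-background volume below threshold -> empty mask, warning not error
  lowv <- voxel_volume(array(100, c(8, 8, 8)), 10)
  expect_warning(mlow <- segment_volume(lowv, 1, 490), "empty")
  expect_false(any(mlow$data))

  expect_error(segment_volume(cyl$vol, 1, 0), "positive")
})

test_that("normalized histograms sum to one and place mass correctly", {
  cyl <- make_cylinder(value = 900)
  m <- voxel_mask(cyl$vol$data > 0, "whole")
  h <- tmd_histogram(cyl$vol, m)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(h$frequency > 0), 1L)  # single occupied bin

  # two-valued volume, 50/50 split
  a <- cyl$vol$data
  vals <- which(a > 0)
  a[vals[seq(1, length(vals), by = 2)]] <- 800
  a[vals[seq(2, length(vals), by = 2)]] <- 1000
  v2 <- voxel_volume(a, 10)
  h2 <- tmd_histogram(v2, m)
  occ <- h2$frequency[h2$frequency > 0]
  expect_equal(length(occ), 2L)
  expect_equal(unname(occ), c(0.5, 0.5), tolerance = 1 / sum(m$data))

  expect_error(tmd_histogram(cyl$vol, voxel_mask(array(FALSE, dim(a)))),
               "no nonzero")
})

test_that("intensity profiles are flat for uniform sections and dip at rims", {
  cyl <- make_cylinder(value = 900)
  m <- voxel_mask(cyl$vol$data > 0, "whole")
  pr <- intensity_profile(cyl$vol, m, slice_index = 10)
  expect_equal(range(pr$position), c(0, 1))
  expect_true(all(abs(pr$density - 900) < 1e-9))

  # 3-voxel lower-density rim: dips near positions 0 and 1
  rec <- make_record(tmd_surface_deficit = 200, tmd_fracture_deficit = 0,
                     tmd_voxel_noise = 0)
  tv <- generate_tmd_volume(rec, voxel_size = 8, seed = 1)
  prr <- intensity_profile(tv$volume, tv$whole,
                           slice_index = dim(tv$volume$data)[3] %/% 2)
  inner <- prr$density[prr$position > 0.35 & prr$position < 0.65]
  edges <- prr$density[prr$position < 0.05 | prr$position > 0.95]
  expect_lt(mean(edges), mean(inner) - 50)

  # rigid 90-degree in-plane rotation leaves the profile unchanged
  rot <- function(a) {
    d <- dim(a)
    b <- array(a[d[1]:1, , ], d)
    aperm(b, c(2, 1, 3))
  }
  vr <- voxel_volume(rot(tv$volume$data), tv$volume$voxel_size)
  mr <- voxel_mask(rot(tv$whole$data), "whole")
  prr2 <- intensity_profile(vr, mr,
                            slice_index = dim(tv$volume$data)[3] %/% 2)
  expect_equal(prr2$density, prr$density, tolerance = 1e-9)

  expect_error(intensity_profile(cyl$vol, m, slice_index = 999),
               "out of range")
})

test_that("zone statistics recover configured deficits", {
  rec <- make_record(tmd_base = 950, tmd_surface_deficit = 0,
                     tmd_fracture_deficit = 10, tmd_voxel_noise = 0)
  tv <- generate_tmd_volume(rec, voxel_size = 8, seed = 2)
  zs <- zone_stats(tv$volume, tv$whole, tv$fracture)
  expect_equal(zs$diff_remainder_fracture, 10, tolerance = 1e-9)
  expect_equal(zs$remainder$mean, 950, tolerance = 1e-9)
  expect_equal(zs$remainder$sd, 0)

  # fracture mask = whole mask: zero paired difference
  zs2 <- zone_stats(tv$volume, tv$whole,
                    voxel_mask(tv$whole$data, "fracture_zone"))
  expect_equal(zs2$diff_whole_fracture, 0)

  # bounds
  expect_gte(zs$whole$mean, min(tv$volume$data[tv$whole$data]))
  expect_lte(zs$whole$mean, max(tv$volume$data[tv$whole$data]))

  # fracture must be a subset of whole
  bad <- array(TRUE, dim(tv$volume$data))
  expect_error(zone_stats(tv$volume, tv$whole,
                          voxel_mask(bad, "fracture_zone")), "subset")
})

test_that("mean cross-sectional area matches the analytic cylinder", {
  # radius 80 um cylinder, length 1 mm, voxel 5 um
  nxy <- 41; r_vox <- 16; nz <- 200
  a <- array(FALSE, c(nxy, nxy, nz))
  cx <- (nxy + 1) / 2
  ix <- matrix(rep(seq_len(nxy), nxy), nxy, nxy)
  inside <- sqrt((ix - cx)^2 + (t(ix) - cx)^2) <= r_vox
  for (k in seq_len(nz)) a[, , k] <- inside
  m <- voxel_mask(a, "whole")
  area <- mean_cross_area(m, voxel_size = 5, axis_length = 1)
  expect_equal(area, pi * 0.08^2, tolerance = 0.03)

  # doubling the length halves the area
  expect_equal(mean_cross_area(m, 5, 2), area / 2)

  expect_error(mean_cross_area(voxel_mask(array(FALSE, c(3, 3, 3))), 5, 1),
               "empty")
  expect_error(mean_cross_area(m, 5, 0), "positive")
})

test_that("NRRD volumes and masks round-trip through both encodings", {
  rec <- make_record(tmd_voxel_noise = 20)
  tv <- generate_tmd_volume(rec, voxel_size = 8, seed = 3)
  for (enc in c("raw", "ascii")) {
    f <- tempfile(fileext = ".nrrd")
    write_nrrd(tv$volume, f, encoding = enc)
    back <- read_nrrd(f)
    expect_equal(back$data, tv$volume$data,
                 tolerance = if (enc == "ascii") 1e-12 else 0)
    expect_equal(back$voxel_size, 8)
    unlink(f)
  }
  f <- tempfile(fileext = ".nrrd")
  write_nrrd(tv$fracture, f)
  mk <- read_nrrd(f, as_mask = TRUE, label = "fracture_zone")
  expect_identical(mk$data, tv$fracture$data)
  unlink(f)
})
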