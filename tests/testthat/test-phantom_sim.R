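test_that("default material table satisfies its spectral design constraints", {
  mats <- default_materials()
  expect_length(mats, 12)
  ids <- vapply(mats, `[[`, integer(1), "class_id")
  expect_setequal(ids, 1:12)
  expect_identical(mats, default_materials()) # deterministic

  mus <- material_mu_matrix(mats)
  water <- mus[, "water"]
  # linearity in concentration within the HA family
  expect_equal(mus[, "HA400"] - water, 2 * (mus[, "HA200"] - water))
  expect_equal(mus[, "HA800"] - water, 16 * (mus[, "HA50"] - water))
  # engineered confusable pairs: equal band-integrated attenuation
  expect_lt(abs(sum(mus[, "I5"]) - sum(mus[, "HA100"])), 1e-6)
  expect_lt(abs(sum(mus[, "I10"]) - sum(mus[, "HA200"])), 1e-6)
  # but different normalized spectral shapes
  sh_ha <- mus[, "HA800"] - water
  sh_i <- mus[, "I15"] - water
  cosine <- sum(sh_ha * sh_i) / sqrt(sum(sh_ha^2) * sum(sh_i^2))
  expect_lt(cosine, 0.99)
})

test_that("layout drawing covers all materials and is seed-deterministic", {
  l5 <- make_layouts(5, rng_seed = 0)
  expect_length(l5, 5)
  used <- unique(unlist(lapply(l5, `[[`, "assignment")))
  expect_setequal(used, 1:12)
  expect_identical(l5, make_layouts(5, rng_seed = 0))
  expect_false(identical(l5, make_layouts(5, rng_seed = 1)))

  l1 <- make_layouts(1, rng_seed = 3, coverage = FALSE)
  expect_length(unique(l1[[1]]$assignment), 8)
  expect_error(make_layouts(1, rng_seed = 0, coverage = TRUE), "cover")
})

test_that("phantom geometry is validated", {
  expect_error(phantom_layout(rep(1L, 8), ring_radius_mm = 49), "boundary")
  expect_error(phantom_layout(rep(1L, 8), ring_radius_mm = 2), "overlap")
  lay <- phantom_layout(1:8)
  d_ring <- sqrt(rowSums(lay$positions[-1, ]^2))
  expect_equal(d_ring, rep(lay$ring_radius_mm, 7)) # equidistant ring
})

test_that("noiseless renders are exact and rod geometry matches analytic area", {
  acq <- tiny_acq(image_size = 96L, n_slices = 1L, voxel = 1.0,
                  noise_sigma0 = 0, bias = 0, seed = 1L)
  lay <- phantom_layout(c(3L, 7L, rep(NA_integer_, 6)))
  scan <- render_scan(lay, acq)
  mus <- material_mu_matrix()
  lab <- scan$labels$labels[1, , ]
  for (f in 1:5) {
    vals <- scan$volume$values[1, f, , ]
    expect_true(all(vals[lab == 3L] == mus[f, "HA200"])) # exact noiseless limit
    expect_true(all(vals[lab == 7L] == mus[f, "I10"]))
  }
  # rasterized disk area vs analytic pi * (r / voxel)^2
  r_vox <- 5 / acq$voxel_size_mm
  for (cid in c(3L, 7L))
    expect_lt(abs(sum(lab == cid) - pi * r_vox^2) / (pi * r_vox^2), 0.02)
})

test_that("noise realization is seeded and labels are noise-independent", {
  lay <- phantom_layout(c(1L, 6L, rep(NA_integer_, 6)))
  a1 <- render_scan(lay, tiny_acq(seed = 5L))
  a2 <- render_scan(lay, tiny_acq(seed = 5L))
  a3 <- render_scan(lay, tiny_acq(seed = 6L))
  expect_identical(a1$volume$values, a2$volume$values)
  expect_false(identical(a1$volume$values, a3$volume$values))
  expect_identical(a1$labels$labels, a3$labels$labels)
  # rods traverse the full axial extent: identical label slices
  expect_identical(a1$labels$labels[1, , ], a1$labels$labels[2, , ])
})

test_that("per-bin noise scales with inverse square root of bin width", {
  lay <- phantom_layout(rep(NA_integer_, 8))
  acq <- tiny_acq(image_size = 96L, n_slices = 1L, noise_sigma0 = 0.02,
                  bias = 0, seed = 2L)
  scan <- render_scan(lay, acq)
  w <- diff(acq$bin_edges_keV)
  outside <- scan$labels$labels[1, , ] == 0L
  # air voxels outside the phantom are pure noise
  grid <- (seq_len(96) - 48.5) * acq$voxel_size_mm
  air <- outer(grid, grid, function(x, y) x^2 + y^2) > 50^2
  for (f in c(1, 5)) {
    s_emp <- sd(scan$volume$values[1, f, , ][air & outside])
    s_exp <- 0.02 * sqrt(max(w) / w[f])
    expect_lt(abs(s_emp - s_exp) / s_exp, 0.1)
  }
})

test_that("simulated datasets regenerate bit-identically from the manifest", {
  dir <- withr::local_tempdir()
  acq <- tiny_acq(image_size = 32L, n_slices = 2L, voxel = 2.9, seed = 11L)
  man <- simulate_dataset(3, acq, dir)
  expect_length(man$scans, 3)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  s2 <- read_scan(file.path(dir, "scan_002.rds"))
  regen <- regenerate_scan(file.path(dir, "manifest.json"), 2)
  expect_identical(s2$volume$values, regen$volume$values)
  expect_identical(s2$labels$labels, regen$labels$labels)
})

test_that("an empty dataset writes a manifest and no scan files", {
  dir <- withr::local_tempdir()
  man <- simulate_dataset(0, tiny_acq(), dir)
  expect_length(man$scans, 0)
  expect_identical(list.files(dir, pattern = "rds$"), character(0))
})

test_that("mean rod intensity increases strictly along the HA series", {
  acq <- tiny_acq(image_size = 96L, n_slices = 1L, voxel = 1.0,
                  noise_sigma0 = 0, bias = 0)
  lay <- phantom_layout(c(1L, 2L, 3L, 4L, 5L, rep(NA_integer_, 3)))
  scan <- render_scan(lay, acq)
  lab <- scan$labels$labels[1, , ]
  vals <- matrix(scan$volume$values[1, , , ], nrow = 5) # bins x voxels
  means <- vapply(1:5, function(cid)
    mean(vals[, as.vector(lab == cid)]), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("NIfTI export writes one volume per bin plus labels", {
  dir <- withr::local_tempdir()
  lay <- phantom_layout(c(1L, rep(NA_integer_, 7)))
  scan <- render_scan(lay, tiny_acq(image_size = 32L, voxel = 2.9))
  paths <- export_scan_nifti(scan, dir, "t")
  expect_length(paths, 6)
  img <- RNifti::readNifti(paths[1])
  expect_identical(dim(img), c(32L, 32L, 2L))
  expect_equal(RNifti::pixdim(img)[1], 2.9, tolerance = 1e-6)
})
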