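#' Acquisition parameters for the synthetic multi-energy scanner
#'
#' Bundles the parameters that define one simulated acquisition: the energy-bin
#' edges, voxel size, slice count, in-plane image size, the reconstructed-image
#' noise level, the cupping/beam-hardening bias amplitude, and the RNG seed.
#'
#' Per-bin noise is Gaussian in reconstructed intensity with
#' `sigma_f = noise_sigma0 * sqrt(w_ref / w_f)` where `w_f` is the width of bin
#' `f` in keV and `w_ref` the widest bin, so narrow bins (fewer photons) are
#' noisier. The default edges 7, 12, 15, 18, 21, 120 keV give five bins.
#'
#' @param bin_edges_keV ascending numeric vector of F+1 bin edges (keV)
#' @param voxel_size_mm in-plane voxel size in mm
#' @param n_slices number of axial slices
#' @param image_size in-plane image size (H = W)
#' @param noise_sigma0 noise sigma of the widest bin (attenuation units)
#' @param bias_amplitude amplitude of the multiplicative radial bias field
#' @param seed integer RNG seed for the noise realization
#' @return an `acquisition_params` list
#' @export
acquisition_params <- function(bin_edges_keV = c(7, 12, 15, 18, 21, 120),
                               voxel_size_mm = 0.1, n_slices = 100L,
                               image_size = 512L, noise_sigma0 = 0.01,
                               bias_amplitude = 0.05, seed = 0L) {
  if (any(diff(bin_edges_keV) <= 0)) stopf("bin_edges_keV must be strictly ascending")
  if (n_slices < 1) stopf("n_slices must be >= 1")
  if (image_size < 16) stopf("image_size must be >= 16")
  if (!all(is.finite(c(bin_edges_keV, voxel_size_mm, noise_sigma0, bias_amplitude))))
    stopf("acquisition parameters must be finite")
  structure(list(bin_edges_keV = as.numeric(bin_edges_keV),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size),
                 noise_sigma0 = as.numeric(noise_sigma0),
                 bias_amplitude = as.numeric(bias_amplitude),
                 seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Cylindrical phantom layout with eight rod positions
#'
#' One central rod position plus seven equally spaced on a ring. `assignment`
#' maps position index (1..8) to a material class id (or `NA` for an empty
#' position).
#'
#' @param assignment integer vector of length 8 of class ids (1..12) or `NA`
#' @param phantom_diameter_mm,rod_diameter_mm geometry in mm
#' @param ring_radius_mm radius of the 7-rod ring
#' @return a `phantom_layout` list with `positions` (8 x 2 matrix, mm)
#' @export
phantom_layout <- function(assignment = rep(NA_integer_, 8),
                           phantom_diameter_mm = 100, rod_diameter_mm = 10,
                           ring_radius_mm = 0.325 * phantom_diameter_mm) {
  if (length(assignment) != 8) stopf("assignment must have length 8")
  ang <- 2 * pi * (0:6) / 7
  positions <- rbind(c(0, 0), cbind(ring_radius_mm * cos(ang),
                                    ring_radius_mm * sin(ang)))
  rod_r <- rod_diameter_mm / 2
  r_ph <- phantom_diameter_mm / 2
  d_center <- sqrt(rowSums(positions^2))
  if (any(d_center + rod_r > r_ph)) stopf("rod outside phantom boundary")
  dd <- as.matrix(stats::dist(positions))
  if (any(dd[upper.tri(dd)] < rod_diameter_mm)) stopf("rods overlap")
  structure(list(phantom_diameter_mm = phantom_diameter_mm,
                 rod_diameter_mm = rod_diameter_mm,
                 ring_radius_mm = ring_radius_mm,
                 positions = positions,
                 assignment = as.integer(assignment)),
            class = "phantom_layout")
}

#' Draw rod-to-position assignments for a set of scans
#'
#' Each scan receives eight distinct materials out of the twelve. When
#' `coverage` is `TRUE` (the default) the layouts are drawn so that every
#' material appears in at least one scan, emulating an acquisition campaign in
#' which all materials are represented across the dataset. The draw is a pure
#' function of `rng_seed`.
#'
#' @param n_scans number of scans (>= 1)
#' @param materials material table, see [default_materials()]
#' @param rng_seed integer seed
#' @param coverage require every material to appear in some scan
#' @return list of `n_scans` [phantom_layout()] objects
#' @export
make_layouts <- function(n_scans, materials = default_materials(),
                         rng_seed = 0L, coverage = TRUE) {
  if (n_scans < 1) stopf("n_scans must be >= 1")
  n_mat <- length(materials)
  ids <- vapply(materials, `[[`, integer(1), "class_id")
  if (coverage && 8 * n_scans < n_mat)
    stopf("cannot cover %d materials with %d scans of 8 rods", n_mat, n_scans)
  with_seed_(rng_seed, {
    for (iter in seq_len(1000)) {
      picks <- lapply(seq_len(n_scans), function(i) sample(ids, 8))
      if (!coverage || length(unique(unlist(picks))) == n_mat) {
        return(lapply(picks, phantom_layout))
      }
    }
    stopf("failed to draw covering layouts") # unreachable for n_scans >= 2
  })
}

# Per-bin noise sigmas implied by the bin widths.
bin_sigmas <- function(acq) {
  w <- diff(acq$bin_edges_keV)
  acq$noise_sigma0 * sqrt(max(w) / w)
}

#' Render one synthetic multi-energy scan
#'
#' Rasterizes the phantom onto the image grid: every slice contains the same
#' rod disks (rods traverse the full axial extent). Voxel intensity in bin `f`
#' is the material's `mu[f]`, multiplied by a smooth radial bias field
#' `1 + A * (1/2 - (r/R)^2)` inside the phantom (a second-order stand-in for
#' cupping/beam hardening, amplitude `A = bias_amplitude`), plus zero-mean
#' Gaussian noise with per-bin sigma (see [acquisition_params()]). Labels use a
#' voxel-center inclusion test; non-rod phantom interior renders with water
#' intensity but is labeled background (water is a class only where a water rod
#' is placed), and everything outside the phantom is air (zero attenuation).
#'
#' @param layout a [phantom_layout()]
#' @param acq an [acquisition_params()]
#' @param materials material table
#' @return list with `volume` (a `spectral_volume`: `values` is Z x F x H x W)
#'   and `labels` (a `label_volume`: Z x H x W integers in 0..12)
#' @export
render_scan <- function(layout, acq, materials = default_materials()) {
  stopifnot(inherits(layout, "phantom_layout"), inherits(acq, "acquisition_params"))
  N <- acq$image_size
  nf <- length(acq$bin_edges_keV) - 1L
  v <- acq$voxel_size_mm
  mus <- material_mu_matrix(materials)
  if (nrow(mus) != nf) stopf("material table has %d bins, acquisition %d", nrow(mus), nf)
  coord <- (seq_len(N) - (N + 1) / 2) * v
  X <- matrix(coord, N, N)        # varies along rows (H axis)
  Y <- matrix(coord, N, N, byrow = TRUE)
  r_ph <- layout$phantom_diameter_mm / 2
  rod_r <- layout$rod_diameter_mm / 2
  r2 <- X^2 + Y^2
  inside <- r2 <= r_ph^2

  label2d <- matrix(0L, N, N)
  for (k in seq_len(8)) {
    cid <- layout$assignment[k]
    if (is.na(cid)) next
    p <- layout$positions[k, ]
    if (sqrt(sum(p^2)) + rod_r > r_ph) stopf("rod %d outside phantom boundary", k)
    label2d[(X - p[1])^2 + (Y - p[2])^2 <= rod_r^2] <- cid
  }

  mu_water <- mus[, "water"]
  bias <- 1 + acq$bias_amplitude * (0.5 - r2 / r_ph^2)
  base <- array(0, c(N, N, nf)) # H x W x F noiseless slice
  for (f in seq_len(nf)) {
    sl <- matrix(0, N, N)
    sl[inside] <- mu_water[f]
    for (cid in sort(unique(label2d[label2d > 0L])))
      sl[label2d == cid] <- mus[f, cid]
    base[, , f] <- sl * ifelse(inside, bias, 1)
  }

  sig <- bin_sigmas(acq)
  vals <- array(0, c(acq$n_slices, nf, N, N))
  with_seed_(acq$seed, {
    for (z in seq_len(acq$n_slices)) {
      for (f in seq_len(nf)) {
        noise <- if (sig[f] > 0) matrix(rnorm(N * N, 0, sig[f]), N, N) else 0
        vals[z, f, , ] <- base[, , f] + noise
      }
    }
  })
  labels <- array(rep(label2d, each = acq$n_slices), c(acq$n_slices, N, N))
  list(volume = structure(list(values = vals,
                               bin_edges_keV = acq$bin_edges_keV,
                               voxel_size_mm = v),
                          class = "spectral_volume"),
       labels = structure(list(labels = labels), class = "label_volume"))
}

#' Write / read one scan in the native container format
#'
#' One compressed archive (gzip-compressed R serialization) per scan holding
#' the documented keys: `image` (Z x F x H x W double), `labels` (Z x H x W
#' integer), `bin_edges` (F+1), `voxel_size_mm` (scalar), `scan_id` (string).
#'
#' @param scan list as returned by [render_scan()]
#' @param path file path (conventionally `.rds`)
#' @param scan_id identifier string stored in the container
#' @export
write_scan <- function(scan, path, scan_id = "scan") {
  obj <- list(image = scan$volume$values,
              labels = scan$labels$labels,
              bin_edges = scan$volume$bin_edges_keV,
              voxel_size_mm = scan$volume$voxel_size_mm,
              scan_id = scan_id)
  ok <- try(saveRDS(obj, path, compress = "gzip"), silent = TRUE)
  if (inherits(ok, "try-error")) stopf("failed to write scan to '%s'", path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stopf("scan file not found: '%s'", path)
  obj <- readRDS(path)
  list(volume = structure(list(values = obj$image,
                               bin_edges_keV = obj$bin_edges,
                               voxel_size_mm = obj$voxel_size_mm),
                          class = "spectral_volume"),
       labels = structure(list(labels = obj$labels), class = "label_volume"),
       scan_id = obj$scan_id)
}

#' Simulate and write a multi-scan phantom dataset
#'
#' Draws `n_scans` rod layouts (covering all materials when possible), renders
#' each scan with a per-scan noise seed derived from `acq$seed`, writes the
#' native containers plus a JSON manifest sufficient to regenerate the dataset
#' bit-identically.
#'
#' @param n_scans number of scans
#' @param acq [acquisition_params()]
#' @param out_dir output directory (created if missing)
#' @param materials material table
#' @return the manifest, invisibly
#' @export
simulate_dataset <- function(n_scans, acq, out_dir,
                             materials = default_materials()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  manifest <- list(format = "spffunet-scan-v1",
                   n_scans = as.integer(n_scans),
                   acquisition = unclass(acq),
                   materials = materials,
                   layout_seed = acq$seed,
                   scans = list())
  if (n_scans >= 1) {
    layouts <- make_layouts(n_scans, materials, rng_seed = acq$seed,
                            coverage = 8 * n_scans >= length(materials))
    for (i in seq_len(n_scans)) {
      scan_id <- sprintf("scan_%03d", i)
      scan_seed <- acq$seed + i
      acq_i <- acq; acq_i$seed <- as.integer(scan_seed)
      scan <- render_scan(layouts[[i]], acq_i, materials)
      write_scan(scan, file.path(out_dir, paste0(scan_id, ".rds")), scan_id)
      manifest$scans[[i]] <- list(scan_id = scan_id,
                                  file = paste0(scan_id, ".rds"),
                                  seed = scan_seed,
                                  assignment = layouts[[i]]$assignment)
    }
  }
  # digits = I(17) guarantees binary round-trip of the doubles, which the
  # bit-identical regeneration contract needs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Regenerate one scan from a dataset manifest
#'
#' @param manifest manifest list or path to `manifest.json`
#' @param i scan index
#' @return scan list as from [render_scan()]
#' @export
regenerate_scan <- function(manifest, i) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE,
                                    simplifyMatrix = FALSE)
  acq <- do.call(acquisition_params, manifest$acquisition[
    setdiff(names(manifest$acquisition), character(0))])
  mats <- lapply(manifest$materials, function(m) {
    m$mu <- as.numeric(unlist(m$mu)); m$class_id <- as.integer(m$class_id); m
  })
  entry <- manifest$scans[[i]]
  layout <- phantom_layout(as.integer(unlist(entry$assignment)))
  acq$seed <- as.integer(entry$seed)
  render_scan(layout, acq, mats)
}

#' Export a scan as NIfTI volumes (one file per energy bin plus labels)
#'
#' @param scan list as from [render_scan()] or [read_scan()]
#' @param dir output directory
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
export_scan_nifti <- function(scan, dir, prefix = "scan") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- scan$volume$voxel_size_mm
  nf <- dim(scan$volume$values)[2]
  paths <- character(0)
  as_nifti <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(v, v, v)
    img
  }
  for (f in seq_len(nf)) {
    arr <- aperm(scan$volume$values[, f, , , drop = FALSE][, 1, , ], c(2, 3, 1))
    p <- file.path(dir, sprintf("%s_bin%d.nii.gz", prefix, f))
    RNifti::writeNifti(as_nifti(arr), p)
    paths <- c(paths, p)
  }
  lab <- aperm(scan$labels$labels, c(2, 3, 1))
  p <- file.path(dir, sprintf("%s_labels.nii.gz", prefix))
  RNifti::writeNifti(as_nifti(lab * 1), p)
  invisible(c(paths, p))
}
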