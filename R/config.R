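#' Fixed 13-class display palette
#'
#' Background (class 0) is fully transparent; the 12 material classes get
#' fixed, distinct colors so overlays are comparable across models.
#'
#' @return character vector of 13 colors (RGBA hex), named by class id 0..12
#' @export
default_palette <- function() {
  cols <- c("#00000000",
            "#8DD3C7", "#FFFFB3", "#BEBADA", "#FB8072", "#80B1D3",
            "#FDB462", "#B3DE69", "#FCCDE5", "#D9D9D9", "#BC80BD",
            "#CCEBC5", "#FFED6F")
  names(cols) <- as.character(0:12)
  cols
}

#' Experiment configuration
#'
#' One serializable record tying the pipeline together: paths, acquisition
#' parameters, augmentation parameters, network configuration, training
#' protocol, seeds and the class palette. Round-trips through a YAML file.
#'
#' @param data_dir,out_dir paths
#' @param acq an [acquisition_params()]
#' @param augment an [augment_params()]
#' @param network a [network_config()]
#' @param protocol a [train_protocol()]
#' @param seeds integer vector of training seeds
#' @param palette class palette (see [default_palette()])
#' @return an `experiment_config` list
#' @export
experiment_config <- function(data_dir = "data", out_dir = "out",
                              acq = acquisition_params(),
                              augment = augment_params(),
                              network = network_config(),
                              protocol = train_protocol(),
                              seeds = c(1L, 2L, 3L),
                              palette = default_palette()) {
  structure(list(data_dir = data_dir, out_dir = out_dir, acq = acq,
                 augment = augment, network = network, protocol = protocol,
                 seeds = as.integer(seeds), palette = palette),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#' @param config an [experiment_config()]
#' @param path YAML file path
#' @export
write_config <- function(config, path) {
  plain <- list(
    data_dir = config$data_dir, out_dir = config$out_dir,
    acq = unclass(config$acq),
    augment = unclass(config$augment),
    network = unclass(config$network)[
      c("variant", "base_channels", "levels", "n_bins", "n_classes",
        "se_reduction", "film_enc_dim", "leaky_slope")],
    protocol = c(unclass(config$protocol)[
      setdiff(names(config$protocol), "augment")],
      list(augment = NULL)),
    seeds = config$seeds, palette = as.list(config$palette))
  plain$protocol$augment <- NULL
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  y <- yaml::read_yaml(path)
  pal <- unlist(y$palette)
  experiment_config(
    data_dir = y$data_dir, out_dir = y$out_dir,
    acq = do.call(acquisition_params, y$acq),
    augment = do.call(augment_params, c(
      y$augment[c("g_max", "flip", "rot90", "noise_sigma", "train_mode")],
      list(brightness_range = unlist(y$augment$brightness_range)))),
    network = do.call(network_config, y$network),
    protocol = do.call(train_protocol, y$protocol),
    seeds = as.integer(unlist(y$seeds)),
    palette = pal)
}

#' Desk-scale study conditions for the end-to-end recovery experiment
#'
#' The reduced problem instance used by the package's end-to-end checks and
#' by `scripts/acceptance.R`: five scans of eight 96 x 96 slices (1.1 mm
#' voxels cover the 100 mm phantom with margin), default noise and bias, a
#' base-8 two-level network, and a short high-rate protocol (Adam 5e-3,
#' batch 1, 10 epochs; the 1e-4 / 200-epoch defaults are calibrated for the
#' full-scale instance). See the methods vignette for the rationale.
#'
#' @param seed base seed; the dataset and every derived stream follow from it
#' @return list with `n_scans`, `acq`, `config` (spff), `config_blind`,
#'   `protocol`, and `train_seeds` (three seeds derived from `seed`)
#' @export
desk_scale <- function(seed = 0L) {
  seed <- as.integer(seed) %% 100000L
  list(n_scans = 5L,
       acq = acquisition_params(image_size = 96L, n_slices = 8L,
                                voxel_size_mm = 1.1, seed = seed),
       config = network_config("spff", base_channels = 8L, levels = 2L),
       config_blind = network_config("blind_control", base_channels = 8L,
                                     levels = 2L),
       protocol = train_protocol(lr = 5e-3, max_epochs = 10L,
                                 batch_size = 1L),
       train_seeds = seed + 1:3)
}
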