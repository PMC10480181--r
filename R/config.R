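# Allowed configuration keys per stage; unknown keys are rejected with the
# offending field path. All coordinates are 0-based, row-major, half-open.
runConfigSchema <- function() {
  list(
    seed = "scalar", output_dir = "scalar", verbosity = "scalar",
    synthesis = list(
      size = "vector", n_cells = "scalar", n_fibers = "scalar",
      background_level = "scalar", channels = "scalar",
      stripe = list(kind = "scalar", tile_h = "scalar", tile_w = "scalar",
                    amplitude = "scalar", angle_theta = "scalar",
                    per_tile_jitter = "scalar"),
      artifact = list(kind = "scalar", region_type = "scalar",
                      region = "vector", blur_sigma = "scalar",
                      attenuation = "scalar", fringe_period = "scalar",
                      fringe_amplitude = "scalar", rim_width = "scalar",
                      depth = "scalar")),
    sampling = list(patch = "scalar", n = "scalar", min_overlap = "scalar",
                    stride = "scalar", band_halfwidth = "scalar"),
    arch = list(patch_size = "scalar", in_channels = "scalar",
                base_channels = "scalar", n_downsample = "scalar",
                n_residual_blocks = "scalar", disc_layers = "scalar"),
    training = list(lr0 = "scalar", beta1 = "scalar", beta2 = "scalar",
                    epochs = "scalar", decay_start_epoch = "scalar",
                    lambda_cons = "scalar", batch_size = "scalar",
                    log_every = "scalar", max_steps = "scalar"),
    correction = list(step = "scalar", blend = "scalar"),
    metrics = list(data_range = "scalar", rois = "list"),
    io = list(input = "scalar", reference = "scalar", mask = "scalar",
              model = "scalar", output = "scalar"))
}

validateKeys <- function(x, schema, path = "") {
  for (nm in names(x)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(schema))
      stop(errorCondition(paste0("unknown configuration key: ", here),
                          class = c("stripecor_config_error", "error")))
    if (is.list(schema[[nm]]) && !identical(schema[[nm]], "list")) {
      if (!is.list(x[[nm]]))
        stop(errorCondition(paste0("expected a mapping at: ", here),
                            class = c("stripecor_config_error", "error")))
      validateKeys(x[[nm]], schema[[nm]], here)
    }
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' Loads a YAML configuration, validates every key against the pipeline
#' schema (unknown keys are rejected, with the offending field path in the
#' error), and returns a [RunConfig-class].
#'
#' @param path YAML file path.
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  asRunConfig(raw)
}

#' @rdname readRunConfig
#' @param raw a named list as parsed from YAML.
#' @export
asRunConfig <- function(raw) {
  validateKeys(raw, runConfigSchema())
  new("RunConfig",
      stages = raw[setdiff(names(raw), c("seed", "output_dir", "verbosity"))],
      seed = as.integer(raw$seed %||% 1L),
      outputDir = as.character(raw$output_dir %||% "stripecor-out"),
      verbosity = as.integer(raw$verbosity %||% 1L))
}
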