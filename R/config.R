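# Run configuration: a single JSON document holding every analysis constant
# exactly once (green threshold 100, control-gene Ct cutoff 32, 0.4 um
# voxels, 3 x 3 median kernel, alpha 0.05, ...). The pipeline and the CLI
# read only this structure, so a config + seed fully determines a run.

#' Default pipeline configuration
#'
#' Every entry is traceable either to the acquisition/analysis convention the
#' package reproduces or to a documented package design choice; see the
#' methods vignette. The structure round-trips losslessly through JSON.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return a named list (class `run_config`).
#' @examples
#' cfg <- default_config(mitoquant = list(green_threshold = 120))
#' cfg$mitoquant$green_threshold
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    synth = list(
      n_stacks_per_group = 4L, stack_dim = c(64L, 64L, 64L),
      n_astrocytes = 2L,
      mito_saline = list(enclosed = 3L, external = 8L, border = 1L),
      mito_microbead = list(enclosed = 7L, external = 8L, border = 1L),
      noise_sd = 0,
      ct = list(n_control = 33L, n_treated = 39L, reactive_fraction = 0.3,
                fold_change = list(Gulp1 = 2.5, Lgals3 = 7.8),
                baseline_dct_mean = 5, baseline_dct_sd = 0.85,
                dropout_prob = 0.05),
      iop = list(n_eyes_per_group = 10L, baseline_mmHg = 15,
                 amplitude_mmHg = 10, peak_day = 7, noise_sd = 1),
      retina = list(n_retinas_per_group = 6L, n_fields = 8L,
                    density_control = 3500, density_loss_pct = 15,
                    field_area_mm2 = 0.1, density_cv = 0.08)),
    mitoquant = list(green_threshold = 100, red_threshold = "otsu",
                     connectivity = 26L, min_voxels = 0L,
                     median_filter = TRUE, voxel_size_um = 0.4,
                     category_bins = c(0L, 5L, 20L)),
    scqpcr = list(qc_cutoff = 32, qc_mode = "both", ct_ceiling = 40,
                  reference = "pooled", conf = 0.95),
    stats = list(alpha = 0.05),
    rgc = list(blur_sigma = 1, min_area = 20, split_touching = FALSE))
  merge_config(cfg, list(...))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read / write a run configuration as JSON
#'
#' Values in the file override the package defaults, so a config file needs
#' to state only what it changes.
#'
#' @param path JSON file.
#' @param cfg a config list (from [default_config()]).
#' @return `read_config()`: a full config list; `write_config()`: the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_gq("config file not found: %s", path)
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(over$synth$stack_dim))
    over$synth$stack_dim <- as.integer(over$synth$stack_dim)
  do.call(default_config, over)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
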