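# Pipeline orchestration: synthetic cohort generation -> per-stack
# mitochondria quantification -> cohort summary and group comparison ->
# single-cell qPCR calls -> IOP / retina statistics -> versioned report.

REPORT_VERSION <- "1.0"

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[gliaquant %s] ", format(Sys.time(), "%H:%M:%S")),
                       sprintf(fmt, ...))
}

derive_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 7919) %% 2147483629)

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, as configured: synthetic stack generation and per-stack
#' quantification for a saline and a microbead group; the per-astrocyte
#' cohort summary (here each stack's astrocytes contribute their enclosed
#' counts) and a Wilcoxon-gated comparison of incorporation fractions;
#' single-cell qPCR generation and per-gene calls; IOP curve generation with
#' cumulative IOP comparison; retina field generation with density
#' comparison. Identical config + seed give an identical report.
#'
#' @param config a [default_config()] list (or path to a JSON config).
#' @param out_dir optional directory for the JSON + CSV report bundle.
#' @param verbose log stage timings to stderr (default TRUE).
#' @return the report (nested list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  seed <- cfg$seed
  report <- list(report_version = REPORT_VERSION, seed = seed, config = cfg)
  t0 <- Sys.time()

  ## --- imaging arm -------------------------------------------------------
  log_stage(verbose, "stage mitoquant: %d stacks per group",
            cfg$synth$n_stacks_per_group)
  groups <- c("saline", "microbead")
  stack_rows <- list(); astro_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mito <- if (g == "saline") cfg$synth$mito_saline else cfg$synth$mito_microbead
    for (s in seq_len(cfg$synth$n_stacks_per_group)) {
      sim <- make_stack(dim = cfg$synth$stack_dim,
                        n_astrocytes = cfg$synth$n_astrocytes,
                        n_enclosed = mito$enclosed, n_external = mito$external,
                        n_border = mito$border, noise_sd = cfg$synth$noise_sd,
                        voxel_size_um = cfg$mitoquant$voxel_size_um,
                        seed = derive_seed(seed, gi * 1000L + s))
      q <- quantify_stack(sim$stack,
                          green_threshold = cfg$mitoquant$green_threshold,
                          red_threshold = cfg$mitoquant$red_threshold,
                          connectivity = cfg$mitoquant$connectivity,
                          min_voxels = cfg$mitoquant$min_voxels,
                          median_filter = cfg$mitoquant$median_filter)
      stack_rows[[length(stack_rows) + 1L]] <- data.frame(
        group = g, stack = s,
        astro_volume_um3 = q$quant$astro_volume_um3,
        enclosed_mito_volume_um3 = q$quant$enclosed_mito_volume_um3,
        incorporation_fraction_pct = q$quant$incorporation_fraction_pct,
        n_components = q$quant$n_components, n_enclosed = q$quant$n_enclosed)
      # attribute enclosed components to astrocyte instances via the truth
      # masks (instance segmentation of the green channel is out of scope)
      d <- dim(sim$stack$green)
      enc_ids <- q$enclosures$component_id[q$enclosures$enclosed]
      per_astro <- vapply(sim$truth$astro_masks, function(mvox) {
        inside <- 0L
        for (cc in q$components$components) {
          if (!(cc$id %in% enc_ids)) next
          if (all(lin_idx(cc$voxels, d) %in% mvox)) inside <- inside + 1L
        }
        inside
      }, integer(1))
      astro_rows[[length(astro_rows) + 1L]] <-
        data.frame(group = g, stack = s,
                   astrocyte = seq_along(per_astro), enclosed_count = per_astro)
    }
  }
  stacks_df <- do.call(rbind, stack_rows)
  astro_df <- do.call(rbind, astro_rows)
  cohort <- summarize_cohort(astro_df, bins = cfg$mitoquant$category_bins)
  frac_test <- two_group_test(
    stacks_df$incorporation_fraction_pct[stacks_df$group == "saline"],
    stacks_df$incorporation_fraction_pct[stacks_df$group == "microbead"],
    gate_alpha = cfg$stats$alpha)
  report$mitoquant <- list(
    stacks = stacks_df, astrocytes = astro_df,
    cohort = list(per_group = cohort$per_group,
                  categories = as.data.frame(cohort$categories)),
    fraction_medians = vapply(split(stacks_df$incorporation_fraction_pct,
                                    stacks_df$group), median, numeric(1),
                              na.rm = TRUE),
    fraction_test = test_result_json(frac_test))

  ## --- single-cell qPCR arm ---------------------------------------------
  log_stage(verbose, "stage scqpcr: %d + %d cells, %d genes",
            cfg$synth$ct$n_control, cfg$synth$ct$n_treated,
            length(default_gene_panel()))
  fc <- cfg$synth$ct$fold_change
  fc <- if (is.null(fc)) NULL else unlist(fc)
  ctsim <- make_ct_table(n_control = cfg$synth$ct$n_control,
                         n_treated = cfg$synth$ct$n_treated,
                         reactive_fraction = cfg$synth$ct$reactive_fraction,
                         fold_change = fc,
                         baseline_dct_mean = cfg$synth$ct$baseline_dct_mean,
                         baseline_dct_sd = cfg$synth$ct$baseline_dct_sd,
                         dropout_prob = cfg$synth$ct$dropout_prob,
                         ceiling = cfg$scqpcr$ct_ceiling,
                         seed = derive_seed(seed, 5000L))
  calls <- gene_calls(ctsim$table, qc_cutoff = cfg$scqpcr$qc_cutoff,
                      reference = cfg$scqpcr$reference)
  report$scqpcr <- list(n_cells = nrow(ctsim$table$ct), calls = calls)

  ## --- IOP arm -----------------------------------------------------------
  log_stage(verbose, "stage stats: IOP curves for %d eyes per group",
            cfg$synth$iop$n_eyes_per_group)
  iop_rows <- list()
  for (gi in seq_along(groups)) {
    for (e in seq_len(cfg$synth$iop$n_eyes_per_group)) {
      ser <- make_iop_series(groups[gi],
                             baseline_mmHg = cfg$synth$iop$baseline_mmHg,
                             amplitude_mmHg = cfg$synth$iop$amplitude_mmHg,
                             peak_day = cfg$synth$iop$peak_day,
                             noise_sd = cfg$synth$iop$noise_sd,
                             label = sprintf("%s_%02d", groups[gi], e),
                             seed = derive_seed(seed, 6000L + gi * 100L + e))
      iop_rows[[length(iop_rows) + 1L]] <- data.frame(
        group = groups[gi], eye = e, ciop = cumulative_iop(ser),
        max_iop = max(ser$iop))
    }
  }
  iop_df <- do.call(rbind, iop_rows)
  report$iop <- list(
    eyes = iop_df,
    ciop_test = test_result_json(two_group_test(
      iop_df$ciop[iop_df$group == "saline"],
      iop_df$ciop[iop_df$group == "microbead"],
      gate_alpha = cfg$stats$alpha)))

  ## --- retina arm --------------------------------------------------------
  log_stage(verbose, "stage rgc: %d retinas per group",
            cfg$synth$retina$n_retinas_per_group)
  rc <- cfg$synth$retina
  retina_rows <- list()
  for (gi in seq_along(groups)) {
    dens0 <- if (groups[gi] == "saline") rc$density_control else
      rc$density_control * (1 - rc$density_loss_pct / 100)
    for (rt in seq_len(rc$n_retinas_per_group)) {
      rseed <- derive_seed(seed, 7000L + gi * 500L + rt)
      dens <- with_seed(rseed, rnorm(1, dens0, rc$density_cv * dens0))
      counts <- vapply(seq_len(rc$n_fields), function(f) {
        fld <- make_retina_field(density = dens,
                                 field_area_mm2 = rc$field_area_mm2,
                                 seed = derive_seed(rseed, f))
        as.integer(count_nuclei(fld$image, blur_sigma = cfg$rgc$blur_sigma,
                                min_area = cfg$rgc$min_area,
                                split_touching = cfg$rgc$split_touching))
      }, integer(1))
      rd <- retina_density(counts, rc$field_area_mm2, n_fields = rc$n_fields)
      retina_rows[[length(retina_rows) + 1L]] <- data.frame(
        group = groups[gi], retina = rt, mean_density = rd$mean_density)
    }
  }
  retina_df <- do.call(rbind, retina_rows)
  report$rgc <- list(
    retinas = retina_df,
    density_test = test_result_json(two_group_test(
      retina_df$mean_density[retina_df$group == "saline"],
      retina_df$mean_density[retina_df$group == "microbead"],
      gate_alpha = cfg$stats$alpha)))

  log_stage(verbose, "pipeline finished in %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    write.csv(stacks_df, file.path(out_dir, "stack_quant.csv"), row.names = FALSE)
    write.csv(astro_df, file.path(out_dir, "astrocytes.csv"), row.names = FALSE)
    write.csv(calls, file.path(out_dir, "gene_calls.csv"), row.names = FALSE)
    write_heatmap_csv(ctsim$table, file.path(out_dir, "heatmap_z.csv"),
                      qc_cutoff = cfg$scqpcr$qc_cutoff,
                      reference = cfg$scqpcr$reference)
    write.csv(iop_df, file.path(out_dir, "iop.csv"), row.names = FALSE)
    write.csv(retina_df, file.path(out_dir, "retina_density.csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}
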