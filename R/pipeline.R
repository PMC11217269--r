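#' Read a pipeline configuration file
#'
#' The configuration is a single DCF (`key: value`) text file. Recognised
#' keys: `spectra` (wide CSV path; its `_metadata.csv` sidecar is found
#' automatically), `environment`, `fatty_acids`, `community` (CSV paths,
#' each optional), `output_dir`, `seed`, `n_permutations`,
#' `sg_half_window`, `sg_polyorder`, `snv_range` (`"analysis"` or
#' `"full"`), `rectify` (`"negclip"`/`"abs"`), `run_pca`, `run_rda`,
#' `run_anosim` (`true`/`false`). Unknown keys error.
#'
#' @param path path to the DCF config file.
#' @return a validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- c("spectra", "environment", "fatty_acids", "community",
             "output_dir", "seed", "n_permutations", "sg_half_window",
             "sg_polyorder", "snv_range", "rectify",
             "run_pca", "run_rda", "run_anosim")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop_("unknown config key(s): %s", paste(unknown, collapse = ", "))
  as_flag <- function(x, default) {
    if (is.null(x)) default else tolower(trimws(x)) %in% c("true", "yes", "1")
  }
  cfg <- list(
    spectra = raw$spectra,
    environment = raw$environment,
    fatty_acids = raw$fatty_acids,
    community = raw$community,
    output_dir = raw$output_dir %||% "icephenome_out",
    seed = as.integer(raw$seed %||% 1L),
    n_permutations = as.integer(raw$n_permutations %||% 999L),
    sg_half_window = as.integer(raw$sg_half_window %||% 4L),
    sg_polyorder = as.integer(raw$sg_polyorder %||% 3L),
    snv_range = raw$snv_range %||% "analysis",
    rectify = raw$rectify %||% "negclip",
    run_pca = as_flag(raw$run_pca, TRUE),
    run_rda = as_flag(raw$run_rda, FALSE),
    run_anosim = as_flag(raw$run_anosim, FALSE),
    config_path = path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$spectra)) stop_("config lacks the required 'spectra' path")
  for (key in c("spectra", "environment", "fatty_acids", "community")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop_("config path '%s' does not exist: %s", key, p)
  }
  if (!cfg$snv_range %in% c("analysis", "full"))
    stop_("snv_range must be 'analysis' or 'full'")
  if (!cfg$rectify %in% c("negclip", "abs"))
    stop_("rectify must be 'negclip' or 'abs'")
  cfg
}

#' Write a tidy CSV with a provenance header
#'
#' Prepends a `#`-comment line carrying the run seed and the config file
#' hash so every output records how it was produced; read back with
#' `read.csv(..., comment.char = "#")`.
#' @keywords internal
write_output_csv <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# icephenome seed=%s config_md5=%s", seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: **read** (spectra + optional tables), **preprocess**
#' (Savitzky-Golay second derivative, crop, SNV), **quantify** (band
#' areas per cell, log10), **stats** (PCA; RDA against the environment
#' table and ANOSIM on the community table when enabled and provided).
#' Any stage failure aborts with the failing stage named. Outputs are
#' deterministic for a fixed config + seed.
#'
#' @param config a config list from [read_pipeline_config()] or a path
#'   to a DCF config file.
#' @return a run report: list with `stages` (data frame of stage, records
#'   processed), `outputs` (paths written), `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  hash <- unname(tools::md5sum(config$config_path %||% config$spectra))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  outputs <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  spectra <- run_stage("read", read_spectra(config$spectra))
  env_tab <- if (!is.null(config$environment))
    run_stage("read", ice_core_table(config$environment)) else NULL
  fa_tab <- if (!is.null(config$fatty_acids))
    run_stage("read", fatty_acid_table(config$fatty_acids)) else NULL
  community <- if (!is.null(config$community))
    run_stage("read", utils::read.csv(config$community, check.names = FALSE)) else NULL
  stages$read <- length(spectra)

  ranges <- if (config$snv_range == "analysis") default_analysis_ranges() else NULL
  pre <- run_stage("preprocess", lapply(
    spectra, preprocess_spectrum,
    half_window = config$sg_half_window, polyorder = config$sg_polyorder,
    snv_ranges = ranges))
  stages$preprocess <- length(pre)

  registry <- default_band_registry()
  profiles <- run_stage("quantify",
                        profile_cells(pre, registry, rectify = config$rectify))
  stages$quantify <- nrow(profiles)
  p_path <- file.path(config$output_dir, "cell_profiles.csv")
  write_output_csv(profiles, p_path, config$seed, hash)
  outputs <- c(outputs, p_path)

  stat_records <- 0L
  if (config$run_pca) {
    log_cols <- grep("^log10_", names(profiles), value = TRUE)
    mat <- as.matrix(profiles[, log_cols])
    rownames(mat) <- profiles$cell_id
    keep <- stats::complete.cases(mat)
    ord <- run_stage("stats", pca_ordination(mat[keep, , drop = FALSE]))
    sc <- data.frame(cell_id = profiles$cell_id[keep], ord$scores,
                     check.names = FALSE)
    s_path <- file.path(config$output_dir, "pca_scores.csv")
    write_output_csv(sc, s_path, config$seed, hash)
    e_path <- file.path(config$output_dir, "pca_explained.csv")
    write_output_csv(data.frame(axis = paste0("PC", seq_along(ord$explained)),
                                explained_fraction = ord$explained),
                     e_path, config$seed, hash)
    outputs <- c(outputs, s_path, e_path)
    stat_records <- stat_records + sum(keep)
  }
  if (config$run_anosim && !is.null(community)) {
    counts <- as.matrix(community[, setdiff(names(community),
                                            c("sample_id", "site"))])
    res <- run_stage("stats", anosim(bray_curtis(counts), community$site,
                                     n_permutations = config$n_permutations,
                                     seed = config$seed))
    a_path <- file.path(config$output_dir, "anosim.csv")
    write_output_csv(data.frame(statistic = res$statistic, p_value = res$p_value,
                                n_permutations = res$n_permutations,
                                method = res$method, seed = config$seed),
                     a_path, config$seed, hash)
    outputs <- c(outputs, a_path)
    stat_records <- stat_records + nrow(counts)
  }
  if (config$run_rda && !is.null(env_tab)) {
    # site x week mean profiles against their environmental drivers
    log_cols <- grep("^log10_", names(profiles), value = TRUE)
    agg <- stats::aggregate(profiles[, log_cols],
                            by = list(site = profiles$site, week = profiles$week),
                            FUN = mean, na.rm = TRUE)
    env_key <- env_tab[, c("site", "week")]
    idx <- match(paste(agg$site, agg$week), paste(env_key$site, env_key$week))
    if (anyNA(idx))
      stop_("pipeline stage 'stats' failed: environment table lacks site/week rows: %s",
            paste(paste(agg$site, agg$week)[is.na(idx)], collapse = "; "))
    env <- env_tab[idx, , drop = FALSE]
    preds <- cbind(brine_volume = brine_volume_fraction(
                     env$bulk_salinity_ppt, env$ice_temperature_c),
                   bulk_salinity = env$bulk_salinity_ppt,
                   ice_nox = env$nox_um,
                   water_temperature = env$water_temperature_c)
    res <- run_stage("stats", rda_ordination(
      as.matrix(agg[, log_cols]), preds,
      n_permutations = config$n_permutations, seed = config$seed))
    r_path <- file.path(config$output_dir, "rda.csv")
    write_output_csv(data.frame(constrained_fraction = res$constrained_fraction,
                                pseudo_f = res$pseudo_f, p_value = res$p_value,
                                n_permutations = res$n_permutations,
                                seed = config$seed),
                     r_path, config$seed, hash)
    outputs <- c(outputs, r_path)
    stat_records <- stat_records + nrow(agg)
  }
  stages$stats <- stat_records

  list(stages = data.frame(stage = names(stages),
                           records = unlist(stages, use.names = FALSE)),
       outputs = outputs, seed = config$seed)
}

#' Recompute the in-paper numeric targets from packaged fixtures
#'
#' Twelve registered reference quantities -- brine physics, seasonal
#' nutrient summaries and fatty-acid class sums -- are recomputed from
#' the packaged tables and compared with their printed values at the
#' stated tolerance. Failures are rows (`pass = FALSE`), never errors.
#'
#' @return data frame: `id`, `computed`, `printed`, `tolerance`, `pass`.
#' @export
reproduce_paper <- function() {
  ice <- ice_core_table()
  fa <- fatty_acid_table()
  inner <- ice[ice$site == "inner", ]
  outer <- ice[ice$site == "outer", ]
  vb_inner <- brine_volume_fraction(inner$bulk_salinity_ppt, inner$ice_temperature_c)
  ratios <- function(rows) lapply(seq_len(nrow(rows)),
                                  function(i) nutrient_ratios(rows[i, ]))
  n_si_outer <- vapply(ratios(outer), `[[`, numeric(1), "n_si")
  si_p_inner <- vapply(ratios(inner), `[[`, numeric(1), "si_p")
  sums_outer <- fa_class_sums(fa$fa_name, fa$outer_pct)
  sums_inner <- fa_class_sums(fa$fa_name, fa$inner_pct)
  rows <- list(
    list("brine_salinity_w1_inner",
         brine_salinity(inner$ice_temperature_c[inner$week == "Week 1"]),
         37.36, 0.01),
    list("inner_brine_volume_mean_pct", mean(vb_inner), 24, 0.5),
    list("outer_bulk_salinity_mean", mean(outer$bulk_salinity_ppt), 10.1, 0.05),
    list("inner_nox_mean_um", summarize_series(inner$nox_um)$mean, 5.0, 0.05),
    list("inner_nox_sd_um", summarize_series(inner$nox_um)$sd, 3.7, 0.05),
    list("n_si_outer_max", max(n_si_outer, na.rm = TRUE), 5.29, 0.005),
    list("si_p_inner_max", max(si_p_inner, na.rm = TRUE), 8.36, 0.005),
    list("outer_sum_mufa_pct", sums_outer$mufa, 54, 0.5),
    list("outer_sum_pufa_pct", sums_outer$pufa, 16, 0.5),
    list("outer_sum_omega9_pct", sums_outer$omega9, 4.1, 0.05),
    list("outer_sum_epa_dha_pct", sums_outer$epa_plus_dha, 7.8, 0.05),
    list("inner_big_four_pct", sums_inner$big_four, 56.5, 0.05))
  out <- data.frame(
    id = vapply(rows, `[[`, character(1), 1L),
    computed = vapply(rows, `[[`, numeric(1), 2L),
    printed = vapply(rows, `[[`, numeric(1), 3L),
    tolerance = vapply(rows, `[[`, numeric(1), 4L))
  out$pass <- abs(out$computed - out$printed) <= out$tolerance
  out
}
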