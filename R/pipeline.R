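# End-to-end seeded pipeline ---------------------------------------------

#' Full-run configuration
#'
#' Bundles the generator, preprocessing, blend design and model settings
#' of a complete authentication run.
#'
#' @param seed Master seed for every stochastic draw.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param preprocess A [preprocess_config()].
#' @param design A [blend_design()] for the calibration campaign.
#' @param lda_levels Blend levels (% v/v, 0 = pure CAO) of the LDA screen.
#' @param lda_wavenumbers Marker wavenumbers for LDA features.
#' @param plsr_factors Latent factors per calibration model.
#' @param pure_replicates Replicate measurements per pure-oil brand in the
#'   classification stage.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(seed = 1,
                       generator = generator_config(seed = seed),
                       preprocess = preprocess_config(),
                       design = design_table5(),
                       lda_levels = c(0, 1, 3, 5, 10),
                       lda_wavenumbers = lda_marker_wavenumbers,
                       plsr_factors = 4,
                       pure_replicates = 3L) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(preprocess, "preprocess_config"),
            inherits(design, "blend_design"))
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), generator = generator,
                 preprocess = preprocess, design = design,
                 lda_levels = lda_levels,
                 lda_wavenumbers = lda_wavenumbers,
                 plsr_factors = plsr_factors,
                 pure_replicates = as.integer(pure_replicates)),
            class = "run_config")
}

stage <- function(name, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the complete authentication workflow
#'
#' Executes generate -> smooth -> ratio screen -> PCA -> LDA -> PLSR on
#' synthetic data and writes CSV tables plus a JSON summary, each stamped
#' with the configuration hash and seed. Runs are byte-identical for a
#' fixed configuration.
#'
#' @param config A [run_config()].
#' @param output_dir Directory for the report bundle (created if needed).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_full <- function(config = run_config(), output_dir = tempfile("camspec_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- fnv1a_hash(unclass(config))
  gen <- config$generator

  lib <- stage("generate", {
    if (!length(config$design$cao_brands) || !length(config$design$levels))
      stop("empty blend design")
    build_endmember_library(gen$seed)
  })
  pure_set <- stage("generate-pure-oils", {
    sp <- list()
    for (oil in names(lib))
      for (b in paste0(oil, "-", 1:7))
        for (r in seq_len(config$pure_replicates))
          sp[[length(sp) + 1]] <- synth_spectrum(lib[[oil]], gen, b, r)
    spectrum_set(sp)
  })
  design_set <- stage("generate-blends", generate_design(config$design, gen, lib))
  lda_set <- stage("generate-lda-groups",
                   generate_classification_set(config$lda_levels, gen,
                                               library = lib))

  smooth_cfg <- config$preprocess
  pure_smooth <- stage("smooth", {
    if (smooth_cfg$sg_window > 1)
      savgol_smooth(pure_set, smooth_cfg$sg_window, smooth_cfg$sg_polyorder)
    else pure_set
  })

  rt <- stage("ratio", ratio_table(pure_smooth))
  ladder_rt <- stage("ratio-ladder", ratio_table(template_ladder(
    cfg = generator_config(grid_step = gen$grid_step, noise_sd = 0,
                           seed = gen$seed))))
  ratio_digest <- stats::aggregate(ratio ~ oil_type, rt,
                                   function(r) c(min = min(r), max = max(r)))
  ratio_digest <- data.frame(oil_type = ratio_digest$oil_type,
                             min_ratio = ratio_digest$ratio[, "min"],
                             max_ratio = ratio_digest$ratio[, "max"])

  regions <- list("4000-650" = region_spec(4000, 650),
                  "3050-2750,1800-650" = region_spec(c(3050, 1800), c(2750, 650)),
                  "3050-2750" = region_spec(3050, 2750),
                  "1800-650" = region_spec(1800, 650))
  pca_tab <- stage("pca-regions", {
    pp <- preprocess_set(pure_set, preprocess_config(
      sg_window = smooth_cfg$sg_window, sg_polyorder = smooth_cfg$sg_polyorder,
      derivative_order = smooth_cfg$derivative_order,
      derivative_polyorder = smooth_cfg$derivative_polyorder,
      region = region_spec(4000, 650)))
    explained_variance_profile(pp, regions, 3)
  })

  lda_res <- stage("lda", {
    feats <- extract_features(
      if (smooth_cfg$sg_window > 1)
        savgol_smooth(lda_set, smooth_cfg$sg_window, smooth_cfg$sg_polyorder)
      else lda_set,
      config$lda_wavenumbers)
    loo_cross_validate(feats)
  })

  plsr_tab <- stage("plsr", run_calibration_suite(
    design_set, config$plsr_factors, config$preprocess))

  write.csv(rt, file.path(output_dir, "ratio_table.csv"), row.names = FALSE)
  write.csv(pca_tab, file.path(output_dir, "pca_variance.csv"), row.names = FALSE)
  write.csv(as.data.frame(lda_res$cv$counts),
            file.path(output_dir, "lda_confusion_cv.csv"))
  write.csv(as.data.frame(lda_res$resubstitution$counts),
            file.path(output_dir, "lda_confusion_resub.csv"))
  write.csv(plsr_tab, file.path(output_dir, "plsr_metrics.csv"), row.names = FALSE)

  summary <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    n_pure = length(pure_set),
    n_design = length(design_set),
    ratio = list(digest = ratio_digest,
                 ladder_crossover_level = crossover_level(ladder_rt),
                 pure_cao_all_flagged_pure = all(
                   rt$label[rt$oil_type == "CAO"] == LABEL_PURE),
                 other_oils_all_flagged = all(
                   rt$label[rt$oil_type != "CAO"] == LABEL_SUSPECT)),
    pca = list(variance = pca_tab),
    lda = list(cv_accuracy_pct = lda_res$cv$accuracy_pct,
               resub_accuracy_pct = lda_res$resubstitution$accuracy_pct,
               cv_counts = as.data.frame(as.table(lda_res$cv$counts)),
               resub_counts = as.data.frame(as.table(lda_res$resubstitution$counts))),
    plsr = list(metrics = plsr_tab)
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}
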