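#' Pipeline configuration
#'
#' Bundles every setting of the simulate -> code -> fit -> BMS -> stage-2
#' pipeline under one global seed. Per-stage seeds are derived
#' deterministically from the global seed and the stage name, so any stage is
#' independently reproducible.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param n_subjects Cohort size.
#' @param trace_spec A [trace_spec()].
#' @param model Generating core model of the synthetic cohort.
#' @param param_ranges,trait,coding Cohort settings (see [generate_cohort()]).
#' @param priors A [prior_spec()].
#' @param control A [fit_control()].
#' @param models Core models entered into stage-1 BMS.
#' @param bms_alpha0,bms_tol,bms_max_iter,n_exceed BMS settings.
#' @param literal Use the literal softmax form.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 20,
                            trace_spec = slotbelief::trace_spec(),
                            model = "M2",
                            param_ranges = default_param_ranges(),
                            trait = trait_model(), coding = "WLN",
                            priors = prior_spec(), control = fit_control(),
                            models = core_models(), bms_alpha0 = 1,
                            bms_tol = 1e-6, bms_max_iter = 500,
                            n_exceed = 1e5, literal = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = n_subjects, trace_spec = trace_spec,
                 model = model, param_ranges = param_ranges, trait = trait,
                 coding = coding, priors = priors, control = control,
                 models = models, bms_alpha0 = bms_alpha0, bms_tol = bms_tol,
                 bms_max_iter = bms_max_iter, n_exceed = n_exceed,
                 literal = literal),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: generate the pre-determined trace; simulate
#' the synthetic cohort and write it as CSV; enumerate the twelve
#' perceptual/response datasets; fit every core model to every subject in
#' every dataset; run random-effects BMS per dataset; run the stage-2
#' construct-validity comparison. Writes all tabular outputs as CSV,
#' structured outputs as JSON, and a run manifest with the seed and the MD5
#' hash of every output file. Rerunning with an identical configuration
#' reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`trace`, `cohort`,
#'   `datasets`, `fits`, `bms`, `stage2`, `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "trace"
  result <- tryCatch({
    message("[slotbelief] stage: trace")
    trace <- generate_trace(config$trace_spec)
    write_trace(trace, file.path(config$out_dir, "trace.csv"))

    stage <- "cohort"
    message("[slotbelief] stage: cohort")
    cohort <- generate_cohort(config$n_subjects, trace, config$model,
                              config$param_ranges, config$trait,
                              config$coding,
                              seed = derive_seed(config$seed, "cohort"),
                              out_dir = file.path(config$out_dir, "cohort"))

    stage <- "code"
    message("[slotbelief] stage: code")
    datasets <- enumerate_datasets(trace, cohort)

    stage <- "fit"
    fits <- list()
    for (lab in names(datasets)) {
      message("[slotbelief] stage: fit ", lab)
      fits[[lab]] <- lapply(setNames(config$models, config$models),
                            function(m) fit_dataset(datasets[[lab]], m,
                                                    config$priors,
                                                    config$control,
                                                    config$literal))
      all_fits <- do.call(c, unname(fits[[lab]]))
      write_fits(all_fits, file.path(config$out_dir,
                                     paste0("fits_", lab, ".json")))
    }

    stage <- "bms"
    message("[slotbelief] stage: bms")
    bms <- lapply(setNames(names(datasets), names(datasets)), function(lab) {
      rfx_bms(evidence_matrix(fits[[lab]]), alpha0 = config$bms_alpha0,
              tol = config$bms_tol, max_iter = config$bms_max_iter,
              n_exceed = config$n_exceed,
              seed = derive_seed(config$seed, paste0("bms-", lab)))
    })
    r_matrix <- t(vapply(bms, function(b) b$r, numeric(length(config$models))))
    write.csv(data.frame(dataset = rownames(r_matrix), r_matrix),
              file.path(config$out_dir, "bms_model_probabilities.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(bms, function(b) list(alpha = as.list(b$alpha), r = as.list(b$r),
                                   exceedance = as.list(b$exceedance),
                                   winner = b$winner,
                                   iterations = b$iterations,
                                   converged = b$converged)),
      file.path(config$out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)

    stage <- "stage2"
    message("[slotbelief] stage: stage2")
    stage2 <- tryCatch(
      stage2_select(fits, bms, cohort$covariates),
      error = function(e) {
        message("[slotbelief] stage2 skipped: ", conditionMessage(e))
        structure(list(error = conditionMessage(e)), class = "stage2_skip")
      })
    if (inherits(stage2, "stage2_result")) {
      write.csv(stage2$table,
                file.path(config$out_dir, "stage2_ranking.csv"),
                row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(winner = stage2$winner, bonferroni_level = stage2$bonferroni_level,
             table = stage2$table, skipped = stage2$skipped),
        file.path(config$out_dir, "stage2.json"), auto_unbox = TRUE,
        digits = NA)
    } else {
      jsonlite::write_json(list(error = stage2$error),
                           file.path(config$out_dir, "stage2.json"),
                           auto_unbox = TRUE)
    }

    list(trace = trace, cohort = cohort, datasets = datasets, fits = fits,
         bms = bms, stage2 = stage2)
  }, error = function(e) {
    stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- write_manifest(config)
  result$manifest <- manifest
  invisible(result)
}

write_manifest <- function(config) {
  files <- sort(list.files(config$out_dir, recursive = TRUE,
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "", names(hashes))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("slotbelief")),
                   n_subjects = config$n_subjects, model = config$model,
                   files = as.list(hashes))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}
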