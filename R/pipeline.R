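#' Default end-to-end run configuration
#'
#' A small synthetic-cohort demonstration configuration that completes on
#' one CPU in well under a minute. Every stage parameter is named here so a
#' config round-trips through YAML serialization unchanged.
#'
#' @param out_dir output directory.
#' @param seed global seed fanned out to the stage substreams.
#' @return nested configuration list.
#' @export
default_run_config <- function(out_dir = tempfile("alcoscore_run_"), seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, episcore = TRUE, ewas = TRUE, assoc = TRUE),
    synthgen = list(
      n_samples = 400L, n_cpgs = 500L, n_batches = 2L,
      arch = list(n_small = 50L, n_medium = 20L, n_large = 10L,
                  frac_small = 1e-4, frac_medium = 1e-3, frac_large = 1e-2,
                  total_methylome_variance = NULL),
      report = list(p_normal = 0.628, p_more = 0.225, p_less = 0.097,
                    deviation_sd = 0.4, habitual_drives_methylome = TRUE),
      write_matrices = FALSE
    ),
    split = list(train = 0.52, test = 0.48),
    episcore = list(alpha = 0.5, nfolds = 10L,
                    preselect_extra = 100L),
    bayesr = list(mixture_variances = c(1e-4, 1e-3, 1e-2),
                  burn_in = 200L, draws_retained = 400L, thin = 1L,
                  used_iterations = 400L, pip_threshold = 0.95),
    assoc = list(beta_continuous = 0.3, log_or = 0.2, log_hr = 0.15,
                 beta_brain = -0.2)
  )
}

log_stage <- function(log_path, stage, t0, params) {
  line <- sprintf("[%s] stage=%s wall=%.2fs params={%s}",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0,
                  paste(names(params), unlist(params), sep = "=", collapse = ", "))
  cat(line, "\n", file = log_path, append = TRUE)
  message(line)
}

#' Run the end-to-end analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stages in analysis order: cohort simulation, phenotype
#' preparation and train/test split, the EpiScore design grid plus a final
#' full-cohort model, the mixture-model EWAS with variance partitioning,
#' and the phenome association battery. Produces a machine-readable
#' `summary.json` (deterministic for a given config) and a human log with
#' package version, seeds and parameter echoes. A stage failure halts with
#' a stage-named error; artifacts of completed stages are retained.
#'
#' @param config configuration list as from [default_run_config()].
#' @return report bundle (list of stage outputs), invisibly; artifacts are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(sprintf("alcoscore %s | seed=%d\n",
              as.character(utils::packageVersion("alcoscore")), config$seed),
      file = log_path)
  summary <- list(seed = config$seed)
  bundle <- list()
  run_stage <- function(name, fn) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage(log_path, name, t0, list(seed = config$seed))
    out
  }

  ## --- simulate -----------------------------------------------------------
  sc <- run_stage("simulate", function() {
    sg <- config$synthgen
    methyl <- simulate_methylome(sg$n_samples, sg$n_cpgs, sg$n_batches,
                                 seed = config$seed)
    arch <- do.call(effect_architecture, sg$arch)
    report <- do.call(reporting_model, sg$report)
    sc <- simulate_phenotype(methyl, arch, report, seed = config$seed)
    sc <- simulate_outcomes(sc, config$assoc$beta_continuous,
                            config$assoc$log_or, config$assoc$log_hr,
                            config$assoc$beta_brain, seed = config$seed)
    if (isTRUE(sg$write_matrices)) {
      write_matrix(sc$methyl, file.path(config$out_dir, "methyl.tsv"))
      write_cohort(sc$cohort, file.path(config$out_dir, "cohort.tsv"))
    }
    sc
  })
  bundle$cohort <- sc
  summary$simulate <- list(
    n_samples = nrow(sc$cohort), n_cpgs = ncol(sc$methyl),
    n_causal = length(sc$truth$causal),
    target_methylome_variance = sc$truth$target_ve,
    realized_methylome_variance = sc$truth$realized_ve
  )

  split <- split_cohort(sc, c(train = config$split$train,
                              test = config$split$test),
                        seed = config$seed)

  ## --- episcore -----------------------------------------------------------
  if (isTRUE(config$stages$episcore)) {
    es <- run_stage("episcore", function() {
      set.seed(substream_seed(config$seed, "effects"))
      extras <- sample(setdiff(colnames(sc$methyl), sc$truth$causal),
                       min(config$episcore$preselect_extra,
                           ncol(sc$methyl) - length(sc$truth$causal)))
      presel <- sort(c(sc$truth$causal, extras))
      grid <- design_grid(split$train, split$test,
                          feature_sets = list(all = NULL, preselected = presel),
                          training_subsets = c("everyone", "normal_week"),
                          alpha = config$episcore$alpha,
                          nfolds = config$episcore$nfolds,
                          seed = config$seed)
      final <- train_elastic_net(
        suppressMessages(preselect_features(sc$methyl, presel)),
        log_units(sc$cohort$units),
        alpha = config$episcore$alpha, nfolds = config$episcore$nfolds,
        seed = config$seed, feature_label = "preselected",
        subset_label = "full_cohort")
      list(grid = grid, final = final, preselected = presel)
    })
    bundle$episcore <- es
    utils::write.csv(es$grid$report,
                     file.path(config$out_dir, "episcore_grid.csv"),
                     row.names = FALSE)
    best <- es$grid$report[es$grid$report$subset_label == "all", ]
    best <- best[which.max(best$incremental_r2), ]
    summary$episcore <- list(
      n_models = length(es$grid$models),
      final_n_features = es$final$meta$n_selected,
      best_cell = paste(best$training_subset, best$feature_set, sep = "."),
      best_test_r = best$pearson_r,
      best_test_incremental_r2 = best$incremental_r2
    )
  }

  ## --- ewas ---------------------------------------------------------------
  if (isTRUE(config$stages$ewas)) {
    ew <- run_stage("ewas", function() {
      bc <- config$bayesr
      cfg <- bayesr_config(
        mixture_variances = as.numeric(bc$mixture_variances),
        burn_in = bc$burn_in, draws_retained = bc$draws_retained,
        thin = bc$thin, used_iterations = bc$used_iterations,
        pip_threshold = bc$pip_threshold, seed = config$seed)
      post <- bayesr_ewas(m_values(sc$methyl), sc$cohort$units,
                          sc$cohort$age, sc$cohort$sex, sc$cohort$smoking,
                          batch = sc$cohort$batch, config = cfg)
      post
    })
    bundle$ewas <- ew
    utils::write.csv(ew$summary,
                     file.path(config$out_dir, "ewas_summary.csv"),
                     row.names = FALSE)
    leads <- call_significant(ew)
    summary$ewas <- list(
      variance_explained_mean = ew$ve_mean,
      variance_explained_cri = ew$ve_cri,
      n_lead_cpgs = nrow(leads),
      geweke_z_sigma2 = geweke(ew$sigma2)$z
    )
  }

  ## --- assoc --------------------------------------------------------------
  if (isTRUE(config$stages$assoc) && isTRUE(config$stages$episcore)) {
    as_res <- run_stage("assoc", function() {
      score <- suppressMessages(project(bundle$episcore$final, sc$methyl))
      association_battery(sc$outcomes, log_units(sc$cohort$units), score,
                          sc$cohort$age, sc$cohort$sex)
    })
    bundle$assoc <- as_res
    utils::write.csv(as_res, file.path(config$out_dir, "associations.csv"),
                     row.names = FALSE)
    summary$assoc <- list(
      n_tests = nrow(as_res),
      n_fdr_significant = sum(as_res$p_fdr < 0.05)
    )
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$summary <- summary
  invisible(bundle)
}
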