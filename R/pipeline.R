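# End-to-end orchestration: simulate -> extract -> pca -> predict ->
# cluster -> report, driven by a single validated configuration.

#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline exposes. Unknown keys are
#' rejected by [run_pipeline()] before any stage runs, so configuration
#' typos fail fast.
#'
#' @return Named list with sections `simulator`, `predict`, `cluster`, and
#'   `io`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulator = list(
      n_subjects = 50L, phenotypes = 0L, phenotype_gap = 0.6,
      rater_noise_sd = 0.8, day2 = FALSE
    ),
    predict = list(
      alpha_grid = seq(0.1, 1, by = 0.1), n_lambda = 50L,
      lambda_ratio = 1e-3, df_cap_frac = 0.5
    ),
    cluster = list(
      grid = c(6L, 6L), epochs = 200L, restarts = 10L, k = c(2L, 3L, 4L),
      rf_seeds = 10L, tsne_perplexity = 30, tsne_lr = 200, tsne_iters = 1000L
    ),
    io = list(write_sessions = FALSE)
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0L) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste0(path, extra, collapse = ", ")),
                 class = "pdmotor_validation_error")
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) next
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(cfg)
}

merge_config <- function(cfg) {
  ref <- default_run_config()
  check_config_keys(cfg, ref)
  utils::modifyList(ref, cfg)
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON file; keys must match [default_run_config()].
#' @return Merged, validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on a simulated cohort: session
#' simulation, 62-metric extraction, PCA dimensionality curves (UPDRS
#' items, motor metrics, combined), df-capped elastic-net grid search with
#' LOOCV, SOM + Ward phenotyping (with random-forest importance, the
#' dominance table, t-SNE + K-means, and the UPDRS subtype comparison),
#' and a reproducibility manifest. Partial outputs are preserved when a
#' stage fails.
#'
#' @param config Configuration list (see [default_run_config()]); unknown
#'   keys abort before any stage runs.
#' @param out_dir Output directory for the report bundle.
#' @param stages Character vector of stages to run, in pipeline order.
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("simulate", "extract", "pca", "predict",
                                    "cluster", "report")) {
  cfg <- merge_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)
  if ("simulate" %in% stages) {
    sim_cfg <- do.call(sim_config, c(cfg$simulator, list(seed = cfg$seed)))
    res$cohort <- simulate_cohort(sim_cfg)
    readr::write_csv(res$cohort$updrs, file.path(out_dir, "updrs.csv"),
                     progress = FALSE)
    readr::write_csv(res$cohort$truth, file.path(out_dir, "truth.csv"),
                     progress = FALSE)
    if (isTRUE(cfg$io$write_sessions)) {
      write_cohort(res$cohort, file.path(out_dir, "sessions"))
    }
  }
  if ("extract" %in% stages) {
    day1 <- Filter(function(s) s$visit_day == 1L, res$cohort$sessions)
    res$metrics <- extract_cohort(day1)
    write_metrics_csv(res$metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(metric_inventory(),
                     file.path(out_dir, "metric_dictionary.csv"),
                     progress = FALSE)
  }
  if ("pca" %in% stages) {
    updrs1 <- res$cohort$updrs[res$cohort$updrs$visit_day == 1L, ]
    z_updrs <- standardize_table(updrs1[updrs_items()])
    z_metrics <- standardize_table(
      impute_median(res$metrics[metric_names()])
    )
    res$pca <- list(
      updrs = pca_curve(z_updrs),
      metrics = pca_curve(z_metrics),
      combined = combined_pca(z_updrs, z_metrics)
    )
    curves <- dplyr::bind_rows(lapply(names(res$pca), function(nm) {
      dplyr::mutate(tidy(res$pca[[nm]]), set = nm)
    }))
    readr::write_csv(curves, file.path(out_dir, "pca_explained.csv"),
                     progress = FALSE)
  }
  if ("predict" %in% stages) {
    updrs1 <- res$cohort$updrs[res$cohort$updrs$visit_day == 1L, ]
    x <- impute_median(res$metrics[metric_names()])
    y <- updrs1$total
    res$prediction <- enet_grid_search(
      x, y,
      alpha_grid = cfg$predict$alpha_grid,
      n_lambda = cfg$predict$n_lambda,
      lambda_ratio = cfg$predict$lambda_ratio,
      df_cap_frac = cfg$predict$df_cap_frac
    )
    jsonlite::write_json(
      list(
        alpha = res$prediction$fit$alpha,
        lambda = res$prediction$fit$lambda,
        df = res$prediction$fit$df,
        mae = res$prediction$cv$mae,
        r2 = res$prediction$cv$r2,
        coefficients = as.list(res$prediction$fit$coefficients),
        per_subject_predictions = res$prediction$cv$predictions
      ),
      file.path(out_dir, "prediction.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if ("cluster" %in% stages) {
    z <- standardize_table(impute_median(res$metrics[metric_names()]))
    som <- train_som(z, grid = cfg$cluster$grid, epochs = cfg$cluster$epochs,
                     restarts = cfg$cluster$restarts, seed = cfg$seed)
    cuts <- ward_cut(som, k = cfg$cluster$k)
    labels3 <- cuts$assignments$cluster[cuts$assignments$k == 3L]
    imp <- rf_importance(z, labels3, n_seeds = cfg$cluster$rf_seeds,
                         seed = cfg$seed)
    dom <- dominance(z, labels3)
    tk <- tsne_kmeans(z, k = 3L, perplexity = cfg$cluster$tsne_perplexity,
                      lr = cfg$cluster$tsne_lr, iters = cfg$cluster$tsne_iters,
                      seed = cfg$seed)
    updrs1 <- res$cohort$updrs[res$cohort$updrs$visit_day == 1L, ]
    egg <- eggers_classify(updrs1)
    comp <- compare_partitions(labels3, egg$phenotype, x = z)
    res$clustering <- list(som = som, cuts = cuts, importance = imp,
                           dominance = dom, tsne = tk, eggers = egg,
                           comparison = comp)
    readr::write_csv(cuts$assignments, file.path(out_dir, "cluster_labels.csv"),
                     progress = FALSE)
    readr::write_csv(imp, file.path(out_dir, "rf_importance.csv"),
                     progress = FALSE)
    readr::write_csv(dom$counts, file.path(out_dir, "dominance.csv"),
                     progress = FALSE)
    readr::write_csv(
      tibble::tibble(merge = seq_along(cuts$tree$height),
                     height = cuts$tree$height),
      file.path(out_dir, "ward_linkage.csv"), progress = FALSE
    )
    jsonlite::write_json(
      list(ari = comp$ari,
           silhouette_som_ward = comp$silhouette_a,
           silhouette_updrs_subtypes = comp$silhouette_b),
      file.path(out_dir, "cluster_comparison.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if ("report" %in% stages) {
    jsonlite::write_json(
      list(
        config_hash = rlang::hash(cfg),
        seed = cfg$seed,
        package_version = as.character(utils::packageVersion("pdmotor")),
        stages = stages,
        generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      ),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE
    )
  }
  invisible(res)
}
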