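#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run with the field's
#' conventional defaults: DEG thresholds (linear fold change 1.5, FDR
#' 0.05), diffusion settings (alpha 0.5, L1 tolerance 1e-6), stratified
#' 5-fold CV with 11 repeats for the median AUC, a 100-permutation
#' baseline, and top-100 prediction sets for disease comparison. All
#' randomness flows from the single `seed`; per-stage seeds are derived
#' from it by fixed offsets.
#'
#' @param out_dir Output directory for the run.
#' @param network,expression,groups,signature,labels Input file paths
#'   (TSV). Either `expression` + `groups` or a precomputed `signature`
#'   must be given, unless `simulate = TRUE`.
#' @param simulate If `TRUE`, inputs are generated by [simulate_disease()]
#'   with `scenario`.
#' @param scenario A [synthetic_scenario()] used when `simulate = TRUE`.
#' @param fc_threshold,fdr_threshold DEG thresholds.
#' @param alpha,tol,max_iter Diffusion settings.
#' @param k,repeats CV folds and repetitions.
#' @param n_perm Label permutations for the baseline (0 skips it).
#' @param n_boot Bootstrap resamples for penalty tuning.
#' @param top_k Top-rank cut for prediction gene sets.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            network = NULL, expression = NULL, groups = NULL,
                            signature = NULL, labels = NULL,
                            simulate = FALSE,
                            scenario = synthetic_scenario(seed = seed),
                            fc_threshold = 1.5, fdr_threshold = 0.05,
                            alpha = 0.5, tol = 1e-6, max_iter = 10000L,
                            k = 5L, repeats = 11L, n_perm = 100L,
                            n_boot = 25L, top_k = 100L, seed = 1L) {
  structure(
    list(out_dir = out_dir, network = network, expression = expression,
         groups = groups, signature = signature, labels = labels,
         simulate = simulate, scenario = scenario,
         fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
         alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
         k = as.integer(k), repeats = as.integer(repeats),
         n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
         top_k = as.integer(top_k), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full prioritization pipeline
#'
#' Executes signature calling, the four network scorings, the
#' cross-validated consensus, ROC/AUC evaluation and (optionally) the
#' label-permutation baseline, writing every intermediate table as TSV plus
#' a machine-readable `summary.json` and the exact configuration as
#' `config.yaml` into `config$out_dir`. Re-running with an identical
#' configuration and seed reproduces the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`signature`,
#'   `scores`, `cv`, `importance`, `baseline`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      sim <- simulate_disease(config$scenario)
      list(net = sim$network, expression = sim$expression,
           groups = sim$groups, signature = NULL, labels = sim$labels)
    } else {
      if (is.null(config$network)) abort("missing network file")
      if (is.null(config$labels)) abort("missing labels file")
      if (!file.exists(config$labels)) {
        abort(sprintf("labels file '%s' does not exist", config$labels))
      }
      list(
        net = read_network(config$network),
        expression = if (!is.null(config$expression))
          read_tsv_plain(config$expression),
        groups = if (!is.null(config$groups))
          read_tsv_plain(config$groups),
        signature = if (!is.null(config$signature))
          read_signature(config$signature),
        labels = read_tsv_plain(config$labels)
      )
    }
  })

  sig <- stage("signature", {
    if (!is.null(inputs$signature)) inputs$signature
    else if (!is.null(inputs$expression)) {
      differential_expression(inputs$expression, inputs$groups,
                              fc_threshold = config$fc_threshold,
                              fdr_threshold = config$fdr_threshold)
    } else abort("need either an expression matrix + groups or a signature")
  })

  signal <- stage("signature", {
    map_signature_to_network(sig, inputs$net,
                             fc_threshold = config$fc_threshold,
                             fdr_threshold = config$fdr_threshold,
                             quiet = TRUE)
  })

  scores <- stage("scoring", {
    score_nodes(inputs$net, signal, alpha = config$alpha, tol = config$tol,
                max_iter = config$max_iter)
  })

  fm <- stage("consensus", assemble_features(scores, inputs$labels))
  cv <- stage("consensus", {
    cross_validated_predict(fm, k = config$k, seed = config$seed,
                            n_boot = config$n_boot)
  })
  imp <- feature_importance(cv)

  med <- stage("evaluation", {
    if (config$repeats > 1L) {
      repeated_cv_auc(fm, k = config$k, repeats = config$repeats,
                      seed = config$seed + 101L, n_boot = config$n_boot)
    } else list(aucs = cv$auc$auc, median_auc = cv$auc$auc)
  })

  baseline <- NULL
  if (config$n_perm > 0L) {
    baseline <- stage("permutation", {
      permutation_baseline(fm, k = config$k, n_perm = config$n_perm,
                           seed = config$seed + 202L,
                           n_boot = config$n_boot)
    })
  }

  summary <- list(
    n_nodes = length(inputs$net$nodes),
    n_edges = nrow(inputs$net$edges),
    n_deg = sum(signal$is_deg),
    n_targets = sum(fm$label),
    auc = cv$auc$auc,
    median_auc = med$median_auc,
    baseline_median_auc = if (!is.null(baseline)) baseline$median_auc,
    importance = setNames(as.list(imp$importance), imp$method),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("netprior"))
  )

  stage("output", {
    write_signature(sig, file.path(config$out_dir, "signature.tsv"))
    write_tsv_plain(scores, file.path(config$out_dir, "scores.tsv"))
    write_tsv_plain(cv$predictions,
                    file.path(config$out_dir, "predictions.tsv"))
    write_tsv_plain(imp, file.path(config$out_dir, "importance.tsv"))
    if (!is.null(baseline)) {
      write_tsv_plain(tibble(permutation = seq_along(baseline$aucs),
                             auc = baseline$aucs),
                      file.path(config$out_dir, "permutation_aucs.tsv"))
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(summary,
                           file.path(config$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (requireNamespace("yaml", quietly = TRUE)) {
      cfg <- config
      cfg$scenario <- unclass(cfg$scenario)
      yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
    }
  })

  invisible(list(signature = sig, signal = signal, scores = scores,
                 features = fm, cv = cv, importance = imp,
                 median_auc = med, baseline = baseline, summary = summary))
}
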