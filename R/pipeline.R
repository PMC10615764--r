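# End-to-end orchestration: simulate -> connectome -> classify -> attribute
# -> univariate stats -> report, from one configuration with a master seed
# fanned out per stage by name (adding a stage never shifts another stage's
# random stream).

#' Pipeline run configuration
#'
#' Bundles one or two cohort generator configs, the contrasts and model
#' families to run, and the experiment budgets.
#'
#' @param cohorts Named list of one or two [cohort_config()]s.
#' @param contrasts Character vector of contrast names (see
#'   [contrast_spec()]).
#' @param models Named list of [model_spec()]s (or character vector of
#'   families, which get default specs).
#' @param folds CV folds (default 5).
#' @param n_perms Permutations for SVM families (default 0 = skip);
#'   `n_perms_gcn` for GCN families.
#' @param ablation_repeats Repeats for the ablation study (0 = skip).
#' @param ablation_regions Regions to ablate (`NULL` = all).
#' @param explain Run the edge-mask explainer after GCN experiments?
#' @param univariate Run the mass-univariate stage?
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
run_config <- function(cohorts, contrasts = "mdd_vs_hc",
                       models = "svm_linear", folds = 5L, n_perms = 0L,
                       n_perms_gcn = n_perms, ablation_repeats = 0L,
                       ablation_regions = NULL, explain = FALSE,
                       univariate = TRUE, seed = 1L) {
  if (inherits(cohorts, "cohort_config")) cohorts <- list(cohort1 = cohorts)
  stopifnot(length(cohorts) %in% 1:2,
            all(vapply(cohorts, inherits, logical(1), "cohort_config")))
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  if (is.character(models)) {
    models <- stats::setNames(lapply(models, model_spec), models)
  }
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "family")
  }
  structure(list(cohorts = cohorts, contrasts = contrasts, models = models,
                 folds = as.integer(folds), n_perms = as.integer(n_perms),
                 n_perms_gcn = as.integer(n_perms_gcn),
                 ablation_repeats = as.integer(ablation_repeats),
                 ablation_regions = ablation_regions, explain = explain,
                 univariate = univariate, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys `cohorts` (list of
#'   [cohort_config()] argument lists), and optionally `contrasts`, `models`
#'   (list of family names or `model_spec` argument lists), `folds`,
#'   `n_perms`, `n_perms_gcn`, `ablation_repeats`, `explain`, `univariate`,
#'   `seed`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$cohorts))
  cohorts <- lapply(y$cohorts, function(args) {
    if (!is.null(args$planted_effects)) {
      args$planted_effects <- as.data.frame(args$planted_effects)
    }
    do.call(cohort_config, args)
  })
  models <- y$models %||% "svm_linear"
  if (is.list(models)) {
    models <- lapply(models, function(m) {
      if (is.character(m)) model_spec(m) else do.call(model_spec, m)
    })
  }
  run_config(cohorts = cohorts, contrasts = y$contrasts %||% "mdd_vs_hc",
             models = models, folds = y$folds %||% 5L,
             n_perms = y$n_perms %||% 0L,
             n_perms_gcn = y$n_perms_gcn %||% (y$n_perms %||% 0L),
             ablation_repeats = y$ablation_repeats %||% 0L,
             ablation_regions = y$ablation_regions,
             explain = isTRUE(y$explain),
             univariate = !isFALSE(y$univariate), seed = y$seed %||% 1L)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation, classification experiments (every
#' contrast x model x cohort, with optional permutation tests),
#' cross-dataset transfer (two cohorts), the edge-mask explainer and
#' region-ablation study (GCN models), the mass-univariate stage, and
#' cross-cohort consensus. Writes a machine-readable `results.json`, TSV
#' tables and a plain-text summary into `out_dir`; every stage's seed is
#' derived from the master seed by stage name. Rerunning with the same
#' config is metric-identical for the deterministic stages.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @param out_dir Output directory.
#' @param verbose Log per-stage progress messages?
#' @return A list with all stage results (classification tibble, attribution
#'   and univariate objects, consensus tables), invisibly; the same content
#'   is on disk.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  summary_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    summary_lines <<- c(summary_lines, line)
    pipeline_log(verbose, "%s", line)
  }

  # -- simulate ---------------------------------------------------------
  cohorts <- lapply(names(config$cohorts), function(nm) {
    cfg <- config$cohorts[[nm]]
    cfg$seed <- child_seed(seed, paste0("simulate_", nm))
    co <- generate_cohort(cfg)
    write_tsv_plain(co$manifest, file.path(out_dir, paste0("manifest_", nm, ".tsv")))
    note("simulate %s: %d subjects, %d regions, seed %d",
         nm, nrow(co$manifest), length(co$region_labels), cfg$seed)
    co
  })
  names(cohorts) <- names(config$cohorts)

  # -- classify ---------------------------------------------------------
  class_rows <- list()
  gcn_fits <- list()
  for (nm in names(cohorts)) {
    for (ct in config$contrasts) {
      for (mn in names(config$models)) {
        spec <- config$models[[mn]]
        es <- child_seed(seed, paste("classify", nm, ct, mn))
        n_perms <- if (is_gcn_family(spec$family)) config$n_perms_gcn
                   else config$n_perms
        res <- if (n_perms > 0) {
          permutation_test(cohorts[[nm]], ct, spec, n_perms = n_perms,
                           k = config$folds, seed = es)
        } else {
          run_cv_experiment(cohorts[[nm]], ct, spec, k = config$folds,
                            seed = es)
        }
        note("classify %s/%s/%s: balanced accuracy %.3f (sd %.3f)%s",
             nm, ct, mn, res$mean_balanced_accuracy, res$sd_balanced_accuracy,
             if (n_perms > 0) sprintf(", p = %.4g", res$p_value) else "")
        class_rows[[paste(nm, ct, mn)]] <- dplyr::bind_cols(
          tibble::tibble(cohort = nm, contrast = ct, model = mn, seed = es),
          generics::glance(res))
      }
    }
  }
  classification <- dplyr::bind_rows(class_rows)
  write_tsv_plain(
    dplyr::select(classification, -dplyr::any_of("hyper")),
    file.path(out_dir, "classification.tsv"))

  # -- cross-dataset ----------------------------------------------------
  transfer <- NULL
  if (length(cohorts) == 2) {
    dirs <- list(c(1, 2), c(2, 1))
    transfer <- dplyr::bind_rows(lapply(dirs, function(dd) {
      dplyr::bind_rows(lapply(names(config$models), function(mn) {
        xs <- child_seed(seed, paste("transfer", dd[1], mn))
        met <- cross_dataset_eval(cohorts[[dd[1]]], cohorts[[dd[2]]],
                                  config$models[[mn]], seed = xs)
        note("transfer %s->%s/%s: balanced accuracy %.3f",
             names(cohorts)[dd[1]], names(cohorts)[dd[2]], mn,
             met$balanced_accuracy)
        dplyr::bind_cols(tibble::tibble(train = names(cohorts)[dd[1]],
                                        test = names(cohorts)[dd[2]],
                                        model = mn), met)
      }))
    }))
    write_tsv_plain(transfer, file.path(out_dir, "transfer.tsv"))
  }

  # -- attribute --------------------------------------------------------
  ablations <- list(); explanations <- list()
  gcn_models <- names(config$models)[vapply(config$models, function(s)
    is_gcn_family(s$family), logical(1))]
  if (length(gcn_models) && (config$ablation_repeats > 0 || config$explain)) {
    mn <- gcn_models[[1]]
    for (nm in names(cohorts)) {
      if (config$ablation_repeats > 0) {
        as_ <- child_seed(seed, paste("ablate", nm))
        ab <- ablate_region(cohorts[[nm]], config$contrasts[[1]],
                            config$models[[mn]],
                            regions = config$ablation_regions,
                            n_repeats = config$ablation_repeats, seed = as_)
        ablations[[nm]] <- ab
        write_tsv_plain(ab$regions,
                        file.path(out_dir, paste0("ablation_", nm, ".tsv")))
        note("ablate %s: top region %s (mean drop %.2f pp)", nm,
             ab$regions$label[which.max(ab$regions$mean_drop)],
             max(ab$regions$mean_drop))
      }
      if (config$explain) {
        es <- child_seed(seed, paste("explain", nm))
        sub <- subsample_balanced(cohorts[[nm]], config$contrasts[[1]],
                                  child_seed(es, "sub"))
        y <- contrast_labels(config$contrasts[[1]], sub$manifest)
        graphs <- cohort_graphs(sub, config$models[[mn]]$sparsity)
        folds <- make_folds(y, sub$manifest$site, k = 5,
                            seed = child_seed(es, "split"))
        tr_ex <- which(folds != 1)
        te_ex <- which(folds == 1)
        spec <- config$models[[mn]]
        hyper <- spec$grid[1, , drop = FALSE]
        model <- gcn_train(graphs[tr_ex], y[tr_ex],
                           hidden = hyper$hidden %||% spec$hidden,
                           n_layers = hyper$n_layers %||% spec$n_layers,
                           epochs = spec$epochs, lr = spec$lr,
                           decay_every = spec$decay_every,
                           decay_factor = spec$decay_factor,
                           dropout = spec$dropout,
                           batch_size = spec$batch_size,
                           seed = child_seed(es, "fit"))
        ex <- explain_gcn(model, graphs[te_ex], y[te_ex],
                          seed = child_seed(es, "mask"))
        explanations[[nm]] <- ex
        write_tsv_plain(ex$top_edges,
                        file.path(out_dir, paste0("explainer_edges_", nm, ".tsv")))
        write_fc_matrix(ex$mask,
                        file.path(out_dir, paste0("explainer_mask_", nm, ".tsv")))
        note("explain %s: top edge %s | %s (weight %.3f)", nm,
             ex$top_edges$region_i[1], ex$top_edges$region_j[1],
             ex$top_edges$weight[1])
      }
    }
  }

  # -- univariate stats -------------------------------------------------
  univariate <- list()
  if (config$univariate) {
    for (nm in names(cohorts)) {
      uv <- univariate_connections(cohorts[[nm]], config$contrasts[[1]])
      univariate[[nm]] <- uv
      write_tsv_plain(uv$table, file.path(out_dir, paste0("univariate_", nm, ".tsv")))
      write_tsv_plain(uv$degrees, file.path(out_dir, paste0("degrees_", nm, ".tsv")))
      note("univariate %s: %d significant connections at FDR %.2g",
           nm, sum(uv$table$significant), uv$q)
    }
  }

  # -- consensus --------------------------------------------------------
  consensus <- list()
  if (length(ablations) == 2) {
    consensus$ablation <- rank_consensus(ablations[[1]], ablations[[2]])
    write_tsv_plain(consensus$ablation, file.path(out_dir, "consensus_regions.tsv"))
  }
  if (length(explanations) == 2) {
    consensus$edges <- rank_consensus(explanations[[1]], explanations[[2]])
    write_tsv_plain(consensus$edges, file.path(out_dir, "consensus_edges.tsv"))
  }

  results <- list(
    seed = seed,
    classification = classification,
    transfer = transfer,
    ablation = lapply(ablations, function(a) a$regions),
    explainer_top_edges = lapply(explanations, function(e) e$top_edges),
    univariate_significant = lapply(univariate, function(u)
      sum(u$table$significant)),
    consensus = lapply(consensus, as.data.frame))
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(cohorts = cohorts, classification = classification,
                 transfer = transfer, ablations = ablations,
                 explanations = explanations, univariate = univariate,
                 consensus = consensus))
}
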