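#' Select IPTs and build the modified annotation matrix for a cohort
#'
#' Convenience wrapper running annotation propagation, cohort-wide term
#' counting, informative-term selection and nested-IPT deduplication, and
#' attaching the resulting matrix to the cohort. Term frequencies use all
#' individuals irrespective of diagnosis, so this is computed once, outside
#' any cross-validation.
#'
#' @param ont A [ontology()] object.
#' @param x A [cohort()] object.
#' @param lower_frac,upper_frac Frequency bounds (fractions of the cohort).
#' @return List with `cohort` (IPT matrix attached), `ipts`, `counts`
#'   (propagated term counts), `propagated` (the propagated matrix).
#' @export
prepare_ipt_features <- function(ont, x, lower_frac = 0.02,
                                 upper_frac = 0.10) {
  stopifnot(inherits(ont, "phen_ontology"), inherits(x, "phen_cohort"))
  prop <- propagate(ont, x$annotations)
  counts <- term_counts(prop)
  cfg <- ipt_config(cohort_size(x), lower_frac = lower_frac,
                    upper_frac = upper_frac)
  ipts <- select_ipts(ont, counts, cfg)
  m <- dedup_ipt_annotations(ont, x$annotations, ipts)
  list(cohort = set_ipt_matrix(x, m), ipts = ipts, counts = counts,
       propagated = prop)
}

#' Default pipeline configuration
#'
#' All tunables of [run_pipeline()] with their defaults. Supply overrides as
#' a (possibly nested) list or a YAML file with the same structure.
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    scenario = NULL,                 # name from scenario_library(), or NULL
    input = list(obo = NULL, phenotypes = NULL, annotations = NULL,
                 diagnoses = NULL, root = NULL),
    ipt = list(lower_frac = 0.02, upper_frac = 0.10),
    filter = list(min_cases_per_gene = 10, require_single_diagnosis = TRUE,
                  min_quant_fields = 5),
    model = list(pseudocount = 0.5, adjust = 2),
    optimizer = list(n_eval = 2000, loocv_weights = "pooled"),
    evaluate = list(loocv = TRUE, bootstrap_B = 100),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full pipeline
#'
#' End to end: obtain a cohort (either a named scenario from
#' [scenario_library()] or ontology + cohort TSV files), select informative
#' terms, apply inclusion filters, fit per-gene models, compute the
#' likelihood table, optimize combination weights, evaluate (training and
#' optionally leave-one-out cross-validation plus the .632 bootstrap of
#' recall), and write all artifacts plus a manifest (seed, config hash,
#' input checksums, package version) to `out_dir`. Reruns with the same
#' config and seed reproduce deterministic outputs byte for byte.
#'
#' @param config A YAML file path or a list of overrides to
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory results: `cohort`, `ipts`,
#'   `models`, `likelihoods`, `weights`, `metrics`, `bootstrap`,
#'   `generalization`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  seed <- as.integer(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_checksums <- character(0)
  if (!is.null(cfg$scenario)) {
    lib <- scenario_library(seed = seed)
    if (!cfg$scenario %in% names(lib)) {
      stop("pipeline stage [input]: unknown scenario '", cfg$scenario, "'")
    }
    built <- build_scenario(lib[[cfg$scenario]])
    ont <- built$ontology
    coh <- built$cohort
  } else {
    paths <- cfg$input
    needed <- c("obo", "phenotypes", "annotations", "diagnoses")
    if (any(vapply(paths[needed], is.null, logical(1)))) {
      stop("pipeline stage [input]: need either `scenario` or all of ",
           paste(needed, collapse = ", "))
    }
    ont <- load_obo(paths$obo, root = paths$root)
    coh <- load_cohort(paths$phenotypes, paths$annotations,
                       paths$diagnoses, ont)
    input_checksums <- tools::md5sum(unlist(paths[needed]))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  prep <- stage("select-ipts", prepare_ipt_features(
    ont, coh, lower_frac = cfg$ipt$lower_frac,
    upper_frac = cfg$ipt$upper_frac))
  coh <- prep$cohort
  write_ipts(prep$ipts, file.path(out_dir, "ipts.tsv"))
  ipt_df <- data.frame(individual_id = rownames(coh$ipt_matrix),
                       coh$ipt_matrix + 0L, check.names = FALSE)
  write_tsv(ipt_df, file.path(out_dir, "ipt_matrix.tsv"))

  filt <- stage("filter", filter_cohort(
    coh, min_cases_per_gene = cfg$filter$min_cases_per_gene,
    require_single_diagnosis = cfg$filter$require_single_diagnosis,
    min_quant_fields = cfg$filter$min_quant_fields))
  coh <- filt$cohort
  write_tsv(filt$exclusions, file.path(out_dir, "exclusions.tsv"))
  genes <- filt$modeled_genes
  if (length(genes) == 0L) {
    stop("pipeline stage [filter]: no gene has enough diagnosed individuals")
  }

  models <- stage("train", lapply(stats::setNames(genes, genes), function(g)
    suppressWarnings(fit_gene_model(
      coh, g, pseudocount = cfg$model$pseudocount,
      adjust = cfg$model$adjust,
      min_cases = cfg$filter$min_cases_per_gene))))
  write_models_json(models, file.path(out_dir, "models.json"))

  lik <- stage("predict", likelihood_table(models, coh))
  write_tsv(lik, file.path(out_dir, "likelihoods.tsv"))

  evals <- stage("evaluate", lapply(stats::setNames(genes, genes),
                                    function(g) {
    evaluate_gene(coh, g, seed = seed, n_eval = cfg$optimizer$n_eval,
                  pseudocount = cfg$model$pseudocount,
                  adjust = cfg$model$adjust,
                  min_cases = cfg$filter$min_cases_per_gene,
                  modes = if (isTRUE(cfg$evaluate$loocv))
                    c("train", "loocv") else "train",
                  loocv_weights = cfg$optimizer$loocv_weights)
  }))
  metrics <- do.call(rbind, lapply(evals, function(e) e$metrics))
  rownames(metrics) <- NULL
  write_tsv(metrics, file.path(out_dir, "metrics.tsv"))
  wdf <- do.call(rbind, lapply(genes, function(g) {
    w <- evals[[g]]$weights
    data.frame(gene = g, w0 = w[1L], w1 = w[2L], w2 = w[3L], w3 = w[4L],
               w4 = w[5L],
               f1_train = metrics$f1[metrics$gene == g &
                                       metrics$mode == "train" &
                                       metrics$source == "combined"],
               stringsAsFactors = FALSE)
  }))
  write_tsv(wdf, file.path(out_dir, "weights.tsv"))

  boot <- NULL
  if (!is.null(cfg$evaluate$bootstrap_B) && cfg$evaluate$bootstrap_B >= 1) {
    boot <- do.call(rbind, lapply(genes, function(g) {
      b <- bootstrap632_recall(coh, g, B = cfg$evaluate$bootstrap_B,
                               seed = seed,
                               pseudocount = cfg$model$pseudocount,
                               adjust = cfg$model$adjust,
                               min_cases = cfg$filter$min_cases_per_gene)
      data.frame(gene = g, recall_632 = b$estimate, apparent = b$apparent,
                 oob = b$oob, B = b$B, stringsAsFactors = FALSE)
    }))
    write_tsv(boot, file.path(out_dir, "bootstrap_recall.tsv"))
  }

  gen <- do.call(rbind, lapply(genes, function(g) {
    lr_g <- evals[[g]]$lr_train
    lr_g <- lr_g[lr_g$label, , drop = FALSE]
    if (nrow(lr_g) < 4L) return(NULL)
    q <- quartile_generalization(lr_g, evals[[g]]$weights)
    do.call(rbind, lapply(rownames(q$quartiles), function(src) {
      data.frame(gene = g, source = src, q1 = q$quartiles[src, "q1"],
                 q2 = q$quartiles[src, "q2"], q3 = q$quartiles[src, "q3"],
                 generalizes = unname(q$generalizes[src]),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(gen)) write_tsv(gen, file.path(out_dir, "generalization.tsv"))

  summ <- if (length(genes) >= 3L) {
    cohort_summary(metrics[metrics$mode == "train", ])
  } else NULL

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    package = "phenolr",
    version = as.character(utils::packageVersion("phenolr")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = as.list(input_checksums),
    n_individuals = cohort_size(coh),
    modeled_genes = genes,
    n_ipts = nrow(prep$ipts),
    output_md5 = {
      fs <- list.files(out_dir, pattern = "\\.(tsv|json|yaml)$",
                       full.names = TRUE)
      as.list(stats::setNames(unname(tools::md5sum(fs)), basename(fs)))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = coh, ipts = prep$ipts, models = models,
                 likelihoods = lik, weights = wdf, metrics = metrics,
                 bootstrap = boot, generalization = gen, summary = summ,
                 manifest = manifest))
}
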