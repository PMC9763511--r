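#' Confusion counts, precision, recall and F1
#'
#' Standard definitions. When there are no positive calls, precision is
#' undefined; it is recorded as 0 with `precision_undefined = TRUE` and F1 is
#' 0 (the convention used throughout weight optimization: evidence that never
#' outweighs the prior scores an F1 of 0).
#'
#' @param calls Logical classification calls.
#' @param labels Logical ground-truth labels (at least one positive).
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`,
#'   `precision_undefined`.
#' @export
confusion_and_f1 <- function(calls, labels) {
  if (length(calls) != length(labels)) stop("calls/labels length mismatch")
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  if (!any(labels)) stop("need at least one positive label")
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  fn <- sum(!calls & labels)
  tn <- sum(!calls & !labels)
  undef <- (tp + fp) == 0L
  precision <- if (undef) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (tp == 0L) 0 else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
       recall = recall, f1 = f1, precision_undefined = undef)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative, with ties contributing 1/2. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric scores (higher means more case-like).
#' @param labels Logical labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Leave-one-out cross-validated likelihoods
#'
#' For each individual in turn, refits the gene model on the cohort without
#' them (same pseudocount and bandwidth settings; the IPT feature set is
#' fixed, having been selected from annotation frequencies that use no
#' diagnosis labels) and scores the held-out individual. Folds in which a
#' feature drops below 2 non-missing case values skip that feature, as at fit
#' time.
#'
#' @param x A [cohort()] object with IPT matrix.
#' @param gene Gene symbol with at least `min_cases` diagnosed individuals.
#' @param pseudocount,adjust As [fit_gene_model()].
#' @param min_cases Case-count requirement checked on the full cohort;
#'   individual folds may dip below it by one.
#' @return Data frame shaped like [likelihood_table()] rows, one per
#'   individual, each computed with that individual held out.
#' @export
loocv <- function(x, gene, pseudocount = 0.5, adjust = 2, min_cases = 10) {
  stopifnot(inherits(x, "phen_cohort"))
  ph <- x$phenotypes
  n <- nrow(ph)
  n_cases <- sum(!is.na(ph$diagnosis) & ph$diagnosis == gene)
  if (n_cases < min_cases) {
    stop("gene ", gene, " has ", n_cases, " cases; ", min_cases, " required")
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- subset_cohort(x, setdiff(seq_len(n), i))
    model <- suppressWarnings(
      fit_gene_model(train, gene, pseudocount = pseudocount,
                     adjust = adjust, min_cases = 2))
    rows[[i]] <- gene_loglrs(model, subset_cohort(x, i))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' .632 bootstrap estimate of recall
#'
#' `0.368 * apparent recall + 0.632 * mean out-of-bag recall` over `B`
#' bootstrap resamples of the cohort. Because the gene class is a small
#' minority, only recall of the class of interest is estimated this way.
#' Calls are the plain naive Bayes classification (combined score with
#' `w0 = log prior odds` of the fitted cohort and unit weights) unless a
#' weight vector is supplied. Resamples lacking 2 cases in-bag or any
#' out-of-bag case are redrawn (counted, not silently ignored).
#'
#' @param x A [cohort()] object with IPT matrix.
#' @param gene Gene symbol.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param weights Optional fixed weight vector `w0..w4`; by default the naive
#'   Bayes weights of each fitted model are used.
#' @param pseudocount,adjust,min_cases As [fit_gene_model()].
#' @return List with `estimate`, `apparent`, `oob` (mean out-of-bag recall),
#'   `B`, `redraws`.
#' @export
bootstrap632_recall <- function(x, gene, B = 100, seed = 1L, weights = NULL,
                                pseudocount = 0.5, adjust = 2,
                                min_cases = 10) {
  stopifnot(B >= 1)
  ph <- x$phenotypes
  n <- nrow(ph)
  is_case <- !is.na(ph$diagnosis) & ph$diagnosis == gene
  if (sum(is_case) < min_cases) {
    stop("gene ", gene, " has ", sum(is_case), " cases; ", min_cases,
         " required")
  }
  nb_scores <- function(model, cohort_part) {
    lr <- gene_loglrs(model, cohort_part)
    w <- weights %||% c(log(model$prior / (1 - model$prior)), 1, 1, 1, 1)
    combine_scores(w, lr)
  }
  full_model <- suppressWarnings(
    fit_gene_model(x, gene, pseudocount = pseudocount, adjust = adjust,
                   min_cases = min_cases))
  app_calls <- nb_scores(full_model, x) > 0
  apparent <- sum(app_calls & is_case) / sum(is_case)

  oob_recalls <- numeric(B)
  redraws <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (sum(is_case[idx]) >= 2L && sum(is_case[idx]) < length(idx) &&
            any(is_case[oob])) break
        redraws <- redraws + 1L
      }
      train <- subset_cohort(x, idx)
      model <- suppressWarnings(
        fit_gene_model(train, gene, pseudocount = pseudocount,
                       adjust = adjust, min_cases = 2))
      test <- subset_cohort(x, oob)
      calls <- nb_scores(model, test) > 0
      case_oob <- is_case[oob]
      oob_recalls[b] <- sum(calls & case_oob) / sum(case_oob)
    }
  })
  oob <- mean(oob_recalls)
  list(estimate = 0.368 * apparent + 0.632 * oob, apparent = apparent,
       oob = oob, B = B, redraws = redraws)
}

#' Quartile-based model generalization report
#'
#' Orders a gene's diagnosed individuals by their total combined likelihood
#' and reports, for each data type, the weight-scaled log likelihood ratio of
#' the individuals at quartiles 1, 2 (median) and 3 — poor, typical and good
#' fits to the gene model. A data type is said to generalize when the median
#' individual's scaled value is positive: the model then agrees with the
#' assigned diagnosis for a typical case, not just the best-fitting ones.
#'
#' @param lr_gene Likelihood table rows for one gene restricted to its
#'   diagnosed individuals (>= 4 rows).
#' @param weights Named weight vector `w0..w4` (e.g. from
#'   [optimize_weights()]).
#' @return List of class `phen_generalization`: `gene`, `quartiles` (matrix,
#'   data types x q1/q2/q3 of scaled values), `totals` (combined scores at
#'   the quartile individuals), `individuals` (their IDs), `generalizes`
#'   (named logical per data type).
#' @export
quartile_generalization <- function(lr_gene, weights) {
  lr_gene <- as.data.frame(lr_gene)
  n <- nrow(lr_gene)
  if (n < 4L) stop("need at least 4 diagnosed individuals")
  stopifnot(length(weights) == 5L)
  w <- as.numeric(weights)
  total <- combine_scores(w, lr_gene)
  ord <- order(total)
  qidx <- ord[ceiling(c(0.25, 0.5, 0.75) * n)]
  scaled <- rbind(sex = w[2L] * lr_gene$loglr_sex[qidx],
                  growth = w[3L] * lr_gene$loglr_growth[qidx],
                  development = w[4L] * lr_gene$loglr_dev[qidx],
                  hpo = w[5L] * lr_gene$loglr_hpo[qidx])
  colnames(scaled) <- c("q1", "q2", "q3")
  structure(list(gene = lr_gene$gene[1L], quartiles = scaled,
                 totals = stats::setNames(total[qidx], c("q1", "q2", "q3")),
                 individuals = lr_gene$individual_id[qidx],
                 generalizes = scaled[, "q2"] > 0),
            class = "phen_generalization")
}

#' Train and cross-validated metrics for one gene
#'
#' The full per-gene evaluation: fits the model, computes the likelihood
#' table, derives metrics for each single data type (naive Bayes calls:
#' prior log odds plus that type's log likelihood ratio), the combined
#' optimized model, and the HPO-only optimized ablation. Single-data-type
#' optimized solutions seed the combined optimization, so the combined F1 is
#' never below any single-source optimized F1 on the same training data. In
#' `loocv` mode the same metrics are computed from held-out likelihoods;
#' combined weights are then either re-optimized on the pooled held-out
#' table (`loocv_weights = "pooled"`) or reused from training
#' (`loocv_weights = "train"`).
#'
#' @param x A [cohort()] object with IPT matrix.
#' @param gene Gene symbol.
#' @param seed Integer seed for all optimizations.
#' @param n_eval Annealing budget per optimization.
#' @param pseudocount,adjust,min_cases As [fit_gene_model()].
#' @param modes Subset of `c("train", "loocv")`.
#' @param loocv_weights `"pooled"` or `"train"` (see Details).
#' @return List with `metrics` (data frame: one row per mode x source),
#'   `weights` (combined), `weights_hpo_only`, `lr_train`, and `lr_loocv`
#'   when requested.
#' @export
evaluate_gene <- function(x, gene, seed = 1L, n_eval = 2000,
                          pseudocount = 0.5, adjust = 2, min_cases = 10,
                          modes = c("train", "loocv"),
                          loocv_weights = c("pooled", "train")) {
  modes <- match.arg(modes, several.ok = TRUE)
  loocv_weights <- match.arg(loocv_weights)
  model <- suppressWarnings(
    fit_gene_model(x, gene, pseudocount = pseudocount, adjust = adjust,
                   min_cases = min_cases))
  lr_train <- gene_loglrs(model, x)
  labels <- lr_train$label
  n_cases <- sum(labels)
  w0_nb <- log(mean(labels) / (1 - mean(labels)))
  sources <- c(sex = "loglr_sex", growth = "loglr_growth",
               dev = "loglr_dev", hpo = "loglr_hpo")

  single_opts <- lapply(names(sources), function(s) {
    optimize_weights(lr_train, labels, active = s, seed = seed,
                     n_eval = n_eval)
  })
  names(single_opts) <- names(sources)
  opt <- optimize_weights(lr_train, labels, seed = seed, n_eval = n_eval,
                          extra_starts = lapply(single_opts,
                                                function(o) o$weights))
  opt_hpo <- optimize_hpo_only(lr_train, labels, seed = seed,
                               n_eval = n_eval)

  metric_row <- function(mode, source, scores, lab) {
    cm <- confusion_and_f1(scores > 0, lab)
    data.frame(gene = gene, mode = mode, source = source, tp = cm$tp,
               fp = cm$fp, fn = cm$fn, tn = cm$tn,
               precision = cm$precision, recall = cm$recall, f1 = cm$f1,
               precision_undefined = cm$precision_undefined,
               auc = roc_auc(scores, lab), n_cases = n_cases,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  table_metrics <- function(mode, lr, lab, comb_w, hpo_w) {
    out <- list()
    for (s in names(sources)) {
      out[[s]] <- metric_row(mode, s, w0_nb + lr[[sources[[s]]]], lab)
    }
    out$combined <- metric_row(mode, "combined",
                               combine_scores(comb_w, lr), lab)
    out$hpo_only <- metric_row(mode, "hpo_only_optimized",
                               combine_scores(hpo_w, lr), lab)
    out
  }
  if ("train" %in% modes) {
    rows <- c(rows, table_metrics("train", lr_train, labels,
                                  opt$weights, opt_hpo$weights))
  }
  lr_cv <- NULL
  if ("loocv" %in% modes) {
    lr_cv <- loocv(x, gene, pseudocount = pseudocount, adjust = adjust,
                   min_cases = min_cases)
    if (loocv_weights == "pooled") {
      cv_opt <- optimize_weights(lr_cv, lr_cv$label, seed = seed,
                                 n_eval = n_eval)
      cv_hpo <- optimize_hpo_only(lr_cv, lr_cv$label, seed = seed,
                                  n_eval = n_eval)
      cw <- cv_opt$weights
      hw <- cv_hpo$weights
    } else {
      cw <- opt$weights
      hw <- opt_hpo$weights
    }
    rows <- c(rows, table_metrics("loocv", lr_cv, lr_cv$label, cw, hw))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, weights = opt$weights,
       weights_hpo_only = opt_hpo$weights,
       single_source = single_opts,
       lr_train = lr_train, lr_loocv = lr_cv)
}

#' Cohort-level summary of per-gene metrics
#'
#' Per-source medians of precision, recall and F1; the Pearson correlation of
#' F1 with the number of diagnosed individuals per gene (two-sided p-value
#' from the t approximation; reported as `NA` with a note when F1 has zero
#' variance); and the count of genes with at least a satisfactory AUC
#' (>= 0.6).
#'
#' @param metrics Data frame of [evaluate_gene()] metric rows across >= 3
#'   genes (any single mode).
#' @param auc_threshold Satisfactory-AUC cutoff.
#' @return List with `medians` (data frame by source), `correlation` (data
#'   frame by source: `r`, `p`, `note`), `auc_satisfactory` (named count per
#'   source), `n_genes`.
#' @export
cohort_summary <- function(metrics, auc_threshold = 0.6) {
  metrics <- as.data.frame(metrics)
  if (length(unique(metrics$gene)) < 3L) stop("need metrics for >= 3 genes")
  by_source <- split(metrics, metrics$source)
  medians <- do.call(rbind, lapply(names(by_source), function(s) {
    d <- by_source[[s]]
    data.frame(source = s, precision = stats::median(d$precision),
               recall = stats::median(d$recall),
               f1 = stats::median(d$f1), auc = stats::median(d$auc),
               stringsAsFactors = FALSE)
  }))
  correlation <- do.call(rbind, lapply(names(by_source), function(s) {
    d <- by_source[[s]]
    if (stats::sd(d$f1) == 0 || stats::sd(d$n_cases) == 0) {
      data.frame(source = s, r = NA_real_, p = NA_real_,
                 note = "undefined: zero variance",
                 stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(d$f1, d$n_cases, method = "pearson")
      data.frame(source = s, r = unname(ct$estimate), p = ct$p.value,
                 note = "", stringsAsFactors = FALSE)
    }
  }))
  auc_ok <- vapply(by_source, function(d) sum(d$auc >= auc_threshold),
                   integer(1))
  list(medians = medians, correlation = correlation,
       auc_satisfactory = auc_ok, n_genes = length(unique(metrics$gene)))
}
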