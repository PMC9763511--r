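#' Rule-of-thumb kernel bandwidth (nrd0)
#'
#' Silverman's rule of thumb, `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, scaled by
#' an adjustment multiplier. The classifiers use an increased bandwidth
#' (`adjust = 2` by default at fit time) so the class densities are smoother
#' than a plain density estimate, which stabilises likelihood ratios in the
#' tails for the modest per-gene sample sizes typical of rare-disorder
#' cohorts. For degenerate samples where both the standard deviation and the
#' IQR are zero, the scale falls back to `max(|x[1]|, 1)`.
#'
#' @param x Numeric values; `NA`s are dropped; at least 2 values required.
#' @param adjust Positive bandwidth multiplier.
#' @return Positive bandwidth.
#' @export
nrd0_bandwidth <- function(x, adjust = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 non-missing values for a bandwidth")
  stopifnot(adjust > 0)
  lo <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (!is.finite(lo) || lo == 0) lo <- max(abs(x[1L]), 1)
  0.9 * lo * n^(-1 / 5) * adjust
}

#' Fit a Gaussian kernel density
#'
#' Stores the sample and its nrd0 bandwidth; evaluation is the exact kernel
#' sum (no grid interpolation), so densities are reproducible to machine
#' precision.
#'
#' @param x Numeric values; `NA`s dropped.
#' @param adjust Bandwidth multiplier (see [nrd0_bandwidth()]).
#' @return An object of class `phen_kde` with elements `samples`, `bw`,
#'   `adjust`.
#' @export
kde_fit <- function(x, adjust = 2) {
  x <- x[!is.na(x)]
  structure(list(samples = x, bw = nrd0_bandwidth(x, adjust = adjust),
                 adjust = adjust),
            class = "phen_kde")
}

#' Evaluate a kernel density
#'
#' @param kde A [kde_fit()] object.
#' @param q Numeric query points.
#' @param floor Lower bound applied to the density before any ratio is taken,
#'   to keep log likelihood ratios finite far in the tails.
#' @return Numeric densities at `q` (`NA` in, `NA` out).
#' @export
kde_density <- function(kde, q, floor = 0) {
  stopifnot(inherits(kde, "phen_kde"))
  h <- kde$bw
  xs <- kde$samples
  d <- vapply(q, function(v) {
    if (is.na(v)) return(NA_real_)
    mean(stats::dnorm((v - xs) / h)) / h
  }, numeric(1))
  pmax(d, floor, na.rm = FALSE)
}

#' Fit a per-gene naive Bayes phenotype model
#'
#' Class M1 is "diagnosed with `gene`"; the complement class is every other
#' individual in the cohort (diagnosed with another gene or undiagnosed).
#' Three classifier families are fitted, one per data type:
#' * sex: a 2x2 probability table with additive pseudocount smoothing;
#' * growth and developmental milestones: one Gaussian-kernel density per
#'   feature per class, on non-missing values, with increased bandwidth;
#' * IPT annotations: Bernoulli presence rates per term per class, smoothed
#'   with the same pseudocount so no rate is exactly 0 or 1.
#' The class prior is the observed frequency `n_cases / N`.
#'
#' @param x A [cohort()] object with an IPT matrix attached
#'   (see [set_ipt_matrix()]).
#' @param gene Gene symbol.
#' @param pseudocount Additive smoothing count for the sex table and the
#'   Bernoulli rates.
#' @param adjust KDE bandwidth multiplier.
#' @param min_cases Minimum number of diagnosed individuals required.
#' @return An object of class `phen_gene_model`.
#' @export
fit_gene_model <- function(x, gene, pseudocount = 0.5, adjust = 2,
                           min_cases = 10) {
  stopifnot(inherits(x, "phen_cohort"))
  if (is.null(x$ipt_matrix)) {
    stop("cohort has no IPT matrix; run dedup_ipt_annotations() and ",
         "set_ipt_matrix() first")
  }
  ph <- x$phenotypes
  is_case <- !is.na(ph$diagnosis) & ph$diagnosis == gene
  n_cases <- sum(is_case)
  n <- nrow(ph)
  if (n_cases < min_cases) {
    stop("gene ", gene, " has ", n_cases, " diagnosed individuals; ",
         min_cases, " required")
  }
  if (n_cases == n) stop("complement class is empty for gene ", gene)

  sex_tab <- matrix(NA_real_, 2, 2,
                    dimnames = list(class = c("case", "other"),
                                    sex = c("male", "female")))
  for (cl in c(TRUE, FALSE)) {
    sx <- ph$sex[if (cl) is_case else !is_case]
    cnt <- c(male = sum(sx == "male", na.rm = TRUE),
             female = sum(sx == "female", na.rm = TRUE))
    sex_tab[if (cl) "case" else "other", ] <-
      (cnt + pseudocount) / (sum(cnt) + 2 * pseudocount)
  }

  fit_block <- function(features) {
    out <- list()
    for (f in features) {
      v_case <- ph[[f]][is_case]
      v_other <- ph[[f]][!is_case]
      usable <- sum(!is.na(v_case)) >= 2L && sum(!is.na(v_other)) >= 2L
      if (!usable) {
        warning("feature ", f, " unusable for gene ", gene,
                " (<2 non-missing values in a class); skipped",
                call. = FALSE)
        out[[f]] <- list(usable = FALSE)
      } else {
        out[[f]] <- list(usable = TRUE,
                         case = kde_fit(v_case, adjust = adjust),
                         other = kde_fit(v_other, adjust = adjust))
      }
    }
    out
  }

  A <- x$ipt_matrix
  rate <- function(rows) (colSums(A[rows, , drop = FALSE]) + pseudocount) /
    (sum(rows) + 2 * pseudocount)
  hpo_rates <- cbind(case = rate(is_case), other = rate(!is_case))

  structure(list(gene = gene, prior = n_cases / n, n_cases = n_cases,
                 n = n, pseudocount = pseudocount, adjust = adjust,
                 sex_table = sex_tab,
                 growth_kdes = fit_block(growth_features()),
                 dev_kdes = fit_block(dev_features()),
                 hpo_rates = hpo_rates,
                 ipt_terms = colnames(A)),
            class = "phen_gene_model")
}

#' @export
print.phen_gene_model <- function(x, ...) {
  cat("<phen_gene_model> ", x$gene, ": ", x$n_cases, "/", x$n,
      " cases (prior ", signif(x$prior, 3), "), ",
      length(x$ipt_terms), " IPT features\n", sep = "")
  invisible(x)
}

# density floor applied before log ratios; keeps tails finite
.kde_floor <- 1e-12

# Vectorized per-data-type log likelihood ratios for every individual of a
# cohort under one gene model. Rows align with x$phenotypes.
gene_loglrs <- function(model, x) {
  stopifnot(inherits(model, "phen_gene_model"), inherits(x, "phen_cohort"))
  ph <- x$phenotypes
  n <- nrow(ph)

  lr_sex <- rep(0, n)
  for (s in c("male", "female")) {
    hit <- !is.na(ph$sex) & ph$sex == s
    lr_sex[hit] <- log(model$sex_table["case", s] /
                         model$sex_table["other", s])
  }

  block_lr <- function(kdes, features) {
    tot <- rep(0, n)
    for (f in features) {
      k <- kdes[[f]]
      if (is.null(k) || !k$usable) next
      v <- ph[[f]]
      ok <- !is.na(v)
      if (!any(ok)) next
      d1 <- kde_density(k$case, v[ok], floor = .kde_floor)
      d0 <- kde_density(k$other, v[ok], floor = .kde_floor)
      tot[ok] <- tot[ok] + log(d1 / d0)
    }
    tot
  }

  A <- x$ipt_matrix
  if (is.null(A)) stop("cohort has no IPT matrix")
  if (!identical(colnames(A), model$ipt_terms)) {
    if (!setequal(colnames(A), model$ipt_terms)) {
      stop("cohort IPT terms do not match the model's feature set")
    }
    A <- A[, model$ipt_terms, drop = FALSE]
  }
  p1 <- model$hpo_rates[, "case"]
  p0 <- model$hpo_rates[, "other"]
  w_present <- log(p1 / p0)
  w_absent <- log((1 - p1) / (1 - p0))
  lr_hpo <- as.numeric(A %*% w_present + (!A) %*% w_absent)

  data.frame(individual_id = ph$individual_id, gene = model$gene,
             loglr_sex = lr_sex,
             loglr_growth = block_lr(model$growth_kdes, growth_features()),
             loglr_dev = block_lr(model$dev_kdes, dev_features()),
             loglr_hpo = lr_hpo,
             label = !is.na(ph$diagnosis) & ph$diagnosis == model$gene,
             stringsAsFactors = FALSE)
}

#' Sex log likelihood ratio for one individual
#'
#' `log P(sex | M1) / P(sex | complement)`; missing sex contributes 0.
#'
#' @param model A [fit_gene_model()] object.
#' @param sex `"male"`, `"female"` or `NA`.
#' @return A real number.
#' @export
loglr_sex <- function(model, sex) {
  stopifnot(inherits(model, "phen_gene_model"))
  if (is.na(sex)) return(0)
  if (!sex %in% c("male", "female")) stop("sex must be male/female/NA")
  log(model$sex_table["case", sex] / model$sex_table["other", sex])
}

#' Continuous-block log likelihood ratio for one individual
#'
#' Sum over the block's features of `log f_case(x) / f_other(x)` under the
#' class kernel densities, with densities floored before the ratio. Missing
#' or unusable features contribute 0.
#'
#' @param model A [fit_gene_model()] object.
#' @param values Named numeric vector of feature values (names from the
#'   block's feature set; absent names count as missing).
#' @param block `"growth"` or `"development"`.
#' @return A real number.
#' @export
loglr_continuous <- function(model, values, block = c("growth",
                                                      "development")) {
  stopifnot(inherits(model, "phen_gene_model"))
  block <- match.arg(block)
  features <- if (block == "growth") growth_features() else dev_features()
  kdes <- if (block == "growth") model$growth_kdes else model$dev_kdes
  tot <- 0
  for (f in features) {
    v <- if (f %in% names(values)) values[[f]] else NA_real_
    k <- kdes[[f]]
    if (is.na(v) || is.null(k) || !k$usable) next
    tot <- tot + log(kde_density(k$case, v, floor = .kde_floor) /
                       kde_density(k$other, v, floor = .kde_floor))
  }
  tot
}

#' HPO-term log likelihood ratio for one individual
#'
#' Bernoulli naive Bayes over the IPT feature set: each term contributes
#' `log P(present | M1)/P(present | complement)` if the individual carries it
#' and the corresponding absent-ratio otherwise. The signed per-term
#' contributions are returned so supporting (positive) and opposing
#' (negative) terms can be listed for clinical review.
#'
#' @param model A [fit_gene_model()] object.
#' @param terms Character vector of IPT IDs the individual is annotated with
#'   (after deduplication).
#' @return List with `total` (sum of contributions) and `contributions`
#'   (named numeric, one entry per IPT feature).
#' @export
loglr_hpo <- function(model, terms) {
  stopifnot(inherits(model, "phen_gene_model"))
  present <- model$ipt_terms %in% terms
  p1 <- model$hpo_rates[, "case"]
  p0 <- model$hpo_rates[, "other"]
  contrib <- ifelse(present, log(p1 / p0), log((1 - p1) / (1 - p0)))
  names(contrib) <- model$ipt_terms
  list(total = sum(contrib), contributions = contrib)
}

#' Per-individual, per-gene likelihood table
#'
#' Evaluates every fitted gene model on every individual of the cohort,
#' producing one row per (individual, gene) with the four per-data-type log
#' likelihood ratios and the diagnosis label. This is the input to weight
#' optimization and all evaluation.
#'
#' @param models List of [fit_gene_model()] objects.
#' @param x A [cohort()] object with IPT matrix.
#' @return Data frame with columns `individual_id`, `gene`, `loglr_sex`,
#'   `loglr_growth`, `loglr_dev`, `loglr_hpo`, `label`.
#' @export
likelihood_table <- function(models, x) {
  out <- do.call(rbind, lapply(models, gene_loglrs, x = x))
  rownames(out) <- NULL
  out
}

#' Per-individual evidence report
#'
#' For one individual and one gene model, lists the informative terms
#' supporting (positive log LR contribution) and opposing (negative) the
#' diagnosis, together with the per-data-type totals — the layout of a
#' clinical evidence table.
#'
#' @param model A [fit_gene_model()] object.
#' @param x A [cohort()] object with IPT matrix.
#' @param individual_id Individual to report on.
#' @param weights Optional weight vector (see [combine_scores()]); when
#'   given, the combined score is included.
#' @return List with elements `individual_id`, `gene`, `loglr` (named totals),
#'   `supporting` and `opposing` (named numeric, sorted by magnitude), and
#'   optionally `score`.
#' @export
evidence_report <- function(model, x, individual_id, weights = NULL) {
  idx <- match(individual_id, x$phenotypes$individual_id)
  if (is.na(idx)) stop("unknown individual: ", individual_id)
  lr <- gene_loglrs(model, subset_cohort(x, idx))
  terms_here <- colnames(x$ipt_matrix)[x$ipt_matrix[idx, ]]
  h <- loglr_hpo(model, terms_here)
  # report only terms whose state is informative either way
  contrib <- h$contributions[h$contributions != 0]
  labels_for <- function(v) v[order(-abs(v))]
  out <- list(individual_id = individual_id, gene = model$gene,
              loglr = c(sex = lr$loglr_sex, growth = lr$loglr_growth,
                        development = lr$loglr_dev, hpo = lr$loglr_hpo),
              supporting = labels_for(contrib[contrib > 0]),
              opposing = labels_for(contrib[contrib < 0]))
  if (!is.null(weights)) {
    out$score <- combine_scores(weights, lr)
  }
  out
}

#' Serialize gene models to JSON
#'
#' Writes gene, prior, sex table, KDE samples and bandwidths, Bernoulli rates
#' and the IPT feature list at full numeric precision, so a reloaded model
#' reproduces every likelihood ratio exactly.
#'
#' @param models List of [fit_gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  ser <- lapply(models, function(m) {
    blk <- function(kdes) lapply(kdes, function(k) {
      if (!k$usable) return(list(usable = FALSE))
      list(usable = TRUE,
           case = list(samples = k$case$samples, bw = k$case$bw,
                       adjust = k$case$adjust),
           other = list(samples = k$other$samples, bw = k$other$bw,
                        adjust = k$other$adjust))
    })
    list(gene = m$gene, prior = m$prior, n_cases = m$n_cases, n = m$n,
         pseudocount = m$pseudocount, adjust = m$adjust,
         sex_table = list(case = as.list(m$sex_table["case", ]),
                          other = as.list(m$sex_table["other", ])),
         growth_kdes = blk(m$growth_kdes), dev_kdes = blk(m$dev_kdes),
         hpo_rates = list(terms = m$ipt_terms,
                          case = unname(m$hpo_rates[, "case"]),
                          other = unname(m$hpo_rates[, "other"])))
  })
  names(ser) <- vapply(models, function(m) m$gene, character(1))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read gene models from JSON
#'
#' @param path A file written by [write_models_json()].
#' @return Named list of `phen_gene_model` objects.
#' @export
read_models_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    blk <- function(kdes) lapply(kdes, function(k) {
      if (!isTRUE(k$usable)) return(list(usable = FALSE))
      mk <- function(s) structure(list(samples = as.numeric(unlist(s$samples)),
                                       bw = s$bw, adjust = s$adjust),
                                  class = "phen_kde")
      list(usable = TRUE, case = mk(k$case), other = mk(k$other))
    })
    terms <- as.character(unlist(m$hpo_rates$terms))
    rates <- cbind(case = as.numeric(unlist(m$hpo_rates$case)),
                   other = as.numeric(unlist(m$hpo_rates$other)))
    rownames(rates) <- terms
    st <- matrix(c(m$sex_table$case$male, m$sex_table$other$male,
                   m$sex_table$case$female, m$sex_table$other$female),
                 2, 2, dimnames = list(class = c("case", "other"),
                                       sex = c("male", "female")))
    structure(list(gene = m$gene, prior = m$prior, n_cases = m$n_cases,
                   n = m$n, pseudocount = m$pseudocount, adjust = m$adjust,
                   sex_table = st, growth_kdes = blk(m$growth_kdes),
                   dev_kdes = blk(m$dev_kdes), hpo_rates = rates,
                   ipt_terms = terms),
              class = "phen_gene_model")
  })
}
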