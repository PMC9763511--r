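#' Generate a toy phenotype ontology
#'
#' A layered rooted DAG: the root, a layer of top-level terms, and further
#' layers where each term of layer k has `branching` children in layer k+1.
#' A configurable fraction of nodes below the top level additionally receive
#' a second parent drawn from the previous layer, giving the multiple-parent
#' structure of a real phenotype ontology. Deterministic under the seed.
#'
#' @param layers Number of layers below the root (>= 2).
#' @param branching Children per term (>= 2).
#' @param multi_parent_frac Fraction of nodes in layers 2+ that get a second
#'   parent.
#' @param seed Integer seed.
#' @return A [ontology()] object whose term IDs are `HP:`-style strings;
#'   leaves are the terms of the deepest layer.
#' @export
make_ontology <- function(layers = 3, branching = 3, multi_parent_frac = 0,
                          seed = 1L) {
  stopifnot(layers >= 2, branching >= 2,
            multi_parent_frac >= 0, multi_parent_frac <= 1)
  id_of <- function(k) sprintf("HP:%07d", k)
  withr::with_seed(as.integer(seed), {
    counter <- 1L
    root <- id_of(counter)
    terms <- root
    parents <- list()
    labels <- c(stats::setNames("Phenotypic abnormality (synthetic)", root))
    prev <- root
    for (l in seq_len(layers)) {
      layer <- character(0)
      for (p in prev) {
        for (b in seq_len(branching)) {
          counter <- counter + 1L
          t <- id_of(counter)
          parents[[t]] <- p
          labels[t] <- paste0("Synthetic term L", l, " #", counter)
          layer <- c(layer, t)
        }
      }
      if (l >= 2 && multi_parent_frac > 0 && length(prev) > 1L) {
        extra <- stats::runif(length(layer)) < multi_parent_frac
        for (i in which(extra)) {
          t <- layer[i]
          others <- setdiff(prev, parents[[t]])
          parents[[t]] <- c(parents[[t]], sample(others, 1L))
        }
      }
      terms <- c(terms, layer)
      prev <- layer
    }
    ontology(terms, parents, labels = labels, root = root)
  })
}

#' Leaf terms of an ontology
#' @param ont A [ontology()] object.
#' @return Character vector of terms with no children.
#' @export
ontology_leaves <- function(ont) {
  ont$terms[vapply(ont$children[ont$terms], length, 1L) == 0L]
}

#' Per-gene planted effect profile
#'
#' Describes how a diagnosed group differs from the cohort background: a sex
#' ratio, additive mean shifts on the five growth attributes (Z units for the
#' Z-scored attributes, months for gestation), additive delays on the four
#' developmental milestones (months), and elevated annotation probabilities
#' for chosen ontology terms.
#'
#' @param gene Gene symbol.
#' @param n_cases Number of diagnosed individuals (>= 1).
#' @param sex_female_prob Probability a case is female (background is 0.5).
#' @param growth_shift Numeric length-5 vector of shifts, in the order
#'   gestation, birthweight, height, weight, head circumference.
#' @param dev_delay Numeric length-4 vector of delays, in the order walked,
#'   first words, social smile, sat.
#' @param term_boost Named numeric vector: term ID -> per-case annotation
#'   probability (replacing the background probability for that term).
#' @return A list of class `effect_profile`.
#' @export
effect_profile <- function(gene, n_cases, sex_female_prob = 0.5,
                           growth_shift = numeric(5),
                           dev_delay = numeric(4),
                           term_boost = stats::setNames(numeric(0),
                                                        character(0))) {
  stopifnot(n_cases >= 1, length(growth_shift) == 5L,
            length(dev_delay) == 4L,
            sex_female_prob >= 0, sex_female_prob <= 1,
            all(term_boost >= 0), all(term_boost <= 1))
  structure(list(gene = gene, n_cases = as.integer(n_cases),
                 sex_female_prob = sex_female_prob,
                 growth_shift = as.numeric(growth_shift),
                 dev_delay = as.numeric(dev_delay),
                 term_boost = term_boost),
            class = "effect_profile")
}

#' Simulation configuration
#'
#' @param n_background Number of undiagnosed background individuals.
#' @param genes List of [effect_profile()]s.
#' @param background_term_prob Probability each individual is annotated to
#'   each eligible leaf term of the ontology.
#' @param missingness Named numeric: per-block probability that an
#'   individual's whole `growth` or `development` block is missing.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background, genes = list(),
                       background_term_prob = 0.02,
                       missingness = c(growth = 0.05, development = 0.05),
                       seed = 1L) {
  stopifnot(n_background >= 0,
            all(c("growth", "development") %in% names(missingness)))
  structure(list(n_background = as.integer(n_background), genes = genes,
                 background_term_prob = background_term_prob,
                 missingness = missingness, seed = as.integer(seed)),
            class = "sim_config")
}

# reference distributions for the background population; milestones are
# months at attainment, truncated at zero
.sim_reference <- list(
  gestation = c(mean = 9, sd = 0.5),
  birthweight_z = c(mean = 0, sd = 1),
  height_z = c(mean = 0, sd = 1),
  weight_z = c(mean = 0, sd = 1),
  ofc_z = c(mean = 0, sd = 1),
  walked = c(mean = 13, sd = 2.5),
  first_words = c(mean = 12, sd = 3),
  social_smile = c(mean = 2, sd = 0.8),
  sat = c(mean = 7, sd = 1.5)
)

# sample from a normal truncated below at zero (exact inverse-CDF draw)
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate a developmental-disorder-like cohort
#'
#' Background individuals draw growth Z scores from the standard normal,
#' gestation and milestones from reference normals truncated at zero, sex
#' uniformly, and annotate each leaf term of the ontology independently with
#' the background probability. Diagnosed individuals add their gene's planted
#' shifts and delays, use the gene's sex ratio, and annotate boosted terms
#' with elevated probability. Annotations are emitted at the annotated terms
#' only — propagation to ancestors is the pipeline's job. Whole-block
#' missingness is applied per individual. Deterministic under the config
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param ont A [ontology()] object (e.g. [make_ontology()]).
#' @return A [cohort()] object (raw annotations, no IPT matrix yet).
#' @export
simulate_cohort <- function(cfg, ont) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ont, "phen_ontology"))
  leaves <- ontology_leaves(ont)
  for (g in cfg$genes) {
    unknown <- setdiff(names(g$term_boost), ont$terms)
    if (length(unknown) > 0) {
      stop("term_boost for gene ", g$gene, " references unknown term(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  n_cases_tot <- sum(vapply(cfg$genes, function(g) g$n_cases, integer(1)))
  n <- cfg$n_background + n_cases_tot
  ids <- sprintf("IND_%05d", seq_len(n))
  gene_of <- c(rep(NA_character_, cfg$n_background),
               unlist(lapply(cfg$genes,
                             function(g) rep(g$gene, g$n_cases))))
  profiles <- stats::setNames(cfg$genes,
                              vapply(cfg$genes, function(g) g$gene,
                                     character(1)))
  feats <- quant_features()
  withr::with_seed(cfg$seed, {
    ph <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
    female_prob <- ifelse(is.na(gene_of), 0.5,
                          vapply(gene_of, function(g) {
                            if (is.na(g)) 0.5
                            else profiles[[g]]$sex_female_prob
                          }, numeric(1)))
    ph$sex <- ifelse(stats::runif(n) < female_prob, "female", "male")
    shift_for <- function(f) {
      gi <- match(f, feats)
      vapply(gene_of, function(g) {
        if (is.na(g)) return(0)
        pr <- profiles[[g]]
        if (gi <= 5L) pr$growth_shift[gi] else pr$dev_delay[gi - 5L]
      }, numeric(1))
    }
    for (f in feats) {
      r <- .sim_reference[[f]]
      mu <- r[["mean"]] + shift_for(f)
      ph[[f]] <- if (f %in% growth_features() && f != "gestation") {
        stats::rnorm(n, mu, r[["sd"]])
      } else {
        rtruncnorm0(n, mu, r[["sd"]])
      }
    }
    miss_g <- stats::runif(n) < cfg$missingness[["growth"]]
    miss_d <- stats::runif(n) < cfg$missingness[["development"]]
    for (f in growth_features()) ph[[f]][miss_g] <- NA_real_
    for (f in dev_features()) ph[[f]][miss_d] <- NA_real_

    ann_terms <- unique(c(leaves,
                          unlist(lapply(cfg$genes,
                                        function(g) names(g$term_boost)))))
    prob <- matrix(cfg$background_term_prob, nrow = n,
                   ncol = length(ann_terms),
                   dimnames = list(ids, ann_terms))
    prob[, setdiff(ann_terms, leaves)] <- 0  # non-leaf terms: boost only
    for (g in cfg$genes) {
      rows <- which(!is.na(gene_of) & gene_of == g$gene)
      for (t in names(g$term_boost)) prob[rows, t] <- g$term_boost[[t]]
    }
    ann <- matrix(stats::runif(n * length(ann_terms)), nrow = n) < prob
    dimnames(ann) <- dimnames(prob)
  })
  diag_df <- data.frame(individual_id = ids[!is.na(gene_of)],
                        gene = gene_of[!is.na(gene_of)],
                        stringsAsFactors = FALSE)
  cohort(ph, ann, diag_df)
}

#' Library of fixed simulation scenarios
#'
#' Named, seeded scenarios that plant qualitatively distinct signals, each on
#' a shared toy ontology (`make_ontology(layers = 3, branching = 3,
#' multi_parent_frac = 0.1)`):
#' * `growth_dominant`: strong head-circumference and height shifts, weak
#'   term signal — growth should out-predict HPO terms;
#' * `development_dominant`: large milestone delays, weak term signal;
#' * `hpo_dominant`: strongly boosted annotation probabilities, no
#'   quantitative signal;
#' * `sex_biased`: 95% female cases with a moderate term signal, emulating an
#'   X-linked syndrome;
#' * `small_n_strong`: only 10 cases but strong multi-type signal — models
#'   from few individuals should still cross-validate well;
#' * `null`: no planted effect of any kind (calibration control).
#'
#' @param seed Base seed; each scenario derives its own fixed offset from it.
#' @param n_background Background individuals per scenario.
#' @return Named list; each element has `config` (a [sim_config()]),
#'   `ontology_spec` (arguments for [make_ontology()]) and `gene` (the
#'   planted gene symbol, `NA` for the null scenario's undifferentiated
#'   gene).
#' @export
scenario_library <- function(seed = 1L, n_background = 200L) {
  seed <- as.integer(seed)
  spec <- list(layers = 3, branching = 3, multi_parent_frac = 0.1,
               seed = seed)
  ont <- do.call(make_ontology, spec)
  leaves <- ontology_leaves(ont)
  boost <- function(idx, p) stats::setNames(rep_len(p, length(idx)),
                                            leaves[idx])
  scen <- function(name, offset, profile, missingness = c(growth = 0.05,
                                                          development = 0.05)) {
    list(name = name,
         config = sim_config(n_background = n_background,
                             genes = list(profile),
                             missingness = missingness,
                             seed = seed + offset),
         ontology_spec = spec, gene = profile$gene)
  }
  list(
    growth_dominant = scen("growth_dominant", 101L, effect_profile(
      "GENE_GRO", n_cases = 25, growth_shift = c(0, 0, 1.5, 0, 2.5),
      term_boost = boost(1L, 0.10))),
    development_dominant = scen("development_dominant", 202L, effect_profile(
      "GENE_DEV", n_cases = 25, dev_delay = c(10, 8, 2, 5),
      term_boost = boost(2L, 0.10))),
    hpo_dominant = scen("hpo_dominant", 303L, effect_profile(
      "GENE_HPO", n_cases = 25,
      term_boost = boost(c(3L, 10L, 17L), c(0.7, 0.6, 0.5)))),
    sex_biased = scen("sex_biased", 404L, effect_profile(
      "GENE_SEX", n_cases = 25, sex_female_prob = 0.95,
      term_boost = boost(5L, 0.3))),
    # complete records for the small group: the scenario exists to study
    # models built from exactly 10 cases, which whole-block missingness
    # would silently shrink below the fitting floor
    small_n_strong = scen("small_n_strong", 505L, effect_profile(
      "GENE_SMALL", n_cases = 10, growth_shift = c(0, 0, 0, 0, 2),
      dev_delay = c(8, 6, 0, 4),
      term_boost = boost(c(7L, 12L), c(0.7, 0.6))),
      missingness = c(growth = 0, development = 0)),
    null = scen("null", 606L, effect_profile("GENE_NULL", n_cases = 20))
  )
}

#' Materialize a scenario
#'
#' Builds the scenario's ontology and simulates its cohort.
#'
#' @param scenario One element of [scenario_library()].
#' @return List with `ontology` and `cohort`.
#' @export
build_scenario <- function(scenario) {
  ont <- do.call(make_ontology, scenario$ontology_spec)
  list(ontology = ont, cohort = simulate_cohort(scenario$config, ont))
}
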