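test_that("nrd0 bandwidth follows the rule of thumb and its fallback", {
  x <- 1:5
  expect_equal(nrd0_bandwidth(x),
               0.9 * min(stats::sd(x), stats::IQR(x) / 1.34) * 5^(-0.2),
               tolerance = 1e-12)
  # agrees with the reference implementation on non-degenerate samples
  withr::with_seed(1, y <- stats::rnorm(40))
  expect_equal(nrd0_bandwidth(y), stats::bw.nrd0(y), tolerance = 1e-12)
  # degenerate constant sample: positive, finite
  h <- nrd0_bandwidth(c(2, 2, 2, 2))
  expect_true(is.finite(h) && h > 0)
  expect_equal(h, 0.9 * 2 * 4^(-0.2), tolerance = 1e-12)
  # linear in adjust
  expect_equal(nrd0_bandwidth(x, adjust = 2), 2 * nrd0_bandwidth(x),
               tolerance = 1e-12)
  expect_error(nrd0_bandwidth(c(1, NA)), "at least 2")
})

test_that("kernel density equals the direct kernel sum and integrates to 1", {
  withr::with_seed(2, x <- stats::rnorm(25, 1, 2))
  k <- kde_fit(x, adjust = 2)
  q <- seq(-6, 8, length.out = 100)
  expect_equal(kde_density(k, q), oracle_kernel_density(x, k$bw, q),
               tolerance = 1e-9)
  int <- stats::integrate(function(v) kde_density(k, v), -Inf, Inf,
                          rel.tol = 1e-8)
  expect_equal(int$value, 1, tolerance = 1e-6)
})

sex_fixture <- function(pseudocount = 0) {
  # 10 cases (9 female / 1 male) over a 40-strong 50/50 background
  f <- fixture_cohort(n_cases = 10, n_bg = 40, case_female = 0.9)
  fit_gene_model(f$cohort, "GENE_A", pseudocount = pseudocount,
                 min_cases = 10)
}

test_that("sex table and log-LR match hand contingency arithmetic", {
  m <- sex_fixture(pseudocount = 0)
  expect_equal(m$sex_table["case", "female"], 0.9, tolerance = 1e-12)
  expect_equal(m$sex_table["other", "female"], 0.5, tolerance = 1e-12)
  expect_equal(loglr_sex(m, "female"), log(1.8), tolerance = 1e-12)
  expect_equal(loglr_sex(m, "female"), log(1.8) , tolerance = 1e-12)
  expect_equal(loglr_sex(m, NA), 0)
  # female-biased model scores females above males
  expect_gt(loglr_sex(m, "female"), loglr_sex(m, "male"))
})

test_that("class prior is the observed class frequency", {
  f <- fixture_cohort(n_cases = 17, n_bg = 1713)
  m <- fit_gene_model(f$cohort, "GENE_A")
  expect_equal(m$prior, 17 / 1730, tolerance = 1e-12)
})

test_that("continuous log-LR: symmetry at equal samples, sign at the case mode", {
  f <- fixture_cohort()
  m <- fit_gene_model(f$cohort, "GENE_A")
  # identical class samples give 0 everywhere
  same <- kde_fit(c(1, 2, 3, 4), adjust = 2)
  m2 <- m
  for (feat in names(m2$growth_kdes)) {
    m2$growth_kdes[[feat]] <- list(usable = TRUE, case = same, other = same)
  }
  vals <- stats::setNames(rep(1.7, 5), names(m2$growth_kdes))
  expect_equal(loglr_continuous(m2, vals, "growth"), 0, tolerance = 1e-12)
  # planted +2 ofc shift: the case mode scores positive
  expect_gt(loglr_continuous(m, c(ofc_z = 2), "growth"), 0)
  # missing features contribute nothing
  expect_equal(loglr_continuous(m, c(ofc_z = NA_real_), "growth"), 0)
})

test_that("HPO log-LR is the sum of signed per-term Bernoulli contributions", {
  f <- fixture_cohort()
  m <- fit_gene_model(f$cohort, "GENE_A")
  terms <- m$ipt_terms[c(1, 3)]
  h <- loglr_hpo(m, terms)
  manual <- 0
  for (t in m$ipt_terms) {
    p1 <- m$hpo_rates[t, "case"]
    p0 <- m$hpo_rates[t, "other"]
    manual <- manual + if (t %in% terms) log(p1 / p0) else
      log((1 - p1) / (1 - p0))
  }
  expect_equal(h$total, manual, tolerance = 1e-9)
  expect_equal(sum(h$contributions), h$total, tolerance = 1e-9)
  # equal class rates contribute 0
  m3 <- m
  m3$hpo_rates[, "other"] <- m3$hpo_rates[, "case"]
  expect_equal(loglr_hpo(m3, terms)$total, 0, tolerance = 1e-12)
  # boosted term contributes positively when present, negatively when absent
  boosted <- m$ipt_terms[which.max(m$hpo_rates[, "case"] -
                                     m$hpo_rates[, "other"])]
  expect_gt(loglr_hpo(m, boosted)$contributions[boosted], 0)
  expect_lt(loglr_hpo(m, character(0))$contributions[boosted], 0)
})

test_that("uniform-random case subsets fit distributions close to the background", {
  # cases drawn uniformly from the cohort: fitted case KDE ~ background KDE
  ont <- make_ontology(layers = 2, branching = 3, seed = 9)
  withr::with_seed(9, {
    n <- 400
    ids <- sprintf("u%03d", seq_len(n))
    ph <- data.frame(individual_id = ids,
                     sex = sample(c("male", "female"), n, TRUE),
                     stringsAsFactors = FALSE)
    for (f in phenolr:::quant_features()) ph[[f]] <- stats::rnorm(n)
    leaves <- ontology_leaves(ont)
    ann <- matrix(stats::runif(n * length(leaves)) < 0.15, n,
                  dimnames = list(ids, leaves))
    cases <- sample(ids, 60)
  })
  dx <- data.frame(individual_id = cases, gene = "GENE_U")
  coh <- cohort(ph, ann, dx)
  prep <- prepare_ipt_features(ont, coh, upper_frac = 0.5)
  m <- fit_gene_model(prep$cohort, "GENE_U")
  ks <- stats::ks.test(m$growth_kdes$ofc_z$case$samples,
                       m$growth_kdes$ofc_z$other$samples)
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(m$hpo_rates[, "case"] - m$hpo_rates[, "other"])), 0.05)
})

test_that("parameter recovery: planted +2 ofc shift puts the case KDE mode near +2", {
  f <- fixture_cohort(n_cases = 30, n_bg = 120, seed = 21)
  m <- fit_gene_model(f$cohort, "GENE_A")
  grid <- seq(-2, 6, by = 0.01)
  mode <- grid[which.max(kde_density(m$growth_kdes$ofc_z$case, grid))]
  expect_lt(abs(mode - 2), 0.5)
})

test_that("swapping class labels negates every log likelihood ratio", {
  f <- fixture_cohort(n_cases = 15, n_bg = 35)
  coh <- f$cohort
  m1 <- fit_gene_model(coh, "GENE_A", min_cases = 10)
  swapped <- coh
  dx <- swapped$phenotypes$diagnosis
  swapped$phenotypes$diagnosis <- ifelse(is.na(dx), "GENE_A", NA_character_)
  m2 <- fit_gene_model(swapped, "GENE_A", min_cases = 10)
  lr1 <- phenolr:::gene_loglrs(m1, coh)
  lr2 <- phenolr:::gene_loglrs(m2, swapped)
  for (col in c("loglr_sex", "loglr_growth", "loglr_dev", "loglr_hpo")) {
    expect_equal(lr1[[col]], -lr2[[col]], tolerance = 1e-9)
  }
})

test_that("positive pseudocount keeps all log-LRs finite", {
  f <- fixture_cohort(n_cases = 10, n_bg = 40)
  coh <- f$cohort
  # force a term never seen in the gene class
  coh$ipt_matrix[coh$phenotypes$diagnosis %in% "GENE_A", 2] <- FALSE
  coh$ipt_matrix[!coh$phenotypes$diagnosis %in% "GENE_A", 2] <- TRUE
  m <- fit_gene_model(coh, "GENE_A", pseudocount = 0.5)
  lr <- phenolr:::gene_loglrs(m, coh)
  expect_true(all(is.finite(as.matrix(
    lr[, c("loglr_sex", "loglr_growth", "loglr_dev", "loglr_hpo")]))))
})

test_that("features with under 2 case values are flagged unusable and skipped", {
  f <- fixture_cohort(n_cases = 10, n_bg = 40)
  coh <- f$cohort
  is_case <- coh$phenotypes$diagnosis %in% "GENE_A"
  coh$phenotypes$walked[is_case] <- NA_real_
  expect_warning(m <- fit_gene_model(coh, "GENE_A"), "walked")
  expect_false(m$dev_kdes$walked$usable)
  lr <- phenolr:::gene_loglrs(m, coh)
  expect_true(all(is.finite(lr$loglr_dev)))
})

test_that("likelihood table is complete, consistent and serializable", {
  f <- fixture_cohort(n_cases = 12, n_bg = 38)
  coh <- f$cohort
  coh$phenotypes$diagnosis[20:31] <- "GENE_B"
  models <- list(fit_gene_model(coh, "GENE_A"),
                 fit_gene_model(coh, "GENE_B"))
  tab <- likelihood_table(models, coh)
  expect_identical(nrow(tab), 2L * cohort_size(coh))
  # rows match single-individual evaluation
  i <- 5L
  one <- phenolr:::gene_loglrs(models[[1]], subset_cohort(coh, i))
  row <- tab[tab$gene == "GENE_A" &
               tab$individual_id == coh$phenotypes$individual_id[i], ]
  expect_equal(row$loglr_hpo, one$loglr_hpo, tolerance = 1e-12)
  expect_equal(row$loglr_growth, one$loglr_growth, tolerance = 1e-12)
  # JSON round trip reproduces the table exactly
  path <- withr::local_tempfile(fileext = ".json")
  write_models_json(models, path)
  back <- read_models_json(path)
  tab2 <- likelihood_table(back, coh)
  expect_equal(tab2, tab, tolerance = 0)
})

test_that("evidence report lists signed supporting and opposing terms", {
  f <- fixture_cohort()
  m <- fit_gene_model(f$cohort, "GENE_A")
  id <- f$cohort$phenotypes$individual_id[1]
  rep <- evidence_report(m, f$cohort, id,
                         weights = c(log(m$prior / (1 - m$prior)),
                                     1, 1, 1, 1))
  expect_true(all(rep$supporting > 0))
  expect_true(all(rep$opposing < 0))
  expect_equal(unname(rep$loglr["hpo"]),
               sum(rep$supporting) + sum(rep$opposing), tolerance = 1e-9)
  expect_true(is.numeric(rep$score))
})
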