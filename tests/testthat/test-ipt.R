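# toy ontology matching a worked selection example:
# top-level A expanded (count over the upper bound), child B retained,
# child C dropped (below the lower bound)
toy_selection_ontology <- function() {
  ontology(c("R", "A", "B", "C"), list(A = "R", B = "A", C = "A"))
}

test_that("term counts equal per-column tallies", {
  m <- matrix(FALSE, 3, 2, dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  expect_identical(unname(term_counts(m)), c(0L, 0L))
  chain <- ontology(c("T0", "T1", "T2"), list(T1 = "T0", T2 = "T1"))
  p <- propagate(chain, annotation_matrix(
    data.frame(individual_id = "i", term_id = "T2")))
  expect_true(all(term_counts(p) == 1L))
  withr::with_seed(5, {
    r <- matrix(stats::runif(20 * 15) < 0.3, 20, 15,
                dimnames = list(sprintf("i%d", 1:20), sprintf("t%d", 1:15)))
  })
  manual <- vapply(seq_len(15), function(j) sum(r[, j]), integer(1))
  expect_identical(unname(term_counts(r)), manual)
})

test_that("selection retains in-band children, expands frequent ones, drops rare ones", {
  ont <- toy_selection_ontology()
  counts <- c(R = 10000, A = 1500, B = 600, C = 150)
  cfg <- ipt_config(10000, lower_frac = 0.02, upper_frac = 0.10)
  got <- select_ipts(ont, counts, cfg)
  expect_setequal(got$term, c("A", "B"))
  expect_identical(got$depth[got$term == "B"], 1L)
  expect_identical(got$top_level[got$term == "B"], "A")
})

test_that("all top-level terms are IPTs even when counts are below bounds", {
  ont <- toy_selection_ontology()
  counts <- c(R = 10000, A = 1, B = 0, C = 0)
  got <- select_ipts(ont, counts, ipt_config(10000))
  expect_identical(got$term, "A")
  expect_identical(got$depth, 0L)
})

test_that("a term reachable from two top-level terms is placed once, under the first", {
  # D reachable from both A (first) and B; both A and B are expanded
  ont <- ontology(c("R", "A", "B", "D"),
                  list(A = "R", B = "R", D = c("A", "B")))
  counts <- c(A = 2000, B = 2000, D = 500)
  got <- select_ipts(ont, counts, ipt_config(10000))
  expect_identical(sum(got$term == "D"), 1L)
  expect_identical(got$top_level[got$term == "D"], "A")
})

test_that("selection equals exhaustive recursive enumeration on random ontologies", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      layers <- sample(2:4, 1)
      branching <- sample(2:4, 1)
      mpf <- stats::runif(1, 0, 0.3)
    })
    ont <- make_ontology(layers = layers, branching = branching,
                         multi_parent_frac = mpf, seed = seed * 13L)
    n <- 1000
    withr::with_seed(seed * 7L, {
      counts <- stats::setNames(
        as.numeric(stats::rbinom(length(ont$terms), n, 0.08)), ont$terms)
    })
    cfg <- ipt_config(n, lower_frac = 0.02, upper_frac = 0.10)
    got <- select_ipts(ont, counts, cfg)
    want <- oracle_select_ipts(ont, counts, cfg$lower, cfg$upper)
    g <- as.data.frame(got)[order(got$term),
                            c("term", "top_level", "depth")]
    w <- want[order(want$term), c("term", "top_level", "depth")]
    rownames(g) <- rownames(w) <- NULL
    expect_identical(g, w)
    # determinism
    again <- select_ipts(ont, counts, cfg)
    expect_identical(got, again)
  }
})

test_that("widening bounds to the whole cohort keeps top levels plus their children", {
  ont <- make_ontology(layers = 3, branching = 3, seed = 4)
  counts <- stats::setNames(rep(5, length(ont$terms)), ont$terms)
  cfg <- ipt_config(10, lower_frac = 1e-9, upper_frac = 1 - 1e-9)
  got <- select_ipts(ont, counts, cfg)
  expected <- unique(c(ont$top_level,
                       unlist(ont$children[ont$top_level])))
  expect_setequal(got$term, expected)
})

test_that("nested-IPT deduplication follows original annotations", {
  # chain R -> P -> M -> C, with P and C both IPTs and M not
  ont <- ontology(c("R", "P", "M", "C"), list(P = "R", M = "P", C = "M"))
  counts <- c(P = 5, M = 5, C = 3)  # M above upper: expanded, not an IPT
  cfg <- ipt_config(10, lower_frac = 0.25, upper_frac = 0.45)
  ipts <- select_ipts(ont, counts, cfg)
  expect_setequal(ipts$term, c("P", "C"))
  m <- annotation_matrix(data.frame(
    individual_id = c("i", "j"), term_id = c("C", "M")),
    individuals = c("i", "j"))
  got <- dedup_ipt_annotations(ont, m, ipts)
  # i annotated at IPT C only: parent IPT P cleared
  expect_true(got["i", "C"])
  expect_false(got["i", "P"])
  # j annotated at non-IPT M: P retained, no intervening IPT
  expect_false(got["j", "C"])
  expect_true(got["j", "P"])
})

test_that("deduplication matches the per-cell oracle on random cohorts", {
  for (seed in 1:4) {
    ont <- make_ontology(layers = 3, branching = 2,
                         multi_parent_frac = 0.3, seed = seed + 50L)
    withr::with_seed(seed, {
      terms <- sample(ont$terms[-1], 10)
      m <- matrix(stats::runif(15 * 10) < 0.25, 15, 10,
                  dimnames = list(sprintf("x%02d", 1:15), terms))
      counts <- term_counts(propagate(ont, m))
    })
    ipts <- select_ipts(ont, counts, ipt_config(15, 0.1, 0.6))
    got <- dedup_ipt_annotations(ont, m, ipts)
    for (i in rownames(m)) {
      orig <- colnames(m)[m[i, ]]
      for (p in ipts$term) {
        expect_identical(
          got[i, p],
          oracle_dedup_cell(ont$parents, orig, ipts$term, p),
          info = paste(seed, i, p))
      }
    }
    # no IPT annotation implied solely by another IPT annotation
    prop <- propagate(ont, m)
    expect_true(all(colSums(got) <=
                      colSums(prop[, ipts$term, drop = FALSE])))
  }
})

test_that("with no nested IPTs the matrix is only restricted to IPT columns", {
  ont <- ontology(c("R", "A", "B"), list(A = "R", B = "R"))
  ipts <- select_ipts(ont, c(A = 1, B = 1), ipt_config(10))
  m <- annotation_matrix(data.frame(individual_id = c("i", "j"),
                                    term_id = c("A", "B")),
                         individuals = c("i", "j"))
  got <- dedup_ipt_annotations(ont, m, ipts)
  expect_identical(got, propagate(ont, m)[, ipts$term])
})

test_that("TF-IDF-IC scores and ranking match direct computation", {
  # 3-gene toy cohort: term t_excl exclusive to gene A at full penetrance
  ids <- sprintf("p%02d", 1:12)
  dx <- stats::setNames(rep(c("A", "B", "C"), each = 4), ids)
  m <- matrix(FALSE, 12, 4,
              dimnames = list(ids, c("t_all", "t_excl", "t_b", "t_rare")))
  m[, "t_all"] <- TRUE
  m[1:4, "t_excl"] <- TRUE
  m[5:8, "t_b"] <- TRUE
  m[c(1, 5), "t_rare"] <- TRUE
  sc <- tf_idf_ic_scores(m, dx)
  # a term annotated to everyone has IC 0 hence score 0 for all genes
  expect_true(all(sc$score[sc$term == "t_all"] == 0))
  # exclusive fully-penetrant term ranks first for its gene
  a <- sc[sc$gene == "A", ]
  expect_identical(a$term[a$rank == 1], "t_excl")
  # against the loop oracle
  want <- oracle_tfidf(m, dx)
  key <- paste(sc$gene, sc$term)
  expect_equal(sc$score[match(paste(want$gene, want$term), key)],
               want$score, tolerance = 1e-12)
  expect_error(tf_idf_ic_scores(m, dx[1:4]), "at least 2 genes")
})

test_that("TF-IDF-IC ranking matches recomputation on a random cohort", {
  withr::with_seed(42, {
    ids <- sprintf("r%02d", 1:50)
    dx <- stats::setNames(sample(c("G1", "G2", "G3"), 30, replace = TRUE),
                          ids[1:30])
    m <- matrix(stats::runif(50 * 12) < 0.25, 50, 12,
                dimnames = list(ids, sprintf("t%02d", 1:12)))
  })
  sc <- tf_idf_ic_scores(m, dx)
  want <- oracle_tfidf(m, dx)
  for (g in unique(sc$gene)) {
    sg <- sc[sc$gene == g, ]
    wg <- want[want$gene == g, ]
    wg <- wg[order(-wg$score, wg$term), ]
    expect_identical(sg$term, wg$term)  # identical ranking incl. tie-break
  }
})

test_that("IPT rank report equals linear-scan lookup", {
  f <- fixture_cohort()
  coh2 <- f$cohort
  # add a second gene so scoring is defined
  coh2$phenotypes$diagnosis[30:39] <- "GENE_B"
  dx <- stats::setNames(coh2$phenotypes$diagnosis,
                        coh2$phenotypes$individual_id)
  dx <- dx[!is.na(dx)]
  prop <- propagate(f$ontology, coh2$annotations)
  sc <- tf_idf_ic_scores(prop, dx)
  rep <- ipt_rank_report(sc, f$ipts)
  ks <- withr::with_seed(3, sample(seq_len(nrow(rep)), 10))
  for (k in ks) {
    g <- rep$gene[k]; t <- rep$term[k]
    sg <- sc[sc$gene == g, ]
    pos <- which(sg$term == t)
    expect_identical(rep$rank[k],
                     if (length(pos) == 0) NA_integer_ else sg$rank[pos])
  }
  # an IPT scored 0 ranks behind every positively scored term for that gene
  zero <- sc$gene == rep$gene[1] & sc$score == 0
  if (any(zero) && any(sc$score[sc$gene == rep$gene[1]] > 0)) {
    expect_true(min(sc$rank[zero]) > max(sc$rank[sc$gene == rep$gene[1] &
                                                   sc$score > 0]))
  }
})
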