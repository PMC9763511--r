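# Independent brute-force oracles. These deliberately avoid the package's
# internal data structures and algorithms: ancestor closures are computed by
# a worklist over the raw parent map, term selection by recursive
# enumeration, densities by explicit kernel sums, and optima by grid search.

# transitive closure of parent edges by repeated lookup (no memoization)
oracle_ancestors <- function(parents, t) {
  seen <- character(0)
  work <- parents[[t]] %||% character(0)
  while (length(work) > 0) {
    p <- work[[1]]
    work <- work[-1]
    if (p %in% seen) next
    seen <- c(seen, p)
    work <- c(work, parents[[p]] %||% character(0))
  }
  sort(seen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-cell annotation closure: individual x term matrix after propagation
oracle_propagate <- function(parents, m, all_terms) {
  reach <- unique(unlist(c(colnames(m),
                           lapply(colnames(m),
                                  function(t) oracle_ancestors(parents, t)))))
  out_terms <- all_terms[all_terms %in% reach]
  res <- matrix(FALSE, nrow(m), length(out_terms),
                dimnames = list(rownames(m), out_terms))
  for (i in seq_len(nrow(m))) {
    for (t in colnames(m)) {
      if (!m[i, t]) next
      res[i, t] <- TRUE
      for (a in oracle_ancestors(parents, t)) res[i, a] <- TRUE
    }
  }
  res
}

# exhaustive recursive enumeration of informative-term selection:
# reach(tl) = nodes reachable from top-level tl via chains of nodes whose
# count exceeds the upper bound; a reached node in [lower, upper] is an IPT.
oracle_select_ipts <- function(ont, counts, lower, upper) {
  cnt <- function(t) if (t %in% names(counts)) as.numeric(counts[[t]]) else 0
  tls <- ont$top_level
  reach_depth <- function(tl) {
    depth <- stats::setNames(integer(0), character(0))
    frontier <- tl
    d <- 0L
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (t in frontier) {
        expandable <- (t == tl) || cnt(t) > upper
        if (!expandable) next
        for (ch in ont$children[[t]]) {
          if (!ch %in% names(depth)) {
            depth[ch] <- d + 1L
            nxt <- c(nxt, ch)
          }
        }
      }
      frontier <- unique(nxt)
      d <- d + 1L
    }
    depth
  }
  reaches <- lapply(tls, reach_depth)
  names(reaches) <- tls
  rows <- data.frame(term = tls, top_level = tls, depth = 0L,
                     stringsAsFactors = FALSE)
  seen <- tls
  for (tl in tls) {
    r <- reaches[[tl]]
    for (t in names(r)) {
      if (t %in% seen) next
      # placement: first top-level (in declared order) whose reach holds t
      first_tl <- tls[vapply(tls, function(x)
        t %in% names(reaches[[x]]), logical(1))][1]
      if (first_tl != tl) next  # will be (or was) handled under first_tl
      if (cnt(t) >= lower && cnt(t) <= upper) {
        rows <- rbind(rows, data.frame(term = t, top_level = tl,
                                       depth = unname(r[t]),
                                       stringsAsFactors = FALSE))
      }
      seen <- c(seen, t)
    }
  }
  rows[order(match(rows$top_level, tls), rows$term), ]
}

# per-cell expectation for the deduplicated IPT matrix: IPT p is kept for an
# individual iff some originally annotated term implies p with no other IPT
# strictly below p on the way
oracle_dedup_cell <- function(parents, original_terms, ipt_terms, p) {
  for (t in original_terms) {
    cl <- c(t, oracle_ancestors(parents, t))
    if (!p %in% cl) next
    mediated <- FALSE
    for (q in intersect(cl, ipt_terms)) {
      if (q != p && p %in% oracle_ancestors(parents, q)) {
        mediated <- TRUE
        break
      }
    }
    if (!mediated) return(TRUE)
  }
  FALSE
}

# direct Gaussian kernel sum
oracle_kernel_density <- function(samples, h, q) {
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    s <- 0
    for (x in samples) s <- s + stats::dnorm((q[i] - x) / h)
    out[i] <- s / (length(samples) * h)
  }
  out
}

# all-pairs AUC with half-credit ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# direct TF-IDF-IC evaluation by loops
oracle_tfidf <- function(m, diagnoses) {
  genes <- sort(unique(unname(diagnoses)))
  out <- list()
  for (g in genes) {
    inds <- names(diagnoses)[diagnoses == g]
    for (term in colnames(m)) {
      cohort_frac <- mean(m[, term])
      if (cohort_frac == 0) next
      g_t <- 0
      for (g2 in genes) {
        i2 <- names(diagnoses)[diagnoses == g2]
        if (any(m[i2, term])) g_t <- g_t + 1
      }
      if (g_t == 0) next
      tf <- mean(m[inds, term])
      idf <- log(length(genes) / g_t)
      ic <- -log(cohort_frac)
      out[[length(out) + 1]] <- data.frame(
        gene = g, term = term, score = tf * idf * ic,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# exhaustive F1 over a lattice of weight vectors
oracle_grid_f1 <- function(lr, labels, grid0, grid) {
  m <- as.matrix(lr[, c("loglr_sex", "loglr_growth", "loglr_dev",
                        "loglr_hpo")])
  best <- 0
  for (w0 in grid0) for (w1 in grid) for (w2 in grid) {
    for (w3 in grid) for (w4 in grid) {
      calls <- (w0 + m %*% c(w1, w2, w3, w4)) > 0
      tp <- sum(calls & labels)
      if (tp == 0) next
      fp <- sum(calls & !labels)
      fn <- sum(!calls & labels)
      p <- tp / (tp + fp)
      r <- tp / (tp + fn)
      f1 <- 2 * p * r / (p + r)
      if (f1 > best) best <- f1
    }
  }
  best
}

# small deterministic cohort with planted structure, built by hand (no
# simulate_cohort), for classifier fixtures
fixture_cohort <- function(n_cases = 10, n_bg = 40, seed = 7,
                           case_female = 0.9) {
  ont <- make_ontology(layers = 2, branching = 3, seed = seed)
  withr::with_seed(seed, {
    n <- n_cases + n_bg
    ids <- sprintf("F%03d", seq_len(n))
    is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_bg))
    sex <- character(n)
    sex[is_case] <- rep(c("female", "male"),
                        c(round(case_female * n_cases),
                          n_cases - round(case_female * n_cases)))
    sex[!is_case] <- rep(c("female", "male"), length.out = n_bg)
    ph <- data.frame(individual_id = ids, sex = sex,
                     stringsAsFactors = FALSE)
    for (f in phenolr:::growth_features()) {
      ph[[f]] <- stats::rnorm(n) + ifelse(is_case & f == "ofc_z", 2, 0)
    }
    for (f in phenolr:::dev_features()) {
      ph[[f]] <- abs(stats::rnorm(n, 10, 2)) +
        ifelse(is_case & f == "walked", 6, 0)
    }
    leaves <- ontology_leaves(ont)
    prob <- matrix(0.1, n, length(leaves), dimnames = list(ids, leaves))
    prob[is_case, 1] <- 0.8
    ann <- matrix(stats::runif(n * length(leaves)), n) < prob
    dimnames(ann) <- dimnames(prob)
    dx <- data.frame(individual_id = ids[is_case], gene = "GENE_A",
                     stringsAsFactors = FALSE)
    coh <- cohort(ph, ann, dx)
    prep <- prepare_ipt_features(ont, coh, lower_frac = 0.02,
                                 upper_frac = 0.4)
    list(ontology = ont, cohort = prep$cohort, ipts = prep$ipts)
  })
}
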