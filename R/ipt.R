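#' Informative-term selection configuration
#'
#' Frequency bounds for informative phenotypic term (IPT) selection, expressed
#' as fractions of the cohort. The defaults (2% and 10%) target terms frequent
#' enough to describe many individuals yet rare enough to retain information
#' content. Bounds are inclusive on both ends.
#'
#' @param cohort_size Number of individuals in the cohort used for counting.
#' @param lower_frac Minimum annotation fraction for a term to be retained.
#' @param upper_frac Fraction above which a term is expanded into its children
#'   instead of being retained.
#' @return A list of class `ipt_config` with elements `lower_frac`,
#'   `upper_frac`, `cohort_size`, `lower` and `upper` (absolute counts).
#' @export
ipt_config <- function(cohort_size, lower_frac = 0.02, upper_frac = 0.10) {
  stopifnot(cohort_size >= 1, lower_frac > 0, lower_frac < upper_frac,
            upper_frac < 1)
  structure(list(lower_frac = lower_frac, upper_frac = upper_frac,
                 cohort_size = cohort_size,
                 lower = lower_frac * cohort_size,
                 upper = upper_frac * cohort_size),
            class = "ipt_config")
}

#' Per-term annotation counts
#'
#' Number of distinct individuals annotated to each term. The input should
#' already be propagated so that counts reflect direct and implied use.
#'
#' @param m Logical annotation matrix (individuals x terms).
#' @return Named integer vector of counts per term.
#' @export
term_counts <- function(m) {
  stopifnot(is.matrix(m))
  counts <- colSums(m)
  storage.mode(counts) <- "integer"
  counts
}

#' Select informative phenotypic terms (IPTs)
#'
#' Top-down frequency-bounded expansion. Every top-level term (child of the
#' root) is an IPT unconditionally. From each top-level term, in declaration
#' order, children are examined breadth-first (children in lexicographic term
#' ID order): a child used by more individuals than the upper bound is
#' expanded (its own children are examined); a child within the bounds
#' (inclusive) is retained as an IPT and not expanded; a child below the lower
#' bound is dropped. A term reachable from several top-level terms is placed
#' under the first top-level term whose traversal reaches it, and recorded
#' once.
#'
#' @param ont A [ontology()] object.
#' @param counts Named vector of propagated annotation counts (terms without
#'   an entry count as zero), as from [term_counts()].
#' @param cfg An [ipt_config()].
#' @return An object of class `phen_ipts`: a data frame with columns `term`,
#'   `label`, `top_level` (the single top-level term the IPT is placed under),
#'   `depth` (levels below its top-level term) and `count`.
#' @export
select_ipts <- function(ont, counts, cfg) {
  stopifnot(inherits(ont, "phen_ontology"), inherits(cfg, "ipt_config"))
  if (length(ont$top_level) == 0L) {
    stop("ontology has no top-level terms (no children of the root)")
  }
  cnt <- function(t) if (t %in% names(counts)) as.numeric(counts[[t]]) else 0
  placed <- character(0)   # IPTs already recorded (any top level)
  visited <- character(0)  # terms already examined (expanded or dropped)
  rows <- list()
  for (tl in ont$top_level) {
    rows[[length(rows) + 1L]] <-
      data.frame(term = tl, label = unname(ont$labels[[tl]]),
                 top_level = tl, depth = 0L, count = cnt(tl),
                 stringsAsFactors = FALSE)
    placed <- c(placed, tl)
    kids0 <- sort(ont$children[[tl]])
    queue <- data.frame(term = kids0,
                        depth = rep(1L, length(kids0)),
                        stringsAsFactors = FALSE)
    while (nrow(queue) > 0L) {
      t <- queue$term[1L]; d <- queue$depth[1L]
      queue <- queue[-1L, , drop = FALSE]
      if (t %in% placed || t %in% visited) next
      n <- cnt(t)
      if (n > cfg$upper) {
        visited <- c(visited, t)
        kids <- sort(ont$children[[t]])
        if (length(kids) > 0L) {
          queue <- rbind(queue,
                         data.frame(term = kids,
                                    depth = rep(d + 1L, length(kids)),
                                    stringsAsFactors = FALSE))
        }
      } else if (n >= cfg$lower) {
        rows[[length(rows) + 1L]] <-
          data.frame(term = t, label = unname(ont$labels[[t]]),
                     top_level = tl, depth = d, count = n,
                     stringsAsFactors = FALSE)
        placed <- c(placed, t)
      } else {
        visited <- c(visited, t)  # below lower bound: dropped, not expanded
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phen_ipts", "data.frame")
  out
}

#' @export
print.phen_ipts <- function(x, ...) {
  cat("<phen_ipts> ", nrow(x), " informative terms under ",
      length(unique(x$top_level)), " top-level terms\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Build the IPT-modified annotation matrix
#'
#' Propagates the original annotations and then removes redundancy between
#' nested IPTs: an individual's annotation to an IPT `p` is deleted when every
#' originally annotated term that implies `p` also implies another IPT
#' strictly below `p` (i.e. the annotation to `p` arises only through
#' propagation from descendant IPTs). Annotations to `p` implied by a
#' descendant with no intervening IPT — including direct annotation to `p`
#' itself — are retained. The result is restricted to IPT columns.
#'
#' Note `m` must be the original (pre-propagation) annotation matrix:
#' redundancy is judged against what was originally recorded, which a
#' propagated matrix no longer distinguishes. Passing an already-propagated
#' matrix treats every implied term as original and removes nothing.
#'
#' @param ont A [ontology()] object.
#' @param m Original logical annotation matrix (individuals x terms).
#' @param ipts A [select_ipts()] result.
#' @return Logical matrix, individuals x IPT terms (in IPT order).
#' @export
dedup_ipt_annotations <- function(ont, m, ipts) {
  stopifnot(inherits(ont, "phen_ontology"), is.matrix(m),
            inherits(ipts, "phen_ipts"))
  ipt_terms <- ipts$term
  # per original term t: the IPTs t supports directly, i.e. IPT p in
  # closure(t) with no other IPT of closure(t) strictly below p
  support <- function(t) {
    cl <- c(t, ont$ancestors[[t]])
    cand <- intersect(cl, ipt_terms)
    keep <- vapply(cand, function(p) {
      below <- cand[cand != p & vapply(cand, function(q)
        p %in% ont$ancestors[[q]], logical(1))]
      length(below) == 0L
    }, logical(1))
    cand[keep]
  }
  sup <- lapply(stats::setNames(colnames(m), colnames(m)), support)
  res <- matrix(FALSE, nrow = nrow(m), ncol = length(ipt_terms),
                dimnames = list(rownames(m), ipt_terms))
  for (t in colnames(m)) {
    rows <- which(m[, t])
    if (length(rows) == 0L || length(sup[[t]]) == 0L) next
    res[rows, match(sup[[t]], ipt_terms)] <- TRUE
  }
  res
}

#' TF-IDF-IC term scores per gene
#'
#' Ranks terms per gene by the product of term frequency within the gene's
#' diagnosed individuals (TF), log inverse gene-document frequency (IDF,
#' natural log of the number of genes over the number of genes with at least
#' one annotated individual for the term) and information content (IC,
#' negative natural log of the cohort-wide annotation fraction). Terms
#' annotated to no individual cohort-wide are excluded (IC undefined). This is
#' the conventional information-retrieval baseline the informative-term set
#' is compared against.
#'
#' @param m Propagated logical annotation matrix over the whole cohort.
#' @param diagnoses Named character vector: individual ID -> gene symbol, for
#'   diagnosed individuals. At least two distinct genes are required.
#' @return Data frame with columns `gene`, `term`, `tf`, `idf`, `ic`, `score`
#'   and `rank` (per-gene descending score, ties broken by term ID).
#' @export
tf_idf_ic_scores <- function(m, diagnoses) {
  stopifnot(is.matrix(m))
  diagnoses <- diagnoses[names(diagnoses) %in% rownames(m)]
  genes <- sort(unique(unname(diagnoses)))
  if (length(genes) < 2L) stop("need at least 2 genes with diagnoses")
  cohort_frac <- colMeans(m)
  terms <- colnames(m)[cohort_frac > 0]
  ic <- -log(cohort_frac[terms])
  tf_mat <- vapply(genes, function(g) {
    colMeans(m[names(diagnoses)[diagnoses == g], terms, drop = FALSE])
  }, numeric(length(terms)))  # terms x genes
  tf_mat <- matrix(tf_mat, nrow = length(terms),
                   dimnames = list(terms, genes))
  g_t <- rowSums(tf_mat > 0)
  out <- do.call(rbind, lapply(genes, function(g) {
    keep <- g_t > 0
    tf <- tf_mat[keep, g]
    idf <- log(length(genes) / g_t[keep])
    df <- data.frame(gene = g, term = terms[keep], tf = unname(tf),
                     idf = unname(idf), ic = unname(ic[keep]),
                     stringsAsFactors = FALSE)
    df$score <- df$tf * df$idf * df$ic
    df <- df[order(-df$score, df$term), ]
    df$rank <- seq_len(nrow(df))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Rank positions of IPTs within per-gene TF-IDF-IC rankings
#'
#' For each gene, reports where each informative term falls in that gene's
#' full TF-IDF-IC ranking (the data behind a rank-occurrence heat map). IPTs
#' excluded from scoring (zero cohort-wide use) get rank `NA`.
#'
#' @param scores A [tf_idf_ic_scores()] result.
#' @param ipts A [select_ipts()] result.
#' @return Data frame with columns `gene`, `term`, `rank`.
#' @export
ipt_rank_report <- function(scores, ipts) {
  stopifnot(inherits(ipts, "phen_ipts"))
  genes <- unique(scores$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    sg <- scores[scores$gene == g, ]
    data.frame(gene = g, term = ipts$term,
               rank = sg$rank[match(ipts$term, sg$term)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write an IPT set to TSV
#'
#' Columns: `term_id`, `label`, `top_level_term`, `depth`, `cohort_count`.
#'
#' @param ipts A [select_ipts()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ipts <- function(ipts, path) {
  df <- data.frame(term_id = ipts$term, label = ipts$label,
                   top_level_term = ipts$top_level, depth = ipts$depth,
                   cohort_count = ipts$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
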