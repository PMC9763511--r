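#' Construct a phenotype ontology
#'
#' Builds a rooted directed acyclic graph of phenotype terms from a term list
#' and `is_a` parent edges. Terms that cannot reach the root via parent edges
#' are dropped with a message (this is how annotations outside the
#' "Phenotypic abnormality" subtree, e.g. inheritance modifiers, are kept out
#' of the model). Cycles are a validation error.
#'
#' @param terms Character vector of term IDs, in declaration order. The order
#'   matters: top-level terms are traversed in this order during informative
#'   term selection.
#' @param parents Named list mapping a term ID to the character vector of its
#'   `is_a` parents. Terms absent from the list are treated as parentless.
#' @param labels Optional named character vector of human-readable term names.
#' @param root Term ID of the root ("Phenotypic abnormality" analogue). If
#'   `NULL`, the unique parentless term is used; multiple parentless terms
#'   without an explicit root are an error.
#' @param alt_ids Optional named character vector mapping alternate IDs to
#'   primary term IDs (used to remap annotations).
#' @return An object of class `phen_ontology`: a list with elements `terms`,
#'   `parents`, `children`, `labels`, `root`, `top_level` (children of the
#'   root, in `terms` order), `ancestors` (precomputed strict-ancestor sets)
#'   and `alt_ids`.
#' @export
ontology <- function(terms, parents, labels = NULL, root = NULL,
                     alt_ids = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    stop("duplicate term IDs: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  full <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) full[[t]] <- character(0)
  for (t in intersect(names(parents), terms)) {
    ps <- unique(as.character(parents[[t]]))
    bad <- setdiff(ps, terms)
    if (length(bad) > 0) {
      stop("term ", t, " has unknown parent(s): ", paste(bad, collapse = ", "))
    }
    full[[t]] <- ps
  }
  parentless <- terms[vapply(full, length, 1L) == 0L]
  if (is.null(root)) {
    if (length(parentless) != 1L) {
      stop("cannot infer root: ", length(parentless),
           " parentless terms; supply `root` explicitly")
    }
    root <- parentless
  } else if (!root %in% terms) {
    stop("declared root ", root, " is not among the terms")
  }

  anc <- compute_ancestors(terms, full)
  reaches <- vapply(terms, function(t) t == root || root %in% anc[[t]],
                    logical(1))
  if (any(!reaches)) {
    message("dropping ", sum(!reaches),
            " term(s) not descending from root ", root, ": ",
            paste(utils::head(terms[!reaches], 10L), collapse = ", "),
            if (sum(!reaches) > 10L) ", ..." else "")
    terms <- terms[reaches]
    full <- lapply(full[terms], function(ps) intersect(ps, terms))
    anc <- compute_ancestors(terms, full)
  }

  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) children[[t]] <- character(0)
  for (t in terms) for (p in full[[t]]) children[[p]] <- c(children[[p]], t)

  if (is.null(labels)) labels <- stats::setNames(terms, terms)
  labels <- labels[intersect(names(labels), terms)]
  missing_lab <- setdiff(terms, names(labels))
  labels[missing_lab] <- missing_lab

  structure(list(
    terms = terms,
    parents = full,
    children = children,
    labels = labels[terms],
    root = root,
    top_level = terms[terms %in% children[[root]]],
    ancestors = anc,
    alt_ids = alt_ids %||% stats::setNames(character(0), character(0))
  ), class = "phen_ontology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoized DFS over parent edges; flags cycles via the in-progress state.
compute_ancestors <- function(terms, parents) {
  anc <- stats::setNames(vector("list", length(terms)), terms)
  state <- stats::setNames(integer(length(terms)), terms)
  visit <- function(t) {
    if (state[[t]] == 1L) {
      stop("cycle detected in ontology involving term ", t, call. = FALSE)
    }
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    res <- character(0)
    for (p in parents[[t]]) res <- c(res, p, visit(p))
    anc[[t]] <<- sort(unique(res))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in terms) visit(t)
  anc
}

#' @export
print.phen_ontology <- function(x, ...) {
  cat("<phen_ontology> ", length(x$terms), " terms, root ", x$root,
      ", ", length(x$top_level), " top-level terms\n", sep = "")
  invisible(x)
}

#' Strict ancestors of a term
#'
#' All terms reachable from `term` by following `is_a` edges, up to and
#' including the root; the term itself is excluded. The root therefore has an
#' empty ancestor set.
#'
#' @param ont A [ontology()] object.
#' @param term A term ID present in the ontology.
#' @return Character vector of ancestor term IDs (sorted).
#' @export
ancestors <- function(ont, term) {
  stopifnot(inherits(ont, "phen_ontology"))
  if (!term %in% ont$terms) stop("unknown term: ", term)
  ont$ancestors[[term]]
}

#' Resolve term IDs against an ontology
#'
#' Maps alternate IDs to their primary ID; unknown IDs become `NA`.
#'
#' @param ont A [ontology()] object.
#' @param ids Character vector of term IDs.
#' @return Character vector of primary IDs with `NA` for unknown input.
#' @export
resolve_terms <- function(ont, ids) {
  ids <- as.character(ids)
  alt <- ont$alt_ids
  hit <- ids %in% names(alt)
  ids[hit] <- alt[ids[hit]]
  ids[!ids %in% ont$terms] <- NA_character_
  ids
}

#' Parse an OBO 1.2 flat file into an ontology
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `is_a`, `alt_id` and
#' `is_obsolete`. Obsolete terms are excluded; their IDs and all `alt_id`s are
#' recorded so annotations citing them can be remapped (alt IDs) or rejected.
#' Only `is_a` edges define the hierarchy; all other relationship types are
#' ignored, matching the phenotype-propagation convention for HPO.
#'
#' @param path Path to an OBO file.
#' @param root Optional root term ID (e.g. `"HP:0000118"` for the real HPO);
#'   if `NULL` the unique parentless term is used.
#' @return A [ontology()] object.
#' @export
load_obo <- function(path, root = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas in ", path)
  other_starts <- grep("^\\[", lines)
  bounds <- c(other_starts, length(lines) + 1L)

  ids <- character(0)
  labels <- character(0)
  parents <- list()
  alt_map <- character(0)
  obsolete <- character(0)

  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, end)]
    body <- body[nzchar(trimws(body))]
    get_field <- function(key) {
      v <- body[startsWith(body, paste0(key, ":"))]
      v <- sub(paste0("^", key, ":\\s*"), "", v)
      sub("\\s*!.*$", "", v)  # strip trailing OBO comments
    }
    id <- get_field("id")
    if (length(id) != 1L || !nzchar(id)) {
      stop("malformed [Term] stanza at line ", s, ": missing id")
    }
    if (isTRUE(tolower(get_field("is_obsolete")) == "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    nm <- get_field("name")
    labels[id] <- if (length(nm) >= 1L) nm[1L] else id
    parents[[id]] <- get_field("is_a")
    for (a in get_field("alt_id")) alt_map[a] <- id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s) in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # remap edge targets given through an alt_id; drop edges to obsolete/unknown
  parents <- lapply(parents, function(ps) {
    hit <- ps %in% names(alt_map)
    ps[hit] <- alt_map[ps[hit]]
    unknown <- setdiff(ps, ids)
    if (length(unknown) > 0) {
      warning("dropping is_a edge(s) to unknown/obsolete term(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    intersect(ps, ids)
  })
  ontology(ids, parents, labels = labels, root = root, alt_ids = alt_map)
}

#' Write an ontology to OBO 1.2
#'
#' Emits one `[Term]` stanza per term with `id`, `name` and `is_a` lines, in
#' the ontology's term order. `load_obo(write_obo(ont))` round-trips the term
#' set and edge set.
#'
#' @param ont A [ontology()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "phen_ontology"))
  out <- c("format-version: 1.2", "")
  for (t in ont$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", ont$labels[[t]]),
             vapply(ont$parents[[t]],
                    function(p) paste0("is_a: ", p, " ! ", ont$labels[[p]]),
                    character(1)),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build a binary annotation matrix from long-format pairs
#'
#' @param pairs Data frame with columns `individual_id` and `term_id`.
#' @param individuals Optional character vector fixing row order (defaults to
#'   order of first appearance); individuals without annotations get all-zero
#'   rows.
#' @param terms Optional character vector fixing column order.
#' @return Logical matrix, individuals in rows, terms in columns.
#' @export
annotation_matrix <- function(pairs, individuals = NULL, terms = NULL) {
  stopifnot(all(c("individual_id", "term_id") %in% names(pairs)))
  individuals <- individuals %||% unique(as.character(pairs$individual_id))
  terms <- terms %||% unique(as.character(pairs$term_id))
  m <- matrix(FALSE, nrow = length(individuals), ncol = length(terms),
              dimnames = list(individuals, terms))
  if (nrow(pairs) > 0) {
    i <- match(as.character(pairs$individual_id), individuals)
    j <- match(as.character(pairs$term_id), terms)
    if (anyNA(i)) stop("annotation references unknown individual(s)")
    if (anyNA(j)) stop("annotation references term(s) outside `terms`")
    m[cbind(i, j)] <- TRUE
  }
  m
}

#' Propagate annotations to all ancestor terms
#'
#' Applies the true-path rule: an annotation to a term implies annotation to
#' every ancestor of that term. Columns are added for ancestors not present in
#' the input; column order follows the ontology's term order. The operation is
#' idempotent and never removes an annotation.
#'
#' @param ont A [ontology()] object.
#' @param m Logical annotation matrix (individuals x terms); all columns must
#'   be ontology terms.
#' @return Logical matrix with the propagated annotations.
#' @export
propagate <- function(ont, m) {
  stopifnot(inherits(ont, "phen_ontology"), is.matrix(m))
  in_terms <- colnames(m)
  bad <- setdiff(in_terms, ont$terms)
  if (length(bad) > 0) {
    stop("annotation matrix has term(s) not in the ontology: ",
         paste(bad, collapse = ", "))
  }
  reach <- unique(unlist(c(in_terms,
                           lapply(in_terms, function(t) ont$ancestors[[t]])),
                         use.names = FALSE))
  out_terms <- ont$terms[ont$terms %in% reach]
  res <- matrix(FALSE, nrow = nrow(m), ncol = length(out_terms),
                dimnames = list(rownames(m), out_terms))
  for (t in in_terms) {
    rows <- which(m[, t])
    if (length(rows) == 0L) next
    cols <- match(c(t, ont$ancestors[[t]]), out_terms)
    res[rows, cols] <- TRUE
  }
  res
}
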