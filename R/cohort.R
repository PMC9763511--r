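# Feature blocks used throughout: five growth attributes (gestation in
# months, the rest as Z scores against an age/sex reference) and four
# developmental milestones (age in months).
growth_features <- function() {
  c("gestation", "birthweight_z", "height_z", "weight_z", "ofc_z")
}
dev_features <- function() {
  c("walked", "first_words", "social_smile", "sat")
}
quant_features <- function() c(growth_features(), dev_features())

#' Construct a cohort object
#'
#' Bundles the three tables the pipeline operates on: a phenotype table (one
#' row per individual: sex, growth, milestones), raw leaf-level ontology
#' annotations, and diagnoses. A `diagnosis` column is derived on the
#' phenotype table holding the gene for individuals with exactly one recorded
#' diagnosis and `NA` otherwise (none, or more than one).
#'
#' @param phenotypes Data frame with columns `individual_id`, `sex`
#'   ("male"/"female", `NA` allowed) and the nine quantitative features
#'   `gestation`, `birthweight_z`, `height_z`, `weight_z`, `ofc_z`, `walked`,
#'   `first_words`, `social_smile`, `sat` (`NA` allowed).
#' @param annotations Logical matrix (individuals x terms) of original,
#'   unpropagated annotations; row names must match `individual_id`s.
#' @param diagnoses Data frame with columns `individual_id`, `gene`; an
#'   individual may appear more than once (multiple diagnoses).
#' @param ipt_matrix Optional IPT-modified annotation matrix (see
#'   [dedup_ipt_annotations()]); required before model fitting.
#' @return An object of class `phen_cohort`.
#' @export
cohort <- function(phenotypes, annotations, diagnoses, ipt_matrix = NULL) {
  req <- c("individual_id", "sex", quant_features())
  missing_cols <- setdiff(req, names(phenotypes))
  if (length(missing_cols) > 0) {
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(phenotypes$individual_id)
  if (anyDuplicated(ids)) {
    stop("duplicate individual_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad_sex <- !is.na(phenotypes$sex) &
    !phenotypes$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("sex outside {male, female} for individual(s): ",
         paste(ids[bad_sex], collapse = ", "))
  }
  stopifnot(is.matrix(annotations))
  extra <- setdiff(rownames(annotations), ids)
  if (length(extra) > 0) {
    stop("annotation matrix has unknown individual(s): ",
         paste(extra, collapse = ", "))
  }
  # align annotation rows to the phenotype table; absent rows become all-zero
  ann <- matrix(FALSE, nrow = length(ids), ncol = ncol(annotations),
                dimnames = list(ids, colnames(annotations)))
  present <- intersect(ids, rownames(annotations))
  ann[present, ] <- annotations[present, , drop = FALSE]
  if (length(present) < length(ids)) {
    warning(length(ids) - length(present),
            " individual(s) have no annotations; empty term sets assumed",
            call. = FALSE)
  }
  stopifnot(all(c("individual_id", "gene") %in% names(diagnoses)))
  diagnoses$individual_id <- as.character(diagnoses$individual_id)
  ndiag <- table(diagnoses$individual_id)
  single <- names(ndiag)[ndiag == 1L]
  dx <- stats::setNames(rep(NA_character_, length(ids)), ids)
  hit <- diagnoses$individual_id %in% single
  dx[diagnoses$individual_id[hit]] <- diagnoses$gene[hit]
  phenotypes$individual_id <- ids
  phenotypes$diagnosis <- unname(dx[ids])
  structure(list(phenotypes = phenotypes, annotations = ann,
                 diagnoses = diagnoses, ipt_matrix = ipt_matrix),
            class = "phen_cohort")
}

#' @export
print.phen_cohort <- function(x, ...) {
  cat("<phen_cohort> ", nrow(x$phenotypes), " individuals, ",
      sum(!is.na(x$phenotypes$diagnosis)), " with a single diagnosis (",
      length(unique(stats::na.omit(x$phenotypes$diagnosis))), " genes), ",
      ncol(x$annotations), " annotated terms\n", sep = "")
  invisible(x)
}

#' Number of individuals in a cohort
#' @param x A [cohort()] object.
#' @return Integer count.
#' @export
cohort_size <- function(x) nrow(x$phenotypes)

#' Subset a cohort by individual
#'
#' Keeps the given individuals in all component tables (including the IPT
#' matrix if present). Used by cross-validation and the bootstrap; `keep` may
#' contain repeats, as in a bootstrap resample, in which case duplicated
#' individuals are re-identified by a positional suffix.
#'
#' @param x A [cohort()] object.
#' @param keep Integer indices (repeats allowed) or character IDs.
#' @return A [cohort()]-like object (class `phen_cohort`).
#' @export
subset_cohort <- function(x, keep) {
  stopifnot(inherits(x, "phen_cohort"))
  ids <- x$phenotypes$individual_id
  idx <- if (is.character(keep)) match(keep, ids) else as.integer(keep)
  if (anyNA(idx)) stop("subset references unknown individual(s)")
  ph <- x$phenotypes[idx, , drop = FALSE]
  new_ids <- ids[idx]
  if (anyDuplicated(new_ids)) {
    new_ids <- make.unique(new_ids, sep = "__rep")
  }
  ph$individual_id <- new_ids
  rownames(ph) <- NULL
  ann <- x$annotations[idx, , drop = FALSE]
  rownames(ann) <- new_ids
  ipt <- x$ipt_matrix
  if (!is.null(ipt)) {
    ipt <- ipt[idx, , drop = FALSE]
    rownames(ipt) <- new_ids
  }
  dx <- ph$diagnosis
  diag_df <- data.frame(individual_id = new_ids[!is.na(dx)],
                        gene = dx[!is.na(dx)], stringsAsFactors = FALSE)
  structure(list(phenotypes = ph, annotations = ann, diagnoses = diag_df,
                 ipt_matrix = ipt), class = "phen_cohort")
}

#' Attach an IPT-modified annotation matrix to a cohort
#'
#' @param x A [cohort()] object.
#' @param ipt_matrix Logical matrix (individuals x IPT terms) from
#'   [dedup_ipt_annotations()]; rows must cover the cohort's individuals.
#' @return The cohort with `$ipt_matrix` set.
#' @export
set_ipt_matrix <- function(x, ipt_matrix) {
  stopifnot(inherits(x, "phen_cohort"), is.matrix(ipt_matrix))
  ids <- x$phenotypes$individual_id
  if (!all(ids %in% rownames(ipt_matrix))) {
    stop("IPT matrix does not cover all individuals in the cohort")
  }
  x$ipt_matrix <- ipt_matrix[ids, , drop = FALSE]
  x
}
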