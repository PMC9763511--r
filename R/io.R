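# TSV dialect used throughout: UTF-8, tab-separated, header row, "NA" for
# missing, no quoting. Leading '#' lines are treated as comments on read.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(path, " missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a cohort to its three TSV files
#'
#' Emits `phenotypes.tsv` (one row per individual), `annotations.tsv`
#' (long format: `individual_id`, `term_id`) and `diagnoses.tsv`
#' (`individual_id`, `gene`) into a directory — exactly the dialect
#' [load_cohort()] reads.
#'
#' @param x A [cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "phen_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             diagnoses = file.path(dir, "diagnoses.tsv"))
  ph <- x$phenotypes[, c("individual_id", "sex", quant_features())]
  write_tsv(ph, paths[["phenotypes"]])
  idx <- which(x$annotations, arr.ind = TRUE)
  ann <- data.frame(individual_id = rownames(x$annotations)[idx[, 1L]],
                    term_id = colnames(x$annotations)[idx[, 2L]],
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$individual_id, ann$term_id), ]
  write_tsv(ann, paths[["annotations"]])
  write_tsv(x$diagnoses[order(x$diagnoses$individual_id,
                              x$diagnoses$gene), ],
            paths[["diagnoses"]])
  invisible(paths)
}

#' Load a cohort from phenotype, annotation and diagnosis TSVs
#'
#' Validates as it reads: duplicate individuals, sex values outside
#' male/female and annotation terms unknown to the ontology (after alternate
#' ID remapping) are named errors with the offending line; individuals
#' present in the phenotype table but absent from the annotation file get an
#' empty term set with a warning. Per-file row counts are reported via
#' `message()`.
#'
#' @param phenotypes_tsv,annotations_tsv,diagnoses_tsv File paths.
#' @param ont A [ontology()] object used to validate and remap term IDs.
#' @return A [cohort()] object.
#' @export
load_cohort <- function(phenotypes_tsv, annotations_tsv, diagnoses_tsv,
                        ont) {
  stopifnot(inherits(ont, "phen_ontology"))
  ph <- read_tsv_checked(phenotypes_tsv,
                         c("individual_id", "sex", quant_features()))
  ph$individual_id <- as.character(ph$individual_id)
  dup <- duplicated(ph$individual_id)
  if (any(dup)) {
    stop(phenotypes_tsv, ": duplicate individual ",
         ph$individual_id[which(dup)[1L]], " at data line ", which(dup)[1L])
  }
  bad_sex <- which(!is.na(ph$sex) & !ph$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    stop(phenotypes_tsv, ": sex '", ph$sex[bad_sex[1L]],
         "' outside {male, female} at data line ", bad_sex[1L])
  }
  for (f in quant_features()) ph[[f]] <- as.numeric(ph[[f]])

  ann <- read_tsv_checked(annotations_tsv, c("individual_id", "term_id"))
  ann$individual_id <- as.character(ann$individual_id)
  resolved <- resolve_terms(ont, ann$term_id)
  if (anyNA(resolved)) {
    i <- which(is.na(resolved))[1L]
    stop(annotations_tsv, ": unknown term ID '", ann$term_id[i],
         "' at data line ", i)
  }
  unknown_ind <- which(!ann$individual_id %in% ph$individual_id)
  if (length(unknown_ind) > 0) {
    stop(annotations_tsv, ": unknown individual '",
         ann$individual_id[unknown_ind[1L]], "' at data line ",
         unknown_ind[1L])
  }
  ann$term_id <- resolved
  unannotated <- setdiff(ph$individual_id, ann$individual_id)
  if (length(unannotated) > 0) {
    warning(length(unannotated), " individual(s) have no annotations; ",
            "empty term sets assumed (e.g. ", unannotated[1L], ")",
            call. = FALSE)
  }
  m <- annotation_matrix(ann, individuals = ph$individual_id)

  dx <- read_tsv_checked(diagnoses_tsv, c("individual_id", "gene"))
  dx$individual_id <- as.character(dx$individual_id)
  unknown_dx <- which(!dx$individual_id %in% ph$individual_id)
  if (length(unknown_dx) > 0) {
    stop(diagnoses_tsv, ": unknown individual '",
         dx$individual_id[unknown_dx[1L]], "' at data line ",
         unknown_dx[1L])
  }
  message("loaded ", nrow(ph), " individuals, ", nrow(ann),
          " annotations, ", nrow(dx), " diagnoses")
  cohort(ph, m, dx)
}

#' Cohort inclusion filtering
#'
#' Applies the modeling inclusion rules: individuals with multiple recorded
#' diagnoses are dropped (optional), individuals with too few of the nine
#' quantitative fields present are dropped, and — after those drops — genes
#' with fewer than `min_cases_per_gene` diagnosed individuals are not
#' modeled (their individuals remain in the cohort as part of every other
#' gene's complement class). Every excluded individual is logged with a
#' reason code; inclusion and exclusion partition the input.
#'
#' @param x A [cohort()] object.
#' @param min_cases_per_gene Minimum diagnosed individuals for a gene to be
#'   modeled (inclusive; >= 2).
#' @param require_single_diagnosis Drop individuals with more than one
#'   recorded diagnosis.
#' @param min_quant_fields Minimum count of the 9 quantitative fields that
#'   must be non-missing ("relatively complete record").
#' @return List with `cohort` (filtered), `modeled_genes` (character),
#'   `exclusions` (data frame `individual_id`, `reason`).
#' @export
filter_cohort <- function(x, min_cases_per_gene = 10,
                          require_single_diagnosis = TRUE,
                          min_quant_fields = 5) {
  stopifnot(inherits(x, "phen_cohort"), min_cases_per_gene >= 2)
  ph <- x$phenotypes
  n_dx <- table(x$diagnoses$individual_id)
  multi <- names(n_dx)[n_dx > 1L]
  excl <- data.frame(individual_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(ph))
  if (require_single_diagnosis && length(multi) > 0) {
    hit <- ph$individual_id %in% multi
    drop <- drop | hit
    excl <- rbind(excl, data.frame(individual_id = ph$individual_id[hit],
                                   reason = "multiple_diagnoses",
                                   stringsAsFactors = FALSE))
  }
  n_present <- rowSums(!is.na(ph[, quant_features()]))
  hit <- !drop & n_present < min_quant_fields
  drop <- drop | hit
  if (any(hit)) {
    excl <- rbind(excl, data.frame(individual_id = ph$individual_id[hit],
                                   reason = "incomplete_quantitative",
                                   stringsAsFactors = FALSE))
  }
  kept <- subset_cohort(x, which(!drop))
  if (cohort_size(kept) == 0L) {
    stop("no individuals remain after filtering (",
         nrow(excl), " excluded)")
  }
  counts <- table(stats::na.omit(kept$phenotypes$diagnosis))
  modeled <- sort(names(counts)[counts >= min_cases_per_gene])
  message("filter: kept ", cohort_size(kept), "/", nrow(ph),
          " individuals; ", length(modeled), " modelable gene(s)")
  list(cohort = kept, modeled_genes = modeled, exclusions = excl)
}
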