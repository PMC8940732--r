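# Plain-text readers/writers for the pipeline's tabular interchange formats:
# per-subject regional feature TSVs + metadata CSV (aparcstats2table-style),
# case-control map CSVs and region x gene expression TSVs.

#' Write a cohort to per-subject feature TSVs plus a metadata CSV
#'
#' @param subjects List of [subject_morphometry()] objects.
#' @param metadata Cohort metadata data frame.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata CSV path.
#' @export
write_cohort <- function(subjects, metadata, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in subjects) {
    f <- data.frame(region = s$region_labels, s$features, check.names = FALSE)
    utils::write.table(f, file.path(dir, paste0(s$subject_id, "_features.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(metadata, meta_path, row.names = FALSE, quote = FALSE)
  invisible(meta_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Region order in every feature table must match `region_labels` exactly
#' (inputs are rejected rather than silently reordered).
#'
#' @param dir Directory containing `<subject_id>_features.tsv` files and
#'   `metadata.csv`.
#' @param region_labels Expected region order; defaults to the shipped
#'   Desikan-Killiany manifest when the tables have 68 rows.
#' @return List with `subjects` and `metadata`.
#' @export
read_cohort <- function(dir, region_labels = NULL) {
  metadata <- utils::read.csv(file.path(dir, "metadata.csv"),
                              stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    tab <- utils::read.delim(file.path(dir, paste0(m$subject_id, "_features.tsv")),
                             check.names = FALSE)
    feats <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(feats) <- tab$region
    expected <- region_labels
    if (is.null(expected) && nrow(feats) == 68L) expected <- dk_regions()$region
    if (!is.null(expected) && !identical(tab$region, expected)) {
      stop("region order in ", m$subject_id,
           " does not match the expected manifest", call. = FALSE)
    }
    subject_morphometry(m$subject_id, m$group, m$age, m$sex, m$icv, feats)
  })
  list(subjects = subjects, metadata = metadata)
}

#' Write a case-control map to CSV
#'
#' @param map A `case_control_map` from [fit_region_models()].
#' @param path Output CSV path.
#' @export
write_case_control_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a precomputed region x gene expression matrix from TSV
#'
#' Bypasses the donor-level pipeline: first column `region`, remaining
#' columns one per gene.  Values must lie in `[0, 1]`.
#'
#' @param path TSV path.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$region
  m <- m[, order(colnames(m)), drop = FALSE]
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("expression values must lie in [0, 1]", call. = FALSE)
  }
  structure(m, class = c("expression_matrix", class(m)))
}

#' Write an expression matrix to TSV
#'
#' @param mat An `expression_matrix` (regions x genes).
#' @param path Output TSV path.
#' @export
write_expression_matrix <- function(mat, path) {
  tab <- data.frame(region = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
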