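# Gene-set overlap enrichment of the PLS1 gene lists via Fisher's exact
# test, plus GMT reading/writing and omnibus cell-type set construction.

#' Read a GMT gene-set file
#'
#' @param path Tab-delimited GMT file: set name, description, then member
#'   genes.
#' @return Named list of character vectors; descriptions in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Merge study-specific cell-type gene lists into omnibus sets
#'
#' For each cell type, takes the union of the per-study gene lists and
#' intersects it with the background universe (the genes that passed
#' expression preprocessing).  Cell types named in `drop` (e.g. neuron
#' subsets absent from some studies, or pericytes annotated by a single
#' study) are excluded.  Sets that are empty after filtering are kept with
#' size 0 and a warning.
#'
#' @param study_sets Named list (one element per cell type) of lists of
#'   per-study gene vectors.
#' @param background Character vector: the gene universe.
#' @param drop Cell-type names to exclude.
#' @return A `gene_set_collection`: list with `sets` and `background`.
#' @export
build_omnibus_celltype_sets <- function(study_sets, background,
                                        drop = character(0)) {
  study_sets <- study_sets[setdiff(names(study_sets), drop)]
  sets <- lapply(study_sets, function(studies) {
    intersect(unique(unlist(studies)), background)
  })
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    warning("empty omnibus set(s) after background filtering: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, background = unique(background)),
            class = "gene_set_collection")
}

#' Fisher's exact overlap enrichment
#'
#' For each gene set, forms the 2x2 table of the target list against the set
#' within the background universe and tests whether the overlap exceeds the
#' random-subset expectation (the null is that the odds ratio is no larger
#' than 1).  The default test is one-sided ("greater"), equal to the
#' hypergeometric upper tail; the odds ratio is the conditional
#' maximum-likelihood estimate from [stats::fisher.test()], with the sample
#' odds ratio (`ad/bc`, Haldane 0.5-corrected when a cell is zero) also
#' reported.  P-values are BH-adjusted across the sets tested in one call.
#'
#' @param target Character vector (e.g. PLS1+ genes); must be a subset of
#'   `background`.
#' @param sets Named list of gene sets (filtered to `background`).
#' @param background Gene universe.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return Data frame `set, n_set, n_target, overlap, odds_ratio, sample_or,
#'   p, p_fdr`; zero-size sets get `NA` odds ratio and p = 1.
#' @export
fisher_enrichment <- function(target, sets, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  bad <- setdiff(target, background)
  if (length(bad)) {
    stop("target gene(s) outside the background: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  target <- unique(target)
  if (!is.list(sets)) sets <- list(set = sets)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    a <- length(intersect(target, s))
    b <- length(target) - a
    cc <- length(s) - a
    d <- length(background) - a - b - cc
    if (length(s) == 0L || length(target) == 0L) {
      return(data.frame(set = nm, n_set = length(s), n_target = length(target),
                        overlap = a, odds_ratio = NA_real_, sample_or = NA_real_,
                        p = 1, stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                             alternative = alternative)
    sor <- if (a * d == 0 || b * cc == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else (a * d) / (b * cc)
    data.frame(set = nm, n_set = length(s), n_target = length(target),
               overlap = a, odds_ratio = unname(ft$estimate),
               sample_or = sor, p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment panels for the PLS1 gene lists
#'
#' Runs [fisher_enrichment()] of the PLS1+ and PLS1- lists against each
#' supplied collection (e.g. cell types, pain genes, disorder genes), with
#' FDR correction applied within each panel (for cell types, across the cell
#' types tested).
#'
#' @param pls_result A `pls_result` from [pls_bootstrap_z()], or a list with
#'   `pls1_plus` and `pls1_minus` character vectors.
#' @param collections Named list of `gene_set_collection` objects (or lists
#'   with `sets` and `background`).
#' @return Nested list: `result[[panel]][[list]]` is an
#'   `enrichment_result`, for `list` in `pls1_plus`, `pls1_minus`.
#' @export
run_enrichment_panels <- function(pls_result, collections) {
  stopifnot(length(pls_result$pls1_plus) > 0L || length(pls_result$pls1_minus) > 0L)
  lapply(collections, function(coll) {
    list(
      pls1_plus = fisher_enrichment(
        intersect(pls_result$pls1_plus, coll$background),
        coll$sets, coll$background),
      pls1_minus = fisher_enrichment(
        intersect(pls_result$pls1_minus, coll$background),
        coll$sets, coll$background))
  })
}
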