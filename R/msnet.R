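#' Construct a subject morphometry record
#'
#' One subject's regional structural features plus the covariates used in
#' case-control models.  The five canonical features are gray matter volume
#' (mm^3), surface area (mm^2), cortical thickness (mm), mean curvature
#' (mm^-1) and Gaussian curvature (mm^-2), but any >= 2 features are
#' accepted.
#'
#' @param subject_id Character scalar.
#' @param group `"case"` or `"control"`.
#' @param age Years.
#' @param sex 0/1 indicator.
#' @param icv Total intracranial volume (mm^3).
#' @param features Numeric region x feature matrix with region rownames and
#'   feature colnames; all values finite.
#' @param region_labels Expected region order; defaults to the rownames of
#'   `features`.
#' @return A `subject_morphometry` object.
#' @export
subject_morphometry <- function(subject_id, group, age, sex, icv, features,
                                region_labels = rownames(features)) {
  group <- match.arg(group, c("case", "control"))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 3L) stop("need at least 3 regions", call. = FALSE)
  if (ncol(features) < 2L) stop("need at least 2 features", call. = FALSE)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  if (is.null(region_labels)) stop("region labels required", call. = FALSE)
  if (!identical(rownames(features), region_labels)) {
    stop("feature rownames must match region_labels exactly", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         age = as.numeric(age), sex = as.numeric(sex), icv = as.numeric(icv),
         features = features, region_labels = region_labels),
    class = "subject_morphometry")
}

# Reject cohorts whose subjects disagree on region order.
check_cohort_regions <- function(subjects) {
  labs <- subjects[[1L]]$region_labels
  same <- vapply(subjects, function(s) identical(s$region_labels, labs), logical(1))
  if (!all(same)) stop("all subjects must share an identical region order", call. = FALSE)
  labs
}

#' Z-score regional features
#'
#' Each feature is normalised to mean 0, SD 1 (sample SD, n-1 denominator).
#' With `scope = "within_subject"` the mean/SD are taken over a subject's own
#' regions, feature by feature; with `scope = "dataset_pooled"` they are taken
#' over all regions of all subjects jointly.  The wording "sample mean and
#' standard deviation" admits both readings, so both are offered; the scope
#' used is recorded as an attribute.
#'
#' @param subjects List of [subject_morphometry()] objects.
#' @param scope `"within_subject"` (default) or `"dataset_pooled"`.
#' @return The subjects with normalised feature matrices; attribute
#'   `norm_scope` records the scope.
#' @export
normalize_features <- function(subjects,
                               scope = c("within_subject", "dataset_pooled")) {
  scope <- match.arg(scope)
  stopifnot(length(subjects) >= 1L)
  check_cohort_regions(subjects)
  zscore <- function(x, mu, s, feat) {
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("feature '%s' has zero variance in the normalization scope", feat),
           call. = FALSE)
    }
    (x - mu) / s
  }
  if (scope == "within_subject") {
    subjects <- lapply(subjects, function(s) {
      f <- s$features
      for (k in seq_len(ncol(f))) {
        f[, k] <- zscore(f[, k], mean(f[, k]), stats::sd(f[, k]), colnames(f)[k])
      }
      s$features <- f
      s
    })
  } else {
    pooled <- do.call(rbind, lapply(subjects, `[[`, "features"))
    mu <- colMeans(pooled)
    s <- apply(pooled, 2L, stats::sd)
    subjects <- lapply(subjects, function(sub) {
      f <- sub$features
      for (k in seq_len(ncol(f))) {
        f[, k] <- zscore(f[, k], mu[k], s[k], colnames(f)[k])
      }
      sub$features <- f
      sub
    })
  }
  attr(subjects, "norm_scope") <- scope
  subjects
}

#' Compute a subject's morphometric-similarity matrix
#'
#' The MS matrix is the region x region Pearson correlation of normalised
#' feature vectors: entry (j, k) is the correlation, across features, between
#' region j's and region k's feature profiles.  The diagonal is stored as 1
#' but excluded from every downstream summary.  A region whose feature vector
#' has zero variance yields missing edges (reported via a warning and the
#' `n_missing_edges` attribute).
#'
#' @param subject A normalised [subject_morphometry()].
#' @return An `ms_matrix` object: list with `subject_id` and the symmetric
#'   `matrix`.
#' @export
compute_ms_matrix <- function(subject) {
  f <- subject$features
  if (ncol(f) < 2L) stop("need at least 2 features", call. = FALSE)
  sds <- apply(f, 1L, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  m <- suppressWarnings(stats::cor(t(f)))
  if (length(degenerate)) {
    m[degenerate, ] <- NA_real_
    m[, degenerate] <- NA_real_
    warning(sprintf("subject %s: %d region(s) with zero-variance features; edges set missing",
                    subject$subject_id, length(degenerate)), call. = FALSE)
  }
  diag(m) <- 1
  dimnames(m) <- list(subject$region_labels, subject$region_labels)
  structure(list(subject_id = subject$subject_id, matrix = m,
                 n_missing_regions = length(degenerate)),
            class = "ms_matrix")
}

#' Regional and global MS profile
#'
#' Regional MS of region j is the mean of row j of the MS matrix excluding
#' the diagonal (the node's weighted degree, "hubness"); global MS is the
#' mean of the regional values.  Missing edges are dropped from the row means
#' (mean over available edges).
#'
#' @param ms An `ms_matrix`.
#' @return A `regional_ms_profile`: list with `subject_id`, named
#'   `regional_ms` vector and `global_ms`.
#' @export
regional_profile <- function(ms) {
  m <- ms$matrix
  diag(m) <- NA_real_
  regional <- rowMeans(m, na.rm = TRUE)
  regional[!is.finite(regional)] <- NA_real_
  structure(list(subject_id = ms$subject_id, regional_ms = regional,
                 global_ms = mean(regional, na.rm = TRUE)),
            class = "regional_ms_profile")
}

#' Run the MS pipeline over a cohort
#'
#' Normalises features, computes each subject's MS matrix and collects the
#' regional profiles into a subjects x regions matrix.
#'
#' @param subjects List of [subject_morphometry()] objects.
#' @inheritParams normalize_features
#' @param exclude_features Optional character vector of feature names to drop
#'   before normalisation (used by the leave-one-feature-out analysis).
#' @return List with `regional` (subjects x regions matrix, rownames =
#'   subject ids), `global` (named vector) and `norm_scope`.
#' @export
ms_pipeline <- function(subjects, scope = c("within_subject", "dataset_pooled"),
                        exclude_features = NULL) {
  scope <- match.arg(scope)
  if (!is.null(exclude_features)) {
    subjects <- lapply(subjects, function(s) {
      keep <- setdiff(colnames(s$features), exclude_features)
      if (length(keep) < 2L) stop("fewer than 2 features remain after exclusion", call. = FALSE)
      s$features <- s$features[, keep, drop = FALSE]
      s
    })
  }
  labs <- check_cohort_regions(subjects)
  norm <- normalize_features(subjects, scope)
  profs <- lapply(norm, function(s) regional_profile(compute_ms_matrix(s)))
  regional <- do.call(rbind, lapply(profs, `[[`, "regional_ms"))
  rownames(regional) <- vapply(subjects, `[[`, character(1), "subject_id")
  colnames(regional) <- labs
  global <- vapply(profs, `[[`, numeric(1), "global_ms")
  names(global) <- rownames(regional)
  list(regional = regional, global = global, norm_scope = scope)
}
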