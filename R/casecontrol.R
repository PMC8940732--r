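# Case-control inference on regional MS: per-region covariate-adjusted OLS,
# leave-one-feature-out sensitivity, cytoarchitectonic aggregation, hub
# susceptibility quadrants and the cross-condition principal component.

# Vectorised OLS of a response matrix on group + age + sex + icv.
# Returns the group-contrast t, its df and derived quantities per column.
ols_group_fit <- function(Y, metadata) {
  Y <- as.matrix(Y)
  if (!all(c("group", "age", "sex", "icv") %in% names(metadata))) {
    stop("metadata needs columns group, age, sex, icv", call. = FALSE)
  }
  if (nrow(Y) != nrow(metadata)) stop("response/metadata row mismatch", call. = FALSE)
  grp <- as.numeric(metadata$group == "case")
  if (sum(grp) < 2L || sum(1 - grp) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  X <- cbind(intercept = 1, case = grp, age = metadata$age,
             sex = metadata$sex, icv = metadata$icv)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit_block <- function(Yb, Xb) {
    qb <- qr(Xb)
    beta <- qr.coef(qb, Yb)
    res <- qr.resid(qb, Yb)
    df <- nrow(Xb) - ncol(Xb)
    sigma2 <- colSums(res^2) / df
    xtxi <- chol2inv(qr.R(qb))[2L, 2L]
    se <- sqrt(sigma2 * xtxi)
    t <- as.numeric(beta[2L, ]) / se
    list(t = t, df = df, estimate = as.numeric(beta[2L, ]))
  }
  ok <- !apply(Y, 2L, anyNA)
  t <- rep(NA_real_, ncol(Y)); est <- t; df <- rep(NA_real_, ncol(Y))
  if (any(ok)) {
    fb <- fit_block(Y[, ok, drop = FALSE], X)
    t[ok] <- fb$t; est[ok] <- fb$estimate; df[ok] <- fb$df
  }
  if (any(!ok)) {
    warning(sprintf("%d region(s) contain missing values; fitted on complete rows",
                    sum(!ok)), call. = FALSE)
    for (j in which(!ok)) {
      keep <- !is.na(Y[, j])
      if (sum(keep) <= ncol(X) + 1L) next
      fb <- fit_block(Y[keep, j, drop = FALSE], X[keep, , drop = FALSE])
      t[j] <- fb$t; est[j] <- fb$estimate; df[j] <- fb$df
    }
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df, estimate = est,
       n_case = sum(grp), n_control = sum(1 - grp))
}

# Signed inverse-normal transform of a two-sided p: monotone in t.
signed_z <- function(t, p) {
  p <- pmax(pmin(p, 1), 1e-300)
  sign(t) * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Fit per-region case-control models
#'
#' Ordinary least squares of regional MS on group with age, sex and
#' intracranial volume as covariates; one model per region.  Reported per
#' region: the group-contrast t statistic, a signed-z transform of its
#' two-sided p (used for the cross-condition PCA), Cohen's d obtained from
#' the adjusted contrast as `d = t * sqrt(1/n1 + 1/n2)`, the raw p and its
#' Benjamini-Hochberg adjustment across regions.
#'
#' @param regional Subjects x regions matrix of regional MS (rownames =
#'   subject ids matching `metadata$subject_id`).
#' @param metadata Data frame with `subject_id`, `group` ("case"/"control"),
#'   `age`, `sex`, `icv`.
#' @param dataset_id Label stored with the map.
#' @return A `case_control_map` data frame: `region, t_stat, z_stat,
#'   cohen_d, p, p_fdr`, with attributes `dataset_id`, `covariates_used`,
#'   `df`, `n_case`, `n_control`.
#' @export
fit_region_models <- function(regional, metadata, dataset_id = "dataset") {
  regional <- as.matrix(regional)
  if (!is.null(rownames(regional)) && !is.null(metadata$subject_id)) {
    idx <- match(rownames(regional), metadata$subject_id)
    if (anyNA(idx)) stop("metadata missing some subjects", call. = FALSE)
    metadata <- metadata[idx, , drop = FALSE]
  }
  fit <- ols_group_fit(regional, metadata)
  d <- fit$t * sqrt(1 / fit$n_case + 1 / fit$n_control)
  out <- data.frame(
    region = colnames(regional) %||% paste0("region_", seq_len(ncol(regional))),
    t_stat = fit$t, z_stat = signed_z(fit$t, fit$p), cohen_d = d,
    p = fit$p, p_fdr = stats::p.adjust(fit$p, method = "BH"),
    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "covariates_used") <- c("age", "sex", "icv")
  attr(out, "df") <- fit$df
  attr(out, "n_case") <- fit$n_case
  attr(out, "n_control") <- fit$n_control
  class(out) <- c("case_control_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global MS case-control comparison
#'
#' The same covariate-adjusted model applied to each subject's global MS
#' (mean of the regional values).
#'
#' @param global Named numeric vector of global MS per subject.
#' @inheritParams fit_region_models
#' @return List with `t_stat`, `df`, `p`, `estimate` (adjusted case-control
#'   difference).
#' @export
global_comparison <- function(global, metadata) {
  g <- matrix(global, ncol = 1L, dimnames = list(names(global), "global"))
  if (!is.null(names(global)) && !is.null(metadata$subject_id)) {
    idx <- match(names(global), metadata$subject_id)
    if (anyNA(idx)) stop("metadata missing some subjects", call. = FALSE)
    metadata <- metadata[idx, , drop = FALSE]
  }
  fit <- ols_group_fit(g, metadata)
  list(t_stat = fit$t[1L], df = fit$df[1L], p = fit$p[1L],
       estimate = fit$estimate[1L])
}

#' Leave-one-feature-out sensitivity of the case-control map
#'
#' Recomputes the MS change map with each structural feature excluded before
#' MS calculation and correlates (Spearman) each leave-one-out t map with the
#' all-features map.  The feature whose exclusion changes the topography the
#' most (smallest correlation) is flagged.
#'
#' @param subjects List of [subject_morphometry()] objects (raw features).
#' @inheritParams fit_region_models
#' @param scope Normalisation scope passed to [ms_pipeline()].
#' @return List with `full` (case_control_map), `maps` (per-excluded-feature
#'   maps), `rho` (named Spearman correlations with the full map) and
#'   `most_influential` (feature name minimising rho).
#' @export
leave_one_feature_out <- function(subjects, metadata, dataset_id = "dataset",
                                  scope = "within_subject") {
  feats <- colnames(subjects[[1L]]$features)
  if (length(feats) < 3L) stop("need at least 3 features", call. = FALSE)
  full_pipe <- ms_pipeline(subjects, scope)
  full <- fit_region_models(full_pipe$regional, metadata, dataset_id)
  maps <- lapply(feats, function(f) {
    pipe <- ms_pipeline(subjects, scope, exclude_features = f)
    fit_region_models(pipe$regional, metadata, paste0(dataset_id, "_drop_", f))
  })
  names(maps) <- feats
  rho <- vapply(maps, function(m) {
    stats::cor(m$t_stat, full$t_stat, method = "spearman")
  }, numeric(1))
  list(full = full, maps = maps, rho = rho,
       most_influential = feats[which.min(rho)])
}

#' Aggregate regional MS into cytoarchitectonic classes
#'
#' Each subject's class value is the mean of regional MS over the class's
#' member regions; the per-region case-control machinery is then applied per
#' class.
#'
#' @inheritParams fit_region_models
#' @param class_map Data frame `region, class` covering every column of
#'   `regional`.
#' @return A `case_control_map` with one row per class.
#' @export
aggregate_von_economo <- function(regional, metadata, class_map,
                                  dataset_id = "dataset") {
  regs <- colnames(regional)
  idx <- match(regs, class_map$region)
  if (anyNA(idx)) {
    stop("class map does not cover region(s): ",
         paste(regs[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cls <- class_map$class[idx]
  classes <- sort(unique(cls))
  agg <- vapply(classes, function(cl) {
    rowMeans(regional[, cls == cl, drop = FALSE])
  }, numeric(nrow(regional)))
  colnames(agg) <- classes
  rownames(agg) <- rownames(regional)
  fit_region_models(agg, metadata, dataset_id)
}

#' Hub susceptibility: change vs. healthy-control hubness
#'
#' Correlates (Spearman) the case-control change per region with the mean
#' regional MS in healthy controls, and labels each region with one of four
#' sign quadrants of (control MS, change): low-MS regions that gain MS
#' (dedifferentiation), high-MS regions that gain (hypercoupling), low-MS
#' regions that lose (hyperdifferentiation), high-MS regions that lose
#' (decoupling).  Only the signs matter, so any monotone change statistic
#' (Cohen's d is used by convention) gives identical labels.  Significance of
#' rho against spatial nulls is delegated to [spin_p()].
#'
#' @param delta Numeric change per region (e.g. the `cohen_d` column of a
#'   case-control map), named by region.
#' @param control_ms Mean regional MS in controls, same order.
#' @return List with `rho`, `quadrants` (data frame region/label) and
#'   `percentages` (named, sums to 100).
#' @export
hub_susceptibility <- function(delta, control_ms) {
  if (length(delta) != length(control_ms)) stop("length mismatch", call. = FALSE)
  if (stats::sd(delta) == 0 || stats::sd(control_ms) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  rho <- stats::cor(delta, control_ms, method = "spearman")
  lab <- ifelse(control_ms < 0,
                ifelse(delta >= 0, "dedifferentiation", "hyperdifferentiation"),
                ifelse(delta >= 0, "hypercoupling", "decoupling"))
  lvls <- c("dedifferentiation", "hypercoupling", "hyperdifferentiation", "decoupling")
  pct <- 100 * as.numeric(table(factor(lab, levels = lvls))) / length(lab)
  names(pct) <- lvls
  list(rho = rho,
       quadrants = data.frame(region = names(delta) %||% seq_along(delta),
                              label = lab, stringsAsFactors = FALSE),
       percentages = pct)
}

#' Cross-condition principal component of MS change
#'
#' PCA of the region x condition matrix of case-control signed-z statistics
#' with columns standardised (correlation-matrix PCA), so the eigenvalues sum
#' to the number of conditions and explained variance is
#' `eigenvalue / n_conditions * 100`.  The first component's sign is fixed so
#' that its region scores correlate positively with the mean of the input
#' maps.
#'
#' @param zmat Region x condition numeric matrix (e.g. `z_stat` columns of
#'   [fit_region_models()] maps, one column per condition).
#' @return List with `pc_scores` (PC1 region scores), `scores` (all
#'   components), `explained_variance_pct`, `eigenvalues`, `loadings`.
#' @export
cross_condition_pca <- function(zmat) {
  zmat <- as.matrix(zmat)
  if (ncol(zmat) < 2L) stop("need at least 2 condition maps", call. = FALSE)
  sds <- apply(zmat, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant condition column(s): ",
         paste(colnames(zmat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(zmat, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  expl <- 100 * eig / sum(eig)
  flip <- stats::cor(pc$x[, 1L], rowMeans(scale(zmat)))
  if (is.finite(flip) && flip < 0) {
    pc$x[, 1L] <- -pc$x[, 1L]
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
  }
  list(pc_scores = stats::setNames(pc$x[, 1L], rownames(zmat)),
       scores = pc$x, explained_variance_pct = expl, eigenvalues = eig,
       loadings = pc$rotation)
}

#' Spearman correlation between two cortical maps
#'
#' Ties are mid-ranked.  When a spin-permutation table and geometry are
#' supplied, a spatial-null p-value is attached via [spin_p()].
#'
#' @param map_a,map_b Equal-length numeric vectors.
#' @param spins Optional `spin_null` object from [generate_spins()].
#' @return List with `rho` and, when `spins` is given, `p_spin`.
#' @export
correlate_maps <- function(map_a, map_b, spins = NULL) {
  if (length(map_a) != length(map_b)) stop("length mismatch", call. = FALSE)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("correlation undefined for constant map", call. = FALSE)
  }
  if (is.null(spins)) {
    list(rho = stats::cor(map_a, map_b, method = "spearman"))
  } else {
    sp <- spin_p(map_a, map_b, spins, statistic = "spearman")
    list(rho = sp$rho, p_spin = sp$p_spin)
  }
}
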