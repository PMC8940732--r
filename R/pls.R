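# Partial least squares (univariate response, SIMPLS) linking regional gene
# expression to the cross-condition MS-change map, with permutation inference
# on explained variance and bootstrap inference on gene weights.

# Column z-scoring with a zero-variance guard (degenerate columns -> 0).
scale_cols_safe <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  Xc <- sweep(X, 2L, mu)
  s[s == 0 | !is.finite(s)] <- Inf
  sweep(Xc, 2L, s, `/`)
}

# SIMPLS for a univariate response on pre-centred inputs.  Scores are
# orthonormal, so per-component explained variance in y is q_a^2 / ||y0||^2.
simpls_core <- function(X0, y0, n_components) {
  n <- nrow(X0); G <- ncol(X0)
  A <- min(n_components, n - 1L, G)
  W <- matrix(0, G, A); Tm <- matrix(0, n, A); V <- matrix(0, G, A)
  qv <- numeric(A)
  s <- crossprod(X0, y0)
  a_done <- 0L
  for (a in seq_len(A)) {
    r <- s
    t <- as.numeric(X0 %*% r)
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t <- t / nt; r <- r / nt
    q <- sum(y0 * t)
    if (q < 0) { t <- -t; r <- -r; q <- -q }  # scores align positively with y
    p <- crossprod(X0, t)
    v <- p
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv < 1e-12) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    W[, a] <- r; Tm[, a] <- t; V[, a] <- v; qv[a] <- q
    a_done <- a
  }
  if (a_done < A) {
    W <- W[, seq_len(a_done), drop = FALSE]
    Tm <- Tm[, seq_len(a_done), drop = FALSE]
    qv <- qv[seq_len(a_done)]
  }
  ssy <- sum(y0^2)
  list(weights = W, scores = Tm, y_loadings = qv,
       pct_var_explained = 100 * qv^2 / ssy, n_components = a_done)
}

#' Fit a PLS regression of a cortical map on gene expression
#'
#' Univariate-response SIMPLS: gene expression (regions x genes) predicts a
#' regional map.  Predictor columns and the response are z-scored by default
#' so gene weights are comparable across genes; for a univariate response
#' the first weight vector is proportional to `X'y` (the gene-map
#' covariances).  Component scores are sign-fixed to correlate positively
#' with the response.
#'
#' @param X Regions x genes numeric matrix.
#' @param y Regional response vector (e.g. cross-condition PC1 scores).
#' @param n_components Number of components to extract (capped at
#'   `min(nrow(X) - 1, ncol(X))`).
#' @param scale Z-score `X` columns and `y` before fitting (default TRUE; a
#'   raw-scale fit is available with `FALSE`).
#' @return List with `weights` (genes x components), `scores` (regions x
#'   components), `y_loadings`, `pct_var_explained` (per-component % of
#'   var(y)) and `n_components`.
#' @export
pls_fit <- function(X, y, n_components = 1L, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant predictor column(s): ",
           paste(utils::head(colnames(X)[sds == 0], 5L), collapse = ", "),
           call. = FALSE)
    }
    X0 <- scale_cols_safe(X)
    y0 <- as.numeric(scale(y))
  } else {
    X0 <- sweep(X, 2L, colMeans(X))
    y0 <- y - mean(y)
  }
  fit <- simpls_core(X0, y0, n_components)
  rownames(fit$weights) <- colnames(X)
  rownames(fit$scores) <- rownames(X)
  fit
}

#' Permutation test on PLS explained variance
#'
#' Permutes the response `n_perm` times, refits, and reports for each
#' component the add-one permutation p-value
#' `(1 + #{null pct_var >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams pls_fit
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return List with `observed` (per-component % variance) and `perm_p`.
#' @export
pls_permutation_test <- function(X, y, n_components = 1L, n_perm = 1000L,
                                 seed = 1L, scale = TRUE) {
  stop_if_not_count(n_perm, "n_perm", min = 99L)
  obs_fit <- pls_fit(X, y, n_components, scale = scale)
  obs <- obs_fit$pct_var_explained
  A <- length(obs)
  X0 <- if (scale) scale_cols_safe(as.matrix(X)) else
    sweep(as.matrix(X), 2L, colMeans(X))
  exceed <- numeric(A)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- sample(as.numeric(y))
      y0 <- if (scale) as.numeric(scale(yp)) else yp - mean(yp)
      nul <- simpls_core(X0, y0, A)$pct_var_explained
      nul <- c(nul, rep(0, A - length(nul)))
      exceed <- exceed + (nul >= obs)
    }
  })
  list(observed = obs, perm_p = (1 + exceed) / (n_perm + 1))
}

#' Bootstrap Z-scores and thresholded gene lists for PLS1
#'
#' Resamples the regions with replacement, refits PLS1, sign-aligns each
#' bootstrap weight vector to the original (flipped when their correlation
#' is negative), and scores each gene by `Z = weight / bootstrap SE` (SE =
#' SD over bootstraps).  Gene-level p-values use the normal approximation to
#' Z (two-sided), BH-adjusted over all genes; genes with `Z > z_thresh` form
#' the PLS1+ list, `Z < -z_thresh` PLS1-.  Bootstrap draws with a constant
#' response are redrawn (counted, capped at `10 * n_boot` attempts).
#'
#' @inheritParams pls_fit
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the bootstrap stream.
#' @param z_thresh Threshold for the PLS1+/PLS1- lists (default 3).
#' @return A `pls_result` list: `weights`, `se`, `z_scores`, `p`, `p_fdr`,
#'   `region_scores`, `pct_var_explained`, `pls1_plus`, `pls1_minus`,
#'   `threshold`, `n_redrawn`.
#' @export
pls_bootstrap_z <- function(X, y, n_boot = 1000L, seed = 1L, z_thresh = 3,
                            scale = TRUE) {
  stop_if_not_count(n_boot, "n_boot", min = 100L)
  X <- as.matrix(X)
  y <- as.numeric(y)
  fit <- pls_fit(X, y, 1L, scale = scale)
  w0 <- fit$weights[, 1L]
  n <- nrow(X)
  boots <- matrix(NA_real_, ncol(X), n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    b <- 1L; attempts <- 0L
    while (b <= n_boot && attempts < 10L * n_boot) {
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (stats::sd(yb) == 0) { n_redrawn <- n_redrawn + 1L; next }
      Xb <- X[idx, , drop = FALSE]
      X0 <- if (scale) scale_cols_safe(Xb) else sweep(Xb, 2L, colMeans(Xb))
      y0 <- if (scale) as.numeric(scale(yb)) else yb - mean(yb)
      fb <- simpls_core(X0, y0, 1L)
      if (fb$n_components < 1L) { n_redrawn <- n_redrawn + 1L; next }
      wb <- fb$weights[, 1L]
      if (stats::cor(wb, w0) < 0) wb <- -wb
      boots[, b] <- wb
      b <- b + 1L
    }
    if (b <= n_boot) {
      stop("too many degenerate bootstrap resamples", call. = FALSE)
    }
  })
  se <- apply(boots, 1L, stats::sd)
  z <- w0 / se
  z[se == 0] <- NA_real_
  p <- 2 * stats::pnorm(-abs(z))
  p_fdr <- stats::p.adjust(p, method = "BH")
  genes <- colnames(X) %||% as.character(seq_len(ncol(X)))
  structure(
    list(weights = stats::setNames(w0, genes),
         se = stats::setNames(se, genes),
         z_scores = stats::setNames(z, genes),
         p = stats::setNames(p, genes),
         p_fdr = stats::setNames(p_fdr, genes),
         region_scores = fit$scores[, 1L],
         pct_var_explained = fit$pct_var_explained,
         pls1_plus = genes[!is.na(z) & z > z_thresh],
         pls1_minus = genes[!is.na(z) & z < -z_thresh],
         threshold = z_thresh, n_redrawn = n_redrawn),
    class = "pls_result")
}
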