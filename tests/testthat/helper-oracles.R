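# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders.  The oracles deliberately
# avoid the code paths they verify.

# Pearson correlation from first principles.
brute_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Spearman via explicit mid-ranks + brute Pearson.
brute_spearman <- function(a, b) brute_pearson(rank(a), rank(b))

# OLS group-contrast t via the normal equations.
brute_ols_t <- function(y, metadata) {
  X <- cbind(1, as.numeric(metadata$group == "case"), metadata$age,
             metadata$sex, metadata$icv)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  se <- sqrt((sum(res^2) / df) * solve(XtX)[2, 2])
  t <- beta[2] / se
  list(t = as.numeric(t), p = 2 * pt(-abs(as.numeric(t)), df), df = df)
}

# Upper-tail hypergeometric P(overlap >= a) by direct summation.
brute_hyper_tail <- function(a, n_target, n_set, n_background) {
  ks <- a:min(n_target, n_set)
  sum(exp(lchoose(n_set, ks) + lchoose(n_background - n_set, n_target - ks) -
          lchoose(n_background, n_target)))
}

# Univariate-response PLS via textbook NIPALS with deflation; returns
# normalised score vectors for comparison with the SIMPLS fit.
nipals_pls1 <- function(X, y, n_components) {
  X <- scale(X)
  y <- as.numeric(scale(y))
  scores <- matrix(0, nrow(X), n_components)
  weights <- matrix(0, ncol(X), n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(X, y)
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(X %*% w)
    p <- crossprod(X, t) / sum(t^2)
    q <- sum(y * t) / sum(t^2)
    X <- X - t %*% t(p)
    y <- y - t * q
    scores[, a] <- t / sqrt(sum(t^2))
    weights[, a] <- w
  }
  list(scores = scores, weights = weights)
}

# Hand-built subject with given feature matrix and default covariates.
toy_subject <- function(id, features, group = "control", age = 45, sex = 0,
                        icv = 1.5e6) {
  rownames(features) <- paste0("region_", seq_len(nrow(features)))
  subject_morphometry(id, group, age, sex, icv, features)
}

# Small random cohort of hand-built subjects (no planted structure).
toy_cohort <- function(n_per_group = 10, n_regions = 8, n_features = 5,
                       seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  subjects <- lapply(seq_len(n), function(i) {
    toy_subject(sprintf("s%02d", i),
                matrix(rnorm(n_regions * n_features,
                             mean = rep(seq_len(n_regions), n_features)),
                       n_regions, n_features,
                       dimnames = list(NULL, paste0("f", seq_len(n_features)))),
                group = if (i <= n_per_group) "case" else "control",
                age = runif(1, 25, 65), sex = rbinom(1, 1, 0.5),
                icv = rnorm(1, 1.5e6, 1e5))
  })
  meta <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    group = vapply(subjects, `[[`, character(1), "group"),
    age = vapply(subjects, `[[`, numeric(1), "age"),
    sex = vapply(subjects, `[[`, numeric(1), "sex"),
    icv = vapply(subjects, `[[`, numeric(1), "icv"),
    stringsAsFactors = FALSE)
  list(subjects = subjects, metadata = meta)
}

# Toy donor table on a line of region points 10 mm apart; the intensity
# matrix is supplied directly (samples = one per region unless stated).
toy_donor <- function(donor_id, intensities, above = NULL,
                      probe_to_gene = NULL) {
  ns <- nrow(intensities)
  if (is.null(above)) above <- matrix(TRUE, ns, ncol(intensities),
                                      dimnames = dimnames(intensities))
  if (is.null(probe_to_gene)) {
    probe_to_gene <- data.frame(probe = colnames(intensities),
                                gene = sub("^p_", "", colnames(intensities)),
                                stringsAsFactors = FALSE)
  }
  samples <- data.frame(sample_id = rownames(intensities),
                        x = 10 * seq_len(ns), y = 0, z = 0,
                        hemisphere = "L", division = "cortex",
                        stringsAsFactors = FALSE)
  donor_sample_table(donor_id, samples, intensities, above, probe_to_gene)
}

toy_region_points <- function(n) {
  data.frame(region = paste0("region_", seq_len(n)), x = 10 * seq_len(n),
             y = 0, z = 0, hemisphere = "L", division = "cortex",
             stringsAsFactors = FALSE)
}
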