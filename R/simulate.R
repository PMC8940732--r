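# Synthetic-data generators.  Every downstream stage of the pipeline is
# testable against the planted ground truth these produce: cohorts with a
# known regional-MS shift, donor-level expression with known spatial
# alignment to a target map, and gene sets with a known enrichment odds
# ratio.  Each generator draws from its own seeded RNG stream.

#' Configuration for the cohort generator
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_regions Number of cortical regions (default 68; >= 3).
#' @param n_features Structural features per region (default 5; >= 2).
#' @param effect_map Signed per-region shift of regional MS planted in cases
#'   (case minus control), length `n_regions`; default all zero.
#' @param covariate_effects Named coefficients (`age`, `sex`, `icv`) scaling
#'   how standardised covariates shift a subject's overall coupling (and
#'   hence regional MS).
#' @param noise_sd Within-subject feature noise SD on the latent scale
#'   (> 0).
#' @param seed Integer seed for the subject-level stream.
#' @param template_seed Seed for the fixed regional "profile" template;
#'   cohorts sharing a template share their healthy-control MS topography.
#' @return A `morph_sim_config` list.
#' @export
morph_sim_config <- function(n_cases, n_controls, n_regions = 68L,
                             n_features = 5L,
                             effect_map = rep(0, n_regions),
                             covariate_effects = c(age = 0.01, sex = 0.01,
                                                   icv = 0.01),
                             noise_sd = 0.25, seed = 1L,
                             template_seed = 1000L) {
  stop_if_not_count(n_cases, "n_cases", 2L)
  stop_if_not_count(n_controls, "n_controls", 2L)
  stop_if_not_count(n_regions, "n_regions", 3L)
  stop_if_not_count(n_features, "n_features", 2L)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop("`noise_sd` must be a positive number", call. = FALSE)
  }
  if (length(effect_map) != n_regions) {
    stop("`effect_map` must have length n_regions", call. = FALSE)
  }
  if (!all(c("age", "sex", "icv") %in% names(covariate_effects))) {
    stop("`covariate_effects` needs named entries age, sex, icv", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_regions = as.integer(n_regions),
                 n_features = as.integer(n_features),
                 effect_map = as.numeric(effect_map),
                 covariate_effects = covariate_effects[c("age", "sex", "icv")],
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed),
                 template_seed = as.integer(template_seed)),
            class = "morph_sim_config")
}

# Region labels: the shipped DK manifest when sizes match, generic otherwise.
sim_region_labels <- function(n_regions, hemisphere = "both") {
  reg <- dk_regions(hemisphere)
  if (nrow(reg) == n_regions) reg$region else paste0("region_", seq_len(n_regions))
}

# Fixed cohort template.  Each region's latent feature profile is
#   lambda_j * c  +  tau_j * u_j  +  noise,
# where c is a cluster axis orthogonal to the all-ones feature direction
# (so row-mean centering in the Pearson step does not eat it), lambda_j is
# bimodal (a dominant positively coupled cluster and a smaller anticoupled
# one) and tau_j gives anticoupled regions larger idiosyncratic residuals.
# A region's position along the axis then drives its regional MS
# ("hubness") in a way that survives the per-subject feature z-scoring, and
# perturbing lambda_j is the knob the calibration loop turns to plant MS
# shifts.
cohort_template <- function(cfg) {
  with_seed(derive_seed(cfg$template_seed, 1L), {
    K <- cfg$n_features
    ones <- rep(1 / sqrt(K), K)
    cvec <- stats::rnorm(K)
    cvec <- cvec - sum(cvec * ones) * ones
    cvec <- cvec / sqrt(sum(cvec^2))
    U <- matrix(stats::rnorm(cfg$n_regions * K), cfg$n_regions, K)
    U <- U - (U %*% cvec) %*% t(cvec)
    if (K >= 4L) U <- U - (U %*% ones) %*% t(ones)
    U <- U / sqrt(rowSums(U^2))
    lambda <- ifelse(stats::runif(cfg$n_regions) < 0.7,
                     stats::runif(cfg$n_regions, 0.5, 0.8),
                     stats::runif(cfg$n_regions, -0.9, -0.4))
    tau <- ifelse(lambda > 0, 0.1, 1.0)
    # Plausible raw scales for the five canonical features (volume mm^3,
    # area mm^2, thickness mm, mean curvature mm^-1, Gaussian curvature
    # mm^-2); per-feature z-scoring removes them again.
    scales <- if (K == 5L) c(900, 350, 0.25, 0.02, 0.08) else rep(1, K)
    offsets <- if (K == 5L) c(5200, 1800, 2.5, 0.13, 0.25) else rep(0, K)
    feats <- if (K == 5L) {
      c("gm_volume", "surface_area", "thickness", "mean_curv", "gauss_curv")
    } else paste0("feat_", seq_len(K))
    list(cvec = cvec, U = U, lambda = lambda, tau = tau, scales = scales,
         offsets = offsets, feature_names = feats)
  })
}

# Draw one subject's feature matrix given per-region couplings.
draw_features <- function(tpl, lambda, noise_sd) {
  latent <- lambda * matrix(tpl$cvec, length(lambda), length(tpl$cvec),
                            byrow = TRUE) +
    tpl$tau * tpl$U +
    noise_sd * matrix(stats::rnorm(length(tpl$U)), nrow(tpl$U))
  f <- sweep(sweep(latent, 2L, tpl$scales, `*`), 2L, tpl$offsets, `+`)
  colnames(f) <- tpl$feature_names
  f
}

# Case-arm couplings for a given additive shift and spread multiplier.
case_lambda <- function(tpl, deltas, spread) {
  lbar <- mean(tpl$lambda)
  lbar + (1 + spread) * (tpl$lambda - lbar) + deltas
}

# Mean regional MS for a batch of subjects drawn at given couplings.
mean_regional_ms <- function(tpl, lambda, noise_sd, m, labels) {
  acc <- numeric(length(lambda))
  for (i in seq_len(m)) {
    f <- draw_features(tpl, lambda, noise_sd)
    rownames(f) <- labels
    s <- subject_morphometry(paste0("cal_", i), "control", 45, 0, 1.5e6, f)
    s <- normalize_features(list(s))[[1L]]
    acc <- acc + regional_profile(compute_ms_matrix(s))$regional_ms
  }
  acc / m
}

#' Calibrate latent perturbations for a requested MS effect map
#'
#' There is no closed form from feature-space perturbations to shifts in
#' regional MS, so the generator calibrates empirically against simulated
#' batches.  Three knobs are turned: a multiplier on the coupling spread, a
#' multiplier on the case arm's feature noise (the two global knobs; their
#' regional response patterns are nearly collinear but mix mean and pattern
#' in different proportions, so together they span global level and
#' hub-gradient changes), and per-region additive coupling shifts for the
#' remaining region-specific structure.  Each round measures the induced
#' case-minus-control regional MS difference, solves a least-squares step
#' for the two global knobs against their empirically measured response
#' vectors, and applies damped additive updates to the region shifts, until
#' the induced map is within `tol` (default 10%) of the request or the
#' iteration budget is spent.  Uses an internal RNG stream, so the result
#' is deterministic given the config.
#'
#' @param cfg A [morph_sim_config()].
#' @param m Calibration batch size per iteration (subjects per arm).
#' @param max_iter Inner iteration budget for the region shifts per round.
#' @param tol Relative tolerance on the induced shift.
#' @return Numeric vector of per-region coupling shifts, with attributes
#'   `spread` and `noise_mult` (the calibrated global knobs) and `achieved`
#'   (the last measured shift).
#' @export
calibrate_effect_deltas <- function(cfg, m = 400L, max_iter = 4L, tol = 0.1) {
  d <- cfg$effect_map
  if (all(d == 0)) {
    return(structure(rep(0, cfg$n_regions), spread = 0, noise_mult = 1,
                     achieved = rep(0, cfg$n_regions)))
  }
  tpl <- cohort_template(cfg)
  labels <- sim_region_labels(cfg$n_regions)
  active <- which(abs(d - mean(d)) > 1e-12 | abs(d) > 1e-12)
  delta <- rep(0, cfg$n_regions)
  reg_slope <- 0.15                    # approx. d(regional MS)/d(delta)
  spread <- 0
  nmult <- 1
  clips <- function(s) max(min(s, 3), -0.6)
  clipn <- function(v) max(min(v, 2.5), 0.4)
  achieved <- rep(0, cfg$n_regions)
  glob_tol <- max(tol * max(abs(d)), 1e-3)
  with_seed(derive_seed(cfg$template_seed, 2L), {
    # the control baseline depends only on the template, so measure it once
    # at double precision and reuse it in every iteration
    ctrl <- mean_regional_ms(tpl, tpl$lambda, cfg$noise_sd, 2L * m, labels)
    meas <- function(dl, sp, nv, mm) {
      mean_regional_ms(tpl, case_lambda(tpl, dl, sp), cfg$noise_sd * nv, mm,
                       labels) - ctrl
    }
    # empirical response vectors of the two global knobs (measured once)
    r_s <- meas(delta, 0.3, 1, 2L * m) / 0.3
    r_n <- meas(delta, 0, 0.8, 2L * m) / -0.2
    B <- cbind(r_s, r_n)
    for (outer in seq_len(6L)) {
      achieved <- meas(delta, spread, nmult, 2L * m)
      resid <- d - achieved
      rel_err <- if (length(active)) {
        max(abs(resid[active]) / pmax(abs(d[active]), 5e-3))
      } else 0
      if (rel_err <= tol && abs(mean(resid)) <= glob_tol) break
      # damped least-squares step on (spread, noise) against the residual
      coefs <- tryCatch(qr.solve(B, resid), error = function(e) c(0, 0))
      spread <- clips(spread + 0.8 * coefs[1])
      nmult <- clipn(nmult + 0.8 * coefs[2])
      # region shifts absorb the mean-centred structure the global knobs
      # cannot express; their own net leakage is re-absorbed by the knobs
      # on the next round
      for (it in seq_len(max_iter)) {
        achieved <- meas(delta, spread, nmult, m)
        rc <- d - achieved
        rc <- rc - mean(rc)
        if (max(abs(rc[active]) / pmax(abs(d[active]), 5e-3)) <= tol) break
        delta[active] <- delta[active] + 0.7 * rc[active] / reg_slope
        delta <- pmax(pmin(delta, 1.2), -1.2)
      }
    }
  })
  structure(delta, spread = spread, noise_mult = nmult, achieved = achieved)
}

#' Simulate a case-control morphometry cohort
#'
#' Generates `n_cases + n_controls` subjects whose expected case-minus-
#' control difference in regional MS equals the configured `effect_map` (up
#' to the calibration tolerance and sampling noise).  Covariates are drawn
#' as age ~ U(25, 65) years, sex ~ Bernoulli(0.5), ICV ~ N(1.5e6, 1.5e5)
#' mm^3, and modulate each subject's coupling spread via the configured
#' coefficients (so the case-control models have real covariate signal to
#' adjust for).
#'
#' @param cfg A [morph_sim_config()].
#' @param deltas Optional precomputed coupling shifts from
#'   [calibrate_effect_deltas()] (calibrated from scratch when `NULL`);
#'   passing them explicitly lets Monte-Carlo studies reuse one calibration
#'   across replicate seeds.
#' @return List with `subjects` (list of [subject_morphometry()]),
#'   `metadata` (data frame `subject_id, group, age, sex, icv`) and `truth`
#'   (effect map, calibrated deltas, covariate coefficients, seeds).
#' @export
simulate_cohort <- function(cfg, deltas = NULL) {
  stopifnot(inherits(cfg, "morph_sim_config"))
  if (is.null(deltas)) deltas <- calibrate_effect_deltas(cfg)
  tpl <- cohort_template(cfg)
  labels <- sim_region_labels(cfg$n_regions)
  n <- cfg$n_cases + cfg$n_controls
  group <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  ce <- cfg$covariate_effects
  subjects <- vector("list", n)
  meta <- data.frame(subject_id = sprintf("sub_%03d", seq_len(n)),
                     group = group, age = NA_real_, sex = NA_real_,
                     icv = NA_real_, stringsAsFactors = FALSE)
  spread_case <- attr(deltas, "spread") %||% 0
  nmult_case <- attr(deltas, "noise_mult") %||% 1
  lbar <- mean(tpl$lambda)
  with_seed(derive_seed(cfg$seed, 3L), {
    for (i in seq_len(n)) {
      age <- stats::runif(1L, 25, 65)
      sex <- stats::rbinom(1L, 1L, 0.5)
      icv <- stats::rnorm(1L, 1.5e6, 1.5e5)
      cov_shift <- ce[["age"]] * (age - 45) / 11.55 +
        ce[["sex"]] * (sex - 0.5) +
        ce[["icv"]] * (icv - 1.5e6) / 1.5e5
      s_i <- cov_shift + if (group[i] == "case") spread_case else 0
      lam <- lbar + (1 + s_i) * (tpl$lambda - lbar) +
        if (group[i] == "case") as.numeric(deltas) else 0
      f <- draw_features(tpl, lam, cfg$noise_sd *
                           if (group[i] == "case") nmult_case else 1)
      rownames(f) <- labels
      subjects[[i]] <- subject_morphometry(meta$subject_id[i], group[i],
                                           age, sex, icv, f)
      meta$age[i] <- age; meta$sex[i] <- sex; meta$icv[i] <- icv
    }
  })
  list(subjects = subjects, metadata = meta,
       truth = list(effect_map = cfg$effect_map, deltas = as.numeric(deltas),
                    spread = spread_case, noise_mult = nmult_case,
                    covariate_effects = ce, noise_sd = cfg$noise_sd,
                    seed = cfg$seed, template_seed = cfg$template_seed))
}

#' Configuration for the donor-level expression generator
#'
#' @param n_genes Number of genes (one probe per gene).
#' @param n_regions Number of (left-hemisphere cortical) regions, default
#'   34.
#' @param n_donors Number of donor brains, default 6.
#' @param n_signal_pos,n_signal_neg Numbers of genes with planted positive /
#'   negative spatial alignment to the target map.
#' @param alignment_strength Alignment in `[0, 1]`: 0 = independent, 1 =
#'   perfectly (anti-)correlated in the noiseless limit.
#' @param donor_noise_sd SD of donor- and sample-level intensity noise; 0
#'   makes all donors exact replicates.
#' @param samples_per_region Tissue samples placed near each region centroid
#'   per donor (default 2).
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes, n_regions = 34L, n_donors = 6L,
                                  n_signal_pos = 0L, n_signal_neg = 0L,
                                  alignment_strength = 0.7,
                                  donor_noise_sd = 0.5,
                                  samples_per_region = 2L, seed = 1L) {
  stop_if_not_count(n_genes, "n_genes", 1L)
  stop_if_not_count(n_regions, "n_regions", 3L)
  stop_if_not_count(n_donors, "n_donors", 2L)
  stop_if_not_count(n_signal_pos, "n_signal_pos", 0L)
  stop_if_not_count(n_signal_neg, "n_signal_neg", 0L)
  stop_if_not_prob(alignment_strength, "alignment_strength")
  if (n_signal_pos + n_signal_neg > n_genes) {
    stop("n_signal_pos + n_signal_neg must not exceed n_genes", call. = FALSE)
  }
  if (donor_noise_sd < 0) stop("`donor_noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_regions = as.integer(n_regions),
                 n_donors = as.integer(n_donors),
                 n_signal_pos = as.integer(n_signal_pos),
                 n_signal_neg = as.integer(n_signal_neg),
                 alignment_strength = as.numeric(alignment_strength),
                 donor_noise_sd = as.numeric(donor_noise_sd),
                 samples_per_region = as.integer(samples_per_region),
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate donor-level expression tables aligned to a target map
#'
#' Each signal gene's true regional profile is
#' `a * z(target) + sqrt(1 - a^2) * noise` (negated for the negative-signal
#' group), null genes are independent noise; donors observe the true profile
#' plus donor- and sample-level noise scaled by `donor_noise_sd`.  Samples
#' are jittered around synthetic region centroids (within the 2 mm pass-1
#' assignment radius), all probes are above background, and one probe maps
#' to each gene, so the tables exercise the full donor-processing pipeline.
#'
#' @param cfg An [expression_sim_config()].
#' @param target_map Numeric vector of length `n_regions` (e.g. the
#'   cross-condition PC1 restricted to the left hemisphere).
#' @return List with `tables` (list of [donor_sample_table()]),
#'   `region_points` (geometry for [assign_samples()]) and `truth`
#'   (signal gene ids, true profiles, config echo).
#' @export
simulate_expression <- function(cfg, target_map) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  if (length(target_map) != cfg$n_regions) {
    stop("target_map length must equal n_regions", call. = FALSE)
  }
  if (stats::sd(target_map) == 0) stop("constant target_map", call. = FALSE)
  regions <- sim_region_labels(cfg$n_regions, hemisphere = "L")
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  probes <- paste0("p_", genes)
  sig_pos <- genes[seq_len(cfg$n_signal_pos)]
  sig_neg <- genes[cfg$n_signal_pos + seq_len(cfg$n_signal_neg)]
  tz <- as.numeric(scale(target_map))
  a <- cfg$alignment_strength
  with_seed(derive_seed(cfg$seed, 4L), {
    noise_prof <- matrix(stats::rnorm(cfg$n_regions * cfg$n_genes),
                         cfg$n_regions, cfg$n_genes,
                         dimnames = list(regions, genes))
    signs <- stats::setNames(rep(0, cfg$n_genes), genes)
    signs[sig_pos] <- 1; signs[sig_neg] <- -1
    true_prof <- sweep(noise_prof, 2L, sqrt(1 - ifelse(signs != 0, a^2, 0)), `*`) +
      tz %o% (signs * a)
    # Synthetic mm-space layout: centroids on a coarse 3D grid, one
    # hemisphere, cortical division; spacing far exceeds the 2 mm radius.
    k <- ceiling(cfg$n_regions^(1 / 3))
    grid <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k),
                                  z = seq_len(k)))[seq_len(cfg$n_regions), ] * 10
    region_points <- data.frame(region = regions, x = grid[, 1],
                                y = grid[, 2], z = grid[, 3],
                                hemisphere = "L", division = "cortex",
                                stringsAsFactors = FALSE)
    tables <- lapply(seq_len(cfg$n_donors), function(d) {
      donor_shift <- matrix(stats::rnorm(cfg$n_regions * cfg$n_genes),
                            cfg$n_regions, cfg$n_genes)
      ns <- cfg$n_regions * cfg$samples_per_region
      rid <- rep(seq_len(cfg$n_regions), each = cfg$samples_per_region)
      samples <- data.frame(
        sample_id = sprintf("d%02d_s%03d", d, seq_len(ns)),
        x = region_points$x[rid] + stats::runif(ns, -1, 1),
        y = region_points$y[rid] + stats::runif(ns, -1, 1),
        z = region_points$z[rid] + stats::runif(ns, -1, 1),
        hemisphere = "L", division = "cortex", stringsAsFactors = FALSE)
      inten <- 8 + 1.5 * true_prof[rid, , drop = FALSE] +
        cfg$donor_noise_sd * (donor_shift[rid, , drop = FALSE] +
          matrix(stats::rnorm(ns * cfg$n_genes), ns, cfg$n_genes))
      dimnames(inten) <- list(samples$sample_id, probes)
      donor_sample_table(
        sprintf("donor_%02d", d), samples, inten,
        matrix(TRUE, ns, cfg$n_genes, dimnames = dimnames(inten)),
        data.frame(probe = probes, gene = genes, stringsAsFactors = FALSE))
    })
    list(tables = tables, region_points = region_points,
         truth = list(signal_pos = sig_pos, signal_neg = sig_neg,
                      alignment_strength = a,
                      donor_noise_sd = cfg$donor_noise_sd,
                      true_profiles = true_prof, seed = cfg$seed))
  })
}

#' Configuration for the gene-set generator
#'
#' @param background_size Size of the gene universe.
#' @param set_size Size of the annotated gene set (`<= background_size`).
#' @param target_list_size Size of the target list (`<= background_size`).
#' @param planted_odds_ratio Odds ratio (> 0) of the Fisher noncentral
#'   hypergeometric distribution the overlap is drawn from.
#' @param seed Integer seed.
#' @return A `geneset_sim_config` list.
#' @export
geneset_sim_config <- function(background_size, set_size, target_list_size,
                               planted_odds_ratio = 1, seed = 1L) {
  stop_if_not_count(background_size, "background_size", 1L)
  stop_if_not_count(set_size, "set_size", 0L)
  stop_if_not_count(target_list_size, "target_list_size", 1L)
  if (set_size > background_size) stop("set_size > background_size", call. = FALSE)
  if (target_list_size > background_size) {
    stop("target_list_size > background_size", call. = FALSE)
  }
  if (!is.numeric(planted_odds_ratio) || planted_odds_ratio <= 0 ||
      !is.finite(planted_odds_ratio)) {
    stop("`planted_odds_ratio` must be a positive finite number", call. = FALSE)
  }
  structure(list(background_size = as.integer(background_size),
                 set_size = as.integer(set_size),
                 target_list_size = as.integer(target_list_size),
                 planted_odds_ratio = as.numeric(planted_odds_ratio),
                 seed = as.integer(seed)),
            class = "geneset_sim_config")
}

# Fisher noncentral hypergeometric draw by direct pmf enumeration:
# P(a) proportional to C(K, a) C(N-K, n-a) OR^a over the feasible support.
rnoncentral_hyper <- function(N, K, n, odds_ratio) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  supp <- lo:hi
  if (length(supp) == 1L) return(supp)
  lp <- lchoose(K, supp) + lchoose(N - K, n - supp) + supp * log(odds_ratio)
  lp <- lp - max(lp)
  supp[sample.int(length(supp), 1L, prob = exp(lp))]
}

#' Simulate a gene set and target list with a planted odds ratio
#'
#' The overlap count between the target list and the gene set is drawn from
#' the Fisher noncentral hypergeometric distribution with the configured
#' odds ratio, so the enrichment machinery can be checked for calibration
#' (odds ratio 1) and power (odds ratio > 1) against known truth.
#'
#' @param cfg A [geneset_sim_config()].
#' @return List with `background`, `gene_set`, `target_list` and `truth`
#'   (planted odds ratio, drawn overlap, seed).
#' @export
simulate_genesets <- function(cfg) {
  stopifnot(inherits(cfg, "geneset_sim_config"))
  background <- sprintf("G%06d", seq_len(cfg$background_size))
  with_seed(derive_seed(cfg$seed, 5L), {
    gene_set <- sort(sample(background, cfg$set_size))
    if (cfg$set_size == 0L) {
      overlap <- 0L
      target <- sort(sample(background, cfg$target_list_size))
    } else {
      overlap <- rnoncentral_hyper(cfg$background_size, cfg$set_size,
                                   cfg$target_list_size,
                                   cfg$planted_odds_ratio)
      outside <- setdiff(background, gene_set)
      target <- sort(c(sample(gene_set, overlap),
                       sample(outside, cfg$target_list_size - overlap)))
    }
    list(background = background, gene_set = gene_set, target_list = target,
         truth = list(planted_odds_ratio = cfg$planted_odds_ratio,
                      overlap = overlap, seed = cfg$seed))
  })
}
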