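# Donor-level microarray processing: probe background filtering,
# differential-stability probe selection, sample-to-region assignment,
# robust-sigmoid normalisation and cross-donor averaging into a single
# region x gene expression matrix.

#' Construct a donor sample table
#'
#' @param donor_id Character scalar.
#' @param samples Data frame with `sample_id, x, y, z, hemisphere, division`
#'   (`hemisphere` in `{"L","R"}`, `division` in `{"cortex","subcortex"}`);
#'   coordinates in mm.
#' @param intensities Sample x probe numeric matrix (rownames = sample ids,
#'   colnames = probe ids).
#' @param above_background Logical matrix, same shape as `intensities`.
#' @param probe_to_gene Data frame `probe, gene` covering every probe column.
#' @return A `donor_sample_table` object.
#' @export
donor_sample_table <- function(donor_id, samples, intensities,
                               above_background, probe_to_gene) {
  intensities <- as.matrix(intensities)
  above_background <- as.matrix(above_background)
  if (!identical(dim(intensities), dim(above_background))) {
    stop("intensities and above_background must have identical shape", call. = FALSE)
  }
  if (nrow(samples) != nrow(intensities)) {
    stop("sample metadata / intensity row mismatch", call. = FALSE)
  }
  if (!all(colnames(intensities) %in% probe_to_gene$probe)) {
    stop("probe_to_gene must cover every probe", call. = FALSE)
  }
  structure(list(donor_id = as.character(donor_id), samples = samples,
                 intensities = intensities,
                 above_background = above_background,
                 probe_to_gene = probe_to_gene),
            class = "donor_sample_table")
}

#' Intensity-based probe filtering
#'
#' Discards probes whose intensity is below background in at least half of
#' the samples.  By default the sample fraction is pooled over donors; with
#' `per_donor = TRUE` the criterion must hold within every donor separately.
#'
#' @param tables List of [donor_sample_table()] objects.
#' @param max_below Fraction threshold; a probe is kept iff its
#'   below-background fraction is strictly less than this (default 0.5, i.e.
#'   probes below background in >= 50% of samples are discarded).
#' @param per_donor Apply the criterion within each donor instead of pooled.
#' @return Character vector of retained probe ids.
#' @export
filter_probes <- function(tables, max_below = 0.5, per_donor = FALSE) {
  probes <- colnames(tables[[1L]]$intensities)
  frac_below <- function(tab) {
    colMeans(!tab$above_background[, probes, drop = FALSE])
  }
  if (per_donor) {
    keep <- Reduce(`&`, lapply(tables, function(t) frac_below(t) < max_below))
  } else {
    below <- Reduce(`+`, lapply(tables, function(t) {
      colSums(!t$above_background[, probes, drop = FALSE])
    }))
    total <- sum(vapply(tables, function(t) nrow(t$above_background), integer(1)))
    keep <- (below / total) < max_below
  }
  probes[keep]
}

#' Assign tissue samples to parcels
#'
#' Two-pass assignment.  Pass 1: each sample is assigned to the nearest
#' region representative point sharing its hemisphere and cortical/
#' subcortical division, provided it lies within `radius` mm; otherwise it is
#' left unassigned.  Pass 2: any region that received no sample is given its
#' centroid-nearest same-hemisphere, same-division sample (a sample may serve
#' several regions in this pass), so every region ends up with a value.
#'
#' @param table A [donor_sample_table()].
#' @param region_points Data frame `region, x, y, z, hemisphere, division`
#'   with one representative point (e.g. centroid) per region, mm
#'   coordinates.
#' @param radius Pass-1 matching radius in mm (default 2).
#' @return Data frame `sample_id, region` (pass-2 rows flagged in the
#'   `pass` column).
#' @export
assign_samples <- function(table, region_points, radius = 2) {
  if (nrow(region_points) == 0L) stop("empty region geometry", call. = FALSE)
  smp <- table$samples
  d2 <- function(i, j) {
    sqrt((smp$x[i] - region_points$x[j])^2 +
         (smp$y[i] - region_points$y[j])^2 +
         (smp$z[i] - region_points$z[j])^2)
  }
  assigned <- data.frame(sample_id = character(0), region = character(0),
                         pass = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(smp))) {
    j <- which(region_points$hemisphere == smp$hemisphere[i] &
               region_points$division == smp$division[i])
    if (!length(j)) next
    dd <- d2(i, j)
    jmin <- j[which.min(dd)]
    if (min(dd) <= radius) {
      assigned <- rbind(assigned, data.frame(
        sample_id = smp$sample_id[i], region = region_points$region[jmin],
        pass = 1L, stringsAsFactors = FALSE))
    }
  }
  empty <- setdiff(region_points$region, assigned$region)
  for (r in empty) {
    j <- which(region_points$region == r)
    i <- which(smp$hemisphere == region_points$hemisphere[j] &
               smp$division == region_points$division[j])
    if (!length(i)) next
    dd <- vapply(i, d2, numeric(1), j = j)
    assigned <- rbind(assigned, data.frame(
      sample_id = smp$sample_id[i[which.min(dd)]], region = r,
      pass = 2L, stringsAsFactors = FALSE))
  }
  assigned
}

# Region-aggregated donor profile: mean intensity over a region's samples.
aggregate_by_region <- function(table, assignment, probes = NULL) {
  if (is.null(probes)) probes <- colnames(table$intensities)
  regions <- unique(assignment$region)
  out <- matrix(NA_real_, length(regions), length(probes),
                dimnames = list(regions, probes))
  for (r in regions) {
    ids <- assignment$sample_id[assignment$region == r]
    rows <- match(ids, table$samples$sample_id)
    out[r, ] <- colMeans(table$intensities[rows, probes, drop = FALSE])
  }
  out
}

#' Differential stability of probes across donors
#'
#' For each probe, the mean over all donor pairs of the Spearman correlation
#' between the two donors' region-aggregated expression profiles.  Pairs
#' with fewer than 3 common non-missing regions are skipped with a warning;
#' a probe whose every pair is skipped gets `NA`.
#'
#' @param profiles List (one per donor) of region x probe matrices with
#'   region rownames.
#' @return Named numeric vector of differential stability per probe.
#' @export
differential_stability <- function(profiles) {
  n <- length(profiles)
  if (n < 2L) stop("need at least 2 donors", call. = FALSE)
  probes <- colnames(profiles[[1L]])
  pairs <- utils::combn(n, 2L)
  acc <- matrix(NA_real_, ncol(pairs), length(probes))
  skipped <- 0L
  for (k in seq_len(ncol(pairs))) {
    a <- profiles[[pairs[1L, k]]]
    b <- profiles[[pairs[2L, k]]]
    common <- intersect(rownames(a), rownames(b))
    a <- a[common, probes, drop = FALSE]
    b <- b[common, probes, drop = FALSE]
    if (!anyNA(a) && !anyNA(b) && length(common) >= 3L) {
      # column-wise Spearman: Pearson on per-column ranks
      ra <- scale(apply(a, 2L, rank))
      rb <- scale(apply(b, 2L, rank))
      r <- colSums(ra * rb) / (length(common) - 1L)
      r[!is.finite(r)] <- NA_real_  # tied-constant columns
      acc[k, ] <- r
      next
    }
    for (pi in seq_along(probes)) {
      pa <- a[, pi]
      pb <- b[, pi]
      ok <- !is.na(pa) & !is.na(pb)
      if (sum(ok) < 3L) { skipped <- skipped + 1L; next }
      acc[k, pi] <- stats::cor(pa[ok], pb[ok], method = "spearman")
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d donor-pair/probe combination(s) skipped (<3 common regions)",
                    skipped), call. = FALSE)
  }
  ds <- colMeans(acc, na.rm = TRUE)
  ds[!is.finite(ds)] <- NA_real_
  stats::setNames(ds, probes)
}

#' Select one probe per gene by differential stability
#'
#' Keeps, for each gene, the probe with the highest differential stability;
#' ties are broken by lexicographically smallest probe id for
#' reproducibility.  Genes whose probes all have missing stability are
#' dropped with a warning.
#'
#' @param ds Named stability vector from [differential_stability()].
#' @param probe_to_gene Data frame `probe, gene`.
#' @return Data frame `gene, probe, ds`, sorted by gene id.
#' @export
select_probes <- function(ds, probe_to_gene) {
  map <- probe_to_gene[probe_to_gene$probe %in% names(ds), , drop = FALSE]
  map$ds <- ds[map$probe]
  map <- map[order(map$gene, -ifelse(is.na(map$ds), -Inf, map$ds), map$probe), ]
  sel <- map[!duplicated(map$gene), c("gene", "probe", "ds")]
  dropped <- sel$gene[is.na(sel$ds)]
  if (length(dropped)) {
    warning("gene(s) with no stable probe dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    sel <- sel[!is.na(sel$ds), , drop = FALSE]
  }
  sel <- sel[order(sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Robust sigmoid normalisation
#'
#' `x' = 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))`.  The IQR/1.35
#' scale is the normal-consistent robust analogue of the standard deviation,
#' making the transform equivariant under positive affine maps of the input.
#'
#' @param x Numeric vector (a gene's values across regions, within a donor).
#' @return Normalised vector; all `NA` when `IQR(x) == 0`.
#' @export
robust_sigmoid <- function(x) {
  iqr <- stats::IQR(x, na.rm = TRUE)
  if (!is.finite(iqr) || iqr == 0) return(rep(NA_real_, length(x)))
  1 / (1 + exp(-(x - stats::median(x, na.rm = TRUE)) / (iqr / 1.35)))
}

#' Normalise donor profiles and average into one expression matrix
#'
#' Per donor: samples assigned to the same region are averaged; each gene is
#' then robust-sigmoid normalised across regions and min-max rescaled to
#' `[0, 1]`; finally the scaled profiles are averaged across donors.  A
#' gene/donor with zero IQR is set to 0.5 for that donor with a warning.
#'
#' @param tables List of [donor_sample_table()] objects.
#' @param assignments List of assignment data frames (one per donor), from
#'   [assign_samples()].
#' @param selection Probe selection from [select_probes()]; `NULL` uses all
#'   probes as their own genes.
#' @param region_order Optional region ordering for the output rows.
#' @return An `expression_matrix`: regions x genes numeric matrix in
#'   `[0, 1]`, with attributes `provenance` (per-donor sample counts per
#'   region) and `selection`.
#' @export
normalize_and_average <- function(tables, assignments, selection = NULL,
                                  region_order = NULL) {
  if (is.null(selection)) {
    probes <- colnames(tables[[1L]]$intensities)
    selection <- data.frame(gene = probes, probe = probes, ds = NA_real_,
                            stringsAsFactors = FALSE)
    selection <- selection[order(selection$gene), ]
  }
  donor_mats <- vector("list", length(tables))
  flat_iqr <- 0L
  for (d in seq_along(tables)) {
    agg <- aggregate_by_region(tables[[d]], assignments[[d]], selection$probe)
    colnames(agg) <- selection$gene
    for (g in seq_len(ncol(agg))) {
      v <- robust_sigmoid(agg[, g])
      if (all(is.na(v))) {
        flat_iqr <- flat_iqr + 1L
        agg[, g] <- 0.5
        next
      }
      rng <- range(v, na.rm = TRUE)
      agg[, g] <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else 0.5
    }
    donor_mats[[d]] <- agg
  }
  if (flat_iqr > 0L) {
    warning(sprintf("%d donor/gene profile(s) had zero IQR; set to 0.5", flat_iqr),
            call. = FALSE)
  }
  regions <- unique(unlist(lapply(donor_mats, rownames)))
  if (!is.null(region_order)) {
    regions <- region_order[region_order %in% regions]
  } else {
    regions <- sort(regions)
  }
  genes <- sort(selection$gene)
  acc <- matrix(0, length(regions), length(genes), dimnames = list(regions, genes))
  cnt <- acc
  for (d in seq_along(donor_mats)) {
    m <- donor_mats[[d]][, genes, drop = FALSE]
    rr <- intersect(regions, rownames(m))
    msub <- m[rr, , drop = FALSE]
    ok <- !is.na(msub)
    asub <- acc[rr, , drop = FALSE]
    csub <- cnt[rr, , drop = FALSE]
    asub[ok] <- asub[ok] + msub[ok]
    csub[ok] <- csub[ok] + 1
    acc[rr, ] <- asub
    cnt[rr, ] <- csub
  }
  out <- acc / cnt
  out[!is.finite(out)] <- NA_real_
  prov <- lapply(seq_along(tables), function(d) {
    tab <- table(assignments[[d]]$region)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(prov) <- vapply(tables, `[[`, character(1), "donor_id")
  structure(out, provenance = prov, selection = selection,
            class = c("expression_matrix", class(out)))
}

#' Build a region x gene expression matrix from donor tables
#'
#' Full donor-level pipeline: background probe filtering, per-donor sample
#' assignment, differential-stability probe selection, robust-sigmoid
#' normalisation and donor averaging.
#'
#' @inheritParams normalize_and_average
#' @inheritParams assign_samples
#' @inheritParams filter_probes
#' @param region_points Region representative points (see
#'   [assign_samples()]); restrict to left-hemisphere cortical regions for
#'   the 34-region association analysis.
#' @return An `expression_matrix` (see [normalize_and_average()]).
#' @export
build_expression_matrix <- function(tables, region_points, radius = 2,
                                    max_below = 0.5, per_donor = FALSE,
                                    region_order = region_points$region) {
  probes <- filter_probes(tables, max_below = max_below, per_donor = per_donor)
  if (!length(probes)) stop("no probes pass the background filter", call. = FALSE)
  assignments <- lapply(tables, assign_samples, region_points = region_points,
                        radius = radius)
  profiles <- lapply(seq_along(tables), function(d) {
    aggregate_by_region(tables[[d]], assignments[[d]], probes)
  })
  ds <- differential_stability(profiles)
  sel <- select_probes(ds, tables[[1L]]$probe_to_gene)
  normalize_and_average(tables, assignments, sel, region_order = region_order)
}

#' Leave-one-donor-out sensitivity of the expression matrix
#'
#' Rebuilds the expression matrix with each donor excluded and reports the
#' mean pairwise Pearson correlation of the resulting matrices' first
#' principal-component region scores (sign-aligned to the first matrix).
#'
#' @inheritParams build_expression_matrix
#' @return List with `matrices`, `pc1` (regions x n_donors score matrix) and
#'   `mean_pc1_cor`.
#' @export
leave_one_donor_out <- function(tables, region_points, radius = 2,
                                max_below = 0.5, per_donor = FALSE) {
  n <- length(tables)
  if (n < 3L) stop("need at least 3 donors", call. = FALSE)
  mats <- lapply(seq_len(n), function(d) {
    build_expression_matrix(tables[-d], region_points, radius = radius,
                            max_below = max_below, per_donor = per_donor)
  })
  genes <- Reduce(intersect, lapply(mats, colnames))
  regions <- Reduce(intersect, lapply(mats, rownames))
  pc1 <- vapply(mats, function(m) {
    p <- stats::prcomp(m[regions, genes, drop = FALSE], center = TRUE,
                       scale. = FALSE)
    p$x[, 1L]
  }, numeric(length(regions)))
  for (d in seq_len(n)[-1L]) {
    if (stats::cor(pc1[, 1L], pc1[, d]) < 0) pc1[, d] <- -pc1[, d]
  }
  cc <- stats::cor(pc1)
  list(matrices = mats, pc1 = pc1,
       mean_pc1_cor = mean(cc[upper.tri(cc)]))
}
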