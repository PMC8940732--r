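# Donor-level expression processing: probe filtering, differential
# stability, sample assignment, robust-sigmoid normalisation, donor
# averaging and the leave-one-donor-out sensitivity check.

test_that("probe filtering applies the >=50% below-background rule", {
  above <- cbind(p_always = rep(TRUE, 10),
                 p_half = rep(c(TRUE, FALSE), 5),     # exactly 50% below
                 p_four = c(rep(FALSE, 4), rep(TRUE, 6)))  # 40% below
  inten <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10),
                                            colnames(above)))
  rownames(above) <- rownames(inten)
  tab <- toy_donor("d1", inten, above)
  kept <- filter_probes(list(tab))
  expect_true("p_always" %in% kept)
  expect_false("p_half" %in% kept)   # boundary read literally: discarded
  expect_true("p_four" %in% kept)
})

test_that("per-donor filtering requires the criterion in every donor", {
  mk <- function(frac_below) {
    above <- matrix(rep(c(FALSE, TRUE), c(frac_below * 10, 10 - frac_below * 10)),
                    10, 1, dimnames = list(paste0("s", 1:10), "p_x"))
    inten <- matrix(1, 10, 1, dimnames = dimnames(above))
    toy_donor("d", inten, above)
  }
  tabs <- list(mk(0.2), mk(0.6))  # pooled 40% below; donor 2 fails alone
  expect_equal(filter_probes(tabs), "p_x")
  expect_length(filter_probes(tabs, per_donor = TRUE), 0)
})

test_that("differential stability equals the mean pairwise Spearman", {
  p1 <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(paste0("region_", 1:5), "p_a"))
  expect_equal(unname(differential_stability(list(p1, p1))), 1)
  p_rev <- p1[5:1, , drop = FALSE]
  rownames(p_rev) <- rownames(p1)
  expect_equal(unname(differential_stability(list(p1, p_rev))), -1)
  set.seed(3)
  profs <- lapply(1:3, function(d) {
    m <- matrix(rnorm(5 * 4), 5, 4,
                dimnames = list(paste0("region_", 1:5), paste0("p_", letters[1:4])))
    m
  })
  ds <- differential_stability(profs)
  oracle <- vapply(paste0("p_", letters[1:4]), function(p) {
    mean(c(brute_spearman(profs[[1]][, p], profs[[2]][, p]),
           brute_spearman(profs[[1]][, p], profs[[3]][, p]),
           brute_spearman(profs[[2]][, p], profs[[3]][, p])))
  }, numeric(1))
  expect_equal(ds, oracle, tolerance = 1e-12)
})

test_that("differential stability is invariant to monotone transforms", {
  set.seed(5)
  profs <- lapply(1:3, function(d) {
    matrix(runif(6 * 2, 1, 4), 6, 2,
           dimnames = list(paste0("region_", 1:6), c("p_a", "p_b")))
  })
  ds0 <- differential_stability(profs)
  profs2 <- profs
  profs2[[2]] <- exp(profs2[[2]])   # strictly increasing transform
  expect_equal(differential_stability(profs2), ds0, tolerance = 1e-12)
})

test_that("probe selection takes the stability maximum with lexical ties", {
  ds <- c(p_b = 0.9, p_a = 0.9, p_c = 0.5, p_d = NA)
  map <- data.frame(probe = c("p_a", "p_b", "p_c", "p_d"),
                    gene = c("G1", "G1", "G2", "G3"))
  expect_warning(sel <- select_probes(ds, map), "G3")
  expect_equal(sel$probe[sel$gene == "G1"], "p_a")  # lexicographic tie-break
  expect_equal(sel$probe[sel$gene == "G2"], "p_c")
  expect_false("G3" %in% sel$gene)
})

test_that("sample assignment follows the two-pass radius rule", {
  pts <- toy_region_points(3)  # regions at x = 10, 20, 30
  samples <- data.frame(sample_id = c("on", "near", "far"),
                        x = c(10, 20.9, 33), y = 0, z = 0,
                        hemisphere = "L", division = "cortex")
  inten <- matrix(1:6, 3, 2, dimnames = list(samples$sample_id, c("p_a", "p_b")))
  tab <- donor_sample_table("d", samples, inten,
                            matrix(TRUE, 3, 2, dimnames = dimnames(inten)),
                            data.frame(probe = c("p_a", "p_b"),
                                       gene = c("A", "B")))
  asg <- assign_samples(tab, pts)
  expect_equal(asg$region[asg$sample_id == "on" & asg$pass == 1], "region_1")
  expect_equal(asg$region[asg$sample_id == "near" & asg$pass == 1], "region_2")
  expect_false("far" %in% asg$sample_id[asg$pass == 1])  # > 2 mm from all
  # pass 2: region_3 has no pass-1 sample; its closest sample is "far"
  expect_equal(asg$sample_id[asg$region == "region_3"], "far")
  expect_equal(asg$pass[asg$region == "region_3"], 2L)
  # hemisphere constraint: flipping the sample hemisphere blocks assignment
  tab2 <- tab; tab2$samples$hemisphere <- "R"
  expect_equal(nrow(assign_samples(tab2, pts)), 0L)
})

test_that("robust sigmoid matches the hand computation and centre", {
  x <- c(1, 2, 3, 10)
  iqr <- IQR(x)        # type-7 quartiles: 4.75 - 1.75 = 3
  expect_equal(iqr, 3)
  hand <- 1 / (1 + exp(-(x - 2.5) / (3 / 1.35)))
  expect_equal(robust_sigmoid(x), hand, tolerance = 1e-12)
  # a value at the median maps to exactly 0.5
  y <- c(1, 4, 9)
  expect_equal(robust_sigmoid(y)[2], 0.5)
  expect_true(all(is.na(robust_sigmoid(rep(2, 5)))))
})

test_that("normalisation rescales each donor gene to [0,1] and averages", {
  set.seed(9)
  inten1 <- matrix(runif(5 * 3, 2, 8), 5, 3,
                   dimnames = list(paste0("s", 1:5), paste0("p_", c("a", "b", "c"))))
  inten2 <- inten1 + rnorm(15)
  rownames(inten2) <- rownames(inten1)
  tabs <- list(toy_donor("d1", inten1), toy_donor("d2", inten2))
  pts <- toy_region_points(5)
  asg <- lapply(tabs, assign_samples, region_points = pts)
  em <- normalize_and_average(tabs, asg, region_order = pts$region)
  expect_true(all(em >= 0 & em <= 1))
  expect_equal(rownames(em), pts$region)
  expect_equal(colnames(em), sort(colnames(em)))
  # single-donor path: min 0 and max 1 per gene after rescaling
  em1 <- normalize_and_average(tabs[1], asg[1], region_order = pts$region)
  expect_equal(unname(apply(em1, 2, min)), rep(0, 3))
  expect_equal(unname(apply(em1, 2, max)), rep(1, 3))
})

test_that("the normalised matrix is invariant under positive affine inputs", {
  set.seed(13)
  inten <- matrix(runif(6 * 4, 1, 5), 6, 4,
                  dimnames = list(paste0("s", 1:6), paste0("p_", letters[1:4])))
  pts <- toy_region_points(6)
  t1 <- toy_donor("d1", inten)
  t2 <- toy_donor("d1", 3.7 * inten + 11)  # x -> a x + b, a > 0
  a1 <- list(assign_samples(t1, pts))
  em1 <- normalize_and_average(list(t1), a1, region_order = pts$region)
  em2 <- normalize_and_average(list(t2), a1, region_order = pts$region)
  expect_equal(unclass(em1), unclass(em2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-IQR donor genes fall back to 0.5 with a warning", {
  inten <- matrix(c(rep(4, 5), 1:5), 5, 2,
                  dimnames = list(paste0("s", 1:5), c("p_flat", "p_ok")))
  pts <- toy_region_points(5)
  tab <- toy_donor("d1", inten)
  asg <- list(assign_samples(tab, pts))
  expect_warning(em <- normalize_and_average(list(tab), asg,
                                             region_order = pts$region),
                 "zero IQR")
  expect_equal(unname(em[, "p_flat"]), rep(0.5, 5))
})

test_that("full pipeline output is deterministic, bounded and ordered", {
  tm <- sin(seq(0, 2 * pi, length.out = 12))
  cfg <- expression_sim_config(n_genes = 30, n_regions = 12, n_donors = 4,
                               n_signal_pos = 5, seed = 17)
  sim <- simulate_expression(cfg, tm)
  em1 <- build_expression_matrix(sim$tables, sim$region_points)
  em2 <- build_expression_matrix(sim$tables, sim$region_points)
  expect_identical(em1, em2)
  expect_true(all(em1 >= 0 & em1 <= 1, na.rm = TRUE))
  expect_equal(colnames(em1), sort(colnames(em1)))
  expect_equal(rownames(em1), sim$region_points$region)
  expect_false(any(colSums(!is.na(em1)) == 0))
})

test_that("leave-one-donor-out correlation degrades with donor noise", {
  tm <- cos(seq_len(15))
  run <- function(noise) {
    cfg <- expression_sim_config(n_genes = 40, n_regions = 15, n_donors = 4,
                                 n_signal_pos = 10, donor_noise_sd = noise,
                                 seed = 19)
    sim <- simulate_expression(cfg, tm)
    leave_one_donor_out(sim$tables, sim$region_points)$mean_pc1_cor
  }
  r0 <- run(0)
  expect_equal(r0, 1, tolerance = 1e-9)
  expect_gt(run(0.2), run(2.5))
})

test_that("expression matrices round-trip through TSV", {
  tm <- sin(seq_len(8))
  cfg <- expression_sim_config(n_genes = 10, n_regions = 8, n_donors = 3,
                               seed = 23)
  sim <- simulate_expression(cfg, tm)
  em <- build_expression_matrix(sim$tables, sim$region_points)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path)
  expect_equal(unclass(back), unclass(em), tolerance = 1e-9,
               ignore_attr = TRUE)
})
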