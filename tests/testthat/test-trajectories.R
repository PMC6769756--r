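test_that("ML frequency equals the pooled closed form and its
          optimizer route", {
  expect_equal(ml_frequency(c(2, 1), c(4, 2)), 0.5)
  expect_equal(ml_frequency(c(0, 0), c(5, 3)), 0)
  expect_equal(ml_frequency(c(5, 3), c(5, 3)), 1)
  expect_true(is.na(ml_frequency(0L, 0L)))
  # individuals with d = 0 are ignored
  expect_equal(ml_frequency(c(2, 0), c(4, 0)), 0.5)
  set.seed(14)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    d <- rpois(n, 8)
    r <- rbinom(n, d, runif(1))
    if (sum(d) == 0 || sum(r) == 0 || sum(r) == sum(d)) next
    expect_equal(ml_frequency(r, d, method = "optimize"),
                 sum(r) / sum(d), tolerance = 1e-9)
  }
  # grid search confirms the maximizer on one configuration
  r <- c(3, 1, 4); d <- c(6, 2, 9)
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  ll <- vapply(grid, function(p) sum(dbinom(r, d, p, log = TRUE)), 0)
  expect_equal(ml_frequency(r, d), grid[which.max(ll)],
               tolerance = 1e-4)
})

test_that("the estimate is invariant to splitting an individual's
          reads", {
  # individual (5 of 9) split into pseudo-individuals (3 of 5, 2 of 4)
  expect_equal(ml_frequency(c(3, 2, 2), c(5, 4, 4)),
               ml_frequency(c(5, 2), c(9, 4)))
})

test_that("temporal bins are half-open sliding windows", {
  meta <- data.frame(sample_id = sprintf("a%02d", 1:12),
                     age_bp = rep(100, 12))
  bins <- bin_samples(meta)
  # every bin whose window covers age 100 contains all 12 samples
  expect_true(all(vapply(bins, function(b) length(b$members), 0L) ==
                    12L))
  covering <- vapply(bins, function(b)
    b$lo <= 100 && 100 < b$hi, TRUE)
  expect_true(all(covering))
  # a sample aged exactly c + 500 belongs to the next bin only
  meta2 <- data.frame(sample_id = c("x", "y"), age_bp = c(750, 500))
  bins2 <- bin_samples(meta2)
  b250 <- bins2[[which(vapply(bins2, `[[`, 0, "center") == 250)]]
  expect_false("x" %in% b250$members)  # 750 = 250 + 500
  expect_true("y" %in% b250$members)
  # modern samples (age 0) are never binned
  expect_equal(length(bin_samples(data.frame(sample_id = "m",
                                             age_bp = 0))), 0L)
})

test_that("bins failing the per-site minimum are missing", {
  set.seed(15)
  n <- 30
  sites <- annotate_sites(
    site_table("chr1", seq_len(n) * 100L, rep("coding", n),
               rep(2, n), rep("A:44,G:2", n)),
    rep(list(c("A", "G")), n))
  meta <- data.frame(sample_id = sprintf("a%02d", 1:9),
                     breed = "ancient", group = "ancient",
                     age_bp = rep(1000, 9), mean_depth = 5)
  cm <- count_matrix(meta$sample_id, sites$chrom, sites$pos,
                     sites$deleterious_allele,
                     matrix(1L, 9, n), matrix(4L, 9, n))
  traj <- estimate_trajectories(cm, sites, meta, pl_config(),
                                include_modern = FALSE)
  expect_true(all(is.na(traj$f)))  # 9 < 10 genotyped
  traj2 <- estimate_trajectories(cm, sites, meta,
                                 pl_config(min_bin_n = 5),
                                 include_modern = FALSE)
  expect_true(all(traj2$f == 0.25, na.rm = TRUE))
  expect_false(all(is.na(traj2$f)))
})

test_that("trajectory classes follow the fixed/absent thresholds", {
  f <- rbind(c(1.0, 0.995, 0.99),
             c(0.0, 0.005, 0.0),
             c(0.0, 0.3, 0.0),
             c(NA, NA, NA),
             c(NA, 0.999, NA))
  expect_identical(classify_trajectory(f),
                   c("fixed", "absent", "dynamic", "unclassified",
                     "fixed"))
})

test_that("frequency shifts are signed old-to-young differences", {
  sites <- annotate_sites(
    site_table("chr1", c(10L, 20L), rep("coding", 2), c(2, 2),
               rep("A:44,G:2", 2)),
    rep(list(c("A", "G")), 2))
  traj <- structure(list(
    f = rbind(c(0.5, 0.10, 0.14), c(0.2, 0.2, 0.2)),
    n = NULL, centers = c(2250, 1250, 250),
    site_index = 1:2, sites = sites), class = "pl_traj")
  ds <- delta_series(traj, centers = c(2250, 1250, 250))
  d1 <- ds[ds$site == 1 & ds$interval_center == 250, ]
  expect_equal(d1$delta_abs, 0.04)
  expect_gt(d1$delta_signed, 0)
  expect_true(all(ds$delta_abs[ds$site == 2] == 0))
  expect_error(delta_series(traj, centers = c(3250, 2250)), "absent")
})

test_that("pooled comparison recovers an injected frequency shift and
          is zero for identical pools", {
  set.seed(16)
  n <- 1500
  sites <- annotate_sites(
    site_table("chr1", sort(sample.int(1e7, n)), rep("coding", n),
               rep(2, n), rep("A:44,G:2", n)),
    rep(list(c("A", "G")), n))
  meta <- data.frame(sample_id = c(sprintf("a%02d", 1:20),
                                   sprintf("m%02d", 1:20)),
                     breed = "x", group = rep(c("ancient", "other"),
                                              each = 20),
                     age_bp = rep(c(1000, 0), each = 20),
                     mean_depth = 10)
  p_anc <- runif(n, 0.1, 0.6)
  draw <- function(p) {
    d <- matrix(rpois(20 * n, 10), 20, n)
    r <- matrix(rbinom(20 * n, as.vector(d), rep(p, each = 20)), 20, n)
    list(r = r, d = d)
  }
  anc <- draw(p_anc); mod <- draw(pmin(p_anc + 0.05, 1))
  cm <- count_matrix(meta$sample_id, sites$chrom, sites$pos,
                     sites$deleterious_allele,
                     rbind(anc$r, mod$r), rbind(anc$d, mod$d))
  pc <- pooled_comparison(cm, sites, meta, ascertain_modern = FALSE)
  expect_equal(pc$difference[pc$stratum == "all"], 0.05,
               tolerance = 0.01)
  # identical pools -> zero difference
  cm0 <- count_matrix(meta$sample_id, sites$chrom, sites$pos,
                      sites$deleterious_allele,
                      rbind(anc$r, anc$r), rbind(anc$d, anc$d))
  pc0 <- pooled_comparison(cm0, sites, meta, ascertain_modern = FALSE)
  expect_equal(pc0$difference[pc0$stratum == "all"], 0)
})

test_that("overlapping bins sharing samples give near-identical
          estimates", {
  set.seed(17)
  n <- 400
  sites <- annotate_sites(
    site_table("chr1", seq_len(n) * 50L, rep("coding", n),
               rep(2, n), rep("A:44,G:2", n)),
    rep(list(c("A", "G")), n))
  meta <- data.frame(sample_id = sprintf("a%02d", 1:30),
                     breed = "ancient", group = "ancient",
                     age_bp = round(runif(30, 950, 1050)),
                     mean_depth = 10)
  p <- runif(n, 0.1, 0.5)
  d <- matrix(rpois(30 * n, 10), 30, n)
  r <- matrix(rbinom(30 * n, as.vector(d), rep(p, each = 30)), 30, n)
  cm <- count_matrix(meta$sample_id, sites$chrom, sites$pos,
                     sites$deleterious_allele, r, d)
  traj <- estimate_trajectories(cm, sites, meta, pl_config(),
                                include_modern = FALSE)
  # bins centered at 750 and 1000 share every sample here
  c750 <- which(traj$centers == 750)
  c1000 <- which(traj$centers == 1000)
  expect_equal(traj$f[, c750], traj$f[, c1000])
})
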