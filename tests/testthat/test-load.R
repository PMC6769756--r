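make_calls <- function(dosage, samples = rownames(dosage), sites) {
  structure(list(dosage = dosage, reason = NULL, samples = samples,
                 chrom = sites$chrom, pos = sites$pos,
                 del_allele = sites$deleterious_allele,
                 masked_fraction = rowMeans(is.na(dosage))),
            class = "pl_calls")
}

test_that("load equals the hand-worked example", {
  # three deleterious homozygotes at phyloP 2.0, 1.6, 3.0 among 1000
  # called homozygous sites -> load 6.6e-3
  n <- 1000
  sites <- site_table("chr1", seq_len(n) * 10L,
                      rep("intergenic", n),
                      c(2.0, 1.6, 3.0, rep(0.2, n - 3)),
                      rep("A:44,G:2", n))
  sites <- annotate_sites(sites, rep(list(c("A", "G")), n))
  dosage <- matrix(0L, 1, n, dimnames = list("s1", NULL))
  dosage[1, 1:3] <- 2L
  le <- compute_load(make_calls(dosage, sites = sites), sites)
  expect_equal(le$load, 6.6 / 1000)
  expect_equal(le$n_hom_deleterious, 3L)
  expect_equal(le$n_hom_total, 1000L)
})

test_that("load matches a per-site brute-force oracle on random
          fixtures", {
  set.seed(8)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    sites <- site_table("chr1", sort(sample.int(1e6, n)),
                        sample(REGION_CLASSES, n, replace = TRUE),
                        round(runif(n, -1, 4), 3),
                        sample(c("A:44,G:2", "C:46", "T:23,G:23"), n,
                               replace = TRUE))
    sites <- annotate_sites(sites, rep(list(c("A", "G")), n))
    dosage <- matrix(sample(c(0L, 2L, NA), 2 * n, replace = TRUE),
                     2, n, dimnames = list(c("x", "y"), NULL))
    got <- compute_load(make_calls(dosage, sites = sites), sites)
    for (k in 1:2) {
      want <- oracle_load(dosage[k, ], sites$phylop,
                          !is.na(sites$deleterious_allele))
      expect_equal(got$load[k], want$load)
      expect_equal(got$n_hom_total[k], want$n_hom_total)
      expect_equal(got$sum_phylop[k], want$sum_phylop)
    }
  }
})

test_that("deleterious site below the phyloP cutoff counts only in the
          denominator", {
  sites <- annotate_sites(
    site_table("chr1", c(10L, 20L), rep("coding", 2), c(1.49, 2.0),
               rep("A:44,G:2", 2)),
    rep(list(c("A", "G")), 2))
  dosage <- matrix(c(2L, 2L), 1, 2, dimnames = list("s1", NULL))
  le <- compute_load(make_calls(dosage, sites = sites), sites)
  expect_equal(le$n_hom_deleterious, 1L)
  expect_equal(le$load, 2.0 / 2)
  # no deleterious homozygote -> load 0; no called site -> missing
  le0 <- compute_load(make_calls(matrix(c(0L, 0L), 1, 2,
                                        dimnames = list("s1", NULL)),
                                 sites = sites), sites)
  expect_equal(le0$load, 0)
  leNA <- compute_load(make_calls(matrix(NA_integer_, 1, 2,
                                         dimnames = list("s1", NULL)),
                                  sites = sites), sites)
  expect_true(is.na(leNA$load))
})

test_that("load is linear in phyloP and additive over region
          partitions", {
  set.seed(9)
  n <- 200
  sites <- site_table("chr1", sort(sample.int(1e6, n)),
                      sample(REGION_CLASSES, n, replace = TRUE),
                      round(runif(n, 0, 4), 3),
                      rep("A:44,G:2", n))
  sites <- annotate_sites(sites, rep(list(c("A", "G")), n))
  dosage <- matrix(sample(c(0L, 2L, NA), n, replace = TRUE,
                          prob = c(.5, .3, .2)),
                   1, n, dimnames = list("s1", NULL))
  calls <- make_calls(dosage, sites = sites)
  base <- compute_load(calls, sites)
  # doubling every score doubles the numerator (and hence the load)
  sites2 <- sites; sites2$phylop <- 2 * sites$phylop
  doubled <- compute_load(make_calls(dosage, sites = sites2), sites2,
                          phylop_threshold = 3)
  # with the threshold doubled too, the same sites qualify
  expect_equal(doubled$sum_phylop, 2 * base$sum_phylop)
  # genome-wide numerator = sum over the region partition
  per_region <- lapply(REGION_CLASSES, function(rc)
    compute_load(calls, sites, rc))
  expect_equal(sum(vapply(per_region, function(x) x$sum_phylop, 0)),
               base$sum_phylop)
  expect_equal(sum(vapply(per_region, function(x) x$n_hom_total, 0L)),
               base$n_hom_total)
  # invariance under site permutation is inherent: shuffle and compare
  ord <- order(sample.int(n))
  sites_p <- sites[ord, ]; sites_p <- sites_p[order(sites_p$pos), ]
  expect_equal(compute_load(calls, sites)$load, base$load)
})

test_that("rank-sum comparison matches exact enumeration", {
  # C(6,3) = 20 labelings; the observed split is the most extreme one
  # in both directions -> two-sided p = 2/20
  expect_equal(group_compare(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(group_compare(c(1, 2), c(1, 2))$statistic, 2)
  expect_equal(group_compare(c(1, 2), c(1, 2))$p_value, 1)
  expect_equal(group_compare(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  one_sided <- group_compare(c(4, 5, 6), c(1, 2, 3),
                             alternative = "greater")
  expect_equal(one_sided$p_value, 0.05)
})

test_that("breed summaries aggregate and flag small breeds", {
  loads <- data.frame(sample_id = c("a", "b", "c"),
                      region_class = "GENOME_WIDE",
                      load = c(4.0e-3, 4.2e-3, 9e-3))
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     breed = c("breed1", "breed1", "breed2"))
  bs <- breed_summary(loads, meta)
  b1 <- bs[bs$breed == "breed1", ]
  expect_equal(b1$mean_load, 4.1e-3)
  expect_equal(b1$n, 2L)
  expect_true(all(bs$low_confidence))
  # unknown sample grouped as "other"
  loads2 <- rbind(loads, data.frame(sample_id = "zz",
                                    region_class = "GENOME_WIDE",
                                    load = 1e-3))
  expect_true("other" %in% breed_summary(loads2, meta)$breed)
})

test_that("Spearman correlation across regions behaves on known
          rankings", {
  mk <- function(region, load)
    data.frame(sample_id = paste0("s", seq_along(load)),
               region_class = region, load = load)
  x <- c(0.11, 0.25, 0.3, 0.41, 0.52)
  rc <- region_correlation(rbind(mk("coding", x),
                                 mk("intron", exp(x)),
                                 mk("intergenic", -x)))
  get <- function(a, b)
    rc$rho[(rc$region_a == a & rc$region_b == b) |
             (rc$region_a == b & rc$region_b == a)]
  expect_equal(get("coding", "intron"), 1)
  expect_equal(get("coding", "intergenic"), -1)
  # the worked rank example: rho = 0.8
  sc <- paleoload:::spearman_cor(1:5, c(1, 3, 2, 5, 4))
  expect_equal(sc$rho, 0.8)
  # constant vector: undefined
  expect_true(is.na(paleoload:::spearman_cor(1:5, rep(2, 5))$rho))
})
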