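test_that("dN - dS matches hand counts and vanishes for identical
          sequences", {
  n <- 200
  ind <- rep(0L, n); og <- rep(0L, n)
  idx <- list(constrained = 1:100, neutral = 101:200)
  same <- dn_ds(ind, og, idx$constrained, idx$neutral)
  expect_equal(same$dn_minus_ds, 0)
  # 2 diffs / 100 constrained, 5 diffs / 100 neutral -> -0.03
  og2 <- og; og2[c(3, 7)] <- 1L; og2[100 + c(1, 2, 3, 4, 5)] <- 1L
  z <- dn_ds(ind, og2, idx$constrained, idx$neutral)
  expect_equal(z$dN, 0.02); expect_equal(z$dS, 0.05)
  expect_equal(z$dn_minus_ds, -0.03)
  # argument sets can be given in any order
  z_swap <- dn_ds(ind, og2, idx$neutral, idx$constrained)
  expect_equal(z_swap$dn_minus_ds, 0.03)
  # missing sites are excluded from the denominators
  ind_na <- ind; ind_na[1:50] <- NA
  expect_equal(dn_ds(ind_na, og2, idx$constrained,
                     idx$neutral)$n_constrained, 50)
  expect_true(is.na(dn_ds(ind_na, og2, rep(FALSE, n),
                          idx$neutral)$dN))
})

test_that("permuting the constrained label drives mean dN - dS to
          zero", {
  set.seed(19)
  n <- 2000
  ind <- rbinom(n, 1, 0.05)
  og <- rbinom(n, 1, 0.05)
  diffs <- replicate(100, {
    lab <- sample(rep(c(TRUE, FALSE), each = n / 2))
    dn_ds(ind, og, lab, !lab)$dn_minus_ds
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(100) + 1e-4)
})

test_that("r-squared pairs respect the distance window and LD
          structure", {
  set.seed(20)
  n_samp <- 60
  base <- rbinom(n_samp, 2, 0.4)
  dosage <- cbind(base, base, rbinom(n_samp, 2, 0.4))
  # positions: sites 1-2 close, site 3 at 60 kb from site 1
  pairs <- ld_r2_pairs(dosage, rep("chr1", 3), c(1000L, 2000L, 61000L),
                       max_dist_bp = 50000)
  expect_true(any(pairs$i == 1 & pairs$j == 2))
  expect_equal(pairs$r2[pairs$i == 1 & pairs$j == 2], 1)
  expect_false(any(pairs$i == 1 & pairs$j == 3))  # 60 kb apart
  # different chromosomes never pair
  p2 <- ld_r2_pairs(dosage, c("chr1", "chr2", "chr2"),
                    c(1000L, 1000L, 2000L), 50000)
  expect_false(any(p2$i == 1))
  # monomorphic sites yield no pairs
  p3 <- ld_r2_pairs(cbind(rep(1L, n_samp), base),
                    rep("chr1", 2), c(1L, 2L), 50000)
  expect_equal(nrow(p3), 0L)
})

test_that("independent sites have r-squared near 1/n on average", {
  set.seed(22)
  n_samp <- 1000
  dosage <- matrix(rbinom(n_samp * 40, 2, 0.3), n_samp, 40)
  pairs <- ld_r2_pairs(dosage, rep("chr1", 40), seq_len(40) * 100L,
                       max_dist_bp = 50000)
  expect_gt(nrow(pairs), 500)
  expect_equal(mean(pairs$r2), 1 / n_samp, tolerance = 0.3)
})

test_that("LD blocks pick the most central SNP, leftmost on ties", {
  pos <- c(100L, 200L, 300L)
  # chain: B linked to A and C -> B is the hub
  chain <- data.frame(i = c(1L, 2L), j = c(2L, 3L), r2 = c(0.9, 0.9))
  bl <- cluster_ld_blocks(chain, 3L, pos)
  expect_equal(max(bl$block), 1L)
  expect_identical(bl$representative, c(FALSE, TRUE, FALSE))
  # complete triangle: all degrees equal -> leftmost wins
  tri <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                    r2 = rep(0.9, 3))
  bl2 <- cluster_ld_blocks(tri, 3L, pos)
  expect_identical(bl2$representative, c(TRUE, FALSE, FALSE))
  # no edges: every SNP its own representative
  bl3 <- cluster_ld_blocks(chain[0, ], 3L, pos)
  expect_true(all(bl3$representative))
  expect_equal(length(unique(bl3$block)), 3L)
  # edges below the threshold are ignored
  weak <- data.frame(i = 1L, j = 2L, r2 = 0.1)
  expect_true(all(cluster_ld_blocks(weak, 3L, pos)$representative))
})

test_that("missingness filter keeps sites at or below 10%", {
  dosage <- matrix(0L, 20, 3)
  dosage[1, 2] <- NA          # 1/20 = 5%
  dosage[1:3, 3] <- NA        # 3/20 = 15%
  expect_identical(missingness_filter(dosage), c(TRUE, TRUE, FALSE))
  expect_true(all(missingness_filter(matrix(1L, 5, 4))))
})

test_that("the IBD HMM finds degenerate and null inbreeding", {
  set.seed(23)
  n <- 3000
  pos <- sort(sample.int(5e7, n))
  chrom <- rep("chr1", n)
  freqs <- runif(n, 0.2, 0.5)
  # no heterozygote anywhere: fully autozygous
  fit1 <- fit_ibd_hmm(rep(0L, n), chrom, pos, freqs)
  expect_gt(fit1$F, 0.95)
  expect_gt(fit1$ibd_fraction, 0.99)
  # Hardy-Weinberg heterozygosity throughout: no inbreeding
  het <- rbinom(n, 1, 2 * freqs * (1 - freqs))
  fit0 <- fit_ibd_hmm(het, chrom, pos, freqs)
  expect_lt(fit0$F, 0.05)
  # EM likelihood never decreases
  expect_true(all(diff(fit0$loglik) > -1e-6))
  expect_true(all(diff(fit1$loglik) > -1e-6))
})

test_that("forward-backward posteriors are proper probabilities", {
  set.seed(24)
  n <- 500
  emis <- cbind(runif(n, 0.2, 1), runif(n, 0.2, 1))
  sw <- runif(n - 1, 0, 1)
  fb <- paleoload:::hmm_forward_backward(emis, sw, 0.3)
  expect_equal(rowSums(fb$gamma), rep(1, n), tolerance = 1e-9)
  expect_equal(rowSums(fb$xi), rep(1, n - 1), tolerance = 1e-9)
  expect_true(all(fb$gamma >= 0 & fb$gamma <= 1))
  # forward-backward likelihood equals direct summation on a tiny case
  emis3 <- matrix(c(0.9, 0.4, 0.7, 0.1, 0.6, 0.3), 3, 2)
  sw3 <- c(0.5, 0.8); F <- 0.25
  A <- function(s) rbind(c(1 - F * s, F * s),
                         c((1 - F) * s, 1 - (1 - F) * s))
  direct <- 0
  for (s1 in 1:2) for (s2 in 1:2) for (s3 in 1:2)
    direct <- direct + c(1 - F, F)[s1] * emis3[1, s1] *
      A(sw3[1])[s1, s2] * emis3[2, s2] *
      A(sw3[2])[s2, s3] * emis3[3, s3]
  fb3 <- paleoload:::hmm_forward_backward(emis3, sw3, F)
  expect_equal(fb3$loglik, log(direct), tolerance = 1e-12)
})

test_that("the HMM recovers simulated inbreeding and tract structure", {
  set.seed(25)
  n <- 20000
  pos <- sort(sample.int(1e8, n))
  chrom <- rep("chr1", n)
  freqs <- runif(n, 0.15, 0.5)
  ind <- sample_individual_genotypes(freqs, chrom, pos, 0.25,
                                     mean_roh_length_bp = 2e6)
  fit <- fit_ibd_hmm(as.integer(ind$genotype == 1L), chrom, pos, freqs)
  expect_lt(abs(fit$F - ind$F_realized), 0.05)
  # decoded fraction agrees with the fitted stationary probability
  expect_lt(abs(fit$ibd_fraction - fit$F), 0.05)
  # tracts are sorted and non-overlapping
  if (nrow(fit$tracts) > 1) {
    expect_true(all(diff(fit$tracts$start) > 0))
    expect_true(all(fit$tracts$end[-nrow(fit$tracts)] <
                      fit$tracts$start[-1]))
  }
})

test_that("effective size follows the harmonic form", {
  expect_equal(effective_population_size(20, 5000), 79.68127,
               tolerance = 1e-6)
  expect_equal(effective_population_size(300, 300), 600)
  expect_equal(effective_population_size(5000, 20),
               effective_population_size(20, 5000))
  expect_equal(effective_population_size(1, 1e6), 4, tolerance = 1e-5)
  expect_error(effective_population_size(0, 10), "positive")
})

test_that("ROH lengths convert from the log2 scale to kilobases", {
  expect_equal(log2_to_kb(18), 262)
  expect_equal(log2_to_kb(10), 1)
})

test_that("load-inbreeding correlation is monotone-consistent", {
  loads <- data.frame(sample_id = sprintf("s%d", 1:10),
                      load = seq(1e-3, 2e-3, length.out = 10))
  ibd <- data.frame(sample_id = sprintf("s%d", 1:10),
                    F = seq(0.05, 0.3, length.out = 10))
  expect_equal(correlate_load_inbreeding(loads, ibd)$rho, 1)
  expect_error(correlate_load_inbreeding(loads[1:3, ], ibd),
               "at least 5")
  sub <- correlate_load_inbreeding(loads, ibd,
                                   subset = sprintf("s%d", 1:6))
  expect_equal(sub$n, 6)
})
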