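#' Divergence-based purging proxy (dN - dS)
#'
#' Average mismatch fraction of one haploid genome against an outgroup
#' haplotype, computed separately at constrained sites (dN) and
#' nearly-neutral sites (dS). Efficient negative selection keeps dN below
#' dS, so more negative dN - dS means stronger purging of deleterious
#' variation.
#'
#' @param ind_hap,outgroup_hap Haploid allele vectors (0/1 coding on the
#'   same site set; `NA` missing).
#' @param constrained,neutral Logical or integer site subsets.
#' @return A list with `dN`, `dS`, `dn_minus_ds` and the compared site
#'   counts; values are `NA` when a set has no comparable site.
#' @export
dn_ds <- function(ind_hap, outgroup_hap, constrained, neutral) {
  stopifnot(length(ind_hap) == length(outgroup_hap))
  rate <- function(subset) {
    a <- ind_hap[subset]; b <- outgroup_hap[subset]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(c(NA_real_, 0))
    c(mean(a[ok] != b[ok]), sum(ok))
  }
  dn <- rate(constrained); ds <- rate(neutral)
  list(dN = dn[1L], dS = ds[1L], dn_minus_ds = dn[1L] - ds[1L],
       n_constrained = dn[2L], n_neutral = ds[2L])
}

#' Pairwise linkage disequilibrium (r-squared) within a distance window
#'
#' Squared Pearson correlation of allele dosages for every SNP pair on
#' the same chromosome less than `max_dist_bp` apart, with pairwise
#' deletion of missing genotypes. Monomorphic sites yield no pairs.
#'
#' @param dosage Samples x sites dosage matrix (0/1/2, `NA` missing).
#' @param chrom,pos Site coordinates (sorted within chromosome).
#' @param max_dist_bp Maximum pair distance (strict).
#' @return A `data.frame` with site indices `i`, `j` and `r2`.
#' @export
ld_r2_pairs <- function(dosage, chrom, pos, max_dist_bp = 50000) {
  n <- length(pos)
  stopifnot(ncol(dosage) == n, length(chrom) == n)
  v <- apply(dosage, 2L, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1L
  })
  out_i <- integer(0); out_j <- integer(0); out_r2 <- numeric(0)
  for (i in seq_len(n)) {
    if (!v[i]) next
    j <- i + 1L
    while (j <= n && chrom[j] == chrom[i] &&
           pos[j] - pos[i] < max_dist_bp) {
      if (v[j]) {
        r <- suppressWarnings(cor(dosage[, i], dosage[, j],
                                  use = "pairwise.complete.obs"))
        if (is.finite(r)) {
          out_i <- c(out_i, i); out_j <- c(out_j, j)
          out_r2 <- c(out_r2, r^2)
        }
      }
      j <- j + 1L
    }
  }
  data.frame(i = out_i, j = out_j, r2 = out_r2)
}

#' Cluster linked SNPs into blocks and pick representatives
#'
#' Builds a graph with an edge for every pair at or above the r-squared
#' threshold, takes connected components as LD blocks, and selects as
#' block representative the most central SNP — the one with the highest
#' degree, ties broken by leftmost position. Singleton SNPs represent
#' themselves.
#'
#' @param pairs Output of [ld_r2_pairs()].
#' @param n_sites Total number of sites.
#' @param pos Site positions (tie-breaking).
#' @param r2_threshold Minimum r-squared for an edge.
#' @return A `data.frame` with `site`, `block`, `degree` and
#'   `representative`.
#' @export
cluster_ld_blocks <- function(pairs, n_sites, pos, r2_threshold = 0.2) {
  stopifnot(length(pos) == n_sites)
  keep <- pairs$r2 >= r2_threshold
  g <- igraph::make_empty_graph(n = n_sites, directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(pairs$i[keep], pairs$j[keep]))
  comp <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  rep_flag <- logical(n_sites)
  for (b in split(seq_len(n_sites), comp)) {
    best <- b[deg[b] == max(deg[b])]
    rep_flag[best[which.min(pos[best])]] <- TRUE
  }
  data.frame(site = seq_len(n_sites), block = as.integer(comp),
             degree = as.integer(deg), representative = rep_flag)
}

#' Filter sites by genotype missingness
#'
#' @param dosage Samples x sites dosage matrix.
#' @param max_missing_frac Maximum tolerated fraction of missing
#'   genotypes per site.
#' @return Logical vector over sites.
#' @export
missingness_filter <- function(dosage, max_missing_frac = 0.10) {
  colMeans(is.na(dosage)) <= max_missing_frac
}

#' Co-estimate inbreeding and IBD tracts with a two-state HMM
#'
#' Hidden states are IBD (autozygous) and non-IBD. At a SNP with
#' population frequency p, a heterozygous genotype is emitted with
#' probability `2 p (1 - p) (1 - eps)` outside IBD tracts and with a
#' small leak probability `eps` (error/mutation) inside them.
#' Consecutive sites are coupled through an exponential distance kernel:
#' over a gap of `delta` bp the chain switches with scale
#' `1 - exp(-rate * delta)`, directed into each state proportionally to
#' the stationary probabilities `(1 - F, F)`. The three parameters — the
#' inbreeding coefficient F, the switch rate (inverse mean tract length)
#' and `eps` — are fitted by EM (numerical M-steps on the expected
#' complete-data log-likelihood, so the observed-data likelihood is
#' non-decreasing); iteration stops when the largest absolute parameter
#' change drops below `em_epsilon`, or earlier once the observed-data
#' likelihood has stabilized (relevant near the F = 0 and F = 1
#' boundaries, where parameters crawl along a flat ridge). IBD tracts
#' are reported by posterior decoding (state probability > 0.5).
#'
#' @param het 0/1 heterozygosity indicators per site (`NA` dropped).
#' @param chrom,pos Ordered site coordinates; chromosome changes decouple
#'   the chain.
#' @param freqs Population allele frequencies in (0, 1), one per site.
#' @param em_epsilon Convergence criterion on (F, eps, mean switch
#'   probability).
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE`.
#' @param init Optional named list overriding the starting values `F`,
#'   `rate`, `eps`.
#' @return An object of class `pl_ibd`: `F` (fitted stationary IBD
#'   probability), `rate`, `eps`, `tracts` (chrom/start/end),
#'   `ibd_fraction` (posterior-decoded fraction of sites in tracts),
#'   `posterior` (per-site IBD probability), `loglik` (trace),
#'   `em_iterations`, `converged`.
#' @export
fit_ibd_hmm <- function(het, chrom, pos, freqs, em_epsilon = 1e-7,
                        max_iter = 100L, init = NULL) {
  ok <- !is.na(het)
  het <- het[ok]; chrom <- chrom[ok]; pos <- pos[ok]; freqs <- freqs[ok]
  n <- length(het)
  stopifnot(n >= 2L, all(het %in% c(0L, 1L)),
            all(freqs > 0), all(freqs < 1),
            length(chrom) == n, length(pos) == n)
  gaps <- diff(pos)
  cross <- chrom[-1L] != chrom[-n]
  gaps[cross] <- Inf
  hw <- 2 * freqs * (1 - freqs)

  eps <- init$eps %||% 0.01
  Fc <- init$F %||% min(0.95, max(0.05, 1 - mean(het) / mean(hw)))
  rate <- init$rate %||% (1 / 2e6)

  emis_mat <- function(eps) {
    p_het_non <- hw * (1 - eps)
    cbind(ifelse(het == 1L, p_het_non, 1 - p_het_non),
          ifelse(het == 1L, eps, 1 - eps))
  }
  sw_of <- function(rate) {
    s <- 1 - exp(-rate * gaps)
    pmin(pmax(s, 1e-12), 1)
  }
  q_trans <- function(Fv, rate, fb) {
    s <- sw_of(rate)
    xi <- fb$xi
    g1 <- fb$gamma[1L, ]
    sum(xi[, 1L] * log(pmax(1 - Fv * s, 1e-300)) +
        xi[, 2L] * log(pmax(Fv * s, 1e-300)) +
        xi[, 3L] * log(pmax((1 - Fv) * s, 1e-300)) +
        xi[, 4L] * log(pmax(1 - (1 - Fv) * s, 1e-300))) +
      g1[1L] * log(max(1 - Fv, 1e-300)) + g1[2L] * log(max(Fv, 1e-300))
  }
  q_emis <- function(eps, fb) {
    p_het_non <- pmin(pmax(hw * (1 - eps), 1e-300), 1 - 1e-300)
    le_non <- ifelse(het == 1L, log(p_het_non), log1p(-p_het_non))
    le_ibd <- ifelse(het == 1L, log(eps), log1p(-eps))
    sum(fb$gamma[, 1L] * le_non + fb$gamma[, 2L] * le_ibd)
  }

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  fb <- NULL
  repeat {
    iter <- iter + 1L
    fb <- hmm_forward_backward(emis_mat(eps), sw_of(rate), Fc)
    loglik <- c(loglik, fb$loglik)

    opt <- optim(c(stats::qlogis(min(max(Fc, 1e-6), 1 - 1e-6)),
                   log(rate)),
                 function(par) -q_trans(stats::plogis(par[1L]),
                                        exp(par[2L]), fb),
                 method = "Nelder-Mead",
                 control = list(maxit = 200L))
    F_new <- stats::plogis(opt$par[1L])
    rate_new <- exp(opt$par[2L])
    eps_new <- stats::optimize(function(x) q_emis(x, fb),
                               c(1e-9, 0.2), maximum = TRUE,
                               tol = 1e-10)$maximum

    finite_gaps <- gaps[is.finite(gaps)]
    sw_scale <- if (length(finite_gaps)) mean(finite_gaps) else 1
    change <- max(abs(F_new - Fc), abs(eps_new - eps),
                  abs(1 - exp(-rate_new * sw_scale) -
                        (1 - exp(-rate * sw_scale))))
    Fc <- F_new; rate <- rate_new; eps <- eps_new
    if (change < em_epsilon) { converged <- TRUE; break }
    # secondary stop: observed-data likelihood has stabilized (helps
    # boundary cases such as F near 0 or 1 where parameters crawl)
    if (iter >= 3L &&
        abs(loglik[iter] - loglik[iter - 1L]) < 1e-6 * (1 + abs(loglik[iter]))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  fb <- hmm_forward_backward(emis_mat(eps), sw_of(rate), Fc)
  loglik <- c(loglik, fb$loglik)
  post <- fb$gamma[, 2L]
  states <- as.integer(post > 0.5)
  structure(list(F = Fc, rate = rate, eps = eps,
                 tracts = tracts_from_states(states, chrom, pos),
                 ibd_fraction = mean(states),
                 posterior = post, loglik = loglik,
                 em_iterations = iter, converged = converged),
            class = "pl_ibd")
}

#' @export
print.pl_ibd <- function(x, ...) {
  cat(sprintf(
    "IBD HMM fit: F = %.4f (%d tracts, %.1f%% of sites), eps = %.2e\n",
    x$F, nrow(x$tracts), 100 * x$ibd_fraction, x$eps))
  cat(sprintf("  EM: %d iterations, converged = %s\n",
              x$em_iterations, x$converged))
  invisible(x)
}

#' Variance effective population size of a sex-skewed breeding stock
#'
#' `Ne = 4 Nm Nf / (Nm + Nf)` for `Nm` breeding males and `Nf` breeding
#' females.
#'
#' @param n_males,n_females Positive breeding-stock sizes.
#' @return The effective size.
#' @examples
#' effective_population_size(20, 5000)  # ~80
#' @export
effective_population_size <- function(n_males, n_females) {
  if (any(n_males <= 0) || any(n_females <= 0))
    stop("breeding-stock sizes must be positive")
  4 * n_males * n_females / (n_males + n_females)
}

#' Convert a log2 tract length to kilobases
#'
#' ROH length distributions are conveniently summarized on a log2 (bp)
#' scale; this helper converts a log2 value back to (decimal) kilobases,
#' rounded to the nearest integer, for reporting. A value of 18
#' corresponds to 262 Kb.
#'
#' @param log2_bp Tract length as log2 of base pairs.
#' @return Length in Kb.
#' @examples
#' log2_to_kb(18)  # 262
#' @export
log2_to_kb <- function(log2_bp) round(2^log2_bp / 1000)

#' Correlate mutational load with inbreeding
#'
#' Spearman rank correlation between per-sample loads and inbreeding
#' coefficients, optionally on a subgroup (e.g. samples above a depth
#' cutoff).
#'
#' @param loads `data.frame` with `sample_id` and `load`.
#' @param ibd `data.frame` with `sample_id` and `F`.
#' @param subset Optional character vector of sample ids to keep.
#' @param min_n Minimum matched sample size (error below it).
#' @return A list with `rho`, `p_value` and `n`.
#' @export
correlate_load_inbreeding <- function(loads, ibd, subset = NULL,
                                      min_n = 5L) {
  m <- merge(loads[, c("sample_id", "load")],
             ibd[, c("sample_id", "F")], by = "sample_id")
  if (!is.null(subset)) m <- m[m$sample_id %in% subset, ]
  if (nrow(m) < min_n)
    stop("need at least ", min_n, " matched samples, got ", nrow(m))
  spearman_cor(m$load, m$F)
}
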