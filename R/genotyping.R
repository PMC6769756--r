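#' Genotype likelihoods from biallelic read counts
#'
#' Per-read model: a read drawn from allele A reports base b with
#' probability `1 - e` when `b == A` and `e / 3` otherwise; for a
#' heterozygous genotype each read comes from either allele with
#' probability one half. The site likelihood of a genotype is the product
#' over reads, and likelihoods are normalized over the three genotypes of
#' the biallelic site (hom-ref, het, hom-alt).
#'
#' @param n_ref,n_alt Reads supporting the reference and the alternative
#'   (deleterious) allele.
#' @param e Per-read error rate, `0 <= e < 0.75`.
#' @return Named numeric vector `c(RR, RA, AA)` summing to 1. With zero
#'   reads the likelihoods are uniform.
#' @examples
#' genotype_likelihoods(10, 0, e = 0.01)
#' @export
genotype_likelihoods <- function(n_ref, n_alt, e = 0.005) {
  stopifnot(length(n_ref) == 1L, length(n_alt) == 1L,
            n_ref >= 0, n_alt >= 0, e >= 0, e < 0.75)
  if (n_ref + n_alt == 0L)
    return(c(RR = 1 / 3, RA = 1 / 3, AA = 1 / 3))
  ll <- genotype_loglik_matrix(n_ref, n_alt, e)[1L, ]
  p <- exp(ll - max(ll))
  p / sum(p)
}

# Vectorized log-likelihoods; n_ref, n_alt vectors -> matrix n x 3.
# nlog() keeps 0 * log(0) = 0 so that e = 0 stays exact.
genotype_loglik_matrix <- function(n_ref, n_alt, e) {
  nlog <- function(n, l) ifelse(n == 0L, 0, n * l)
  l_hit <- log1p(-e); l_miss <- log(e / 3)
  l_het <- log(0.5 * (1 - e) + 0.5 * e / 3)
  cbind(RR = nlog(n_ref, l_hit) + nlog(n_alt, l_miss),
        RA = nlog(n_ref + n_alt, l_het),
        AA = nlog(n_ref, l_miss) + nlog(n_alt, l_hit))
}

#' Call a strict homozygous genotype
#'
#' The most likely genotype is called only when it is homozygous and its
#' normalized likelihood strictly exceeds the call threshold; all other
#' sites are masked with a reason code (`below_threshold`,
#' `heterozygous`, `no_data`).
#'
#' @param norm_likelihoods Named vector `c(RR, RA, AA)` summing to 1.
#' @param call_threshold Strict lower bound for the winning homozygote's
#'   normalized likelihood.
#' @param no_data Set `TRUE` when the site had zero reads.
#' @return A list with `genotype` (`"RR"`, `"AA"` or `NA`) and `reason`
#'   (`ok`, `below_threshold`, `heterozygous`, `no_data`).
#' @examples
#' call_genotype(c(RR = 0.995, RA = 0.005, AA = 0))
#' call_genotype(c(RR = 0.004, RA = 0.995, AA = 0.001))
#' @export
call_genotype <- function(norm_likelihoods, call_threshold = 0.99,
                          no_data = FALSE) {
  stopifnot(abs(sum(norm_likelihoods) - 1) < 1e-6)
  if (no_data)
    return(list(genotype = NA_character_, reason = "no_data"))
  k <- which.max(norm_likelihoods)
  g <- names(norm_likelihoods)[k]
  if (g == "RA")
    return(list(genotype = NA_character_, reason = "heterozygous"))
  if (norm_likelihoods[k] <= call_threshold)
    return(list(genotype = NA_character_, reason = "below_threshold"))
  list(genotype = g, reason = "ok")
}

#' Genotype-call matrix from read counts
#'
#' Applies the likelihood model and the strict homozygous-call rule to
#' every (sample, site) cell of a read-count matrix.
#'
#' @param counts A [count_matrix()] object (`r` = deleterious-allele
#'   reads, `d` = total depth).
#' @param e Per-read error rate.
#' @param call_threshold Strict normalized-likelihood threshold.
#' @return An object of class `pl_calls`: a list with `dosage`
#'   (samples x sites; 0 = hom reference, 2 = hom deleterious, `NA` =
#'   masked), `reason` (character matrix), the site coordinates and the
#'   per-sample masked fraction.
#' @export
call_matrix <- function(counts, e = 0.005, call_threshold = 0.99) {
  stopifnot(inherits(counts, "pl_counts"))
  n_alt <- as.vector(counts$r)
  depth <- as.vector(counts$d)
  n_ref <- depth - n_alt
  ll <- genotype_loglik_matrix(n_ref, n_alt, e)
  m <- apply(ll, 1L, max)
  p <- exp(ll - m)
  p <- p / rowSums(p)
  k <- max.col(p, ties.method = "first")
  win <- p[cbind(seq_along(k), k)]
  dosage <- rep(NA_integer_, length(k))
  reason <- rep("ok", length(k))
  reason[k == 2L] <- "heterozygous"
  reason[k != 2L & win <= call_threshold] <- "below_threshold"
  reason[depth == 0L] <- "no_data"
  called <- reason == "ok"
  dosage[called & k == 1L] <- 0L
  dosage[called & k == 3L] <- 2L
  dim(dosage) <- dim(counts$r)
  dim(reason) <- dim(counts$r)
  rownames(dosage) <- rownames(reason) <- counts$samples
  structure(list(dosage = dosage, reason = reason,
                 samples = counts$samples, chrom = counts$chrom,
                 pos = counts$pos, del_allele = counts$del_allele,
                 masked_fraction = rowMeans(is.na(dosage))),
            class = "pl_calls")
}

#' @export
print.pl_calls <- function(x, ...) {
  cat(sprintf("homozygous genotype calls: %d samples x %d sites\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  masked: %.1f%% (median across samples)\n",
              100 * median(x$masked_fraction)))
  invisible(x)
}

#' Write genotype calls as TSV
#'
#' Long format `sample chrom pos genotype reason`, with `genotype` the
#' called homozygous allele pair or `MASKED`.
#'
#' @param calls A `pl_calls` object.
#' @param sites Annotated site table supplying the reference allele (the
#'   major alignment-column allele).
#' @param path File path.
#' @export
write_calls <- function(calls, sites, path) {
  stopifnot(inherits(calls, "pl_calls"))
  cc <- parse_column_counts(sites$column_counts)
  ref <- vapply(cc, major_column_allele, "")
  n_s <- length(calls$samples); n_v <- length(calls$pos)
  dos <- as.vector(calls$dosage)
  g <- rep("MASKED", length(dos))
  ref_rep <- rep(ref, each = n_s)
  alt_rep <- rep(calls$del_allele, each = n_s)
  g[!is.na(dos) & dos == 0L] <- strrep(ref_rep[!is.na(dos) & dos == 0L], 2L)
  g[!is.na(dos) & dos == 2L] <- strrep(alt_rep[!is.na(dos) & dos == 2L], 2L)
  df <- data.frame(sample = rep(calls$samples, times = n_v),
                   chrom = rep(calls$chrom, each = n_s),
                   pos = rep(calls$pos, each = n_s),
                   genotype = g,
                   reason = as.vector(calls$reason))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
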