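#' Per-genome mutational load
#'
#' The load of a genome over a set of sites is the sum of phyloP scores
#' at called-homozygous positions carrying the deleterious allele (with
#' phyloP at least the constraint threshold), divided by the total number
#' of called homozygous sites in the set — deleterious-carrying or not.
#' Masked sites enter neither numerator nor denominator; sites without a
#' defined deleterious allele contribute only to the denominator.
#'
#' @param calls A [call_matrix()] result.
#' @param sites Annotated site table aligned with the call columns.
#' @param region Character vector of region classes to restrict to, or
#'   `"GENOME_WIDE"` (the default) for all sites.
#' @param phylop_threshold Minimum phyloP for a homozygous deleterious
#'   site to count in the numerator.
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `region_class`, `n_hom_deleterious`, `sum_phylop`, `n_hom_total`,
#'   `load` (`NA` when no homozygous site was called).
#' @export
compute_load <- function(calls, sites, region = "GENOME_WIDE",
                         phylop_threshold = 1.5) {
  stopifnot(inherits(calls, "pl_calls"),
            ncol(calls$dosage) == nrow(sites))
  region_label <- paste(region, collapse = "+")
  in_region <- if (identical(region, "GENOME_WIDE"))
    rep(TRUE, nrow(sites))
  else {
    stopifnot(all(region %in% REGION_CLASSES))
    sites$region_class %in% region
  }
  dos <- calls$dosage[, in_region, drop = FALSE]
  ph <- sites$phylop[in_region]
  del_ok <- !is.na(sites$deleterious_allele[in_region]) &
    ph >= phylop_threshold
  hom <- !is.na(dos)
  hom_del <- hom & dos == 2L
  hom_del[, !del_ok] <- FALSE
  n_hom_total <- as.integer(rowSums(hom))
  n_hom_del <- as.integer(rowSums(hom_del))
  sum_phylop <- as.vector(hom_del %*% ph)
  data.frame(sample_id = calls$samples,
             region_class = region_label,
             n_hom_deleterious = n_hom_del,
             sum_phylop = sum_phylop,
             n_hom_total = n_hom_total,
             load = ifelse(n_hom_total > 0, sum_phylop / n_hom_total,
                           NA_real_),
             row.names = NULL)
}

#' Summarize loads per breed
#'
#' @param loads Output of [compute_load()] (possibly several region
#'   classes bound together).
#' @param meta Sample metadata with `sample_id` and `breed`.
#' @return A `data.frame` keyed by breed and region class with mean,
#'   median, range and sample size; breeds represented by fewer than
#'   three genomes are flagged `low_confidence`. Samples whose breed is
#'   missing from the metadata are grouped as `"other"`.
#' @export
breed_summary <- function(loads, meta) {
  breed <- meta$breed[match(loads$sample_id, meta$sample_id)]
  breed[is.na(breed)] <- "other"
  key <- interaction(breed, loads$region_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(loads, key), function(g) {
    data.frame(breed = breed[match(g$sample_id[1L], loads$sample_id)],
               region_class = g$region_class[1L],
               n = nrow(g),
               mean_load = mean(g$load, na.rm = TRUE),
               median_load = median(g$load, na.rm = TRUE),
               min_load = suppressWarnings(min(g$load, na.rm = TRUE)),
               max_load = suppressWarnings(max(g$load, na.rm = TRUE)),
               low_confidence = nrow(g) < 3L)
  }))
  rownames(out) <- NULL
  out[order(out$region_class, -out$mean_load), ]
}

#' Two-sample Wilcoxon rank-sum comparison of loads
#'
#' Exact enumeration when the pooled sample size is at most 12 and the
#' data are tie-free; the tie-corrected normal approximation otherwise.
#' With all observations tied the p-value is 1.
#'
#' @param x,y Numeric load vectors (each of length at least 2).
#' @param alternative Passed to [stats::wilcox.test()]; two-sided by
#'   default.
#' @return A list with `statistic` (the Mann-Whitney U for `x`),
#'   `p_value` and `method`.
#' @examples
#' group_compare(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
group_compare <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all tied)"))
  exact <- (length(x) + length(y) <= 12L) &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

# Spearman rank correlation with average ranks for ties; p-value by the
# t approximation. Returns NA correlation for constant input.
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Pairwise correlation of loads across region classes
#'
#' Spearman rank correlation of per-sample loads between every pair of
#' region classes.
#'
#' @param loads Long `data.frame` from [compute_load()] run per region
#'   class (rows = sample x region).
#' @param min_n Minimum number of paired observations per comparison.
#' @return A `data.frame` with `region_a`, `region_b`, `rho`, `p_value`,
#'   `n`.
#' @export
region_correlation <- function(loads, min_n = 5L) {
  regions <- unique(loads$region_class)
  if (length(regions) < 2L) stop("need at least two region classes")
  wide <- lapply(regions, function(rc) {
    g <- loads[loads$region_class == rc, ]
    setNames(g$load, g$sample_id)
  })
  names(wide) <- regions
  samples <- Reduce(intersect, lapply(wide, names))
  pairs <- utils::combn(regions, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- wide[[pairs[1L, j]]][samples]
    b <- wide[[pairs[2L, j]]][samples]
    if (sum(is.finite(a) & is.finite(b)) < min_n)
      stop("fewer than ", min_n, " paired observations for ",
           pairs[1L, j], " vs ", pairs[2L, j])
    sc <- spearman_cor(a, b)
    data.frame(region_a = pairs[1L, j], region_b = pairs[2L, j],
               rho = sc$rho, p_value = sc$p_value, n = sc$n)
  })
  do.call(rbind, out)
}
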