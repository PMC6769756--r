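#' Maximum-likelihood allele frequency from pooled read counts
#'
#' Maximizes the product over individuals of Binomial(r_i; d_i, p) in the
#' shared frequency p. Individuals with zero depth are ignored. The
#' maximizer has the closed form sum(r) / sum(d) (the pooled-binomial
#' MLE); `method = "optimize"` instead locates the root of the score
#' function numerically and is kept as an independent route for
#' verification.
#'
#' @param r Deleterious-allele read counts per individual.
#' @param d Total depths per individual (`0 <= r <= d`).
#' @param method `"closed_form"` (default) or `"optimize"`.
#' @return The ML frequency in `[0, 1]`, or `NA` when the total depth is
#'   zero.
#' @examples
#' ml_frequency(c(2, 1), c(4, 2))  # 0.5
#' @export
ml_frequency <- function(r, d, method = c("closed_form", "optimize")) {
  method <- match.arg(method)
  stopifnot(length(r) == length(d), all(r >= 0), all(r <= d))
  keep <- d > 0
  r <- r[keep]; d <- d[keep]
  R <- sum(r); D <- sum(d)
  if (D == 0) return(NA_real_)
  if (R == 0) return(0)
  if (R == D) return(1)
  if (method == "closed_form") return(R / D)
  score <- function(p) R / p - (D - R) / (1 - p)
  uniroot(score, c(1e-12, 1 - 1e-12), tol = 1e-13)$root
}

#' Temporal bins of ancient samples
#'
#' Sliding windows of `bin_width` years stepped every `bin_step` years;
#' a sample of age a belongs to the bin centered at c when
#' `a` lies in `[c - width/2, c + width/2)` (half-open, so a sample at
#' the upper edge falls into the next bin only). Only samples with
#' `age_bp > 0` are binned.
#'
#' @param meta Sample metadata (`sample_id`, `age_bp`).
#' @param bin_width,bin_step Window width and step, in years.
#' @return A list of bins, each a list with `center`, `lo`, `hi` and
#'   `members` (sample ids); bins without members are dropped. The
#'   minimum per-site sample count is enforced later, at estimation
#'   time.
#' @export
bin_samples <- function(meta, bin_width = 1000, bin_step = 250) {
  anc <- meta[meta$age_bp > 0, ]
  if (nrow(anc) == 0L) return(list())
  centers <- seq(bin_step, max(anc$age_bp) + bin_width / 2, by = bin_step)
  bins <- lapply(centers, function(ct) {
    lo <- ct - bin_width / 2; hi <- ct + bin_width / 2
    members <- anc$sample_id[anc$age_bp >= lo & anc$age_bp < hi]
    list(center = ct, lo = lo, hi = hi, members = members)
  })
  Filter(function(b) length(b$members) > 0L, bins)
}

#' Per-bin ML frequency trajectories
#'
#' For each site and temporal bin, pools the read counts of the bin's
#' members and computes the ML frequency, provided at least `min_bin_n`
#' individuals are genotyped (depth > 0) at that site in that bin. The
#' modern panel enters as its own bin at 0 BP.
#'
#' @param counts A [count_matrix()] object.
#' @param sites Annotated site table aligned with the count columns.
#' @param meta Sample metadata.
#' @param config A [pl_config()] object (binning scheme, `min_bin_n`).
#' @param transversions_only Drop transition sites entirely.
#' @param include_modern Add the pooled modern panel as a bin at 0 BP.
#' @return An object of class `pl_traj`: list with `f` (sites x bins ML
#'   frequencies, `NA` where uninformative), `n` (individuals genotyped),
#'   `centers` (years BP), `site_index` (columns of `counts` retained)
#'   and the matching `sites` rows.
#' @export
estimate_trajectories <- function(counts, sites, meta,
                                  config = pl_config(),
                                  transversions_only = FALSE,
                                  include_modern = TRUE) {
  stopifnot(inherits(counts, "pl_counts"),
            nrow(sites) == ncol(counts$r))
  keep <- !is.na(sites$deleterious_allele)
  if (transversions_only)
    keep <- keep & !is.na(sites$mutation_class) &
      sites$mutation_class == "transversion"
  site_index <- which(keep)
  bins <- bin_samples(meta, config$bin_width_years, config$bin_step_years)
  centers <- vapply(bins, `[[`, 0, "center")
  members <- lapply(bins, `[[`, "members")
  if (include_modern && any(meta$age_bp == 0)) {
    centers <- c(centers, 0)
    members <- c(members, list(meta$sample_id[meta$age_bp == 0]))
  }
  ord <- order(centers, decreasing = TRUE)  # oldest first
  centers <- centers[ord]; members <- members[ord]
  n_bins <- length(centers)
  f <- matrix(NA_real_, length(site_index), n_bins)
  ng <- matrix(0L, length(site_index), n_bins)
  for (b in seq_len(n_bins)) {
    rows <- match(members[[b]], counts$samples)
    rows <- rows[!is.na(rows)]
    if (!length(rows)) next
    rb <- counts$r[rows, site_index, drop = FALSE]
    db <- counts$d[rows, site_index, drop = FALSE]
    n_g <- colSums(db > 0L)
    fb <- colSums(rb) / colSums(db)  # pooled-binomial MLE per site
    fb[n_g < config$min_bin_n] <- NA_real_
    f[, b] <- fb
    ng[, b] <- n_g
  }
  structure(list(f = f, n = ng, centers = centers,
                 site_index = site_index,
                 sites = sites[site_index, , drop = FALSE]),
            class = "pl_traj")
}

#' @export
print.pl_traj <- function(x, ...) {
  cat(sprintf("allele-frequency trajectories: %d sites x %d bins\n",
              nrow(x$f), length(x$centers)))
  cat("  bin centers (years BP):", paste(x$centers, collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify a variant's temporal trajectory
#'
#' A variant is `fixed` when every available ML frequency (ancient bins
#' and, when present, the modern panel) is at least the fixed threshold,
#' `absent` when every one is below the absent threshold, `dynamic`
#' otherwise and `unclassified` with no informative bin.
#'
#' @param traj A `pl_traj` object, or a numeric matrix of per-bin
#'   frequencies (sites in rows).
#' @param fixed_threshold,absent_threshold Classification cutoffs.
#' @param phylop_min Optionally restrict to sites with at least this
#'   phyloP (rows failing it are `NA`); requires a `pl_traj` input.
#' @return Character vector, one class per site.
#' @export
classify_trajectory <- function(traj, fixed_threshold = 0.99,
                                absent_threshold = 0.01,
                                phylop_min = NULL) {
  f <- if (inherits(traj, "pl_traj")) traj$f else as.matrix(traj)
  cls <- apply(f, 1L, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return("unclassified")
    if (all(row >= fixed_threshold)) return("fixed")
    if (all(row < absent_threshold)) return("absent")
    "dynamic"
  })
  if (!is.null(phylop_min)) {
    stopifnot(inherits(traj, "pl_traj"))
    cls[traj$sites$phylop < phylop_min] <- NA_character_
  }
  cls
}

#' Frequency shifts between non-overlapping time bins
#'
#' Computes, for each variant, the change in ML frequency between
#' consecutive non-overlapping bins (by default centered at 3250, 2250,
#' 1250 and 250 years BP). The shift from the older to the younger bin is
#' reported at the younger bin's center.
#'
#' @param traj A `pl_traj` object.
#' @param centers Non-overlapping bin centers, oldest to youngest.
#' @return A `data.frame` with `site` (row index into `traj`),
#'   `interval_center`, `delta_abs` and `delta_signed`
#'   (younger minus older); intervals with a missing endpoint are
#'   dropped.
#' @export
delta_series <- function(traj, centers = c(3250, 2250, 1250, 250)) {
  stopifnot(inherits(traj, "pl_traj"), length(centers) >= 2L)
  centers <- sort(centers, decreasing = TRUE)
  cols <- match(centers, traj$centers)
  if (any(is.na(cols)))
    stop("bin center(s) absent from trajectories: ",
         paste(centers[is.na(cols)], collapse = ", "))
  out <- lapply(seq_len(length(centers) - 1L), function(k) {
    older <- traj$f[, cols[k]]; younger <- traj$f[, cols[k + 1L]]
    ok <- !is.na(older) & !is.na(younger)
    data.frame(site = which(ok),
               interval_center = rep(centers[k + 1L], sum(ok)),
               delta_abs = abs(younger - older)[ok],
               delta_signed = (younger - older)[ok])
  })
  do.call(rbind, out)
}

#' Pooled modern-versus-ancient frequency comparison
#'
#' Pools all ancient and all modern samples, estimates each variant's ML
#' frequency in both pools, and reports the mean frequency per pool and
#' the modern-minus-ancient difference, stratified by mutation class
#' (transitions vs transversions). By default the comparison is
#' ascertained on deleterious alleles observed in the modern panel
#' (pooled modern count > 0), mirroring a variant set discovered in
#' modern genomes.
#'
#' @param counts A [count_matrix()] object.
#' @param sites Annotated site table.
#' @param meta Sample metadata.
#' @param min_n Minimum individuals genotyped per pool and site.
#' @param ascertain_modern Restrict to variants discovered in the
#'   modern panel, i.e. carried as a called homozygous genotype by at
#'   least one modern sample (raw read counts cannot be used for
#'   discovery: at pooled depths of thousands of reads, sequencing
#'   error alone puts a few deleterious-allele reads at almost every
#'   site).
#' @param calls Optional [call_matrix()] result used for the
#'   ascertainment; computed internally (default error rate) when
#'   absent.
#' @param transversions_only Drop transition sites entirely.
#' @return A `data.frame` with one row per stratum (`transition`,
#'   `transversion`, `all`): mean ancient and modern frequency, their
#'   difference and the number of variants.
#' @export
pooled_comparison <- function(counts, sites, meta, min_n = 10L,
                              ascertain_modern = TRUE, calls = NULL,
                              transversions_only = FALSE) {
  stopifnot(inherits(counts, "pl_counts"))
  anc_rows <- match(meta$sample_id[meta$age_bp > 0], counts$samples)
  mod_rows <- match(meta$sample_id[meta$age_bp == 0], counts$samples)
  anc_rows <- anc_rows[!is.na(anc_rows)]
  mod_rows <- mod_rows[!is.na(mod_rows)]
  if (!length(anc_rows) || !length(mod_rows))
    stop("both an ancient and a modern pool are required")
  pool_f <- function(rows) {
    R <- colSums(counts$r[rows, , drop = FALSE])
    D <- colSums(counts$d[rows, , drop = FALSE])
    n_g <- colSums(counts$d[rows, , drop = FALSE] > 0L)
    ifelse(n_g >= min_n & D > 0, R / D, NA_real_)
  }
  f_anc <- pool_f(anc_rows)
  f_mod <- pool_f(mod_rows)
  keep <- !is.na(sites$deleterious_allele) & !is.na(f_anc) & !is.na(f_mod)
  if (ascertain_modern) {
    if (is.null(calls)) calls <- call_matrix(counts)
    hom_del <- calls$dosage[mod_rows, , drop = FALSE] == 2L
    keep <- keep & colSums(hom_del, na.rm = TRUE) > 0L
  }
  if (transversions_only)
    keep <- keep & !is.na(sites$mutation_class) &
      sites$mutation_class == "transversion"
  strata <- list(all = keep,
                 transition = keep & !is.na(sites$mutation_class) &
                   sites$mutation_class == "transition",
                 transversion = keep & !is.na(sites$mutation_class) &
                   sites$mutation_class == "transversion")
  out <- lapply(names(strata), function(nm) {
    ix <- strata[[nm]]
    if (!any(ix))
      return(data.frame(stratum = nm, n = 0L,
                        mean_f_ancient = NA_real_,
                        mean_f_modern = NA_real_,
                        difference = NA_real_))
    data.frame(stratum = nm, n = sum(ix),
               mean_f_ancient = mean(f_anc[ix]),
               mean_f_modern = mean(f_mod[ix]),
               difference = mean(f_mod[ix]) - mean(f_anc[ix]))
  })
  do.call(rbind, out)
}
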