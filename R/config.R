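#' Pipeline configuration
#'
#' Collects the thresholds and window parameters shared across all analysis
#' stages: the phyloP cutoff separating constrained from nearly-neutral
#' sites, the strict homozygous genotype-call threshold, the fixed/absent
#' trajectory cutoffs, the temporal binning scheme, the LD-pruning distance
#' and the EM convergence criterion used by the IBD model.
#'
#' @param phylop_threshold Minimum phyloP score for a site to count as
#'   evolutionarily constrained, so that its rare allele is treated as
#'   deleterious. Sites with `phylop >= phylop_threshold` are constrained.
#' @param call_threshold Normalized genotype likelihood a homozygous
#'   genotype must exceed (strictly) to be called; everything else is
#'   masked.
#' @param fixed_threshold A variant whose ML frequency is at least this in
#'   every informative time bin is classified as (nearly) fixed.
#' @param absent_threshold A variant whose ML frequency is below this in
#'   every informative time bin is classified as (nearly) absent.
#' @param bin_width_years Width of the sliding temporal windows, in years.
#' @param bin_step_years Step between successive window centers, in years.
#' @param min_bin_n Minimum number of individuals genotyped (depth > 0) at
#'   a site within a bin for its frequency estimate to be retained.
#' @param ld_max_dist_bp Maximum pair distance, in bp, for LD (r-squared)
#'   computation.
#' @param ld_r2_threshold Minimum r-squared for two SNPs to be linked into
#'   the same LD block.
#' @param em_epsilon EM convergence criterion: iteration stops when the
#'   largest absolute parameter change falls below this value.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A named list of class `pl_config`.
#' @examples
#' cfg <- pl_config()
#' cfg$phylop_threshold
#' @export
pl_config <- function(phylop_threshold = 1.5,
                      call_threshold = 0.99,
                      fixed_threshold = 0.99,
                      absent_threshold = 0.01,
                      bin_width_years = 1000,
                      bin_step_years = 250,
                      min_bin_n = 10,
                      ld_max_dist_bp = 50000,
                      ld_r2_threshold = 0.2,
                      em_epsilon = 1e-7,
                      seed = NULL) {
  stopifnot(is.numeric(phylop_threshold), length(phylop_threshold) == 1L,
            is.finite(phylop_threshold))
  if (!(absent_threshold > 0 && absent_threshold < fixed_threshold &&
        fixed_threshold <= 1))
    stop("need 0 < absent_threshold < fixed_threshold <= 1")
  if (!(call_threshold > 0 && call_threshold < 1))
    stop("call_threshold must lie in (0, 1)")
  if (!(bin_step_years > 0 && bin_width_years > 0 &&
        bin_step_years <= bin_width_years))
    stop("need 0 < bin_step_years <= bin_width_years")
  stopifnot(min_bin_n >= 1, ld_max_dist_bp > 0,
            ld_r2_threshold >= 0, ld_r2_threshold <= 1, em_epsilon > 0)
  structure(list(phylop_threshold = phylop_threshold,
                 call_threshold = call_threshold,
                 fixed_threshold = fixed_threshold,
                 absent_threshold = absent_threshold,
                 bin_width_years = bin_width_years,
                 bin_step_years = bin_step_years,
                 min_bin_n = min_bin_n,
                 ld_max_dist_bp = ld_max_dist_bp,
                 ld_r2_threshold = ld_r2_threshold,
                 em_epsilon = em_epsilon,
                 seed = seed),
            class = "pl_config")
}

#' @export
print.pl_config <- function(x, ...) {
  cat("paleoload configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a [pl_config()] object;
#'   `write_config()` invisibly returns `path`.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_config(pl_config(min_bin_n = 5), p)
#' read_config(p)$min_bin_n
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pl_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(pl_config, vals)
}

#' @rdname read_config
#' @param config A [pl_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pl_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}
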