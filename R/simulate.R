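`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario parameters for the synthetic-data generator
#'
#' Defines a horse-like study design: deleterious variants segregating at
#' low frequency over several millennia under drift and recessive
#' selection, a recent bottleneck-driven inbreeding burst, heterochronous
#' ancient samples with modest sequencing depth and post-mortem damage,
#' and a panel of modern genomes carrying IBD tracts.
#'
#' Defaults give 20,000 variant sites of which about half are constrained
#' (phyloP >= 1.5, hence deleterious), 150 ancient genomes spread over the
#' last ~3.7 millennia and 150 modern genomes split into working, hotblood
#' and warmblood management groups with group-specific inbreeding levels.
#' The ancestral population is large (Ne = 10,000, so allele frequencies
#' are nearly steady across the sampled millennia) and collapses to
#' Ne = 80 — the effective size implied by a breeding stock of 20
#' stallions and 5000 mares — 250 years before present.
#'
#' @param n_sites Number of variant sites simulated.
#' @param region_mix Proportions of the five region classes (must sum
#'   to 1).
#' @param prop_constrained Fraction of sites with phyloP >= 1.5.
#' @param phylop_tail_mean Mean phyloP of constrained sites, per region
#'   class.
#' @param ancestral_Ne,bottleneck_Ne Diploid effective sizes before/after
#'   the collapse.
#' @param bottleneck_time_years Years before present at which the
#'   bottleneck starts.
#' @param selection_scale k in s = -k * phyloP for constrained sites
#'   (recessive, h = 0); neutral sites have s = 0.
#' @param generation_time_years Generation time (years).
#' @param span_years Total simulated time span (years before present).
#' @param n_ancient,n_modern Panel sizes.
#' @param sample_schedule Optional data.frame with columns `age_bp`,
#'   `n` and `depth_mean` describing the ancient sampling design; by
#'   default a deterministic schedule of age points every 250 years
#'   across `ancient_age_range`, each carrying an equal share of
#'   `n_ancient` individuals whose mean depths ramp across
#'   `ancient_depth_range`.
#' @param ancient_age_range Age range (years BP) of ancient samples.
#' @param ancient_depth_range Range of per-sample mean depths for ancient
#'   genomes.
#' @param modern_depth Mean depth of modern genomes.
#' @param error_rate Per-read sequencing error rate.
#' @param damage_rate Per-read C-to-T (and complementary G-to-A)
#'   post-mortem conversion rate for ancient samples.
#' @param user_treated If `TRUE`, USER enzymatic treatment is emulated by
#'   reducing `damage_rate` tenfold.
#' @param modern_F_ranges Named list of inbreeding-coefficient ranges for
#'   the three modern management groups.
#' @param mean_roh_length_bp Mean IBD tract length (bp).
#' @param genome_length_bp Total genome length (bp), spread over
#'   `n_chrom` chromosomes.
#' @param n_chrom Number of chromosomes.
#' @param prop_start_fixed Fraction of sites whose deleterious allele is
#'   already fixed at the start of the simulation (ancient standing
#'   variation that spread before the sampled period).
#' @param init_beta Shape parameters of the Beta distribution of initial
#'   frequencies for the remaining sites (rare standing variation).
#' @param purging_strength Probability that a deleterious autozygous draw
#'   inside an IBD tract is purged (replaced by the non-carrier allele);
#'   0 disables purging.
#' @param ti_prob Probability that the deleterious allele forms a
#'   transition with the reference allele.
#' @param outgroup_divergence Per-site divergence of the outgroup at
#'   neutral sites.
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the parameters and this seed.
#' @return A named list of class `pl_scenario`.
#' @export
scenario_params <- function(n_sites = 20000,
                            region_mix = c(coding = 0.05,
                                           upstream2kb = 0.05,
                                           downstream2kb = 0.05,
                                           intron = 0.35,
                                           intergenic = 0.50),
                            prop_constrained = 0.5,
                            phylop_tail_mean = c(coding = 2.316,
                                                 upstream2kb = 2.096,
                                                 downstream2kb = 2.097,
                                                 intron = 2.0,
                                                 intergenic = 1.964),
                            ancestral_Ne = 10000,
                            bottleneck_Ne = 80,
                            bottleneck_time_years = 250,
                            selection_scale = 0.001,
                            generation_time_years = 8,
                            span_years = 3800,
                            n_ancient = 150,
                            n_modern = 150,
                            sample_schedule = NULL,
                            ancient_age_range = c(50, 3700),
                            ancient_depth_range = c(1, 39),
                            modern_depth = 10,
                            error_rate = 0.005,
                            damage_rate = 0.02,
                            user_treated = TRUE,
                            modern_F_ranges = list(working = c(0.15, 0.35),
                                                   hotblood = c(0, 0.10),
                                                   warmblood = c(0, 0.15)),
                            mean_roh_length_bp = 5e6,
                            genome_length_bp = 2.5e8,
                            n_chrom = 5,
                            prop_start_fixed = 0.10,
                            init_beta = c(0.25, 8),
                            purging_strength = 0,
                            ti_prob = 2 / 3,
                            outgroup_divergence = 0.005,
                            seed = 1L) {
  stopifnot(n_sites >= 0,
            abs(sum(region_mix) - 1) < 1e-8,
            setequal(names(region_mix), REGION_CLASSES),
            prop_constrained >= 0, prop_constrained <= 1,
            ancestral_Ne >= 2, bottleneck_Ne >= 2,
            selection_scale >= 0, generation_time_years > 0,
            span_years > bottleneck_time_years,
            error_rate >= 0, error_rate < 1,
            damage_rate >= 0, damage_rate < 1,
            purging_strength >= 0, purging_strength <= 1,
            prop_start_fixed >= 0, prop_start_fixed <= 1,
            ti_prob >= 0, ti_prob <= 1,
            mean_roh_length_bp > 0, genome_length_bp > n_sites,
            n_chrom >= 1)
  for (rg in modern_F_ranges)
    stopifnot(all(rg >= 0), all(rg <= 1))
  structure(as.list(environment()), class = "pl_scenario")
}

# Deterministic one-generation update for a recessive deleterious allele
# at frequency p with selection coefficient s <= 0 against the
# deleterious homozygote (h = 0).
wf_post_selection <- function(p, s) {
  a <- abs(s)
  (p^2 * (1 - a) + p * (1 - p)) / (1 - a * p^2)
}

#' Forward Wright-Fisher allele-frequency trajectories
#'
#' Simulates per-generation binomial resampling of `2 Ne` allele copies
#' with recessive selection against the deleterious homozygote, under a
#' piecewise-constant demography (ancestral size collapsing to the
#' bottleneck size at `bottleneck_time_years` before present). Boundary
#' frequencies 0 and 1 are absorbing.
#'
#' @param params A [scenario_params()] object.
#' @param p0 Initial frequencies (one per site); drawn from the scenario's
#'   initial-frequency model when `NULL`.
#' @param s Selection coefficients (<= 0, one per site); all zero when
#'   `NULL`.
#' @param deterministic If `TRUE`, skip drift and iterate the
#'   deterministic selection recursion (infinite-Ne limit).
#' @return A list with `freq` (sites x generations matrix), `age_bp`
#'   (years BP of each generation column, last column = present), `p0`
#'   and `s`.
#' @export
simulate_frequency_trajectories <- function(params, p0 = NULL, s = NULL,
                                            deterministic = FALSE) {
  stopifnot(inherits(params, "pl_scenario"))
  gen <- params$generation_time_years
  n_gen <- floor(params$span_years / gen) + 1L
  age_bp <- (n_gen - seq_len(n_gen)) * gen
  n <- if (!is.null(p0)) length(p0) else params$n_sites
  if (is.null(p0)) {
    fixed <- runif(n) < params$prop_start_fixed
    p0 <- ifelse(fixed, 1,
                 rbeta(n, params$init_beta[1], params$init_beta[2]))
  }
  if (is.null(s)) s <- numeric(n)
  stopifnot(length(s) == n, all(p0 >= 0), all(p0 <= 1), all(abs(s) < 1))
  freq <- matrix(0, n, n_gen)
  freq[, 1L] <- p0
  if (n > 0L) for (g in 2L:n_gen) {
    ne <- if (age_bp[g] < params$bottleneck_time_years)
      params$bottleneck_Ne else params$ancestral_Ne
    p_sel <- wf_post_selection(freq[, g - 1L], s)
    freq[, g] <- if (deterministic) p_sel
                 else rbinom(n, 2L * ne, p_sel) / (2 * ne)
  }
  list(freq = freq, age_bp = age_bp, p0 = p0, s = s)
}

# Map an age (years BP) to the nearest simulated generation column.
age_to_generation <- function(age_bp, traj) {
  ix <- vapply(age_bp, function(a) which.min(abs(traj$age_bp - a)), 0L)
  as.integer(ix)
}

# Switch scales 1 - exp(-dist / mean_tract) between consecutive sites;
# chromosome changes fully randomize the chain (scale 1).
switch_scales <- function(chrom, pos, mean_tract_bp) {
  n <- length(pos)
  if (n <= 1L) return(numeric(0))
  d <- diff(pos)
  sw <- 1 - exp(-d / mean_tract_bp)
  sw[chrom[-1L] != chrom[-n]] <- 1
  sw
}

#' Draw one diploid genome given allele frequencies and inbreeding
#'
#' IBD status is simulated as a two-state Markov chain along the genome
#' with stationary IBD probability `F_target` and mean tract length
#' `mean_roh_length_bp`. Inside IBD tracts one allele is drawn at the
#' population frequency and duplicated (autozygosity); outside, the
#' genotype is a Hardy-Weinberg draw. With `purging_strength > 0`, a
#' deleterious autozygous draw (s < 0) is replaced by the non-carrier
#' allele with that probability, emulating selection against recessive
#' homozygotes exposed inside ROHs.
#'
#' @param freqs Per-site deleterious-allele frequencies at the
#'   individual's time.
#' @param chrom,pos Ordered site coordinates.
#' @param F_target Stationary IBD fraction in `[0, 1]`.
#' @param mean_roh_length_bp Mean IBD tract length (bp).
#' @param s Per-site selection coefficients (used only by purging).
#' @param purging_strength See [scenario_params()].
#' @return A list with `genotype` (0/1/2 copies of the deleterious
#'   allele), `ibd` (0/1 per site), `F_realized` and `tracts`
#'   (data.frame chrom/start/end).
#' @export
sample_individual_genotypes <- function(freqs, chrom, pos, F_target,
                                        mean_roh_length_bp = 5e6,
                                        s = NULL, purging_strength = 0) {
  n <- length(freqs)
  stopifnot(length(chrom) == n, length(pos) == n,
            F_target >= 0, F_target <= 1,
            all(freqs >= 0), all(freqs <= 1))
  if (n == 0L)
    return(list(genotype = integer(0), ibd = integer(0),
                F_realized = NA_real_,
                tracts = data.frame(chrom = character(0),
                                    start = integer(0), end = integer(0))))
  sw <- switch_scales(chrom, pos, mean_roh_length_bp)
  ibd <- sim_two_state_chain(sw, F_target)
  g <- integer(n)
  out <- ibd == 0L
  g[out] <- rbinom(sum(out), 2L, freqs[out])
  hap <- rbinom(sum(!out), 1L, freqs[!out])
  if (purging_strength > 0 && !is.null(s)) {
    sel <- s[!out] < 0
    purge <- sel & hap == 1L & runif(length(hap)) < purging_strength
    hap[purge] <- 0L
  }
  g[!out] <- 2L * hap
  list(genotype = g, ibd = ibd, F_realized = mean(ibd),
       tracts = tracts_from_states(ibd, chrom, pos))
}

tracts_from_states <- function(states, chrom, pos) {
  n <- length(states)
  if (n == 0L || !any(states == 1L))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  brk <- c(TRUE, states[-1L] != states[-n] | chrom[-1L] != chrom[-n])
  run_id <- cumsum(brk)
  keep <- tapply(states, run_id, `[`, 1L) == 1L
  starts <- tapply(pos, run_id, min)[keep]
  ends <- tapply(pos, run_id, max)[keep]
  chr <- tapply(chrom, run_id, `[`, 1L)[keep]
  data.frame(chrom = as.character(chr), start = as.integer(starts),
             end = as.integer(ends), row.names = NULL)
}

damage_partner <- function(base) c(C = "T", G = "A")[base]

# Probability that a read supports the deleterious (alt) allele given the
# alt-allele dosage fraction q, the sequencing error rate e and the
# effective damage rate delta (C->T on C templates, G->A on G templates).
read_alt_prob <- function(q, e, delta, ref, alt) {
  d_ref <- ifelse(ref %in% c("C", "G"), delta, 0)
  d_alt <- ifelse(alt %in% c("C", "G"), delta, 0)
  hit_after_damage <- ifelse(!is.na(damage_partner(ref)) &
                               damage_partner(ref) == alt, 1 - e, e / 3)
  p_ref_tmpl <- (1 - d_ref) * (e / 3) + d_ref * hit_after_damage
  p_alt_tmpl <- (1 - d_alt) * (1 - e) + d_alt * (e / 3)
  q * p_alt_tmpl + (1 - q) * p_ref_tmpl
}

#' Simulate read counts from diploid genotypes
#'
#' Per-site depth is Poisson with the sample's mean depth; each read is
#' drawn from the true genotype with sequencing error `error_rate`
#' (uniform over the three other bases) and, for damaged (ancient)
#' samples, an additional C-to-T / G-to-A post-mortem conversion applied
#' at the template level. USER treatment scales the damage rate down
#' tenfold.
#'
#' @param genotypes Samples x sites integer matrix (0/1/2 copies of the
#'   deleterious allele).
#' @param depth_mean Per-sample mean depth (recycled if scalar).
#' @param error_rate Per-read error rate.
#' @param damage_rate Per-sample damage rate (0 for modern samples;
#'   recycled if scalar).
#' @param user_treated Logical; halves nothing but divides the damage
#'   rate by 10 when `TRUE`.
#' @param ref,alt Per-site reference and deleterious alleles.
#' @param chrom,pos Site coordinates for the returned container.
#' @param samples Sample ids.
#' @return A [count_matrix()] object.
#' @export
simulate_read_counts <- function(genotypes, depth_mean,
                                 error_rate = 0.005, damage_rate = 0,
                                 user_treated = TRUE, ref, alt,
                                 chrom, pos, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  n_s <- nrow(genotypes); n_v <- ncol(genotypes)
  depth_mean <- rep_len(depth_mean, n_s)
  damage_rate <- rep_len(damage_rate, n_s)
  stopifnot(all(depth_mean > 0), length(ref) == n_v, length(alt) == n_v)
  samples <- samples %||% rownames(genotypes) %||%
    sprintf("s%03d", seq_len(n_s))
  r <- matrix(0L, n_s, n_v); d <- matrix(0L, n_s, n_v)
  for (i in seq_len(n_s)) {
    di <- rpois(n_v, depth_mean[i])
    delta <- damage_rate[i] * if (user_treated) 0.1 else 1
    p_alt <- read_alt_prob(genotypes[i, ] / 2, error_rate, delta, ref, alt)
    r[i, ] <- rbinom(n_v, di, pmin(pmax(p_alt, 0), 1))
    d[i, ] <- di
  }
  count_matrix(samples, chrom, pos, alt, r, d)
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generative model: site annotations (region classes,
#' phyloP scores, alignment-column tallies), Wright-Fisher frequency
#' trajectories, heterochronous diploid genomes with IBD tracts, read
#' counts with error and damage, an outgroup haplotype, and sample
#' metadata. With `outdir` set, everything is written in the package's
#' standard text formats together with a ground-truth JSON and the
#' scenario YAML.
#'
#' @param params A [scenario_params()] object.
#' @param outdir Optional output directory (created if needed).
#' @return Invisibly, a list with `params`, `sites` (annotated site
#'   table), `meta`, `counts`, `dosage` (sites x samples true-genotype
#'   dosages, NA where depth is 0), `outgroup` (0/1 per site) and `truth`
#'   (initial/sampled frequencies, selection coefficients, realized
#'   inbreeding, IBD tracts, genotypes, trajectory object).
#' @export
generate_dataset <- function(params = scenario_params(), outdir = NULL) {
  stopifnot(inherits(params, "pl_scenario"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_sites

  # --- sites ---------------------------------------------------------
  chrom_len <- floor(params$genome_length_bp / params$n_chrom)
  per_chrom <- diff(floor(seq(0, n, length.out = params$n_chrom + 1L)))
  chrom <- rep(sprintf("chr%d", seq_len(params$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(chrom_len - 1L, k))), use.names = FALSE)
  if (n == 0L) pos <- integer(0)
  region <- sample(REGION_CLASSES, n, replace = TRUE,
                   prob = params$region_mix[REGION_CLASSES])
  constrained <- runif(n) < params$prop_constrained
  phylop <- numeric(n)
  if (any(constrained)) {
    tail_mean <- params$phylop_tail_mean[region[constrained]] - 1.5
    phylop[constrained] <- 1.5 + rexp(sum(constrained), rate = 1 / tail_mean)
  }
  if (any(!constrained)) {
    x <- rnorm(sum(!constrained), 0, 0.7)
    while (any(x >= 1.5)) x[x >= 1.5] <- rnorm(sum(x >= 1.5), 0, 0.7)
    phylop[!constrained] <- x
  }
  ref <- sample(NUCLEOTIDES, n, replace = TRUE)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  alt <- character(n)
  is_ti <- runif(n) < params$ti_prob
  alt[is_ti] <- ti_partner[ref[is_ti]]
  if (any(!is_ti))
    alt[!is_ti] <- vapply(ref[!is_ti], function(b) {
      tv <- setdiff(NUCLEOTIDES, c(b, ti_partner[b]))
      tv[sample.int(2L, 1L)]
    }, "")
  n_del_col <- sample(0:3, n, replace = TRUE,
                      prob = c(0.55, 0.25, 0.15, 0.05))
  cc <- character(n)
  has_del <- n_del_col > 0L
  cc[has_del] <- sprintf("%s:%d,%s:%d", ref[has_del],
                         46L - n_del_col[has_del], alt[has_del],
                         n_del_col[has_del])
  cc[!has_del] <- sprintf("%s:46", ref[!has_del])
  sites <- site_table(chrom, pos, region, round(phylop, 4), cc)
  sample_alleles <- Map(c, ref, alt)
  sites <- annotate_sites(sites, sample_alleles)

  # --- trajectories --------------------------------------------------
  s <- ifelse(constrained, -params$selection_scale * phylop, 0)
  traj <- simulate_frequency_trajectories(params, s = s)

  # --- samples -------------------------------------------------------
  meta <- build_metadata(params)
  gen_ix <- age_to_generation(meta$age_bp, traj)
  n_samp <- nrow(meta)
  geno <- matrix(0L, n_samp, n, dimnames = list(meta$sample_id, NULL))
  ibd_tracts <- vector("list", n_samp)
  names(ibd_tracts) <- meta$sample_id
  F_real <- numeric(n_samp)
  for (i in seq_len(n_samp)) {
    ind <- sample_individual_genotypes(
      traj$freq[, gen_ix[i]], chrom, pos, meta$F_target[i],
      params$mean_roh_length_bp, s = s,
      purging_strength = params$purging_strength)
    geno[i, ] <- ind$genotype
    ibd_tracts[[i]] <- ind$tracts
    F_real[i] <- ind$F_realized
  }

  # --- read counts ---------------------------------------------------
  counts <- simulate_read_counts(
    geno, meta$mean_depth, params$error_rate,
    damage_rate = ifelse(meta$age_bp > 0, params$damage_rate, 0),
    user_treated = params$user_treated,
    ref = ref, alt = alt, chrom = chrom, pos = pos,
    samples = meta$sample_id)

  dosage <- t(geno)
  dosage[t(counts$d) == 0L] <- NA_integer_

  # --- outgroup: divergence reduced at selected sites ----------------
  div <- params$outgroup_divergence * exp(-abs(s) * 500)
  outgroup <- as.integer(runif(n) < div)

  truth <- list(p0 = traj$p0, s = s, ref = ref, alt = alt,
                freq = traj$freq, age_bp = traj$age_bp,
                genotypes = geno, F_target = meta$F_target,
                F_realized = F_real, ibd_tracts = ibd_tracts)
  meta_out <- meta[, c("sample_id", "breed", "group", "age_bp",
                       "mean_depth")]
  res <- list(params = params, sites = sites, meta = meta_out,
              counts = counts, dosage = dosage, outgroup = outgroup,
              truth = truth)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_site_table(sites, file.path(outdir, "sites.tsv"))
    write_counts(counts, file.path(outdir, "counts.tsv"))
    write_metadata(meta_out, file.path(outdir, "metadata.tsv"))
    write_vcf(chrom, pos, ref, alt, dosage, meta$sample_id,
              file.path(outdir, "genotypes.vcf"))
    write.table(data.frame(chrom = chrom, pos = pos,
                           outgroup_allele = outgroup),
                file.path(outdir, "outgroup.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    keep_ages <- seq(0, params$span_years, by = 250)
    keep_ix <- age_to_generation(keep_ages, traj)
    slim <- list(
      p0 = traj$p0, s = s,
      freq_ages_bp = traj$age_bp[keep_ix],
      freq = if (n > 0L) unname(as.data.frame(t(traj$freq[, keep_ix,
                                                          drop = FALSE])))
             else list(),
      samples = data.frame(sample_id = meta$sample_id,
                           F_target = meta$F_target,
                           F_realized = F_real))
    jsonlite::write_json(slim, file.path(outdir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
    yaml::write_yaml(
      lapply(Filter(function(x) !is.list(x) || !is.null(names(x)),
                    unclass(params)), unclass),
      file.path(outdir, "scenario.yaml"))
  }
  invisible(res)
}

default_ancient_schedule <- function(params) {
  rg <- params$ancient_age_range
  n_pts <- max(1L, round(diff(rg) / 250) + 1L)
  ages <- round(seq(rg[1], rg[2], length.out = min(n_pts,
                                                   params$n_ancient)))
  share <- diff(floor(seq(0, params$n_ancient,
                          length.out = length(ages) + 1L)))
  data.frame(age_bp = ages, n = share,
             depth_mean = NA_real_)  # ramp filled per group below
}

expand_schedule <- function(schedule, depth_range) {
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    k <- schedule$n[i]
    if (k == 0L) return(NULL)
    depth <- if (!is.na(schedule$depth_mean[i]))
      rep(schedule$depth_mean[i], k)
    else if (k == 1L) mean(depth_range)
    else round(seq(depth_range[1], depth_range[2], length.out = k), 1)
    data.frame(age_bp = schedule$age_bp[i], mean_depth = pmax(depth, 0.5))
  })
  do.call(rbind, rows)
}

build_metadata <- function(params) {
  anc <- NULL
  if (params$n_ancient > 0) {
    schedule <- params$sample_schedule %||%
      default_ancient_schedule(params)
    ind <- expand_schedule(schedule, params$ancient_depth_range)
    ind <- ind[order(ind$age_bp), , drop = FALSE]
    anc <- data.frame(sample_id = sprintf("anc%03d", seq_len(nrow(ind))),
                      breed = "ancient", group = "ancient",
                      age_bp = ind$age_bp,
                      mean_depth = ind$mean_depth,
                      F_target = 0)
  }
  groups <- rep(names(params$modern_F_ranges),
                length.out = params$n_modern)
  groups <- sort(groups)
  mod <- if (params$n_modern > 0)
    data.frame(sample_id = sprintf("mod%03d", seq_len(params$n_modern)),
               breed = paste0(groups, "_",
                              rep_len(c("a", "b"), params$n_modern)),
               group = groups, age_bp = 0,
               mean_depth = params$modern_depth,
               F_target = vapply(groups, function(g) {
                 rg <- params$modern_F_ranges[[g]]
                 runif(1, rg[1], rg[2])
               }, 0))
  else NULL
  out <- rbind(anc, mod)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), breed = character(0),
                      group = character(0), age_bp = numeric(0),
                      mean_depth = numeric(0), F_target = numeric(0))
  rownames(out) <- NULL
  out
}
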