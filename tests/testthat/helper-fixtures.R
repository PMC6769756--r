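# Small in-code fixtures shared across the suite.

# A hand-built 6-site annotation table covering all region classes and
# both sides of the constraint threshold.
tiny_sites <- function() {
  site_table(chrom = rep("chr1", 6),
             pos = c(100L, 200L, 300L, 400L, 500L, 600L),
             region_class = c("coding", "coding", "upstream2kb",
                              "intron", "intergenic", "downstream2kb"),
             phylop = c(2.0, 1.6, 3.0, 1.49, 0.2, 1.5),
             column_counts = c("A:44,G:2", "C:46", "T:45,A:1",
                               "G:44,T:2", "A:40,C:6", "C:23,G:23"))
}

tiny_annotated <- function() {
  annotate_sites(tiny_sites(),
                 list(c("A", "G"), c("C", "T"), c("T", "A"),
                      c("G", "T"), c("A", "C"), c("C", "G")))
}

# Counts for 3 samples over the 6 sites; r = deleterious-allele reads.
tiny_counts <- function() {
  s <- tiny_annotated()
  r <- rbind(c(10L, 0L, 10L, 10L, 0L, 0L),
             c(0L, 10L, 0L, 0L, 5L, 0L),
             c(10L, 10L, 0L, 10L, 0L, 0L))
  d <- matrix(10L, 3, 6)
  d[2, 6] <- 0L
  count_matrix(c("s1", "s2", "s3"), s$chrom, s$pos,
               s$deleterious_allele, r, d)
}

# Brute-force genotype likelihoods: explicit product over reads.
oracle_genotype_likelihoods <- function(n_ref, n_alt, e) {
  p_read <- function(base, allele) if (base == allele) 1 - e else e / 3
  reads <- c(rep("R", n_ref), rep("A", n_alt))
  lik <- vapply(list(c("R", "R"), c("R", "A"), c("A", "A")),
                function(g) prod(vapply(reads, function(b)
                  0.5 * p_read(b, g[1]) + 0.5 * p_read(b, g[2]), 0)),
                0)
  names(lik) <- c("RR", "RA", "AA")
  lik / sum(lik)
}

# Brute-force load: explicit per-site loop over one sample's calls.
oracle_load <- function(dosage_row, phylop, deleterious_defined,
                        threshold = 1.5) {
  num <- 0; n_hom <- 0L; n_del <- 0L
  for (j in seq_along(dosage_row)) {
    g <- dosage_row[j]
    if (is.na(g)) next
    n_hom <- n_hom + 1L
    if (g == 2L && deleterious_defined[j] && phylop[j] >= threshold) {
      num <- num + phylop[j]
      n_del <- n_del + 1L
    }
  }
  list(load = if (n_hom > 0) num / n_hom else NA_real_,
       n_hom_total = n_hom, n_hom_deleterious = n_del,
       sum_phylop = num)
}

# Exhaustive topology search: the additive matrix's generating topology
# is the unique one whose least-squares branch fit reproduces it.
oracle_best_topology <- function(dmat) {
  n <- nrow(dmat)
  stopifnot(n <= 6)
  cand <- phangorn::allTrees(n, rooted = FALSE,
                             tip.label = rownames(dmat))
  rss <- vapply(cand, function(tr) {
    fit <- phangorn::nnls.tree(as.dist(dmat), tr, method = "unrooted")
    sum((as.matrix(cophenetic(fit))[rownames(dmat), rownames(dmat)] -
           dmat)^2)
  }, 0)
  cand[[which.min(rss)]]
}

# Random additive distance matrix from a random unrooted topology with
# strictly positive branch lengths; returns the tree and its matrix.
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
  D <- as.matrix(cophenetic(tr))
  list(tree = tr, dmat = D[order(rownames(D)), order(rownames(D))])
}

small_scenario <- function(...) {
  defaults <- list(n_sites = 600, n_ancient = 40, n_modern = 40,
                   genome_length_bp = 5e7, n_chrom = 2)
  do.call(scenario_params, utils::modifyList(defaults, list(...)))
}
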