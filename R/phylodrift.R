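#' Pseudo-haploidize read counts
#'
#' The standard low-coverage ancient-DNA convention: each (sample, site)
#' cell is represented by a single allele drawn uniformly over its reads,
#' i.e. the deleterious allele with probability `r / d`. Zero-depth cells
#' are missing.
#'
#' @param counts A [count_matrix()] object.
#' @param seed Optional integer seed making the draw reproducible.
#' @return A samples x sites integer matrix (1 = deleterious allele,
#'   0 = reference-like allele, `NA` = missing), with the seed stored as
#'   an attribute.
#' @export
pseudo_haploidize <- function(counts, seed = NULL) {
  stopifnot(inherits(counts, "pl_counts"))
  if (!is.null(seed)) set.seed(seed)
  p <- counts$r / ifelse(counts$d == 0L, 1L, counts$d)
  h <- matrix(rbinom(length(p), 1L, as.vector(p)),
              nrow(counts$r), ncol(counts$r),
              dimnames = dimnames(counts$r))
  h[counts$d == 0L] <- NA_integer_
  attr(h, "seed") <- seed
  h
}

#' Select nearly-neutral sites for distance computation
#'
#' Keeps sites below the constraint threshold (phyloP < 1.5 by default)
#' with at most `max_missing` missing haploid calls across the panel.
#'
#' @param sites Site table aligned with the haploid matrix columns.
#' @param haploid Matrix from [pseudo_haploidize()].
#' @param phylop_threshold Constraint cutoff.
#' @param max_missing Maximum missing calls per site.
#' @return Logical vector over sites.
#' @export
neutral_site_filter <- function(sites, haploid, phylop_threshold = 1.5,
                                max_missing = 1L) {
  stopifnot(nrow(sites) == ncol(haploid))
  sites$phylop < phylop_threshold &
    colSums(is.na(haploid)) <= max_missing
}

#' Pairwise mismatch distances between haploid genomes
#'
#' For each pair of samples, the fraction of mismatching alleles over
#' sites where both are non-missing.
#'
#' @param haploid Samples x sites matrix of 0/1 alleles (`NA` missing).
#' @param subset Optional logical or integer site subset (e.g. from
#'   [neutral_site_filter()]).
#' @return A symmetric distance matrix with zero diagonal and an
#'   `n_shared` attribute (pairwise site counts); pairs without shared
#'   sites are `NA`.
#' @export
pairwise_distance <- function(haploid, subset = NULL) {
  if (!is.null(subset)) haploid <- haploid[, subset, drop = FALSE]
  stopifnot(nrow(haploid) >= 2L)
  obs <- !is.na(haploid)
  a1 <- haploid == 1L; a1[!obs] <- FALSE
  a0 <- haploid == 0L; a0[!obs] <- FALSE
  mism <- tcrossprod(a1 * 1, a0 * 1)
  mism <- mism + t(mism)
  shared <- tcrossprod(obs * 1)
  dmat <- ifelse(shared > 0, mism / shared, NA_real_)
  diag(dmat) <- 0
  dimnames(dmat) <- list(rownames(haploid), rownames(haploid))
  attr(dmat, "n_shared") <- shared
  dmat
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative NJ (consistent on additive matrices). Negative
#' branch lengths, which NJ can produce on noisy input, are clamped to
#' zero with the deficit shifted onto the sibling branch. The tree can be
#' left unrooted, rooted on an outgroup tip, or midpoint rooted.
#'
#' @param dmat Complete symmetric distance matrix (`n >= 3`).
#' @param root `"none"`, `"outgroup"` or `"midpoint"`.
#' @param outgroup Tip label, required for outgroup rooting.
#' @return A `phylo` tree.
#' @export
nj_build <- function(dmat, root = c("none", "outgroup", "midpoint"),
                     outgroup = NULL) {
  root <- match.arg(root)
  dmat <- as.matrix(dmat)
  if (any(is.na(dmat))) stop("distance matrix has missing entries")
  stopifnot(nrow(dmat) >= 3L, isTRUE(all.equal(dmat, t(dmat))))
  tree <- ape::nj(dmat)
  tree <- clamp_negative_branches(tree)
  switch(root,
         none = tree,
         outgroup = {
           if (is.null(outgroup) || !outgroup %in% tree$tip.label)
             stop("outgroup tip not found in tree")
           ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
         },
         midpoint = phangorn::midpoint(tree))
}

clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs))
      tree$edge.length[sibs[1L]] <-
        tree$edge.length[sibs[1L]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Stem branch lengths of named clades
#'
#' For each named tip set (breed or management group), reports the length
#' of the branch subtending its most recent common ancestor — a proxy for
#' lineage-specific drift. Non-monophyletic tip sets are reported as
#' missing, with a warning.
#'
#' @param tree A rooted `phylo` tree (root it first, e.g. on the
#'   outgroup).
#' @param clades Named list of tip-label vectors.
#' @return A `data.frame` (`clade`, `n_tips`, `stem_length`,
#'   `monophyletic`) sorted by decreasing stem length.
#' @export
internal_branches <- function(tree, clades) {
  stopifnot(inherits(tree, "phylo"), length(clades) >= 1L,
            !is.null(names(clades)))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (use nj_build(root = ...))")
  rows <- lapply(names(clades), function(nm) {
    tips <- clades[[nm]]
    if (!all(tips %in% tree$tip.label))
      stop("unknown tip label in clade ", nm)
    mono <- length(tips) == 1L ||
      ape::is.monophyletic(tree, tips)
    len <- NA_real_
    if (mono) {
      node <- if (length(tips) == 1L) match(tips, tree$tip.label)
              else ape::getMRCA(tree, tips)
      e <- which(tree$edge[, 2L] == node)
      if (length(e) == 1L) len <- tree$edge.length[e]
    } else {
      warning("clade ", nm, " is not monophyletic; stem length missing")
    }
    data.frame(clade = nm, n_tips = length(tips), stem_length = len,
               monophyletic = mono)
  })
  out <- do.call(rbind, rows)
  out[order(-out$stem_length, na.last = TRUE), ]
}

#' Bootstrap support for internal edges
#'
#' Resamples sites with replacement, rebuilds the NJ tree per replicate,
#' and reports for each internal node of the reference tree the fraction
#' of replicates containing the same bipartition.
#'
#' @param haploid Samples x sites haploid matrix.
#' @param n_replicates Number of bootstrap replicates.
#' @param subset Optional site subset applied before resampling.
#' @param seed Optional integer seed.
#' @return The reference `phylo` tree with `node.label` set to support
#'   proportions in `[0, 1]`.
#' @export
bootstrap_support <- function(haploid, n_replicates = 100L,
                              subset = NULL, seed = NULL) {
  stopifnot(n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(subset)) haploid <- haploid[, subset, drop = FALSE]
  ref <- nj_build(pairwise_distance(haploid))
  boots <- lapply(seq_len(n_replicates), function(i) {
    cols <- sample.int(ncol(haploid), replace = TRUE)
    nj_build(pairwise_distance(haploid[, cols, drop = FALSE]))
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- counts / n_replicates
  ref
}
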