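#' @rdname site_table
#' @export
REGION_CLASSES <- c("coding", "upstream2kb", "downstream2kb", "intron",
                    "intergenic")

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Assign the deleterious allele at a site
#'
#' At an annotated site, the putatively deleterious allele is the one that
#' is rarer than (or absent from) the column of the multi-species
#' alignment, provided that at most two distinct variants segregate across
#' the alignment column and the sampled genomes together. Sites with more
#' than two variants, tied column counts, or non-nucleotide symbols get no
#' assignment.
#'
#' @param column_counts Named integer vector tallying alleles in the
#'   alignment column, e.g. `c(A = 44, G = 2)`.
#' @param sample_alleles Character vector of alleles observed among the
#'   sampled genomes at this site (may be empty).
#' @return A single nucleotide, or `NA_character_` when no assignment is
#'   possible.
#' @examples
#' assign_deleterious_allele(c(A = 44, G = 2), c("A", "G"))  # "G"
#' assign_deleterious_allele(c(A = 46), c("A", "T"))         # "T"
#' assign_deleterious_allele(c(A = 30, G = 10, C = 6))       # NA
#' @export
assign_deleterious_allele <- function(column_counts,
                                      sample_alleles = character()) {
  if (length(column_counts) == 0L)
    stop("column_counts must be non-empty")
  if (is.null(names(column_counts)) || any(!nzchar(names(column_counts))))
    stop("column_counts must be a named vector")
  sample_alleles <- unique(as.character(sample_alleles))
  if (!all(names(column_counts) %in% NUCLEOTIDES) ||
      !all(sample_alleles %in% NUCLEOTIDES)) {
    warning("non-nucleotide symbol at site; dropping assignment")
    return(NA_character_)
  }
  column_counts <- column_counts[column_counts > 0]
  if (length(column_counts) == 0L)
    stop("column_counts has no positive entries")
  variants <- union(names(column_counts), sample_alleles)
  if (length(variants) > 2L) return(NA_character_)
  if (length(column_counts) == 2L) {
    if (column_counts[1L] == column_counts[2L]) return(NA_character_)
    return(names(column_counts)[which.min(column_counts)])
  }
  # column monomorphic: a sample allele absent from the column, if any
  extra <- setdiff(sample_alleles, names(column_counts))
  if (length(extra) == 1L) return(extra)
  NA_character_
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A/G and C/T); the remaining four unordered pairs are transversions.
#'
#' @param a1,a2 Single distinct nucleotides; the order is irrelevant.
#' @return `"transition"` or `"transversion"` (vectorized over inputs).
#' @examples
#' classify_mutation("C", "T")  # transition
#' classify_mutation("A", "C")  # transversion
#' @export
classify_mutation <- function(a1, a2) {
  a1 <- toupper(as.character(a1)); a2 <- toupper(as.character(a2))
  stopifnot(length(a1) == length(a2))
  if (!all(a1 %in% NUCLEOTIDES) || !all(a2 %in% NUCLEOTIDES))
    stop("alleles must be one of A, C, G, T")
  if (any(a1 == a2))
    stop("equal alleles do not define a mutation")
  purine <- c("A", "G")
  ifelse((a1 %in% purine) == (a2 %in% purine), "transition", "transversion")
}

#' Is a site evolutionarily constrained?
#'
#' A site counts as constrained when its phyloP score reaches the
#' configured minimum (boundary included).
#'
#' @param phylop Numeric phyloP score(s); must be finite.
#' @param threshold Constraint cutoff (default 1.5).
#' @return Logical vector.
#' @examples
#' classify_constraint(c(1.49, 1.5, 2.316))
#' @export
classify_constraint <- function(phylop, threshold = 1.5) {
  if (any(!is.finite(phylop))) stop("phylop must be finite")
  phylop >= threshold
}

#' Parse / format alignment-column allele tallies
#'
#' The on-disk representation of an alignment column is a compact string
#' such as `"A:44,G:2"`.
#'
#' @param x For `parse_column_counts()`, a character vector of tally
#'   strings; for `format_column_counts()`, a list of named integer
#'   vectors (or a single named vector).
#' @return `parse_column_counts()` returns a list of named integer
#'   vectors; `format_column_counts()` a character vector.
#' @examples
#' parse_column_counts("A:44,G:2")
#' format_column_counts(c(A = 46))
#' @export
parse_column_counts <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), function(parts) {
    kv <- strsplit(parts, ":", fixed = TRUE)
    if (any(lengths(kv) != 2L))
      stop("malformed column_counts entry: ", paste(parts, collapse = ","))
    counts <- as.integer(vapply(kv, `[`, "", 2L))
    if (any(is.na(counts)) || any(counts < 0))
      stop("malformed column_counts entry: ", paste(parts, collapse = ","))
    setNames(counts, vapply(kv, `[`, "", 1L))
  })
}

#' @rdname parse_column_counts
#' @export
format_column_counts <- function(x) {
  if (!is.list(x)) x <- list(x)
  vapply(x, function(cc)
    paste(sprintf("%s:%d", names(cc), as.integer(cc)), collapse = ","),
    "")
}

major_column_allele <- function(cc) names(cc)[which.max(cc)]

#' Build and validate a site-annotation table
#'
#' One row per genomic position, carrying the region class, the phyloP
#' conservation score and the allele tally of the multi-species alignment
#' column. `annotate_sites()` derives the deleterious allele, the
#' constraint flag and the transition/transversion class given the alleles
#' observed among the sampled genomes.
#'
#' @param chrom Chromosome identifiers.
#' @param pos 1-based positions (bp).
#' @param region_class One of `r toString(REGION_CLASSES)` per site.
#' @param phylop Finite phyloP scores.
#' @param column_counts Character tallies (see [parse_column_counts()]).
#' @return A `data.frame` with one row per site, ordered as given.
#' @examples
#' s <- site_table("chr1", c(100, 200), c("coding", "intron"),
#'                 c(2.0, 0.3), c("A:44,G:2", "C:46"))
#' annotate_sites(s, list(c("A", "G"), c("C", "T")))
#' @export
site_table <- function(chrom, pos, region_class, phylop, column_counts) {
  sites <- data.frame(chrom = as.character(chrom),
                      pos = as.integer(pos),
                      region_class = as.character(region_class),
                      phylop = as.numeric(phylop),
                      column_counts = as.character(column_counts),
                      stringsAsFactors = FALSE)
  validate_sites(sites)
  sites
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "region_class", "phylop", "column_counts")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("site table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(sites) == 0L) return(invisible(sites))
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (any(!is.finite(sites$phylop))) stop("phylop must be finite")
  bad <- which(!sites$region_class %in% REGION_CLASSES)
  if (length(bad))
    stop("unknown region class at row ", bad[1L], ": ",
         sites$region_class[bad[1L]])
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("site table must be sorted by (chrom, pos)")
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicated (chrom, pos) in site table")
  invisible(sites)
}

#' @rdname site_table
#' @param sites A site table.
#' @param sample_alleles List (one character vector per site) of alleles
#'   observed among the sampled genomes, or `NULL` for none.
#' @param phylop_threshold Constraint cutoff passed to
#'   [classify_constraint()].
#' @export
annotate_sites <- function(sites, sample_alleles = NULL,
                           phylop_threshold = 1.5) {
  validate_sites(sites)
  n <- nrow(sites)
  if (is.null(sample_alleles)) sample_alleles <- rep(list(character()), n)
  stopifnot(length(sample_alleles) == n)
  cc <- parse_column_counts(sites$column_counts)
  del <- character(n); mut <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    del[i] <- assign_deleterious_allele(cc[[i]], sample_alleles[[i]])
    if (!is.na(del[i])) {
      other <- setdiff(union(names(cc[[i]]), sample_alleles[[i]]), del[i])
      if (length(other) == 1L)
        mut[i] <- classify_mutation(other, del[i])
    }
  }
  sites$deleterious_allele <- del
  sites$constrained <- classify_constraint(sites$phylop, phylop_threshold)
  sites$mutation_class <- mut
  sites
}

#' Resolve overlapping region classes by precedence
#'
#' When a position is annotated with several region classes, the most
#' specific one wins: coding > upstream2kb > downstream2kb > intron >
#' intergenic.
#'
#' @param classes Character vector of candidate classes for one position.
#' @return The winning class.
#' @examples
#' resolve_region_class(c("intron", "coding"))
#' @export
resolve_region_class <- function(classes) {
  classes <- match.arg(classes, REGION_CLASSES, several.ok = TRUE)
  REGION_CLASSES[min(match(classes, REGION_CLASSES))]
}
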