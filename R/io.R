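SAMPLE_GROUPS <- c("working", "hotblood", "warmblood", "przewalski",
                   "hybrid", "ancient", "other")

#' Read and write the site-annotation table
#'
#' Tab-separated with header `chrom pos region_class phylop column_counts`
#' (alignment-column tallies encoded as `"A:44,G:2"`). Extra columns are
#' preserved on read. Rows must be sorted by chromosome and position.
#'
#' @param path File path.
#' @return `read_site_table()` returns a validated site table;
#'   `write_site_table()` invisibly returns `path`.
#' @export
read_site_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "region_class", "phylop", "column_counts")
  if (!all(need %in% names(df)))
    stop("site table header must contain: ", paste(need, collapse = " "))
  bad <- which(is.na(df$pos) | is.na(df$phylop))
  if (length(bad))
    stop("malformed site table row at line ", bad[1L] + 1L)
  validate_sites(df)
  df
}

#' @rdname read_site_table
#' @param sites A site table.
#' @export
write_site_table <- function(sites, path) {
  validate_sites(sites)
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-individual deleterious-allele read counts
#'
#' `count_matrix()` assembles the central read-count container: for every
#' (sample, site) pair, `r` is the number of reads supporting the
#' deleterious allele and `d` the total read depth (`d = 0` encodes
#' missing data). The on-disk format is a long TSV with columns
#' `sample chrom pos del_allele r d`.
#'
#' @param samples Character vector of sample ids (row order of `r`, `d`).
#' @param chrom,pos Site coordinates (column order of `r`, `d`).
#' @param del_allele Deleterious allele per site (may be `NA`).
#' @param r,d Integer matrices, samples x sites.
#' @return An object of class `pl_counts`.
#' @export
count_matrix <- function(samples, chrom, pos, del_allele, r, d) {
  r <- as.matrix(r); d <- as.matrix(d)
  stopifnot(length(samples) == nrow(r), length(chrom) == ncol(r),
            length(pos) == ncol(r), length(del_allele) == ncol(r),
            identical(dim(r), dim(d)))
  if (any(r < 0) || any(r > d))
    stop("counts must satisfy 0 <= r <= d elementwise")
  rownames(r) <- rownames(d) <- samples
  structure(list(samples = as.character(samples),
                 chrom = as.character(chrom),
                 pos = as.integer(pos),
                 del_allele = as.character(del_allele),
                 r = r, d = d),
            class = "pl_counts")
}

#' @export
print.pl_counts <- function(x, ...) {
  cat(sprintf("deleterious-allele read counts: %d samples x %d sites\n",
              length(x$samples), length(x$pos)))
  cat(sprintf("  missing (d = 0): %.1f%%\n", 100 * mean(x$d == 0)))
  invisible(x)
}

#' @rdname count_matrix
#' @param path File path.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  need <- c("sample", "chrom", "pos", "del_allele", "r", "d")
  if (!all(need %in% names(df)))
    stop("counts header must contain: ", paste(need, collapse = " "))
  bad <- which(is.na(df$r) | is.na(df$d) | df$r < 0 | df$r > df$d)
  if (length(bad))
    stop("malformed counts row (need 0 <= r <= d) at line ", bad[1L] + 1L)
  samples <- unique(df$sample)
  key <- paste(df$chrom, df$pos)
  ukey <- unique(key)
  site_ix <- match(key, ukey)
  samp_ix <- match(df$sample, samples)
  n_s <- length(samples); n_v <- length(ukey)
  r <- matrix(0L, n_s, n_v); d <- matrix(0L, n_s, n_v)
  r[cbind(samp_ix, site_ix)] <- as.integer(df$r)
  d[cbind(samp_ix, site_ix)] <- as.integer(df$d)
  first <- !duplicated(key)
  count_matrix(samples, df$chrom[first], df$pos[first],
               df$del_allele[first], r, d)
}

#' @rdname count_matrix
#' @param counts A `pl_counts` object.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "pl_counts"))
  n_s <- length(counts$samples); n_v <- length(counts$pos)
  df <- data.frame(sample = rep(counts$samples, times = n_v),
                   chrom = rep(counts$chrom, each = n_s),
                   pos = rep(counts$pos, each = n_s),
                   del_allele = rep(counts$del_allele, each = n_s),
                   r = as.vector(counts$r),
                   d = as.vector(counts$d))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' TSV with columns `sample_id breed group age_bp mean_depth`; `age_bp`
#' is years before present (0 for modern genomes) and `group` one of
#' working, hotblood, warmblood, przewalski, hybrid, ancient, other.
#'
#' @param path File path.
#' @return A validated `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "breed", "group", "age_bp", "mean_depth")
  if (!all(need %in% names(df)))
    stop("metadata header must contain: ", paste(need, collapse = " "))
  validate_metadata(df)
  df
}

validate_metadata <- function(meta) {
  if (any(!meta$group %in% SAMPLE_GROUPS))
    stop("unknown sample group; expected one of: ",
         paste(SAMPLE_GROUPS, collapse = ", "))
  if (any(meta$age_bp < 0)) stop("age_bp must be >= 0")
  if (any(meta$group == "ancient" & meta$age_bp <= 0))
    stop("ancient samples must have age_bp > 0")
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id")
  invisible(meta)
}

#' @rdname read_metadata
#' @param meta Metadata `data.frame`.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a genotype matrix as VCF
#'
#' Only the GT field of a VCF 4.2 subset is used. Genotypes are returned
#' as ALT-allele dosages (0, 1, 2; `NA` for missing).
#'
#' @param path File path.
#' @return `load_vcf()` returns a list with `chrom`, `pos`, `ref`, `alt`
#'   and `dosage` (sites x samples integer matrix).
#' @export
load_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  list(chrom = unname(fix[, "CHROM"]),
       pos = as.integer(fix[, "POS"]),
       ref = unname(fix[, "REF"]),
       alt = unname(fix[, "ALT"]),
       dosage = dos)
}

#' @rdname load_vcf
#' @param chrom,pos,ref,alt Per-site fields.
#' @param dosage Sites x samples integer matrix of ALT dosages (NA for
#'   missing).
#' @param samples Sample ids (column names of the VCF body).
#' @export
write_vcf <- function(chrom, pos, ref, alt, dosage, samples, path) {
  stopifnot(nrow(dosage) == length(pos), ncol(dosage) == length(samples))
  gt <- matrix("./.", nrow(dosage), ncol(dosage))
  gt[!is.na(dosage) & dosage == 0L] <- "0/0"
  gt[!is.na(dosage) & dosage == 1L] <- "0/1"
  gt[!is.na(dosage) & dosage == 2L] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=paleoload",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  if (length(pos) > 0L) {
    body <- cbind(chrom, pos, ".", ref, alt, ".", ".", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write trees in Newick format
#'
#' Thin wrappers over the ape Newick parser/serializer.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `read_newick()` returns a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
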