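#' Genotype matrix container
#'
#' Holds biallelic diploid genotypes as an alt-allele dosage matrix
#' (samples x sites, values 0/1/2 or `NA` for missing), the site table,
#' and, when the source data are phased, a haplotype matrix with two rows
#' per diploid sample. Per-genotype depth (`DP`) and allele depths (`AD`)
#' are carried along when present so genotype-level filters can be applied.
#'
#' @param geno integer matrix, samples x sites, alt-allele dosage with `NA`
#'   for missing genotypes.
#' @param sites tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param samples character vector of sample identifiers (rownames of `geno`).
#' @param hap optional 0/1 haplotype matrix with rows `<sample>_h1`,
#'   `<sample>_h2` interleaved per sample; `NULL` for unphased data.
#' @param phased logical flag.
#' @param dp,ad_ref,ad_alt optional numeric matrices (samples x sites).
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, samples = rownames(geno), hap = NULL,
                            phased = !is.null(hap), dp = NULL,
                            ad_ref = NULL, ad_alt = NULL) {
  if (!is.matrix(geno)) abort("`geno` must be a matrix")
  sites <- as_tibble(sites)
  if (nrow(sites) != ncol(geno)) {
    abort("`sites` must have one row per column of `geno`")
  }
  if (is.null(samples)) abort("sample names are required")
  if (anyDuplicated(samples)) abort("sample names must be unique")
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) abort("dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples
  if (!is.null(hap) && nrow(hap) != 2L * nrow(geno)) {
    abort("`hap` must have two rows per sample")
  }
  structure(
    list(geno = geno, sites = sites, samples = samples, hap = hap,
         phased = isTRUE(phased), dp = dp, ad_ref = ad_ref, ad_alt = ad_alt),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%s)\n",
              nrow(x$geno), ncol(x$geno),
              if (x$phased) "phased" else "unphased"))
  chroms <- unique(x$sites$chrom)
  cat("  contigs:", paste(head(chroms, 5), collapse = ", "),
      if (length(chroms) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Subset sites by logical/integer index, keeping all per-genotype matrices
# in register with the site table.
subset_sites <- function(gm, keep) {
  sub <- function(m) if (is.null(m)) NULL else m[, keep, drop = FALSE]
  genotype_matrix(
    geno = gm$geno[, keep, drop = FALSE],
    sites = gm$sites[keep, , drop = FALSE],
    samples = gm$samples,
    hap = sub(gm$hap), phased = gm$phased,
    dp = sub(gm$dp), ad_ref = sub(gm$ad_ref), ad_alt = sub(gm$ad_alt)
  )
}

#' Per-species alt or derived allele frequencies
#'
#' Computes per-site allele frequencies for every species in the population
#' map. When `outgroup` is given, sites are polarized so that the returned
#' frequencies are derived-allele frequencies: the outgroup's major allele is
#' taken as ancestral and sites with no outgroup data are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap tibble with columns `sample`, `species`.
#' @param outgroup optional species name used to polarize alleles.
#' @return list with `freq` (species x sites matrix), `n` (non-missing allele
#'   counts), `sites` (tibble, with `derived_is_alt` when polarized).
#' @export
allele_freqs <- function(gm, popmap, outgroup = NULL) {
  popmap <- as_tibble(popmap)
  missing_samples <- setdiff(popmap$sample, gm$samples)
  if (length(missing_samples)) {
    abort(paste0("samples in popmap absent from genotypes: ",
                 paste(missing_samples, collapse = ", ")))
  }
  species <- unique(popmap$species)
  counts <- matrix(0, length(species), ncol(gm$geno),
                   dimnames = list(species, NULL))
  ns <- counts
  for (sp in species) {
    rows <- popmap$sample[popmap$species == sp]
    g <- gm$geno[rows, , drop = FALSE]
    counts[sp, ] <- colSums(g, na.rm = TRUE)
    ns[sp, ] <- 2 * colSums(!is.na(g))
  }
  freq <- counts / ns
  freq[ns == 0] <- NA_real_
  sites <- gm$sites
  if (!is.null(outgroup)) {
    if (!outgroup %in% species) abort("outgroup species absent from popmap")
    keep <- ns[outgroup, ] > 0
    freq <- freq[, keep, drop = FALSE]
    ns <- ns[, keep, drop = FALSE]
    sites <- sites[keep, , drop = FALSE]
    # ancestral allele = outgroup major allele; ties resolved toward ref
    derived_is_alt <- freq[outgroup, ] <= 0.5
    flip <- !derived_is_alt
    freq[, flip] <- 1 - freq[, flip]
    sites$derived_is_alt <- derived_is_alt
  }
  list(freq = freq, n = ns, sites = sites,
       polarized = !is.null(outgroup), outgroup = outgroup)
}
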