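#' H12 haplotype homozygosity
#'
#' Garud's H12 over the haplotype frequency spectrum
#' \eqn{f_1 \ge f_2 \ge \ldots}: \eqn{H12 = (f_1 + f_2)^2 + \sum_{i \ge 3}
#' f_i^2}. Only SNPs with minor-allele frequency above `maf_min` contribute
#' to haplotype identity; haplotypes with missing alleles at the retained
#' SNPs are dropped.
#'
#' @param hap 0/1 haplotype matrix (haplotypes x SNPs) for one window.
#' @param maf_min minor-allele-frequency cutoff for SNPs (default 0.05).
#' @return H12 in `(0, 1]`, or `NA` when fewer than two complete haplotypes
#'   remain.
#' @export
h12 <- function(hap, maf_min = 0.05) {
  if (is.null(dim(hap))) hap <- matrix(hap, nrow = 1)
  keep_snp <- snp_maf(hap) > maf_min
  h <- hap[, keep_snp, drop = FALSE]
  complete <- rowSums(is.na(h)) == 0
  h <- h[complete, , drop = FALSE]
  if (nrow(h) < 2) return(NA_real_)
  key <- apply(h, 1, paste, collapse = "")
  f <- sort(as.numeric(table(key)) / nrow(h), decreasing = TRUE)
  if (length(f) == 1) return(1)
  (f[1] + f[2])^2 + sum(f[-(1:2)]^2)
}

snp_maf <- function(hap) {
  p <- colMeans(hap, na.rm = TRUE)
  pmin(p, 1 - p)
}

#' nSL selection scan
#'
#' For each focal SNP the statistic compares haplotype-tract lengths
#' between carriers of the ancestral and the derived allele: `SL_A` (and
#' `SL_D`) is the mean, over pairs of ancestral-carrying (derived-carrying)
#' haplotypes, of the number of consecutive SNPs - including the focal
#' one - over which the pair is identical; the raw score is
#' \eqn{\ln(SL_A / SL_D)}. Raw scores are standardized to zero mean and
#' unit variance within derived-allele-frequency bins computed over the
#' whole input. SNPs where either allele class has fewer than two carriers,
#' or with minor-allele frequency below `maf_min`, are skipped.
#'
#' @param hap 0/1 haplotype matrix (haplotypes x SNPs), phased, polarized
#'   (1 = derived), no missing values at scored SNPs.
#' @param positions optional SNP positions (carried through to the output).
#' @param maf_min minor-allele-frequency cutoff.
#' @param n_bins number of derived-allele-frequency bins used for
#'   standardization.
#' @return tibble (`snp`, `pos`, `daf`, `nsl_raw`, `nsl_std`), `NA` rows
#'   for skipped SNPs.
#' @export
nsl <- function(hap, positions = NULL, maf_min = 0.05, n_bins = 50) {
  n <- nrow(hap)
  m <- ncol(hap)
  if (is.null(positions)) positions <- seq_len(m)
  daf <- colMeans(hap)
  scored <- pmin(daf, 1 - daf) >= maf_min &
    colSums(hap) >= 2 & colSums(1 - hap) >= 2
  sum_d <- numeric(m); cnt_d <- numeric(m)
  sum_a <- numeric(m); cnt_a <- numeric(m)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      tract <- pair_tracts(hap[i, ], hap[j, ])
      both_d <- hap[i, ] == 1 & hap[j, ] == 1
      both_a <- hap[i, ] == 0 & hap[j, ] == 0
      sum_d <- sum_d + tract * both_d
      cnt_d <- cnt_d + both_d
      sum_a <- sum_a + tract * both_a
      cnt_a <- cnt_a + both_a
    }
  }
  raw <- rep(NA_real_, m)
  ok <- scored & cnt_d > 0 & cnt_a > 0
  raw[ok] <- log((sum_a[ok] / cnt_a[ok]) / (sum_d[ok] / cnt_d[ok]))
  std <- standardize_by_bin(raw, daf, n_bins)
  tibble(snp = seq_len(m), pos = positions, daf = daf,
         nsl_raw = raw, nsl_std = std)
}

# Length (in SNPs, inclusive of the focal SNP) of the maximal identical
# tract around every SNP for one haplotype pair.
pair_tracts <- function(x, y) {
  mism <- which(x != y)
  m <- length(x)
  left <- c(0L, mism)
  right <- c(mism, m + 1L)
  out <- integer(m)
  bounds_i <- findInterval(seq_len(m), c(0L, mism, m + 1L))
  starts <- left[bounds_i]
  ends <- right[bounds_i]
  out <- ends - starts - 1L
  out[x != y] <- 0L
  out
}

standardize_by_bin <- function(raw, daf, n_bins) {
  std <- rep(NA_real_, length(raw))
  bin <- pmin(floor(daf * n_bins), n_bins - 1)
  for (b in unique(bin[!is.na(raw)])) {
    idx <- which(bin == b & !is.na(raw))
    if (length(idx) < 2) next
    mu <- mean(raw[idx])
    sdev <- sd(raw[idx])
    if (sdev > 0) std[idx] <- (raw[idx] - mu) / sdev
  }
  std
}

#' Window-averaged selection scan
#'
#' Computes per-window mean |standardized nSL| and H12 for one species'
#' phased haplotypes.
#'
#' @param hap 0/1 haplotype matrix (haplotypes x SNPs), polarized.
#' @param sites tibble (`chrom`, `pos`) for the SNP columns.
#' @param windows window grid tibble.
#' @inheritParams nsl
#' @return `windows` with columns `mean_abs_nsl`, `h12`, `n_snps`.
#' @export
selection_scan <- function(hap, sites, windows, maf_min = 0.05, n_bins = 50) {
  win_id <- assign_windows(sites, windows)
  ns <- nsl(hap, sites$pos, maf_min = maf_min, n_bins = n_bins)
  out <- as_tibble(windows)
  res <- purrr::map_dfr(seq_len(nrow(out)), function(w) {
    idx <- which(win_id == w)
    vals <- ns$nsl_std[idx]
    tibble(
      mean_abs_nsl = if (any(!is.na(vals))) mean(abs(vals), na.rm = TRUE)
      else NA_real_,
      h12 = if (length(idx) >= 1) h12(hap[, idx, drop = FALSE], maf_min)
      else NA_real_,
      n_snps = length(idx)
    )
  })
  bind_cols(out, res)
}

#' Classify deleterious SNPs from PROVEAN and SIFT scores
#'
#' A nonsynonymous SNP is deleterious when its PROVEAN score is at most
#' `provean_max` and its SIFT score is at least `sift_min` (the published
#' rule, applied verbatim), and tolerant otherwise. `sift_direction =
#' "conventional"` flips the SIFT conjunct to the usual `< sift_min`
#' reading. Sites missing either score are left unclassified (`NA`).
#'
#' @param annotations tibble with columns `provean`, `sift`.
#' @param provean_max,sift_min rule thresholds.
#' @param sift_direction `"as_printed"` (SIFT >= threshold) or
#'   `"conventional"` (SIFT < threshold).
#' @return `annotations` with a logical `deleterious` column.
#' @export
classify_deleterious <- function(annotations, provean_max = -2.5,
                                 sift_min = 0.05,
                                 sift_direction = c("as_printed",
                                                    "conventional")) {
  sift_direction <- match.arg(sift_direction)
  out <- as_tibble(annotations)
  sift_ok <- if (sift_direction == "as_printed") {
    out$sift >= sift_min
  } else {
    out$sift < sift_min
  }
  out$deleterious <- out$provean <= provean_max & sift_ok
  out$deleterious[is.na(out$provean) | is.na(out$sift)] <- NA
  out
}

#' Per-genome genetic burden
#'
#' Counts derived alleles per diploid genome at deleterious and fourfold
#' degenerate (neutral reference) sites under the additive model
#' (heterozygotes contribute 1, derived homozygotes 2) and the recessive
#' model (only derived homozygotes, contributing 2). The burden is the
#' deleterious count divided by the fourfold count under the same model;
#' `NA` when the denominator is zero.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap tibble (`sample`, `species`) used to polarize by the
#'   outgroup.
#' @param outgroup outgroup species for ancestral-allele inference.
#' @param deleterious_sites,fourfold_sites integer site indices (columns of
#'   `gm`) for the two site classes.
#' @return tibble per sample and model: `sample`, `model`,
#'   `deleterious_count`, `fourfold_count`, `burden`.
#' @export
genetic_burden <- function(gm, popmap, outgroup, deleterious_sites,
                           fourfold_sites) {
  af <- allele_freqs(gm, popmap, outgroup = outgroup)
  # derived dosage per genotype: flip dosage where the alt allele is ancestral
  kept <- which(paste(gm$sites$chrom, gm$sites$pos) %in%
                  paste(af$sites$chrom, af$sites$pos))
  geno <- gm$geno[, kept, drop = FALSE]
  flip <- !af$sites$derived_is_alt
  geno[, flip] <- 2L - geno[, flip]
  site_map <- match(kept, seq_len(ncol(gm$geno)))
  class_of <- function(orig_idx) which(kept %in% orig_idx)
  d_idx <- class_of(deleterious_sites)
  f_idx <- class_of(fourfold_sites)
  samples <- setdiff(gm$samples,
                     popmap$sample[popmap$species == outgroup])
  purrr::map_dfr(samples, function(s) {
    g <- geno[s, ]
    counts <- function(idx, model) {
      gg <- g[idx]
      if (model == "additive") sum(gg, na.rm = TRUE)
      else 2 * sum(gg == 2, na.rm = TRUE)
    }
    purrr::map_dfr(c("additive", "recessive"), function(model) {
      dc <- counts(d_idx, model)
      fc <- counts(f_idx, model)
      tibble(sample = s, model = model, deleterious_count = dc,
             fourfold_count = fc,
             burden = if (fc > 0) dc / fc else NA_real_)
    })
  })
}

#' Compare a statistic between called regions and the genomic background
#'
#' Two-sided Wilcoxon-Mann-Whitney U test (exact when sample sizes permit
#' and no ties are present, normal approximation with tie correction
#' otherwise).
#'
#' @param region_values,background_values numeric vectors (both non-empty).
#' @return one-row tibble (`u`, `p`, `n1`, `n2`).
#' @export
region_vs_background_test <- function(region_values, background_values) {
  x <- region_values[!is.na(region_values)]
  y <- background_values[!is.na(background_values)]
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble(u = unname(wt$statistic), p = wt$p.value,
         n1 = length(x), n2 = length(y))
}
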