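# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (exhaustive enumeration, direct formulas)
# and never call the implementation paths they check.

# genotype_matrix from a dosage matrix (samples x sites)
toy_gm <- function(geno, chrom = "chr1", pos = seq_len(ncol(geno)),
                   ref = "A", alt = "T", dp = NULL, ad_ref = NULL,
                   ad_alt = NULL, hap = NULL) {
  samples <- rownames(geno) %||% paste0("s", seq_len(nrow(geno)))
  rownames(geno) <- samples
  genotype_matrix(
    geno = geno,
    sites = tibble::tibble(chrom = chrom, pos = pos,
                           ref = rep_len(ref, ncol(geno)),
                           alt = rep_len(alt, ncol(geno))),
    samples = samples, hap = hap, phased = !is.null(hap),
    dp = dp, ad_ref = ad_ref, ad_alt = ad_alt
  )
}

# phased genotype_matrix from a 0/1 haplotype matrix (2 rows per sample);
# ref is the 0 allele so dosage counts 1-alleles
hap_gm <- function(hap, chrom = "chr1", pos = seq_len(ncol(hap)),
                   species = NULL) {
  n_s <- nrow(hap) / 2
  if (is.null(species)) species <- rep("sp", n_s)
  samples <- paste0(species, "_",
                    stats::ave(seq_len(n_s), species, FUN = seq_along))
  odd <- seq(1, nrow(hap), 2)
  geno <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  rownames(geno) <- samples
  rownames(hap) <- as.vector(t(outer(samples, c("_h1", "_h2"), paste0)))
  gm <- genotype_matrix(
    geno = geno,
    sites = tibble::tibble(chrom = chrom, pos = pos,
                           ref = "A", alt = "T"),
    samples = samples, hap = hap, phased = TRUE
  )
  list(gm = gm,
       popmap = tibble::tibble(sample = samples, species = species))
}

one_window <- function(len = 1000) {
  tibble::tibble(chrom = "chr1", start = 0, end = len)
}

# exhaustive mean pairwise difference per site across haplotypes
brute_pi <- function(hap) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(hap[i, ] != hap[j, ])
  }
  tot / choose(n, 2)
}

# dxy oracle: mean pairwise difference between haplotypes of two groups
brute_dxy <- function(hap1, hap2) {
  tot <- 0
  for (i in seq_len(nrow(hap1))) {
    for (j in seq_len(nrow(hap2))) tot <- tot + sum(hap1[i, ] != hap2[j, ])
  }
  tot / (nrow(hap1) * nrow(hap2))
}

# Tajima's D oracle: direct transcription of the 1989 constants, written
# independently of the package internals
oracle_tajd <- function(hap) {
  n <- nrow(hap)
  cnt <- colSums(hap)
  seg <- cnt > 0 & cnt < n
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  k <- brute_pi(hap)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - s / a1) / sqrt(c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1))
}

# Weir & Cockerham (1984) single-locus theta for two pops, written out
# directly from the published definitions
oracle_wc_fst <- function(geno1, geno2) {
  r <- 2
  n_i <- c(length(geno1), length(geno2))
  p_i <- c(mean(geno1) / 2, mean(geno2) / 2)
  h_i <- c(mean(geno1 == 1), mean(geno2 == 1))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# ABBA/BABA site-pattern counting D for fixed (0/1) taxon alleles
oracle_pattern_d <- function(taxa) {
  abba <- sum(taxa[1, ] == 0 & taxa[2, ] == 1 & taxa[3, ] == 1 &
                taxa[4, ] == 0)
  baba <- sum(taxa[1, ] == 1 & taxa[2, ] == 0 & taxa[3, ] == 1 &
                taxa[4, ] == 0)
  if (abba + baba == 0) return(NA_real_)
  (abba - baba) / (abba + baba)
}

# haplotype-spectrum H12 oracle
oracle_h12 <- function(hap) {
  f <- sort(table(apply(hap, 1, paste, collapse = "")), decreasing = TRUE)
  f <- as.numeric(f) / nrow(hap)
  if (length(f) == 1) return(1)
  (f[1] + f[2])^2 + sum(f[-(1:2)]^2)
}

# exhaustive pairwise-tract nSL oracle: scan outward SNP by SNP
oracle_nsl_raw <- function(hap, focal) {
  m <- ncol(hap)
  tract <- function(i, j) {
    if (hap[i, focal] != hap[j, focal]) return(0)
    len <- 1
    k <- focal - 1
    while (k >= 1 && hap[i, k] == hap[j, k]) { len <- len + 1; k <- k - 1 }
    k <- focal + 1
    while (k <= m && hap[i, k] == hap[j, k]) { len <- len + 1; k <- k + 1 }
    len
  }
  der <- which(hap[, focal] == 1)
  anc <- which(hap[, focal] == 0)
  if (length(der) < 2 || length(anc) < 2) return(NA_real_)
  mean_class <- function(ids) {
    prs <- utils::combn(ids, 2)
    mean(apply(prs, 2, function(p) tract(p[1], p[2])))
  }
  log(mean_class(anc) / mean_class(der))
}

# hypergeometric upper-tail by direct combinatorial summation
oracle_hyper_p <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# BH step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one small shared admixture simulation, built once per test run
shared_sim_cache <- new.env(parent = emptyenv())
shared_admix_sim <- function() {
  if (is.null(shared_sim_cache$sim)) {
    ev <- data.frame(donor = "P3", recipient = "P2", time = 2000,
                     prop = 0.3, window_frac = 0.2)
    cfg <- sim_config(
      tree = "(((P1:10000,P2:10000):30000,P3:40000):20000,OUT:60000);",
      n_diploids = 6, n_windows = 80, window_len = 10000,
      scaling_coeffs = c(a = 0, b = 0),
      admixture_events = ev, seed = 424242
    )
    shared_sim_cache$sim <- simulate_dataset(cfg)
  }
  shared_sim_cache$sim
}

# column-subset a genotype_matrix, keeping side matrices aligned
subset_sites_for_test <- function(gm, idx) {
  sub <- function(m) if (is.null(m)) NULL else m[, idx, drop = FALSE]
  genotype_matrix(gm$geno[, idx, drop = FALSE], gm$sites[idx, ],
                  gm$samples, hap = sub(gm$hap), phased = gm$phased,
                  dp = sub(gm$dp), ad_ref = sub(gm$ad_ref),
                  ad_alt = sub(gm$ad_alt))
}
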