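#' PCA summarization of a window statistic across units
#'
#' Standardizes each unit's (species or contrast) per-window vector to zero
#' mean and unit variance, drops windows with any missing value, and
#' performs PCA over units. The PC1 sign is fixed so the mean loading is
#' positive, making PC1 scores a consensus landscape for the statistic.
#'
#' @param data long tibble (`window`, `unit`, `value`) or a numeric matrix
#'   windows x units.
#' @return object of class `landscape_pca` with `scores` (tibble `window`,
#'   `pc1`), `loadings` (tibble `unit`, `pc1`), `var_explained`,
#'   `dropped_windows`, `dropped_units`.
#' @export
summarize_pca <- function(data) {
  if (is.matrix(data)) {
    m <- data
  } else {
    data <- as_tibble(data)
    wide <- tidyr::pivot_wider(data, names_from = "unit",
                               values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide[[1]])
  }
  if (ncol(m) < 2) abort("PCA needs at least two units")
  zero_var <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE)) == 0
  zero_var[is.na(zero_var)] <- TRUE
  if (any(zero_var)) {
    warn(paste("dropping zero-variance units:",
               paste(colnames(m)[zero_var], collapse = ", ")))
    m <- m[, !zero_var, drop = FALSE]
  }
  complete <- rowSums(is.na(m)) == 0
  dropped <- rownames(m)[!complete] %||% which(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) abort("too few complete windows for PCA")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  sgn <- if (mean(pc$rotation[, 1]) < 0) -1 else 1
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tibble(window = rownames(m) %||% seq_len(nrow(m)),
                      pc1 = sgn * pc$x[, 1]),
      loadings = tibble(unit = colnames(m), pc1 = sgn * pc$rotation[, 1]),
      var_explained = var_explained,
      rotation = pc$rotation, sdev = pc$sdev,
      dropped_windows = dropped,
      dropped_units = if (any(zero_var)) names(zero_var)[zero_var] else character(0)
    ),
    class = "landscape_pca"
  )
}

#' @export
print.landscape_pca <- function(x, ...) {
  cat(sprintf("<landscape_pca> %d windows x %d units; PC1 = %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), 100 * x$var_explained[1]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Average-rank ties; p-value from the t approximation.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return one-row tibble (`rho`, `p`, `n`); `NA` with a warning for
#'   constant input.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper-triangle entries, with a
#' one-sided permutation p-value (labels of the second matrix permuted,
#' add-one smoothing).
#'
#' @param a,b symmetric distance matrices over the same tip set (matching
#'   dimnames are aligned).
#' @param n_perm number of permutations.
#' @return one-row tibble (`r`, `p`, `n_perm`).
#' @export
mantel <- function(a, b, n_perm = 999) {
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) abort("tip sets differ")
    b <- b[rownames(a), rownames(a)]
  } else if (!all(dim(a) == dim(b))) {
    abort("matrices must have matching dimensions")
  }
  ut <- upper.tri(a)
  va <- a[ut]
  r_obs <- mantel_r(va, b, ut)
  if (is.na(r_obs)) return(tibble(r = NA_real_, p = NA_real_, n_perm = n_perm))
  hits <- 0L
  n <- nrow(a)
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_p <- mantel_r(va, b[perm, perm], ut)
    if (!is.na(r_p) && r_p >= r_obs) hits <- hits + 1L
  }
  tibble(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

mantel_r <- function(va, b, ut) {
  vb <- b[ut]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

#' Per-window tree concordance
#'
#' Mantel correlation (no permutations) between each window's tip distance
#' matrix and the genome-wide matrix. Windows whose matrix misses tips or
#' has zero variance (star-like windows) return `NA`.
#'
#' @param window_mats list of per-window distance matrices (or `NULL`
#'   entries).
#' @param genome_mat genome-wide distance matrix.
#' @return tibble (`window`, `concordance`).
#' @export
tree_concordance <- function(window_mats, genome_mat) {
  purrr::map_dfr(seq_along(window_mats), function(w) {
    m <- window_mats[[w]]
    val <- if (is.null(m) ||
               !setequal(rownames(m), rownames(genome_mat))) {
      NA_real_
    } else {
      mm <- m[rownames(genome_mat), rownames(genome_mat)]
      ut <- upper.tri(genome_mat)
      mantel_r(genome_mat[ut], mm, ut)
    }
    tibble(window = w, concordance = val)
  })
}

#' Per-window between-species distance matrices
#'
#' Mean per-site allele-frequency distance between species in each window
#' (the dXY-style distance used to build window trees for concordance);
#' windows with fewer than `min_snps` usable SNPs return `NULL`. A
#' neighbor-joining tree can be built from any returned matrix with
#' [nj_tree()].
#'
#' @param gm a [genotype_matrix()].
#' @param popmap tibble (`sample`, `species`).
#' @param windows window grid.
#' @param min_snps minimum usable SNPs per window.
#' @return list of species x species distance matrices (or `NULL`).
#' @export
window_distance_matrices <- function(gm, popmap, windows, min_snps = 5) {
  af <- allele_freqs(gm, popmap)
  species <- rownames(af$freq)
  win_id <- assign_windows(af$sites, windows)
  lapply(seq_len(nrow(windows)), function(w) {
    idx <- which(win_id == w)
    if (length(idx) < min_snps) return(NULL)
    p <- af$freq[, idx, drop = FALSE]
    d <- matrix(0, length(species), length(species),
                dimnames = list(species, species))
    for (i in seq_along(species)) {
      for (j in seq_len(i - 1)) {
        pi_ <- p[i, ]; pj <- p[j, ]
        ok <- !is.na(pi_) & !is.na(pj)
        if (!sum(ok)) return(NULL)
        d[i, j] <- d[j, i] <- mean(pi_[ok] * (1 - pj[ok]) +
                                     pj[ok] * (1 - pi_[ok]))
      }
    }
    d
  })
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over the standard NJ algorithm, provided for building
#' window trees from SNP distances in synthetic tests.
#'
#' @param d distance matrix.
#' @return a `phylo` object.
#' @export
nj_tree <- function(d) ape::nj(stats::as.dist(d))

#' Permutation test for window autocorrelation
#'
#' Statistic: the mean over lags `1..max_lag` of the lag-k Spearman
#' autocorrelation of window values along each chromosome, averaged over
#' chromosomes. Significance by permuting window values within chromosomes;
#' one-sided p with add-one smoothing.
#'
#' @param values tibble (`chrom`, `value`) with windows in genomic order.
#' @param n_perm number of permutations.
#' @param max_lag largest lag (windows).
#' @param min_windows minimum windows required per chromosome.
#' @return one-row tibble (`statistic`, `p`, `n_perm`); `NA` when no
#'   chromosome is usable or values are constant.
#' @export
autocorr_permutation <- function(values, n_perm = 1000, max_lag = 5,
                                 min_windows = 50) {
  values <- as_tibble(values)
  by_chr <- split(values$value, values$chrom)
  by_chr <- by_chr[vapply(by_chr, length, 1L) >= min_windows]
  by_chr <- lapply(by_chr, function(v) v[!is.na(v)])
  by_chr <- by_chr[vapply(by_chr, length, 1L) >= min_windows]
  if (!length(by_chr) ||
      all(vapply(by_chr, function(v) sd(v) == 0, logical(1)))) {
    return(tibble(statistic = NA_real_, p = NA_real_, n_perm = n_perm))
  }
  stat <- autocorr_stat(by_chr, max_lag)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- lapply(by_chr, sample)
    if (autocorr_stat(perm, max_lag) >= stat) hits <- hits + 1L
  }
  tibble(statistic = stat, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

autocorr_stat <- function(by_chr, max_lag) {
  per_chr <- vapply(by_chr, function(v) {
    r <- rank(v)
    lags <- vapply(seq_len(max_lag), function(k) {
      n <- length(r)
      if (n - k < 3) return(NA_real_)
      suppressWarnings(cor(r[seq_len(n - k)], r[(k + 1):n],
                           method = "spearman"))
    }, numeric(1))
    mean(lags, na.rm = TRUE)
  }, numeric(1))
  mean(per_chr, na.rm = TRUE)
}

#' Phylogenetic contrasts from a species tree
#'
#' One contrast per internal node of the rooted binary ingroup tree; a
#' species pair belongs to the contrast at its MRCA, so the contrasts
#' partition all pairs. Per-window contrast values are unweighted means
#' over member pairs.
#'
#' @param tree Newick or `phylo` for the ingroup (outgroup dropped first
#'   when `outgroup` given).
#' @param outgroup optional outgroup tip to drop.
#' @return tibble (`contrast`, `species1`, `species2`): one row per member
#'   pair.
#' @export
build_contrasts <- function(tree, outgroup = NULL) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (!is.null(outgroup)) phy <- ape::drop.tip(phy, outgroup)
  if (!ape::is.binary(phy)) abort("contrasts need a binary tree")
  ntip <- length(phy$tip.label)
  clades <- clade_tip_sets(phy)
  out <- list()
  for (v in (ntip + 1):(ntip + phy$Nnode)) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    left <- clades[[as.character(kids[1])]]
    right <- clades[[as.character(kids[2])]]
    pairs <- expand.grid(species1 = left, species2 = right,
                         stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- tibble(
      contrast = paste0("node", v - ntip),
      species1 = pairs$species1, species2 = pairs$species2
    )
  }
  bind_rows(out)
}

#' Per-contrast averaged window values
#'
#' Averages a pairwise window statistic over the species pairs belonging to
#' each contrast (unweighted mean over member pairs per window).
#'
#' @param pair_tbl tibble with `chrom`, `start`, `species1`, `species2` and
#'   a `value` column.
#' @param contrasts output of [build_contrasts()].
#' @param value name of the value column in `pair_tbl`.
#' @return tibble (`contrast`, `chrom`, `start`, `value`).
#' @export
contrast_values <- function(pair_tbl, contrasts, value = "value") {
  pair_tbl <- as_tibble(pair_tbl)
  pair_tbl$value <- pair_tbl[[value]]
  keyed <- pair_tbl |>
    mutate(pair_key = purrr::map2_chr(.data$species1, .data$species2,
                                      ~ paste(sort(c(.x, .y)), collapse = "|")))
  ckey <- contrasts |>
    mutate(pair_key = purrr::map2_chr(.data$species1, .data$species2,
                                      ~ paste(sort(c(.x, .y)), collapse = "|"))) |>
    select("contrast", "pair_key")
  keyed |>
    dplyr::inner_join(ckey, by = "pair_key") |>
    group_by(.data$contrast, .data$chrom, .data$start) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Correlation-versus-divergence dynamics across contrasts
#'
#' Given per-contrast correlation coefficients between a pair of window
#' statistics, and per-contrast net divergence d_a as a divergence-time
#' proxy, fits an ordinary least-squares regression of the coefficient on
#' d_a and reports the Spearman rank correlation of the same.
#'
#' @param dyn tibble (`contrast`, `stat_pair`, `coefficient`, `d_a`).
#' @return tibble per stat pair: `stat_pair`, `slope`, `intercept`,
#'   `slope_p`, `spearman_rho`, `n`.
#' @export
dynamics <- function(dyn) {
  dyn <- as_tibble(dyn)
  purrr::map_dfr(unique(dyn$stat_pair), function(spair) {
    d <- dyn |> filter(.data$stat_pair == spair,
                       !is.na(.data$coefficient), !is.na(.data$d_a))
    if (nrow(d) < 3 || sd(d$d_a) == 0) {
      return(tibble(stat_pair = spair, slope = NA_real_,
                    intercept = NA_real_, slope_p = NA_real_,
                    spearman_rho = NA_real_, n = nrow(d)))
    }
    fit <- lm(coefficient ~ d_a, data = d)
    sm <- summary(fit)$coefficients
    sp <- spearman(d$d_a, d$coefficient)
    tibble(stat_pair = spair, slope = coef(fit)[["d_a"]],
           intercept = coef(fit)[["(Intercept)"]],
           slope_p = if (nrow(sm) > 1) sm["d_a", 4] else NA_real_,
           spearman_rho = sp$rho, n = nrow(d))
  })
}
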