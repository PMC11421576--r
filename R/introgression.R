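#' Enumerate valid trios from a rooted species tree
#'
#' A trio (P1, P2, P3) is valid when P1 and P2 are mutually closer to each
#' other than either is to P3, i.e. P3 lies outside the clade spanned by
#' the MRCA of P1 and P2. Each unordered \{P1, P2\} pair is emitted once, in
#' tree tip order.
#'
#' @param tree Newick string or `phylo` (may include the outgroup).
#' @param outgroup tip label excluded from the ingroup (dropped before
#'   enumeration).
#' @return tibble (`p1`, `p2`, `p3`).
#' @export
enumerate_trios <- function(tree, outgroup = NULL) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label) abort("outgroup tip absent from tree")
    phy <- ape::drop.tip(phy, outgroup)
  }
  if (!ape::is.binary(phy)) {
    warn("non-binary tree: resolving multifurcations arbitrarily")
    phy <- ape::multi2di(phy)
  }
  tips <- phy$tip.label
  if (length(tips) < 3) {
    return(tibble(p1 = character(), p2 = character(), p3 = character()))
  }
  clade_tips <- clade_tip_sets(phy)
  out <- list()
  for (i in seq_along(tips)[-length(tips)]) {
    for (j in seq((i + 1), length(tips))) {
      mrca <- ape::getMRCA(phy, c(tips[i], tips[j]))
      inside <- clade_tips[[as.character(mrca)]]
      p3s <- setdiff(tips, inside)
      if (length(p3s)) {
        out[[length(out) + 1L]] <- tibble(p1 = tips[i], p2 = tips[j], p3 = p3s)
      }
    }
  }
  bind_rows(out)
}

clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- list()
  for (v in (ntip + 1):(ntip + phy$Nnode)) {
    sets[[as.character(v)]] <- ape::extract.clade(phy, v)$tip.label
  }
  for (v in seq_len(ntip)) sets[[as.character(v)]] <- phy$tip.label[v]
  sets
}

#' Per-site ABBA/BABA components for a trio
#'
#' With derived-allele frequencies \eqn{p_1, p_2, p_3, p_O},
#' ABBA \eqn{= (1-p_1) p_2 p_3 (1-p_O)} and
#' BABA \eqn{= p_1 (1-p_2) p_3 (1-p_O)} per site. Sites missing data in any
#' of the four populations are skipped.
#'
#' @param af polarized frequencies from [allele_freqs()] (with `outgroup`).
#' @param trio character vector `c(p1, p2, p3)`.
#' @return tibble (`chrom`, `pos`, `abba`, `baba`).
#' @export
site_patterns <- function(af, trio) {
  if (!isTRUE(af$polarized)) abort("frequencies must be outgroup-polarized")
  need <- c(trio, af$outgroup)
  if (!all(need %in% rownames(af$freq))) abort("trio species absent from freqs")
  p <- af$freq[need, , drop = FALSE]
  ok <- colSums(is.na(p)) == 0
  p1 <- p[1, ok]; p2 <- p[2, ok]; p3 <- p[3, ok]; po <- p[4, ok]
  tibble(
    chrom = af$sites$chrom[ok], pos = af$sites$pos[ok],
    abba = (1 - p1) * p2 * p3 * (1 - po),
    baba = p1 * (1 - p2) * p3 * (1 - po)
  )
}

#' Patterson's D statistic for one trio
#'
#' \eqn{D = (\sum ABBA - \sum BABA) / (\sum ABBA + \sum BABA)} over all
#' usable sites; `NA` when the denominator is zero.
#'
#' @inheritParams site_patterns
#' @return one-row tibble (`p1`, `p2`, `p3`, `d`, `abba`, `baba`,
#'   `n_sites`).
#' @export
patterson_d <- function(af, trio) {
  pat <- site_patterns(af, trio)
  A <- sum(pat$abba); B <- sum(pat$baba)
  tibble(p1 = trio[1], p2 = trio[2], p3 = trio[3],
         d = if (A + B > 0) (A - B) / (A + B) else NA_real_,
         abba = A, baba = B, n_sites = nrow(pat))
}

#' Block-jackknife test for the D statistic
#'
#' Splits the site-level ABBA/BABA series into contiguous genomic blocks of
#' `block_size` bp, recomputes D with each block deleted in turn, and
#' derives a standard error from the delete-one estimates; Z = D/SE with a
#' two-sided normal p-value.
#'
#' @param patterns tibble from [site_patterns()].
#' @param block_size block length in bp.
#' @param min_blocks minimum number of non-empty blocks required.
#' @return one-row tibble (`d`, `se`, `z`, `p`, `n_blocks`).
#' @export
block_jackknife <- function(patterns, block_size = 1e6, min_blocks = 20) {
  block <- paste(patterns$chrom, floor(patterns$pos / block_size))
  info <- patterns$abba + patterns$baba > 0
  blocks <- unique(block[info])
  nb <- length(blocks)
  if (nb < min_blocks) {
    abort(sprintf(paste("only %d non-empty jackknife blocks (need >= %d);",
                        "use more data or a smaller block_size"),
                  nb, min_blocks))
  }
  A <- sum(patterns$abba); B <- sum(patterns$baba)
  if (A + B <= 0) abort("no informative sites")
  d_full <- (A - B) / (A + B)
  a_blk <- tapply(patterns$abba, block, sum)[blocks]
  b_blk <- tapply(patterns$baba, block, sum)[blocks]
  d_del <- (A - a_blk - (B - b_blk)) / (A - a_blk + B - b_blk)
  se <- sqrt((nb - 1) / nb * sum((d_del - mean(d_del))^2))
  if (se == 0) {
    warn("jackknife SE is zero; p-value unavailable")
    return(tibble(d = d_full, se = 0, z = NA_real_, p = NA_real_,
                  n_blocks = nb))
  }
  z <- d_full / se
  tibble(d = d_full, se = se, z = z, p = 2 * pnorm(-abs(z)), n_blocks = nb)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, monotone non-decreasing in `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' D statistics with jackknife significance for many trios
#'
#' Convenience wrapper running [patterson_d()] and [block_jackknife()] per
#' trio and appending BH q-values across trios.
#'
#' @inheritParams site_patterns
#' @param trios tibble from [enumerate_trios()].
#' @inheritParams block_jackknife
#' @return tibble with one row per trio.
#' @export
d_statistics <- function(af, trios, block_size = 1e6, min_blocks = 20) {
  res <- purrr::map_dfr(seq_len(nrow(trios)), function(i) {
    trio <- c(trios$p1[i], trios$p2[i], trios$p3[i])
    pat <- site_patterns(af, trio)
    jk <- block_jackknife(pat, block_size, min_blocks)
    bind_cols(tibble(p1 = trio[1], p2 = trio[2], p3 = trio[3]), jk)
  })
  res$q <- bh_fdr(res$p)
  res
}

#' f4-admixture ratio with random P3 split
#'
#' Estimates the admixture proportion from P3 into P2 by randomly halving
#' the P3 haplotypes into subsets P3a and P3b (seeded) and forming
#' \eqn{f_4(P1, P2; P3a, O) / f_4(P1, P3b; P3a, O)} with
#' \eqn{f_4(A, B; C, D) = \sum (p_A - p_B)(p_C - p_D)} over usable sites.
#'
#' @param gm a phased [genotype_matrix()].
#' @param popmap tibble (`sample`, `species`).
#' @param trio character `c(p1, p2, p3)`.
#' @param outgroup outgroup species name.
#' @param seed integer seed for the P3 split.
#' @return one-row tibble (`p1`, `p2`, `p3`, `f4_ratio`, `seed`,
#'   `n_sites`); `f4_ratio` is `NA` with a warning when the denominator is
#'   not positive.
#' @export
f4_ratio <- function(gm, popmap, trio, outgroup, seed = 1) {
  hf <- hap_species_freqs(gm, popmap)
  f4_ratio_from_haps(hf, trio, outgroup, seed)
}

# Precompute per-species haplotype row indices for the phased matrix.
hap_species_freqs <- function(gm, popmap) {
  if (!gm$phased || is.null(gm$hap)) abort("f4-ratio needs phased haplotypes")
  popmap <- as_tibble(popmap)
  idx <- lapply(split(popmap$sample, popmap$species), function(smp) {
    rows <- match(smp, gm$samples)
    sort(c(2 * rows - 1, 2 * rows))
  })
  list(hap = gm$hap, idx = idx, sites = gm$sites)
}

f4_ratio_from_haps <- function(hf, trio, outgroup, seed = 1) {
  for (sp in c(trio, outgroup)) {
    if (!sp %in% names(hf$idx)) abort(paste("species absent from popmap:", sp))
  }
  i3 <- hf$idx[[trio[3]]]
  if (length(i3) < 2) abort("P3 needs at least two haplotypes")
  halves <- withr::with_seed(seed, sample(i3))
  p3a_idx <- halves[seq_len(floor(length(i3) / 2))]
  p3b_idx <- setdiff(i3, p3a_idx)
  fr <- function(rows) colMeans(hf$hap[rows, , drop = FALSE], na.rm = TRUE)
  po_raw <- fr(hf$idx[[outgroup]])
  # polarize: outgroup major allele is ancestral
  flip <- po_raw > 0.5
  pol <- function(p) ifelse(flip, 1 - p, p)
  p1 <- pol(fr(hf$idx[[trio[1]]]))
  p2 <- pol(fr(hf$idx[[trio[2]]]))
  p3a <- pol(fr(p3a_idx))
  p3b <- pol(fr(p3b_idx))
  po <- pol(po_raw)
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3a) | is.na(p3b) | is.na(po))
  # orientation chosen so the denominator (shared P3a/P3b drift relative to
  # P1 and the outgroup) is positive in expectation
  num <- sum((p2[ok] - p1[ok]) * (p3a[ok] - po[ok]))
  den <- sum((p3b[ok] - p1[ok]) * (p3a[ok] - po[ok]))
  val <- if (den > 0) num / den else {
    warn("f4-ratio denominator not positive; returning NA")
    NA_real_
  }
  tibble(p1 = trio[1], p2 = trio[2], p3 = trio[3], f4_ratio = val,
         seed = seed, n_sites = sum(ok))
}

#' Reduce redundant trios sharing a P2-P3 pair
#'
#' Trios are grouped by their unordered \{P2, P3\} pair and the trio with
#' the maximum D is kept from each group; ties are broken by smaller
#' p-value, then lexicographic P1.
#'
#' @param results trio table with columns `p1`, `p2`, `p3`, `d` and
#'   optionally `p`.
#' @return reduced tibble, one row per distinct P2-P3 pair.
#' @export
dedup_trios <- function(results) {
  results <- as_tibble(results)
  if (!"p" %in% names(results)) results$p <- NA_real_
  results |>
    mutate(pair_key = purrr::map2_chr(.data$p2, .data$p3,
                                      ~ paste(sort(c(.x, .y)), collapse = "|"))) |>
    group_by(.data$pair_key) |>
    arrange(dplyr::desc(.data$d), .data$p, .data$p1, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"pair_key")
}

#' f-branch statistic
#'
#' Assigns f4-ratio signal to specific tree branches: for a branch `b` and
#' donor species `C`, \eqn{f_b(C)} is the median over lineages `A` in the
#' sister clade of `b` of the minimum over lineages `B` descending from `b`
#' of the f4-ratio \eqn{f_4\mbox{-ratio}(A, B; C, O)}. No value is produced
#' for donors inside the clade of `b`'s parent (the trio would be invalid).
#'
#' @inheritParams f4_ratio
#' @param tree Newick or `phylo` including the outgroup tip.
#' @param outgroup outgroup species (tip label and popmap species).
#' @return tibble (`branch`, `branch_tips`, `donor`, `fb`).
#' @export
f_branch <- function(gm, popmap, tree, outgroup, seed = 1) {
  phy_full <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  phy <- ape::drop.tip(phy_full, outgroup)
  tips <- phy$tip.label
  ntip <- length(tips)
  clades <- clade_tip_sets(phy)
  hf <- hap_species_freqs(gm, popmap)
  cache <- new.env(parent = emptyenv())
  f4r <- function(a, b, c) {
    key <- paste(a, b, c, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- f4_ratio_from_haps(hf, c(a, b, c), outgroup, seed)$f4_ratio
    cache[[key]] <- val
    val
  }
  root <- ntip + 1L
  out <- list()
  for (v in setdiff(seq_len(ntip + phy$Nnode), root)) {
    parent <- phy$edge[phy$edge[, 2] == v, 1]
    sibs <- setdiff(phy$edge[phy$edge[, 1] == parent, 2], v)
    clade_b <- clades[[as.character(v)]]
    sister <- unlist(lapply(sibs, function(s) clades[[as.character(s)]]))
    parent_clade <- clades[[as.character(parent)]]
    donors <- setdiff(tips, parent_clade)
    if (!length(donors)) next
    branch_name <- if (v <= ntip) tips[v] else {
      paste0("mrca(", paste(range_label(clade_b), collapse = ","), ")")
    }
    for (C in donors) {
      mins <- vapply(sister, function(A) {
        vals <- vapply(clade_b, function(B) f4r(A, B, C), numeric(1))
        if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
      }, numeric(1))
      fb <- if (all(is.na(mins))) NA_real_ else median(mins, na.rm = TRUE)
      out[[length(out) + 1L]] <- tibble(
        branch = branch_name,
        branch_tips = paste(clade_b, collapse = ","),
        donor = C, fb = fb
      )
    }
  }
  bind_rows(out)
}

range_label <- function(tips) {
  if (length(tips) <= 2) tips else c(tips[1], tips[length(tips)])
}

#' Windowed fd and fdM introgression statistics
#'
#' Per window, fd uses the dynamic-donor denominator (the donor allele
#' frequency is the larger of \eqn{p_2} and \eqn{p_3} at each site); fdM is
#' the symmetric modification whose positive values indicate P2-P3 gene
#' flow and negative values P1-P3 gene flow. Windows with fewer than
#' `min_sites` ABBA/BABA-informative sites report `NA`.
#'
#' @inheritParams site_patterns
#' @param windows tibble (`chrom`, `start`, `end`).
#' @param min_sites minimum informative sites per window.
#' @return `windows` with columns `fd`, `fdm`, `n_informative`.
#' @export
window_fd_fdm <- function(af, trio, windows, min_sites = 10) {
  if (!isTRUE(af$polarized)) abort("frequencies must be outgroup-polarized")
  need <- c(trio, af$outgroup)
  p <- af$freq[need, , drop = FALSE]
  ok <- colSums(is.na(p)) == 0
  p1 <- p[1, ]; p2 <- p[2, ]; p3 <- p[3, ]; po <- p[4, ]
  dnum <- function(a, b, c, d) (1 - a) * b * c * (1 - d) - a * (1 - b) * c * (1 - d)
  num <- dnum(p1, p2, p3, po)
  pd_fd <- pmax(p2, p3)
  den_fd <- dnum(p1, pd_fd, pd_fd, po)
  pdm1 <- pmax(p2, p3)
  pdm2 <- pmax(p1, p3)
  den_fdm <- ifelse(p2 >= p1,
                    dnum(p1, pdm1, pdm1, po),
                    -dnum(pdm2, p2, pdm2, po))
  abba <- (1 - p1) * p2 * p3 * (1 - po)
  baba <- p1 * (1 - p2) * p3 * (1 - po)
  informative <- ok & (abba + baba) > 0
  win_id <- assign_windows(af$sites, windows)
  out <- as_tibble(windows)
  agg <- function(x, which_rows) {
    vapply(seq_len(nrow(windows)), function(w) {
      sum(x[which_rows & win_id == w], na.rm = TRUE)
    }, numeric(1))
  }
  n_inf <- vapply(seq_len(nrow(windows)), function(w) {
    sum(informative & win_id == w, na.rm = TRUE)
  }, numeric(1))
  num_w <- agg(num, ok)
  fd <- num_w / agg(den_fd, ok)
  fdm <- num_w / agg(den_fdm, ok)
  fd[n_inf < min_sites] <- NA_real_
  fdm[n_inf < min_sites] <- NA_real_
  out$fd <- fd
  out$fdm <- fdm
  out$n_informative <- as.integer(n_inf)
  out
}

#' Call candidate introgression regions from fdM
#'
#' Implements the top-X% caller calibrated by the f4-ratio: with
#' \eqn{X = 100 \cdot multiplier \cdot f_4\mbox{-ratio}} percent, the
#' \eqn{k = \mathrm{round}(X\% \times n_{scored})} windows with the highest
#' fdM are called, ties at the cutoff admitted in position order.
#'
#' @param fdm_tbl output of [window_fd_fdm()].
#' @param f4_ratio the trio's f4-ratio (proportion, e.g. 0.03).
#' @param multiplier scale factor from f4-ratio to the percent threshold
#'   (default 1: X% = 100 x f4-ratio).
#' @return `fdm_tbl` with a logical `called` column.
#' @export
call_regions <- function(fdm_tbl, f4_ratio, multiplier = 1) {
  out <- as_tibble(fdm_tbl)
  out$called <- FALSE
  if (is.na(f4_ratio) || f4_ratio <= 0) return(out)
  scored <- which(!is.na(out$fdm))
  k <- round(multiplier * f4_ratio * length(scored))
  if (k <= 0) return(out)
  ord <- scored[order(-out$fdm[scored], out$chrom[scored], out$start[scored])]
  out$called[ord[seq_len(min(k, length(ord)))]] <- TRUE
  out
}

#' Genomic background for a species pair
#'
#' The background complementary to introgression calls: windows not called
#' in any trio involving either of the two species under consideration.
#'
#' @param all_calls tibble binding [call_regions()] outputs across trios,
#'   with columns `p2`, `p3`, `chrom`, `start`, `end`, `called`.
#' @param windows full window grid.
#' @param pair character vector of the two species under consideration.
#' @return `windows` with a logical `background` column.
#' @export
introgression_background <- function(all_calls, windows, pair) {
  rel <- all_calls |>
    filter(.data$called,
           .data$p2 %in% pair | .data$p3 %in% pair)
  key <- function(x) paste(x$chrom, x$start)
  out <- as_tibble(windows)
  out$background <- !(key(out) %in% key(rel))
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided enrichment p-value \eqn{P(X \ge k)} for drawing `k` labelled
#' genes among `n` genes in called regions, when `K` of the `N` genes
#' genome-wide carry the label.
#'
#' @param k labelled genes in the called set.
#' @param n genes in the called set.
#' @param K labelled genes genome-wide.
#' @param N genes genome-wide.
#' @return one-row tibble (`k`, `n`, `K`, `N`, `p`).
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (K > N || n > N) abort("K and n must not exceed N")
  if (k > min(n, K)) abort("k cannot exceed min(n, K)")
  tibble(k = k, n = n, K = K, N = N,
         p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}
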