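#' Windowed within-species diversity statistics
#'
#' Computes per-window, per-species nucleotide diversity (pi), Watterson's
#' theta and Tajima's D from called genotypes. Per site, with `n` the number
#' of non-missing alleles and `p` the alternate-allele frequency, the
#' pairwise-diversity contribution is \eqn{2 p (1-p) n/(n-1)}; window pi is
#' the sum over used sites divided by the accessible window length.
#' Watterson's theta is \eqn{S / (a_1 L)} with \eqn{a_1 = \sum_{i<n} 1/i}
#' evaluated at the window's median `n`, and Tajima's D uses the standard
#' 1989 constants. Sites with fewer than `min_n` non-missing alleles are
#' excluded; windows with fewer than `min_snps` polymorphic sites (or zero
#' accessible length) report `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap tibble (`sample`, `species`).
#' @param windows tibble (`chrom`, `start`, `end`), 0-based half-open,
#'   optionally with an `accessible` column of usable bp per window.
#' @param species species to compute (default: all in `popmap`).
#' @param min_snps minimum segregating sites per window before statistics
#'   are reported.
#' @param min_n minimum non-missing allele count for a site to be used.
#' @return tibble with one row per window x species: `chrom`, `start`,
#'   `end`, `species`, `pi`, `theta_w`, `tajima_d`, `n_snps`, `n_sites`.
#' @export
window_diversity <- function(gm, popmap, windows, species = NULL,
                             min_snps = 10, min_n = 4) {
  popmap <- as_tibble(popmap)
  windows <- as_tibble(windows)
  species <- species %||% unique(popmap$species)
  if (!all(species %in% popmap$species)) {
    abort(paste("species absent from popmap:",
                paste(setdiff(species, popmap$species), collapse = ", ")))
  }
  win_id <- assign_windows(gm$sites, windows)
  acc <- window_accessible(windows)
  purrr::map_dfr(species, function(sp) {
    rows <- popmap$sample[popmap$species == sp]
    g <- gm$geno[rows, , drop = FALSE]
    cnt <- colSums(g, na.rm = TRUE)
    n <- 2 * colSums(!is.na(g))
    use <- n >= min_n & !is.na(win_id)
    seg <- use & cnt > 0 & cnt < n
    pi_site <- ifelse(seg, 2 * cnt * (n - cnt) / (n * pmax(n - 1, 1)), 0)
    out <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
      idx <- which(win_id == w & use)
      s_idx <- which(win_id == w & seg)
      L <- acc[w]
      n_snps <- length(s_idx)
      if (L <= 0 || n_snps < min_snps) {
        return(tibble(pi = NA_real_, theta_w = NA_real_,
                      tajima_d = NA_real_, n_snps = n_snps, n_sites = L))
      }
      if (n_snps == 0) {
        return(tibble(pi = 0, theta_w = 0, tajima_d = NA_real_,
                      n_snps = 0L, n_sites = L))
      }
      n_med <- median(n[s_idx])
      k_hat <- sum(pi_site[s_idx])
      td <- tajimas_d(k_hat, n_snps, n_med)
      a1 <- sum(1 / seq_len(max(round(n_med) - 1, 1)))
      tibble(pi = k_hat / L, theta_w = n_snps / (a1 * L),
             tajima_d = td, n_snps = n_snps, n_sites = L)
    })
    bind_cols(windows[c("chrom", "start", "end")], species = sp, out)
  })
}

# Tajima's (1989) D from the pairwise-difference total, the number of
# segregating sites and the sample size; NA when S = 0 or n < 2.
tajimas_d <- function(k_hat, s, n) {
  if (is.na(s) || s == 0 || n < 2) return(NA_real_)
  nn <- round(n)
  i <- seq_len(nn - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (nn + 1) / (3 * (nn - 1))
  b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * s + e2 * s * (s - 1))
  if (denom == 0) return(NA_real_)
  (k_hat - s / a1) / denom
}

#' Windowed between-species divergence statistics
#'
#' Computes absolute divergence \eqn{d_{XY}} (mean over used sites of
#' \eqn{p_1(1-p_2) + p_2(1-p_1)}, divided by accessible length) and
#' relative differentiation FST as a ratio of sums across the window's
#' sites, under either the Hudson estimator (Bhatia et al. ratio of sums,
#' the default) or Weir & Cockerham's 1984 estimator.
#'
#' @inheritParams window_diversity
#' @param pair character vector of two species names.
#' @param estimator `"hudson"` or `"wc"`.
#' @return tibble per window: `chrom`, `start`, `end`, `species1`,
#'   `species2`, `fst`, `dxy`, `n_snps`, `n_sites`.
#' @export
window_divergence <- function(gm, popmap, pair, windows,
                              estimator = c("hudson", "wc"),
                              min_snps = 10) {
  estimator <- match.arg(estimator)
  popmap <- as_tibble(popmap)
  windows <- as_tibble(windows)
  if (length(pair) != 2) abort("`pair` must name two species")
  if (!all(pair %in% popmap$species)) abort("pair species absent from popmap")
  win_id <- assign_windows(gm$sites, windows)
  acc <- window_accessible(windows)
  g1 <- gm$geno[popmap$sample[popmap$species == pair[1]], , drop = FALSE]
  g2 <- gm$geno[popmap$sample[popmap$species == pair[2]], , drop = FALSE]
  c1 <- colSums(g1, na.rm = TRUE); n1 <- 2 * colSums(!is.na(g1))
  c2 <- colSums(g2, na.rm = TRUE); n2 <- 2 * colSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, c1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, c2 / n2, NA_real_)
  dxy_site <- p1 * (1 - p2) + p2 * (1 - p1)
  use_dxy <- n1 > 0 & n2 > 0 & !is.na(win_id)
  if (estimator == "hudson") {
    use_fst <- n1 >= 2 & n2 >= 2 & !is.na(win_id)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
      p2 * (1 - p2) / pmax(n2 - 1, 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    h1 <- colSums(g1 == 1, na.rm = TRUE) / pmax(colSums(!is.na(g1)), 1)
    h2 <- colSums(g2 == 1, na.rm = TRUE) / pmax(colSums(!is.na(g2)), 1)
    wc <- wc_components(colSums(!is.na(g1)), colSums(!is.na(g2)),
                        p1, p2, h1, h2)
    use_fst <- colSums(!is.na(g1)) >= 1 & colSums(!is.na(g2)) >= 1 &
      (colSums(!is.na(g1)) + colSums(!is.na(g2))) > 2 & !is.na(win_id)
    num <- wc$a
    den <- wc$a + wc$b + wc$c
  }
  purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    d_idx <- which(win_id == w & use_dxy)
    f_idx <- which(win_id == w & use_fst)
    L <- acc[w]
    poly <- d_idx[dxy_site[d_idx] > 0]
    n_snps <- length(poly)
    if (L <= 0 || n_snps < min_snps) {
      return(tibble(chrom = windows$chrom[w], start = windows$start[w],
                    end = windows$end[w], species1 = pair[1],
                    species2 = pair[2], fst = NA_real_, dxy = NA_real_,
                    n_snps = n_snps, n_sites = L))
    }
    fst <- {
      dd <- sum(den[f_idx], na.rm = TRUE)
      if (dd > 0) sum(num[f_idx], na.rm = TRUE) / dd else NA_real_
    }
    tibble(chrom = windows$chrom[w], start = windows$start[w],
           end = windows$end[w], species1 = pair[1], species2 = pair[2],
           fst = fst, dxy = sum(dxy_site[d_idx]) / L,
           n_snps = n_snps, n_sites = L)
  })
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# n1, n2 are diploid genotype counts; p the allele frequencies; h the
# observed heterozygote proportions.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  ntot <- n1 + n2
  nbar <- ntot / r
  nc <- (ntot - (n1^2 + n2^2) / ntot) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / ntot
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / ntot
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Genome-wide divergence summary and net divergence
#'
#' Aggregates per-window tables into genome-wide means (weighted by
#' accessible window length) and computes net divergence
#' \eqn{d_a = d_{XY} - \bar{\pi}} for each species pair, the proxy for
#' divergence time used in the landscape dynamics analysis.
#'
#' @param diversity_tbl output of [window_diversity()] covering both species.
#' @param divergence_tbl output of [window_divergence()].
#' @return tibble per pair: `species1`, `species2`, `mean_dxy`, `mean_pi`,
#'   `mean_fst`, `d_a`, `n_windows`.
#' @export
divergence_summary <- function(diversity_tbl, divergence_tbl) {
  pairs <- distinct(divergence_tbl, .data$species1, .data$species2)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    sp1 <- pairs$species1[i]; sp2 <- pairs$species2[i]
    dv <- divergence_tbl |>
      filter(.data$species1 == sp1, .data$species2 == sp2, !is.na(.data$dxy))
    p1 <- diversity_tbl |> filter(.data$species == sp1, !is.na(.data$pi))
    p2 <- diversity_tbl |> filter(.data$species == sp2, !is.na(.data$pi))
    key <- function(x) paste(x$chrom, x$start)
    common <- Reduce(intersect, list(key(dv), key(p1), key(p2)))
    if (!length(common)) abort("no common windows between pi and dxy tables")
    dv <- dv[match(common, key(dv)), ]
    p1 <- p1[match(common, key(p1)), ]
    p2 <- p2[match(common, key(p2)), ]
    wts <- dv$n_sites
    mean_dxy <- sum(dv$dxy * wts) / sum(wts)
    mean_fst <- sum(dv$fst * wts, na.rm = TRUE) /
      sum(wts[!is.na(dv$fst)])
    mean_pi <- (sum(p1$pi * wts) + sum(p2$pi * wts)) / (2 * sum(wts))
    tibble(species1 = sp1, species2 = sp2, mean_dxy = mean_dxy,
           mean_pi = mean_pi, mean_fst = mean_fst,
           d_a = mean_dxy - mean_pi, n_windows = length(common))
  })
}

#' Mutation rate from divergence and divergence time
#'
#' Implements \eqn{\mu = d / 2T}: the per-site per-year mutation rate
#' implied by the genetic divergence `d` between two lineages that split
#' `T` years ago.
#'
#' @param d genetic divergence (substitutions per site), non-negative.
#' @param T_years divergence time in years, positive.
#' @return mutation rate per site per year.
#' @examples
#' mutation_rate(0.0857, 52.2e6) # ~8.21e-10
#' @export
mutation_rate <- function(d, T_years) {
  if (any(T_years <= 0)) abort("`T_years` must be positive")
  if (any(d < 0)) abort("`d` must be non-negative")
  d / (2 * T_years)
}

# Map sites to window indices (NA when outside every window).
assign_windows <- function(sites, windows) {
  out <- rep(NA_integer_, nrow(sites))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(sites$chrom == chr)
    if (!length(si)) next
    # pos is 1-based; windows 0-based half-open
    idx <- findInterval(sites$pos[si] - 1L, windows$start[wi])
    ok <- idx >= 1 & (sites$pos[si] - 1L) < windows$end[wi][pmax(idx, 1)]
    out[si[ok]] <- wi[idx[ok]]
  }
  out
}

window_accessible <- function(windows) {
  if ("accessible" %in% names(windows)) windows$accessible
  else windows$end - windows$start
}
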