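test_that("PCA of identical units puts all variance on PC1 with equal loadings", {
  set.seed(41)
  v <- rnorm(100)
  m <- cbind(a = v, b = v * 2 + 3)  # identical after standardization
  pca <- summarize_pca(m)
  expect_equal(pca$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(unname(abs(pca$loadings$pc1[1])),
               unname(abs(pca$loadings$pc1[2])), tolerance = 1e-12)
  expect_true(all(pca$loadings$pc1 > 0))
})

test_that("PCA of uncorrelated units approaches a 50% PC1 share", {
  set.seed(42)
  m <- cbind(a = rnorm(5000), b = rnorm(5000))
  pca <- summarize_pca(m)
  expect_lt(abs(pca$var_explained[1] - 0.5), 0.05)
})

test_that("PC1 scores track the unit mean when loadings share sign", {
  set.seed(43)
  base <- rnorm(400)
  m <- sapply(1:4, function(i) base + rnorm(400, sd = 0.5))
  colnames(m) <- paste0("u", 1:4)
  pca <- summarize_pca(m)
  expect_true(all(pca$loadings$pc1 > 0))
  r <- cor(pca$scores$pc1, rowMeans(scale(m)), method = "spearman")
  expect_gt(r, 0.95)
})

test_that("PCA variance shares are invariant to window and unit permutation", {
  set.seed(44)
  m <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[, 2] <- m[, 1] + rnorm(100, sd = 0.3)
  p1 <- summarize_pca(m)
  p2 <- summarize_pca(m[sample(100), c(3, 1, 2)])
  expect_equal(p1$var_explained, p2$var_explained, tolerance = 1e-12)
  # long input and zero-variance units
  long <- tidyr::expand_grid(window = 1:50, unit = c("a", "b"))
  long$value <- rnorm(100)
  expect_s3_class(summarize_pca(long), "landscape_pca")
  m3 <- cbind(m, d = rep(1, 100))
  expect_warning(summarize_pca(m3), "zero-variance")
})

test_that("Spearman correlation handles ties and degenerate input", {
  expect_equal(spearman(1:3, 3:1)$rho, -1)
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  # hand-ranked ties oracle: ranks (1.5, 1.5, 3) vs (1, 2, 3)
  s <- spearman(c(1, 1, 2), c(1, 2, 3))
  expect_equal(s$rho, 1.5 / (sqrt(1.5) * sqrt(2)), tolerance = 1e-12)
  expect_warning(out <- spearman(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman(1:2, 2:1), "3 complete")
})

test_that("Mantel r equals direct Pearson on the upper triangle", {
  set.seed(45)
  a <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  a[upper.tri(a)] <- c(1, 2, 3, 4, 5, 6)
  a <- a + t(a)
  b <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  b[upper.tri(b)] <- c(2, 1, 4, 3, 7, 5)
  b <- b + t(b)
  withr::with_seed(1, m <- mantel(a, b, n_perm = 499))
  expect_equal(m$r, cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 7, 5)),
               tolerance = 1e-12)
  # identical matrices: r = 1 and minimal achievable p
  withr::with_seed(2, m1 <- mantel(a, a, n_perm = 199))
  expect_equal(m1$r, 1)
  expect_lte(m1$p, 0.05)
  expect_error(mantel(a, b[c(1, 2, 3, 4), c(1, 2, 4, 3)][1:3, 1:3]),
               "differ")
})

test_that("Mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(46)
  d1 <- as.matrix(dist(matrix(rnorm(24), 8)))
  d2 <- as.matrix(dist(matrix(rnorm(24), 8)))
  rownames(d1) <- colnames(d1) <- rownames(d2) <- colnames(d2) <-
    paste0("t", 1:8)
  ours <- withr::with_seed(3, mantel(d1, d2, n_perm = 999))
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.1)
})

test_that("tree concordance is 1 for matching windows and NA for stars", {
  g <- cophenetic_matrix("((A:1,B:1):1,(C:1,D:1):1);")
  star <- matrix(1, 4, 4, dimnames = dimnames(g))
  diag(star) <- 0
  tc <- tree_concordance(list(g, star, NULL), g)
  expect_equal(tc$concordance[1], 1)
  expect_true(is.na(tc$concordance[2]))
  expect_true(is.na(tc$concordance[3]))
})

test_that("admixed windows show lower tree concordance on simulation", {
  sim <- shared_admix_sim()
  gm <- sim_genotype_matrix(sim)
  mats <- window_distance_matrices(gm, sim$samples, sim$windows)
  genome <- cophenetic_matrix(sim$tree)
  ing <- c("P1", "P2", "P3", "OUT")
  genome <- genome[ing, ing]
  tc <- tree_concordance(mats, genome)
  adm <- sim$truth$admixed_windows[[1]]
  expect_gt(mean(tc$concordance[-adm], na.rm = TRUE),
            mean(tc$concordance[adm], na.rm = TRUE))
  # any window matrix yields a proper NJ tree
  first <- which(!vapply(mats, is.null, logical(1)))[1]
  expect_s3_class(nj_tree(mats[[first]]), "phylo")
})

test_that("autocorrelation permutation test behaves at its extremes", {
  # smooth gradient: minimal p
  g <- tibble::tibble(chrom = "chr1", value = seq_len(80))
  withr::with_seed(4, out <- autocorr_permutation(g, n_perm = 99))
  expect_equal(out$p, 0.01, tolerance = 1e-12)
  # constant values: statistic absent
  cst <- tibble::tibble(chrom = "chr1", value = rep(1, 80))
  expect_true(is.na(autocorr_permutation(cst, n_perm = 19)$statistic))
  # too few windows: absent
  few <- tibble::tibble(chrom = "chr1", value = rnorm(10))
  expect_true(is.na(autocorr_permutation(few, n_perm = 19)$p))
})

test_that("contrasts partition all species pairs by MRCA", {
  ctr <- build_contrasts("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(length(unique(ctr$contrast)), 3L)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  root_pairs <- ctr[ctr$contrast == "node1", ]
  expect_setequal(key(root_pairs$species1, root_pairs$species2),
                  c("A C", "A D", "B C", "B D"))
  expect_equal(nrow(ctr), choose(4, 2))
  expect_false(any(duplicated(key(ctr$species1, ctr$species2))))
  # a 12-tip binary tree yields 11 contrasts
  phy <- ape::read.tree(text = "(((((((((((t1:1,t2:1):1,t3:2):1,t4:3):1,t5:4):1,t6:5):1,t7:6):1,t8:7):1,t9:8):1,t10:9):1,t11:10):1,t12:11);")
  ctr12 <- build_contrasts(phy)
  expect_equal(length(unique(ctr12$contrast)), 11L)
  expect_equal(nrow(ctr12), choose(12, 2))
})

test_that("contrast averaging and dynamics regression behave", {
  pair_tbl <- tidyr::expand_grid(
    chrom = "chr1", start = c(0, 100),
    pair = c("A|B", "A|C", "B|C")
  )
  pair_tbl$species1 <- sub("\\|.*", "", pair_tbl$pair)
  pair_tbl$species2 <- sub(".*\\|", "", pair_tbl$pair)
  pair_tbl$value <- c(1, 2, 3, 4, 5, 6)
  ctr <- build_contrasts("((A:1,B:1):1,C:2);")
  cv <- contrast_values(pair_tbl, ctr, "value")
  root <- cv[cv$contrast == "node1", ]
  expect_equal(sort(root$value), sort(c(mean(c(2, 3)), mean(c(5, 6)))))
  # dynamics: constant coefficients give slope 0; increasing give rho 1
  dyn <- tibble::tibble(
    contrast = rep(paste0("n", 1:5), 2),
    stat_pair = rep(c("flat", "rising"), each = 5),
    coefficient = c(rep(0.4, 5), seq(0.1, 0.5, 0.1)),
    d_a = rep(seq(0.001, 0.005, 0.001), 2)
  )
  out <- suppressWarnings(dynamics(dyn))
  expect_equal(out$slope[out$stat_pair == "flat"], 0, tolerance = 1e-12)
  expect_equal(out$spearman_rho[out$stat_pair == "rising"], 1)
  expect_true(is.na(dynamics(dyn[dyn$contrast %in% c("n1", "n2"), ])$slope[1]))
})
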