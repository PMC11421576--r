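# frequency container for hand-specified derived-allele frequencies
freq_af <- function(freq, pos = seq_len(ncol(freq)), outgroup = "O") {
  list(freq = freq, n = matrix(10, nrow(freq), ncol(freq),
                               dimnames = dimnames(freq)),
       sites = tibble::tibble(chrom = "chr1", pos = pos),
       polarized = TRUE, outgroup = outgroup)
}

test_that("trio enumeration follows the tree topology", {
  t1 <- enumerate_trios("((A:1,B:1):1,C:2);")
  expect_equal(nrow(t1), 1L)
  expect_equal(unlist(t1[1, ], use.names = FALSE), c("A", "B", "C"))
  t2 <- enumerate_trios("((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  expect_equal(nrow(t2), 4L)
  expect_setequal(paste(t2$p1, t2$p2, t2$p3),
                  c("A B C", "A B D", "C D A", "C D B"))
  # outgroup dropped; 2-tip ingroup has no valid trio
  t3 <- enumerate_trios("((A:1,B:1):1,OUT:2);", outgroup = "OUT")
  expect_equal(nrow(t3), 0L)
})

test_that("Patterson's D single-pattern limits", {
  f <- function(p) freq_af(matrix(p, 4, 1,
                                  dimnames = list(c("P1", "P2", "P3", "O"),
                                                  NULL)))
  d1 <- patterson_d(f(c(0, 1, 1, 0)), c("P1", "P2", "P3"))
  expect_equal(d1$d, 1)
  expect_equal(d1$abba, 1)
  expect_equal(d1$baba, 0)
  expect_equal(patterson_d(f(c(1, 0, 1, 0)), c("P1", "P2", "P3"))$d, -1)
  sym <- freq_af(cbind(c(0, 1, 1, 0), c(1, 0, 1, 0)),
                 pos = 1:2)
  rownames(sym$freq) <- c("P1", "P2", "P3", "O")
  expect_equal(patterson_d(sym, c("P1", "P2", "P3"))$d, 0)
  # all-zero patterns: D absent
  expect_true(is.na(patterson_d(f(c(0, 0, 0, 0)), c("P1", "P2", "P3"))$d))
})

test_that("frequency D equals the site-pattern-count oracle on fixed alleles", {
  set.seed(21)
  for (rep in 1:25) {
    m <- sample(5:50, 1)
    taxa <- matrix(rbinom(4 * m, 1, 0.5), 4, m,
                   dimnames = list(c("P1", "P2", "P3", "O"), NULL))
    taxa["O", ] <- 0L  # polarized: outgroup ancestral
    af <- freq_af(taxa, pos = seq_len(m))
    d <- patterson_d(af, c("P1", "P2", "P3"))$d
    expect_equal(d, oracle_pattern_d(taxa))
  }
})

test_that("block jackknife handles degenerate and undersized input", {
  pat <- tibble::tibble(chrom = "chr1", pos = seq_len(10) * 100,
                        abba = 1, baba = 0)
  expect_error(block_jackknife(pat, block_size = 100, min_blocks = 20),
               "blocks")
  # identical blocks: SE zero, p unavailable
  expect_warning(
    out <- block_jackknife(pat, block_size = 100, min_blocks = 5),
    "SE"
  )
  expect_true(is.na(out$p))
  expect_equal(out$d, 1)
})

test_that("jackknife Z is stable in block count on i.i.d. data", {
  set.seed(22)
  m <- 4000
  pat <- tibble::tibble(chrom = "chr1", pos = seq_len(m) * 10,
                        abba = rexp(m), baba = rexp(m))
  z1 <- block_jackknife(pat, block_size = 1000)$z
  z2 <- block_jackknife(pat, block_size = 500)$z
  expect_lt(abs(z1 - z2), 1)
})

test_that("BH q-values match the hand step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 4)), rep(0.07, 4))
  set.seed(23)
  p <- runif(30)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("f4-ratio limits: complete replacement near 1, no admixture near 0", {
  set.seed(24)
  m <- 4000
  base <- rbinom(m, 1, 0.5)
  drift <- function(x, eps) ifelse(runif(m) < eps, 1L - x, x)
  mk_block <- function(proto) {
    do.call(rbind, lapply(seq_len(8), function(i) drift(proto, 0.02)))
  }
  p3 <- mk_block(base)
  hap <- rbind(mk_block(drift(base, 0.2)),  # P1: diverged control
               p3[c(1, 3, 5, 7, 2, 4, 6, 8), ],  # P2 == shuffled P3 copies
               p3,
               matrix(0L, 2, m))  # outgroup, ancestral
  fx <- hap_gm(hap, species = c(rep("P1", 4), rep("P2", 4), rep("P3", 4),
                                "O"))
  r1 <- f4_ratio(fx$gm, fx$popmap, c("P1", "P2", "P3"), "O", seed = 2)
  expect_gt(r1$f4_ratio, 0.8)
  # P2 identical to P1: numerator is exactly zero
  hap2 <- hap
  hap2[9:16, ] <- hap[1:8, ]
  fx2 <- hap_gm(hap2, species = c(rep("P1", 4), rep("P2", 4), rep("P3", 4),
                                  "O"))
  r0 <- f4_ratio(fx2$gm, fx2$popmap, c("P1", "P2", "P3"), "O", seed = 2)
  expect_lt(abs(r0$f4_ratio), 0.05)
})

test_that("f4-ratio is insensitive to the P3 split seed", {
  sim <- shared_admix_sim()
  gm <- sim_genotype_matrix(sim)
  vals <- vapply(1:10, function(s) {
    f4_ratio(gm, sim$samples, c("P1", "P2", "P3"), "OUT",
             seed = s)$f4_ratio
  }, numeric(1))
  expect_lt(sd(vals), 0.1 * abs(mean(vals)) + 0.01)
})

test_that("trio de-duplication keeps the maximum-D trio per P2-P3 pair", {
  res <- tibble::tibble(
    p1 = c("A", "B", "C"), p2 = c("X", "X", "Y"), p3 = c("Y", "Y", "X"),
    d = c(0.1, 0.3, 0.2), p = c(0.01, 0.02, 0.03)
  )
  out <- dedup_trios(res)
  expect_equal(nrow(out), 1L)
  expect_equal(out$d, 0.3)
  single <- dedup_trios(res[1, ])
  expect_equal(nrow(single), 1L)
  # ties broken by smaller p then lexicographic P1
  tie <- tibble::tibble(p1 = c("B", "A"), p2 = "X", p3 = "Y",
                        d = 0.2, p = c(0.5, 0.5))
  expect_equal(dedup_trios(tie)$p1, "A")
})

test_that("windowed fd and fdM behave on designed patterns and track each other", {
  # window where P2 and P3 share all derived alleles absent from P1
  shared <- matrix(c(0, 1, 1, 0), 4, 10,
                   dimnames = list(c("P1", "P2", "P3", "O"), NULL))
  noise <- matrix(rbinom(4 * 30, 1, 0.2), 4, 30,
                  dimnames = list(c("P1", "P2", "P3", "O"), NULL))
  noise["O", ] <- 0
  af <- freq_af(cbind(shared, noise), pos = c(1:10, 101:130))
  wins <- tibble::tibble(chrom = "chr1", start = c(0, 100),
                         end = c(100, 200))
  fdm <- window_fd_fdm(af, c("P1", "P2", "P3"), wins, min_sites = 1)
  expect_equal(fdm$fdm[1], 1)
  expect_equal(which.max(fdm$fdm), 1L)
  # ABBA == BABA in a window gives zero
  bal <- matrix(c(0, 1, 1, 0, 1, 0, 1, 0), 4, 12,
                dimnames = list(c("P1", "P2", "P3", "O"), NULL))
  af2 <- freq_af(bal, pos = 1:12)
  fdm2 <- window_fd_fdm(af2, c("P1", "P2", "P3"), one_window(100),
                        min_sites = 1)
  expect_equal(fdm2$fd, 0)
  expect_equal(fdm2$fdm, 0)
  # fd and fdM strongly rank-correlated along simulated chromosomes with
  # ILS-rich windows (recent radiation, dense informative sites)
  ev <- data.frame(donor = "P3", recipient = "P2", time = 2000, prop = 0.3,
                   window_frac = 0.2)
  cfg <- sim_config(
    tree = "(((P1:10000,P2:10000):10000,P3:20000):20000,OUT:40000);",
    n_diploids = 6, n_windows = 60, window_len = 10000,
    scaling_coeffs = c(a = 0, b = 0), admixture_events = ev, seed = 777
  )
  sim <- simulate_dataset(cfg)
  gm <- sim_genotype_matrix(sim)
  af3 <- allele_freqs(gm, sim$samples, outgroup = "OUT")
  f <- window_fd_fdm(af3, c("P1", "P2", "P3"), sim$windows, min_sites = 10)
  expect_gte(cor(f$fd, f$fdm, method = "spearman", use = "complete.obs"),
             0.95)
})

test_that("the region caller implements the top-X% rule deterministically", {
  set.seed(25)
  fdm_tbl <- tibble::tibble(chrom = "chr1", start = (0:999) * 1e4,
                            end = (1:1000) * 1e4, fdm = rnorm(1000))
  called <- call_regions(fdm_tbl, 0.03)
  expect_equal(sum(called$called), 30L)
  expect_equal(sum(call_regions(fdm_tbl, 0)$called), 0L)
  # called set is exactly the top-k by fdM
  expect_equal(sort(fdm_tbl$fdm[called$called], decreasing = TRUE),
               sort(fdm_tbl$fdm, decreasing = TRUE)[1:30])
  expect_identical(called, call_regions(fdm_tbl, 0.03))
  # NA windows are never called and shrink the scored denominator
  fdm_tbl$fdm[1:500] <- NA
  expect_equal(sum(call_regions(fdm_tbl, 0.1)$called), 50L)
})

test_that("background excludes windows called in trios sharing a species", {
  wins <- tibble::tibble(chrom = "chr1", start = (0:9) * 100,
                         end = (1:10) * 100)
  calls <- tibble::tibble(
    chrom = "chr1", start = c(0, 100, 200), end = c(100, 200, 300),
    called = TRUE,
    p2 = c("A", "A", "C"), p3 = c("B", "D", "D")
  )
  bg <- introgression_background(calls, wins, c("A", "B"))
  expect_false(any(bg$background[1:2]))
  expect_true(bg$background[3])  # C-D call does not involve A or B
  expect_true(all(bg$background[4:10]))
})

test_that("f-branch localizes a single simulated pulse and respects its domain", {
  sim <- shared_admix_sim()
  gm <- sim_genotype_matrix(sim)
  fb <- f_branch(gm, sim$samples, sim$tree, "OUT", seed = 1)
  # no donor from inside a branch's own clade
  expect_false(any(fb$branch == fb$donor))
  # strongest signal: branch P2 receiving from donor P3
  top <- fb[which.max(fb$fb), ]
  expect_equal(top$branch, "P2")
  expect_equal(top$donor, "P3")
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  expect_equal(hypergeom_enrichment(5, 5, 5, 10)$p, 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(0, 5, 5, 10)$p, 1)
  # below expectation: p > 0.5
  expect_gt(hypergeom_enrichment(1, 10, 10, 20)$p, 0.5)
  set.seed(26)
  for (rep in 1:10) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_enrichment(k, n, K, N)$p,
                 oracle_hyper_p(k, n, K, N), tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment(1, 5, 11, 10), "exceed")
})
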