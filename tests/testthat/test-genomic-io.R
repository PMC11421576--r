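write_toy_vcf <- function(lines, path = withr::local_tempfile(
                            fileext = ".vcf", .local_envir = parent.frame())) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    lines
  ), path)
  path
}

test_that("VCF genotypes become dosages with missing kept distinct from zero", {
  p <- write_toy_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t0|0\t1|1",
    "chr1\t20\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t0/1\t0/0",
    "chr1\t30\t.\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|1\t0|0",
    "chr1\t40\t.\tT\tA\t.\tPASS\t.\tGT\t0|0\t0|0\t0|1",
    "chr1\t50\t.\tC\tG\t.\tPASS\t.\tGT\t1|0\t1|1\t0|0"
  ))
  gm <- read_vcf(p)
  expect_equal(dim(gm), c(3L, 5L))
  expect_equal(unname(gm$geno[, 1]), c(1L, 0L, 2L))
  expect_true(is.na(gm$geno["s1", 2]))
  expect_equal(unname(gm$geno["s2", 2]), 1L)
  # mixed phasing means no haplotype matrix
  expect_false(gm$phased)
  # a fully phased file gets haplotypes
  p2 <- write_toy_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1"
  ))
  gm2 <- read_vcf(p2)
  expect_true(gm2$phased)
  expect_equal(unname(gm2$hap[, 1]), c(0L, 1L))
  expect_error(read_vcf(p2, popmap = data.frame(sample = "sX",
                                                species = "A")),
               "sX")
})

test_that("site filter cascade removes and attributes records as specified", {
  # 8 records: 1 triallelic, 1 indel, 1 with missing rate 0.5,
  # 1 with het rate 0.6, 4 clean
  geno <- rbind(
    s1 = c(0L, 0L, NA, 1L, 0L, 1L, 0L, 2L),
    s2 = c(0L, 1L, NA, 1L, 0L, 0L, 1L, 2L),
    s3 = c(1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L),
    s4 = c(0L, 0L, NA, 1L, 1L, 0L, 0L, 1L),
    s5 = c(0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L),
    s6 = c(0L, 0L, NA, 0L, 0L, 0L, 1L, 0L)
  )
  gm <- toy_gm(geno,
               ref = c("A", "A", "A", "A", "ATT", "A", "C", "G"),
               alt = c("T", "T,G", "T", "T", "A", "G", "T", "A"))
  out <- apply_site_filters(gm, rules = c("multiallelic", "missing",
                                          "heterozygosity", "indel"))
  expect_equal(ncol(out$geno), 4L)
  rep <- filter_report(out)
  expect_equal(rep$removed[rep$rule == "multiallelic"], 1L)
  expect_equal(rep$removed[rep$rule == "indel"], 1L)
  expect_equal(rep$removed[rep$rule == "missing"], 1L)
  expect_equal(rep$removed[rep$rule == "heterozygosity"], 1L)
  # all-clean input passes through unchanged
  clean <- subset_ok <- apply_site_filters(out, rules = c("multiallelic",
                                                          "missing",
                                                          "heterozygosity",
                                                          "indel"))
  expect_equal(clean$geno, out$geno)
  # empty input gives empty output and zero counts
  empty <- toy_gm(matrix(integer(0), nrow = 2, ncol = 0,
                         dimnames = list(c("a", "b"), NULL)),
                  pos = integer(0), ref = character(0), alt = character(0))
  eout <- apply_site_filters(empty, rules = "indel")
  expect_equal(ncol(eout$geno), 0L)
  expect_true(all(filter_report(eout)$removed == 0L))
})

test_that("site filters are order-stable under site permutation", {
  set.seed(1)
  geno <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 4)
  rownames(geno) <- paste0("s", 1:4)
  gm <- toy_gm(geno, ref = sample(c("A", "AT"), 15, TRUE),
               alt = sample(c("T", "G,C"), 15, TRUE))
  out1 <- apply_site_filters(gm, rules = c("multiallelic", "missing",
                                           "heterozygosity", "indel"),
                             max_missing = 0.5)
  perm <- sample(15)
  gm_p <- subset_sites_for_test(gm, perm)
  out2 <- apply_site_filters(gm_p, rules = c("multiallelic", "missing",
                                             "heterozygosity", "indel"),
                             max_missing = 0.5)
  expect_setequal(paste(out1$sites$chrom, out1$sites$pos),
                  paste(out2$sites$chrom, out2$sites$pos))
})

test_that("depth rule needs DP and uses mean depth over non-missing genotypes", {
  geno <- rbind(s1 = c(0L, 0L), s2 = c(1L, 1L))
  gm <- toy_gm(geno)
  expect_error(apply_site_filters(gm, rules = "depth"), "DP")
  dp <- rbind(c(2, 200), c(3, 150))
  gm2 <- toy_gm(geno, dp = dp)
  out <- apply_site_filters(gm2, rules = "depth")
  expect_equal(ncol(out$geno), 0L)
  expect_equal(sum(filter_report(out)$removed), 2L)
})

test_that("genotype filters apply the read-support rules", {
  # hom-ref with DP=3 -> missing; het AD=(9,1) -> missing (minor reads 1);
  # het AD=(6,4) -> retained
  geno <- rbind(s1 = c(0L, 1L, 1L))
  gm <- toy_gm(geno,
               dp = rbind(c(3, 10, 10)),
               ad_ref = rbind(c(3, 9, 6)),
               ad_alt = rbind(c(0, 1, 4)))
  out <- apply_genotype_filters(gm)
  expect_true(is.na(out$geno[1, 1]))
  expect_true(is.na(out$geno[1, 2]))
  expect_equal(unname(out$geno[1, 3]), 1L)
  expect_error(apply_genotype_filters(toy_gm(geno)), "AD")
})

test_that("window grids tile contigs and flag terminal partials", {
  w <- make_windows(c(chr1 = 250000), 100000)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start[3], 200000)
  expect_equal(w$end[3], 250000)
  expect_true(w$partial[3])
  expect_equal(nrow(make_windows(c(chr1 = 100000), 100000)), 1L)
  expect_error(make_windows(c(chr1 = 1000), 0), "size")
})

test_that("gene density merges overlapping CDS and splits at boundaries", {
  wins <- make_windows(c(chr1 = 200000), 100000)
  # one 100 bp CDS fully inside the first window
  cds <- data.frame(chrom = "chr1", start = 11, end = 110)
  gd <- gene_density(cds, wins)
  expect_equal(gd$gene_density, c(100, 0))
  # CDS straddling the boundary contributes its overlap to each side
  cds2 <- data.frame(chrom = "chr1", start = 99951, end = 100050)
  gd2 <- gene_density(cds2, wins)
  expect_equal(gd2$gene_density, c(50, 50))
  # overlapping CDS on both strands counted once after merging
  cds3 <- data.frame(chrom = "chr1", start = c(101, 151), end = c(200, 250),
                     strand = c("+", "-"))
  gd3 <- gene_density(cds3, wins)
  expect_equal(gd3$gene_density[1], 150)
  # union-length invariant: window totals equal merged CDS length
  set.seed(2)
  starts <- sample(1:190000, 30)
  cds4 <- data.frame(chrom = "chr1", start = starts,
                     end = pmin(starts + sample(50:5000, 30, TRUE), 200000))
  ir <- IRanges::reduce(IRanges::IRanges(cds4$start, cds4$end))
  expect_equal(sum(gene_density(cds4, wins)$gene_density),
               sum(IRanges::width(ir)))
})

test_that("degeneracy classification matches codon-table facts and the oracle", {
  # GGA: glycine; third position fourfold, second position zero-fold
  fa <- c(chr1 = "ATGGGATTTTAA")
  cds <- data.frame(chrom = "chr1", start = 1, end = 12)
  deg <- classify_degeneracy(cds, fa)
  expect_equal(deg$degeneracy[deg$pos == 6], "4-fold")  # GGA pos 3
  expect_equal(deg$degeneracy[deg$pos == 5], "0-fold")  # GGA pos 2
  expect_equal(deg$degeneracy[deg$pos == 3], "0-fold")  # ATG pos 3
  # brute-force enumeration oracle over a random 60-codon CDS
  set.seed(3)
  seq60 <- paste(sample(c("A", "C", "G", "T"), 180, TRUE), collapse = "")
  fa2 <- c(chr1 = seq60)
  deg2 <- classify_degeneracy(data.frame(chrom = "chr1", start = 1,
                                         end = 180), fa2)
  code <- Biostrings::GENETIC_CODE
  nucs <- strsplit(seq60, "")[[1]]
  for (p in sample(1:180, 30)) {
    ci <- (p - 1) %/% 3
    codon <- nucs[(3 * ci + 1):(3 * ci + 3)]
    within <- p - 3 * ci
    aa <- code[[paste(codon, collapse = "")]]
    syn <- 0
    for (b in setdiff(c("A", "C", "G", "T"), codon[within])) {
      alt <- codon; alt[within] <- b
      if (code[[paste(alt, collapse = "")]] == aa) syn <- syn + 1
    }
    want <- if (syn == 3) "4-fold" else if (syn == 0) "0-fold" else "2-fold"
    expect_equal(deg2$degeneracy[deg2$pos == p], want)
  }
  # minus-strand CDS is read in its own frame
  fa3 <- c(chr1 = "TTATCCCAT")  # reverse complement of ATGGGATAA
  deg3 <- classify_degeneracy(data.frame(chrom = "chr1", start = 1, end = 9,
                                         strand = "-"), fa3)
  expect_equal(deg3$degeneracy[deg3$pos == 4], "4-fold")  # GGA third base
})

test_that("cophenetic distances sum branch lengths along tip paths", {
  m <- cophenetic_matrix("((A:1,B:1):1,C:2);")
  expect_equal(m["A", "B"], 2)
  expect_equal(m["A", "C"], 4)
  expect_equal(m["A", "A"], 0)
  expect_true(isSymmetric(m))
  expect_error(cophenetic_matrix("((A,B),C);"), "branch lengths")
  m2 <- cophenetic_matrix("((A,B),C);", unit_lengths = TRUE)
  expect_equal(m2["A", "B"], 2)
})
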