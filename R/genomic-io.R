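#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (via vcfR), keeps site order, converts genotypes to
#' alt-allele dosages with missing genotypes encoded as `NA` (distinct from
#' dosage 0), and attaches a phased haplotype matrix when every genotype is
#' phased. Per-genotype `DP` and `AD` are extracted when present.
#'
#' @param path VCF file.
#' @param popmap optional tibble (`sample`, `species`); every mapped sample
#'   must be present in the VCF.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  sites <- tibble(
    chrom = unname(fix[, "CHROM"]), pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"])
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!is.null(popmap)) {
    popmap <- as_tibble(popmap)
    absent <- setdiff(popmap$sample, samples)
    if (length(absent)) {
      abort(paste0("popmap samples absent from VCF: ",
                   paste(absent, collapse = ", ")))
    }
  }
  phased_mat <- grepl("|", gt, fixed = TRUE)
  alleles <- gsub("|", "/", gt, fixed = TRUE)
  a1 <- sub("/.*", "", alleles)
  a2 <- sub(".*/", "", alleles)
  to_num <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out
  }
  d1 <- to_num(a1)
  d2 <- to_num(a2)
  # non-first alternate alleles (multiallelic records) carry no dosage here;
  # such sites are meant to be removed by the multiallelic site filter
  d1[d1 > 1L] <- NA_integer_
  d2[d2 > 1L] <- NA_integer_
  dosage <- d1 + d2
  dosage[is.na(gt)] <- NA_integer_
  geno <- matrix(dosage, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE,
                 dimnames = list(samples, NULL))
  all_phased <- all(phased_mat[!is.na(gt)])
  hap <- NULL
  if (all_phased && nrow(gt)) {
    h1 <- matrix(d1, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE)
    h2 <- matrix(d2, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE)
    hap <- matrix(NA_integer_, 2 * length(samples), nrow(gt))
    hap[seq(1, nrow(hap), 2), ] <- h1
    hap[seq(2, nrow(hap), 2), ] <- h2
    rownames(hap) <- as.vector(t(outer(samples, c("_h1", "_h2"), paste0)))
  }
  grab <- function(el, as_num = TRUE) {
    if (!el %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) return(NULL)
    m <- vcfR::extract.gt(v, element = el)
    mm <- matrix(m, nrow = ncol(m), ncol = nrow(m), byrow = TRUE,
                 dimnames = list(colnames(m), NULL))
    mm
  }
  dp <- grab("DP")
  if (!is.null(dp)) dp <- matrix(suppressWarnings(as.numeric(dp)),
                                 nrow = nrow(dp), dimnames = dimnames(dp))
  ad <- grab("AD")
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad)) {
    ad_ref <- matrix(suppressWarnings(as.numeric(sub(",.*", "", ad))),
                     nrow = nrow(ad), dimnames = dimnames(ad))
    ad_alt <- matrix(suppressWarnings(as.numeric(sub("^[^,]*,", "", ad))),
                     nrow = nrow(ad), dimnames = dimnames(ad))
  }
  genotype_matrix(geno, sites, samples, hap = hap, phased = all_phased,
                  dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
}

#' Site-level filter cascade
#'
#' Discards sites matching any of the following rules, applied in order
#' (a site removed by several rules is attributed to the first): (1) inside
#' a repeat mask; (2) more than two alleles; (3) site mean depth > `max_depth`
#' or < `min_depth` (mean of per-sample DP over non-missing genotypes);
#' (4) missing rate >= `max_missing`; (5) heterozygosity rate (proportion of
#' heterozygotes among non-missing genotypes) > `max_het`; (6) indels.
#' Rules are individually switchable via the `rules` argument.
#'
#' @param gm a [genotype_matrix()].
#' @param repeat_mask optional tibble (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param rules character subset of
#'   `c("repeat", "multiallelic", "depth", "missing", "heterozygosity", "indel")`.
#' @param min_depth,max_depth,max_missing,max_het rule thresholds.
#' @return filtered [genotype_matrix()] with a `filter_report` attribute
#'   (tibble of per-rule removal counts, retrievable via [filter_report()]).
#' @export
apply_site_filters <- function(gm, repeat_mask = NULL,
                               rules = c("repeat", "multiallelic", "depth",
                                         "missing", "heterozygosity", "indel"),
                               min_depth = 5, max_depth = 100,
                               max_missing = 0.3, max_het = 0.5) {
  rules <- match.arg(rules, several.ok = TRUE)
  m <- ncol(gm$geno)
  removed_by <- rep(NA_character_, m)
  flag <- function(idx, rule) {
    idx <- idx & is.na(removed_by)
    removed_by[idx] <<- rule
  }
  if ("repeat" %in% rules && !is.null(repeat_mask)) {
    rm_tbl <- as_tibble(repeat_mask)
    in_mask <- rep(FALSE, m)
    for (i in seq_len(nrow(rm_tbl))) {
      in_mask <- in_mask |
        (gm$sites$chrom == rm_tbl$chrom[i] &
           gm$sites$pos > rm_tbl$start[i] & gm$sites$pos <= rm_tbl$end[i])
    }
    flag(in_mask, "repeat")
  }
  if ("multiallelic" %in% rules) {
    flag(grepl(",", gm$sites$alt, fixed = TRUE), "multiallelic")
  }
  if ("depth" %in% rules) {
    if (is.null(gm$dp)) abort("depth rule requested but DP is absent")
    dpm <- gm$dp
    dpm[is.na(gm$geno)] <- NA
    mean_dp <- colMeans(dpm, na.rm = TRUE)
    flag(!is.na(mean_dp) & (mean_dp > max_depth | mean_dp < min_depth),
         "depth")
  }
  if ("missing" %in% rules) {
    miss <- colMeans(is.na(gm$geno))
    flag(miss >= max_missing, "missing")
  }
  if ("heterozygosity" %in% rules) {
    het <- colSums(gm$geno == 1, na.rm = TRUE) /
      pmax(colSums(!is.na(gm$geno)), 1)
    flag(het > max_het, "heterozygosity")
  }
  if ("indel" %in% rules) {
    is_indel <- nchar(gm$sites$ref) != 1L |
      (nchar(gm$sites$alt) != 1L & !grepl(",", gm$sites$alt, fixed = TRUE))
    flag(is_indel, "indel")
  }
  keep <- is.na(removed_by)
  report <- tibble(
    rule = c("repeat", "multiallelic", "depth", "missing",
             "heterozygosity", "indel"),
    removed = unname(vapply(
      c("repeat", "multiallelic", "depth", "missing", "heterozygosity",
        "indel"),
      function(r) sum(removed_by == r, na.rm = TRUE), integer(1)
    ))
  )
  out <- subset_sites(gm, keep)
  attr(out, "filter_report") <- report
  out
}

#' @rdname apply_site_filters
#' @export
filter_report <- function(gm) attr(gm, "filter_report")

#' Genotype-level filters
#'
#' Sets individual genotypes to missing unless they meet the read-support
#' rules: homozygous genotypes must be supported by at least `min_hom_reads`
#' reads; heterozygous genotypes need the minor allele supported by at least
#' `min_minor_reads` reads and a minor/major read ratio strictly between
#' `ratio_range[1]` and `ratio_range[2]`.
#'
#' @param gm a [genotype_matrix()] with `AD` (and `DP`) matrices.
#' @param min_hom_reads,min_minor_reads,ratio_range rule thresholds.
#' @return a [genotype_matrix()] with failing genotypes set to `NA`.
#' @export
apply_genotype_filters <- function(gm, min_hom_reads = 4,
                                   min_minor_reads = 2,
                                   ratio_range = c(0.1, 0.9)) {
  if (is.null(gm$ad_ref) || is.null(gm$ad_alt)) {
    abort("genotype filters need AD (allele depth)")
  }
  depth <- if (!is.null(gm$dp)) gm$dp else gm$ad_ref + gm$ad_alt
  geno <- gm$geno
  hom <- !is.na(geno) & geno != 1
  geno[hom & (is.na(depth) | depth < min_hom_reads)] <- NA_integer_
  het <- !is.na(geno) & geno == 1
  minor <- pmin(gm$ad_ref, gm$ad_alt)
  major <- pmax(gm$ad_ref, gm$ad_alt)
  ratio <- minor / major
  bad_het <- het & (is.na(minor) | minor < min_minor_reads |
                      !(ratio > ratio_range[1] & ratio < ratio_range[2]))
  geno[bad_het] <- NA_integer_
  out <- gm
  out$geno <- geno
  out
}

#' Partition contigs into non-overlapping windows
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param size window size in bp.
#' @return tibble (`chrom`, `start`, `end`, `partial`), 0-based half-open;
#'   the terminal window of each contig is kept and flagged when shorter
#'   than `size`.
#' @export
make_windows <- function(contig_lengths, size) {
  stopifnot_scalar_number(size, "size", lower = 1)
  purrr::map_dfr(names(contig_lengths), function(chr) {
    len <- contig_lengths[[chr]]
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    tibble(chrom = chr, start = starts, end = ends,
           partial = (ends - starts) < size)
  })
}

#' Gene density per window
#'
#' Gene density is the total length (bp) of coding sequence overlapping each
#' window; CDS intervals overlapping one another (e.g. isoforms, both
#' strands) are merged before summing, and a CDS straddling a window
#' boundary contributes only its overlap to each window.
#'
#' @param gff GFF3 path, or a data frame with columns `chrom`, `start`,
#'   `end` (1-based closed, GFF convention) for CDS features.
#' @param windows tibble from [make_windows()].
#' @return `windows` with a `gene_density` column (bp of merged CDS).
#' @export
gene_density <- function(gff, windows) {
  cds <- read_cds_table(gff)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cds$chrom, IRanges::IRanges(cds$start, cds$end)
  ))
  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1, windows$end)
  )
  hits <- GenomicRanges::findOverlaps(win_gr, gr)
  ov <- IRanges::pintersect(win_gr[S4Vectors::queryHits(hits)],
                            gr[S4Vectors::subjectHits(hits)])
  dens <- rep(0, nrow(windows))
  w <- S4Vectors::queryHits(hits)
  if (length(w)) {
    agg <- tapply(IRanges::width(ov), w, sum)
    dens[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- as_tibble(windows)
  out$gene_density <- dens
  out
}

# Accept a GFF3 file path or an in-memory CDS table.
read_cds_table <- function(gff) {
  if (is.data.frame(gff)) {
    tbl <- as_tibble(gff)
    if (!"strand" %in% names(tbl)) tbl$strand <- "+"
    if (!"phase" %in% names(tbl)) tbl$phase <- 0L
    if (!"parent" %in% names(tbl)) tbl$parent <- "cds1"
    return(tbl)
  }
  g <- rtracklayer::import(gff)
  cds <- g[g$type == "CDS"]
  parent <- if (!is.null(cds$Parent) && length(cds$Parent)) {
    vapply(as.list(cds$Parent), function(p) {
      if (length(p)) p[[1]] else NA_character_
    }, character(1))
  } else {
    rep(NA_character_, length(cds))
  }
  parent[is.na(parent)] <- paste0("cds_", seq_len(sum(is.na(parent))))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    phase = {
      ph <- cds$phase
      if (is.null(ph)) rep(0L, length(cds)) else {
        ph <- suppressWarnings(as.integer(as.character(ph)))
        ph[is.na(ph)] <- 0L
        ph
      }
    },
    parent = parent
  )
}

#' Classify coding-site degeneracy
#'
#' Labels every CDS position 0-fold, 2-fold or 4-fold degenerate by
#' enumerating the three possible substitutions at that codon position and
#' counting how many are synonymous under the standard genetic code
#' (4-fold: all synonymous; 0-fold: none; 2-fold otherwise). Positions
#' covered by overlapping transcripts with conflicting labels get the most
#' constrained (lowest) label. CDS whose phase-adjusted length is not a
#' multiple of three are skipped with a warning.
#'
#' @param gff GFF3 path or CDS table (see [gene_density()]); multi-exon
#'   transcripts are concatenated by their `parent` attribute.
#' @param fasta reference FASTA path or a named character vector of
#'   sequences.
#' @return tibble (`chrom`, `pos` 1-based, `degeneracy` in
#'   `c("0-fold", "2-fold", "4-fold")`).
#' @export
classify_degeneracy <- function(gff, fasta) {
  cds <- read_cds_table(gff)
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    names(x) <- sub("\\s.*", "", names(x))
    stats::setNames(as.character(x), names(x))
  } else {
    fasta
  }
  out <- list()
  for (tx in unique(cds$parent)) {
    part <- cds[cds$parent == tx, , drop = FALSE]
    strand <- part$strand[1]
    part <- part[order(part$start, decreasing = (strand == "-")), ,
                 drop = FALSE]
    chrom <- part$chrom[1]
    if (!chrom %in% names(seqs)) abort(paste("contig missing from FASTA:", chrom))
    genome_pos <- unlist(lapply(seq_len(nrow(part)), function(i) {
      p <- part$start[i]:part$end[i]
      if (strand == "-") rev(p) else p
    }))
    nucs <- strsplit(seqs[[chrom]], "")[[1]][genome_pos]
    if (strand == "-") nucs <- chartr("ACGTacgt", "TGCAtgca", nucs)
    phase <- part$phase[1]
    if (phase > 0) {
      genome_pos <- genome_pos[-seq_len(phase)]
      nucs <- nucs[-seq_len(phase)]
    }
    if (length(nucs) %% 3 != 0) {
      warn(paste("CDS length not a multiple of 3 after phase; skipping", tx))
      next
    }
    nucs <- toupper(nucs)
    deg <- codon_degeneracy_vector(nucs)
    out[[tx]] <- tibble(chrom = chrom, pos = genome_pos, degeneracy = deg)
  }
  res <- bind_rows(out)
  if (!nrow(res)) return(tibble(chrom = character(), pos = integer(),
                                degeneracy = character()))
  # most-constrained label on conflicts between overlapping transcripts
  res |>
    mutate(rank = match(.data$degeneracy, c("0-fold", "2-fold", "4-fold"))) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(degeneracy = c("0-fold", "2-fold", "4-fold")[min(.data$rank)],
              .groups = "drop")
}

# Degeneracy labels for an in-frame nucleotide vector (length divisible by 3).
codon_degeneracy_vector <- function(nucs) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  ncod <- length(nucs) / 3
  deg <- character(length(nucs))
  for (ci in seq_len(ncod)) {
    idx <- (3 * (ci - 1) + 1):(3 * ci)
    codon <- nucs[idx]
    if (any(!codon %in% bases)) {
      deg[idx] <- NA_character_
      next
    }
    aa <- code[[paste(codon, collapse = "")]]
    for (p in 1:3) {
      syn <- 0L
      for (bse in setdiff(bases, codon[p])) {
        alt <- codon
        alt[p] <- bse
        if (code[[paste(alt, collapse = "")]] == aa) syn <- syn + 1L
      }
      deg[idx[p]] <- if (syn == 3L) "4-fold" else if (syn == 0L) "0-fold" else "2-fold"
    }
  }
  deg
}

#' Cophenetic (tip-to-tip path length) distance matrix
#'
#' @param tree Newick string or `phylo` object.
#' @param unit_lengths replace missing branch lengths with 1 when `TRUE`.
#' @return symmetric matrix of path-length distances over tips.
#' @export
cophenetic_matrix <- function(tree, unit_lengths = FALSE) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy$edge.length)) {
    if (!unit_lengths) abort("tree has no branch lengths (set unit_lengths = TRUE)")
    phy$edge.length <- rep(1, nrow(phy$edge))
  }
  stats::cophenetic(phy)
}
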