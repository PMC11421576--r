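#' Configuration for the multispecies coalescent simulator
#'
#' Describes a simulated study system: a rooted, ultrametric species tree
#' (branch lengths in generations) including a designated outgroup tip, a
#' per-window recombination/gene-density landscape that modulates the local
#' mutation supply through a scaling factor
#' \eqn{\lambda_w = \exp(a \log \rho_w - b g_w)} (normalized to mean 1),
#' and optional one-pulse admixture events confined to a known subset of
#' windows. Every quantity here is a *condition* of the simulated study,
#' not a tuning dial: defaults emulate a small shrub/tree system with
#' diploid effective size 10,000 and per-window neutral diversity around
#' 0.005/site.
#'
#' @param tree Newick string for the rooted ultrametric species tree,
#'   branch lengths in generations, including the outgroup tip.
#' @param outgroup tip label used for polarization (one diploid is sampled).
#' @param ne diploid effective population size; either a single number used
#'   on every branch or a named vector keyed by tip/node label.
#' @param mu per-site per-generation mutation rate.
#' @param n_diploids diploid samples per ingroup species.
#' @param n_windows,window_len number and length (bp) of non-overlapping,
#'   non-recombining windows laid end-to-end on one contig.
#' @param landscape optional tibble with columns `rho` and `gene_density`
#'   (one row per window); simulated log-normal/uniform tracks by default.
#' @param scaling_coeffs numeric `c(a, b)` linking the landscape to
#'   \eqn{\lambda_w}.
#' @param admixture_events tibble with columns `donor`, `recipient`
#'   (tip labels), `time` (generations), `prop` (pulse proportion
#'   \eqn{\gamma \in [0,1]}), `window_frac` (fraction of windows affected).
#' @param deleterious_fraction fraction of polymorphic sites flagged as
#'   putatively deleterious nonsynonymous variants (they receive PROVEAN and
#'   SIFT scores that satisfy the deleterious rule); an equal fraction of
#'   tolerant nonsynonymous sites is flagged with scores that fail it, so a
#'   classifier is exercised on both sides of the thresholds.
#' @param fourfold_fraction fraction of sites flagged fourfold degenerate.
#' @param seed integer seed; identical configurations with identical seeds
#'   yield byte-identical outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree = "(((A:20000,B:20000):20000,C:40000):40000,OUT:80000);",
                       outgroup = "OUT",
                       ne = 10000,
                       mu = 1.25e-7,
                       n_diploids = 6,
                       n_windows = 200,
                       window_len = 10000,
                       landscape = NULL,
                       scaling_coeffs = c(a = 0.5, b = 0.5),
                       admixture_events = NULL,
                       deleterious_fraction = 0.02,
                       fourfold_fraction = 0.05,
                       seed = 1) {
  stopifnot_scalar_number(mu, "mu", lower = 0)
  stopifnot_scalar_number(n_diploids, "n_diploids", lower = 1)
  stopifnot_scalar_number(n_windows, "n_windows", lower = 1)
  stopifnot_scalar_number(window_len, "window_len", lower = 1)
  stopifnot_scalar_number(deleterious_fraction, "deleterious_fraction", 0, 0.5)
  stopifnot_scalar_number(fourfold_fraction, "fourfold_fraction", 0, 1)
  if (2 * deleterious_fraction + fourfold_fraction > 1) {
    abort("site-class fractions exceed 1")
  }
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) abort("`tree` is not parseable Newick")
  if (!outgroup %in% phy$tip.label) abort("outgroup tip absent from tree")
  if (!ape::is.binary(phy)) abort("species tree must be binary")
  if (any(ne <= 0)) abort("`ne` must be positive")
  nt <- node_times(phy)
  if (!is.null(admixture_events)) {
    admixture_events <- as_tibble(admixture_events)
    needed <- c("donor", "recipient", "time", "prop", "window_frac")
    if (!all(needed %in% names(admixture_events))) {
      abort("admixture_events needs donor, recipient, time, prop, window_frac")
    }
    for (i in seq_len(nrow(admixture_events))) {
      ev <- admixture_events[i, ]
      for (tipnm in c(ev$donor, ev$recipient)) {
        if (!tipnm %in% phy$tip.label) abort(paste("unknown tip", tipnm))
      }
      if (ev$donor == ev$recipient) abort("donor and recipient must differ")
      if (ev$prop < 0 || ev$prop > 1) abort("admixture prop must be in [0,1]")
      if (ev$window_frac < 0 || ev$window_frac > 1) {
        abort("window_frac must be in [0,1]")
      }
      lim <- min(parent_time(phy, nt, ev$donor),
                 parent_time(phy, nt, ev$recipient))
      if (ev$time <= 0 || ev$time >= lim) {
        abort("admixture time must be younger than both populations' merges")
      }
    }
  }
  if (!is.null(landscape)) {
    landscape <- as_tibble(landscape)
    if (nrow(landscape) != n_windows ||
        !all(c("rho", "gene_density") %in% names(landscape))) {
      abort("landscape needs n_windows rows with columns rho, gene_density")
    }
    if (any(landscape$rho <= 0)) abort("rho must be positive")
  }
  structure(
    list(tree = tree, phy = phy, outgroup = outgroup, ne = ne, mu = mu,
         n_diploids = as.integer(n_diploids),
         n_windows = as.integer(n_windows),
         window_len = as.integer(window_len),
         landscape = landscape, scaling_coeffs = scaling_coeffs,
         admixture_events = admixture_events,
         deleterious_fraction = deleterious_fraction,
         fourfold_fraction = fourfold_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Times (generations before present) of all nodes of an ultrametric tree.
node_times <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  tmax <- max(depth[seq_along(phy$tip.label)])
  tipd <- depth[seq_along(phy$tip.label)]
  if (max(tipd) - min(tipd) > 1e-6 * tmax) {
    abort("species tree must be ultrametric (equal root-to-tip path lengths)")
  }
  tmax - depth
}

parent_time <- function(phy, nt, tip) {
  i <- match(tip, phy$tip.label)
  nt[phy$edge[phy$edge[, 2] == i, 1]]
}

.ne_of <- function(ne, pop) {
  if (length(ne) == 1L && is.null(names(ne))) return(unname(ne))
  if (!is.null(names(ne)) && pop %in% names(ne)) return(unname(ne[pop]))
  if (!is.null(names(ne)) && "default" %in% names(ne)) {
    return(unname(ne["default"]))
  }
  unname(ne[1])
}

# One non-recombining genealogy under the structured coalescent with
# instantaneous population merges at species-tree split times and optional
# backward-in-time admixture pulses (lineage relabeling). Returns the set of
# branches as (descendant tip set, branch length).
sim_window_genealogy <- function(lineages, merges, adm, ne) {
  n0 <- sum(lengths(lineages))
  birth <- numeric(2 * n0)
  tipsets <- vector("list", 2 * n0)
  for (p in names(lineages)) {
    for (id in lineages[[p]]) {
      birth[id] <- 0
      tipsets[[id]] <- id
    }
  }
  next_id <- n0 + 1L
  branch_desc <- vector("list", 2 * (n0 - 1L))
  branch_len <- numeric(2 * (n0 - 1L))
  nb <- 0L
  fixed <- rbind(
    if (nrow(merges)) cbind(merges, type = "merge") else NULL,
    if (nrow(adm)) {
      tibble(time = adm$time, pop1 = adm$recipient, pop2 = adm$donor,
             newpop = NA_character_, prop = adm$prop, type = "adm")
    } else NULL
  )
  if (!is.null(fixed) && !"prop" %in% names(fixed)) fixed$prop <- NA_real_
  if (!is.null(fixed)) fixed <- fixed[order(fixed$time), , drop = FALSE]
  fi <- 1L
  t <- 0
  repeat {
    k <- lengths(lineages)
    rates <- k * (k - 1) / 2 / (2 * vapply(names(lineages), .ne_of, 1, ne = ne))
    total <- sum(rates)
    t_fixed <- if (!is.null(fixed) && fi <= nrow(fixed)) fixed$time[fi] else Inf
    t_coal <- if (total > 0) t + rexp(1L, total) else Inf
    if (t_coal < t_fixed) {
      pop <- names(lineages)[sample.int(length(lineages), 1L, prob = rates)]
      ids <- lineages[[pop]]
      pick <- ids[sample.int(length(ids), 2L)]
      for (id in pick) {
        nb <- nb + 1L
        branch_desc[[nb]] <- tipsets[[id]]
        branch_len[nb] <- t_coal - birth[id]
      }
      newid <- next_id
      next_id <- next_id + 1L
      if (newid > length(birth)) {
        birth <- c(birth, numeric(n0))
        tipsets <- c(tipsets, vector("list", n0))
      }
      birth[newid] <- t_coal
      tipsets[[newid]] <- c(tipsets[[pick[1]]], tipsets[[pick[2]]])
      lineages[[pop]] <- c(setdiff(ids, pick), newid)
      t <- t_coal
    } else if (is.finite(t_fixed)) {
      t <- t_fixed
      ev <- fixed[fi, ]
      if (ev$type == "merge") {
        merged <- c(lineages[[ev$pop1]], lineages[[ev$pop2]])
        lineages[[ev$pop1]] <- NULL
        lineages[[ev$pop2]] <- NULL
        lineages[[ev$newpop]] <- merged
      } else {
        rec <- lineages[[ev$pop1]]
        if (length(rec)) {
          move <- runif(length(rec)) < ev$prop
          if (any(move)) {
            lineages[[ev$pop2]] <- c(lineages[[ev$pop2]], rec[move])
            lineages[[ev$pop1]] <- rec[!move]
          }
        }
      }
      fi <- fi + 1L
    } else {
      abort("coalescent stalled: no rates and no pending events")
    }
    if (sum(lengths(lineages)) == 1L &&
        (is.null(fixed) || fi > nrow(fixed))) {
      break
    }
  }
  list(desc = branch_desc[seq_len(nb)], len = branch_len[seq_len(nb)])
}

#' Simulate a multispecies dataset with ground truth
#'
#' Draws one independent coalescent genealogy per window under the species
#' tree (merging lineages at split times, coalescence rate
#' \eqn{\binom{k}{2} / 2N_e} within branches), realizes admixture pulses by
#' moving each recipient-species lineage to the donor population at the
#' event time with probability \eqn{\gamma} (only in the event's designated
#' windows), and drops mutations on branches as a Poisson process with rate
#' \eqn{\mu \lambda_w L} under the infinite-sites model with uniform
#' positions. Haplotypes are phased and polarized by the simulated ancestral
#' state; REF/ALT labels in the exported view are randomized so that
#' outgroup-based polarization is exercised downstream.
#'
#' Site classes (deleterious/tolerant nonsynonymous with synthetic PROVEAN
#' and SIFT scores, fourfold degenerate) are assigned by independent draws
#' over polymorphic sites. The same seed always reproduces byte-identical
#' output; per-window substreams are derived deterministically so changing
#' the window count does not shift earlier windows.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset` with elements `hap` (haplotype x
#'   site 0/1 matrix, 1 = derived), `sites`, `samples`, `windows`, `tree`,
#'   `truth` and `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  phy <- config$phy
  nt <- node_times(phy)
  ntip <- length(phy$tip.label)
  # populations keyed by node label: tips by name, internal nodes by "node<i>"
  popname <- c(phy$tip.label, paste0("node", ntip + seq_len(phy$Nnode)))
  internal <- ntip + seq_len(phy$Nnode)
  merges <- tibble(
    time = nt[internal],
    pop1 = popname[phy$edge[match(internal, phy$edge[, 1]), 2]],
    pop2 = vapply(internal, function(v) {
      popname[phy$edge[phy$edge[, 1] == v, 2][2]]
    }, character(1)),
    newpop = popname[internal],
    prop = NA_real_
  )
  merges <- merges[order(merges$time), ]

  samples <- purrr::map_dfr(phy$tip.label, function(sp) {
    nd <- if (sp == config$outgroup) 1L else config$n_diploids
    tibble(sample = paste0(sp, "_", seq_len(nd)), species = sp)
  })
  hap_names <- as.vector(t(outer(samples$sample, c("_h1", "_h2"), paste0)))
  n_hap <- length(hap_names)
  hap_species <- rep(samples$species, each = 2)
  lineages0 <- split(seq_len(n_hap), hap_species)[unique(hap_species)]
  lineages0 <- lineages0[phy$tip.label[phy$tip.label %in% names(lineages0)]]

  nw <- config$n_windows
  L <- config$window_len

  # global stage: landscape, event window sets
  set.seed(window_seed(config$seed, 0L))
  landscape <- config$landscape
  if (is.null(landscape)) {
    landscape <- tibble(
      rho = exp(rnorm(nw, 0, 0.6)),
      gene_density = runif(nw, 0, 1)
    )
  }
  a <- config$scaling_coeffs[[1]]
  b <- config$scaling_coeffs[[2]]
  lambda <- exp(a * log(landscape$rho) - b * landscape$gene_density)
  lambda <- lambda / mean(lambda)

  adm <- config$admixture_events
  admixed_windows <- list()
  win_events <- vector("list", nw)
  if (!is.null(adm) && nrow(adm)) {
    for (i in seq_len(nrow(adm))) {
      kw <- round(adm$window_frac[i] * nw)
      wins <- if (kw > 0 && adm$prop[i] > 0) sort(sample.int(nw, kw)) else integer(0)
      admixed_windows[[i]] <- wins
      for (w in wins) win_events[[w]] <- c(win_events[[w]], i)
    }
  }

  # per-window genealogies and mutations
  site_pos <- vector("list", nw)
  site_carriers <- vector("list", nw)
  for (w in seq_len(nw)) {
    set.seed(window_seed(config$seed, w))
    adm_w <- if (length(win_events[[w]])) {
      adm[win_events[[w]], , drop = FALSE]
    } else {
      tibble(donor = character(), recipient = character(),
             time = numeric(), prop = numeric(), window_frac = numeric())
    }
    gen <- sim_window_genealogy(lineages0, merges, adm_w, config$ne)
    nmut <- rpois(length(gen$len), config$mu * lambda[w] * L * gen$len)
    m <- sum(nmut)
    if (m > L) abort("more mutations than positions in a window; increase window_len")
    if (m > 0) {
      offs <- sort(sample.int(L, m))
      carriers <- rep(seq_along(nmut), nmut)
      # shuffle which branch gets which position (positions exchangeable)
      carriers <- carriers[sample.int(m)]
      site_pos[[w]] <- (w - 1L) * L + offs
      site_carriers[[w]] <- lapply(carriers, function(i) gen$desc[[i]])
    } else {
      site_pos[[w]] <- integer(0)
      site_carriers[[w]] <- list()
    }
  }

  m_total <- sum(lengths(site_pos))
  hap <- matrix(0L, n_hap, m_total, dimnames = list(hap_names, NULL))
  col <- 0L
  win_of_site <- integer(m_total)
  for (w in seq_len(nw)) {
    for (j in seq_along(site_pos[[w]])) {
      col <- col + 1L
      hap[site_carriers[[w]][[j]], col] <- 1L
      win_of_site[col] <- w
    }
  }
  pos <- unlist(site_pos)

  # final stage: REF/ALT randomization and site-class annotation
  set.seed(window_seed(config$seed, nw + 1L))
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, m_total, replace = TRUE)
  der_base <- vapply(anc_base, function(bse) sample(setdiff(bases, bse), 1L),
                     character(1))
  anc_is_ref <- runif(m_total) < 0.5
  pf <- config$fourfold_fraction
  pd <- config$deleterious_fraction
  u <- runif(m_total)
  class <- rep("none", m_total)
  class[u < pd] <- "deleterious"
  class[u >= pd & u < 2 * pd] <- "tolerant"
  class[u >= 2 * pd & u < 2 * pd + pf] <- "fourfold"
  provean <- rep(NA_real_, m_total)
  sift <- rep(NA_real_, m_total)
  idx_d <- which(class == "deleterious")
  provean[idx_d] <- runif(length(idx_d), -5, -2.5)
  sift[idx_d] <- runif(length(idx_d), 0.05, 0.2)
  idx_t <- which(class == "tolerant")
  if (length(idx_t)) {
    fail_provean <- runif(length(idx_t)) < 0.5
    provean[idx_t] <- ifelse(fail_provean,
                             runif(length(idx_t), -2.4, 0),
                             runif(length(idx_t), -5, -2.5))
    sift[idx_t] <- ifelse(fail_provean,
                          runif(length(idx_t), 0.05, 0.2),
                          runif(length(idx_t), 0, 0.045))
  }

  sites <- tibble(
    chrom = "chr1", pos = pos, window = win_of_site,
    ref = ifelse(anc_is_ref, anc_base, der_base),
    alt = ifelse(anc_is_ref, der_base, anc_base),
    anc_is_ref = anc_is_ref,
    class = class, provean = provean, sift = sift
  )
  windows <- tibble(
    chrom = "chr1",
    start = (seq_len(nw) - 1L) * L,
    end = seq_len(nw) * L
  )
  truth <- structure(
    list(admixed_windows = admixed_windows,
         lambda = lambda,
         deleterious_sites = which(class == "deleterious"),
         fourfold_sites = which(class == "fourfold"),
         ancestral_is_ref = anc_is_ref),
    class = "sim_truth"
  )
  structure(
    list(hap = hap, sites = sites, samples = samples, windows = windows,
         tree = config$tree, landscape = landscape, truth = truth,
         config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d haplotypes x %d sites, %d windows x %d bp\n",
              nrow(x$hap), ncol(x$hap), nrow(x$windows),
              x$config$window_len))
  invisible(x)
}

#' Convert a simulated dataset to a genotype matrix
#'
#' Produces the same alt-dosage view a reader would obtain from the written
#' VCF (REF/ALT labels randomized at simulation time), with phased
#' haplotypes attached.
#'
#' @param sim a [simulate_dataset()] result.
#' @return a [genotype_matrix()].
#' @export
sim_genotype_matrix <- function(sim) {
  code <- sim$hap
  flip <- !sim$sites$anc_is_ref
  if (any(flip)) code[, flip] <- 1L - code[, flip]
  odd <- seq(1, nrow(code), by = 2)
  geno <- code[odd, , drop = FALSE] + code[odd + 1, , drop = FALSE]
  genotype_matrix(
    geno = geno,
    sites = sim$sites[c("chrom", "pos", "ref", "alt")],
    samples = sim$samples$sample,
    hap = code, phased = TRUE
  )
}

#' Write simulator outputs to disk
#'
#' Writes a VCFv4.2 with phased genotypes, a sample-to-species population
#' map (TSV), the species tree (Newick), the window grid (BED, 0-based
#' half-open), a per-site annotation table (PROVEAN/SIFT scores, degeneracy
#' class, ancestral allele) and the ground-truth tables.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return tibble manifest of written files.
#' @export
write_sim_outputs <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste("cannot create output directory", dir))
  }
  paths <- c(
    vcf = file.path(dir, "sim.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    tree = file.path(dir, "tree.nwk"),
    windows = file.path(dir, "windows.bed"),
    annotations = file.path(dir, "annotations.tsv"),
    truth_windows = file.path(dir, "truth_windows.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv")
  )
  gm <- sim_genotype_matrix(sim)
  write_vcf(gm, paths["vcf"],
            contig_lengths = c(chr1 = nrow(sim$windows) * sim$config$window_len))
  writeLines(c("sample\tspecies",
               paste(sim$samples$sample, sim$samples$species, sep = "\t")),
             paths["popmap"])
  writeLines(sim$tree, paths["tree"])
  writeLines(paste(sim$windows$chrom, sim$windows$start, sim$windows$end,
                   sep = "\t"),
             paths["windows"])
  ann <- sim$sites
  ann$ancestral <- ifelse(ann$anc_is_ref, ann$ref, ann$alt)
  utils::write.table(
    ann[c("chrom", "pos", "ref", "alt", "ancestral", "class",
          "provean", "sift")],
    paths["annotations"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  events <- sim$truth$admixed_windows
  tw <- tibble(
    window = seq_len(nrow(sim$windows)),
    lambda = sim$truth$lambda,
    admixed = seq_len(nrow(sim$windows)) %in% unlist(events)
  )
  utils::write.table(tw, paths["truth_windows"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ts <- tibble(
    site = seq_len(nrow(sim$sites)),
    pos = sim$sites$pos,
    deleterious = seq_len(nrow(sim$sites)) %in% sim$truth$deleterious_sites,
    fourfold = seq_len(nrow(sim$sites)) %in% sim$truth$fourfold_sites
  )
  utils::write.table(ts, paths["truth_sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tibble(name = names(paths), path = unname(paths))
}

#' Write a genotype matrix as VCFv4.2
#'
#' @param gm a [genotype_matrix()]; phased haplotypes are written as `a|b`,
#'   unphased dosages as `a/b`.
#' @param path output file.
#' @param contig_lengths optional named vector for `##contig` headers.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  n_s <- length(gm$samples)
  m <- ncol(gm$geno)
  if (gm$phased && !is.null(gm$hap)) {
    a1 <- gm$hap[seq(1, 2 * n_s, by = 2), , drop = FALSE]
    a2 <- gm$hap[seq(2, 2 * n_s, by = 2), , drop = FALSE]
    sep <- "|"
  } else {
    a1 <- pmax(gm$geno - 1, 0)
    a2 <- pmin(gm$geno, 1)
    sep <- "/"
  }
  gt_cols <- lapply(seq_len(n_s), function(i) {
    g <- paste(a1[i, ], a2[i, ], sep = sep)
    g[is.na(gm$geno[i, ])] <- paste(".", ".", sep = sep)
    g
  })
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=landgen",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- do.call(paste, c(
    list(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
         ".", "PASS", ".", "GT"),
    gt_cols, list(sep = "\t")
  ))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
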