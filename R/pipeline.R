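#' Validate a pipeline configuration
#'
#' @param config list with elements `simulate` (arguments for
#'   [sim_config()]) or `inputs` (paths `vcf`, `popmap`, `tree`), plus
#'   optional `stats` (statistic names), `fdr`, `maf`, `min_snps`,
#'   `block_size`, `n_perm`, `seed`, `out_dir`. May also be a YAML file
#'   path.
#' @return the normalized config list (invisibly errors otherwise).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs needs the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("pi", "theta_w", "tajima_d", "fst", "dxy", "fdm", "h12", "nsl")
  defaults <- list(stats = known, fdr = 0.05, maf = 0.05, min_snps = 5,
                   block_size = NULL, n_perm = 200, seed = 1,
                   out_dir = tempfile("landgen_run_"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  bad <- setdiff(config$stats, known)
  if (length(bad)) {
    abort(paste0("unknown statistic name(s): ", paste(bad, collapse = ", "),
                 " (known: ", paste(known, collapse = ", "), ")"))
  }
  if (config$fdr <= 0 || config$fdr > 1) abort("fdr must be in (0, 1]")
  if (config$maf < 0 || config$maf >= 0.5) abort("maf must be in [0, 0.5)")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    abort("config needs either a `simulate` block or an `inputs` block")
  }
  config
}

#' Run the full comparative-landscape pipeline
#'
#' Orchestrates simulate (or load) -> stats -> introgression -> selection ->
#' landscape from one config, writing every table as TSV (with tool
#' version, config hash and seed in header comments) under
#' `config$out_dir`. Stages run in dependency order; identical config and
#' seed reproduce byte-identical tables.
#'
#' @inheritParams validate_pipeline_config
#' @return tibble manifest (`stage`, `name`, `path`, `n_rows`, `checksum`).
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  manifest <- list()
  emit <- function(stage, name, tbl) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    hdr <- c(sprintf("# landgen %s",
                     as.character(utils::packageVersion("landgen"))),
             sprintf("# config_hash %s", cfg_hash),
             sprintf("# seed %d", as.integer(config$seed)))
    con <- file(path, "wb")
    writeLines(hdr, con)
    utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, name = name, path = path, n_rows = nrow(tbl),
      checksum = rlang::hash(tbl)
    )
    invisible(tbl)
  }

  # --- data stage -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    write_sim_outputs(sim, file.path(config$out_dir, "data"))
    gm <- sim_genotype_matrix(sim)
    popmap <- sim$samples
    tree <- sim$tree
    outgroup <- sim$config$outgroup
    windows <- sim$windows
    truth <- sim$truth
    sites_class <- sim$sites$class
  } else {
    gm <- read_vcf(config$inputs$vcf,
                   popmap = utils::read.table(config$inputs$popmap,
                                              header = TRUE, sep = "\t"))
    popmap <- as_tibble(utils::read.table(config$inputs$popmap,
                                          header = TRUE, sep = "\t"))
    tree <- paste(readLines(config$inputs$tree), collapse = "")
    outgroup <- config$inputs$outgroup
    win_size <- config$window_size %||% 100000
    lens <- tapply(gm$sites$pos, gm$sites$chrom, max)
    windows <- make_windows(stats::setNames(as.numeric(lens), names(lens)),
                            win_size)
    truth <- NULL
    sites_class <- NULL
  }
  ingroup <- setdiff(unique(popmap$species), outgroup)

  # --- window statistics ----------------------------------------------
  div <- window_diversity(gm, popmap, windows, species = ingroup,
                          min_snps = config$min_snps)
  emit("stats", "diversity", div)
  pairs <- utils::combn(ingroup, 2, simplify = FALSE)
  divg <- purrr::map_dfr(pairs, function(pr) {
    window_divergence(gm, popmap, pr, windows, min_snps = config$min_snps)
  })
  emit("stats", "divergence", divg)
  summ <- divergence_summary(div, divg)
  emit("stats", "divergence_summary", summ)

  # --- introgression ---------------------------------------------------
  af <- allele_freqs(gm, popmap, outgroup = outgroup)
  trios <- enumerate_trios(tree, outgroup)
  block_size <- config$block_size %||%
    max(diff(range(gm$sites$pos)) / 25, 1)
  dstats <- d_statistics(af, trios, block_size = block_size)
  f4 <- purrr::map_dfr(seq_len(nrow(trios)), function(i) {
    f4_ratio(gm, popmap, c(trios$p1[i], trios$p2[i], trios$p3[i]),
             outgroup, seed = config$seed)
  })
  dstats$f4_ratio <- f4$f4_ratio[match(paste(dstats$p1, dstats$p2, dstats$p3),
                                       paste(f4$p1, f4$p2, f4$p3))]
  emit("introgression", "trios", dstats)
  kept <- dedup_trios(dstats) |>
    filter(!is.na(.data$q), .data$q < config$fdr)
  calls <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    trio <- c(kept$p1[i], kept$p2[i], kept$p3[i])
    fdm <- window_fd_fdm(af, trio, windows, min_sites = config$min_snps)
    cl <- call_regions(fdm, kept$f4_ratio[i])
    cl$p1 <- trio[1]; cl$p2 <- trio[2]; cl$p3 <- trio[3]
    cl
  })
  if (nrow(calls)) emit("introgression", "fdm_calls", calls)

  # --- selection and burden -------------------------------------------
  if (any(c("h12", "nsl") %in% config$stats) && gm$phased) {
    scans <- purrr::map_dfr(ingroup, function(sp) {
      rows <- match(popmap$sample[popmap$species == sp], gm$samples)
      hap <- gm$hap[sort(c(2 * rows - 1, 2 * rows)), , drop = FALSE]
      sc <- selection_scan(hap, gm$sites, windows, maf_min = config$maf)
      sc$species <- sp
      sc
    })
    emit("selection", "scans", scans)
  }
  if (!is.null(sites_class)) {
    burden <- genetic_burden(gm, popmap, outgroup,
                             which(sites_class == "deleterious"),
                             which(sites_class == "fourfold"))
    emit("selection", "burden", burden)
  }

  # --- landscape -------------------------------------------------------
  pi_long <- div |>
    filter(!is.na(.data$pi)) |>
    mutate(window = paste(.data$chrom, .data$start)) |>
    select("window", unit = "species", value = "pi")
  n_per_unit <- table(pi_long$unit)
  if (length(unique(pi_long$unit)) >= 2 && min(n_per_unit) >= 3) {
    pca <- summarize_pca(pi_long)
    emit("landscape", "pca_pi_loadings",
         mutate(pca$loadings,
                var_explained_pc1 = pca$var_explained[1]))
    emit("landscape", "pca_pi_scores", pca$scores)
  }
  ac_input <- div |>
    filter(.data$species == ingroup[1]) |>
    select("chrom", value = "pi")
  ac <- autocorr_permutation(ac_input, n_perm = config$n_perm,
                             min_windows = min(50, nrow(windows)))
  emit("landscape", "autocorr_pi", ac)
  if (length(ingroup) >= 4) {
    contrasts <- build_contrasts(tree, outgroup)
    emit("landscape", "contrasts", contrasts)
  }
  bind_rows(manifest)
}
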