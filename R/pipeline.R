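#' Run the end-to-end analysis on simulated data
#'
#' Orchestrates the desk-scale pipeline: simulate an annotated genome and
#' polymorphism, generate genotype calls, apply the genotype and site
#' filters, haploidize, annotate SNPs by degeneracy and genomic category,
#' compute per-window diversity statistics, and summarise diversity per
#' group and site class. Every stage draws its seed from the master seed,
#' so identical configurations give identical outputs.
#'
#' @param config List with elements `seed` (mandatory), and optionally
#'   `genome` (args for [simulate_genome_annotation()]), `sim` (args for
#'   [sim_config()]), `filter` (args for [filter_sites()]), `stats`
#'   (args: `window_size`, `n_target_frac`), `classes` (site classes for
#'   the report, default `c("0fold", "4fold", "all")`).
#' @return List: `genome`, `sim`, `geno` (filtered calls), `hap`
#'   (haploidized matrix), `site_class` (per-SNP annotation tibble),
#'   `windows` (window stats per group), `report` (tibble, one row per
#'   group x site class), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- config$seed
  genome_args <- config$genome %||% list(length_bp = 2e5)
  genome <- do.call(simulate_genome_annotation,
                    c(genome_args, list(seed = child_seed(seed, "genome"))))
  sim_args <- config$sim %||% list()
  sim_args$L_bp <- genome$chrom_len
  sim_args$seed <- child_seed(seed, "sim")
  if (is.null(sim_args$n_individuals))
    sim_args$n_individuals <- c(COL = 20L, UTA = 16L)
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_coalescent(cfg)
  sim$sites$chrom <- names(genome$fasta)[1]
  calls <- sim_genotype_calls(sim)
  calls <- mask_genotypes(calls)
  calls <- do.call(filter_sites, c(list(calls), config$filter %||% list()))
  hap <- haploidize(calls, seed = child_seed(seed, "haploidize"))
  # ancestral state is known in simulation: allele 1 is derived
  kept <- match(paste(calls$sites$chrom, calls$sites$pos),
                paste(sim$sites$chrom, sim$sites$pos))
  deg <- classify_degeneracy(genome$fasta,
                             genome$features[genome$features$type == "CDS", ])
  site_class <- classify_category(calls$sites[, c("chrom", "pos")],
                                  genome$features)
  m <- match(paste(site_class$chrom, site_class$pos),
             paste(deg$sites$chrom, deg$sites$pos))
  site_class$degeneracy <- deg$sites$degeneracy[m]
  site_class$site_class <- dplyr::case_when(
    !is.na(site_class$degeneracy) & site_class$degeneracy == 0L ~ "0fold",
    !is.na(site_class$degeneracy) & site_class$degeneracy == 4L ~ "4fold",
    TRUE ~ site_class$category)
  groups <- unique(calls$samples$group)
  groups <- groups[!is.na(groups)]
  classes <- config$classes %||% c("0fold", "4fold", "all")
  stats_args <- config$stats %||% list()
  windows <- purrr::map_dfr(groups, function(g) {
    cols <- which(calls$samples$group == g)
    dplyr::mutate(window_stats(
      hap[, cols, drop = FALSE], calls$sites$chrom, calls$sites$pos,
      window_size = stats_args$window_size %||% 2e4,
      min_callable = stats_args$min_callable %||% 0),
      group = g, .before = 1)
  })
  report <- purrr::map_dfr(groups, function(g) {
    cols <- which(calls$samples$group == g)
    purrr::map_dfr(classes, function(cl) {
      rows <- if (cl == "all") seq_len(nrow(hap)) else
        which(site_class$site_class == cl)
      n_t <- max(2L, round((stats_args$n_target_frac %||% 0.8) *
                             length(cols)))
      if (length(rows) < 3) {
        return(tibble::tibble(group = g, site_class = cl,
                              n_snps = length(rows), n = n_t, L = NA_real_,
                              S = NA_real_, pi = NA_real_,
                              theta_w = NA_real_, theta_h = NA_real_,
                              tajima_d = NA_real_, fay_wu_h = NA_real_))
      }
      sp <- build_sfs(hap[rows, cols, drop = FALSE], n_target = n_t)
      dplyr::bind_cols(tibble::tibble(group = g, site_class = cl,
                                      n_snps = length(rows)),
                       diversity_stats(sp))
    })
  })
  list(genome = genome, sim = sim, geno = calls, hap = hap,
       site_class = site_class, windows = windows, report = report,
       config = config)
}

#' Pairwise Mann-Whitney comparisons of replicate sets
#'
#' Compares bootstrap-replicate distributions of an estimate between
#' groups or site classes with Mann-Whitney U tests and Bonferroni
#' adjustment.
#'
#' @param replicate_sets Named list of numeric vectors (one per group).
#' @return Tibble: `set_a`, `set_b`, `w`, `p`, `p_adjusted`, `n_tests`.
#' @export
compare_groups <- function(replicate_sets) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 2)
  if (any(lengths(replicate_sets) < 3))
    warning("fewer than 3 replicates in some set")
  nm <- names(replicate_sets) %||% paste0("set", seq_along(replicate_sets))
  pairs <- utils::combn(seq_along(replicate_sets), 2)
  n_tests <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(n_tests), function(k) {
    a <- replicate_sets[[pairs[1, k]]]
    b <- replicate_sets[[pairs[2, k]]]
    wt <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(set_a = nm[pairs[1, k]], set_b = nm[pairs[2, k]],
                   w = unname(wt$statistic), p = wt$p.value)
  })
  out$p_adjusted <- pmin(1, out$p * n_tests)
  out$n_tests <- n_tests
  out
}
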