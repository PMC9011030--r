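#' Weir-Cockerham variance components per site
#'
#' Computes the 1984 a (between-population), b (between individuals within
#' populations) and c (within-individual) variance components per biallelic
#' site from diploid genotypes of two or more groups.
#'
#' @param gt_list List of genotype matrices (sites x individuals, alternate
#'   allele dosage 0/1/2, `NA` missing), one per group; equal row counts.
#' @param min_call_frac Minimum fraction of individuals genotyped in every
#'   group for a site to enter the sums.
#' @return Tibble with one row per retained site: `site`, `a`, `b`, `c`.
#' @export
wc_components <- function(gt_list, min_call_frac = 0.5) {
  stopifnot(length(gt_list) >= 2)
  r <- length(gt_list)
  n_sites <- nrow(gt_list[[1]])
  n_i <- sapply(gt_list, function(g) rowSums(!is.na(g)))        # sites x r
  p_i <- sapply(gt_list, function(g) rowSums(g, na.rm = TRUE)) /
    (2 * pmax(n_i, 1))
  h_i <- sapply(gt_list, function(g) rowSums(g == 1L, na.rm = TRUE)) /
    pmax(n_i, 1)
  callable <- n_i >= sapply(gt_list, ncol)[col(n_i)] * min_call_frac
  ok <- rowSums(callable) == r & rowSums(n_i) > 0
  poly <- rowSums(p_i * n_i) > 0 & rowSums(p_i * n_i) < rowSums(n_i)
  keep <- ok & poly & apply(n_i >= 2, 1, all)
  if (!any(keep)) {
    return(tibble::tibble(site = integer(0), a = numeric(0), b = numeric(0),
                          c = numeric(0)))
  }
  n_i <- n_i[keep, , drop = FALSE]
  p_i <- p_i[keep, , drop = FALSE]
  h_i <- h_i[keep, , drop = FALSE]
  nbar <- rowSums(n_i) / r
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tibble::tibble(site = which(keep), a = a, b = b, c = cc)
}

#' Weighted FST and absolute divergence between two groups
#'
#' Weir & Cockerham's weighted (ratio-of-averages) FST,
#' `sum(a) / sum(a + b + c)` across sites, and `dxy`, the mean
#' between-group pairwise difference per callable site.
#'
#' @param gt_a,gt_b Diploid genotype matrices (sites x individuals, dosage
#'   0/1/2, `NA` missing) for the two groups; equal row counts.
#' @param min_call_frac Minimum genotyped fraction in both groups for a site
#'   to be callable.
#' @return One-row tibble: `fst`, `dxy`, `n_sites` (callable),
#'   `n_variant` (sites entering the FST sums).
#' @export
fst_dxy <- function(gt_a, gt_b, min_call_frac = 0.5) {
  stopifnot(nrow(gt_a) == nrow(gt_b))
  n_a <- rowSums(!is.na(gt_a)); n_b <- rowSums(!is.na(gt_b))
  callable <- n_a >= ncol(gt_a) * min_call_frac &
    n_b >= ncol(gt_b) * min_call_frac & n_a >= 1 & n_b >= 1
  if (!any(callable)) {
    return(tibble::tibble(fst = NA_real_, dxy = NA_real_, n_sites = 0L,
                          n_variant = 0L))
  }
  comp <- wc_components(list(gt_a, gt_b), min_call_frac = min_call_frac)
  fst <- if (nrow(comp) > 0 && sum(comp$a + comp$b + comp$c) > 0) {
    sum(comp$a) / sum(comp$a + comp$b + comp$c)
  } else NA_real_
  p_a <- rowSums(gt_a, na.rm = TRUE) / (2 * pmax(n_a, 1))
  p_b <- rowSums(gt_b, na.rm = TRUE) / (2 * pmax(n_b, 1))
  dxy <- sum((p_a * (1 - p_b) + p_b * (1 - p_a))[callable]) / sum(callable)
  tibble::tibble(fst = fst, dxy = dxy, n_sites = sum(callable),
                 n_variant = nrow(comp))
}

#' Relative node depth
#'
#' Normalizes absolute divergence between two groups by their mean
#' divergence to an outgroup, damping mutation-rate variation across
#' windows.
#'
#' @param dxy_ab Between-group divergence per site.
#' @param dx_out,dy_out Divergence of each group to the outgroup.
#' @return RND value, or `NA` when the outgroup divergence is zero.
#' @export
rnd <- function(dxy_ab, dx_out, dy_out) {
  denom <- (dx_out + dy_out) / 2
  ifelse(is.na(denom) | denom <= 0, NA_real_, dxy_ab / denom)
}

#' Long-term effective population size from synonymous diversity
#'
#' `Ne = theta / (4 mu g)` with `mu` the mutation rate per year and `g` the
#' generation time in years, i.e. `theta` over four times the per-generation
#' mutation rate.
#'
#' @param theta_syn Synonymous (4-fold) polymorphism per site.
#' @param mu_per_year Mutation rate per site per year (default 7e-9).
#' @param generation_years Generation time in years (default 2).
#' @param group Optional group label.
#' @return Tibble with `group`, `theta`, `mu_per_generation`, `ne`.
#' @export
#' @examples
#' ne_from_theta(2.8e-3)  # 5e4
ne_from_theta <- function(theta_syn, mu_per_year = 7e-9,
                          generation_years = 2, group = NA_character_) {
  stopifnot(all(theta_syn >= 0), mu_per_year > 0, generation_years > 0)
  mu_gen <- mu_per_year * generation_years
  tibble::tibble(group = group, theta = theta_syn,
                 mu_per_generation = mu_gen, ne = theta_syn / (4 * mu_gen))
}

#' Per-window diversity statistics
#'
#' Cuts each chromosome into fixed, 0-anchored, non-overlapping windows and
#' computes the spectrum-based diversity statistics per window from
#' haploidized data. Windows with fewer callable sites than `min_callable`
#' are masked (`NA` statistics).
#'
#' @param hap Haplotype matrix (sites x haplotypes, 0/1/`NA`).
#' @param chrom,pos Site coordinates (1-based positions), length `nrow(hap)`.
#' @param callable_sites Total callable sites per window for per-site scaling;
#'   if `NA`, the window size in bp is used.
#' @param window_size Window width in bp (default 20 kb).
#' @param n_target Projection size for the per-window spectra (default: 80%
#'   of the haplotype count, rounded).
#' @param min_callable Minimum callable bp for a window to be reported.
#' @param folded Use folded spectra (no Fay & Wu's H).
#' @return Tibble with one row per window: coordinates, `n_snps`, and the
#'   [diversity_stats()] columns.
#' @export
window_stats <- function(hap, chrom, pos, callable_sites = NA,
                         window_size = 2e4, n_target = NULL,
                         min_callable = 5e3, folded = FALSE) {
  stopifnot(length(chrom) == nrow(hap), length(pos) == nrow(hap))
  if (is.null(n_target)) n_target <- max(2L, round(0.8 * ncol(hap)))
  win <- floor((pos - 1) / window_size)
  idx <- split(seq_len(nrow(hap)), paste(chrom, win, sep = ":"))
  purrr::map_dfr(idx, function(ii) {
    w_chrom <- chrom[ii[1]]
    w_start <- win[ii[1]] * window_size
    callable <- if (is.na(callable_sites)) window_size else callable_sites
    base <- tibble::tibble(chrom = w_chrom, start = w_start,
                           end = w_start + window_size, n_snps = length(ii))
    if (callable < min_callable) {
      return(dplyr::bind_cols(base, diversity_stats(
        sfs_spectrum(rep(NA_real_, n_target - 1L), n_target, L = callable))))
    }
    sp <- tryCatch(
      build_sfs(hap[ii, , drop = FALSE], n_target = n_target,
                folded = folded),
      error = function(e) NULL)
    if (is.null(sp)) {
      return(dplyr::bind_cols(base, diversity_stats(
        sfs_spectrum(rep(0, n_target - 1L), n_target, L = callable))))
    }
    sp$L <- callable
    dplyr::bind_cols(base, diversity_stats(sp))
  })
}

#' Diversity versus gene density across windows
#'
#' Spearman rank correlation between window diversity and the genic fraction
#' of each window, on the full window set and on a strided subsample that
#' damps autocorrelation along the genome.
#'
#' @param windows Tibble with at least `chrom`, `start`, `end`, `pi`
#'   (e.g. from [window_stats()]).
#' @param genes Tibble of gene intervals (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param stride Keep every `stride`-th window (per chromosome, in order)
#'   for the subsampled estimate.
#' @return Tibble with rows `all` and `strided`: `rho`, `p_value`,
#'   `n_windows`.
#' @export
diversity_gene_density_correlation <- function(windows, genes, stride = 5L) {
  stopifnot(all(c("chrom", "start", "end", "pi") %in% names(windows)))
  genic_bp <- function(w_chrom, w_start, w_end) {
    g <- genes[genes$chrom == w_chrom, , drop = FALSE]
    if (nrow(g) == 0) return(0)
    ov <- pmin(g$end, w_end) - pmax(g$start - 1, w_start)
    sum(pmax(ov, 0))
  }
  windows <- windows[!is.na(windows$pi), , drop = FALSE]
  if (nrow(windows) < 10) {
    return(tibble::tibble(subset = c("all", "strided"), rho = NA_real_,
                          p_value = NA_real_, n_windows = c(nrow(windows), 0L)))
  }
  windows$gene_frac <- purrr::pmap_dbl(
    list(windows$chrom, windows$start, windows$end), genic_bp) /
    (windows$end - windows$start)
  run_cor <- function(df) {
    ct <- suppressWarnings(
      stats::cor.test(df$pi, df$gene_frac, method = "spearman"))
    tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                   n_windows = nrow(df))
  }
  strided <- windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::filter((dplyr::row_number() - 1L) %% stride == 0L) |>
    dplyr::ungroup()
  dplyr::bind_rows(
    dplyr::mutate(run_cor(windows), subset = "all", .before = 1),
    dplyr::mutate(run_cor(strided), subset = "strided", .before = 1)
  )
}
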