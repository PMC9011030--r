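#' Composite likelihood ratio scan for selective sweeps
#'
#' SweepFinder-style scan: at each grid position the likelihood of the
#' observed site frequencies under a sweep model (lineages escape the sweep
#' at rate `A` per bp of distance; non-escaped lineages collapse onto a
#' founder, star-like) is maximized over `A` on a log grid and compared
#' with the genome-wide background spectrum:
#' `CLR = 2 (ln CL1 - ln CL0)`.
#'
#' @param counts Derived (or minor, when `folded`) allele count per site,
#'   in `1..n-1`.
#' @param pos Site positions (bp), same length.
#' @param n Haploid sample size.
#' @param grid_spacing Grid step in bp (default 20 kb).
#' @param folded Treat counts and background as folded (default TRUE,
#'   avoiding ancestral-state errors); the folded background is
#'   symmetrized internally.
#' @param background Background spectrum (probabilities over classes); by
#'   default the empirical spectrum of all input sites.
#' @param a_grid Log grid of sweep-strength values (escape rate per bp).
#' @param callable_bp Optional callable bp per grid window; grids below
#'   `min_callable` are masked.
#' @param min_callable Minimum callable bp per 20-kb window (default 5 kb).
#' @return Tibble with one row per grid point: `grid_pos`, `clr`,
#'   `a_hat`, `n_sites`, `masked`.
#' @export
clr_scan <- function(counts, pos, n, grid_spacing = 2e4, folded = TRUE,
                     background = NULL,
                     a_grid = 10^seq(-6.5, -2, length.out = 14),
                     callable_bp = NULL, min_callable = 5e3) {
  stopifnot(length(counts) == length(pos), all(counts >= 1),
            all(counts <= n - 1))
  ord <- order(pos)
  pos <- pos[ord]; counts <- counts[ord]
  if (folded) counts <- pmin(counts, n - counts)
  if (is.null(background)) {
    k_max <- if (folded) n %/% 2L else n - 1L
    background <- tabulate(counts, k_max)
    background <- background / sum(background)
  }
  if (sum(background) == 0) stop("empty background spectrum")
  # unfolded background the sweep transform operates on
  p_bg <- if (folded) {
    half <- length(background)
    un <- numeric(n - 1L)
    for (i in seq_len(half)) {
      if (i == n - i) un[i] <- background[i]
      else { un[i] <- background[i] / 2; un[n - i] <- background[i] / 2 }
    }
    un
  } else background
  p_bg <- p_bg / sum(p_bg)
  # star-collapse kernel: P(K | e escapees), from the background projected
  # to the e+1 ancestral lineages with one founder amplified
  proj <- vector("list", n + 1L)
  for (m in 1:(n + 1L)) {
    q <- numeric(m + 1L)  # j = 0..m
    for (jn in 1:(n - 1L)) {
      mm <- min(m, n)
      q[1:(mm + 1L)] <- q[1:(mm + 1L)] +
        p_bg[jn] * dhyper(0:mm, jn, n - jn, mm)
    }
    proj[[m]] <- q
  }
  pk_given_e <- matrix(0, n + 1L, n + 1L)  # rows e = 0..n, cols K = 0..n
  for (e in 0:n) {
    m <- min(e + 1L, n)
    q <- proj[[m]]
    for (j in 0:m) {
      if (q[j + 1L] == 0) next
      k_founder <- if (e == n) j else j - 1L + (n - e)
      k_other <- j
      if (e == n) {
        pk_given_e[e + 1L, j + 1L] <- pk_given_e[e + 1L, j + 1L] + q[j + 1L]
      } else {
        pf <- j / m
        if (j >= 1)
          pk_given_e[e + 1L, k_founder + 1L] <-
            pk_given_e[e + 1L, k_founder + 1L] + q[j + 1L] * pf
        pk_given_e[e + 1L, k_other + 1L] <-
          pk_given_e[e + 1L, k_other + 1L] + q[j + 1L] * (1 - pf)
      }
    }
  }
  # table of P(K | p_e) on a fine escape-probability grid
  pe_grid <- seq(0, 1, length.out = 401)
  pk_table <- vapply(pe_grid, function(pe)
    as.numeric(dbinom(0:n, n, pe) %*% pk_given_e), numeric(n + 1L))
  if (folded) {
    fold_k <- function(v) {  # v over K = 0..n -> folded classes 1..n/2
      vapply(1:(n %/% 2L), function(i)
        if (i == n - i) v[i + 1L] else v[i + 1L] + v[n - i + 1L], numeric(1))
    }
    obs_tab <- apply(pk_table, 2, fold_k)
  } else {
    obs_tab <- pk_table[2:n, , drop = FALSE]
  }
  # condition on polymorphic
  obs_tab <- sweep(obs_tab, 2, pmax(colSums(obs_tab), 1e-300), "/")
  log_obs_tab <- log(pmax(obs_tab, 1e-300))
  bg_use <- if (folded) background else p_bg
  log_bg <- log(pmax(bg_use / sum(bg_use), 1e-300))
  grid_pos <- seq(floor(min(pos) / grid_spacing) * grid_spacing,
                  max(pos), by = grid_spacing)
  cl0_site <- log_bg[counts]
  out <- purrr::map_dfr(grid_pos, function(g) {
    d <- abs(pos - g)
    best <- -Inf; best_a <- NA_real_
    for (a in a_grid) {
      pe <- 1 - exp(-a * d)
      use <- pe < 1 - 1e-4
      if (!any(use)) { ll <- 0 }
      else {
        idx <- pmin(401L, 1L + as.integer(round(pe[use] * 400)))
        ll <- sum(log_obs_tab[cbind(counts[use], idx)] - cl0_site[use])
      }
      if (ll > best) { best <- ll; best_a <- a }
    }
    clr <- 2 * max(best, 0)  # A -> Inf limit gives CL1 = CL0
    tibble::tibble(grid_pos = g, clr = clr, a_hat = best_a,
                   n_sites = length(pos))
  })
  if (!is.null(callable_bp)) {
    stopifnot(length(callable_bp) == nrow(out))
    out$masked <- callable_bp < min_callable
    out$clr[out$masked] <- NA_real_
  } else {
    out$masked <- FALSE
  }
  out
}

# Extended haplotype homozygosity decay for one haplotype class from a
# focal SNP outward; returns the integrated EHH (trapezoid, truncated where
# EHH drops below `cutoff`).
.ihh_one_side <- function(hap, pos, focal_idx, members, step_idx, cutoff,
                          max_gap, max_extend) {
  n_h <- length(members)
  if (n_h < 2) return(NA_real_)
  pairs_tot <- n_h * (n_h - 1) / 2
  cls <- rep(1L, n_h)
  ehh_prev <- 1
  x_prev <- pos[focal_idx]
  ihh <- 0
  for (j in step_idx) {
    gap <- abs(pos[j] - x_prev)
    if (gap > max_gap) break
    if (abs(pos[j] - pos[focal_idx]) > max_extend) break
    key <- cls * 2L + hap[j, members]
    cls <- match(key, unique(key))
    tab <- tabulate(cls)
    ehh <- sum(tab * (tab - 1) / 2) / pairs_tot
    ihh <- ihh + (ehh_prev + ehh) / 2 * gap
    x_prev <- pos[j]
    if (ehh < cutoff) return(ihh)
    ehh_prev <- ehh
  }
  ihh  # hit the edge before decaying; caller decides whether to keep
}

#' Integrated haplotype score scan
#'
#' For each focal SNP with minor allele frequency above `maf`, integrates
#' the decay of extended haplotype homozygosity (EHH) away from the focal
#' SNP separately for carriers of the ancestral and derived alleles,
#' truncating where EHH < `cutoff`, at gaps > `max_gap` or at `max_extend`.
#' The unstandardized score `ln(iHH_A / iHH_D)` is standardized to zero
#' mean and unit variance within derived-allele-frequency bins.
#'
#' @param hap Haplotype matrix (sites x haplotypes, 0 ancestral / 1
#'   derived), polarized.
#' @param pos Site positions in bp.
#' @param maf Minor-allele-frequency threshold (default 0.05).
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap Maximum inter-SNP gap in bp (default 200 kb).
#' @param max_extend Maximum extension from the focal SNP (default 1 Mb).
#' @param bin_width Width of the DAF standardization bins (default 0.02).
#' @param min_bin Minimum SNPs per bin; sparse bins are merged outward.
#' @return Tibble with `pos`, `daf`, `ihh_a`, `ihh_d`, `ihs_raw`, `ihs`
#'   (standardized), `bin`.
#' @export
ihs_scan <- function(hap, pos, maf = 0.05, cutoff = 0.05, max_gap = 2e5,
                     max_extend = 1e6, bin_width = 0.02, min_bin = 300) {
  stopifnot(nrow(hap) == length(pos))
  ord <- order(pos)
  hap <- hap[ord, , drop = FALSE]; pos <- pos[ord]
  n_h <- ncol(hap)
  k_der <- rowSums(hap)
  daf <- k_der / n_h
  # integer-count MAF comparison so ancestral/derived relabeling keeps the
  # same SNP set exactly
  eligible <- which(pmin(k_der, n_h - k_der) > maf * n_h + 1e-9)
  res <- purrr::map_dfr(eligible, function(i) {
    anc <- which(hap[i, ] == 0L); der <- which(hap[i, ] == 1L)
    if (length(anc) < 2 || length(der) < 2) return(NULL)
    left <- if (i > 1) (i - 1):1 else integer(0)
    right <- if (i < nrow(hap)) (i + 1):nrow(hap) else integer(0)
    ihh_a <- sum(.ihh_one_side(hap, pos, i, anc, left, cutoff, max_gap,
                               max_extend),
                 .ihh_one_side(hap, pos, i, anc, right, cutoff, max_gap,
                               max_extend))
    ihh_d <- sum(.ihh_one_side(hap, pos, i, der, left, cutoff, max_gap,
                               max_extend),
                 .ihh_one_side(hap, pos, i, der, right, cutoff, max_gap,
                               max_extend))
    if (is.na(ihh_a) || is.na(ihh_d) || ihh_a <= 0 || ihh_d <= 0)
      return(NULL)
    tibble::tibble(pos = pos[i], daf = daf[i], ihh_a = ihh_a,
                   ihh_d = ihh_d, ihs_raw = log(ihh_a / ihh_d))
  })
  if (nrow(res) == 0) return(res)
  # frequency-bin standardization with outward merging of sparse bins
  edges <- seq(0, 1, by = bin_width)
  res$bin <- findInterval(res$daf, edges, rightmost.closed = TRUE)
  tab <- table(res$bin)
  merged <- as.integer(names(tab))
  remap <- stats::setNames(merged, merged)
  counts <- as.integer(tab)
  # merge sparse bins into their neighbor toward 0.5
  repeat {
    small <- which(counts < min_bin)
    if (length(small) == 0 || length(counts) == 1) break
    s <- small[1]
    target <- if (s == length(counts)) s - 1 else s + 1
    remap[remap == merged[s]] <- merged[target]
    counts[target] <- counts[target] + counts[s]
    counts <- counts[-s]; merged <- merged[-s]
  }
  res$bin <- remap[as.character(res$bin)]
  res <- res |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(ihs = (.data$ihs_raw - mean(.data$ihs_raw)) /
                    stats::sd(.data$ihs_raw)) |>
    dplyr::ungroup()
  res
}

#' Empirical p-values against a simulated null
#'
#' `p = (1 + #(null >= observed)) / (1 + M)`, the standard permutation-style
#' formula, with the null distribution taken from scans of fragments
#' simulated under the fitted neutral demography.
#'
#' @param observed Numeric vector of observed statistics.
#' @param null_values Numeric vector of the same statistic on simulated
#'   null data (same scan parameters).
#' @param two_sided Compare `|observed|` with `|null|` (for iHS).
#' @return Numeric vector of p-values.
#' @export
empirical_null <- function(observed, null_values, two_sided = FALSE) {
  if (length(null_values) == 0) stop("empty null distribution")
  if (two_sided) {
    observed <- abs(observed); null_values <- abs(null_values)
  }
  m <- length(null_values)
  srt <- sort(null_values)
  n_ge <- m - findInterval(observed, srt, left.open = TRUE)
  (1 + n_ge) / (1 + m)
}

#' Benjamini-Hochberg significance calls
#'
#' @param p P-values.
#' @param q FDR threshold (default 0.01).
#' @return Tibble with `p`, `q_value`, `significant`.
#' @export
fdr_call <- function(p, q = 0.01) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  qv <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q_value = qv, significant = !is.na(qv) & qv < q)
}

#' Candidate genes near significant signals
#'
#' A gene is a candidate when its minimum distance to any significant grid
#' interval or SNP is at most `max_dist` bp (overlap counts as distance 0).
#'
#' @param signals Tibble with `chrom` and either `pos` or `start`/`end`
#'   (1-based), already filtered to significant entries; an optional
#'   `group` column is carried through.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param max_dist Maximum distance in bp (default 10 kb).
#' @return Tibble: `gene_id`, `chrom`, `distance`, `group` (if present),
#'   one row per gene x supporting signal set (minimum distance).
#' @export
assign_candidates <- function(signals, genes, max_dist = 1e4) {
  if (nrow(signals) == 0) {
    return(tibble::tibble(gene_id = character(0), chrom = character(0),
                          distance = numeric(0)))
  }
  s_start <- if ("start" %in% names(signals)) signals$start else signals$pos
  s_end <- if ("end" %in% names(signals)) signals$end else signals$pos
  grp <- if ("group" %in% names(signals)) signals$group else
    rep(NA_character_, nrow(signals))
  purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    same <- signals$chrom == genes$chrom[gi]
    if (!any(same)) return(NULL)
    d <- pmax(0, pmax(genes$start[gi] - s_end[same],
                      s_start[same] - genes$end[gi]))
    hits <- which(d <= max_dist)
    if (length(hits) == 0) return(NULL)
    tibble::tibble(gene_id = genes$gene_id[gi], chrom = genes$chrom[gi],
                   distance = min(d), group = grp[same][hits[1]])
  })
}
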