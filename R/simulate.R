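#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults follow
#' the study design the package targets: four groups of a predominantly
#' selfing diploid (inbreeding coefficient F = 0.9) sampled at 78/63/52/39
#' individuals, per-site diversity around 2e-3, and a deleterious gamma DFE
#' at 0-fold sites.
#'
#' @param n_individuals Named integer vector of diploid individuals per
#'   group.
#' @param theta Haploid population-scaled mutation rate `4*N1*mu` per site.
#' @param rho_bp Recombination rate per bp per generation (physical map
#'   scale ~5 cM/Mb); haplotype structure between blocks is free, within
#'   blocks absent, and sweep escape uses `rho_bp * (1 - selfing)`.
#' @param selfing Selfing-derived inbreeding coefficient F in `[0, 1]`.
#' @param demography A [demography_model()] shared by all groups.
#' @param migration Scaled symmetric migration rate `4*N1*m` between groups
#'   (island model).
#' @param dfe List with `shape` and `mean` of the deleterious gamma DFE over
#'   `Ne*s` applied at 0-fold sites.
#' @param adaptive_fraction Probability that a nonsynonymous fixation is
#'   beneficial.
#' @param outgroup_divergence Expected substitutions per site on the
#'   outgroup lineage.
#' @param L_bp Fragment length in bp.
#' @param block_bp Length of the independently simulated genealogy blocks.
#' @param seed Mandatory master seed; per-stage child seeds are derived
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = c(COL = 78L, UTA = 63L, NOR = 52L,
                                         WES = 39L),
                       theta = 0.002, rho_bp = 5e-8, selfing = 0.9,
                       demography = demography_model(), migration = 1,
                       dfe = list(shape = 0.3, mean = 400),
                       adaptive_fraction = 0, outgroup_divergence = 0.02,
                       L_bp = 1e6, block_bp = 5e3, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(theta >= 0, rho_bp >= 0, selfing >= 0, selfing <= 1,
            migration >= 0, adaptive_fraction >= 0, adaptive_fraction <= 1,
            outgroup_divergence >= 0, L_bp > 0, block_bp > 0)
  if (is.null(names(n_individuals)))
    names(n_individuals) <- paste0("G", seq_along(n_individuals))
  structure(list(n_individuals = n_individuals, theta = theta,
                 rho_bp = rho_bp, selfing = selfing, demography = demography,
                 migration = migration, dfe = dfe,
                 adaptive_fraction = adaptive_fraction,
                 outgroup_divergence = outgroup_divergence,
                 L_bp = L_bp, block_bp = block_bp, seed = as.integer(seed)),
            class = "sim_config")
}

#' Deterministic per-stage child seed
#'
#' Derives a stage-specific seed from one master seed so that each
#' stochastic stage is reproducible in isolation; the result stays below
#' `2^31`.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (string).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  (seed * 48271 + sum(utf8ToInt(stage)) * 7919) %% 2147483629 + 1
}

# Epochs seen backwards from the present: deme-size multipliers and epoch
# end times in units of 2*N1 generations (last epoch extends to infinity).
.backward_epochs <- function(demography) {
  if (is.null(demography) || demography$epochs == 1L) {
    return(list(sizes = 1, ends = Inf))
  }
  sizes <- c(rev(demography$size_ratios), 1)
  durations <- rev(demography$times) / 2
  list(sizes = sizes, ends = c(cumsum(durations), Inf))
}

# One coalescent genealogy for n lineages (optionally structured over demes
# with symmetric migration) under piecewise-constant size. Returns branches
# as a list of (leaf index vector, length in 2*N1 generations).
.sim_tree <- function(n, epochs, deme = rep(1L, n), migration = 0) {
  n_demes <- max(deme)
  active_leaves <- as.list(seq_len(n))
  active_deme <- deme
  birth <- rep(0, n)
  branches_leaves <- vector("list", 2 * n)
  branches_len <- numeric(2 * n)
  nb <- 0L
  t_now <- 0
  ep <- 1L
  while (length(active_leaves) > 1L) {
    k_d <- tabulate(active_deme, n_demes)
    size <- epochs$sizes[ep]
    rate_coal <- sum(k_d * (k_d - 1) / 2) / size
    rate_mig <- if (n_demes > 1L) sum(k_d) * migration / 2 else 0
    rate <- rate_coal + rate_mig
    if (rate <= 0) {  # lineages isolated in different demes, no migration
      stop("coalescent cannot complete: isolated lineages without migration")
    }
    dt <- rexp(1, rate)
    if (t_now + dt > epochs$ends[ep]) {
      t_now <- epochs$ends[ep]
      ep <- ep + 1L
      next
    }
    t_now <- t_now + dt
    if (runif(1) < rate_mig / rate) {
      j <- sample.int(length(active_leaves), 1)
      active_deme[j] <- if (n_demes == 2L) 3L - active_deme[j] else
        sample(setdiff(seq_len(n_demes), active_deme[j]), 1)
    } else {
      w <- k_d * (k_d - 1) / 2
      d <- sample.int(n_demes, 1, prob = w)
      in_d <- which(active_deme == d)
      pair <- if (length(in_d) == 2L) in_d else sample(in_d, 2L)
      for (j in pair) {
        nb <- nb + 1L
        branches_leaves[[nb]] <- active_leaves[[j]]
        branches_len[nb] <- t_now - birth[j]
      }
      merged <- c(active_leaves[[pair[1]]], active_leaves[[pair[2]]])
      keep <- setdiff(seq_along(active_leaves), pair)
      active_leaves <- c(active_leaves[keep], list(merged))
      active_deme <- c(active_deme[keep], active_deme[pair[1]])
      birth <- c(birth[keep], t_now)
    }
  }
  list(leaves = branches_leaves[seq_len(nb)], len = branches_len[seq_len(nb)])
}

# Draws derived-allele classes of ~independent segregating sites: each
# genealogy is simulated afresh (level times + subtree sizes only) and
# carries a Poisson number of mutations with mean ~0.7, so inter-site
# genealogical correlation is negligible and counts are ~multinomial.
.sim_iid_site_classes <- function(n, epochs, n_snps) {
  counts <- numeric(n - 1L)
  got <- 0L
  mean_len <- NULL
  warm <- numeric(0)
  one_tree <- function() {
    # level times T_k (k = n..2) under piecewise-constant size
    tk <- numeric(n - 1L)
    sz_levels <- vector("list", n - 1L)
    sz <- rep(1L, n)
    t_now <- 0; ep <- 1L
    for (k in n:2) {
      idx <- n - k + 1L
      repeat {
        rate <- k * (k - 1) / 2 / epochs$sizes[ep]
        dt <- rexp(1, rate)
        if (t_now + dt > epochs$ends[ep]) {
          tk[idx] <- tk[idx] + epochs$ends[ep] - t_now
          t_now <- epochs$ends[ep]; ep <- ep + 1L
        } else {
          tk[idx] <- tk[idx] + dt; t_now <- t_now + dt; break
        }
      }
      sz_levels[[idx]] <- sz[seq_len(k)]
      pair <- sample.int(k, 2L)
      sz[pair[1]] <- sz[pair[1]] + sz[pair[2]]
      sz[pair[2]] <- sz[k]
    }
    list(tk = tk, sz = sz_levels)
  }
  while (got < n_snps) {
    tr <- one_tree()
    lvl_w <- (n:2) * tr$tk
    total <- sum(lvl_w)
    if (is.null(mean_len)) {  # calibrate the per-tree mutation rate
      warm <- c(warm, total)
      if (length(warm) >= 200) mean_len <- mean(warm)
      next
    }
    m <- rpois(1, 0.7 * total / mean_len)
    if (m == 0L) next
    for (u in seq_len(m)) {
      lvl <- sample.int(n - 1L, 1L, prob = lvl_w)
      cls <- tr$sz[[lvl]][sample.int(n - lvl + 1L, 1L)]
      if (cls < n) { counts[cls] <- counts[cls] + 1L; got <- got + 1L }
      if (got >= n_snps) break
    }
  }
  counts
}

# Poisson mutations on a genealogy; returns a list of derived-carrier index
# vectors, one per segregating mutation.
.drop_mutations <- function(tree, mu_total) {
  lens <- tree$len
  n_mut <- rpois(1, sum(lens) * mu_total)
  if (n_mut == 0L) return(list())
  br <- sample.int(length(lens), n_mut, replace = TRUE, prob = lens)
  tree$leaves[br]
}

#' Simulate polymorphism by block-wise coalescent genealogies
#'
#' Generates haplotypes and diploid genotypes for one genomic fragment.
#' Each `block_bp` block receives an independent (structured) coalescent
#' genealogy under the configured epoch demography, with Poisson mutations;
#' linkage is complete within a block and free between blocks, a
#' deliberately coarse haplotype model suited to a highly selfing species.
#' Selfing makes a fraction F of individuals fully autozygous (their two
#' haplotypes are the same sampled lineage).
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_output`: list with `haplotypes`
#'   (sites x haplotypes 0/1), `genotypes` (sites x individuals dosage),
#'   `sites` tibble (`chrom`, `pos`, `block`), `individuals` tibble
#'   (`id`, `group`, `autozygous`, `f`), `hap_of_ind` (two columns of
#'   haplotype indices per individual), and `config`.
#' @export
simulate_coalescent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "coalescent"))
  epochs <- .backward_epochs(config$demography)
  n_ind <- sum(config$n_individuals)
  groups <- rep(names(config$n_individuals), config$n_individuals)
  autozygous <- runif(n_ind) < config$selfing
  # one sampled lineage for an autozygous individual, two otherwise
  n_hap_ind <- ifelse(autozygous, 1L, 2L)
  hap_group <- rep(groups, n_hap_ind)
  n_hap <- length(hap_group)
  deme <- as.integer(factor(hap_group, levels = names(config$n_individuals)))
  n_blocks <- ceiling(config$L_bp / config$block_bp)
  mu_block <- config$theta / 2 * config$block_bp
  out_sites <- vector("list", n_blocks)
  out_alleles <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    tree <- .sim_tree(n_hap, epochs, deme,
                      if (length(config$n_individuals) > 1)
                        config$migration else 0)
    muts <- .drop_mutations(tree, mu_block)
    if (length(muts) == 0L) { out_sites[[b]] <- numeric(0); next }
    b_start <- (b - 1) * config$block_bp
    pos <- sort(sample.int(config$block_bp, length(muts),
                           replace = length(muts) > config$block_bp)) + b_start
    out_sites[[b]] <- pos
    out_alleles[[b]] <- muts
  }
  pos_all <- unlist(out_sites)
  carriers <- do.call(c, out_alleles[lengths(out_sites) > 0])
  n_snp <- length(pos_all)
  hap <- matrix(0L, n_snp, n_hap)
  for (s in seq_len(n_snp)) hap[s, carriers[[s]]] <- 1L
  # individual -> haplotype mapping (autozygous: same column twice)
  hap_idx <- cumsum(n_hap_ind)
  hap2 <- cbind(hap_idx - n_hap_ind + 1L, hap_idx)
  geno <- hap[, hap2[, 1], drop = FALSE] + hap[, hap2[, 2], drop = FALSE]
  structure(list(
    haplotypes = hap,
    genotypes = geno,
    sites = tibble::tibble(
      chrom = "sim1", pos = pos_all,
      block = rep(seq_len(n_blocks), lengths(out_sites))),
    individuals = tibble::tibble(
      id = sprintf("ind%03d", seq_len(n_ind)), group = groups,
      autozygous = autozygous, f = config$selfing),
    hap_group = hap_group,
    hap_of_ind = hap2,
    config = config), class = "sim_output")
}

#' Impose a completed hard sweep on simulated polymorphism
#'
#' Star-like genealogy approximation: each haplotype escapes the sweep at an
#' exponentially distributed recombination distance with rate
#' `r_eff * log(2N) / s` per bp on each side of the swept site
#' (`r_eff = rho_bp * (1 - F)`); within its swept span a haplotype carries
#' the founder haplotype's alleles. `s = 0` returns the input unchanged.
#'
#' @param sim A `sim_output` from [simulate_coalescent()].
#' @param position Sweep position in bp (inside the fragment).
#' @param s Selection coefficient of the swept allele.
#' @param two_n Effective haploid size entering `log(2N)`; default 1e5.
#' @param seed Seed for the escape draws (default: derived from the
#'   config's master seed).
#' @return A modified `sim_output`; monomorphized sites are dropped.
#' @export
inject_sweep <- function(sim, position, s, two_n = 1e5, seed = NULL) {
  stopifnot(inherits(sim, "sim_output"), s >= 0)
  if (position < 0 || position > sim$config$L_bp)
    stop("sweep position outside the simulated fragment")
  if (s == 0) return(sim)
  set.seed(if (is.null(seed)) child_seed(sim$config$seed, "sweep") else seed)
  n_hap <- ncol(sim$haplotypes)
  rate <- sim$config$rho_bp * (1 - sim$config$selfing) * log(two_n) / s
  if (rate > 0) {
    d_left <- rexp(n_hap, rate)
    d_right <- rexp(n_hap, rate)
  } else {  # no effective recombination: nothing escapes the sweep
    d_left <- rep(Inf, n_hap)
    d_right <- rep(Inf, n_hap)
  }
  founder <- sample.int(n_hap, 1)
  d_left[founder] <- Inf; d_right[founder] <- Inf
  pos <- sim$sites$pos
  hap <- sim$haplotypes
  for (j in seq_len(n_hap)) {
    swept <- (pos <= position & position - pos < d_left[j]) |
      (pos > position & pos - position < d_right[j])
    hap[swept, j] <- hap[swept, founder]
  }
  keep <- rowSums(hap) > 0 & rowSums(hap) < n_hap
  sim$haplotypes <- hap[keep, , drop = FALSE]
  sim$genotypes <- hap[keep, sim$hap_of_ind[, 1], drop = FALSE] +
    hap[keep, sim$hap_of_ind[, 2], drop = FALSE]
  sim$sites <- sim$sites[keep, , drop = FALSE]
  sim$sweep <- list(position = position, s = s, founder = founder)
  sim
}

#' Simulate site-frequency-spectrum counts directly
#'
#' Fast generators for SFS-level experiments. Neutral spectra are drawn by
#' block coalescent genealogies (an independent route from the
#' transition-matrix machinery used in fitting); selected spectra are drawn
#' from the Poisson-random-field expected spectra of [expected_sfs()] mixed
#' over a gamma DFE, with mutational weight allocated by each component's
#' segregating intensity.
#'
#' @param n_snps Target number of segregating sites in the spectrum.
#' @param n Haploid sample size.
#' @param demography A [demography_model()].
#' @param gamma_dfe `NULL` for neutral, else `list(shape=, mean=)` of the
#'   deleterious gamma over `Ne*s`.
#' @param seed Seed.
#' @param n_ref Reference size for the selected-site engine.
#' @param n_components Number of gamma draws approximating the DFE mixture.
#' @return An unfolded [sfs_spectrum()] with `L = NA`.
#' @export
simulate_sfs_counts <- function(n_snps, n, demography = NULL,
                                gamma_dfe = NULL, seed, n_ref = 100,
                                n_components = 64) {
  set.seed(seed)
  if (is.null(gamma_dfe)) {
    counts <- .sim_iid_site_classes(n, .backward_epochs(demography), n_snps)
    return(sfs_spectrum(counts, n, label = "neutral"))
  }
  gammas <- rgamma(n_components, shape = gamma_dfe$shape,
                   scale = gamma_dfe$mean / gamma_dfe$shape)
  spectra <- vapply(gammas, function(g)
    expected_sfs(n, gamma = g, demography = demography, n_ref = n_ref),
    numeric(n - 1L))
  w <- colSums(spectra)
  if (sum(w) == 0) stop("DFE so strong that no site segregates")
  n_per <- as.integer(rmultinom(1, n_snps, w / sum(w)))
  counts <- numeric(n - 1L)
  for (m in seq_along(gammas)) {
    if (n_per[m] == 0) next
    counts <- counts + rmultinom(1, n_per[m], spectra[, m])[, 1]
  }
  sfs_spectrum(counts, n, label = "selected")
}

#' Simulate paired neutral and selected spectra for DFE inference
#'
#' Generates the two-class dataset a DFE fit consumes: a neutral spectrum
#' drawn by independent coalescent genealogies, and a selected spectrum
#' drawn from Poisson-random-field expected spectra mixed over a gamma DFE,
#' with absolute selected-class rates tied to the neutral SNP yield per site
#' (equal mutation rate per site in both classes, mutational target ratio
#' `l_ratio`).
#'
#' @param n_neutral_snps Segregating sites in the neutral spectrum.
#' @param n Haploid sample size.
#' @param demography A [demography_model()].
#' @param dfe List with `shape` and `mean` of the gamma over `Ne*s`.
#' @param l_ratio Mutational target ratio (selected sites / neutral sites),
#'   default 2.5 (roughly the 0-fold : 4-fold site ratio of a plant genome).
#' @param seed Seed.
#' @param n_ref Reference Wright-Fisher size.
#' @param n_components Gamma draws approximating the DFE mixture.
#' @return List with `neutral` and `selected` [sfs_spectrum()]s (both with
#'   `L` set) and `truth` (the generating parameters).
#' @export
simulate_dfe_dataset <- function(n_neutral_snps, n, demography = NULL,
                                 dfe = list(shape = 0.3, mean = 400),
                                 l_ratio = 2.5, seed, n_ref = 100,
                                 n_components = 64) {
  set.seed(seed)
  neutral <- simulate_sfs_counts(n_neutral_snps, n, demography,
                                 seed = seed + 1L)
  l_neu <- 1e6  # nominal; only the ratio of targets matters
  neutral$L <- l_neu
  gammas <- rgamma(n_components, shape = dfe$shape,
                   scale = dfe$mean / dfe$shape)
  spectra <- vapply(gammas, function(g)
    expected_sfs(n, gamma = g, demography = demography, n_ref = n_ref),
    numeric(n - 1L))
  e0 <- coalescent_expected_sfs(n, demography)
  s_neu <- sum(neutral$counts)
  lam <- (s_neu / l_neu) * (l_ratio * l_neu) *
    rowMeans(spectra) / sum(e0)
  counts <- rpois(n - 1L, lam)
  selected <- sfs_spectrum(counts, n, L = l_ratio * l_neu,
                           label = "selected")
  list(neutral = neutral, selected = selected,
       truth = list(dfe = dfe, demography = demography, l_ratio = l_ratio,
                    gammas = gammas))
}

#' Simulate a full MK-style dataset with known adaptive fraction
#'
#' Extends [simulate_dfe_dataset()] with divergence: synonymous
#' substitutions accumulate at the neutral rate, nonsynonymous non-adaptive
#' substitutions at the DFE-weighted relative fixation rate, and adaptive
#' substitutions are added so that their expected share of nonsynonymous
#' fixations is `alpha_true` (the realized share is recorded).
#'
#' @inheritParams simulate_dfe_dataset
#' @param alpha_true Expected proportion of nonsynonymous fixations that
#'   are beneficial.
#' @param d_s Expected synonymous substitutions per site on the divergence
#'   lineage.
#' @return List with `neutral`, `selected` spectra, an [mk_table()] `tab`,
#'   and `truth` (including `alpha_realized` and the fixation counts by
#'   origin).
#' @export
simulate_mk_dataset <- function(n_neutral_snps, n, demography = NULL,
                                dfe = list(shape = 0.3, mean = 400),
                                alpha_true = 0, d_s = 0.02, l_ratio = 2.5,
                                seed, n_ref = 100, n_components = 64) {
  ds <- simulate_dfe_dataset(n_neutral_snps, n, demography, dfe, l_ratio,
                             seed, n_ref, n_components)
  set.seed(seed + 2L)
  l_s <- ds$neutral$L
  l_n <- ds$selected$L
  # fixation rates must reflect the same realized DFE components as the
  # polymorphism, or the two halves of the dataset disagree by the mixture's
  # Monte-Carlo error
  mean_relfix <- mean(relative_fixation_rate(ds$truth$gammas))
  d_s_count <- rpois(1, l_s * d_s)
  d_n_non <- rpois(1, l_n * d_s * mean_relfix)
  d_n_adp <- if (alpha_true > 0) {
    rpois(1, l_n * d_s * mean_relfix * alpha_true / (1 - alpha_true))
  } else 0L
  tab <- mk_table(p_n = sum(ds$selected$counts),
                  p_s = sum(ds$neutral$counts),
                  d_n = d_n_non + d_n_adp, d_s = d_s_count,
                  l_n = l_n, l_s = l_s)
  ds$tab <- tab
  ds$truth$alpha_true <- alpha_true
  ds$truth$alpha_realized <-
    if (d_n_non + d_n_adp > 0) d_n_adp / (d_n_non + d_n_adp) else NA_real_
  ds$truth$fixations <- c(neutral_scale = d_s_count,
                          deleterious = d_n_non, beneficial = d_n_adp)
  ds$truth$mean_relfix <- mean_relfix
  ds
}

#' True DFE bin proportions of a gamma distribution over Ne*s
#'
#' @param shape,mean Gamma shape and mean of `Ne*s`.
#' @param breaks Bin edges on the `Ne*s` scale.
#' @return Named numeric vector of bin probabilities (sums to 1).
#' @export
dfe_bin_proportions <- function(shape, mean, breaks = c(0, 1, 10, Inf)) {
  p <- diff(pgamma(breaks, shape = shape, scale = mean / shape))
  names(p) <- paste0("Nes_", utils::head(breaks, -1), "_", breaks[-1])
  p
}
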