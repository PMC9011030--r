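test_that("segregating sites match the Watterson expectation", {
  # theta * L = 10 per fragment, n = 10 haplotypes
  s_obs <- vapply(1:250, function(r) {
    cfg <- sim_config(n_individuals = c(A = 5L), selfing = 0,
                      theta = 0.002, L_bp = 5e3, block_bp = 5e3,
                      seed = 1000 + r)
    nrow(simulate_coalescent(cfg)$haplotypes)
  }, numeric(1))
  expected <- 10 * sum(1 / (1:9))
  se <- sd(s_obs) / sqrt(length(s_obs))
  expect_lt(abs(mean(s_obs) - expected), 3 * se + 1e-9)
})

test_that("pairwise diversity for n = 2 equals theta", {
  pi_obs <- vapply(1:400, function(r) {
    cfg <- sim_config(n_individuals = c(A = 1L), selfing = 0,
                      theta = 0.01, L_bp = 2e3, block_bp = 2e3,
                      seed = 5000 + r)
    sim <- simulate_coalescent(cfg)
    if (nrow(sim$haplotypes) == 0) return(0)
    sum(sim$haplotypes[, 1] != sim$haplotypes[, 2]) / cfg$L_bp
  }, numeric(1))
  se <- sd(pi_obs) / sqrt(length(pi_obs))
  expect_lt(abs(mean(pi_obs) - 0.01), 3 * se + 1e-9)
})

test_that("neutral constant-size fragments give Tajima's D near zero", {
  d_obs <- vapply(1:120, function(r) {
    cfg <- sim_config(n_individuals = c(A = 10L), selfing = 0,
                      theta = 0.005, L_bp = 1e4, block_bp = 2e3,
                      seed = 9000 + r)
    sim <- simulate_coalescent(cfg)
    if (nrow(sim$haplotypes) < 3) return(NA_real_)
    diversity_stats(build_sfs(sim$haplotypes))$tajima_d
  }, numeric(1))
  expect_lt(abs(mean(d_obs, na.rm = TRUE)), 0.15)
})

test_that("simulation is exactly reproducible from (config, seed)", {
  cfg <- sim_config(n_individuals = c(A = 6L, B = 4L), theta = 0.003,
                    L_bp = 2e4, seed = 77)
  s1 <- simulate_coalescent(cfg)
  s2 <- simulate_coalescent(cfg)
  expect_identical(s1$haplotypes, s2$haplotypes)
  expect_identical(s1$sites, s2$sites)
})

test_that("neutral folded SFS matches the constant-size expectation", {
  n <- 20
  sp <- simulate_sfs_counts(6e4, n, NULL, seed = 71)
  folded <- fold_sfs(sp)
  i <- 1:(n %/% 2)
  expected <- 1 / i + 1 / (n - i)
  expected[i == n - i] <- 1 / i[i == n - i]
  p <- stats::chisq.test(folded$counts, p = expected / sum(expected))$p.value
  expect_gt(p, 0.01)
})

test_that("deleterious spectra are left-shifted against paired neutral runs", {
  wins <- vapply(1:20, function(s) {
    neu <- simulate_sfs_counts(3000, 20, NULL, seed = 100 + s)
    del <- simulate_sfs_counts(3000, 20, NULL,
                               gamma_dfe = list(shape = 0.3, mean = 50),
                               seed = 100 + s)
    (del$counts[1] / sum(del$counts)) > (neu$counts[1] / sum(neu$counts))
  }, logical(1))
  expect_true(all(wins))
})

test_that("a hard sweep scoops diversity at its center; s = 0 is identity", {
  ratios <- vapply(1:40, function(r) {
    cfg <- sim_config(n_individuals = c(A = 20L), selfing = 0.9,
                      theta = 0.002, L_bp = 4e5, block_bp = 5e3,
                      seed = 300 + r)
    sim <- simulate_coalescent(cfg)
    sw <- inject_sweep(sim, 2e5, s = 0.05)
    ctr <- abs(sw$sites$pos - 2e5) < 3e4
    flk <- abs(sw$sites$pos - 2e5) > 1.5e5
    ctr0 <- abs(sim$sites$pos - 2e5) < 3e4
    flk0 <- abs(sim$sites$pos - 2e5) > 1.5e5
    (sum(ctr) / sum(ctr0)) / (sum(flk) / sum(flk0))
  }, numeric(1))
  expect_lt(mean(ratios), 0.5)
  cfg <- sim_config(n_individuals = c(A = 10L), theta = 0.002,
                    L_bp = 5e4, seed = 42)
  sim <- simulate_coalescent(cfg)
  expect_identical(inject_sweep(sim, 2.5e4, s = 0), sim)
  expect_error(inject_sweep(sim, 9e9, s = 0.05), "outside")
})

test_that("sweep with no recombination escape collapses the center", {
  cfg <- sim_config(n_individuals = c(A = 15L), selfing = 1, rho_bp = 0,
                    theta = 0.005, L_bp = 5e4, seed = 9)
  sim <- simulate_coalescent(cfg)
  sw <- inject_sweep(sim, 2.5e4, s = 0.05)
  expect_equal(nrow(sw$haplotypes), 0L)  # all sites monomorphic
})

test_that("simulated gene models have valid frames and round-trip GFF", {
  g <- simulate_genome_annotation(5e4, seed = 12)
  cds <- g$features[g$features$type == "CDS", ]
  lens <- cds |>
    dplyr::group_by(parent) |>
    dplyr::summarise(len = sum(end - start + 1))
  expect_true(all(lens$len %% 3 == 0))
  introns <- g$features[g$features$type == "intron", ]
  expect_true(all(introns$end - introns$start + 1 >= 61))
  f <- tempfile(fileext = ".gff3")
  write_gff(g$features, f)
  back <- read_gff(f)
  for (ty in c("gene", "CDS", "intron", "five_prime_UTR")) {
    a <- g$features[g$features$type == ty, c("start", "end")]
    b <- back[back$type == ty, c("start", "end")]
    expect_equal(dplyr::arrange(a, start), dplyr::arrange(b, start),
                 ignore_attr = TRUE)
  }
})

test_that("alignment simulator respects rates and seeds", {
  tree <- "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);"
  s1 <- simulate_alignment(tree, n_cols = 2000, conserved_fraction = 0.3,
                           conserved_rate = 0, seed = 4)
  cons <- which(s1$mask)
  invariant <- apply(s1$aln[, cons, drop = FALSE], 2,
                     function(col) length(unique(col)) == 1)
  expect_true(all(invariant))
  s2 <- simulate_alignment(tree, n_cols = 2000, conserved_fraction = 0.3,
                           conserved_rate = 0, seed = 4)
  expect_identical(s1$aln, s2$aln)
  # neutral columns: observed substitutions/site ~ tree length (small
  # branches, parsimony count is nearly exact)
  s3 <- simulate_alignment(tree, n_cols = 2e4, conserved_fraction = 0,
                           seed = 5)
  tr <- ape::read.tree(text = tree)
  ph <- phangorn::phyDat(s3$aln, type = "DNA")
  obs <- phangorn::parsimony(tr, ph) / 2e4
  expect_equal(obs, sum(tr$edge.length), tolerance = 0.08)
})

test_that("outgroup divergence honours its rate and bookkeeping", {
  cfg <- sim_config(n_individuals = c(A = 5L), theta = 0.005, L_bp = 1e5,
                    seed = 31)
  sim <- simulate_coalescent(cfg)
  s0 <- simulate_divergence(sim, rate = 0)
  expect_true(all(s0$outgroup$outgroup_allele == s0$outgroup$ancestral_allele))
  s1 <- simulate_divergence(sim, rate = 0.05)
  p_obs <- mean(s1$outgroup$diverged)
  n <- nrow(s1$outgroup)
  expect_lt(abs(p_obs - (-expm1(-0.05))),
            3 * sqrt(0.05 * 0.95 / n) + 1e-9)
})

test_that("MK dataset records a recomputable true alpha", {
  ds <- simulate_mk_dataset(5000, 20, NULL, alpha_true = 0.3, d_s = 0.05,
                            seed = 8)
  fx <- ds$truth$fixations
  expect_equal(ds$truth$alpha_realized,
               unname(fx["beneficial"] /
                        (fx["beneficial"] + fx["deleterious"])))
  expect_equal(ds$tab$d_n, unname(fx["beneficial"] + fx["deleterious"]))
})
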