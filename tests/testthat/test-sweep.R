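# Outcrossing fragments: with the default map scale the effective sweep
# footprint (s / (r_eff ln 2N)) is ~80 kb, well inside the fragment, which
# is what a localization test needs.
make_fragment <- function(seed, n_ind = 30, L = 6e5, sweep_at = NULL,
                          s = 0.05) {
  cfg <- sim_config(n_individuals = c(A = n_ind), selfing = 0,
                    theta = 0.002, L_bp = L, block_bp = 5e3, seed = seed)
  sim <- simulate_coalescent(cfg)
  if (!is.null(sweep_at)) sim <- inject_sweep(sim, sweep_at, s = s)
  hap <- sim$haplotypes[, sim$hap_of_ind[, 1], drop = FALSE]
  if (n_ind * 2 == ncol(sim$haplotypes)) hap <- sim$haplotypes[, seq(1, 2 * n_ind, 2), drop = FALSE]
  k <- rowSums(hap); n <- ncol(hap)
  keep <- k > 0 & k < n
  list(counts = k[keep], pos = sim$sites$pos[keep], n = n,
       hap = hap[keep, , drop = FALSE])
}

test_that("CLR is invariant to chromosome relabeling and coordinate shifts", {
  fr <- make_fragment(1, L = 2e5)
  a <- clr_scan(fr$counts, fr$pos, fr$n)
  b <- clr_scan(fr$counts, fr$pos + 1e6, fr$n)
  expect_equal(a$clr, b$clr[seq_len(nrow(a))], tolerance = 1e-9)
})

test_that("null fragments give small CLR, sweeps large and localized", {
  fr0 <- make_fragment(2)
  r0 <- clr_scan(fr0$counts, fr0$pos, fr0$n)
  expect_lt(median(r0$clr), 1)
  expect_true(all(r0$clr >= 0))
  fr1 <- make_fragment(2, sweep_at = 3e5)
  r1 <- clr_scan(fr1$counts, fr1$pos, fr1$n)
  expect_gt(max(r1$clr), max(r0$clr))
  expect_lte(abs(r1$grid_pos[which.max(r1$clr)] - 3e5), 4e4)
})

test_that("grids below the callable threshold are masked", {
  fr <- make_fragment(3, L = 1e5)
  r0 <- clr_scan(fr$counts, fr$pos, fr$n)
  cb <- rep(2e4, nrow(r0)); cb[3] <- 1e3
  r <- clr_scan(fr$counts, fr$pos, fr$n, callable_bp = cb)
  expect_true(r$masked[3])
  expect_true(is.na(r$clr[3]))
})

test_that("iHS standardization contract and antisymmetry hold", {
  fr <- make_fragment(4, n_ind = 40, L = 5e5)
  res <- ihs_scan(fr$hap, fr$pos, min_bin = 100)
  by_bin <- dplyr::summarise(dplyr::group_by(res, bin),
                             m = mean(ihs), s = sd(ihs), n = dplyr::n())
  expect_true(all(abs(by_bin$m) < 1e-10))
  expect_true(all(abs(by_bin$s - 1) < 1e-10))
  res_sw <- ihs_scan(1L - fr$hap, fr$pos, min_bin = 100)
  expect_equal(nrow(res), nrow(res_sw))
  expect_equal(res$ihs_raw, -res_sw$ihs_raw, tolerance = 1e-12)
})

test_that("EHH at the focal SNP is 1 by definition", {
  hap <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  # one step away, all haplotypes still identical within class
  ihh <- selscape:::.ihh_one_side(hap, c(100, 200), 1L, c(1L, 2L), 2L,
                                  cutoff = 0.05, max_gap = 1e5,
                                  max_extend = 1e6)
  expect_true(is.finite(ihh))
  expect_gte(ihh, 0)
})

test_that("empirical p-values follow the permutation formula", {
  null_v <- 1:999
  expect_equal(empirical_null(0, null_v), 1)
  expect_equal(empirical_null(1000, null_v), 1 / 1000)
  expect_equal(empirical_null(500.5, null_v), (1 + 499) / 1000)
  expect_error(empirical_null(1, numeric(0)), "empty null")
})

test_that("BH calls match a hand-computed step-up", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216)
  out <- fdr_call(p, q = 0.05)
  # by hand: max k with p_(k) <= k/10 * 0.05 is k = 2
  expect_equal(out$significant, c(TRUE, TRUE, rep(FALSE, 8)))
  expect_equal(out$q_value, p.adjust(p, "BH"))
  expect_equal(sum(fdr_call(rep(1, 20))$significant), 0L)
})

test_that("candidate genes respect the 10-kb strict boundary", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                          start = c(5e4, 70000, 70001),
                          end = c(5.1e4, 70100, 70200))
  sig <- tibble::tibble(chrom = "chr1", pos = 6e4)
  out <- assign_candidates(sig, genes)
  expect_setequal(out$gene_id, c("g1", "g2"))  # g3 starts 10,001 bp away
  expect_equal(out$distance[out$gene_id == "g1"], 9000)
  # overlap with a grid interval is distance zero
  sig2 <- tibble::tibble(chrom = "chr1", start = 5.05e4, end = 5.2e4)
  out2 <- assign_candidates(sig2, genes)
  expect_equal(out2$distance[out2$gene_id == "g1"], 0)
})

test_that("candidate assignment equals a brute-force distance oracle", {
  set.seed(12)
  genes <- tibble::tibble(gene_id = paste0("g", 1:40), chrom = "chr1",
                          start = sort(sample.int(1e6, 40)))
  genes$end <- genes$start + sample(200:3000, 40, replace = TRUE)
  sig <- tibble::tibble(chrom = "chr1", pos = sort(sample.int(1e6, 15)))
  out <- assign_candidates(sig, genes)
  brute <- vapply(seq_len(nrow(genes)), function(i) {
    d <- pmax(0, pmax(genes$start[i] - sig$pos, sig$pos - genes$end[i]))
    min(d) <= 1e4
  }, logical(1))
  expect_setequal(out$gene_id, genes$gene_id[brute])
})

test_that("removing the sweep lowers the maximum CLR", {
  wins <- vapply(1:10, function(s) {
    with_sweep <- make_fragment(600 + s, L = 4e5, sweep_at = 2e5)
    without <- make_fragment(600 + s, L = 4e5)
    max(clr_scan(with_sweep$counts, with_sweep$pos, with_sweep$n)$clr) >
      max(clr_scan(without$counts, without$pos, without$n)$clr)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
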