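test_that("hypergeometric site projection enumerates exactly", {
  p <- project_site(5, 10, 4)
  manual <- choose(5, 0:4) * choose(5, 4:0) / choose(10, 4)
  expect_equal(unname(p), manual)
})

test_that("folding is idempotent and monomorphic sites only add to L", {
  set.seed(3)
  h <- random_hap(80, 10, seed = 3)
  s <- build_sfs(h)
  f1 <- fold_sfs(s); f2 <- fold_sfs(f1)
  expect_identical(f1, f2)
  h_mono <- rbind(h, matrix(0L, 5, 10))
  s2 <- build_sfs(h_mono)
  expect_equal(s2$counts, s$counts)
  expect_equal(s2$L, s$L + 5)
})

test_that("spectrum statistics equal haplotype-level oracles", {
  for (seed in c(1, 7, 42)) {
    h <- random_hap(60, 12, seed = seed)
    s <- build_sfs(h)
    s$L <- 1
    d <- diversity_stats(s)
    expect_equal(d$pi, oracle_pi(h), tolerance = 1e-12)
    expect_equal(d$theta_w, oracle_theta_w(h), tolerance = 1e-12)
    expect_equal(d$tajima_d, oracle_tajima_d(h), tolerance = 1e-12)
    expect_equal(d$fay_wu_h, oracle_fay_wu_h(h), tolerance = 1e-12)
  }
})

test_that("Tajima's D is zero when pi equals Watterson's theta", {
  n <- 10
  # spectrum proportional to 1/i has pi = theta_w in expectation; scale to
  # make them exactly equal
  xi <- 60 / (1:(n - 1))
  s <- sfs_spectrum(xi, n, L = 1000)
  d <- diversity_stats(s)
  expect_equal(d$pi, d$theta_w, tolerance = 1e-12)
  expect_equal(d$tajima_d, 0, tolerance = 1e-10)
})

test_that("Fay & Wu's H sign follows the frequency of derived alleles", {
  n <- 10
  low <- sfs_spectrum(c(20, rep(0, n - 2)), n, L = 100)
  high <- sfs_spectrum(c(rep(0, n - 2), 20), n, L = 100)
  expect_gt(diversity_stats(low)$fay_wu_h, 0)
  expect_lt(diversity_stats(high)$fay_wu_h, 0)
})

test_that("S = 0 gives missing D and H, not zero", {
  s <- sfs_spectrum(rep(0, 9), 10, L = 100)
  d <- diversity_stats(s)
  expect_true(is.na(d$tajima_d))
  expect_true(is.na(d$fay_wu_h))
})

test_that("weighted FST matches the Weir-Cockerham oracle and limits", {
  set.seed(5)
  for (seed in 1:3) {
    set.seed(seed)
    gt1 <- matrix(rbinom(20 * 10, 2, 0.3), 20, 10)
    gt2 <- matrix(rbinom(20 * 10, 2, 0.6), 20, 10)
    got <- fst_dxy(gt1, gt2)
    expect_equal(got$fst, oracle_wc_fst(gt1, gt2), tolerance = 1e-12)
  }
  # identical frequencies -> near zero
  set.seed(9)
  gt <- matrix(rbinom(200 * 12, 2, 0.4), 200, 12)
  near0 <- fst_dxy(gt[, 1:6], gt[, 7:12])
  expect_lt(abs(near0$fst), 0.08)
  # fixed difference -> FST ~ 1, dxy = 1
  g1 <- matrix(0L, 10, 20); g2 <- matrix(2L, 10, 20)
  fixed <- fst_dxy(g1, g2)
  expect_gt(fixed$fst, 0.97)
  expect_equal(fixed$dxy, 1)
})

test_that("RND normalizes dXY as defined", {
  expect_equal(rnd(0.02, 0.02, 0.02), 1)
  expect_equal(rnd(0, 0.05, 0.03), 0)
  expect_true(is.na(rnd(0.01, 0, 0)))
})

test_that("Ne from synonymous theta follows theta / (4 mu g)", {
  ne <- ne_from_theta(2.8e-3, 7e-9, 2)
  expect_equal(ne$ne, 5e4)
  expect_equal(ne_from_theta(5.6e-3, 7e-9, 2)$ne, 1e5)  # linear in theta
})

test_that("diversity-gene-density correlation and striding behave", {
  w <- tibble::tibble(chrom = "chr1",
                      start = (0:99) * 2e4, end = (1:100) * 2e4,
                      pi = seq(1e-3, 2e-3, length.out = 100))
  genes <- tibble::tibble(chrom = "chr1",
                          start = (0:99) * 2e4 + 1,
                          end = (0:99) * 2e4 + round(seq(19000, 100,
                                                         length.out = 100)))
  out <- diversity_gene_density_correlation(w, genes, stride = 5)
  expect_equal(out$rho[out$subset == "all"], -1, tolerance = 1e-12)
  expect_equal(out$n_windows[out$subset == "strided"], 20L)
})

test_that("projection preserves expected diversity", {
  set.seed(21)
  h <- random_hap(4000, 20, seed = 21)
  full <- build_sfs(h); full$L <- 1
  proj <- build_sfs(h, n_target = 12); proj$L <- 1
  expect_equal(diversity_stats(proj)$pi, diversity_stats(full)$pi,
               tolerance = 0.01)
})

test_that("window stats mask windows below the callable threshold", {
  h <- random_hap(200, 10, seed = 4)[1:100, ]
  pos <- sort(sample.int(6e4, 100))
  w <- window_stats(h, rep("chr1", 100), pos, callable_sites = 2e4,
                    window_size = 2e4, min_callable = 5e3)
  expect_true(all(c("pi", "tajima_d") %in% names(w)))
  w2 <- window_stats(h, rep("chr1", 100), pos, callable_sites = 4e3,
                     window_size = 2e4, min_callable = 5e3)
  expect_true(all(is.na(w2$pi)))
})
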