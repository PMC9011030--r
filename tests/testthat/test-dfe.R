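test_that("neutral expected SFS is proportional to 1/i", {
  e <- expected_sfs(20)
  expect_equal(e / e[1], 1 / (1:19), tolerance = 0.01, ignore_attr = TRUE)
})

test_that("deleterious selection inflates the singleton class", {
  e0 <- expected_sfs(20)
  e50 <- expected_sfs(20, gamma = 50)
  expect_gt(e50[1] / sum(e50), e0[1] / sum(e0))
})

test_that("two-epoch model is continuous in the time -> 0 limit", {
  e1 <- expected_sfs(15)
  e2 <- expected_sfs(15, demography = demography_model(5, 0.002))
  expect_equal(e2 / sum(e2), e1 / sum(e1), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("relative fixation rates bracket the neutral limit", {
  expect_equal(relative_fixation_rate(0), 1)
  expect_equal(relative_fixation_rate(1e-10), 1, tolerance = 1e-6)
  expect_lt(relative_fixation_rate(10), 1e-7)
  expect_gt(relative_fixation_rate(-2), 1)
})

test_that("AIC prefers one epoch on constant-size data", {
  wins <- vapply(1:6, function(s) {
    sp <- simulate_sfs_counts(2e4, 20, NULL, seed = 400 + s)
    fit <- fit_demography(sp, epochs = 1:2, n_starts = 2)
    fit$best$epochs == 1L
  }, logical(1))
  expect_gte(mean(wins), 5 / 6)
})

test_that("a 5x expansion is recovered from the neutral spectrum", {
  sp <- simulate_sfs_counts(1e5, 40, demography_model(5, 2), seed = 19)
  fit <- fit_demography(sp, epochs = 1:2, n_starts = 3)
  expect_equal(fit$best$epochs, 2L)
  expect_gte(fit$best$size_ratios[1], 3.5)
  expect_lte(fit$best$size_ratios[1], 7)
})

test_that("all-neutral input yields a DFE concentrated below Nes = 1", {
  ds <- simulate_dfe_dataset(4e4, 20, NULL,
                             dfe = list(shape = 1, mean = 1e-3),
                             seed = 23)
  # the optimum legitimately pins at the lower boundary of the mean
  expect_warning(
    fit <- fit_dfe(ds$selected, ds$neutral, demography_model(),
                   n_grid = 60),
    "boundary")
  expect_gte(fit$bin_proportions[["Nes_0_1"]], 0.95)
})

test_that("the DFE bin proportions always sum to one", {
  p <- dfe_bin_proportions(0.3, 400)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  p2 <- dfe_bin_proportions(2, 0.5, c(0, 1, 10, Inf))
  expect_equal(sum(p2), 1, tolerance = 1e-9)
})

test_that("plain MK alpha arithmetic and DAF filtering", {
  # pN/pS = 0.3, dN/dS = 0.25 -> alpha = -0.2
  sfs_n <- sfs_spectrum(c(0, 0, 0, 30, 0, 0, 0, 0, 0), 10)
  sfs_s <- sfs_spectrum(c(0, 0, 0, 100, 0, 0, 0, 0, 0), 10)
  a <- mk_alpha(sfs_n, sfs_s, d_n = 25, d_s = 100, daf_cutoff = 0)
  expect_equal(a$alpha, -0.2, tolerance = 1e-12)
  # everything below the 15% cutoff -> undefined, flagged
  low_n <- sfs_spectrum(c(30, rep(0, 8)), 10)
  low_s <- sfs_spectrum(c(100, rep(0, 8)), 10)
  u <- mk_alpha(low_n, low_s, 25, 100, daf_cutoff = 0.15)
  expect_true(is.na(u$alpha))
  expect_true(isTRUE(attr(u, "undefined")))
})

test_that("asymptotic MK handles constant and degenerate fits", {
  n <- 40
  i <- 1:(n - 1)
  # pN/pS constant in x with alpha(x) = 0.3 everywhere
  p_s <- 1e4 / i
  p_n <- 0.7 * p_s
  am <- asymptotic_mk(sfs_spectrum(p_n, n), sfs_spectrum(p_s, n),
                      d_n = 1000, d_s = 1000)
  expect_equal(am$alpha_asym, 0.3, tolerance = 1e-6)
  expect_error(
    asymptotic_mk(sfs_spectrum(p_n[1:4] * c(1, 0, 0, 0), 5),
                  sfs_spectrum(c(1, 0, 0, 0), 5), 10, 10),
    "fewer than 5")
})

test_that("block bootstrap is seeded and degenerates correctly", {
  dat <- tibble::tibble(block = rep(1:25, each = 4), x = 1)
  bb <- block_bootstrap(dat, "block", function(d) mean(d$x), B = 50,
                        seed = 3)
  expect_equal(unname(bb$ci$upper - bb$ci$lower), 0)
  bb1 <- block_bootstrap(dat, "block", function(d) sum(d$x), B = 30,
                         seed = 9)
  bb2 <- block_bootstrap(dat, "block", function(d) sum(d$x), B = 30,
                         seed = 9)
  expect_identical(bb1$ci, bb2$ci)
  expect_warning(
    block_bootstrap(dat[dat$block < 5, ], "block", function(d) mean(d$x),
                    B = 10, seed = 1),
    "fewer than 20 blocks")
})

test_that("bootstrap CIs cover a known mean at roughly nominal rate", {
  cover <- vapply(1:40, function(r) {
    set.seed(r)
    dat <- tibble::tibble(block = rep(1:30, each = 3),
                          x = rnorm(90, mean = 1))
    bb <- block_bootstrap(dat, "block", function(d) mean(d$x), B = 100,
                          seed = r)
    bb$ci$lower <= 1 && 1 <= bb$ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})
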