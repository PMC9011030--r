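test_that("FASTA round trip preserves names and sequences", {
  fa <- c(chr1 = "ACGTACGTGGCC", chr2 = "TTTTAAAACCCC")
  f <- tempfile(fileext = ".fa")
  write_fasta(fa, f)
  expect_identical(read_fasta(f), fa)
})

test_that("region masks exclude their sites from downstream tables", {
  sites <- tibble::tibble(chrom = c("chr1", "chr1", "chr5", "chr7"),
                          pos = c(15.4e6, 25e6, 1e6, 6e6))
  mask <- tibble::tibble(chrom = c("chr1", "chr5", "chr7"),
                         start = c(15.3e6, 0.47e6, 0.45e6),
                         end = c(24.4e6, 3.4e6, 5.1e6))
  keep <- outside_mask(sites, mask)
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(outside_mask(sites, NULL)))
  # masked sites never reach a spectrum built on the kept subset
  hap <- matrix(rep(c(0L, 1L), 8), 4, 4)
  s <- build_sfs(hap[keep[1:4], , drop = FALSE])
  expect_equal(s$L, sum(keep[1:4]))
})

test_that("swept regions are maximal runs of contiguous significant grids", {
  grids <- tibble::tibble(
    grid_pos = seq(0, 18e4, 2e4),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                    TRUE, FALSE))
  out <- swept_regions(grids)
  expect_equal(nrow(out), 3L)
  expect_equal(out$start, c(0, 6e4, 16e4))
  expect_equal(out$end, c(4e4, 12e4, 18e4))
  expect_equal(out$n_grids, c(2L, 3L, 1L))
  none <- swept_regions(tibble::tibble(grid_pos = 0, significant = FALSE))
  expect_equal(nrow(none), 0L)
})
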