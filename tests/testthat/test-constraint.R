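test_that("MAF round trip preserves the alignment", {
  tree <- "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);"
  s <- simulate_alignment(tree, n_cols = 300, conserved_fraction = 0.2,
                          seed = 3)
  f <- tempfile(fileext = ".maf")
  write_maf(s$aln, f)
  back <- read_maf(f)
  expect_identical(back$aln, s$aln)
  expect_equal(back$ref, "a")
})

test_that("neutral tree calibration recovers simulated branch lengths", {
  tree <- "((a:0.08,b:0.12):0.05,(c:0.1,d:0.06):0.05,e:0.15);"
  s <- simulate_alignment(tree, n_cols = 3e4, conserved_fraction = 0,
                          seed = 6)
  fit <- calibrate_neutral_tree(s$aln)
  tr <- ape::read.tree(text = tree)
  expect_equal(sum(fit$edge.length), sum(tr$edge.length), tolerance = 0.1)
  # per-tip pendant edges within 10%-ish at this depth
  d_fit <- ape::cophenetic.phylo(fit)["a", "b"]
  expect_equal(d_fit, 0.2, tolerance = 0.1)
  expect_error(calibrate_neutral_tree(s$aln[, 1:100]), "usable 4-fold")
  expect_error(calibrate_neutral_tree(s$aln[1:2, ]), "3 aligned species")
})

test_that("identical sequences calibrate to (near) zero branch lengths", {
  aln <- matrix("A", 4, 1500,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  aln[, seq(1, 1500, by = 3)] <- "C"  # some composition, still identical
  fit <- calibrate_neutral_tree(aln)
  expect_lt(sum(fit$edge.length), 1e-4)
})

test_that("RS score is E for invariant columns and respects gap projection", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  aln <- rbind(a = c("A", "A", "A"),
               b = c("A", "C", "A"),
               c = c("A", "G", "-"),
               d = c("A", "T", "-"))
  rs <- rs_score(aln, tree, ref = "a")
  total_len <- sum(tree$edge.length)
  expect_equal(rs$rs[1], total_len, tolerance = 1e-8)  # invariant: O = 0
  expect_lt(rs$rs[2], 0)  # saturated column: observed >> expected
  # gap projection: only a and b present -> E is their pairwise path
  expect_equal(rs$e[3], 0.2, tolerance = 1e-8)
  expect_equal(rs$rs[3], 0.2, tolerance = 1e-8)
  # RS never exceeds the projected expectation
  expect_true(all(rs$rs <= rs$e + 1e-9))
})

test_that("columns at the neutral rate average RS near zero", {
  # deep alignment: the per-column ML rate is noisy, and its bias shrinks
  # with the number of aligned species
  tips <- paste0("sp", 1:16)
  tree <- paste0("(", paste(
    sapply(seq(1, 16, 2), function(i)
      sprintf("(%s:0.08,%s:0.08):0.04", tips[i], tips[i + 1])),
    collapse = ","), ");")
  s <- simulate_alignment(tree, n_cols = 6e3, conserved_fraction = 0,
                          seed = 11)
  tr <- ape::read.tree(text = tree)
  rs <- rs_score(s$aln, tr, ref = "sp1")
  expect_lt(abs(mean(rs$rs)), 0.1)
})

test_that("segment finder applies the >12 bp rule exactly", {
  x <- c(rep(-1, 10), rep(1, 13), rep(-1, 10))
  seg <- find_segments(x, threshold = 5, penalty = 0)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 11L)
  expect_equal(seg$length, 13L)
  x12 <- c(rep(-1, 10), rep(1, 12), rep(-1, 10))
  expect_equal(nrow(find_segments(x12, threshold = 5, penalty = 0)), 0L)
})

test_that("segment finder equals the exhaustive oracle on random tracks", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(1000, mean = -0.1, sd = 1)
    got <- find_segments(x, threshold = 3, penalty = 0, min_len = 1L)
    want <- oracle_segments(x, threshold = 3)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("splitting by category keeps only >12 bp sub-segments", {
  feats <- tibble::tibble(chrom = "chr1", source = "x",
                          type = c("gene", "CDS", "intron"),
                          start = c(1, 1, 21), end = c(100, 20, 60),
                          strand = "+", phase = NA_integer_,
                          id = c("g1", NA, NA),
                          parent = c(NA, "t1", "t1"))
  segs <- tibble::tibble(start = 1, end = 30)
  out <- split_by_category(segs, feats)
  expect_equal(nrow(out), 1L)  # 20 bp CDS kept, 10 bp intron piece dropped
  expect_equal(out$category, "CDS")
  expect_equal(out$end - out$start + 1, 20)
  # fully intergenic segment is unchanged
  segs2 <- tibble::tibble(start = 200, end = 260)
  out2 <- split_by_category(segs2, feats)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$category, "intergenic")
  expect_equal(out2$start, 200)
  expect_equal(out2$end, 260)
  # conservation inequality on a random genome
  g <- simulate_genome_annotation(2e4, seed = 3)
  segs3 <- tibble::tibble(start = c(100, 5000), end = c(400, 5400))
  out3 <- split_by_category(segs3, g$features)
  expect_lte(sum(out3$length), sum(segs3$end - segs3$start + 1))
})
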