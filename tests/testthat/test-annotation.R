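test_that("codon degeneracy matches the standard genetic code", {
  deg <- selscape:::.degeneracy_table()
  expect_equal(unname(deg["GGG", 3]), 4L)  # glycine family
  expect_equal(unname(deg["ATG", 2]), 1L)  # Met is unique (0-fold)
  # brute force over all 64 codons: 32 have a 4-fold third position
  expect_equal(sum(deg[, 3] == 4L), 32L)
})

test_that("classify_degeneracy handles strands, phase and bad frames", {
  # one forward gene: CDS "ATGGGGTAA" -> M G *
  fasta <- c(chr1 = paste0("AAAA", "ATGGGGTAA", "TTTT"))
  cds <- tibble::tibble(chrom = "chr1", start = 5, end = 13, strand = "+",
                        phase = 0L, parent = "t1")
  out <- classify_degeneracy(fasta, cds)
  expect_equal(out$sites$degeneracy[out$sites$pos == 10], 4L)  # GGG pos 3
  expect_equal(out$sites$degeneracy[out$sites$pos == 6], 1L)   # ATG pos 2
  # reverse-complement the same gene on the minus strand
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(fasta, "")[[1]]),
                                     collapse = ""))
  fasta2 <- c(chr1 = rc)
  L <- nchar(fasta2)
  cds2 <- tibble::tibble(chrom = "chr1", start = L - 13 + 1, end = L - 5 + 1,
                         strand = "-", phase = 0L, parent = "t1")
  out2 <- classify_degeneracy(fasta2, cds2)
  expect_equal(sort(out2$sites$degeneracy), sort(out$sites$degeneracy))
  # frame violation is skipped with a warning
  cds3 <- tibble::tibble(chrom = "chr1", start = 5, end = 12, strand = "+",
                         phase = 0L, parent = "t1")
  expect_warning(r3 <- classify_degeneracy(fasta, cds3), "multiple of 3")
  expect_equal(r3$n_skipped_tx, 1L)
})

test_that("intron margins and centers partition a 61-bp intron", {
  feats <- tibble::tibble(chrom = "chr1", source = "x",
                          type = c("gene", "intron"),
                          start = c(1, 101), end = c(400, 161),
                          strand = "+", phase = NA_integer_,
                          id = c("g1", NA), parent = c(NA, "t1"))
  pos <- tibble::tibble(chrom = "chr1", pos = 101:161)
  cl <- classify_category(pos, feats)
  expect_equal(sum(cl$category == "intronM"), 60L)
  expect_equal(sum(cl$category == "intronC"), 1L)
  expect_equal(cl$category[31], "intronC")  # position 131, the center base
})

test_that("intergenic proximity uses the 100-bp rule", {
  feats <- tibble::tibble(chrom = "chr1", source = "x", type = "gene",
                          start = 1000, end = 2000, strand = "+",
                          phase = NA_integer_, id = "g1",
                          parent = NA_character_)
  pos <- tibble::tibble(chrom = "chr1", pos = c(901, 899, 2100, 2101))
  cl <- classify_category(pos, feats)
  expect_equal(cl$dist_to_gene, c(99, 101, 100, 101))
  expect_equal(cl$proximal, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("simulated genome categories cover every position exactly once", {
  g <- simulate_genome_annotation(2e4, seed = 5)
  pos <- tibble::tibble(chrom = names(g$fasta), pos = 1:g$chrom_len)
  cl <- classify_category(pos, g$features)
  expect_equal(nrow(cl), g$chrom_len)
  expect_false(any(is.na(cl$category)))
  expect_equal(sum(table(cl$category)), g$chrom_len)
})

test_that("polarization follows the shared-outgroup-allele rule", {
  p <- polarize(c("A", "A", "A"), c("G", "G", "G"),
                c("A", "A", "C"), c(NA, "G", "C"))
  expect_equal(p$ancestral, c("A", NA, NA))
  expect_equal(p$polarized, c(TRUE, FALSE, FALSE))
  expect_equal(p$derived[1], "G")
})

test_that("mutation classes partition polarized SNPs", {
  expect_equal(mutation_class("A", "G"), "WS")
  expect_equal(mutation_class("A", "T"), "WWSS")
  expect_equal(mutation_class("G", "T"), "SW")
  expect_error(mutation_class(NA, "G"), "polarized")
  set.seed(8)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, 3000, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))
  cls <- mutation_class(anc, der)
  expect_equal(length(cls), 3000L)
  expect_setequal(unique(cls), c("WS", "SW", "WWSS"))
  # symmetric mutation: WS and SW equal within binomial error
  tab <- table(cls)
  expect_lt(abs(tab[["WS"]] - tab[["SW"]]) /
              sqrt(tab[["WS"]] + tab[["SW"]]), 4)
})

test_that("recombination binning honors boundaries, masks and terciles", {
  map <- tibble::tibble(chrom = "chr1", start = c(1, 20001, 40001),
                        end = c(20000, 40000, 60000),
                        cm_mb = c(1, 3.2, 8))
  sites <- tibble::tibble(chrom = "chr1", pos = c(100, 25000, 50000, 70000))
  out <- bin_recombination(sites, map)
  expect_equal(out$rec_bin[1:3], c("low", "mid", "high"))
  expect_true(is.na(out$rec_bin[4]))  # outside the map
  expect_equal(attr(out, "excluded"), 1L)
  # mask removes the inversion-like interval
  out2 <- bin_recombination(sites, map,
                            mask = tibble::tibble(chrom = "chr1",
                                                  start = 1, end = 30000))
  expect_true(all(is.na(out2$rec_bin[1:2])))
  # terciles split near-equally with ties broken by order
  map3 <- tibble::tibble(chrom = "chr1", start = seq(1, 1e5, 1e4),
                         end = seq(1, 1e5, 1e4) + 1e4 - 1, cm_mb = 5)
  sites3 <- tibble::tibble(chrom = "chr1", pos = seq(5, 9e4, length.out = 10))
  t3 <- bin_recombination(sites3, map3, mode = "tercile")
  expect_lte(diff(range(table(t3$rec_bin))), 1)
  expect_warning(
    bin_recombination(tibble::tibble(chrom = "chrX", pos = 1), map),
    "masked or outside")
})
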