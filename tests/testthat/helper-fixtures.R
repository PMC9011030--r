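# Shared fixtures, all generated in code.

# A small geno object with explicit depths, for filter tests.
make_geno <- function(gt, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                      chrom = "chr1") {
  gt <- as.matrix(gt)
  sites <- tibble::tibble(chrom = chrom, pos = seq_len(nrow(gt)) * 10L,
                          ref = "A", alt = "G")
  geno_matrix(sites, gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
}

# Random biallelic callset for round-trip tests.
random_geno <- function(n_sites, n_ind, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  gt <- matrix(sample(c(0:2, NA), n_sites * n_ind, replace = TRUE,
                      prob = c(.55, .1, .25, .1)), n_sites, n_ind)
  dp <- matrix(rpois(n_sites * n_ind, 8), n_sites, n_ind)
  ad_alt <- matrix(rbinom(n_sites * n_ind, dp, .4), n_sites, n_ind)
  sites <- tibble::tibble(chrom = "chr1",
                          pos = sort(sample.int(1e6, n_sites)),
                          ref = ref, alt = alt)
  g <- geno_matrix(sites, gt, dp, dp - ad_alt, ad_alt)
  colnames(g$gt) <- g$samples$id
  g
}

# Random haplotype matrix without missing data (for oracle equivalence).
random_hap <- function(n_sites, n_hap, seed) {
  set.seed(seed)
  repeat {
    h <- matrix(rbinom(n_sites * n_hap, 1, runif(1, .1, .5)),
                n_sites, n_hap)
    k <- rowSums(h)
    h <- h[k > 0 & k < n_hap, , drop = FALSE]
    if (nrow(h) >= 2) return(h)
  }
}

# Brute-force estimators straight from definitions, independent of the
# spectrum-based implementations.
oracle_pi <- function(h) {
  n <- ncol(h); tot <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) tot <- tot + sum(h[, a] != h[, b])
  tot / choose(n, 2)
}
oracle_theta_w <- function(h) {
  n <- ncol(h)
  sum(rowSums(h) > 0 & rowSums(h) < n) / sum(1 / (1:(n - 1)))
}
oracle_tajima_d <- function(h) {
  n <- ncol(h)
  S <- nrow(h)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (oracle_pi(h) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
oracle_fay_wu_h <- function(h) {
  n <- ncol(h)
  xi <- tabulate(rowSums(h), n - 1)
  th <- sum(2 * (1:(n - 1))^2 * xi) / (n * (n - 1))
  oracle_pi(h) - th
}
# Weir & Cockerham (1984) theta-hat, written directly from the paper's
# variance components for two populations of diploids.
oracle_wc_fst <- function(gt1, gt2) {
  num <- 0; den <- 0
  for (s in seq_len(nrow(gt1))) {
    g1 <- gt1[s, !is.na(gt1[s, ])]; g2 <- gt2[s, !is.na(gt2[s, ])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    if (p1 == 0 && p2 == 0) next
    if (p1 == 1 && p2 == 1) next
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  num / den
}

# Brute-force maximal-scoring-segment decomposition over all subintervals,
# same tie rules as the scanner's left-to-right scan: maximum sum, then
# minimum end, then maximum start.
oracle_segments <- function(x, threshold) {
  find_best <- function(lo, hi) {
    best <- NULL
    for (s in lo:hi) {
      acc <- 0
      for (e in s:hi) {
        acc <- acc + x[e]
        cand <- c(s, e, acc)
        if (is.null(best) || acc > best[3] ||
            (acc == best[3] && e < best[2]) ||
            (acc == best[3] && e == best[2] && s > best[1])) best <- cand
      }
    }
    best
  }
  acc <- list()
  recurse <- function(lo, hi) {
    if (hi < lo) return()
    b <- find_best(lo, hi)
    if (b[3] < threshold) return()
    acc[[length(acc) + 1]] <<- b
    recurse(lo, b[1] - 1)
    recurse(b[2] + 1, hi)
  }
  recurse(1, length(x))
  if (length(acc) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          score = numeric(0)))
  }
  m <- do.call(rbind, acc)
  out <- tibble::tibble(start = m[, 1], end = m[, 2], score = m[, 3])
  out[order(out$start), ]
}
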