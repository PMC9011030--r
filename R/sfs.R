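#' Site frequency spectrum object
#'
#' A light container for an unfolded or folded site frequency spectrum at a
#' fixed haploid sample size. Counts may be fractional (hypergeometric
#' projection distributes each site's mass over frequency classes).
#'
#' @param counts Numeric vector of (possibly fractional) site counts for
#'   derived-allele count `1..n-1` (unfolded) or minor-allele count
#'   `1..floor(n/2)` (folded).
#' @param n Haploid sample size.
#' @param folded Logical; is `counts` a folded spectrum?
#' @param L Total callable sites behind the spectrum (monomorphic included);
#'   used for per-site statistics.
#' @param label Optional site-class label (e.g. `"4fold"`, `"0fold"`).
#' @return An object of class `sfs`.
#' @export
sfs_spectrum <- function(counts, n, folded = FALSE, L = NA_real_,
                         label = NA_character_) {
  n <- as.integer(n)
  n_classes <- if (folded) n %/% 2L else n - 1L
  stopifnot(length(counts) == n_classes, all(counts >= 0 | is.na(counts)))
  structure(list(counts = as.numeric(counts), n = n, folded = folded,
                 L = as.numeric(L), label = label),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs> n = %d (%s), S = %.1f, L = %s%s\n", x$n,
              if (x$folded) "folded" else "unfolded", sum(x$counts),
              format(x$L), if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sfs <- function(x, ...) {
  tibble::tibble(i = seq_along(x$counts), count = x$counts,
                 frequency = seq_along(x$counts) / x$n)
}

#' Hypergeometric projection of one site to a smaller sample size
#'
#' Distributes a site observed with `k` derived alleles among `m` called
#' chromosomes over derived-allele counts `0..n_target` of a subsample drawn
#' without replacement.
#'
#' @param k Derived-allele count among called chromosomes.
#' @param m Number of called chromosomes (`m >= n_target`).
#' @param n_target Target haploid sample size.
#' @return Numeric vector of probabilities, names `0..n_target`.
#' @export
#' @examples
#' project_site(5, 10, 4)  # C(5,i) C(5,4-i) / C(10,4)
project_site <- function(k, m, n_target) {
  stopifnot(m >= n_target, k >= 0, k <= m)
  setNames(dhyper(0:n_target, k, m - k, n_target), 0:n_target)
}

#' Build a site frequency spectrum from haplotypes
#'
#' Projects each polymorphic site to a common haploid sample size by the
#' expected hypergeometric mass (or by seeded resampling of `n_target`
#' called chromosomes) and accumulates the spectrum. Sites called in fewer
#' than `n_target` chromosomes are discarded; sites whose projected mass
#' falls on class 0 or `n_target` contribute only to the callable length.
#'
#' @param hap Matrix of 0/1/`NA` alleles, sites in rows, haplotypes in
#'   columns. Derived allele coded 1 when polarized; for folded spectra the
#'   coding is arbitrary.
#' @param n_target Target haploid sample size; defaults to the number of
#'   columns (no projection, sites with missing calls dropped).
#' @param folded Build a folded (minor-allele) spectrum.
#' @param method `"hypergeometric"` (deterministic expected counts) or
#'   `"resample"` (one seeded draw of `n_target` chromosomes per site).
#' @param seed Seed for `method = "resample"`.
#' @param label Optional site-class label stored on the spectrum.
#' @return An [sfs_spectrum()] with `L` = number of retained sites.
#' @export
build_sfs <- function(hap, n_target = ncol(hap), folded = FALSE,
                      method = c("hypergeometric", "resample"), seed = NULL,
                      label = NA_character_) {
  method <- match.arg(method)
  hap <- as.matrix(hap)
  m <- rowSums(!is.na(hap))
  k <- rowSums(hap == 1L, na.rm = TRUE)
  keep <- m >= n_target
  if (!any(keep)) stop("no site has >= n_target called chromosomes")
  m <- m[keep]; k <- k[keep]
  counts <- numeric(n_target - 1L)
  if (method == "hypergeometric") {
    tab <- dplyr::count(tibble::tibble(m = m, k = k), .data$m, .data$k)
    for (r in seq_len(nrow(tab))) {
      mass <- dhyper(1:(n_target - 1L), tab$k[r], tab$m[r] - tab$k[r],
                     n_target)
      counts <- counts + tab$n[r] * mass
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    kk <- rhyper(length(m), k, m - k, n_target)
    tab <- table(factor(kk, levels = 1:(n_target - 1L)))
    counts <- as.numeric(tab)
  }
  out <- sfs_spectrum(counts, n_target, folded = FALSE, L = sum(keep),
                      label = label)
  if (folded) fold_sfs(out) else out
}

#' Fold an unfolded spectrum
#'
#' Sums derived-allele classes `i` and `n - i` into minor-allele classes;
#' folding an already folded spectrum is the identity.
#'
#' @param x An [sfs_spectrum()].
#' @return A folded `sfs`.
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"))
  if (x$folded) return(x)
  n <- x$n
  half <- n %/% 2L
  folded <- vapply(1:half, function(i) {
    if (i == n - i) x$counts[i] else x$counts[i] + x$counts[n - i]
  }, numeric(1))
  sfs_spectrum(folded, n, folded = TRUE, L = x$L, label = x$label)
}

#' @importFrom stats rhyper
NULL

# Tajima (1989) constants for sample size n
.tajima_constants <- function(n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Diversity statistics from a site frequency spectrum
#'
#' Standard estimators: nucleotide diversity `pi`, Watterson's `theta_w`
#' (both per site when `L` is known, else per spectrum), Tajima's D with the
#' 1989 variance normalization, and Fay & Wu's H (`pi - theta_H`,
#' unnormalized by default; `normalized = TRUE` applies the Zeng et al. 2006
#' variance). H requires an unfolded spectrum.
#'
#' @param x An [sfs_spectrum()] or a 0/1/`NA` haplotype matrix (sites x
#'   haplotypes), in which case a full-sample spectrum is built first.
#' @param normalized Also normalize Fay & Wu's H by its standard deviation.
#' @param ... Passed to [build_sfs()] for matrix input.
#' @return A one-row tibble with `n`, `L`, `S`, `pi`, `theta_w`,
#'   `theta_h`, `tajima_d`, `fay_wu_h`.
#' @export
diversity_stats <- function(x, normalized = FALSE, ...) {
  if (is.matrix(x)) x <- build_sfs(x, ...)
  stopifnot(inherits(x, "sfs"))
  n <- x$n
  L <- if (is.na(x$L)) 1 else x$L
  xi <- x$counts
  i <- seq_along(xi)
  S <- sum(xi)
  if (is.na(S)) {
    return(tibble::tibble(n = n, L = L, S = NA_real_, pi = NA_real_,
                          theta_w = NA_real_, theta_h = NA_real_,
                          tajima_d = NA_real_, fay_wu_h = NA_real_))
  }
  # 2i(n-i)/(n(n-1)) weights are symmetric in i <-> n-i, so the same formula
  # serves folded and unfolded spectra
  pi_tot <- sum(2 * i * (n - i) / (n * (n - 1)) * xi)
  cst <- .tajima_constants(n)
  theta_w_tot <- S / cst$a1
  tajima_d <- if (S > 0) {
    (pi_tot - theta_w_tot) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  } else NA_real_
  if (!x$folded) {
    theta_h_tot <- sum(2 * i^2 * xi / (n * (n - 1)))
    h <- if (S > 0) pi_tot - theta_h_tot else NA_real_
    if (normalized && S > 0) {
      # Zeng, Fu, Shi & Wu (2006) variance of pi - theta_H
      bn <- sum(1 / (1:(n - 1))^2)
      bn1 <- bn + 1 / n^2
      theta_est <- S / cst$a1
      theta2_est <- S * (S - 1) / (cst$a1^2 + bn)
      v <- theta_est * (n - 2) / (6 * (n - 1)) +
        theta2_est * (18 * n^2 * (3 * n + 2) * bn1 -
                        (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
          (9 * n * (n - 1)^2)
      h <- h / sqrt(v)
    }
  } else {
    theta_h_tot <- NA_real_
    h <- NA_real_
  }
  tibble::tibble(
    n = n, L = L, S = S,
    pi = pi_tot / L, theta_w = theta_w_tot / L,
    theta_h = theta_h_tot / L,
    tajima_d = tajima_d, fay_wu_h = if (is.na(h)) h else h / ifelse(normalized, 1, L)
  )
}
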