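#' Fit epoch demography to a neutral site frequency spectrum
#'
#' Maximum-likelihood fit of 1-, 2- and 3-epoch piecewise-constant size
#' histories to a neutral spectrum (typically 4-fold sites outside conserved
#' regions), with Poisson likelihood per frequency class (overall rate
#' profiled out) and AIC model choice. The expected neutral spectrum is the
#' exact coalescent expectation, so each evaluation is fast.
#'
#' @param neutral_sfs An [sfs_spectrum()] (unfolded or folded).
#' @param epochs Integer vector of model sizes to fit, subset of `1:3`.
#' @param n_starts Random restarts per model (first start is deterministic).
#' @param seed Seed for the restart draws.
#' @return An object of class `demography_fit`: list with `best` (a
#'   [demography_model()]), `models` (all fits), `aic` table.
#' @export
fit_demography <- function(neutral_sfs, epochs = 1:3, n_starts = 4,
                           seed = 1) {
  stopifnot(inherits(neutral_sfs, "sfs"))
  x <- neutral_sfs$counts
  n <- neutral_sfs$n
  model_sfs <- function(dem) {
    m <- coalescent_expected_sfs(n, dem)
    if (neutral_sfs$folded) {
      half <- n %/% 2L
      m <- vapply(1:half, function(i)
        if (i == n - i) m[i] else m[i] + m[n - i], numeric(1))
    }
    m
  }
  loglik <- function(dem) {
    m <- model_sfs(dem)
    if (any(!is.finite(m)) || any(m <= 0)) return(-Inf)
    sum(x * log(m / sum(m)))
  }
  set.seed(seed)
  fits <- list()
  for (ne in sort(epochs)) {
    if (ne == 1L) {
      dem <- demography_model()
      dem$log_lik <- loglik(dem)
      dem$aic <- 2 * 1 - 2 * dem$log_lik  # one parameter: the overall rate
      fits[["1"]] <- dem
      next
    }
    npar <- 2L * (ne - 1L)
    obj <- function(par) {
      ratios <- exp(par[seq_len(ne - 1L)])
      times <- exp(par[ne - 1L + seq_len(ne - 1L)])
      if (any(ratios < 0.02) || any(ratios > 50) || any(times > 20) ||
          any(times < 1e-3)) return(1e9)
      -loglik(demography_model(ratios, times))
    }
    starts <- list(rep(0, npar))
    for (k in seq_len(max(0, n_starts - 1))) {
      starts[[k + 1]] <- c(runif(ne - 1L, log(0.2), log(8)),
                           runif(ne - 1L, log(0.05), log(4)))
    }
    best <- NULL
    for (st in starts) {
      f <- tryCatch(optim(st, obj, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (is.null(best) || !is.finite(best$value)) {
      warning("flat likelihood for the ", ne, "-epoch model")
      next
    }
    ratios <- exp(best$par[seq_len(ne - 1L)])
    times <- exp(best$par[ne - 1L + seq_len(ne - 1L)])
    dem <- demography_model(ratios, times,
                            log_lik = -best$value,
                            aic = 2 * (npar + 1) + 2 * best$value)
    fits[[as.character(ne)]] <- dem
  }
  aic_tab <- tibble::tibble(
    epochs = as.integer(names(fits)),
    log_lik = vapply(fits, function(f) f$log_lik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  best <- fits[[which.min(aic_tab$aic)]]
  structure(list(best = best, models = fits, aic = aic_tab,
                 folded = neutral_sfs$folded, n = n),
            class = "demography_fit")
}

#' @export
print.demography_fit <- function(x, ...) {
  cat("<demography_fit>\n"); print(x$aic); print(x$best); invisible(x)
}

#' @export
tidy.demography_fit <- function(x, ...) x$aic

#' @export
glance.demography_fit <- function(x, ...) {
  b <- x$best
  tibble::tibble(epochs = b$epochs,
                 ratio_2 = if (b$epochs >= 2) b$size_ratios[1] else NA_real_,
                 time_2 = if (b$epochs >= 2) b$times[1] else NA_real_,
                 log_lik = b$log_lik, aic = b$aic)
}

# Expected sample spectra on a fixed log grid of Ne*s values (plus gamma=0
# handled by the caller); the most expensive part of a DFE fit, computed
# once per demography.
.dfe_grid_spectra <- function(n, demography, n_ref, gamma_grid) {
  vapply(gamma_grid, function(g)
    expected_sfs(n, gamma = g, demography = demography, n_ref = n_ref),
    numeric(n - 1L))
}

#' Fit a gamma distribution of deleterious fitness effects
#'
#' Maximum-likelihood fit of (shape, mean) of a gamma DFE over `Ne*s` to a
#' selected-site spectrum, with demography fixed from the neutral fit. The
#' gamma is discretized onto a log-spaced `Ne*s` grid; each grid point's
#' expected spectrum comes from the Wright-Fisher engine and the mixture is
#' refit instantly for any (shape, mean). The overall mutation rate is
#' profiled out, so only the spectrum shape is fit.
#'
#' @param selected_sfs An [sfs_spectrum()] of the selected class (0-fold),
#'   with its mutational target `L` set.
#' @param neutral_sfs The neutral reference spectrum with its `L`; the
#'   neutral SNP yield per site calibrates the absolute selected-class
#'   rates, which is what identifies the strongly deleterious mass. If
#'   `NULL`, only the spectrum shape is fit (the DFE mean is then poorly
#'   identified; a warning is issued).
#' @param demography A [demography_model()] or `demography_fit`.
#' @param n_ref Reference Wright-Fisher size (default 100).
#' @param gamma_range,n_grid Log grid of `Ne*s` values (default 200 points
#'   over 1e-4..1e5; strengths whose rescaled `s` exceeds the engine cap
#'   share one spectrum, so the effective cost is lower).
#' @param n_starts Optimizer restarts.
#' @param bin_breaks `Ne*s` bin edges reported from the fitted gamma.
#' @return An object of class `dfe_fit`.
#' @export
fit_dfe <- function(selected_sfs, neutral_sfs = NULL, demography,
                    n_ref = 100, gamma_range = c(1e-4, 1e5), n_grid = 200,
                    n_starts = 4, bin_breaks = c(0, 1, 10, 100, Inf)) {
  stopifnot(inherits(selected_sfs, "sfs"))
  if (inherits(demography, "demography_fit")) demography <- demography$best
  x <- selected_sfs$counts
  n <- selected_sfs$n
  grid <- exp(seq(log(gamma_range[1]), log(gamma_range[2]),
                  length.out = n_grid))
  spectra <- .dfe_grid_spectra(n, demography, n_ref, grid)
  e0 <- coalescent_expected_sfs(n, demography)  # same scale as the spectra
  if (selected_sfs$folded) {
    half <- n %/% 2L
    fold <- function(m) vapply(1:half, function(i)
      if (i == n - i) m[i] else m[i] + m[n - i], numeric(1))
    spectra <- apply(spectra, 2, fold)
    e0 <- fold(e0)
  }
  absolute <- !is.null(neutral_sfs)
  if (absolute) {
    stopifnot(inherits(neutral_sfs, "sfs"), neutral_sfs$n == n,
              is.finite(neutral_sfs$L), is.finite(selected_sfs$L))
    # expected selected SNPs per class, calibrated by the neutral yield:
    # lambda_i = (S_neu / L_neu) * L_sel * mix_i / sum(e0)
    scale_abs <- sum(neutral_sfs$counts) / neutral_sfs$L *
      selected_sfs$L / sum(e0)
  } else {
    warning("no neutral reference: fitting spectrum shape only; ",
            "E[Ne*s] is weakly identified")
  }
  # bin masses of the gamma on the grid (log-midpoint edges); mass beyond
  # the ends goes to the end points
  log_g <- log(grid)
  edges <- c(-Inf, (log_g[-1] + log_g[-n_grid]) / 2, Inf)
  nll <- function(par) {
    shape <- exp(par[1]); mean_g <- exp(par[2])
    if (shape < 0.02 || shape > 5 || mean_g < 1e-3 || mean_g > 1e5)
      return(1e9)
    w <- diff(pgamma(exp(edges), shape = shape, scale = mean_g / shape))
    m <- as.numeric(spectra %*% w)
    if (any(m <= 0) || sum(m) == 0) return(1e9)
    if (absolute) {
      lam <- scale_abs * m
      -sum(x * log(lam) - lam)
    } else {
      -sum(x * log(m / sum(m)))
    }
  }
  starts <- list(c(log(0.3), log(100)), c(log(0.15), log(1000)),
                 c(log(0.6), log(10)), c(log(1), log(1)))
  best <- NULL
  for (st in starts[seq_len(max(1, n_starts))]) {
    f <- tryCatch(optim(st, nll, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  shape <- exp(best$par[1]); mean_g <- exp(best$par[2])
  boundary <- shape <= 0.021 || shape >= 4.9 || mean_g <= 1.1e-3 ||
    mean_g >= 9e4
  if (boundary) warning("DFE optimum pinned at the parameter boundary")
  structure(list(
    shape = shape, mean = mean_g,
    bin_proportions = dfe_bin_proportions(shape, mean_g, bin_breaks),
    log_lik = -best$value, convergence = best$convergence,
    boundary = boundary, demography = demography, n = n,
    folded = selected_sfs$folded,
    grid = grid), class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("<dfe_fit> gamma DFE: shape = %.3f, E[Ne*s] = %.3g\n",
              x$shape, x$mean))
  print(round(x$bin_proportions, 3))
  invisible(x)
}

#' @export
tidy.dfe_fit <- function(x, ...) {
  tibble::tibble(bin = names(x$bin_proportions),
                 proportion = as.numeric(x$bin_proportions))
}

#' @export
glance.dfe_fit <- function(x, ...) {
  tibble::tibble(shape = x$shape, mean_nes = x$mean, log_lik = x$log_lik,
                 boundary = x$boundary, n = x$n, folded = x$folded)
}

#' Polymorphism and divergence table for MK-style tests
#'
#' @param p_n,p_s Nonsynonymous / synonymous polymorphism counts (after any
#'   derived-allele-frequency filter).
#' @param d_n,d_s Divergence counts.
#' @param l_n,l_s Nonsynonymous / synonymous site totals.
#' @return A one-row tibble of class `mk_table`.
#' @export
mk_table <- function(p_n, p_s, d_n, d_s, l_n = NA_real_, l_s = NA_real_) {
  stopifnot(p_n >= 0, p_s >= 0, d_n >= 0, d_s >= 0)
  out <- tibble::tibble(p_n = p_n, p_s = p_s, d_n = d_n, d_s = d_s,
                        l_n = l_n, l_s = l_s)
  class(out) <- c("mk_table", class(out))
  out
}

# dN/dS as a rate ratio when site totals are known, else a count ratio
.dn_ds <- function(tab) {
  if (!is.na(tab$l_n) && !is.na(tab$l_s)) {
    (tab$d_n / tab$l_n) / (tab$d_s / tab$l_s)
  } else tab$d_n / tab$d_s
}

#' DFE-corrected proportion and rate of adaptive substitution
#'
#' Predicts the number of nonsynonymous substitutions contributed by neutral
#' and deleterious mutations from the fitted gamma DFE (expected relative
#' fixation rate integrated over the gamma), and attributes the excess of
#' observed substitutions to positive selection:
#' `alpha = (dN_obs - dN_pred) / dN_obs`, `omega = alpha * (dN/dS)`.
#'
#' @param tab An [mk_table()] with site totals.
#' @param dfe A `dfe_fit` (or a list with `shape` and `mean`).
#' @param n_quad Quadrature points for the gamma expectation.
#' @return A one-row tibble of class `alpha_omega`: `alpha`, `omega`,
#'   `dn_ds`, `mean_relfix`, `method`.
#' @export
alpha_omega <- function(tab, dfe, n_quad = 4000) {
  stopifnot(inherits(tab, "mk_table"))
  if (tab$d_s == 0) stop("dS = 0: alpha undefined")
  q <- qgamma((seq_len(n_quad) - 0.5) / n_quad, shape = dfe$shape,
              scale = dfe$mean / dfe$shape)
  mean_relfix <- mean(relative_fixation_rate(q))
  d_n_pred <- tab$d_s * (tab$l_n / tab$l_s) * mean_relfix
  alpha <- (tab$d_n - d_n_pred) / tab$d_n
  dn_ds <- .dn_ds(tab)
  out <- tibble::tibble(alpha = alpha, omega = alpha * dn_ds, dn_ds = dn_ds,
                        mean_relfix = mean_relfix, method = "dfe-corrected")
  class(out) <- c("alpha_omega", class(out))
  out
}

#' McDonald-Kreitman alpha with a derived-allele-frequency cutoff
#'
#' `alpha = 1 - (pN/pS) / (dN/dS)` after removing polymorphisms with derived
#' allele frequency below `daf_cutoff` (default 15%), which strips most
#' segregating slightly deleterious variants.
#'
#' @param sfs_n,sfs_s Unfolded spectra of the test (nonsynonymous) and
#'   reference (synonymous) classes.
#' @param d_n,d_s Divergence counts.
#' @param daf_cutoff Minimum derived allele frequency retained.
#' @param l_n,l_s Optional site totals (for omega on the rate scale).
#' @return A one-row `alpha_omega` tibble.
#' @export
mk_alpha <- function(sfs_n, sfs_s, d_n, d_s, daf_cutoff = 0.15,
                     l_n = NA_real_, l_s = NA_real_) {
  stopifnot(inherits(sfs_n, "sfs"), inherits(sfs_s, "sfs"),
            !sfs_n$folded, !sfs_s$folded, sfs_n$n == sfs_s$n)
  n <- sfs_n$n
  keep <- (seq_len(n - 1L) / n) >= daf_cutoff
  p_n <- sum(sfs_n$counts[keep]); p_s <- sum(sfs_s$counts[keep])
  tab <- mk_table(p_n, p_s, d_n, d_s, l_n, l_s)
  if (p_s == 0 || d_n == 0) {
    out <- tibble::tibble(alpha = NA_real_, omega = NA_real_,
                          dn_ds = .dn_ds(tab), mean_relfix = NA_real_,
                          method = "mk")
    class(out) <- c("alpha_omega", class(out))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  alpha <- 1 - (p_n / p_s) / (d_n / d_s)
  dn_ds <- .dn_ds(tab)
  out <- tibble::tibble(alpha = alpha, omega = alpha * dn_ds, dn_ds = dn_ds,
                        mean_relfix = NA_real_, method = "mk")
  class(out) <- c("alpha_omega", class(out))
  out
}

#' Asymptotic McDonald-Kreitman estimate of alpha
#'
#' Computes `alpha(x) = 1 - (dS/dN) * (pN(x)/pS(x))` in derived-allele
#' frequency bins and fits `alpha(x) = a + b * exp(-c x)` by nonlinear least
#' squares; the asymptote `alpha(x -> 1) = a + b exp(-c)` removes the
#' contribution of segregating deleterious variants, which are concentrated
#' at low frequency. Falls back to a linear fit when the exponential does
#' not converge.
#'
#' @param sfs_n,sfs_s Unfolded nonsynonymous and synonymous spectra.
#' @param d_n,d_s Divergence counts.
#' @param n_bins Number of equal-width frequency bins on (0, 1).
#' @param fit_range Frequency range used in the fit.
#' @return An object of class `asymp_mk_fit`: coefficients `a`, `b`, `c`,
#'   `alpha_asym`, the per-bin table, and a `fallback` flag.
#' @export
asymptotic_mk <- function(sfs_n, sfs_s, d_n, d_s, n_bins = 20,
                          fit_range = c(0.1, 0.9)) {
  stopifnot(inherits(sfs_n, "sfs"), !sfs_n$folded, sfs_n$n == sfs_s$n)
  n <- sfs_n$n
  x_freq <- seq_len(n - 1L) / n
  bin <- cut(x_freq, breaks = seq(0, 1, length.out = n_bins + 1),
             include.lowest = TRUE)
  tab <- tibble::tibble(bin = bin, x = x_freq, p_n = sfs_n$counts,
                        p_s = sfs_s$counts) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x = mean(.data$x), p_n = sum(.data$p_n),
                     p_s = sum(.data$p_s), .groups = "drop") |>
    dplyr::filter(.data$p_s > 0) |>
    dplyr::mutate(alpha_x = 1 - (d_s / d_n) * (.data$p_n / .data$p_s))
  usable <- dplyr::filter(tab, .data$x >= fit_range[1],
                          .data$x <= fit_range[2])
  if (nrow(usable) < 5) stop("fewer than 5 usable frequency bins")
  fit <- tryCatch(
    minpack.lm::nlsLM(alpha_x ~ a + b * exp(-cc * x), data = usable,
                      start = list(a = utils::tail(usable$alpha_x, 1),
                                   b = usable$alpha_x[1] -
                                     utils::tail(usable$alpha_x, 1),
                                   cc = 5),
                      lower = c(-20, -20, 1e-4), upper = c(20, 20, 500),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    alpha_asym <- cf[["a"]] + cf[["b"]] * exp(-cf[["cc"]])
    out <- list(a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]],
                alpha_asym = alpha_asym, bins = tab, fallback = FALSE,
                fit = fit)
  } else {
    lf <- stats::lm(alpha_x ~ x, data = usable)
    alpha_asym <- sum(stats::coef(lf))
    out <- list(a = stats::coef(lf)[[1]], b = stats::coef(lf)[[2]], c = NA,
                alpha_asym = alpha_asym, bins = tab, fallback = TRUE,
                fit = lf)
  }
  class(out) <- "asymp_mk_fit"
  out
}

#' @export
print.asymp_mk_fit <- function(x, ...) {
  cat(sprintf("<asymp_mk_fit> alpha_asym = %.3f (%s fit)\n", x$alpha_asym,
              if (x$fallback) "linear fallback" else "exponential"))
  invisible(x)
}

#' @export
tidy.asymp_mk_fit <- function(x, ...) x$bins

#' @export
glance.asymp_mk_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, alpha_asym = x$alpha_asym,
                 fallback = x$fallback)
}

#' Block bootstrap over genomic windows
#'
#' Resamples 20-kb (or other) blocks with replacement and recomputes an
#' estimator, giving percentile confidence intervals that respect linkage
#' within blocks.
#'
#' @param data A tibble carrying a block identifier column.
#' @param block Column name of the block identifier (string).
#' @param statistic Function `data -> numeric` (possibly named vector).
#' @param B Number of bootstrap replicates.
#' @param seed Seed.
#' @param conf Confidence level.
#' @return List with `estimate`, `ci` (tibble of lower/upper per statistic),
#'   and the replicate matrix `replicates`.
#' @export
block_bootstrap <- function(data, block, statistic, B = 200, seed = 1,
                            conf = 0.95) {
  blocks <- unique(data[[block]])
  if (length(blocks) < 20) warning("fewer than 20 blocks; CI will be coarse")
  est <- statistic(data)
  set.seed(seed)
  split_idx <- split(seq_len(nrow(data)), data[[block]])
  reps <- replicate(B, {
    bs <- sample(names(split_idx), length(split_idx), replace = TRUE)
    statistic(data[unlist(split_idx[bs], use.names = FALSE), , drop = FALSE])
  })
  reps <- matrix(reps, ncol = B)
  rownames(reps) <- names(est) %||% paste0("stat", seq_len(nrow(reps)))
  a <- (1 - conf) / 2
  ci <- tibble::tibble(
    statistic = rownames(reps),
    estimate = as.numeric(est),
    lower = apply(reps, 1, quantile, probs = a, na.rm = TRUE),
    upper = apply(reps, 1, quantile, probs = 1 - a, na.rm = TRUE))
  list(estimate = est, ci = ci, replicates = reps)
}

#' @importFrom rlang %||% .data
NULL
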