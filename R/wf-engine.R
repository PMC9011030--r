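#' @importFrom stats dbinom dhyper optim optimize rbinom rpois runif rgamma
#'   rexp rmultinom setNames quantile median sd var cor p.adjust wilcox.test
#'   ks.test pgamma qgamma rnorm complete.cases fisher.test na.omit
NULL

# Cache for Wright-Fisher transition matrices keyed by (2N, s); rebuilding a
# 1001x1001 binomial matrix dominates the cost of a demography fit otherwise.
.wf_cache <- new.env(parent = emptyenv())

#' Wright-Fisher transition matrix with semidominant selection
#'
#' Builds the `(2N+1) x (2N+1)` one-generation transition matrix of a
#' Wright-Fisher population of `N` diploids. The derived allele is
#' semidominant with genotype fitnesses `1`, `1 - s/2`, `1 - s` (so `s > 0`
#' is deleterious); the scaled strength `Ne*s` of a mutation is preserved by
#' rescaling `s` when the model population is smaller than the real one.
#'
#' @param two_n Haploid population size `2N`.
#' @param s Selection coefficient against the derived homozygote.
#' @return A dense transition matrix; rows index the current derived-allele
#'   count `0..2N`, columns the next-generation count.
#' @keywords internal
wf_transition_matrix <- function(two_n, s = 0) {
  key <- paste0(two_n, "|", signif(s, 12))
  hit <- .wf_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (0:two_n) / two_n
  if (s == 0) {
    p_next <- p
  } else {
    # marginal fitness of the derived allele over mean fitness
    w_der <- 1 - s / 2 - (s / 2) * p
    w_bar <- 1 - s * p
    p_next <- p * w_der / w_bar
  }
  p_next <- pmin(pmax(p_next, 0), 1)
  m <- outer(p_next, 0:two_n, function(pp, k) dbinom(k, two_n, pp))
  if (length(.wf_cache) > 40) rm(list = ls(.wf_cache), envir = .wf_cache)
  .wf_cache[[key]] <- m
  m
}

#' Piecewise-constant demographic model
#'
#' Epochs are listed from the ancestral population to the present. The
#' ancestral epoch has relative size 1 (the reference size `N1`); each later
#' epoch has a size ratio relative to the ancestral size and a duration in
#' units of `N1` generations.
#'
#' @param size_ratios Relative sizes `N2/N1` (and `N3/N1`) of the epochs
#'   after the ancestral one; `numeric(0)` for a constant-size model.
#' @param times Durations of those epochs in units of `N1` generations
#'   (most ancient first). Must match `size_ratios` in length.
#' @param log_lik,aic Optional fit diagnostics attached by
#'   [fit_demography()].
#' @return An object of class `demography_model`.
#' @export
#' @examples
#' demography_model()                      # constant size
#' demography_model(size_ratios = 5, times = 2)  # 5x expansion, 2*N1 gens ago
demography_model <- function(size_ratios = numeric(0), times = numeric(0),
                             log_lik = NA_real_, aic = NA_real_) {
  stopifnot(length(size_ratios) == length(times),
            all(size_ratios > 0), all(times > 0))
  structure(
    list(epochs = length(size_ratios) + 1L,
         size_ratios = as.numeric(size_ratios),
         times = as.numeric(times),
         log_lik = log_lik, aic = aic),
    class = "demography_model"
  )
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf("<demography_model> %d epoch(s)\n", x$epochs))
  if (x$epochs > 1L) {
    for (k in seq_along(x$size_ratios)) {
      cat(sprintf("  epoch %d: N/N1 = %.3g, duration = %.3g N1 generations\n",
                  k + 1L, x$size_ratios[k], x$times[k]))
    }
  }
  if (is.finite(x$log_lik))
    cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$log_lik, x$aic))
  invisible(x)
}

# Expected number of segregating sites per population-frequency class
# (1..2N_last - 1) under unit per-copy mutation rate, for scaled selection
# gamma = Ne*s, evolved through the demography at reference size n_ref.
wf_population_sfs <- function(gamma = 0, demography = NULL, n_ref = 100) {
  if (is.null(demography)) demography <- demography_model()
  # |s| capped below 1 so genotype fitnesses stay positive; mutations this
  # strongly selected contribute essentially nothing to polymorphism anyway
  s <- sign(gamma) * min(abs(gamma) / n_ref, 0.9)
  two_n1 <- 2L * as.integer(n_ref)
  m1 <- wf_transition_matrix(two_n1, s)
  q1 <- m1[2:two_n1, 2:two_n1]
  # stationary expected counts: influx of 2*N1 new mutations per generation
  g <- solve(t(diag(two_n1 - 1L) - q1), c(two_n1, rep(0, two_n1 - 2L)))
  g <- as.numeric(g)
  two_n_prev <- two_n1
  if (demography$epochs > 1L) {
    for (k in seq_along(demography$size_ratios)) {
      two_nk <- max(4L, round(2 * n_ref * demography$size_ratios[k]))
      sk <- sign(gamma) * min(abs(gamma) / n_ref, 0.9)
      mk <- wf_transition_matrix(two_nk, sk)
      qk <- mk[2:two_nk, 2:two_nk]
      if (two_nk != two_n_prev) {
        # instantaneous size change: counts resampled binomially at equal
        # frequency (one WF generation at the new size)
        p_prev <- (1:(two_n_prev - 1L)) / two_n_prev
        bmap <- outer(p_prev, 1:(two_nk - 1L),
                      function(pp, j) dbinom(j, two_nk, pp))
        g <- as.numeric(g %*% bmap)
      }
      gens <- max(1L, round(demography$times[k] * n_ref))
      influx <- c(two_nk, rep(0, two_nk - 2L))
      for (t in seq_len(gens)) g <- as.numeric(g %*% qk) + influx
      two_n_prev <- two_nk
    }
  }
  list(g = g, two_n = two_n_prev)
}

#' Expected site frequency spectrum under selection and demography
#'
#' Computes the expected unfolded sample SFS (relative intensities per
#' derived-allele count `1..n-1`) for new mutations of scaled selection
#' strength `gamma = Ne*s`, by evolving the full population frequency
#' distribution of a Wright-Fisher model at reference size `n_ref` through
#' the given demography and binomially sampling down to `n` chromosomes.
#'
#' @param n Haploid sample size.
#' @param gamma Scaled selection coefficient `Ne*s` (positive = deleterious,
#'   0 = neutral, negative = beneficial).
#' @param demography A [demography_model()]; `NULL` for constant size.
#' @param n_ref Reference diploid population size of the model (selection and
#'   time are rescaled so that `Ne*s` and times in `N1` generations are
#'   preserved).
#' @param include_fixed Also return the class `i = n` (derived fixed in the
#'   sample but still segregating in the population).
#' @return Numeric vector of expected relative counts, names `1..n-1`
#'   (or `1..n`).
#' @export
#' @examples
#' e <- expected_sfs(10)
#' round(e / e[1], 3)  # close to 1, 1/2, 1/3, ... under neutrality
expected_sfs <- function(n, gamma = 0, demography = NULL, n_ref = 100,
                         include_fixed = FALSE) {
  stopifnot(n >= 2, n <= 2 * n_ref)
  i_max <- if (include_fixed) n else n - 1L
  constant <- is.null(demography) || demography$epochs == 1L
  if (gamma == 0) {
    out <- coalescent_expected_sfs(n, demography)
  } else if (constant) {
    out <- prf_expected_sfs(n, gamma)
  } else {
    # demographic modulation from the Wright-Fisher engine, anchored
    # class-wise to the exact constant-size PRF solution (cancels the
    # discrete chain's large-s and boundary bias):
    # out = W(g, demog) * [PRF_c(g) / W(g, const)]
    #       * [coal(demog) / W(0, demog)] * [W(0, const) / coal(const)]
    w_d <- .wf_raw_sfs(n, gamma, demography, n_ref)
    w_c <- .wf_raw_sfs(n, gamma, NULL, n_ref)
    w0_d <- .wf_raw_sfs(n, 0, demography, n_ref)
    w0_c <- .wf_raw_sfs(n, 0, NULL, n_ref)
    p_c <- prf_expected_sfs(n, gamma)
    coal_d <- coalescent_expected_sfs(n, demography)
    coal_c <- coalescent_expected_sfs(n, NULL)
    out <- w_d * ifelse(w_c > 0, p_c / w_c, 0) *
      (coal_d / w0_d) * (w0_c / coal_c)
  }
  out <- c(out, out[n - 1L] / 2)[1:i_max]  # crude i = n extension
  names(out) <- 1:i_max
  out
}

# Raw (uncorrected) engine sample spectrum, cached
.wf_raw_sfs <- function(n, gamma, demography, n_ref) {
  key <- paste0("raw|", n, "|", signif(gamma, 10), "|", n_ref, "|",
                .demog_key(demography))
  hit <- .wf_cache[[key]]
  if (!is.null(hit)) return(hit)
  pop <- wf_population_sfs(gamma, demography, n_ref)
  p <- (1:(pop$two_n - 1L)) / pop$two_n
  samp <- outer(1:(n - 1L), p, function(i, pp) dbinom(i, n, pp))
  out <- as.numeric(samp %*% pop$g)
  .wf_cache[[key]] <- out
  out
}

#' Exact expected SFS of selected mutations at constant size
#'
#' Poisson-random-field result: the expected number of segregating sites at
#' derived count `i` is proportional to the diffusion sojourn density of a
#' new semidominant mutation with scaled strength `gamma = Ne*s`
#' (deleterious positive), integrated against binomial sampling:
#' `E[xi_i] ~ int tau(x; gamma) C(n,i) x^i (1-x)^(n-i) dx` with
#' `tau(x) = 2 exp(-2 g x) (1 - exp(-2 g (1-x))) / (x (1-x) (1 - exp(-2 g)))`.
#' Scale matches [coalescent_expected_sfs()] (neutral limit = `2/i`-based).
#'
#' @inheritParams expected_sfs
#' @return Numeric vector over classes `1..n-1`.
#' @export
prf_expected_sfs <- function(n, gamma) {
  key <- paste0("prf|", n, "|", signif(gamma, 10))
  hit <- .wf_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- gamma
  tau <- function(x) {
    if (abs(g) < 1e-8) return(2 / x)
    2 * exp(-2 * g * x) * (-expm1(-2 * g * (1 - x))) /
      (x * (1 - x) * (-expm1(-2 * g)))
  }
  upper <- if (g > 30) min(1, 40 / g) else 1
  out <- vapply(1:(n - 1L), function(i) {
    v <- tryCatch(
      stats::integrate(function(x) tau(x) * dbinom(i, n, x),
                       0, upper, rel.tol = 1e-9, subdivisions = 500L,
                       stop.on.error = FALSE)$value,
      error = function(e) 0)
    max(v, 0)
  }, numeric(1))
  .wf_cache[[key]] <- out
  out
}

#' Exact neutral expected SFS under piecewise-constant demography
#'
#' Classical coalescent result: the expected unfolded spectrum is
#' `E[xi_i] = theta/2 * sum_k k E[T_k] P(i | k)` where `E[T_k]` is the
#' expected time during which `k` ancestral lineages exist and
#' `P(i | k) = C(n-i-1, k-2) / C(n-1, k-1)` is the probability that a branch
#' carrying `k` of the sample's lineages subtends `i` leaves. `E[T_k]` is
#' integrated exactly through the epochs with matrix exponentials of the
#' lineage-death process.
#'
#' @inheritParams expected_sfs
#' @return Relative expected counts for classes `1..n-1` (theta-free scale).
#' @export
coalescent_expected_sfs <- function(n, demography = NULL) {
  tk <- expected_coalescent_times(n, demography)
  k <- 2:n
  lw <- outer(1:(n - 1), k, function(i, kk)
    lchoose(n - i - 1, kk - 2) - lchoose(n - 1, kk - 1))
  as.numeric(exp(lw) %*% (k * tk))
}

#' Expected time with k ancestral lineages
#'
#' @inheritParams expected_sfs
#' @return Numeric vector `E[T_k]` for `k = 2..n`, in units of `2*N1`
#'   generations.
#' @export
expected_coalescent_times <- function(n, demography = NULL) {
  key <- paste0("ect|", n, "|", .demog_key(demography))
  hit <- .wf_cache[[key]]
  if (!is.null(hit)) return(hit)
  epochs <- .backward_epochs(demography)
  m <- n - 1L                       # states k = n..2
  rates <- (n:2) * ((n:2) - 1) / 2  # per unit size-1 time
  p <- c(1, rep(0, m - 1L))         # start with n lineages
  tk <- numeric(m)
  t_prev <- 0
  for (ep in seq_along(epochs$sizes)) {
    nu <- epochs$sizes[ep]
    if (is.finite(epochs$ends[ep])) {
      dt <- epochs$ends[ep] - t_prev
      # generator of the death chain, augmented to accumulate occupancy time
      q <- matrix(0, m, m)
      diag(q) <- -rates / nu
      q[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)] <- rates[-m] / nu
      aug <- rbind(cbind(q, diag(m)), matrix(0, m, 2 * m))
      e_aug <- as.matrix(Matrix::expm(Matrix::Matrix(aug * dt)))
      tk <- tk + as.numeric(p %*% e_aug[seq_len(m), m + seq_len(m)])
      p <- as.numeric(p %*% e_aug[seq_len(m), seq_len(m)])
      t_prev <- epochs$ends[ep]
    } else {
      # final infinite epoch: a death chain visits every state below its
      # start, spending nu / rate_k in each on average
      below <- outer(seq_len(m), seq_len(m), "<=")  # state j reaches state k
      tk <- tk + as.numeric((p %*% below)) * nu / rates
    }
  }
  out <- rev(tk)  # reorder to k = 2..n
  .wf_cache[[key]] <- out
  out
}

.demog_key <- function(demography) {
  if (is.null(demography) || demography$epochs == 1L) return("const")
  paste(signif(c(demography$size_ratios, demography$times), 10),
        collapse = ",")
}


#' Relative fixation rate of selected mutations
#'
#' Probability of fixation of a new semidominant mutation with scaled
#' strength `gamma = Ne*s`, relative to a neutral mutation, from standard
#' diffusion theory: `2*gamma / (exp(2*gamma) - 1)` for deleterious
#' mutations (`gamma > 0`).
#'
#' @param gamma Scaled selection coefficient `Ne*s` (deleterious positive).
#' @return Relative fixation rate in `[0, Inf)`; 1 at `gamma = 0`.
#' @export
relative_fixation_rate <- function(gamma) {
  out <- ifelse(abs(gamma) < 1e-8, 1 - gamma,
                2 * gamma / expm1(2 * gamma))
  # beneficial (gamma < 0): 2|gamma|/(1 - exp(-2|gamma|)) > 1
  as.numeric(out)
}
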