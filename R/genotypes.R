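#' Genotype matrix container
#'
#' Light S3 container for a biallelic SNP callset: a sites tibble plus
#' integer matrices of genotype dosage and depths. All user-facing
#' summaries are tibbles; the matrices stay matrices for scale.
#'
#' @param sites Tibble `chrom`, `pos`, `ref`, `alt` (single bases).
#' @param gt Integer matrix sites x individuals (alternate-allele dosage
#'   0/1/2, `NA` missing).
#' @param dp,ad_ref,ad_alt Matching depth matrices (may be `NULL`).
#' @param samples Tibble `id`, `group`, `f` (per-individual inbreeding
#'   coefficient, may be `NA`).
#' @param log Named integer vector of record-drop counters.
#' @return Object of class `geno`.
#' @export
geno_matrix <- function(sites, gt, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                        samples = NULL, log = integer(0)) {
  stopifnot(nrow(sites) == nrow(gt), all(sites$pos >= 1))
  if (is.null(samples)) {
    samples <- tibble::tibble(id = colnames(gt) %||%
                                paste0("s", seq_len(ncol(gt))),
                              group = NA_character_, f = NA_real_)
  }
  stopifnot(nrow(samples) == ncol(gt))
  structure(list(sites = sites, gt = gt, dp = dp, ad_ref = ad_ref,
                 ad_alt = ad_alt, samples = samples, log = log),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d sites x %d individuals", nrow(x$gt), ncol(x$gt)))
  if (!all(is.na(x$samples$group)))
    cat(" |", paste(sprintf("%s:%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = " "))
  cat("\n")
  if (length(x$log)) {
    cat("  drops:", paste(names(x$log), x$log, sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a biallelic SNP VCF
#'
#' Loads a VCF (v4.x with GT, DP, AD), drops multiallelic and indel
#' records with counters, and attaches group labels from a two-column
#' table.
#'
#' @param path VCF file.
#' @param group_table Optional tibble or TSV path with columns `sample`,
#'   `group` (and optionally `f`). Unknown sample ids raise an error.
#' @return A [geno_matrix()].
#' @export
load_vcf <- function(path, group_table = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alt <- fix$ALT %||% character(0)
  multi <- grepl(",", alt)
  indel <- nchar(fix$REF) != 1 | (nchar(alt) != 1 & !multi)
  keep <- !multi & !indel
  log <- c(multiallelic = sum(multi), indel = sum(indel & !multi))
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt_chr <- vcfR::extract.gt(v, "GT")
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
               dimnames = dimnames(gt_chr))
  gt[gt_chr %in% c("0/0", "0|0")] <- 0L
  gt[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_chr %in% c("1/1", "1|1")] <- 2L
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, "AD")
  ad_ref <- suppressWarnings(
    matrix(as.integer(sub(",.*", "", ad)), nrow(ad), ncol(ad)))
  ad_alt <- suppressWarnings(
    matrix(as.integer(sub(".*,", "", ad)), nrow(ad), ncol(ad)))
  sites <- tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT)
  samples <- tibble::tibble(id = colnames(gt), group = NA_character_,
                            f = NA_real_)
  if (!is.null(group_table)) {
    if (is.character(group_table)) group_table <- read_group_table(group_table)
    miss <- setdiff(samples$id, group_table$sample)
    if (length(miss) > 0)
      stop("sample ids missing from group table: ",
           paste(miss, collapse = ", "))
    m <- match(samples$id, group_table$sample)
    samples$group <- group_table$group[m]
    if ("f" %in% names(group_table)) samples$f <- group_table$f[m]
  }
  geno_matrix(sites, gt, dp, ad_ref, ad_alt, samples, log)
}

#' @rdname load_vcf
#' @param x A `geno` object.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples$id), collapse = "\t"))
  gt_str <- matrix("./.", nrow(x$gt), ncol(x$gt))
  gt_str[x$gt == 0L & !is.na(x$gt)] <- "0/0"
  gt_str[x$gt == 1L & !is.na(x$gt)] <- "0/1"
  gt_str[x$gt == 2L & !is.na(x$gt)] <- "1/1"
  fmt_int <- function(m) {
    if (is.null(m)) return(matrix(".", nrow(x$gt), ncol(x$gt)))
    out <- matrix(".", nrow(m), ncol(m))
    out[!is.na(m)] <- as.character(as.integer(m[!is.na(m)]))
    out
  }
  dp_str <- fmt_int(x$dp)
  ad_str <- matrix(".", nrow(x$gt), ncol(x$gt))
  if (!is.null(x$ad_ref) && !is.null(x$ad_alt)) {
    ok <- !is.na(x$ad_ref) & !is.na(x$ad_alt)
    ad_str[ok] <- paste0(x$ad_ref[ok], ",", x$ad_alt[ok])
  }
  cells <- matrix(paste(gt_str, dp_str, ad_str, sep = ":"),
                  nrow(x$gt), ncol(x$gt))
  body <- vapply(seq_len(nrow(x$gt)), function(i) {
    paste(c(x$sites$chrom[i], x$sites$pos[i], ".", x$sites$ref[i],
            x$sites$alt[i], ".", "PASS", ".", "GT:DP:AD", cells[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname load_vcf
#' @export
read_group_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("sample", "group")
  tibble::as_tibble(tab)
}

#' Mask unreliable genotype calls
#'
#' Per-genotype filters of a low-coverage selfing callset: homozygous
#' calls with depth < 2 are set missing; heterozygous calls with depth
#' < 20, with minor/major allelic-depth ratio < 0.25, or without AD are
#' set missing.
#'
#' @param x A `geno` object with depths.
#' @param hom_min_dp,het_min_dp,het_min_ratio Thresholds (strict `<`).
#' @return The masked `geno`; masking counts appended to `$log`.
#' @export
mask_genotypes <- function(x, hom_min_dp = 2, het_min_dp = 20,
                           het_min_ratio = 0.25) {
  stopifnot(inherits(x, "geno"), !is.null(x$dp))
  gt <- x$gt
  hom <- !is.na(gt) & gt != 1L
  het <- !is.na(gt) & gt == 1L
  dp <- x$dp
  m_hom <- hom & (!is.na(dp) & dp < hom_min_dp)
  m_het_dp <- het & (!is.na(dp) & dp < het_min_dp)
  if (!is.null(x$ad_ref) && !is.null(x$ad_alt)) {
    ad_ok <- !is.na(x$ad_ref) & !is.na(x$ad_alt) &
      (x$ad_ref + x$ad_alt) > 0
    ratio <- pmin(x$ad_ref, x$ad_alt) / pmax(x$ad_ref, x$ad_alt, 1)
    m_het_ratio <- het & ((ad_ok & ratio < het_min_ratio) | !ad_ok)
    n_missing_ad <- sum(het & !ad_ok)
  } else {
    m_het_ratio <- het  # no AD at all: every het fails the ratio test
    n_missing_ad <- sum(het)
  }
  gt[m_hom | m_het_dp | m_het_ratio] <- NA_integer_
  x$gt <- gt
  x$log <- c(x$log, mask_hom_dp = sum(m_hom),
             mask_het_dp = sum(m_het_dp & !m_hom),
             mask_het_ratio = sum(m_het_ratio & !m_het_dp),
             het_missing_ad = n_missing_ad)
  x
}

#' Site-level filters
#'
#' Drops sites genotyped in fewer than half the individuals, with mean
#' depth of 20 or more, with 15% or more heterozygous calls (among called
#' genotypes), or overlapping repeat intervals. Thresholds are strict on
#' the retained side, matching the genotype filters.
#'
#' @param x A `geno` object (masking already applied).
#' @param repeats Optional repeat intervals tibble (`chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param min_call_frac,max_mean_dp,max_het_frac Thresholds.
#' @return Filtered `geno` with per-rule drop counts in `$log`.
#' @export
filter_sites <- function(x, repeats = NULL, min_call_frac = 0.5,
                         max_mean_dp = 20, max_het_frac = 0.15) {
  stopifnot(inherits(x, "geno"))
  n_ind <- ncol(x$gt)
  called <- rowSums(!is.na(x$gt))
  call_ok <- called >= min_call_frac * n_ind
  dp_ok <- if (!is.null(x$dp)) {
    md <- rowMeans(x$dp, na.rm = TRUE)
    is.na(md) | md < max_mean_dp
  } else rep(TRUE, nrow(x$gt))
  het_frac <- rowSums(x$gt == 1L, na.rm = TRUE) / pmax(called, 1)
  het_ok <- het_frac < max_het_frac
  rep_ok <- rep(TRUE, nrow(x$gt))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    for (r in seq_len(nrow(repeats))) {
      hit <- x$sites$chrom == repeats$chrom[r] &
        x$sites$pos >= repeats$start[r] & x$sites$pos <= repeats$end[r]
      rep_ok[hit] <- FALSE
    }
  }
  keep <- call_ok & dp_ok & het_ok & rep_ok
  drops <- c(low_call_rate = sum(!call_ok),
             high_mean_depth = sum(call_ok & !dp_ok),
             high_het = sum(call_ok & dp_ok & !het_ok),
             repeat_region = sum(call_ok & dp_ok & het_ok & !rep_ok))
  if (!any(keep)) warning("no site passed the filters")
  out <- x
  out$sites <- x$sites[keep, , drop = FALSE]
  for (f in c("gt", "dp", "ad_ref", "ad_alt")) {
    if (!is.null(x[[f]])) out[[f]] <- x[[f]][keep, , drop = FALSE]
  }
  out$log <- c(x$log, drops)
  out
}

#' Haploidize diploid genotypes
#'
#' One allele per individual per site: homozygotes deterministically,
#' heterozygotes by a seeded uniform draw, missing stays missing. The
#' standard reduction for a predominantly selfing species in place of
#' statistical phasing.
#'
#' @param x A `geno` object or dosage matrix (0/1/2/`NA`).
#' @param seed Seed for the heterozygote draws.
#' @return Integer haplotype matrix (0/1/`NA`), sites x individuals.
#' @export
haploidize <- function(x, seed = 1) {
  gt <- if (inherits(x, "geno")) x$gt else x
  set.seed(seed)
  hap <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  hap[gt == 0L] <- 0L
  hap[gt == 2L] <- 1L
  het <- which(gt == 1L)
  hap[het] <- sample(0:1, length(het), replace = TRUE)
  hap
}

#' Turn simulated polymorphism into a genotype callset
#'
#' Adds ref/alt alleles and synthetic read depths (Poisson around
#' `mean_depth`, binomial allele split for heterozygotes) to a
#' `sim_output`, yielding a `geno` object the filtering stack can consume.
#'
#' @param sim A `sim_output`.
#' @param mean_depth Mean per-genotype depth (default 4.5, the depth scale
#'   of the low-coverage callset the defaults emulate).
#' @param seed Seed.
#' @return A [geno_matrix()].
#' @export
sim_genotype_calls <- function(sim, mean_depth = 4.5, seed = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  set.seed(if (is.null(seed)) child_seed(sim$config$seed, "calls")
           else seed)
  bases <- c("A", "C", "G", "T")
  n_s <- nrow(sim$genotypes); n_i <- ncol(sim$genotypes)
  ref <- sample(bases, n_s, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  dp <- matrix(rpois(n_s * n_i, mean_depth), n_s, n_i)
  gt <- sim$genotypes
  ad_alt <- matrix(0L, n_s, n_i)
  ad_alt[gt == 2L] <- dp[gt == 2L]
  het <- which(gt == 1L)
  ad_alt[het] <- rbinom(length(het), dp[het], 0.5)
  ad_ref <- dp - ad_alt
  gt[dp == 0L] <- NA_integer_
  sites <- tibble::tibble(chrom = sim$sites$chrom, pos = sim$sites$pos,
                          ref = ref, alt = alt)
  samples <- tibble::tibble(id = sim$individuals$id,
                            group = sim$individuals$group,
                            f = sim$individuals$f)
  geno_matrix(sites, gt, dp, ad_ref, ad_alt, samples)
}

#' @importFrom stats rbinom
NULL
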