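#' Read / write a minimal MAF alignment
#'
#' One alignment block per file section, as produced by the package's own
#' simulator: rows `s <species>.<chrom> <start> <size> <strand> <srcSize>
#' <aligned sequence>`. Returns the alignment as a character matrix
#' (species x columns).
#'
#' @param path MAF file.
#' @return List: `aln` (character matrix, rownames = species), `ref`
#'   (first species), `ref_start` (0-based start on the reference).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  s <- grep("^s ", lines, value = TRUE)
  if (length(s) == 0) stop("no alignment rows in ", path)
  parts <- strsplit(trimws(sub("^s +", "", s)), " +")
  sp <- vapply(parts, function(p) sub("\\..*$", "", p[1]), character(1))
  seqs <- vapply(parts, function(p) p[6], character(1))
  if (length(unique(nchar(seqs))) != 1) stop("ragged alignment block")
  aln <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(aln) <- sp
  list(aln = aln, ref = sp[1],
       ref_start = as.integer(parts[[1]][2]))
}

#' @rdname read_maf
#' @param aln Character matrix (species x columns).
#' @param ref_start 0-based start coordinate of the reference row.
#' @export
write_maf <- function(aln, path, ref_start = 0) {
  n <- ncol(aln)
  rows <- vapply(rownames(aln), function(sp) {
    seqv <- paste(aln[sp, ], collapse = "")
    size <- sum(aln[sp, ] != "-")
    sprintf("s %s.chr1 %d %d + %d %s", sp, ref_start, size, size, seqv)
  }, character(1))
  writeLines(c("##maf version=1", "a score=0", rows, ""), path)
  invisible(path)
}

#' Calibrate a neutral tree on 4-fold degenerate columns
#'
#' Builds the species topology by neighbor joining on Jukes-Cantor
#' distances and then optimizes branch lengths by maximum likelihood under
#' JC, using only the supplied (putatively neutral) 4-fold columns. Branch
#' lengths are in expected substitutions per site, so their sum is the
#' neutral expectation entering the constraint score.
#'
#' @param aln Character matrix (species x columns).
#' @param fourfold_idx Column indices of 4-fold degenerate sites.
#' @param min_columns Minimum usable columns (default 1000).
#' @return An `ape::phylo` tree with ML branch lengths.
#' @export
calibrate_neutral_tree <- function(aln, fourfold_idx = seq_len(ncol(aln)),
                                   min_columns = 1000) {
  if (nrow(aln) < 3) stop("need at least 3 aligned species")
  cols <- aln[, fourfold_idx, drop = FALSE]
  keep <- colSums(cols == "-" | cols == "N") == 0
  cols <- cols[, keep, drop = FALSE]
  if (ncol(cols) < min_columns)
    stop("only ", ncol(cols), " usable 4-fold columns (need ",
         min_columns, ")")
  ph <- phangorn::phyDat(cols, type = "DNA")
  dm <- phangorn::dist.ml(ph, model = "JC69")
  tree <- ape::nj(dm)
  tree$edge.length[tree$edge.length < 0] <- 1e-8
  fit <- phangorn::pml(tree, ph)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, control =
                               phangorn::pml.control(trace = 0))
  fit$tree
}

# JC transition probability matrix for branch length t (expected
# substitutions per site)
.jc_p <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

# Felsenstein pruning log-likelihood of many columns at once for a given
# rate multiplier; lik[[node]] is a 4 x ncol matrix.
.jc_loglik_cols <- function(tree, base_idx, r) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ncols <- ncol(base_idx)
  lik <- vector("list", n_node)
  for (tip in seq_len(n_tip)) {
    m <- matrix(0, 4, ncols)
    b <- base_idx[tip, ]
    known <- !is.na(b)
    m[, !known] <- 1
    m[cbind(b[known], which(known))] <- 1
    lik[[tip]] <- m
  }
  ord <- rev(ape::postorder(tree))
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  lens <- tree$edge.length[ape::postorder(tree)]
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    p <- .jc_p(lens[e] * r)
    contrib <- p %*% lik[[child]]
    if (is.null(lik[[parent]])) lik[[parent]] <- contrib
    else lik[[parent]] <- lik[[parent]] * contrib
  }
  root <- n_tip + 1L
  log(colSums(lik[[root]] * 0.25))
}

#' GERP-style rejected-substitution scores
#'
#' For every alignment column, `RS = E - O`: `E` is the neutral tree length
#' restricted to the species present (gap species contribute nothing), and
#' `O = r_hat * E` where `r_hat` is the ML rate multiplier of the column
#' under Jukes-Cantor on the same pruned tree (`r_hat` searched on a grid
#' over `[0, r_max]`). Invariant columns give `RS = E`; columns evolving at
#' the neutral rate average `RS ~ 0`. All-gap or single-species columns are
#' `NA`.
#'
#' @param aln Character matrix (species x columns), reference species in
#'   `ref` (columns where the reference is gapped are skipped).
#' @param tree Calibrated neutral tree ([calibrate_neutral_tree()]).
#' @param ref Reference species name (default first row).
#' @param r_max Upper bound of the rate multiplier (default 4).
#' @param n_grid Rate-grid resolution (default 40, log-spaced plus 0).
#' @return Tibble with `col` (alignment column), `ref_pos` (1-based
#'   position on the ungapped reference), `e`, `o`, `rs`.
#' @export
rs_score <- function(aln, tree, ref = rownames(aln)[1], r_max = 4,
                     n_grid = 40) {
  stopifnot(ref %in% rownames(aln), ref %in% tree$tip.label)
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ref_gap <- aln[ref, ] == "-"
  ref_pos <- cumsum(!ref_gap)
  use_col <- which(!ref_gap)
  # group columns by their gap pattern: each pattern has its own pruned tree
  gm <- aln[, use_col, drop = FALSE] == "-"
  gap_pat <- apply(gm, 2, function(z) paste0(as.integer(z), collapse = ""))
  r_grid <- c(0, exp(seq(log(0.01), log(r_max), length.out = n_grid - 1)))
  out <- vector("list", length(unique(gap_pat)))
  pi <- 0L
  for (pat in unique(gap_pat)) {
    sel <- use_col[gap_pat == pat]
    present <- rownames(aln)[strsplit(pat, "")[[1]] == "0"]
    pi <- pi + 1L
    if (length(present) < 2) {
      out[[pi]] <- tibble::tibble(col = sel, ref_pos = ref_pos[sel],
                                  e = NA_real_, o = NA_real_, rs = NA_real_)
      next
    }
    sub_tree <- ape::keep.tip(tree, present)
    e_val <- sum(sub_tree$edge.length)
    bi <- matrix(base_code[aln[present, sel, drop = FALSE]],
                 nrow = length(present))
    ll <- vapply(r_grid, function(r) .jc_loglik_cols(sub_tree, bi, r),
                 numeric(length(sel)))
    ll <- matrix(ll, nrow = length(sel))
    r_hat <- r_grid[max.col(ll, ties.method = "first")]
    out[[pi]] <- tibble::tibble(col = sel, ref_pos = ref_pos[sel],
                                e = e_val, o = r_hat * e_val,
                                rs = e_val * (1 - r_hat))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$col)
}

# Maximum-sum contiguous interval of x; ties broken by minimal length,
# then minimal start. Returns c(start, end, sum) or NULL if all values
# yield sum below -Inf guard.
.max_subarray <- function(x) {
  best_sum <- -Inf; best <- NULL
  cur_sum <- 0; cur_start <- 1L
  for (i in seq_along(x)) {
    if (cur_sum <= 0) { cur_sum <- x[i]; cur_start <- i }
    else cur_sum <- cur_sum + x[i]
    if (cur_sum > best_sum) {
      best_sum <- cur_sum; best <- c(cur_start, i)
    }
  }
  if (is.null(best)) return(NULL)
  c(best, best_sum)
}

#' Conserved segments from an RS track
#'
#' Iteratively extracts the maximum-scoring contiguous interval while its
#' cumulative RS reaches `threshold`, removing each accepted interval and
#' recursing into the flanks; segments of length 12 or shorter are
#' discarded (the retained set has length > 12).
#'
#' @param rs Numeric RS values along a contig (NA treated as 0).
#' @param threshold Minimum cumulative penalized RS; default twice the
#'   robust per-site RS spread (`2 * mad(rs)`), standing in for twice the
#'   neutral RS standard deviation.
#' @param penalty Per-site drift penalty subtracted before extraction
#'   (default `0.3 * mad(rs)`). Without it the neutral background has
#'   near-zero drift and maximal segments bridge across distinct
#'   conserved tracts; the penalty makes neutral stretches clearly
#'   score-negative so segments split at them. Set 0 to disable.
#' @param min_len Minimum retained length is `min_len` (strictly greater
#'   than 12 by default).
#' @param offset Coordinate of the first track position minus 1 (reported
#'   intervals are `offset + start/end`, 1-based inclusive).
#' @return Tibble: `start`, `end`, `length`, `score` (penalized cumulative
#'   RS), `mean_rs` (penalized per-site mean), ordered by position.
#' @export
find_segments <- function(rs, threshold = NULL, penalty = NULL,
                          min_len = 13L, offset = 0) {
  rs[is.na(rs)] <- 0
  if (is.null(threshold)) threshold <- 2 * stats::mad(rs)
  if (is.null(penalty)) penalty <- 0.3 * stats::mad(rs)
  rs <- rs - penalty
  acc <- list()
  recurse <- function(lo, hi) {
    if (hi < lo) return()
    seg <- .max_subarray(rs[lo:hi])
    if (is.null(seg) || seg[3] < threshold) return()
    s <- lo + seg[1] - 1L; e <- lo + seg[2] - 1L
    acc[[length(acc) + 1L]] <<- c(s, e, seg[3])
    recurse(lo, s - 1L)
    recurse(e + 1L, hi)
  }
  recurse(1L, length(rs))
  if (length(acc) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), score = numeric(0),
                          mean_rs = numeric(0)))
  }
  m <- do.call(rbind, acc)
  out <- tibble::tibble(start = as.integer(m[, 1] + offset),
                        end = as.integer(m[, 2] + offset),
                        length = as.integer(m[, 2] - m[, 1] + 1),
                        score = m[, 3],
                        mean_rs = m[, 3] / (m[, 2] - m[, 1] + 1))
  out <- dplyr::filter(out, .data$length >= min_len)
  dplyr::arrange(out, .data$start)
}

#' Split conserved segments by genomic category
#'
#' Intersects each segment with the annotation categories (CDS, UTRs,
#' intron margins/centers, intergenic) and keeps sub-segments longer than
#' 12 bp. The non-coding sub-segments are the conserved non-coding
#' sequences (CNS).
#'
#' @param segments Tibble from [find_segments()] with `start`, `end`, plus
#'   a `chrom` column (added if absent).
#' @param features Annotation feature tibble (see [classify_category()]).
#' @param chrom Chromosome of the track when `segments` has no `chrom`.
#' @param min_len Minimum retained sub-segment length (`> 12` bp default).
#' @return Tibble: `chrom`, `start`, `end`, `length`, `category`,
#'   `coding` (logical).
#' @export
split_by_category <- function(segments, features, chrom = "chr1",
                              min_len = 13L) {
  if (!"chrom" %in% names(segments)) segments$chrom <- chrom
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    pos <- segments$start[i]:segments$end[i]
    cls <- classify_category(
      tibble::tibble(chrom = segments$chrom[i], pos = pos), features)
    runs <- rle(cls$category)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    tibble::tibble(chrom = segments$chrom[i],
                   start = pos[starts], end = pos[ends],
                   length = runs$lengths, category = runs$values)
  }) |>
    dplyr::filter(.data$length >= min_len) |>
    dplyr::mutate(coding = .data$category == "CDS")
}
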