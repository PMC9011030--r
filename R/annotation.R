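#' Read a GFF3 gene annotation into a tidy feature table
#'
#' Thin wrapper over [ape::read.gff()] that normalizes the columns the
#' package uses and derives intron intervals from each transcript's exons.
#' Coordinates stay 1-based inclusive, as in the file.
#'
#' @param path GFF3 file.
#' @return Tibble: `chrom`, `source`, `type`, `start`, `end`, `strand`,
#'   `phase`, `id`, `parent`; introns appear as derived `intron` rows.
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path)
  id <- sub("ID=", "", regmatches(g$attributes,
                                  regexpr("ID=[^;]*", g$attributes)))
  ids <- rep(NA_character_, nrow(g))
  ids[grepl("ID=", g$attributes)] <- id
  par <- rep(NA_character_, nrow(g))
  pm <- regexpr("Parent=[^;]*", g$attributes)
  par[pm > 0] <- sub("Parent=", "", regmatches(g$attributes, pm))
  out <- tibble::tibble(chrom = as.character(g$seqid),
                        source = as.character(g$source),
                        type = as.character(g$type),
                        start = g$start, end = g$end,
                        strand = as.character(g$strand),
                        phase = suppressWarnings(as.integer(as.character(g$phase))),
                        id = ids, parent = par)
  if (!any(out$type == "intron")) out <- dplyr::bind_rows(out, derive_introns(out))
  out
}

#' Derive intron intervals from exon rows
#'
#' @param features Feature tibble with `type == "exon"` rows carrying a
#'   `parent` transcript id.
#' @return Tibble of `intron` rows (empty if no multi-exon transcript).
#' @export
derive_introns <- function(features) {
  ex <- dplyr::filter(features, .data$type == "exon", !is.na(.data$parent))
  if (nrow(ex) == 0) return(ex[0, ])
  ex |>
    dplyr::group_by(.data$parent, .data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(intron_start = utils::head(.data$end, -1) + 1,
                   intron_end = utils::tail(.data$start, -1) - 1) |>
    dplyr::rename(start = "intron_start", end = "intron_end") |>
    dplyr::filter(.data$end >= .data$start) |>
    dplyr::mutate(type = "intron", source = "derived", phase = NA_integer_,
                  id = NA_character_)
}

# Degeneracy of each codon position under the standard genetic code:
# deg[codon, pos] = number of bases (of 4) leaving the amino acid unchanged.
.degeneracy_table <- function() {
  hit <- .wf_cache[["degtab"]]
  if (!is.null(hit)) return(hit)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  deg <- matrix(0L, 64, 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    s <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      alt <- vapply(bases, function(b) {
        s2 <- s; s2[p] <- b
        code[[paste(s2, collapse = "")]]
      }, character(1))
      deg[cd, p] <- sum(alt == code[[cd]])
    }
  }
  .wf_cache[["degtab"]] <- deg
  deg
}

#' Codon degeneracy of every CDS site
#'
#' Splices each transcript's CDS (strand-aware, phase-adjusted), translates
#' it under the standard genetic code, and labels every genomic CDS
#' position 0-, 2-, 3- or 4-fold degenerate: `k`-fold means `k` of the four
#' possible bases at that position leave the amino acid unchanged.
#' Positions covered by transcripts that disagree are excluded and counted.
#'
#' @param fasta Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param cds Tibble of CDS intervals: `chrom`, `start`, `end`, `strand`,
#'   `phase`, `parent` (transcript id); 1-based inclusive.
#' @return List: `sites` tibble (`chrom`, `pos`, `degeneracy`) and
#'   `n_conflicts` (positions excluded for conflicting labels),
#'   `n_skipped_tx` (transcripts whose CDS length is not a multiple of 3).
#' @export
classify_degeneracy <- function(fasta, cds) {
  if (inherits(fasta, "DNAStringSet")) {
    fasta <- stats::setNames(as.character(fasta), names(fasta))
  }
  deg_tab <- .degeneracy_table()
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  res <- list(); skipped <- 0L
  for (tx in unique(cds$parent)) {
    rows <- cds[cds$parent == tx, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    strand <- rows$strand[1]
    chrom <- rows$chrom[1]
    pos <- unlist(lapply(seq_len(nrow(rows)), function(r)
      rows$start[r]:rows$end[r]))
    seq_fwd <- strsplit(fasta[[chrom]], "")[[1]][pos]
    if (strand == "-") {
      pos <- rev(pos)
      seqv <- unname(comp[rev(seq_fwd)])
    } else seqv <- seq_fwd
    ph <- rows$phase[if (strand == "-") nrow(rows) else 1]
    if (!is.na(ph) && ph > 0) { pos <- pos[-seq_len(ph)]; seqv <- seqv[-seq_len(ph)] }
    if (length(pos) %% 3 != 0) {
      warning("CDS length of ", tx, " not a multiple of 3; skipped")
      skipped <- skipped + 1L
      next
    }
    n_cod <- length(pos) / 3
    codons <- paste0(seqv[3 * seq_len(n_cod) - 2],
                     seqv[3 * seq_len(n_cod) - 1],
                     seqv[3 * seq_len(n_cod)])
    valid <- codons %in% rownames(deg_tab)
    dmat <- matrix(NA_integer_, n_cod, 3)
    dmat[valid, ] <- deg_tab[codons[valid], , drop = FALSE]
    res[[tx]] <- tibble::tibble(
      chrom = chrom, pos = pos,
      degeneracy = as.integer(t(dmat)[seq_along(pos)]))
  }
  if (length(res) == 0) {
    return(list(sites = tibble::tibble(chrom = character(0),
                                       pos = integer(0),
                                       degeneracy = integer(0)),
                n_conflicts = 0L, n_skipped_tx = skipped))
  }
  all <- dplyr::bind_rows(res)
  all <- dplyr::filter(all, !is.na(.data$degeneracy))
  agg <- all |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(n_lab = dplyr::n_distinct(.data$degeneracy),
                     degeneracy = .data$degeneracy[1], .groups = "drop")
  n_conflicts <- sum(agg$n_lab > 1)
  list(sites = dplyr::select(dplyr::filter(agg, .data$n_lab == 1),
                             "chrom", "pos", "degeneracy"),
       n_conflicts = n_conflicts, n_skipped_tx = skipped)
}

#' Genomic category of arbitrary positions
#'
#' Assigns each position one category with priority CDS > UTR > intron >
#' intergenic; introns are split into margins (first and last
#' `intron_margin` bp) and center; intergenic positions carry their
#' distance to the nearest gene and a proximal flag (within `proximal_bp`
#' of a gene).
#'
#' @param positions Tibble with `chrom`, `pos` (1-based).
#' @param features Feature tibble (from [read_gff()] or the simulator) with
#'   `gene`, `CDS`, `five_prime_UTR`, `three_prime_UTR`, `intron` rows.
#' @param intron_margin Margin width in bp (default 30).
#' @param proximal_bp Proximal-intergenic distance (default 100 bp,
#'   inclusive).
#' @return Input tibble plus `category` (one of `CDS`, `5UTR`, `3UTR`,
#'   `intronM`, `intronC`, `intergenic`), `dist_to_gene`, `proximal`.
#' @export
classify_category <- function(positions, features, intron_margin = 30,
                              proximal_bp = 100) {
  in_any <- function(p_chrom, p_pos, rows) {
    out <- logical(length(p_pos))
    for (ch in unique(p_chrom)) {
      r <- rows[rows$chrom == ch, , drop = FALSE]
      if (nrow(r) == 0) next
      sel <- p_chrom == ch
      hits <- outer(p_pos[sel], r$start, ">=") & outer(p_pos[sel], r$end, "<=")
      out[sel] <- rowSums(hits) > 0
    }
    out
  }
  ft <- function(ty) features[features$type == ty, , drop = FALSE]
  introns <- ft("intron")
  margins <- NULL; centers <- NULL
  if (nrow(introns) > 0) {
    margins <- dplyr::bind_rows(
      dplyr::mutate(introns,
                    end = pmin(.data$end, .data$start + intron_margin - 1)),
      dplyr::mutate(introns,
                    start = pmax(.data$start, .data$end - intron_margin + 1)))
    centers <- introns |>
      dplyr::mutate(start = .data$start + intron_margin,
                    end = .data$end - intron_margin) |>
      dplyr::filter(.data$end >= .data$start)
  }
  cat_out <- rep("intergenic", nrow(positions))
  if (!is.null(centers) && nrow(centers) > 0)
    cat_out[in_any(positions$chrom, positions$pos, centers)] <- "intronC"
  if (!is.null(margins) && nrow(margins) > 0)
    cat_out[in_any(positions$chrom, positions$pos, margins)] <- "intronM"
  cat_out[in_any(positions$chrom, positions$pos, ft("three_prime_UTR"))] <- "3UTR"
  cat_out[in_any(positions$chrom, positions$pos, ft("five_prime_UTR"))] <- "5UTR"
  cat_out[in_any(positions$chrom, positions$pos, ft("CDS"))] <- "CDS"
  genes <- ft("gene")
  dist <- rep(NA_real_, nrow(positions))
  for (ch in unique(positions$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    sel <- positions$chrom == ch
    if (nrow(g) == 0) { dist[sel] <- Inf; next }
    p <- positions$pos[sel]
    d <- vapply(p, function(x)
      min(pmax(0, pmax(g$start - x, x - g$end))), numeric(1))
    dist[sel] <- d
  }
  positions$category <- cat_out
  positions$dist_to_gene <- dist
  positions$proximal <- cat_out == "intergenic" & dist <= proximal_bp
  positions
}

#' Polarize biallelic sites with two outgroups
#'
#' The ancestral allele is the ingroup allele shared with at least one
#' outgroup; a site is unpolarized when both ingroup alleles match an
#' outgroup, or neither does.
#'
#' @param a1,a2 Ingroup allele vectors (single bases).
#' @param out1,out2 Outgroup allele vectors (`NA` = missing).
#' @return Tibble with `ancestral`, `derived`, `polarized`.
#' @export
polarize <- function(a1, a2, out1, out2 = NA_character_) {
  m1 <- (!is.na(out1) & a1 == out1) | (!is.na(out2) & a1 == out2)
  m2 <- (!is.na(out1) & a2 == out1) | (!is.na(out2) & a2 == out2)
  anc <- ifelse(m1 & !m2, a1, ifelse(m2 & !m1, a2, NA_character_))
  der <- ifelse(m1 & !m2, a2, ifelse(m2 & !m1, a1, NA_character_))
  tibble::tibble(ancestral = anc, derived = der, polarized = !is.na(anc))
}

#' GC-biased gene conversion mutation class
#'
#' Strong alleles S = G or C, weak W = A or T. `WS` = weak ancestral to
#' strong derived, `SW` the reverse, `WWSS` = strength-preserving
#' (GC-conservative).
#'
#' @param ancestral,derived Allele vectors of polarized SNPs.
#' @return Character vector in `{"WS", "SW", "WWSS"}`.
#' @export
mutation_class <- function(ancestral, derived) {
  if (any(is.na(ancestral) | is.na(derived)))
    stop("mutation_class requires polarized sites")
  s <- c("G", "C")
  anc_s <- ancestral %in% s
  der_s <- derived %in% s
  ifelse(!anc_s & der_s, "WS", ifelse(anc_s & !der_s, "SW", "WWSS"))
}

#' Recombination rate and bin per site
#'
#' Each site inherits the rate of its genetic-map window; sites in mask
#' intervals (e.g. an unresolved inversion) or outside the map are excluded.
#' Bins are either the fixed thresholds (default 3.2 / 6.4 cM/Mb, intervals
#' `[0,3.2)`, `[3.2,6.4]`, `(6.4,Inf)`) or equal-count terciles with ties
#' broken by genomic order.
#'
#' @param sites Tibble with `chrom`, `pos`.
#' @param map Tibble with `chrom`, `start`, `end`, `cm_mb` (1-based
#'   inclusive windows, non-overlapping).
#' @param mask Optional tibble of intervals to exclude (`chrom`, `start`,
#'   `end`).
#' @param mode `"fixed"` or `"tercile"`.
#' @param thresholds Fixed-mode thresholds.
#' @return Input tibble plus `rate` and `rec_bin`
#'   (`low`/`mid`/`high`/`NA`); excluded sites keep `NA` and are counted in
#'   the `excluded` attribute.
#' @export
bin_recombination <- function(sites, map, mask = NULL,
                              mode = c("fixed", "tercile"),
                              thresholds = c(3.2, 6.4)) {
  mode <- match.arg(mode)
  rate <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    m <- map[map$chrom == ch, , drop = FALSE]
    sel <- which(sites$chrom == ch)
    if (nrow(m) == 0) next
    m <- m[order(m$start), , drop = FALSE]
    w <- findInterval(sites$pos[sel], m$start)
    ok <- w >= 1 & sites$pos[sel] <= m$end[pmax(w, 1)]
    rate[sel[ok]] <- m$cm_mb[w[ok]]
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    for (r in seq_len(nrow(mask))) {
      hit <- sites$chrom == mask$chrom[r] & sites$pos >= mask$start[r] &
        sites$pos <= mask$end[r]
      rate[hit] <- NA_real_
    }
  }
  bin <- rep(NA_character_, nrow(sites))
  ok <- !is.na(rate)
  if (any(ok)) {
    if (mode == "fixed") {
      bin[ok] <- ifelse(rate[ok] < thresholds[1], "low",
                        ifelse(rate[ok] <= thresholds[2], "mid", "high"))
    } else {
      ord <- order(rate[ok], which(ok))  # ties broken by genomic order
      n_ok <- sum(ok)
      tercile <- ceiling(3 * seq_len(n_ok) / n_ok)
      bin[which(ok)[ord]] <- c("low", "mid", "high")[tercile]
    }
  } else {
    warning("all sites masked or outside the genetic map")
  }
  sites$rate <- rate
  sites$rec_bin <- bin
  attr(sites, "excluded") <- sum(!ok)
  sites
}
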