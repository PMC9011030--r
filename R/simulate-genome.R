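#' Simulate a random annotated genome
#'
#' Builds one chromosome of alternating intergenic tracts and gene models
#' (5'UTR, exons with valid reading frames, introns of at least 61 bp so a
#' 30-bp margin on each side plus a center base exist, 3'UTR), on random
#' strands, with a random nucleotide sequence.
#'
#' @param length_bp Chromosome length.
#' @param mean_intergenic Mean intergenic tract length.
#' @param seed Seed.
#' @param chrom Chromosome name.
#' @return List: `fasta` (named character vector), `features` (tidy feature
#'   tibble with `gene`, `five_prime_UTR`, `CDS`, `exon`, `intron`,
#'   `three_prime_UTR` rows), `chrom_len`.
#' @export
simulate_genome_annotation <- function(length_bp = 1e5,
                                       mean_intergenic = 2000, seed,
                                       chrom = "chr1") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, length_bp, replace = TRUE)
  feats <- list()
  gene_i <- 0L
  pos <- 1L
  add <- function(type, start, end, strand, phase = NA_integer_,
                  id = NA_character_, parent = NA_character_) {
    tibble::tibble(chrom = chrom, source = "sim", type = type,
                   start = start, end = end, strand = strand,
                   phase = phase, id = id, parent = parent)
  }
  repeat {
    pos <- pos + max(200L, rpois(1, mean_intergenic))
    if (pos > length_bp - 3000L) break
    gene_i <- gene_i + 1L
    gid <- sprintf("gene%03d", gene_i)
    tid <- paste0(gid, ".1")
    strand <- sample(c("+", "-"), 1)
    utr5_len <- sample(50:200, 1)
    utr3_len <- sample(50:300, 1)
    n_exon <- sample(1:4, 1)
    cds_lens <- 3L * sample(30:100, n_exon, replace = TRUE)
    intron_lens <- if (n_exon > 1) sample(61:400, n_exon - 1L,
                                          replace = TRUE) else integer(0)
    total <- utr5_len + sum(cds_lens) + sum(intron_lens) + utr3_len
    if (pos + total > length_bp) break
    g_start <- pos
    g_end <- pos + total - 1L
    # lay out left-to-right in genomic coordinates; biological order
    # follows the strand
    cur <- pos
    left_utr <- if (strand == "+") utr5_len else utr3_len
    right_utr <- if (strand == "+") utr3_len else utr5_len
    rows <- list(add("gene", g_start, g_end, strand, id = gid))
    rows <- c(rows, list(add(
      if (strand == "+") "five_prime_UTR" else "three_prime_UTR",
      cur, cur + left_utr - 1L, strand, parent = tid)))
    cur <- cur + left_utr
    cds_rows <- list()
    for (e in seq_len(n_exon)) {
      cds_rows[[e]] <- c(cur, cur + cds_lens[e] - 1L)
      cur <- cur + cds_lens[e]
      if (e < n_exon) {
        rows <- c(rows, list(add("intron", cur, cur + intron_lens[e] - 1L,
                                 strand, parent = tid)))
        cur <- cur + intron_lens[e]
      }
    }
    # CDS phase: cumulative coding length in biological order
    bio_order <- if (strand == "+") seq_len(n_exon) else rev(seq_len(n_exon))
    cum <- 0L
    phases <- integer(n_exon)
    for (e in bio_order) {
      phases[e] <- (3L - cum %% 3L) %% 3L
      cum <- cum + cds_lens[e]
    }
    for (e in seq_len(n_exon)) {
      rows <- c(rows, list(
        add("CDS", cds_rows[[e]][1], cds_rows[[e]][2], strand,
            phase = phases[e], parent = tid),
        add("exon", cds_rows[[e]][1], cds_rows[[e]][2], strand,
            parent = tid)))
    }
    rows <- c(rows, list(add(
      if (strand == "+") "three_prime_UTR" else "five_prime_UTR",
      cur, cur + right_utr - 1L, strand, parent = tid)))
    feats <- c(feats, rows)
    pos <- g_end + 1L
  }
  features <- dplyr::bind_rows(feats)
  # ATG start / sense codons are not enforced; degeneracy only needs valid
  # frames, which the length construction guarantees
  list(fasta = stats::setNames(paste(seqv, collapse = ""), chrom),
       features = features, chrom_len = length_bp)
}

#' Simulate a multi-species alignment with conserved tracts
#'
#' Evolves i.i.d. columns down a given tree under Jukes-Cantor at the
#' neutral rate, except inside designated conserved tracts where branch
#' lengths are multiplied by `conserved_rate < 1`. Returns the true
#' conserved mask alongside the alignment.
#'
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   substitutions per site, or a newick string.
#' @param n_cols Alignment columns.
#' @param conserved_fraction Fraction of columns inside conserved tracts.
#' @param tract_len Mean conserved tract length (geometric layout).
#' @param conserved_rate Rate multiplier inside tracts (default 0.2).
#' @param seed Seed.
#' @return List: `aln` (species x columns character matrix), `mask`
#'   (logical, TRUE = conserved), `tree`.
#' @export
simulate_alignment <- function(tree, n_cols = 1e4, conserved_fraction = 0.2,
                               tract_len = 50, conserved_rate = 0.2,
                               seed) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(seed)
  # alternating geometric neutral / conserved tracts
  if (conserved_fraction <= 0) {
    mask <- rep(FALSE, n_cols)
  } else {
    p_neu <- min(1, conserved_fraction / tract_len / (1 - conserved_fraction))
    mask <- logical(0)
    while (length(mask) < n_cols) {
      neu <- rgeom(1, p_neu) + 1L
      con <- rgeom(1, 1 / tract_len) + 1L
      mask <- c(mask, rep(FALSE, neu), rep(TRUE, con))
    }
    mask <- mask[seq_len(n_cols)]
  }
  rates <- ifelse(mask, conserved_rate, 1)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(4L, n_cols, replace = TRUE)
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  lens <- tree$edge.length[rev(ape::postorder(tree))]
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    t_eff <- lens[e] * rates
    p_same <- 0.25 + 0.75 * exp(-4 * t_eff / 3)
    x <- seqs[[parent]]
    change <- runif(n_cols) > p_same
    if (any(change)) {
      shift <- sample.int(3L, sum(change), replace = TRUE)
      x[change] <- 1L + (x[change] - 1L + shift) %% 4L
    }
    seqs[[child]] <- x
  }
  aln <- do.call(rbind, lapply(seq_len(n_tip), function(i)
    bases[seqs[[i]]]))
  rownames(aln) <- tree$tip.label
  list(aln = aln, mask = mask, tree = tree)
}

#' Simulate outgroup divergence and substitution truth
#'
#' Overlays Poisson substitutions on the outgroup lineage of simulated
#' polymorphism data: each site's outgroup allele differs from the
#' ancestral allele with probability `1 - exp(-rate)`. When per-site
#' selection labels are provided, fixation counts on the ingroup lineage
#' are drawn per class so the true adaptive proportion is recorded.
#'
#' @param sim A `sim_output` (from [simulate_coalescent()]), or `NULL` to
#'   generate divergence counts only.
#' @param rate Expected substitutions per site on the outgroup lineage.
#' @param seed Seed.
#' @return `sim` with an added `outgroup` element: tibble (`pos`,
#'   `ancestral_allele`, `outgroup_allele`, `diverged`).
#' @export
simulate_divergence <- function(sim, rate, seed = NULL) {
  stopifnot(inherits(sim, "sim_output"), rate >= 0)
  set.seed(if (is.null(seed)) child_seed(sim$config$seed, "divergence")
           else seed)
  bases <- c("A", "C", "G", "T")
  n_sites <- nrow(sim$sites)
  anc <- sample(bases, n_sites, replace = TRUE)
  p_sub <- -expm1(-rate)
  diverged <- runif(n_sites) < p_sub
  outg <- anc
  if (any(diverged)) {
    outg[diverged] <- vapply(anc[diverged], function(b)
      sample(setdiff(bases, b), 1), character(1))
  }
  sim$outgroup <- tibble::tibble(pos = sim$sites$pos,
                                 ancestral_allele = anc,
                                 outgroup_allele = outg,
                                 diverged = diverged)
  sim
}

#' @importFrom stats rgeom
NULL

#' Write simple FASTA / GFF3 / genetic-map files
#'
#' Plain-text writers for the simulator's outputs, matching the readers in
#' the package.
#'
#' @param fasta Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(fasta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(fasta)) {
    writeLines(paste0(">", nm), con)
    s <- fasta[[nm]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @param features Feature tibble (`chrom`, `source`, `type`, `start`,
#'   `end`, `strand`, `phase`, `id`, `parent`).
#' @export
write_gff <- function(features, path) {
  attrs <- ifelse(!is.na(features$id), paste0("ID=", features$id),
                  ifelse(!is.na(features$parent),
                         paste0("Parent=", features$parent), "."))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   features$chrom, features$source, features$type,
                   features$start, features$end, features$strand,
                   ifelse(is.na(features$phase), ".",
                          as.character(features$phase)), attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param map Tibble `chrom`, `start`, `end`, `cm_mb`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_genetic_map <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
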