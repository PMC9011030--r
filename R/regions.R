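#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Exclude sites inside masked regions
#'
#' Region masks (for example genomic intervals under long-term balancing
#' selection, or an unresolved inversion) must never contribute to spectra
#' or MK tables; this helper flags the surviving sites.
#'
#' @param sites Tibble with `chrom`, `pos` (1-based).
#' @param mask Tibble of intervals `chrom`, `start`, `end` (1-based
#'   inclusive); `NULL` keeps everything.
#' @return Logical vector, `TRUE` for sites outside every mask interval.
#' @export
outside_mask <- function(sites, mask = NULL) {
  keep <- rep(TRUE, nrow(sites))
  if (is.null(mask) || nrow(mask) == 0) return(keep)
  for (r in seq_len(nrow(mask))) {
    hit <- sites$chrom == mask$chrom[r] & sites$pos >= mask$start[r] &
      sites$pos <= mask$end[r]
    keep[hit] <- FALSE
  }
  keep
}

#' Merge significant grid points into swept regions
#'
#' A swept region is a maximal run of contiguous significant grid points
#' (adjacent = one grid spacing apart on the same chromosome); each region
#' spans from the first to the last grid point plus one spacing.
#'
#' @param grids Tibble with `grid_pos`, `significant` (logical), and
#'   optionally `chrom` (single chromosome assumed otherwise).
#' @param grid_spacing Grid step in bp (default 20 kb).
#' @return Tibble `chrom`, `start`, `end`, `n_grids` (BED-style, 0-based
#'   half-open coordinates).
#' @export
swept_regions <- function(grids, grid_spacing = 2e4) {
  if (!"chrom" %in% names(grids)) grids$chrom <- "chr1"
  sig <- grids[!is.na(grids$significant) & grids$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_grids = integer(0)))
  }
  sig <- sig[order(sig$chrom, sig$grid_pos), , drop = FALSE]
  new_run <- c(TRUE, diff(sig$grid_pos) != grid_spacing |
                 sig$chrom[-1] != sig$chrom[-nrow(sig)])
  run_id <- cumsum(new_run)
  sig |>
    dplyr::mutate(run = run_id) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$grid_pos),
                     end = max(.data$grid_pos) + grid_spacing,
                     n_grids = dplyr::n(), .groups = "drop") |>
    dplyr::select(!"run")
}
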