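#' Fraction of block starts near annotated TSSs
#'
#' The tuning-parameter diagnostic: allele-specific signal usually changes
#' at a transcription start site, so the fraction of called blocks whose 5'
#' end lies within a window of any TSS measures how well block boundaries
#' align with promoters. Block starts are strand-aware: on the minus strand
#' the 5' end of a block is its `end` coordinate.
#'
#' @param blocks Tibble of blocks (`chrom`, `start`, `end`, `strand`), e.g.
#'   the significant rows of [call_ase_blocks()] output.
#' @param tss Tibble of TSS intervals in BED convention (`chrom`, `start`,
#'   `end`); TSS strand is ignored.
#' @param window_bp Distance window in base pairs (default 5000).
#' @return Fraction in `[0, 1]`; `NA` if `blocks` is empty.
#' @export
block_tss_fraction <- function(blocks, tss, window_bp = 5000) {
  stopifnot(window_bp >= 0)
  if (nrow(blocks) == 0) {
    warning("no blocks; TSS fraction is undefined")
    return(NA_real_)
  }
  if (nrow(tss) == 0) return(0)
  pt <- ifelse(blocks$strand == "-", blocks$end, blocks$start)
  near <- vapply(seq_len(nrow(blocks)), function(i) {
    on_chrom <- tss$chrom == blocks$chrom[i]
    any(on_chrom &
          pt[i] >= tss$start - window_bp &
          pt[i] < tss$end + window_bp)
  }, logical(1))
  mean(near)
}

#' Scan the tuning parameter against TSS saturation
#'
#' Runs the full block-calling pipeline at every value of `tau_grid` and
#' records, for each window size, the fraction of called blocks starting
#' within the window of a TSS. As `tau` increases this fraction rises and
#' then saturates; the saturation point is the recommended `tau`.
#'
#' @inheritParams call_ase_blocks
#' @param tss TSS intervals (BED-convention tibble).
#' @param tau_grid Values of `tau` to scan (default `10^-(9:1)`, ascending).
#' @param window_sizes Window sizes in bp (default 1, 2, 5 and 10 kb).
#' @param use_significant Use only FDR-significant blocks (default) or all
#'   biased blocks.
#' @return A tibble of class `tss_saturation`: `tau`, `window_bp`,
#'   `fraction`, `n_blocks`.
#' @export
tau_saturation_scan <- function(counts, tss, tau_grid = 10^-(9:1),
                                window_sizes = c(1000, 2000, 5000, 10000),
                                fdr = 0.10, use_significant = TRUE, ...) {
  tau_grid <- sort(tau_grid)
  out <- purrr::map_dfr(tau_grid, function(tau) {
    calls <- call_ase_blocks(counts, tau = tau, fdr = fdr, ...)
    blocks <- dplyr::filter(calls$blocks, .data$state != "S")
    if (use_significant) blocks <- dplyr::filter(blocks, .data$significant)
    purrr::map_dfr(window_sizes, function(w) {
      frac <- if (nrow(blocks) == 0) NA_real_ else
        block_tss_fraction(blocks, tss, w)
      tibble::tibble(tau = tau, window_bp = w, fraction = frac,
                     n_blocks = nrow(blocks))
    })
  })
  class(out) <- c("tss_saturation", class(out))
  out
}

#' Select the tuning parameter from a saturation curve
#'
#' Operationalises "the value at which the curve approaches saturation" as
#' the smallest `tau` whose fraction lies within `epsilon` of the grid
#' maximum at the reference window size. Degenerate curves (all fractions
#' missing, or fewer than 3 grid points with data) fall back to the grid
#' argmax with a warning.
#'
#' @param curve A [tau_saturation_scan()] result.
#' @param epsilon Absolute closeness to the maximum (default 0.02).
#' @param window_bp Reference window size (default 5000).
#' @return Selected `tau` (scalar).
#' @export
select_tau <- function(curve, epsilon = 0.02, window_bp = 5000) {
  cur <- dplyr::filter(curve, .data$window_bp == !!window_bp,
                       !is.na(.data$fraction))
  cur <- dplyr::arrange(cur, .data$tau)
  if (nrow(cur) == 0) stop("saturation curve has no defined fractions at ",
                           "window ", window_bp)
  if (nrow(cur) < 3) {
    warning("saturation curve has fewer than 3 usable grid points; ",
            "returning the argmax")
    return(cur$tau[which.max(cur$fraction)])
  }
  cur$tau[which(cur$fraction >= max(cur$fraction) - epsilon)[1]]
}

#' @rdname tau_saturation_scan
#' @param object A `tss_saturation` tibble.
#' @export
autoplot.tss_saturation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tau, y = .data$fraction,
                               colour = factor(.data$window_bp))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau), y = "fraction of blocks near a TSS",
                  colour = "window (bp)") +
    ggplot2::theme_minimal()
}
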