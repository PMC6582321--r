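#' Stitch a decoded state path into maximal same-state blocks
#'
#' Consecutive SNPs of one (chromosome, strand) chain that share the same
#' decoded hidden state are merged into a block. Block intervals span from
#' the first to the last SNP of the run and are reported in BED convention
#' (0-based half-open), so a single-SNP block has width 1. Allele counts are
#' pooled by summing the per-SNP table counts.
#'
#' @param decoded A tibble as returned by [decode_states()]: per-SNP counts
#'   plus a `state` column, sorted by chain and position.
#' @return A tibble of blocks (all states, including symmetric runs) with
#'   pooled `mat_reads` / `pat_reads` and a `.row_first` / `.row_last` index
#'   range back into `decoded`.
#' @export
stitch_blocks <- function(decoded) {
  stopifnot(is.data.frame(decoded), "state" %in% names(decoded))
  if (!all(decoded$state %in% STATES))
    stop("decoded states must be S, M or P")
  n <- nrow(decoded)
  if (n == 0) return(empty_blocks())
  key <- paste(decoded$chrom, decoded$strand, sep = "\r")
  newrun <- c(TRUE, decoded$state[-1] != decoded$state[-n] |
                key[-1] != key[-n])
  run <- cumsum(newrun)
  first <- which(newrun)
  last <- c(first[-1] - 1L, n)
  tibble::tibble(
    chrom = decoded$chrom[first],
    strand = decoded$strand[first],
    start = decoded$pos[first] - 1L,
    end = decoded$pos[last],
    state = decoded$state[first],
    n_snps = last - first + 1L,
    mat_reads = as.integer(rowsum(decoded$mat_count, run)[, 1]),
    pat_reads = as.integer(rowsum(decoded$pat_count, run)[, 1]),
    .row_first = first,
    .row_last = last
  )
}

empty_blocks <- function() {
  tibble::tibble(
    chrom = character(), strand = character(),
    start = integer(), end = integer(), state = character(),
    n_snps = integer(), mat_reads = integer(), pat_reads = integer(),
    p_value = numeric(), q_value = numeric(), significant = logical()
  )
}

#' Call allele-specific blocks from a per-SNP allele-count table
#'
#' The full pipeline: fit the constrained HMM by EM (unless a fit is
#' supplied), decode the most likely state path with Viterbi, stitch runs
#' of identical states into blocks, pool allele counts per block, test each
#' maternal/paternal block with a two-sided exact binomial test against a
#' balanced null, and control the false discovery rate with
#' Benjamini-Hochberg across all biased blocks genome-wide. Symmetric runs
#' are kept internally for diagnostics but are never hypotheses and never
#' written to output files.
#'
#' The block test guards against false positives the HMM cannot see, e.g. a
#' single read counted at several nearby SNPs. Pooled counts here are sums
#' of the per-SNP table counts; if reads spanning several SNPs are a
#' concern, recount reads per block upstream and re-test.
#'
#' @inheritParams fit_allele_hmm
#' @param fdr False-discovery-rate threshold for the significant set
#'   (default 0.10).
#' @param fit Optional pre-computed [fit_allele_hmm()] result to reuse.
#' @param ... Passed on to [fit_allele_hmm()].
#' @return An object of class `ase_calls`: `blocks` (all stitched blocks
#'   with p/q values on biased blocks and a `significant` flag), `snps`
#'   (the input SNPs with decoded `state` and final per-SNP `call`, where a
#'   SNP is called M or P only inside a significant block), plus `fit`,
#'   `tau` and `fdr`.
#' @examples
#' set.seed(42)
#' sim <- simulate_three_block(rho = 0)
#' calls <- call_ase_blocks(sim, tau = 1e-5)
#' dplyr::filter(tidy(calls), significant)
#' @export
call_ase_blocks <- function(counts, tau = 1e-5, fdr = 0.10, fit = NULL, ...) {
  counts_all <- validate_counts(counts, drop_zero = FALSE)
  kept <- counts_all[counts_all$total_count > 0, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("no SNPs with mapped reads; returning empty call set")
    snps <- counts_all
    snps$state <- NA_character_
    snps$call <- "S"
    return(structure(list(blocks = empty_blocks(), snps = snps,
                          fit = NULL, tau = tau, fdr = fdr),
                     class = "ase_calls"))
  }
  if (is.null(fit)) fit <- fit_allele_hmm(kept, tau = tau, ...)
  dec <- decode_states(kept, fit)
  blocks <- stitch_blocks(dec)
  mp <- blocks$state != "S"
  blocks$p_value <- NA_real_
  blocks$q_value <- NA_real_
  if (any(mp)) {
    tot <- blocks$mat_reads[mp] + blocks$pat_reads[mp]
    blocks$p_value[mp] <- binom_p_two_sided(blocks$mat_reads[mp], tot)
    blocks$q_value[mp] <- p.adjust(blocks$p_value[mp], method = "BH")
  }
  blocks$significant <- !is.na(blocks$q_value) & blocks$q_value <= fdr

  run_of_row <- rep(seq_len(nrow(blocks)), blocks$n_snps)
  dec$call <- ifelse(blocks$significant[run_of_row],
                     blocks$state[run_of_row], "S")

  zero <- counts_all[counts_all$total_count == 0, , drop = FALSE]
  if (nrow(zero) > 0) {
    zero$state <- NA_character_
    zero$call <- "S"
    snps <- dplyr::bind_rows(dec, zero)
    snps <- snps[order(snps$chrom, snps$strand, snps$pos), , drop = FALSE]
  } else {
    snps <- dec
  }

  blocks$.row_first <- NULL
  blocks$.row_last <- NULL
  structure(list(blocks = blocks, snps = snps, fit = fit,
                 tau = tau, fdr = fdr),
            class = "ase_calls")
}

#' @export
print.ase_calls <- function(x, ...) {
  nb <- sum(x$blocks$state != "S")
  ns <- sum(x$blocks$significant)
  cat("Allele-specific block calls\n")
  cat(sprintf("  %d SNPs, %d biased block(s), %d significant at FDR <= %g\n",
              nrow(x$snps), nb, ns, x$fdr))
  invisible(x)
}

#' @rdname call_ase_blocks
#' @param x An `ase_calls` object.
#' @export
tidy.ase_calls <- function(x, ...) x$blocks

#' @rdname call_ase_blocks
#' @export
glance.ase_calls <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$snps),
    n_blocks = sum(x$blocks$state != "S"),
    n_significant = sum(x$blocks$significant),
    tau = x$tau, fdr = x$fdr,
    logLik = if (is.null(x$fit)) NA_real_ else x$fit$loglik
  )
}

#' @rdname call_ase_blocks
#' @param object An `ase_calls` object.
#' @export
autoplot.ase_calls <- function(object, ...) {
  snps <- dplyr::filter(object$snps, .data$total_count > 0)
  snps$frac <- snps$mat_count / snps$total_count
  sig <- dplyr::filter(object$blocks, .data$significant)
  p <- ggplot2::ggplot(snps, ggplot2::aes(x = .data$pos, y = .data$frac,
                                          colour = .data$call)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(S = "grey40", M = "firebrick", P = "steelblue"),
      name = "call") +
    ggplot2::facet_grid(strand ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position", y = "maternal read fraction") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0)
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   fill = .data$state),
      ymin = -0.05, ymax = 1.05, alpha = 0.15, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(
        values = c(M = "firebrick", P = "steelblue"), name = "block")
  p
}
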