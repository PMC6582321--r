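#' Two-sided exact binomial test p-values under a balanced null
#'
#' Vectorised exact two-sided binomial test of `x` successes in `n` trials
#' against a null success probability of 0.5. Because the null pmf is
#' symmetric and unimodal, the two-sided p-value reduces to
#' `min(1, 2 * P(X <= min(x, n - x)))`, which agrees exactly with
#' [stats::binom.test()] at `p = 0.5` while being fast enough to run on
#' every SNP of a genome.
#'
#' @param x Integer vector of successes (maternal read counts).
#' @param n Integer vector of trials (total read counts), `n >= 1`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' binom_p_two_sided(0, 10)
#' binom_p_two_sided(5, 10)
#' @export
binom_p_two_sided <- function(x, n) {
  if (any(n < 1)) stop("binomial test requires at least one trial per entry")
  if (any(x < 0) || any(x > n)) stop("successes must satisfy 0 <= x <= n")
  k <- pmin(x, n - x)
  pmin(1, 2 * pbinom(k, n, 0.5))
}

# Validate a per-SNP allele-count table and return it with canonical columns.
# Required: chrom, pos, mat_count, pat_count (total_count derived if absent).
# strand optional; absent => unstranded ("*").
validate_counts <- function(counts, drop_zero = TRUE, quiet = FALSE) {
  stopifnot(is.data.frame(counts))
  need <- c("chrom", "pos", "mat_count", "pat_count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0)
    stop("counts table is missing column(s): ", paste(missing_cols, collapse = ", "))
  counts <- tibble::as_tibble(counts)
  if (!"total_count" %in% names(counts))
    counts$total_count <- counts$mat_count + counts$pat_count
  if (!"strand" %in% names(counts)) counts$strand <- "*"
  bad <- which(counts$mat_count + counts$pat_count != counts$total_count)
  if (length(bad) > 0)
    stop("maternal + paternal counts do not equal the total on row(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (any(counts$mat_count < 0 | counts$pat_count < 0))
    stop("negative read counts are not allowed")
  if (any(counts$pos < 1) || any(counts$pos != floor(counts$pos)))
    stop("positions must be positive integers (1-based)")
  if (drop_zero) {
    n_zero <- sum(counts$total_count == 0)
    if (n_zero > 0) {
      if (!quiet) message("dropping ", n_zero, " SNP(s) with zero mapped reads")
      counts <- counts[counts$total_count > 0, , drop = FALSE]
    }
  }
  counts
}

# Assemble (chrom, strand) chains for the compiled HMM kernels.
# Returns x, n, 0-based chain offsets, the row order used, and the chain keys.
build_chains <- function(counts) {
  if (nrow(counts) == 0) stop("no SNPs with mapped reads to build chains from")
  key <- paste(counts$chrom, counts$strand, sep = "\r")
  ord <- order(key, counts$pos, method = "radix")
  key <- key[ord]
  pos <- counts$pos[ord]
  run <- rle(key)
  ends <- cumsum(run$lengths)
  starts0 <- c(0L, ends)
  # positions must be strictly increasing within every chain
  same_chain <- rep(seq_along(run$lengths), run$lengths)
  if (any(diff(pos) <= 0 & diff(same_chain) == 0))
    stop("duplicate or non-increasing SNP positions within a (chrom, strand) chain")
  keys <- do.call(rbind, strsplit(run$values, "\r", fixed = TRUE))
  list(
    x = as.integer(counts$mat_count[ord]),
    n = as.integer(counts$total_count[ord]),
    starts = as.integer(starts0),
    order = ord,
    keys = tibble::tibble(chrom = keys[, 1], strand = keys[, 2],
                          n_snps = run$lengths)
  )
}

# Deterministic per-replicate seed derived from (experiment seed, grid index,
# replicate index); kept below 2^31.
derive_seed <- function(seed, grid_i, rep_i) {
  as.integer((abs(as.numeric(seed)) * 7919 + grid_i * 104729 + rep_i * 131) %%
               2147483629)
}

clamp_prob <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)
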