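# Independent oracles used across tests: brute-force enumeration over all
# 3^L hidden-state paths, and a naive confusion-matrix scorer. These never
# share code with the package's recursions.

enum_chain_oracle <- function(x, n, params) {
  L <- length(x)
  p <- params$p
  A <- params$transition
  init <- params$initial
  paths <- as.matrix(do.call(expand.grid, rep(list(1:3), L)))
  lp <- apply(paths, 1, function(s) {
    out <- log(init[s[1]]) + sum(dbinom(x, n, p[s], log = TRUE))
    if (L > 1) out <- out + sum(log(A[cbind(s[-L], s[-1])]))
    out
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best = c("S", "M", "P")[paths[which.max(lp), ]])
}

random_hmm_params <- function() {
  s_row <- as.vector(stats::rgamma(3, 1) + 0.05)
  list(p = sort(stats::runif(3, 0.05, 0.95))[c(2, 3, 1)],  # p_M > p_S > p_P
       transition = transition_matrix(stats::runif(1, 0.01, 0.4),
                                      s_row / sum(s_row)),
       initial = rep(1 / 3, 3))
}

random_chain <- function(len, lambda = 8) {
  n <- pmax(1L, stats::rpois(len, lambda))
  x <- stats::rbinom(len, n, stats::runif(len))
  tibble::tibble(chrom = "chr1", pos = seq_len(len) * 10L, strand = "+",
                 mat_count = x, pat_count = n - x, total_count = n)
}

confusion_oracle <- function(calls, truth) {
  tab <- table(factor(calls, c("S", "M", "P")),
               factor(truth, c("S", "M", "P")))
  tp <- tab["M", "M"] + tab["P", "P"]
  pos <- sum(tab[, c("M", "P")])
  called <- sum(tab[c("M", "P"), ])
  list(
    sensitivity = if (pos > 0) tp / pos else NA_real_,
    specificity = if (sum(tab[, "S"]) > 0) tab["S", "S"] / sum(tab[, "S"])
      else NA_real_,
    precision = if (called > 0) tp / called else NA_real_
  )
}

# chains with planted S/M/S/P/S structure for parameter-recovery tests
make_multistate_chains <- function(n_chains, seg_len = 60, lambda = 10,
                                   p_truth = c(S = 0.5, M = 0.9, P = 0.1)) {
  purrr::map_dfr(seq_len(n_chains), function(i) {
    ps <- p_truth[c("S", "M", "S", "P", "S")]
    cts <- dplyr::bind_rows(purrr::map(ps, function(p)
      sample_snp_counts(seg_len, lambda, p, rho = 0)))
    tibble::tibble(chrom = paste0("chr", i), pos = seq_len(nrow(cts)) * 50L,
                   strand = "+", mat_count = cts$mat_count,
                   pat_count = cts$pat_count, total_count = cts$total_count,
                   truth = rep(c("S", "M", "S", "P", "S"), each = seg_len))
  })
}
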