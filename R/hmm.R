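#' Binomial emission log-probability
#'
#' Log pmf of observing `x` maternal reads among `n` total reads at a SNP
#' whose hidden state has maternal success probability `p`. This is the
#' emission distribution of every state of the model; states differ only in
#' `p`.
#'
#' @param x Maternal read count(s), `0 <= x <= n`.
#' @param n Total read count(s).
#' @param p Success probability in `[0, 1]`. Degenerate values 0 and 1 give
#'   the point-mass pmf (log 0 or `-Inf` accordingly).
#' @return Log-probability vector.
#' @examples
#' emission_log_pmf(3, 10, 0.5)   # log(120 / 1024)
#' emission_log_pmf(10, 10, 1)    # 0
#' @export
emission_log_pmf <- function(x, n, p) {
  if (any(p < 0 | p > 1)) stop("success probability must lie in [0, 1]")
  if (any(x < 0) || any(x > n)) stop("counts must satisfy 0 <= x <= n")
  dbinom(x, n, p, log = TRUE)
}

#' Build the constrained three-state transition matrix
#'
#' Rows are ordered (S, M, P). The S row is free (supplied, typically learned
#' by EM); exits from the biased states are controlled by the tuning
#' parameter `tau`: the M row is `[tau/2, 1 - tau, tau/2]` and the P row is
#' `[tau/2, tau/2, 1 - tau]`. Small `tau` makes biased states sticky,
#' trading specificity for sensitivity of block calls.
#'
#' @param tau Tuning parameter in (0, 1).
#' @param s_row Length-3 probability vector for transitions out of S;
#'   must sum to 1.
#' @return 3x3 row-stochastic matrix with dimnames `(S, M, P)`.
#' @examples
#' transition_matrix(1e-5)
#' @export
transition_matrix <- function(tau, s_row = c(1 - 2e-3, 1e-3, 1e-3)) {
  if (length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must be a single value strictly between 0 and 1")
  if (length(s_row) != 3 || any(s_row < 0) || abs(sum(s_row) - 1) > 1e-8)
    stop("s_row must be a length-3 probability vector summing to 1")
  s_row <- s_row / sum(s_row)
  m <- rbind(s_row,
             c(tau / 2, 1 - tau, tau / 2),
             c(tau / 2, tau / 2, 1 - tau))
  dimnames(m) <- list(STATES, STATES)
  m
}

# Coerce a fitted model or a bare parameter list into the (p, transition,
# initial) triple the kernels expect.
as_hmm_params <- function(params) {
  if (inherits(params, "allele_hmm"))
    return(list(p = params$p, transition = params$transition,
                initial = params$initial))
  stopifnot(is.list(params), all(c("p", "transition") %in% names(params)))
  p <- params$p
  if (length(p) != 3 || any(p < 0 | p > 1))
    stop("emission probabilities must be three values in [0, 1]")
  A <- params$transition
  if (!is.matrix(A) || any(dim(A) != 3) ||
      any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0))
    stop("transition must be a 3x3 row-stochastic matrix")
  initial <- params$initial %||% rep(1 / 3, 3)
  if (length(initial) != 3 || abs(sum(initial) - 1) > 1e-8)
    stop("initial must be a length-3 probability vector")
  list(p = unname(p), transition = unname(A), initial = unname(initial))
}

#' Per-SNP state posteriors via the forward-backward algorithm
#'
#' Runs the scaled forward-backward recursion independently over every
#' (chromosome, strand) chain and returns the posterior probability of each
#' hidden state at each SNP, together with chain log-likelihoods.
#'
#' @param counts Data frame with columns `chrom`, `pos`, `mat_count`,
#'   `pat_count` (and optionally `total_count`, `strand`). SNPs with zero
#'   total reads are dropped.
#' @param params An `allele_hmm` fit or a list with elements `p` (length-3
#'   emission probabilities, order S/M/P), `transition` (3x3 matrix) and
#'   optionally `initial`.
#' @return A tibble with the input coordinates plus `gamma_S`, `gamma_M`,
#'   `gamma_P`. Attributes `loglik` (total) and `chain_loglik` (tibble per
#'   chain) carry the likelihood decomposition.
#' @export
state_posteriors <- function(counts, params) {
  counts <- validate_counts(counts, quiet = TRUE)
  ch <- build_chains(counts)
  pr <- as_hmm_params(params)
  es <- fb_sufficient_stats(ch$x, ch$n, ch$starts, clamp_prob(pr$p),
                            pr$transition, pr$initial)
  out <- counts[ch$order, c("chrom", "pos", "strand", "mat_count",
                            "pat_count", "total_count")]
  out$gamma_S <- es$gamma[, 1]
  out$gamma_M <- es$gamma[, 2]
  out$gamma_P <- es$gamma[, 3]
  attr(out, "loglik") <- es$loglik
  attr(out, "chain_loglik") <- dplyr::mutate(ch$keys, loglik = es$chain_loglik)
  out
}

#' Most likely state path via the Viterbi algorithm
#'
#' @inheritParams state_posteriors
#' @return The counts tibble (sorted by chain and position) with a `state`
#'   column in `{"S", "M", "P"}`.
#' @export
decode_states <- function(counts, params) {
  counts <- validate_counts(counts, quiet = TRUE)
  ch <- build_chains(counts)
  pr <- as_hmm_params(params)
  path <- viterbi_cpp(ch$x, ch$n, ch$starts, clamp_prob(pr$p),
                      pr$transition, pr$initial)
  out <- counts[ch$order, , drop = FALSE]
  out$state <- STATES[path + 1L]
  out
}

#' Fit the three-state allele-specificity HMM by Baum-Welch EM
#'
#' Learns the three emission success probabilities and the free transition
#' row out of the symmetric state, holding the exits from the biased states
#' fixed at the `tau`-constrained values `[tau/2, 1 - tau, tau/2]` (M row)
#' and `[tau/2, tau/2, 1 - tau]` (P row). The initial-state distribution is
#' fixed uniform and not re-estimated: with thousands of SNPs per chain it
#' carries no information, and fixing it removes one EM degree of freedom.
#' Each (chromosome, strand) pair is an independent chain; sufficient
#' statistics are pooled across chains.
#'
#' After EM the states are relabelled, if needed, so that
#' `p_M > p_S > p_P`: EM is invariant to swapping the two biased labels, and
#' the maternal state must be the one with the higher maternal fraction.
#'
#' @inheritParams state_posteriors
#' @param tau Tuning parameter in (0, 1); held fixed throughout EM.
#' @param p_init Starting emission probabilities (order S, M, P).
#' @param s_row_init Starting transition row out of S.
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations; hitting it sets
#'   `converged = FALSE` rather than erroring.
#' @return An object of class `allele_hmm`: emission probabilities `p`,
#'   `transition`, `initial`, `tau`, `loglik`, the per-iteration
#'   `loglik_trace`, `n_iter`, `converged`, `relabelled`, and the chain
#'   summary `chains`.
#' @examples
#' set.seed(1)
#' sim <- simulate_three_block(center_len = 50, flank_len = 50, rho = 0)
#' fit <- fit_allele_hmm(sim, tau = 1e-5)
#' fit$p
#' @export
fit_allele_hmm <- function(counts, tau = 1e-5,
                           p_init = c(S = 0.5, M = 0.9, P = 0.1),
                           s_row_init = c(1 - 2e-3, 1e-3, 1e-3),
                           tol = 1e-6, max_iter = 1000L) {
  counts <- validate_counts(counts, quiet = TRUE)
  ch <- build_chains(counts)
  A <- transition_matrix(tau, s_row_init)
  p <- clamp_prob(unname(p_init))
  initial <- rep(1 / 3, 3)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    es <- fb_sufficient_stats(ch$x, ch$n, ch$starts, p, A, initial)
    trace <- c(trace, es$loglik)
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
    g <- es$gamma
    denom <- colSums(g * ch$n)
    p_new <- ifelse(denom > 0, colSums(g * ch$x) / denom, p)
    p <- clamp_prob(p_new)
    s_row <- es$xi[1, ]
    if (sum(s_row) > 0) A[1, ] <- s_row / sum(s_row)
  }

  fit <- structure(list(
    p = setNames(p, STATES),
    transition = A,
    initial = initial,
    tau = tau,
    loglik = trace[length(trace)],
    loglik_trace = trace,
    n_iter = length(trace),
    converged = converged,
    relabelled = FALSE,
    chains = ch$keys,
    n_snps = length(ch$x)
  ), class = "allele_hmm")
  relabel_states(fit)
}

# Enforce the identifiability convention p_M > p_S > p_P by permuting state
# labels. An M<->P swap is an exact symmetry of the constrained model (the
# tau rows map onto each other); any permutation that moves S additionally
# re-imposes the tau-constrained rows and renormalises the S row.
relabel_states <- function(fit) {
  p <- fit$p
  perm <- c(S = which(rank(-p, ties.method = "first") == 2),
            M = which.max(p), P = which.min(p))
  if (all(perm == 1:3)) return(fit)
  A <- fit$transition[perm, perm]
  A[2, ] <- c(fit$tau / 2, 1 - fit$tau, fit$tau / 2)
  A[3, ] <- c(fit$tau / 2, fit$tau / 2, 1 - fit$tau)
  A[1, ] <- A[1, ] / sum(A[1, ])
  dimnames(A) <- list(STATES, STATES)
  fit$p <- setNames(unname(p[perm]), STATES)
  fit$transition <- A
  fit$relabelled <- TRUE
  fit
}

#' @export
print.allele_hmm <- function(x, ...) {
  cat("Three-state allele-specificity HMM fit\n")
  cat(sprintf("  SNPs: %d in %d chain(s); tau = %g\n",
              x$n_snps, nrow(x$chains), x$tau))
  cat(sprintf("  emission p (S, M, P): %.4f, %.4f, %.4f\n",
              x$p[1], x$p[2], x$p[3]))
  cat(sprintf("  log-likelihood: %.3f after %d EM iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname fit_allele_hmm
#' @param x An `allele_hmm` object.
#' @param ... Unused.
#' @export
tidy.allele_hmm <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("p_", STATES),
             paste0("trans_S_", STATES)),
    estimate = c(unname(x$p), unname(x$transition[1, ]))
  )
}

#' @rdname fit_allele_hmm
#' @export
glance.allele_hmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n_snps = x$n_snps, n_chains = nrow(x$chains), tau = x$tau
  )
}
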