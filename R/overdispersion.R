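#' Beta-binomial log-likelihood of allele counts
#'
#' @param x,n Maternal and total read counts.
#' @param mu Mean maternal fraction in (0, 1).
#' @param rho Intraclass correlation in (0, 1).
#' @return Scalar log-likelihood.
#' @keywords internal
betabinom_loglik <- function(x, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
}

#' Estimate beta-binomial overdispersion from allele counts
#'
#' Maximum-likelihood fit of a beta-binomial distribution (free mean, free
#' dispersion) to per-SNP (maternal, total) read counts, restricted to SNPs
#' covered by at least `min_reads` reads. The dispersion is reported as the
#' intraclass correlation `rho` (the parameterisation in which the
#' conditional variance is `n p (1 - p) (1 + (n - 1) rho)`); `rho = 0` is
#' the pure binomial. Optimisation is by L-BFGS-B on logit-transformed
#' parameters, so estimates near the binomial boundary are handled
#' gracefully.
#'
#' @inheritParams call_ase_blocks
#' @param min_reads Minimum total reads for a SNP to enter the fit
#'   (default 5).
#' @return One-row tibble with `rho`, `mu` (mean maternal fraction),
#'   `loglik` and `n_used`.
#' @examples
#' set.seed(1)
#' cts <- sample_snp_counts(5000, lambda_reads = 10, p = 0.5, rho = 0.25)
#' estimate_overdispersion(cts)$rho
#' @export
estimate_overdispersion <- function(counts, min_reads = 5) {
  stopifnot(is.data.frame(counts), "mat_count" %in% names(counts))
  if (!"total_count" %in% names(counts)) {
    stopifnot("pat_count" %in% names(counts))
    counts$total_count <- counts$mat_count + counts$pat_count
  }
  if (any(counts$mat_count > counts$total_count | counts$mat_count < 0))
    stop("counts must satisfy 0 <= mat_count <= total_count")
  keep <- counts$total_count >= min_reads
  if (sum(keep) < 2)
    stop("need at least 2 SNPs with >= ", min_reads, " reads to fit ",
         "overdispersion")
  x <- counts$mat_count[keep]
  n <- counts$total_count[keep]
  nll <- function(par) {
    -betabinom_loglik(x, n, plogis(par[1]), plogis(par[2]))
  }
  fit <- optim(c(qlogis(clamp_prob(mean(x) / mean(n), 1e-6)), qlogis(0.1)),
               nll, method = "L-BFGS-B",
               lower = c(-15, -15), upper = c(15, 15))
  tibble::tibble(
    rho = plogis(fit$par[2]),
    mu = plogis(fit$par[1]),
    loglik = -fit$value,
    n_used = sum(keep)
  )
}
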