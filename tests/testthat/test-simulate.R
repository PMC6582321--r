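test_that("allele-count sampler honours its degenerate and moment limits", {
  set.seed(301)
  pure <- sample_snp_counts(500, lambda_reads = 6, p = 1, rho = 0.25)
  expect_identical(pure$mat_count, pure$total_count)

  # conditional on depth n, Var(x) = n p (1-p) (1 + (n-1) rho)
  check_var <- function(rho) {
    draws <- sample_snp_counts(1e5, lambda_reads = 10, p = 0.5, rho = rho)
    x <- draws$mat_count[draws$total_count == 10]
    v_theory <- 10 * 0.25 * (1 + 9 * rho)
    m <- length(x)
    se_var <- sqrt((mean((x - mean(x))^4) - stats::var(x)^2) / m)
    expect_lt(abs(stats::var(x) - v_theory), 3 * se_var)
  }
  check_var(0)
  check_var(0.25)
})

test_that("at rho = 0 sampled counts follow the exact binomial law", {
  set.seed(302)
  draws <- sample_snp_counts(1e5, lambda_reads = 10, p = 0.5, rho = 0)
  x <- draws$mat_count[draws$total_count == 10]
  obs <- tabulate(x + 1L, nbins = 11)
  gof <- stats::chisq.test(obs, p = dbinom(0:10, 10, 0.5))
  expect_gt(gof$p.value, 0.01)
})

test_that("three-block datasets have the declared layout and determinism", {
  set.seed(303)
  ds <- simulate_three_block(center_len = 10, flank_len = 5, rho = 0)
  expect_identical(nrow(ds), 20L)
  expect_identical(ds$truth, rep(c("S", "M", "S"), c(5, 10, 5)))
  expect_identical(ds$block, rep(c("flank5", "center", "flank3"), c(5, 10, 5)))
  expect_true(all(diff(ds$pos) > 0))

  sym <- simulate_three_block(center_len = 10, flank_len = 5,
                              p_center = 0.5, rho = 0)
  expect_identical(unique(sym$truth), "S")

  set.seed(42); a <- simulate_three_block(rho = 0.25)
  set.seed(42); b <- simulate_three_block(rho = 0.25)
  expect_identical(a, b)
})

test_that("per-SNP baseline calls extreme SNPs and never single reads", {
  lone <- tibble::tibble(chrom = "chr1", pos = 100L, mat_count = 20L,
                         pat_count = 0L)
  res <- per_snp_binomial_calls(lone)
  expect_identical(res$call, "M")
  expect_equal(res$p_value, 2 * 0.5^20)
  expect_lt(res$q_value, 0.1)

  single_read <- tibble::tibble(chrom = "chr1", pos = 1L, mat_count = 1L,
                                pat_count = 0L)
  expect_identical(per_snp_binomial_calls(single_read)$call, "S")

  balanced <- tibble::tibble(chrom = "chr1", pos = 1L, mat_count = 50L,
                             pat_count = 50L)
  expect_identical(per_snp_binomial_calls(balanced)$call, "S")
})

test_that("calibrated FDR is less conservative than BH yet controls nulls", {
  set.seed(304)
  ds <- simulate_three_block(rho = 0)
  cal <- per_snp_binomial_calls(ds, method = "calibrated")
  bh <- per_snp_binomial_calls(ds, method = "bh")
  expect_gte(sum(cal$call != "S"), sum(bh$call != "S"))
  # realised false discoveries stay near the nominal 10% on average
  fdp <- vapply(1:40, function(seed) {
    set.seed(seed)
    d <- simulate_three_block(rho = 0)
    calls <- per_snp_binomial_calls(d)
    pos <- calls$call != "S"
    if (!any(pos)) return(NA_real_)
    sum(pos & calls$truth == "S") / sum(pos)
  }, numeric(1))
  expect_lt(mean(fdp, na.rm = TRUE), 0.2)
})

test_that("metric definitions match a naive confusion-matrix oracle", {
  expect_equal(unlist(snp_metrics(c("M", "P", "S"), c("M", "P", "S"))[1, 1:3]),
               c(sensitivity = 1, specificity = 1, precision = 1))

  mixed <- snp_metrics(rep("S", 4), c("M", "P", "S", "S"))
  expect_identical(mixed$sensitivity, 0)
  expect_identical(mixed$specificity, 1)
  expect_true(is.na(mixed$precision))

  truth <- c(rep("M", 10), rep("S", 90))
  calls <- c(rep("M", 8), rep("S", 2), rep("M", 2), rep("S", 88))
  got <- snp_metrics(calls, truth)
  expect_equal(got$sensitivity, 0.8)
  expect_equal(got$specificity, 88 / 90)
  expect_equal(got$precision, 0.8)

  for (seed in 1:20) {
    set.seed(seed)
    calls <- sample(c("S", "M", "P"), 60, replace = TRUE)
    truth <- sample(c("S", "M", "P"), 60, replace = TRUE)
    got <- snp_metrics(calls, truth)
    want <- confusion_oracle(calls, truth)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$precision, want$precision)
  }
})

test_that("replicated experiments return one tidy row per cell", {
  res <- run_ase_experiment(center_len = 10, flank_len = 20, rho = 0,
                            n_reps = 3, seed = 7,
                            sweep = list(center_len = c(5, 10, 20)))
  expect_identical(nrow(res), 3L * 2L * 3L)
  expect_setequal(unique(res$metric),
                  c("sensitivity", "specificity", "precision"))
  expect_true(all(res$mean >= 0 & res$mean <= 1, na.rm = TRUE))

  one <- run_ase_experiment(center_len = 20, flank_len = 20, rho = 0,
                            n_reps = 1, seed = 7, methods = "allelehmm")
  expect_true(all(is.na(one$se) | one$se == 0))
})

test_that("sensitivity grows with block length (paired seeds, 2 SE slack)", {
  res <- run_ase_experiment(rho = 0, n_reps = 40, seed = 11,
                            methods = "allelehmm",
                            sweep = list(center_len = c(4, 8, 16)))
  sens <- dplyr::arrange(dplyr::filter(res, metric == "sensitivity"),
                         sweep_value)
  expect_true(all(diff(sens$mean) >
                    -2 * (sens$se[-1] + sens$se[-nrow(sens)])))
})

test_that("overdispersion estimates recover the generating rho", {
  set.seed(305)
  od <- sample_snp_counts(5e4, lambda_reads = 10, p = 0.5, rho = 0.25)
  est <- estimate_overdispersion(od)
  expect_lt(abs(est$rho - 0.25), 0.02)

  set.seed(306)
  bin <- sample_snp_counts(5e4, lambda_reads = 10, p = 0.5, rho = 0)
  expect_lte(estimate_overdispersion(bin)$rho, 0.01)

  # SNPs below the read threshold do not influence the fit
  shallow <- tibble::tibble(mat_count = rep(c(0L, 1L), 50),
                            pat_count = rep(c(1L, 0L), 50),
                            total_count = 1L)
  expect_equal(estimate_overdispersion(dplyr::bind_rows(od, shallow))$rho,
               est$rho, tolerance = 1e-6)
  expect_error(estimate_overdispersion(shallow), "at least 2 SNPs")
})

test_that("overdispersion fit agrees with an independent beta-binomial fitter", {
  set.seed(307)
  cts <- sample_snp_counts(2e4, lambda_reads = 10, p = 0.6, rho = 0.25)
  cts <- cts[cts$total_count >= 5, ]
  ours <- estimate_overdispersion(cts)
  ref <- glmmTMB::glmmTMB(cbind(mat_count, pat_count) ~ 1,
                          family = glmmTMB::betabinomial, data = cts)
  rho_ref <- 1 / (1 + glmmTMB::sigma(ref))
  expect_equal(ours$rho, rho_ref, tolerance = 0.005)
  expect_equal(ours$mu, stats::plogis(unname(glmmTMB::fixef(ref)$cond)),
               tolerance = 0.005)
})
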