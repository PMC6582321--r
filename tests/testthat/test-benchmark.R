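bench_fixture <- function() {
  # three genes: A strongly maternal (90:10), B balanced (5:5), C uncovered
  counts <- tibble::tibble(
    chrom = "chr1",
    pos = c(150L, 250L, 350L, 1150L, 1250L),
    strand = "+",
    mat_count = c(30L, 30L, 30L, 3L, 2L),
    pat_count = c(4L, 3L, 3L, 3L, 2L))
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 1100L, 5000L),
    end = c(400L, 1300L, 6000L),
    name = c("geneA", "geneB", "geneC"),
    strand = "+")
  list(counts = counts, genes = genes)
}

test_that("gene-level pooling, testing and exclusion work as specified", {
  fx <- bench_fixture()
  g <- gene_allele_specificity(fx$counts, fx$genes)
  a <- g[g$name == "geneA", ]
  expect_identical(c(a$mat_reads, a$pat_reads), c(90L, 10L))
  expect_equal(a$fraction, 0.9)
  expect_lt(a$q_value, 0.01)
  b <- g[g$name == "geneB", ]
  expect_equal(b$fraction, 0.5)
  expect_gt(b$p_value, 0.5)
  expect_true(g$excluded[g$name == "geneC"])
  expect_true(is.na(g$fraction[g$name == "geneC"]))
})

test_that("surrogate-truth labels follow the fraction bounds", {
  counts <- tibble::tibble(
    chrom = "chr1", pos = c(150L, 1150L, 2150L, 9999L), strand = "+",
    mat_count = c(90L, 50L, 70L, 1L), pat_count = c(10L, 50L, 30L, 1L))
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100L, 1100L, 2100L),
    end = c(200L, 1200L, 2200L),
    name = c("gM", "gS", "gMid"), strand = "+")
  g <- gene_allele_specificity(counts, genes)
  lab <- surrogate_truth_labels(g, counts)
  expect_identical(lab$truth, c("M", "S", "excluded", "excluded"))
})

test_that("SNPs inheriting conflicting gene labels are excluded", {
  counts <- tibble::tibble(
    chrom = "chr1", pos = c(150L, 160L, 250L), strand = "+",
    mat_count = c(45L, 45L, 5L), pat_count = c(5L, 5L, 45L))
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100L, 140L), end = c(200L, 300L),
    name = c("gMat", "gPat"), strand = "+")
  # gMat pools SNPs 1-2 (90:10, maternal); gPat pools all three (95:55 -> no,
  # 45+45+5 : 5+5+45) = 95:55 fraction 0.633 -> excluded band
  g <- gene_allele_specificity(counts, genes)
  lab <- surrogate_truth_labels(g, counts)
  # SNPs 1-2 sit in both genes: maternal from gMat, excluded from gPat
  expect_identical(lab$truth[1:2], c("excluded", "excluded"))
})

test_that("significance-gated labelling excludes underpowered genes", {
  counts <- tibble::tibble(
    chrom = "chr1", pos = c(150L, 1150L), strand = "+",
    mat_count = c(90L, 2L), pat_count = c(10L, 0L))
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100L, 1100L), end = c(200L, 1200L),
    name = c("deep", "shallow"), strand = "+")
  g <- gene_allele_specificity(counts, genes)
  loose <- surrogate_truth_labels(g, counts)
  strict <- surrogate_truth_labels(g, counts, require_significance = TRUE)
  expect_identical(loose$truth, c("M", "M"))
  expect_identical(strict$truth, c("M", "excluded"))
})

test_that("concordance classes partition biased in-gene calls", {
  fx <- bench_fixture()
  g <- gene_allele_specificity(fx$counts, fx$genes)
  calls <- dplyr::mutate(fx$counts, call = c("M", "P", "M", "M", "S"))
  cls <- classify_concordance(calls, g)
  # geneA is significant-maternal: M calls concordant, P call discordant;
  # geneB is symmetric: its M call is symmetric-gene; S calls are dropped
  expect_identical(nrow(cls), 4L)
  expect_identical(sort(cls$concordance),
                   sort(c("concordant", "concordant", "discordant",
                          "symmetric-gene")))
  expect_identical(nrow(cls),
                   sum(calls$call %in% c("M", "P")))
})

test_that("switch counting ignores intervening symmetric calls", {
  expect_identical(count_specificity_switches(c("M", "M", "M")), 0L)
  expect_identical(count_specificity_switches(c("M", "M", "P", "P")), 1L)
  expect_identical(count_specificity_switches(c("M", "S", "P", "S", "M")), 2L)
  expect_identical(count_specificity_switches(character(0)), 0L)
  # invariant to symmetric runs at the boundaries
  expect_identical(count_specificity_switches(c("S", "M", "P", "S")),
                   count_specificity_switches(c("M", "P")))
})

test_that("annotation-restricted metrics match the generic scorer", {
  set.seed(501)
  ds <- simulate_three_block(rho = 0)
  calls <- call_ase_blocks(ds, tau = 1e-5)$snps
  center <- range(ds$pos[ds$block == "center"])
  genes <- tibble::tibble(chrom = "chr1", start = center[1] - 1L,
                          end = center[2], name = "planted", strand = "+")
  g <- gene_allele_specificity(ds, genes)
  lab <- surrogate_truth_labels(g, calls)
  got <- snp_performance_vs_annotation(lab)
  scored <- lab[lab$total_count > 0 & lab$truth %in% c("S", "M", "P"), ]
  want <- confusion_oracle(scored$call, scored$truth)
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$precision, want$precision)
  expect_gt(got$sensitivity, 0.8)
})

test_that("strongly specific planted genes usually show one allelic state", {
  res <- t(vapply(1:30, function(seed) {
    set.seed(seed)
    ds <- simulate_three_block(rho = 0.25)
    calls <- call_ase_blocks(ds, tau = 1e-5)
    center <- range(ds$pos[ds$block == "center"])
    genes <- tibble::tibble(chrom = "chr1", start = center[1] - 1L,
                            end = center[2], name = "planted", strand = "+")
    sw <- gene_switch_counts(calls$snps, genes)
    sig <- dplyr::filter(calls$blocks, significant,
                         start < center[2], end > center[1])
    c(covered = nrow(sig) >= 1, zero_switches = sw$n_switches == 0)
  }, c(covered = TRUE, zero_switches = TRUE)))
  expect_gte(mean(res[, "covered"]), 0.8)
  expect_gte(mean(res[, "zero_switches"]), 0.8)
})
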