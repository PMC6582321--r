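#' Gene-level allele specificity as a surrogate truth
#'
#' Pools allele-specific read counts over all SNPs inside each gene
#' annotation, tests each gene with a two-sided exact binomial test (null
#' 0.5), and controls the FDR across genes with Benjamini-Hochberg. Because
#' signal across a transcription unit is set at its promoter, the gene-level
#' direction is a usable stand-in for ground truth at every SNP it contains.
#'
#' @inheritParams call_ase_blocks
#' @param genes Tibble of gene intervals in BED convention: `chrom`,
#'   `start`, `end`, `name` (unique id), optionally `strand`.
#' @param stranded Match SNP strand to gene strand when pooling (default
#'   `TRUE` when both carry strand information).
#' @return A tibble with one row per gene: pooled `mat_reads`/`pat_reads`,
#'   `fraction` (maternal), `p_value`, `q_value`, `n_snps`; genes covered
#'   by no SNP keep `NA` statistics and an `excluded` flag.
#' @export
gene_allele_specificity <- function(counts, genes, stranded = TRUE) {
  counts <- validate_counts(counts, drop_zero = FALSE, quiet = TRUE)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (!"strand" %in% names(genes)) genes$strand <- "*"
  genes <- tibble::as_tibble(genes)
  if (anyDuplicated(genes$name)) stop("gene names must be unique")
  hits <- snp_gene_hits(counts, genes, stranded)
  pooled <- dplyr::summarise(
    dplyr::group_by(hits, .data$name),
    mat_reads = sum(.data$mat_count),
    pat_reads = sum(.data$pat_count),
    n_snps = dplyr::n(),
    .groups = "drop")
  out <- dplyr::left_join(genes, pooled, by = "name")
  out$n_snps[is.na(out$n_snps)] <- 0L
  out$excluded <- out$n_snps == 0L | (out$mat_reads + out$pat_reads) == 0
  out$excluded[is.na(out$excluded)] <- TRUE
  out$fraction <- ifelse(out$excluded, NA_real_,
                         out$mat_reads / (out$mat_reads + out$pat_reads))
  out$p_value <- NA_real_
  ok <- !out$excluded
  out$p_value[ok] <- binom_p_two_sided(out$mat_reads[ok],
                                       out$mat_reads[ok] + out$pat_reads[ok])
  out$q_value <- NA_real_
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out
}

# Join SNPs (1-based positions) to genes (0-based half-open intervals).
# Overlaps keep every (SNP, gene) pair; strand matched when requested and
# both sides are stranded.
snp_gene_hits <- function(counts, genes, stranded) {
  counts$.snp <- seq_len(nrow(counts))
  hits <- dplyr::inner_join(counts, genes, by = "chrom",
                            suffix = c("", ".gene"),
                            relationship = "many-to-many")
  hits <- dplyr::filter(hits, .data$pos - 1 >= .data$start,
                        .data$pos - 1 < .data$end)
  if (stranded)
    hits <- dplyr::filter(hits, .data$strand.gene == "*" |
                            .data$strand == "*" |
                            .data$strand == .data$strand.gene)
  hits
}

#' Per-SNP surrogate-truth labels from gene-level allele specificity
#'
#' Every SNP inside a labelled gene inherits that gene's label. Two
#' labelling modes are exposed: the imbalanced-benchmark mode labels purely
#' by the gene's maternal fraction (positives outside `positive_bounds`,
#' negatives strictly inside `negative_bounds`); with
#' `require_significance = TRUE` a gene is positive only if its FDR
#' q-value also clears `q_threshold`. SNPs in genes between the bound sets,
#' in unlabelled genes, or with conflicting labels from overlapping genes
#' are `"excluded"` from scoring.
#'
#' @param gene_tbl Output of [gene_allele_specificity()].
#' @param counts Per-SNP table (same coordinate system as the genes).
#' @param positive_bounds Genes with fraction `< bounds[1]` are
#'   paternal-positive and `> bounds[2]` maternal-positive
#'   (default `c(0.2, 0.8)`).
#' @param negative_bounds Genes with fraction strictly inside these bounds
#'   are negatives (default `c(0.45, 0.55)`).
#' @param require_significance Also require gene `q_value <= q_threshold`
#'   for positive labels.
#' @param q_threshold FDR threshold used when `require_significance`.
#' @param stranded As in [gene_allele_specificity()].
#' @return The counts tibble with a `truth` column in
#'   `{"M", "P", "S", "excluded"}`.
#' @export
surrogate_truth_labels <- function(gene_tbl, counts,
                                   positive_bounds = c(0.2, 0.8),
                                   negative_bounds = c(0.45, 0.55),
                                   require_significance = FALSE,
                                   q_threshold = 0.10,
                                   stranded = TRUE) {
  stopifnot(length(positive_bounds) == 2, length(negative_bounds) == 2,
            positive_bounds[1] < positive_bounds[2],
            negative_bounds[1] < negative_bounds[2],
            positive_bounds[1] <= negative_bounds[1],
            negative_bounds[2] <= positive_bounds[2])
  counts <- validate_counts(counts, drop_zero = FALSE, quiet = TRUE)
  g <- gene_tbl
  g$label <- "excluded"
  ok <- !g$excluded
  pos_m <- ok & g$fraction > positive_bounds[2]
  pos_p <- ok & g$fraction < positive_bounds[1]
  if (require_significance) {
    pos_m <- pos_m & g$q_value <= q_threshold
    pos_p <- pos_p & g$q_value <= q_threshold
  }
  g$label[pos_m] <- "M"
  g$label[pos_p] <- "P"
  g$label[ok & g$fraction > negative_bounds[1] &
            g$fraction < negative_bounds[2]] <- "S"

  hits <- snp_gene_hits(counts, g[, c("chrom", "start", "end", "name",
                                      "strand", "label")],
                        stranded)
  lab <- dplyr::summarise(
    dplyr::group_by(hits, .data$.snp),
    truth = if (dplyr::n_distinct(.data$label) == 1)
      .data$label[1] else "excluded",
    .groups = "drop")
  counts$truth <- "excluded"
  counts$truth[lab$.snp] <- lab$truth
  counts
}

#' Concordance of per-SNP calls with gene-level direction
#'
#' A biased (M/P) SNP call inside a gene is `concordant` if its direction
#' matches the gene's significant direction, `discordant` if opposite, and
#' `symmetric-gene` if the gene shows no significant allele specificity.
#'
#' @param calls Per-SNP tibble with a `call` column (e.g. `snps` from
#'   [call_ase_blocks()] or [per_snp_binomial_calls()] output).
#' @param gene_tbl Output of [gene_allele_specificity()].
#' @param q_threshold Gene significance threshold (default 0.10).
#' @param stranded As in [gene_allele_specificity()].
#' @return Tibble of biased SNP calls inside genes with a `concordance`
#'   column in `{"concordant", "discordant", "symmetric-gene"}`.
#' @export
classify_concordance <- function(calls, gene_tbl, q_threshold = 0.10,
                                 stranded = TRUE) {
  stopifnot("call" %in% names(calls))
  g <- gene_tbl
  g$gene_dir <- "S"
  sig <- !g$excluded & !is.na(g$q_value) & g$q_value <= q_threshold
  g$gene_dir[sig & g$fraction > 0.5] <- "M"
  g$gene_dir[sig & g$fraction < 0.5] <- "P"
  biased <- calls[calls$call %in% c("M", "P"), , drop = FALSE]
  hits <- snp_gene_hits(biased,
                        g[, c("chrom", "start", "end", "name", "strand",
                              "gene_dir")],
                        stranded)
  hits$concordance <- dplyr::case_when(
    hits$gene_dir == "S" ~ "symmetric-gene",
    hits$gene_dir == hits$call ~ "concordant",
    TRUE ~ "discordant"
  )
  hits
}

#' Count allele-specificity switches along a gene
#'
#' Number of transitions between distinct biased directions among the
#' position-ordered calls, ignoring symmetric calls in between (so
#' `M, S, P` counts one switch). A gene covered by a single block has zero
#' switches.
#'
#' @param calls Character vector of per-SNP calls ordered by position.
#' @return Integer switch count.
#' @examples
#' count_specificity_switches(c("M", "S", "P", "S", "M"))
#' @export
count_specificity_switches <- function(calls) {
  biased <- calls[calls %in% c("M", "P")]
  if (length(biased) < 2) return(0L)
  sum(biased[-1] != biased[-length(biased)])
}

#' Per-gene switch counts for a call set
#'
#' @inheritParams classify_concordance
#' @return Tibble with `name` (gene) and `n_switches`.
#' @export
gene_switch_counts <- function(calls, gene_tbl, stranded = TRUE) {
  stopifnot("call" %in% names(calls))
  hits <- snp_gene_hits(calls, gene_tbl[, c("chrom", "start", "end",
                                            "name", "strand")],
                        stranded)
  hits <- dplyr::arrange(hits, .data$name, .data$pos)
  dplyr::summarise(dplyr::group_by(hits, .data$name),
                   n_switches = count_specificity_switches(.data$call),
                   .groups = "drop")
}

#' SNP-level performance against annotation-derived truth
#'
#' Same direction-aware metrics as [snp_metrics()], restricted to SNPs
#' with at least one mapped read that carry a non-excluded surrogate-truth
#' label.
#'
#' @param calls Per-SNP tibble with `call`, `total_count` and `truth`
#'   columns (see [surrogate_truth_labels()]).
#' @return One-row metrics tibble.
#' @export
snp_performance_vs_annotation <- function(calls) {
  stopifnot(all(c("call", "truth", "total_count") %in% names(calls)))
  scored <- calls[calls$total_count > 0 & calls$truth %in% STATES, ,
                  drop = FALSE]
  snp_metrics(scored$call, scored$truth)
}
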