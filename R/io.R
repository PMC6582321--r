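#' Read a tab-delimited per-SNP allele-count table
#'
#' The input dialect is the table produced downstream of allele-aware read
#' mapping: tab-delimited columns chromosome, 1-based SNP position,
#' maternal read count, paternal read count, total read count, and an
#' optional strand column. A header line is detected automatically (the
#' position field of a data row must parse as a positive integer); extra
#' trailing columns are tolerated and ignored. Rows whose maternal +
#' paternal counts do not equal the total are rejected with their row
#' number — the reader never silently repairs data. SNPs with zero mapped
#' reads are dropped with a message.
#'
#' @param path Path to the table.
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @return A validated counts tibble sorted by (chrom, strand, pos).
#' @export
read_snp_counts <- function(path, header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (identical(header, "auto")) {
    f <- strsplit(first, "\t", fixed = TRUE)[[1]]
    header <- length(f) >= 2 && is.na(suppressWarnings(as.integer(f[2])))
  }
  raw <- readr::read_tsv(path, col_names = FALSE, skip = as.integer(header),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 5)
    stop("counts table needs at least 5 tab-delimited columns ",
         "(chrom, pos, maternal, paternal, total): ", path)
  parse_int <- function(v, what) {
    out <- suppressWarnings(as.integer(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad) > 0)
      stop(path, ": row ", bad[1] + as.integer(header), " has a ",
           "non-integer ", what, " field ('", v[bad[1]], "')")
    out
  }
  counts <- tibble::tibble(
    chrom = raw[[1]],
    pos = parse_int(raw[[2]], "position"),
    mat_count = parse_int(raw[[3]], "maternal count"),
    pat_count = parse_int(raw[[4]], "paternal count"),
    total_count = parse_int(raw[[5]], "total count")
  )
  if (ncol(raw) >= 6 && all(raw[[6]] %in% c("+", "-", "*"), na.rm = TRUE))
    counts$strand <- raw[[6]]
  bad <- which(counts$mat_count + counts$pat_count != counts$total_count)
  if (length(bad) > 0)
    stop(path, ": row ", bad[1] + as.integer(header),
         ": maternal + paternal counts do not equal the total")
  counts <- validate_counts(counts)
  ch <- build_chains(counts)  # errors on duplicate positions
  counts[ch$order, , drop = FALSE]
}

#' Write a per-SNP allele-count table
#'
#' Inverse of [read_snp_counts()]: tab-delimited with a header line.
#'
#' @param counts Counts tibble.
#' @param path Output path.
#' @export
write_snp_counts <- function(counts, path) {
  counts <- validate_counts(counts, drop_zero = FALSE, quiet = TRUE)
  cols <- c("chrom", "pos", "mat_count", "pat_count", "total_count",
            "strand")
  readr::write_tsv(counts[, intersect(cols, names(counts))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Minimal BED reader: 3-6 tab-delimited columns (chrom, start, end, and
#' optionally name, score, strand), 0-based half-open coordinates, no
#' header.
#'
#' @param path Path to the BED file.
#' @return Tibble with `chrom`, `start`, `end` and any of `name`, `score`,
#'   `strand` present in the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-integer coordinates in BED file: ", path)
  if (any(out$end <= out$start))
    stop("BED intervals must satisfy start < end: ", path)
  if (ncol(raw) >= 4) out$name <- raw[[4]]
  if (ncol(raw) >= 5) out$score <- suppressWarnings(as.numeric(raw[[5]]))
  if (ncol(raw) >= 6) out$strand <- raw[[6]]
  out
}

#' Write called blocks as two BED6 files
#'
#' Emits `<prefix>.all_blocks.bed` (every maternal/paternal block) and
#' `<prefix>.significant_blocks.bed` (blocks with FDR q-value at or below
#' the call set's threshold). Symmetric runs are never written. Names
#' follow the `"<state>_{M:<mat>,P:<pat>}"` convention; the score is
#' `min(1000, round(-10 log10 q))`. Output is sorted by (chrom, start) and
#' byte-deterministic.
#'
#' @param calls An [call_ase_blocks()] result (or a block tibble with the
#'   same columns plus a `significant` flag).
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_blocks_bed <- function(calls, prefix) {
  blocks <- if (inherits(calls, "ase_calls")) calls$blocks else calls
  blocks <- blocks[blocks$state %in% c("M", "P"), , drop = FALSE]
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  fmt <- function(b) {
    if (nrow(b) == 0) return(character(0))
    score <- pmin(1000, round(-10 * log10(pmax(b$q_value, 1e-300))))
    sprintf("%s\t%d\t%d\t%s_{M:%d,P:%d}\t%d\t%s",
            b$chrom, b$start, b$end, b$state, b$mat_reads, b$pat_reads,
            as.integer(score), ifelse(b$strand == "*", ".", b$strand))
  }
  paths <- paste0(prefix, c(".all_blocks.bed", ".significant_blocks.bed"))
  writeLines(fmt(blocks), paths[1])
  writeLines(fmt(blocks[blocks$significant, , drop = FALSE]), paths[2])
  invisible(paths)
}
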