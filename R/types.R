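#' Construct a single-cell methylome
#'
#' A `CellMethylome` bundles one cell's CpG methylation calls with its
#' sample annotation. Calls are stored as raw read counts per strand-collapsed
#' CpG position; binarisation only happens when a region call matrix is built.
#'
#' @param cell_id Cell identifier (unique within a run).
#' @param calls `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (1-based CpG coordinate), `n_meth`, `n_unmeth`. Rows with the same
#'   position are summed.
#' @param individual_id Donor/animal identifier.
#' @param age_group `"young"` or `"old"` (or `NA`).
#' @param age_weeks Chronological age in weeks.
#' @param n_alignments Number of (paired-end) alignments backing the calls;
#'   used by methylome QC.
#' @return An object of class `CellMethylome` with calls sorted by
#'   `(chrom, pos)`.
#' @export
#' @examples
#' cm <- CellMethylome("c1",
#'   data.frame(chrom = "chr1", pos = c(10, 5), n_meth = c(1, 2), n_unmeth = c(0, 1)))
#' cm$calls
CellMethylome <- function(cell_id, calls, individual_id = NA_character_,
                          age_group = NA_character_, age_weeks = NA_real_,
                          n_alignments = NA_integer_) {
  stopifnot(is.character(cell_id), length(cell_id) == 1)
  calls <- as.data.table(calls)
  required <- c("chrom", "pos", "n_meth", "n_unmeth")
  if (!all(required %in% names(calls))) {
    stop("calls must have columns: ", paste(required, collapse = ", "))
  }
  calls <- calls[, .(chrom = as.character(chrom), pos = as.integer(pos),
                     n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  if (nrow(calls)) {
    if (any(calls$n_meth < 0 | calls$n_unmeth < 0)) {
      stop("methylation call counts must be non-negative")
    }
    ## duplicate positions (e.g. strand pairs already mapped to one
    ## coordinate) are merged by summing counts
    calls <- calls[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                   by = .(chrom, pos)]
    if (any(calls$n_meth + calls$n_unmeth < 1)) {
      stop("every CpG call needs at least one observed read")
    }
    if (any(calls$pos < 1)) stop("CpG positions are 1-based; pos >= 1 required")
    setorder(calls, chrom, pos)
  }
  structure(
    list(cell_id = cell_id, individual_id = individual_id,
         age_group = age_group, age_weeks = age_weeks,
         calls = calls[], n_alignments = n_alignments),
    class = "CellMethylome"
  )
}

#' @export
print.CellMethylome <- function(x, ...) {
  cat(sprintf("<CellMethylome> %s (%s, %s, %s wk): %d CpG calls\n",
              x$cell_id, x$individual_id, x$age_group,
              format(x$age_weeks), nrow(x$calls)))
  invisible(x)
}

#' Number of distinct CpG sites covered in a cell
#'
#' @param cell A [CellMethylome].
#' @return Integer count of covered CpG positions.
#' @export
n_cpg_covered <- function(cell) {
  stopifnot(inherits(cell, "CellMethylome"))
  nrow(cell$calls)
}

#' Construct a genomic region table
#'
#' Regions use BED conventions: 0-based half-open `[start, end)` intervals,
#' each carrying a free-text class label (promoter, CGI, LINE-1, H3K27me3,
#' ...) used to stratify heterogeneity contrasts.
#'
#' @param chrom,start,end,region_id,region_class Vectors of equal length.
#' @return A `data.table` with one row per region.
#' @export
region_table <- function(chrom, start, end, region_id,
                         region_class = NA_character_) {
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), region_id = as.character(region_id),
                   region_class = as.character(region_class))
  if (any(dt$start >= dt$end)) stop("regions require start < end (0-based half-open)")
  if (anyDuplicated(dt$region_id)) stop("region_id values must be unique")
  dt[]
}

#' Construct a region call matrix
#'
#' The cells x CpG-sites binary matrix a region's heterogeneity score is
#' computed from: entries are 1 (methylated), 0 (unmethylated) or `NA`
#' (CpG not covered in that cell).
#'
#' @param region_id Region identifier.
#' @param states Numeric matrix (cells x sites) with entries in {0, 1, NA}.
#' @param cell_ids Row labels; defaults to rownames or `cell_1`, ...
#' @param site_positions Column labels (CpG coordinates); defaults to
#'   colnames or `1:ncol`.
#' @return An object of class `RegionCallMatrix`.
#' @export
RegionCallMatrix <- function(region_id, states, cell_ids = NULL,
                             site_positions = NULL) {
  states <- as.matrix(states)
  ok <- is.na(states) | states == 0 | states == 1
  if (!all(ok)) stop("region call matrix entries must be 0, 1 or NA")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(states)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(states)))
  }
  if (is.null(site_positions)) {
    site_positions <- suppressWarnings(as.integer(colnames(states)))
    if (ncol(states) == 0) site_positions <- integer(0)
    else if (is.null(colnames(states)) || anyNA(site_positions)) {
      site_positions <- seq_len(ncol(states))
    }
  }
  stopifnot(length(cell_ids) == nrow(states),
            length(site_positions) == ncol(states))
  dimnames(states) <- list(cell_ids, site_positions)
  structure(list(region_id = as.character(region_id), cell_ids = cell_ids,
                 site_positions = site_positions, states = states),
            class = "RegionCallMatrix")
}

#' @export
print.RegionCallMatrix <- function(x, ...) {
  cat(sprintf("<RegionCallMatrix> %s: %d cells x %d CpG sites (%.1f%% missing)\n",
              x$region_id, nrow(x$states), ncol(x$states),
              if (length(x$states)) 100 * mean(is.na(x$states)) else 0))
  invisible(x)
}

#' Construct a gene-by-cell expression matrix
#'
#' Raw counts plus the per-cell metrics the RNA analyses need:
#' `mapped_total` is the number of reads mapped to nuclear genes (the RPM
#' denominator; it may exceed the column sums because reads can map outside
#' the quantified gene set), `mito_fraction` the fraction of mapped reads on
#' mitochondrial genes.
#'
#' @param counts Non-negative integer matrix, genes x cells, with dimnames.
#' @param mapped_total Per-cell positive totals of reads mapped to the
#'   (nuclear) transcriptome. Defaults to column sums.
#' @param mito_fraction Per-cell fraction in `[0, 1]`, or `NA` if unknown.
#' @param cell_meta Optional `data.frame` of per-cell annotation
#'   (`individual_id`, `age_group`, `age_weeks`, ...), one row per cell.
#' @return An object of class `ExpressionMatrix`; `n_genes_detected` is
#'   computed as the per-cell count of genes with non-zero counts.
#' @export
ExpressionMatrix <- function(counts, mapped_total = NULL, mito_fraction = NULL,
                             cell_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("cell_", seq_len(ncol(counts)))
  if (is.null(mapped_total)) mapped_total <- colSums(counts)
  mapped_total <- setNames(as.numeric(mapped_total), colnames(counts))
  if (any(mapped_total <= 0)) stop("mapped_total must be positive for every cell")
  if (is.null(mito_fraction)) mito_fraction <- rep(NA_real_, ncol(counts))
  mito_fraction <- setNames(as.numeric(mito_fraction), colnames(counts))
  structure(
    list(counts = counts,
         gene_ids = rownames(counts),
         cell_ids = colnames(counts),
         mapped_total = mapped_total,
         mito_fraction = mito_fraction,
         n_genes_detected = setNames(colSums(counts > 0), colnames(counts)),
         cell_meta = if (is.null(cell_meta)) NULL else as.data.table(cell_meta)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d genes x %d cells (median %d genes/cell)\n",
              nrow(x$counts), ncol(x$counts),
              as.integer(median(x$n_genes_detected))))
  invisible(x)
}
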