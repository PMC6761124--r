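#' Cell-level quality control for the RNA modality
#'
#' A cell passes when it detects at least `min_genes` genes, has at least
#' `min_reads` reads mapped to nuclear genes, and (when known) carries less
#' than `max_mito` of its mapped reads on mitochondrial genes.
#'
#' @param matrix An [ExpressionMatrix].
#' @param min_genes Minimum detected genes; default 1000.
#' @param min_reads Minimum nuclear mapped reads; default 1e5. Cells
#'   exactly at the threshold pass.
#' @param max_mito Maximum mitochondrial fraction (exclusive); default 0.10.
#' @return A `data.table` with one row per cell: `cell_id`, `modality`,
#'   the metrics, `pass`, and `reasons` (comma-joined failed-rule labels,
#'   empty when the cell passes). Cells with unknown `mito_fraction` skip
#'   that rule with a warning.
#' @export
rna_cell_qc <- function(matrix, min_genes = 1000, min_reads = 1e5,
                        max_mito = 0.10) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  mito <- matrix$mito_fraction
  if (anyNA(mito)) {
    warning(sum(is.na(mito)),
            " cell(s) lack mito_fraction; mitochondrial rule skipped for them")
  }
  dt <- data.table(
    cell_id = matrix$cell_ids,
    modality = "rna",
    n_genes_detected = as.integer(matrix$n_genes_detected),
    mapped_total = matrix$mapped_total,
    mito_fraction = mito
  )
  reasons <- lapply(seq_len(nrow(dt)), function(i) {
    r <- character(0)
    if (dt$n_genes_detected[i] < min_genes) r <- c(r, "low_genes")
    if (dt$mapped_total[i] < min_reads) r <- c(r, "low_reads")
    if (!is.na(dt$mito_fraction[i]) && dt$mito_fraction[i] >= max_mito) {
      r <- c(r, "high_mito")
    }
    r
  })
  dt[, pass := lengths(reasons) == 0L]
  dt[, reasons := vapply(reasons, paste, "", collapse = ",")]
  dt[]
}

#' Cell-level quality control for the methylation modality
#'
#' Cells with fewer than `min_alignments` paired-end alignments or fewer
#' than `min_cpg` covered CpG sites are discarded; cells exactly at either
#' threshold pass.
#'
#' @param cells List of [CellMethylome] objects.
#' @param min_alignments Default 1e6.
#' @param min_cpg Default 5e5.
#' @return A `data.table` as in [rna_cell_qc()], `modality = "meth"`.
#' @export
meth_cell_qc <- function(cells, min_alignments = 1e6, min_cpg = 5e5) {
  dt <- data.table(
    cell_id = vapply(cells, function(x) x$cell_id, ""),
    modality = "meth",
    n_alignments = vapply(cells, function(x) as.numeric(x$n_alignments), 0),
    n_cpg_covered = vapply(cells, n_cpg_covered, 0L)
  )
  reasons <- lapply(seq_len(nrow(dt)), function(i) {
    r <- character(0)
    if (is.na(dt$n_alignments[i]) || dt$n_alignments[i] < min_alignments) {
      r <- c(r, "low_alignments")
    }
    if (dt$n_cpg_covered[i] < min_cpg) r <- c(r, "low_cpg")
    r
  })
  dt[, pass := lengths(reasons) == 0L]
  dt[, reasons := vapply(reasons, paste, "", collapse = ",")]
  dt[]
}

## Subsample a single methylome to exactly n_reads call units without
## replacement. Each counted read (methylated or unmethylated) at each site
## is one unit; per-site retained counts follow the multivariate
## hypergeometric induced by uniform sampling of units.
downsample_methylome <- function(cell, n_reads) {
  calls <- cell$calls
  units <- as.numeric(rbind(calls$n_meth, calls$n_unmeth))
  total <- sum(units)
  if (total < n_reads) {
    stop(sprintf("cell %s has %g read units, fewer than n_reads = %g",
                 cell$cell_id, total, n_reads))
  }
  if (total == n_reads) return(cell)
  cs <- cumsum(units)
  chosen <- sample.int(total, n_reads)
  cat_idx <- findInterval(chosen - 0.5, cs) + 1L
  kept <- tabulate(cat_idx, nbins = length(units))
  new_meth <- kept[seq(1, length(kept), by = 2)]
  new_unmeth <- kept[seq(2, length(kept), by = 2)]
  keep_row <- (new_meth + new_unmeth) > 0
  CellMethylome(cell$cell_id,
                data.table(chrom = calls$chrom[keep_row],
                           pos = calls$pos[keep_row],
                           n_meth = new_meth[keep_row],
                           n_unmeth = new_unmeth[keep_row]),
                individual_id = cell$individual_id,
                age_group = cell$age_group, age_weeks = cell$age_weeks,
                n_alignments = cell$n_alignments)
}

#' Equalise sequencing depth and cell numbers across individuals
#'
#' To avoid biases from unequal depth or cell counts between individuals,
#' every cell is down-sampled to the same number of read units and the same
#' number of cells is drawn at random from each individual. A read unit is
#' one counted read at one CpG (read-level data are not retained after
#' calling, so calls are treated as read-weighted draws); units are sampled
#' without replacement, which preserves each site's expected methylated
#' fraction.
#'
#' @param cells List of [CellMethylome] objects spanning one or more
#'   individuals.
#' @param n_reads Target read units per cell; default 1e6.
#' @param n_cells Cells to keep per individual; default 35.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return List of [CellMethylome] objects, exactly `n_cells` per
#'   individual, each with `n_reads` retained units.
#' @export
downsample_cells <- function(cells, n_reads = 1e6, n_cells = 35, seed = 1L) {
  indiv <- vapply(cells, function(x) as.character(x$individual_id), "")
  totals <- vapply(cells, function(x) sum(x$calls$n_meth + x$calls$n_unmeth), 0)
  eligible <- totals >= n_reads
  with_seed(seed, {
    out <- list()
    for (id in unique(indiv)) {
      idx <- which(indiv == id & eligible)
      if (length(idx) < n_cells) {
        stop(sprintf(
          "individual %s has %d cells with >= %g read units; %d required",
          id, length(idx), n_reads, n_cells))
      }
      pick <- sort(idx[sample.int(length(idx), n_cells)])
      out <- c(out, lapply(cells[pick], downsample_methylome, n_reads = n_reads))
    }
    out
  })
}
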