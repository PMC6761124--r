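#' Reads-per-million normalisation
#'
#' Expression is expressed as reads per million of reads mapped to the
#' transcriptome: `count * 1e6 / mapped_total` per cell.
#'
#' @param matrix An [ExpressionMatrix] with positive `mapped_total`.
#' @return A genes x cells numeric matrix of RPM values.
#' @export
normalise_rpm <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (any(matrix$mapped_total <= 0)) stop("mapped_total must be positive")
  sweep(matrix$counts, 2, matrix$mapped_total / 1e6, "/")
}

#' Distance to the median: expression-level-adjusted variability
#'
#' For every gene with mean normalised count of at least `min_mean`, the
#' squared coefficient of variation (CV^2 = variance / mean^2) is computed
#' across cells; genes are ordered by mean expression and the variability
#' trend is fitted as a rolling average of `log2(CV^2)` over `window`
#' genes. A gene's distance to the median (DM) is its `log2(CV^2)` minus
#' that rolling trend, i.e. how much more variable the gene is than genes
#' of similar expression.
#'
#' @param normalised Genes x cells RPM matrix from [normalise_rpm()].
#' @param min_mean Minimum mean normalised count; default 10.
#' @param window Rolling-average window in genes; default 100.
#' @return `data.table` (`gene_id`, `mean_rpm`, `cv2`, `dm`), sorted by
#'   mean expression. Genes with zero variance get `dm = NA`.
#' @export
distance_to_median <- function(normalised, min_mean = 10, window = 100) {
  mu <- rowMeans(normalised)
  keep <- mu >= min_mean
  if (sum(keep) < window) {
    stop(sprintf("only %d genes pass min_mean = %g; need >= window = %d",
                 sum(keep), min_mean, window))
  }
  m <- normalised[keep, , drop = FALSE]
  mu <- mu[keep]
  v <- apply(m, 1, var)
  cv2 <- v / mu^2
  dt <- data.table(gene_id = rownames(m), mean_rpm = mu, cv2 = cv2)
  setorder(dt, mean_rpm, gene_id)
  log_cv2 <- ifelse(dt$cv2 > 0, log2(dt$cv2), NA_real_)
  if (anyNA(log_cv2)) {
    warning(sum(is.na(log_cv2)), " zero-variance gene(s); dm set to NA")
    ok <- !is.na(log_cv2)
    trend <- rep(NA_real_, nrow(dt))
    trend[ok] <- rolling_mean(log_cv2[ok], window)
    dt[, dm := log_cv2 - trend]
  } else {
    dt[, dm := log_cv2 - rolling_mean(log_cv2, window)]
  }
  dt[]
}

#' Expression frequency per age group
#'
#' The frequency of gene expression is the fraction of cells in a group
#' with a non-zero count. Genes whose frequency drops by more than
#' `flag_threshold` from young to old are flagged as frequency-variable.
#'
#' @param matrix An [ExpressionMatrix] (raw counts).
#' @param group_labels Per-cell labels, `"young"` / `"old"`.
#' @param flag_threshold Default 0.15 (a difference above 15% flags).
#' @return `data.table` with `gene_id`, `freq_young`, `freq_old`,
#'   `delta_freq` (young - old) and `flagged`.
#' @export
expression_frequency <- function(matrix, group_labels, flag_threshold = 0.15) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            length(group_labels) == length(matrix$cell_ids))
  for (g in c("young", "old")) {
    if (!any(group_labels == g)) stop("no cells labelled ", g)
  }
  expressed <- matrix$counts > 0
  dt <- data.table(
    gene_id = matrix$gene_ids,
    freq_young = rowMeans(expressed[, group_labels == "young", drop = FALSE]),
    freq_old = rowMeans(expressed[, group_labels == "old", drop = FALSE])
  )
  dt[, delta_freq := freq_young - freq_old]
  dt[, flagged := delta_freq > flag_threshold]
  dt[]
}

#' Top variable genes by distance to the median
#'
#' @param stats Output of [distance_to_median()].
#' @param n Number of genes; 500 per individual and 1000 data-set-wide are
#'   the conventional choices.
#' @return Character vector of gene ids, ranked by decreasing `dm`; ties
#'   broken by gene id for determinism.
#' @export
top_variable_genes <- function(stats, n = 500) {
  dt <- as.data.table(stats)[!is.na(dm)]
  setorder(dt, -dm, gene_id)
  if (n > nrow(dt)) {
    warning("asked for ", n, " genes but only ", nrow(dt), " available")
    n <- nrow(dt)
  }
  dt$gene_id[seq_len(n)]
}

#' Cell-cell Spearman correlation and random cohorts
#'
#' Computes all within-set pairwise Spearman correlations over a gene set
#' (typically the top 500 most variable genes of the individual), and the
#' mean pairwise correlation of `n_iter` randomly drawn cohorts of
#' `cohort_size` cells.
#'
#' @param normalised Genes x cells RPM matrix (one individual).
#' @param gene_set Gene ids to correlate over.
#' @param cohort_size Cells per cohort; default 10.
#' @param n_iter Cohorts to draw; default 1000.
#' @param seed Integer seed; cohort draws are deterministic given the seed.
#' @return List: `pairwise` (`data.table` of `cell_i`, `cell_j`, `rho`),
#'   `cohort_means` (length `n_iter`), `excluded_cells` (constant-profile
#'   cells whose correlations are undefined and excluded).
#' @export
cell_correlation_analysis <- function(normalised, gene_set, cohort_size = 10,
                                      n_iter = 1000, seed = 1L) {
  missing_genes <- setdiff(gene_set, rownames(normalised))
  if (length(missing_genes)) stop("gene_set contains unknown genes")
  sub <- normalised[gene_set, , drop = FALSE]
  n_cells <- ncol(sub)
  if (cohort_size > n_cells) stop("cohort_size exceeds the number of cells")
  constant <- apply(sub, 2, function(x) sd(x) == 0 || !is.finite(sd(x)))
  excluded <- colnames(sub)[constant]
  rho <- suppressWarnings(cor(sub, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pairwise <- data.table(cell_i = colnames(sub)[ut[, 1]],
                         cell_j = colnames(sub)[ut[, 2]],
                         rho = rho[ut])
  pairwise <- pairwise[!is.na(rho)]
  cohort_means <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    idx <- sample(n_cells, cohort_size)
    sub_rho <- rho[idx, idx]
    mean(sub_rho[upper.tri(sub_rho)], na.rm = TRUE)
  }, numeric(1)))
  list(pairwise = pairwise, cohort_means = cohort_means,
       excluded_cells = excluded)
}

#' Similarity of old cells to the young reference transcriptome
#'
#' The young reference is the per-gene mean of `log2(RPM + 1)` across young
#' cells. Each old cell's Spearman correlation with the reference is its
#' similarity score; old cells are ranked by it (rank 1 = most similar).
#' Genes expressed in fewer than `min_cells` cells are excluded. Each
#' gene's expression across old cells is then Spearman-correlated with the
#' similarity score, and the top `n_top` correlated and anticorrelated
#' genes are reported.
#'
#' @param normalised Genes x cells RPM matrix covering both ages.
#' @param young_cells,old_cells Cell id vectors.
#' @param min_cells Gene expression filter; default 5.
#' @param n_top Genes per direction; default 200.
#' @return List: `similarity` (`cell_id`, `rho`, `rank`),
#'   `gene_correlation` (`gene_id`, `rho_similarity`), `top_correlated`,
#'   `top_anticorrelated`.
#' @export
similarity_to_young <- function(normalised, young_cells, old_cells,
                                min_cells = 5, n_top = 200) {
  stopifnot(length(young_cells) >= 1, length(old_cells) >= 2)
  if (!all(c(young_cells, old_cells) %in% colnames(normalised))) {
    stop("young_cells / old_cells must be columns of the normalised matrix")
  }
  expressed_in <- rowSums(normalised[, c(young_cells, old_cells), drop = FALSE] > 0)
  keep <- expressed_in >= min_cells
  if (sum(keep) < 2) stop("fewer than 2 genes pass the min_cells filter")
  lg <- log2(normalised[keep, , drop = FALSE] + 1)
  reference <- rowMeans(lg[, young_cells, drop = FALSE])
  rho <- vapply(old_cells, function(cc) {
    suppressWarnings(cor(lg[, cc], reference, method = "spearman"))
  }, numeric(1))
  sim <- data.table(cell_id = old_cells, rho = rho)
  setorder(sim, -rho, cell_id)
  sim[, rank := seq_len(.N)]
  old_lg <- lg[, old_cells, drop = FALSE]
  rho_by_cell <- rho[old_cells]
  gene_rho <- apply(old_lg, 1, function(x) {
    suppressWarnings(cor(x, rho_by_cell, method = "spearman"))
  })
  gc <- data.table(gene_id = names(gene_rho), rho_similarity = gene_rho)
  gc <- gc[!is.na(rho_similarity)]
  setorder(gc, -rho_similarity, gene_id)
  n_top <- min(n_top, nrow(gc))
  list(similarity = sim[],
       gene_correlation = gc[],
       top_correlated = gc$gene_id[seq_len(n_top)],
       top_anticorrelated = rev(gc$gene_id)[seq_len(n_top)])
}
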