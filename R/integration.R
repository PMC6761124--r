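#' Per-cell association of promoter methylation and expression
#'
#' For every cell, the Pearson correlation across genes between promoter
#' methylation and expression — one association test per cell. Cells with
#' fewer than `min_genes` genes measured in both layers are omitted.
#'
#' @param promoter_meth Genes x cells matrix of per-cell promoter
#'   methylation (coverage-weighted means; `NA` where uncovered).
#' @param expression Genes x cells matrix of per-cell expression (log
#'   RPM), same dimnames as `promoter_meth` (row/column intersection is
#'   used).
#' @param min_genes Minimum matched genes per cell; default 10.
#' @return `data.table` with `cell_id`, `r`, `n_genes_used`; omitted cells
#'   listed in attribute `omitted` with their matched-gene counts.
#' @export
per_cell_association <- function(promoter_meth, expression, min_genes = 10) {
  genes <- intersect(rownames(promoter_meth), rownames(expression))
  cells <- intersect(colnames(promoter_meth), colnames(expression))
  if (length(genes) == 0) stop("no genes shared between the two layers")
  if (length(cells) == 0) stop("no cells shared between the two layers")
  pm <- promoter_meth[genes, cells, drop = FALSE]
  ex <- expression[genes, cells, drop = FALSE]
  res <- lapply(cells, function(cc) {
    ok <- !is.na(pm[, cc]) & !is.na(ex[, cc])
    n <- sum(ok)
    if (n < min_genes) return(data.table(cell_id = cc, r = NA_real_, n_genes_used = n))
    data.table(cell_id = cc,
               r = suppressWarnings(cor(pm[ok, cc], ex[ok, cc])),
               n_genes_used = n)
  })
  res <- rbindlist(res)
  omitted <- res[n_genes_used < min_genes]
  res <- res[n_genes_used >= min_genes]
  data.table::setattr(res, "omitted", omitted)
  res[]
}

## Exact null distribution of the group-1 rank sum under random assignment
## of n1 of the n (mid-)ranks, by dynamic programming over doubled ranks
## (doubling makes mid-ranks integral).
ranksum_exact_p <- function(ranks2, n1, w2, alternative) {
  n <- length(ranks2)
  total <- sum(ranks2)
  ## ways[j + 1, s + 1] = number of size-j subsets with doubled-rank sum s
  ways <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  ways[1, 1] <- 1
  for (r in ranks2) {
    ## 0/1-knapsack update; descending j keeps row j at pre-item values
    ## when row j + 1 is updated
    for (j in n1:1) {
      idx <- (r + 1):(total + 1)
      ways[j + 1, idx] <- ways[j + 1, idx] + ways[j, seq_len(total + 1 - r)]
    }
  }
  dist <- ways[n1 + 1, ]
  support <- which(dist > 0) - 1
  probs <- dist[support + 1] / sum(dist[support + 1])
  eps <- 1e-9
  switch(alternative,
    greater = sum(probs[support >= w2 - eps]),
    less = sum(probs[support <= w2 + eps]),
    two.sided = {
      mu <- sum(probs * support)
      sum(probs[abs(support - mu) >= abs(w2 - mu) - eps])
    })
}

#' Two-group rank-sum (Mann-Whitney-Wilcoxon) contrast
#'
#' Rank-sum test with mid-ranks for ties. For small samples (total n at
#' most `exact_max`) the p-value is exact, computed from the full
#' permutation null distribution of the rank sum (a dynamic program over
#' the ranks, equivalent to enumerating all group assignments); the exact
#' two-sided p is the probability of a rank sum at least as far from its
#' null mean as observed. Larger samples use the normal approximation with
#' tie correction and continuity correction.
#'
#' @param values Numeric vector.
#' @param groups Two-level vector (factor/character) aligned with
#'   `values`; the first level is the "greater" group of the alternative.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @param exact_max Largest total n for the exact computation; default 30.
#' @return List: `statistic` (Mann-Whitney U of group 1), `p`, `method`,
#'   `n` (group sizes).
#' @export
group_contrast <- function(values, groups,
                           alternative = c("two.sided", "greater", "less"),
                           exact_max = 30) {
  alternative <- match.arg(alternative)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two non-empty groups required")
  groups <- droplevels(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 == 0 || n2 == 0) stop("exactly two non-empty groups required")
  n <- n1 + n2
  ranks <- rank(values)
  w <- sum(ranks[groups == levels(groups)[1]])
  u <- w - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    p <- ranksum_exact_p(as.integer(round(2 * ranks)), n1, 2 * w, alternative)
    method <- "exact"
  } else {
    ties <- table(ranks)
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      correction <- switch(alternative,
                           two.sided = sign(z) * 0.5,
                           greater = 0.5, less = -0.5)
      z <- (z - correction) / sqrt(sigma2)
      p <- switch(alternative,
                  two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5),
                  greater = pnorm(z, lower.tail = FALSE),
                  less = pnorm(z))
    }
    method <- "normal_approx"
  }
  list(statistic = u, p = p, method = method, n = c(n1 = n1, n2 = n2))
}

#' Contrast methylation and transcriptional heterogeneity changes
#'
#' Computes a windowed Z-score of the young-to-old change in
#' transcriptional heterogeneity (per-gene distance to the median),
#' mirroring the normalisation used for methylation heterogeneity
#' differences: `d = dm_old - dm_young`, ordered by the mean of the young
#' and old values and standardised in a sliding window. As for the
#' methylation layer, the window ordering uses the covariate the raw
#' statistic depends on — mean expression (`log2` of the young/old mean
#' RPM average) when `mean_rpm` columns are present, otherwise the mean of
#' the two DM values. Promoters are then stratified at
#' `delta_H_z > threshold` and the two strata compared with a rank-sum
#' test on the transcriptional Z-scores.
#'
#' @param delta_meth `data.table` with `gene_id` (or `promoter_id` mapped
#'   to genes) and `delta_H_z` per promoter.
#' @param dm_young,dm_old `data.table`s with `gene_id`, `dm` and ideally
#'   `mean_rpm` (from [distance_to_median()], possibly averaged over
#'   individuals).
#' @param mapping Optional `data.table` with `promoter_id`, `gene_id`
#'   linking the layers; omit when `delta_meth` already carries `gene_id`.
#' @param threshold Stratification cut on `delta_H_z`; default 0.3.
#' @param window Z-score window; default 100.
#' @param alternative Passed to [group_contrast()] with the high-delta
#'   stratum first; default `"greater"`.
#' @return List: `table` (`gene_id`, `delta_H_z`, `d`, `delta_txn_het`,
#'   `high_meth_het`) and `contrast` (the rank-sum result).
#' @export
delta_layer_comparison <- function(delta_meth, dm_young, dm_old,
                                   mapping = NULL, threshold = 0.3,
                                   window = 100, alternative = "greater") {
  dm <- as.data.table(delta_meth)
  if (!is.null(mapping)) {
    dm <- merge(dm, as.data.table(mapping), by = "promoter_id")
  }
  if (!"gene_id" %in% names(dm)) stop("delta_meth needs gene_id (or a mapping)")
  yt <- as.data.table(dm_young)
  ot <- as.data.table(dm_old)
  has_mean <- all(c("mean_rpm") %in% names(yt)) && "mean_rpm" %in% names(ot)
  y <- if (has_mean) yt[, .(gene_id, dm_young = dm, mean_young = mean_rpm)]
       else yt[, .(gene_id, dm_young = dm)]
  o <- if (has_mean) ot[, .(gene_id, dm_old = dm, mean_old = mean_rpm)]
       else ot[, .(gene_id, dm_old = dm)]
  tab <- merge(merge(dm[, .(gene_id, delta_H_z)], y, by = "gene_id"),
               o, by = "gene_id")
  tab <- tab[!is.na(dm_young) & !is.na(dm_old) & !is.na(delta_H_z)]
  tab[, d := dm_old - dm_young]
  if (has_mean) {
    tab[, order_key := log2((mean_young + mean_old) / 2 + 1)]
    tab[, c("mean_young", "mean_old") := NULL]
  } else {
    tab[, order_key := (dm_young + dm_old) / 2]
  }
  setorder(tab, order_key, gene_id)
  tab[, delta_txn_het := sliding_window_z(d, window)]
  tab[, order_key := NULL]
  tab[, high_meth_het := delta_H_z > threshold]
  sizes <- table(tab$high_meth_het)
  if (!all(c("TRUE", "FALSE") %in% names(sizes))) {
    stop(sprintf("a stratum is empty at threshold %g (high = %d, rest = %d)",
                 threshold, sum(tab$high_meth_het), sum(!tab$high_meth_het)))
  }
  contrast <- group_contrast(
    tab$delta_txn_het,
    factor(ifelse(tab$high_meth_het, "high", "rest"), levels = c("high", "rest")),
    alternative = alternative)
  list(table = tab[], contrast = contrast)
}

#' Per-cell promoter methylation matrix
#'
#' Coverage-weighted mean methylation of each promoter region in each
#' cell; cells covering fewer than `min_cpg` CpGs in a promoter contribute
#' `NA` for it.
#'
#' @param cells List of [CellMethylome].
#' @param promoters A [region_table()] of promoter regions whose
#'   `region_id` is the associated gene id.
#' @param min_cpg Minimum covered CpGs per cell and promoter; default 3.
#' @return Promoters x cells numeric matrix of methylated-read fractions.
#' @export
promoter_methylation_matrix <- function(cells, promoters, min_cpg = 3) {
  cell_ids <- vapply(cells, function(x) x$cell_id, "")
  out <- matrix(NA_real_, nrow = nrow(promoters), ncol = length(cells),
                dimnames = list(promoters$region_id, cell_ids))
  for (ci in seq_along(cells)) {
    calls <- cells[[ci]]$calls
    for (ri in seq_len(nrow(promoters))) {
      sub <- calls[chrom == promoters$chrom[ri] &
                     pos > promoters$start[ri] & pos <= promoters$end[ri]]
      if (nrow(sub) >= min_cpg) {
        out[ri, ci] <- sum(sub$n_meth) / sum(sub$n_meth + sub$n_unmeth)
      }
    }
  }
  out
}
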