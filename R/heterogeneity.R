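## Pattern counts for all cell pairs of a region call matrix, via matrix
## products on the methylated / unmethylated indicator matrices. For cells
## i, j: n11 = sites methylated in both, n00 = unmethylated in both,
## n10 / n01 = discordant sites; k = n11 + n00 + n10 + n01 is the number of
## CpGs covered in both cells.
pair_pattern_counts <- function(states) {
  A <- states; A[is.na(A)] <- 0
  B <- 1 - states; B[is.na(B)] <- 0
  n11 <- tcrossprod(A)
  n00 <- tcrossprod(B)
  n10 <- tcrossprod(A, B)
  list(n11 = n11, n00 = n00, n10 = n10, n01 = t(n10))
}

entropy_term <- function(p) ifelse(p > 0, -p * log2(p), 0)

#' Pairwise Hamming / entropy statistics for two cells
#'
#' Restricts to CpG sites covered in both cells (`k` of them). `D` is the
#' normalised Hamming distance: the fraction of those sites at which the
#' two binary states differ. `S` is the joint Shannon entropy, in bits, of
#' the ordered state-pair pattern over the four outcomes
#' `(0,0), (0,1), (1,0), (1,1)`, with `0 log2 0 := 0`; its maximum is 2.
#' The pair weight `w` equals `k`. Pairs sharing fewer than
#' `min_shared_sites` CpGs are not considered.
#'
#' @param row_i,row_j Vectors over the same site columns with entries in
#'   {0, 1, NA}.
#' @param min_shared_sites Minimum shared covered CpGs; default 4.
#' @return A list with `k`, `D`, `S`, `w`, or `NULL` when the pair fails
#'   the shared-coverage filter.
#' @export
#' @examples
#' pair_stats(c(1, 0, 1, 0), c(0, 1, 0, 1))  # D = 1, S = 1
pair_stats <- function(row_i, row_j, min_shared_sites = 4) {
  if (length(row_i) != length(row_j)) {
    stop("cells must be compared over the same site columns")
  }
  shared <- !is.na(row_i) & !is.na(row_j)
  k <- sum(shared)
  if (k < min_shared_sites) return(NULL)
  xi <- row_i[shared]; xj <- row_j[shared]
  D <- sum(abs(xi - xj)) / k
  counts <- c(sum(xi == 0 & xj == 0), sum(xi == 0 & xj == 1),
              sum(xi == 1 & xj == 0), sum(xi == 1 & xj == 1))
  p <- counts / k
  S <- sum(entropy_term(p))
  list(k = k, D = D, S = S, w = k)
}

#' Region heterogeneity score
#'
#' The cell-to-cell methylation heterogeneity of a region is the product of
#' two coverage-weighted means over qualifying cell pairs:
#' \deqn{H(r) = \frac{\sum_c w_c D_c}{\sum_c w_c} \times
#'              \frac{\sum_c w_c S_c}{\sum_c w_c}}
#' with `D` the pairwise normalised Hamming distance, `S` the pairwise
#' joint Shannon entropy and weights `w = k`, the shared covered CpG count
#' of the pair. The score lies in `[0, 2]`, is zero whenever all shared
#' patterns are identical, detects stochastic cell-to-cell heterogeneity,
#' and is robust to missing values because every pair is evaluated only on
#' its shared sites.
#'
#' @param matrix A [RegionCallMatrix] with at least 2 cells.
#' @param min_shared_sites Pairs sharing fewer CpGs are dropped; default 4.
#' @return A list: `H` (NA when no pair qualifies), and `pairs`, a
#'   `data.table` of the qualifying pairs with `i`, `j`, `k`, `D`, `S`.
#' @export
region_heterogeneity <- function(matrix, min_shared_sites = 4) {
  stopifnot(inherits(matrix, "RegionCallMatrix"))
  states <- matrix$states
  n <- nrow(states)
  if (n < 2) stop("region heterogeneity needs at least 2 cells")
  if (ncol(states) == 0) {
    return(list(H = NA_real_,
                pairs = data.table(i = integer(), j = integer(),
                                   k = numeric(), D = numeric(), S = numeric())))
  }
  pc <- pair_pattern_counts(states)
  ut <- upper.tri(pc$n11)
  k <- (pc$n11 + pc$n00 + pc$n10 + pc$n01)[ut]
  idx <- which(ut, arr.ind = TRUE)
  keep <- k >= min_shared_sites
  if (!any(keep)) {
    return(list(H = NA_real_,
                pairs = data.table(i = integer(), j = integer(),
                                   k = numeric(), D = numeric(), S = numeric())))
  }
  k <- k[keep]
  n11 <- pc$n11[ut][keep]; n00 <- pc$n00[ut][keep]
  n10 <- pc$n10[ut][keep]; n01 <- pc$n01[ut][keep]
  D <- (n10 + n01) / k
  S <- entropy_term(n00 / k) + entropy_term(n01 / k) +
       entropy_term(n10 / k) + entropy_term(n11 / k)
  H <- (sum(k * D) / sum(k)) * (sum(k * S) / sum(k))
  list(H = H,
       pairs = data.table(i = idx[keep, 1], j = idx[keep, 2],
                          k = k, D = D, S = S))
}

#' Coverage-weighted mean methylation of a region
#'
#' Each cell contributes its within-region mean weighted by the number of
#' CpGs it covers, which equals the grand mean over all non-missing
#' entries.
#'
#' @param matrix A [RegionCallMatrix].
#' @return Mean methylation in `[0, 1]`; `NA` if no entry is observed.
#' @export
region_mean_methylation <- function(matrix) {
  stopifnot(inherits(matrix, "RegionCallMatrix"))
  if (length(matrix$states) == 0 || all(is.na(matrix$states))) return(NA_real_)
  mean(matrix$states, na.rm = TRUE)
}

#' Summarise one region call matrix into a heterogeneity record
#'
#' @param matrix A [RegionCallMatrix].
#' @param min_shared_sites Passed to [region_heterogeneity()].
#' @return One-row `data.table`: `region_id`, `H`, `mean_meth`,
#'   `n_cpg_total` (site columns), `mean_cpg_per_cell` (mean covered sites
#'   per cell), `n_pairs` (qualifying pairwise comparisons).
#' @export
region_het_record <- function(matrix, min_shared_sites = 4) {
  het <- region_heterogeneity(matrix, min_shared_sites)
  data.table(
    region_id = matrix$region_id,
    H = het$H,
    mean_meth = region_mean_methylation(matrix),
    n_cpg_total = ncol(matrix$states),
    mean_cpg_per_cell = if (length(matrix$states)) mean(rowSums(!is.na(matrix$states))) else 0,
    n_pairs = nrow(het$pairs)
  )
}

#' Heterogeneity records for many regions of one cell set
#'
#' Builds the call matrix of every region from the given cells (typically
#' one individual, or one age group when individuals are pooled) and
#' summarises it with [region_het_record()].
#'
#' @param cells List of [CellMethylome] objects.
#' @param regions A [region_table()].
#' @param binarise_threshold Passed to [build_region_matrix()].
#' @param min_shared_sites Passed to [region_heterogeneity()].
#' @return A `data.table`, one row per region, with `region_class` joined
#'   back on.
#' @export
region_het_table <- function(cells, regions, binarise_threshold = 0.5,
                             min_shared_sites = 4) {
  recs <- rbindlist(lapply(seq_len(nrow(regions)), function(i) {
    m <- build_region_matrix(cells, regions[i], binarise_threshold)
    region_het_record(m, min_shared_sites)
  }))
  recs[, region_class := regions$region_class[match(region_id, regions$region_id)]]
  recs[]
}

#' Coverage and comparability filters on regions
#'
#' Excludes regions with unreliable heterogeneity estimates. A region is
#' kept iff, in BOTH age groups, it has at least `min_cpg_total` CpG sites,
#' at least `min_cpg_per_cell` CpGs covered per cell on average, and at
#' least `min_pairs` cell-to-cell pairwise comparisons; and additionally
#' the two ages do not differ by more than `max_cpg_per_cell_diff` in mean
#' CpGs per cell nor by more than `max_pairs_diff` in pairwise comparisons.
#' Regions present in only one age are excluded.
#'
#' @param young_stats,old_stats `data.table`s with `region_id`,
#'   `n_cpg_total`, `mean_cpg_per_cell`, `n_pairs` (e.g. from
#'   [region_het_table()]).
#' @param min_cpg_total Default 20 (fewer than 20 sites excludes).
#' @param min_cpg_per_cell Default 2.
#' @param min_pairs Default 100 (fewer than 100 comparisons excludes;
#'   exactly 100 is kept).
#' @param max_cpg_per_cell_diff,max_pairs_diff Age coverage-difference
#'   exclusions; defaults 10 and 200 (differences strictly above exclude).
#' @return A `data.table` with `region_id`, `keep`, and `reason` (first
#'   violated rule, empty when kept).
#' @export
filter_regions <- function(young_stats, old_stats,
                           min_cpg_total = 20, min_cpg_per_cell = 2,
                           min_pairs = 100,
                           max_cpg_per_cell_diff = 10, max_pairs_diff = 200) {
  y <- as.data.table(young_stats)
  o <- as.data.table(old_stats)
  all_ids <- union(y$region_id, o$region_id)
  m <- merge(y[, .(region_id, y_cpg = n_cpg_total, y_mcc = mean_cpg_per_cell,
                   y_pairs = n_pairs)],
             o[, .(region_id, o_cpg = n_cpg_total, o_mcc = mean_cpg_per_cell,
                   o_pairs = n_pairs)],
             by = "region_id", all = TRUE)
  reason <- vapply(seq_len(nrow(m)), function(i) {
    r <- m[i]
    if (anyNA(r)) return("missing_in_one_age")
    if (r$y_cpg < min_cpg_total || r$o_cpg < min_cpg_total) return("few_cpg_sites")
    if (r$y_mcc < min_cpg_per_cell || r$o_mcc < min_cpg_per_cell) return("low_cpg_per_cell")
    if (r$y_pairs < min_pairs || r$o_pairs < min_pairs) return("few_pairs")
    if (abs(r$o_mcc - r$y_mcc) > max_cpg_per_cell_diff) return("cpg_coverage_age_diff")
    if (abs(r$o_pairs - r$y_pairs) > max_pairs_diff) return("pair_count_age_diff")
    ""
  }, "")
  out <- data.table(region_id = m$region_id, keep = reason == "", reason = reason)
  out[match(all_ids, region_id)][]
}

#' Mean-methylation normalisation of heterogeneity
#'
#' Raw heterogeneity depends on a region's methylation level (it vanishes
#' as the mean approaches 0 or 1). The normalised measure is the distance
#' to a rolling median of the score as a function of mean methylation:
#' records are restricted to the mean-methylation band, sorted by
#' `mean_meth`, and `H_norm = H - rolling_median(H, window)` with centred
#' windows truncated at the edges.
#'
#' @param records `data.table` with `region_id`, `H`, `mean_meth` (rows
#'   with `NA` in either are dropped).
#' @param window Rolling-median window (observations); default 1000.
#' @param meth_band Inclusive band of mean methylation retained; regions
#'   below 0.05 or above 0.9 are excluded by default.
#' @param min_records Error if fewer records remain; default 50.
#' @return The banded records, sorted by `mean_meth`, with `H_norm` added.
#' @export
normalise_heterogeneity <- function(records, window = 1000,
                                    meth_band = c(0.05, 0.9),
                                    min_records = 50) {
  rec <- as.data.table(records)
  rec <- rec[!is.na(H) & !is.na(mean_meth)]
  rec <- rec[mean_meth >= meth_band[1] & mean_meth <= meth_band[2]]
  if (nrow(rec) < min_records) {
    stop(sprintf(paste0("only %d regions inside the mean-methylation band; ",
                        "need >= %d (consider a smaller window)"),
                 nrow(rec), min_records))
  }
  setorder(rec, mean_meth, region_id)
  rec[, H_norm := H - rolling_median(H, window)]
  rec[]
}

#' Sliding-window Z-score of young/old heterogeneity differences
#'
#' For matched regions, the difference `d = H_norm(old) - H_norm(young)`
#' is Z-score normalised in a sliding window of `window` observations
#' ordered by the mean value of young and old: each region's `d` is
#' standardised against the mean and s.d. of the centred window around it
#' (edge windows truncated; a zero-variance window gives z = 0). Windows
#' are ordered by the mean of the two ages' mean methylation levels — the
#' covariate the raw score depends on — so that the local null the Z-score
#' is taken against is "regions at a similar methylation level", not
#' "regions with similar heterogeneity" (the latter would subtract genuine
#' coordinated shifts back out; it is available as
#' `order_by = "H_norm"`).
#'
#' @param young_records,old_records Outputs of [normalise_heterogeneity()]
#'   for the two ages; their region sets must match exactly.
#' @param window Default 100.
#' @param order_by `"mean_meth"` (default) or `"H_norm"`.
#' @return `data.table` with `region_id`, `H_norm_young`, `H_norm_old`,
#'   `d`, `delta_H_z`, sorted by the window ordering.
#' @export
delta_het_zscore <- function(young_records, old_records, window = 100,
                             order_by = c("mean_meth", "H_norm")) {
  order_by <- match.arg(order_by)
  y <- as.data.table(young_records)
  o <- as.data.table(old_records)
  only_y <- setdiff(y$region_id, o$region_id)
  only_o <- setdiff(o$region_id, y$region_id)
  if (length(only_y) || length(only_o)) {
    stop("unmatched regions between ages: ",
         paste(utils::head(c(only_y, only_o), 10), collapse = ", "),
         if (length(c(only_y, only_o)) > 10) ", ..." else "")
  }
  key_cols <- if (order_by == "mean_meth") {
    list(y = y[, .(region_id, H_norm_young = H_norm, key_y = mean_meth)],
         o = o[, .(region_id, H_norm_old = H_norm, key_o = mean_meth)])
  } else {
    list(y = y[, .(region_id, H_norm_young = H_norm, key_y = H_norm)],
         o = o[, .(region_id, H_norm_old = H_norm, key_o = H_norm)])
  }
  m <- merge(key_cols$y, key_cols$o, by = "region_id")
  m[, d := H_norm_old - H_norm_young]
  m[, order_key := (key_y + key_o) / 2]
  setorder(m, order_key, region_id)
  m[, delta_H_z := sliding_window_z(d, window)]
  m[, c("order_key", "key_y", "key_o") := NULL]
  m[]
}
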