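test_that("RPM normalisation scales by mapped totals", {
  counts <- rbind(g1 = c(5, 10), g2 = c(0, 2))
  colnames(counts) <- c("c1", "c2")
  em <- ExpressionMatrix(counts, mapped_total = c(1e6, 2e6))
  rpm <- normalise_rpm(em)
  expect_equal(unname(rpm["g1", ]), c(5, 5))
  expect_equal(unname(rpm["g2", "c2"]), 1)
  # column sums equal 1e6 x assigned/mapped fraction
  expect_equal(unname(colSums(rpm)),
               unname(1e6 * colSums(counts) / c(1e6, 2e6)))

  # doubling a cell's counts and total leaves RPM unchanged
  em2 <- ExpressionMatrix(counts * 2, mapped_total = c(2e6, 4e6))
  expect_equal(normalise_rpm(em2), rpm)
})

test_that("distance to the median is level-adjusted variability", {
  # constant CV^2 across the mean range: dm = 0 for every gene
  set.seed(6)
  n_genes <- 300; n_cells <- 80
  mu <- seq(20, 500, length.out = n_genes)
  # construct a matrix with exactly known mean and variance pattern by
  # scaling one centred profile: cv2 identical for all genes
  base <- rnorm(n_cells)
  base <- (base - mean(base)) / sd(base)
  rpm <- outer(mu, 1 + 0.3 * base)  # sd/mean = 0.3 for every gene
  rownames(rpm) <- sprintf("g%03d", seq_len(n_genes))
  dm <- distance_to_median(rpm, min_mean = 10, window = 50)
  expect_true(all(abs(dm$dm) < 1e-10))

  # genes under the mean filter are excluded
  rpm2 <- rbind(rpm, low1 = rep(9.9, n_cells))
  dm2 <- distance_to_median(rpm2, min_mean = 10, window = 50)
  expect_false("low1" %in% dm2$gene_id)
  expect_error(distance_to_median(rpm[1:10, ], min_mean = 10, window = 50),
               "window")

  # dm is invariant to a global rescaling of all cells' totals
  dm3 <- distance_to_median(rpm * 2, min_mean = 10, window = 50)
  expect_equal(dm3$dm, dm$dm, tolerance = 1e-12)
})

test_that("dm separates inflated-dispersion genes without tracking the mean", {
  # inflated genes spread across the whole mean range (every 10th gene) so
  # the rolling trend reflects the typical, not the inflated, dispersion
  n_genes <- 600
  disp <- rep(0.1, n_genes)
  inflated_idx <- seq(5, n_genes, by = 10)
  disp[inflated_idx] <- 0.4
  spec <- sim_expr_spec(n_genes = n_genes, n_cells = 200,
                        mean_grid = exp(seq(log(10), log(500), length.out = n_genes)),
                        dispersion = disp,
                        dropout_logit_params = c(2, 1), seed = 31)
  em <- simulate_expression(spec)
  rpm <- normalise_rpm(em)
  dm <- distance_to_median(rpm, min_mean = 10, window = 100)
  expect_lt(abs(cor(dm$dm, dm$mean_rpm, method = "spearman")), 0.15)
  inflated <- sprintf("g%04d", inflated_idx)
  auc <- rank_auc(dm$dm[dm$gene_id %in% inflated],
                  dm$dm[!dm$gene_id %in% inflated])
  expect_gt(auc, 0.9)
})

test_that("expression frequency and the >15% flag behave", {
  counts <- rbind(gA = c(0, 0, 3, 5), gB = c(1, 2, 3, 4))
  colnames(counts) <- paste0("c", 1:4)
  em <- ExpressionMatrix(counts)
  fr <- expression_frequency(em, group_labels = c("young", "young", "old", "old"))
  expect_equal(fr[gene_id == "gA"]$freq_young, 0)
  expect_equal(fr[gene_id == "gA"]$freq_old, 1)
  expect_equal(fr[gene_id == "gB"]$delta_freq, 0)
  expect_false(fr[gene_id == "gB"]$flagged)
  expect_error(expression_frequency(em, rep("young", 4)), "old")

  # dropout shift: detection 0.9 young vs 0.7 old gives delta_freq ~ 0.2
  mkage <- function(seed, p_detect) {
    simulate_expression(sim_expr_spec(
      n_genes = 200, n_cells = 120, mean_grid = rep(50, 200),
      dispersion = 0.1,
      dropout_logit_params = c(stats::qlogis(p_detect), 0), seed = seed))
  }
  ey <- mkage(8, 0.9); eo <- mkage(9, 0.7)
  both <- ExpressionMatrix(cbind(ey$counts, eo$counts))
  fr2 <- expression_frequency(both, c(rep("young", 120), rep("old", 120)))
  se <- sd(fr2$delta_freq) / sqrt(nrow(fr2))
  expect_lt(abs(mean(fr2$delta_freq) - 0.2), 2 * se + 0.005)
  expect_gt(mean(fr2$flagged), 0.8)
})

test_that("top variable genes are ranked deterministically by dm", {
  stats <- data.table::data.table(gene_id = c("b", "a", "c", "d"),
                                  dm = c(2, 2, 1, 3))
  expect_equal(top_variable_genes(stats, 1), "d")
  expect_equal(top_variable_genes(stats, 2), c("d", "a"))  # tie: id order
  expect_warning(all4 <- top_variable_genes(stats, 10), "available")
  expect_length(all4, 4)
})

test_that("cell-cell correlations and cohorts are reproducible", {
  set.seed(77)
  rpm <- matrix(rexp(100 * 12, 1 / 50), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:12)))
  rpm[, 2] <- rpm[, 1]  # duplicated cell
  res <- cell_correlation_analysis(rpm, rownames(rpm), cohort_size = 5,
                                   n_iter = 50, seed = 3)
  dup <- res$pairwise[cell_i == "c01" & cell_j == "c02"]
  expect_equal(dup$rho, 1)
  res2 <- cell_correlation_analysis(rpm, rownames(rpm), cohort_size = 5,
                                    n_iter = 50, seed = 3)
  expect_identical(res$cohort_means, res2$cohort_means)
  expect_error(cell_correlation_analysis(rpm, c("nope"), 5, 10, 1), "unknown")

  # constant cells are excluded with a record
  rpm2 <- rpm; rpm2[, 3] <- 1
  res3 <- cell_correlation_analysis(rpm2, rownames(rpm2), cohort_size = 5,
                                    n_iter = 20, seed = 4)
  expect_equal(res3$excluded_cells, "c03")
  expect_false(any(res3$pairwise$cell_i == "c03" | res3$pairwise$cell_j == "c03"))
})

test_that("lower-dispersion cells correlate more tightly", {
  mk <- function(disp, seed) {
    normalise_rpm(simulate_expression(sim_expr_spec(
      n_genes = 400, n_cells = 60,
      mean_grid = exp(seq(log(5), log(300), length.out = 400)),
      dispersion = disp, dropout_logit_params = c(2, 1), seed = seed)))
  }
  young <- mk(0.1, 41); old <- mk(0.4, 42)
  ry <- cell_correlation_analysis(young, rownames(young), cohort_size = 10,
                                  n_iter = 200, seed = 5)
  ro <- cell_correlation_analysis(old, rownames(old), cohort_size = 10,
                                  n_iter = 200, seed = 6)
  expect_gt(mean(ry$cohort_means > ro$cohort_means), 0.95)
})

test_that("similarity-to-young ranking recovers a synthetic gradient", {
  set.seed(12)
  n_genes <- 300
  young_mean <- rexp(n_genes, 1 / 40)
  perturbed <- young_mean * exp(rnorm(n_genes, 0, 1.5))
  n_young <- 10; n_old <- 15
  young <- sapply(seq_len(n_young), function(i) {
    young_mean * exp(rnorm(n_genes, 0, 0.1))
  })
  alpha <- seq(0, 1, length.out = n_old)  # interpolation towards perturbed
  old <- sapply(seq_len(n_old), function(i) {
    profile <- (1 - alpha[i]) * young_mean + alpha[i] * perturbed
    profile * exp(rnorm(n_genes, 0, 0.05))
  })
  rpm <- cbind(young, old)
  dimnames(rpm) <- list(sprintf("g%03d", 1:n_genes),
                        c(sprintf("y%02d", 1:n_young), sprintf("o%02d", 1:n_old)))
  res <- similarity_to_young(rpm, colnames(rpm)[1:n_young],
                             colnames(rpm)[-(1:n_young)], min_cells = 5,
                             n_top = 50)
  # the recovered ranking follows the generative interpolation order
  expect_gt(cor(res$similarity$rank,
                match(res$similarity$cell_id, sprintf("o%02d", 1:n_old)),
                method = "spearman"), 0.95)
  expect_length(res$top_correlated, 50)

  # an old cell equal to the reference ranks first with rho 1
  lg_ref <- rowMeans(log2(rpm[, 1:n_young] + 1))
  clone <- 2^lg_ref - 1
  rpm2 <- cbind(rpm, oclone = clone)
  res2 <- similarity_to_young(rpm2, colnames(rpm)[1:n_young],
                              c(colnames(rpm)[-(1:n_young)], "oclone"))
  expect_equal(res2$similarity$cell_id[1], "oclone")
  expect_equal(res2$similarity$rho[1], 1)

  # a gene expressed in fewer than five cells is excluded
  rare <- rbind(rpm, rare1 = c(rep(0, n_young + n_old - 4), rep(3, 4)))
  res3 <- similarity_to_young(rare, colnames(rpm)[1:n_young],
                              colnames(rpm)[-(1:n_young)])
  expect_false("rare1" %in% res3$gene_correlation$gene_id)

  # ranking is invariant to gene order and to adding filtered genes
  res4 <- similarity_to_young(rare[sample(nrow(rare)), ],
                              colnames(rpm)[1:n_young],
                              colnames(rpm)[-(1:n_young)])
  expect_equal(res4$similarity, res3$similarity)
})
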