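test_that("pair statistics match hand-worked examples", {
  # identical cells: no mismatches, two patterns (1,1) and (0,0) at
  # frequency 1/2 each -> D = 0, S = 1
  ps <- pair_stats(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(ps$D, 0)
  expect_equal(ps$S, 1)
  expect_equal(ps$w, 4)

  # fully alternating pair: every site mismatches, patterns (1,0) and
  # (0,1) at 1/2 each -> D = 1, S = 1
  ps2 <- pair_stats(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(ps2$D, 1)
  expect_equal(ps2$S, 1)

  # shared-coverage filter: 3 shared sites with the default minimum of 4
  expect_null(pair_stats(c(1, 0, 1, NA), c(1, 0, 1, 1)))
  expect_error(pair_stats(c(1, 0), c(1, 0, 1)), "same site")
})

test_that("region score matches the hand-worked two-cell examples", {
  alt <- RegionCallMatrix("alt", rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_equal(region_heterogeneity(alt)$H, 1)

  ident <- RegionCallMatrix("id", matrix(1, nrow = 5, ncol = 6))
  expect_equal(region_heterogeneity(ident)$H, 0)

  expect_error(region_heterogeneity(RegionCallMatrix("one", matrix(1, 1, 5))),
               "at least 2 cells")

  # no qualifying pair: undefined, not zero
  sparse <- RegionCallMatrix("sp", rbind(c(1, 1, NA, NA, NA),
                                         c(NA, NA, 1, 1, 1)))
  expect_true(is.na(region_heterogeneity(sparse)$H))
})

test_that("region score equals brute-force pair enumeration", {
  set.seed(202)
  for (i in 1:200) {
    n_cells <- sample(4:8, 1)
    n_sites <- sample(4:12, 1)
    miss <- sample(c(0, 0.3), 1)
    states <- random_states(n_cells, n_sites, missing_rate = miss)
    m <- RegionCallMatrix("r", states)
    h_pkg <- region_heterogeneity(m)$H
    h_bf <- brute_force_heterogeneity(states)
    if (is.na(h_bf)) {
      expect_true(is.na(h_pkg))
    } else {
      expect_lt(abs(h_pkg - h_bf), 1e-12)
    }
  }
})

test_that("the score is bounded and invariant to permutations", {
  set.seed(33)
  for (i in 1:20) {
    states <- random_states(6, 10, missing_rate = 0.25)
    m <- RegionCallMatrix("r", states)
    h <- region_heterogeneity(m)$H
    if (!is.na(h)) {
      expect_gte(h, 0)
      expect_lte(h, 2)
    }
    perm_cells <- RegionCallMatrix("r", states[sample(nrow(states)), ])
    perm_sites <- RegionCallMatrix("r", states[, sample(ncol(states))])
    expect_equal(region_heterogeneity(perm_cells)$H, h)
    expect_equal(region_heterogeneity(perm_sites)$H, h)
  }
})

test_that("mean methylation is the coverage-weighted cell mean", {
  # cell A covers 10 sites at mean 0.5, cell B 30 sites all methylated:
  # (10 * 0.5 + 30 * 1) / 40 = 0.875
  states <- matrix(NA_real_, nrow = 2, ncol = 40)
  states[1, 1:10] <- rep(c(1, 0), 5)
  states[2, 11:40] <- 1
  m <- RegionCallMatrix("r", states)
  expect_equal(region_mean_methylation(m), 0.875)
  expect_equal(region_mean_methylation(RegionCallMatrix("r", matrix(1, 2, 3))), 1)
  expect_equal(region_mean_methylation(RegionCallMatrix("r", matrix(c(1, 0), 1))), 0.5)
  expect_true(is.na(region_mean_methylation(
    RegionCallMatrix("r", matrix(NA_real_, 2, 3)))))
})

test_that("region filters keep exactly the regions passing all five rules", {
  mk <- function(id, cpg_y, mcc_y, pairs_y, cpg_o = cpg_y, mcc_o = mcc_y,
                 pairs_o = pairs_y) {
    list(young = data.table::data.table(region_id = id, n_cpg_total = cpg_y,
                                        mean_cpg_per_cell = mcc_y, n_pairs = pairs_y),
         old = data.table::data.table(region_id = id, n_cpg_total = cpg_o,
                                      mean_cpg_per_cell = mcc_o, n_pairs = pairs_o))
  }
  cases <- list(
    mk("clean", 25, 5, 150),
    mk("few_cpg", 19, 5, 150),                      # <20 CpG sites (young)
    mk("low_mcc", 25, 1.9, 150),                    # <2 CpGs per cell
    mk("few_pairs", 25, 5, 99),                     # <100 comparisons
    mk("mcc_diff", 25, 4, 150, 25, 15, 150),        # age difference > 10
    mk("pairs_diff", 25, 5, 120, 25, 5, 350),       # age difference > 200
    mk("boundary", 20, 2, 100, 20, 12, 300)         # all five at the boundary
  )
  young <- data.table::rbindlist(lapply(cases, `[[`, "young"))
  old <- data.table::rbindlist(lapply(cases, `[[`, "old"))
  res <- filter_regions(young, old)
  expect_equal(sort(res$region_id[res$keep]), c("boundary", "clean"))
  expect_equal(res$reason[res$region_id == "few_cpg"], "few_cpg_sites")
  expect_equal(res$reason[res$region_id == "pairs_diff"], "pair_count_age_diff")

  # a region present in one age only is excluded with a reason
  res2 <- filter_regions(young,
                         old[region_id != "clean"])
  expect_false(res2$keep[res2$region_id == "clean"])
  expect_equal(res2$reason[res2$region_id == "clean"], "missing_in_one_age")
})

test_that("normalisation subtracts the rolling-median trend", {
  # identical H everywhere: H_norm = 0
  flat <- data.table::data.table(region_id = sprintf("r%03d", 1:200),
                                 H = 0.4, mean_meth = seq(0.1, 0.8, length.out = 200))
  norm <- normalise_heterogeneity(flat, window = 50)
  expect_true(all(norm$H_norm == 0))

  # smooth trend with one offset record: the offset is recovered
  set.seed(4)
  n <- 400
  mm <- seq(0.06, 0.88, length.out = n)
  h <- 0.5 * sin(mm * 3) + 0.6
  rec <- data.table::data.table(region_id = sprintf("r%03d", 1:n), H = h,
                                mean_meth = mm)
  rec$H[200] <- rec$H[200] + 0.2
  norm2 <- normalise_heterogeneity(rec, window = 101)
  off <- norm2[region_id == "r200"]$H_norm
  expect_lt(abs(off - 0.2), 0.02)
  # and equals an independent rolling-median oracle
  expect_equal(norm2$H_norm,
               norm2$H - oracle_rolling_median(norm2$H, 101),
               tolerance = 1e-12)

  # the mean-methylation band excludes extreme regions
  rec$mean_meth[5] <- 0.95
  rec$mean_meth[6] <- 0.02
  norm3 <- normalise_heterogeneity(rec, window = 101)
  expect_false(any(c("r005", "r006") %in% norm3$region_id))

  expect_error(normalise_heterogeneity(flat[1:10], window = 50),
               "smaller window")
})

test_that("windowed Z-scores standardise the age differences", {
  # all differences equal: z = 0 everywhere (zero-variance rule)
  n <- 150
  base <- data.table::data.table(region_id = sprintf("r%03d", 1:n),
                                 mean_meth = seq(0.1, 0.8, length.out = n))
  y <- data.table::copy(base)[, H_norm := 0.1]
  o <- data.table::copy(base)[, H_norm := 0.3]
  z <- delta_het_zscore(y, o, window = 30)
  expect_true(all(z$delta_H_z == 0))

  # matches an independently coded sliding-window oracle
  set.seed(5)
  y2 <- data.table::copy(base)[, H_norm := rnorm(n, 0, 0.1)]
  o2 <- data.table::copy(base)[, H_norm := rnorm(n, 0.05, 0.1)]
  z2 <- delta_het_zscore(y2, o2, window = 100)
  m <- merge(merge(z2[, .(region_id)],
                   y2[, .(region_id, mean_meth, hy = H_norm)], by = "region_id"),
             o2[, .(region_id, ho = H_norm)], by = "region_id")
  data.table::setorder(m, mean_meth, region_id)
  oracle <- oracle_sliding_z(m$ho - m$hy, 100)
  expect_equal(z2$delta_H_z, oracle[match(z2$region_id, m$region_id)],
               tolerance = 1e-10)

  # unmatched regions are refused with names
  expect_error(delta_het_zscore(y2[-3], o2, window = 30), "r003")
})

test_that("heterogeneity increases monotonically with the mixing level", {
  means <- vapply(c(0, 0.5, 1), function(het) {
    hs <- vapply(1:40, function(s) {
      m <- simulate_region(sim_meth_region_spec(n_cells = 20, n_cpgs = 20,
                                                het_level = het,
                                                missing_rate = 0.2,
                                                seed = 5000 + s * 7 + het * 1009))
      region_heterogeneity(m)$H
    }, numeric(1))
    mean(hs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
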