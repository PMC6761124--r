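# Coupled / decoupled methylation-expression simulation used by the
# integration tests: promoters whose methylation heterogeneity rises with
# age and genes whose old-age expression dispersion is inflated either for
# the same genes (coupled = TRUE) or for an independently chosen set.
simulate_layers <- function(seed, n_prom = 120, n_coupled = 30, coupled = TRUE,
                            n_cells = 25, n_cpgs = 25,
                            norm_window = 75, z_window = 50) {
  het_o <- rep(0.2, n_prom)
  het_o[seq_len(n_coupled)] <- 0.8
  recs <- lapply(c("young", "old"), function(age) {
    data.table::rbindlist(lapply(seq_len(n_prom), function(i) {
      spec <- sim_meth_region_spec(
        n_cells = n_cells, n_cpgs = n_cpgs, mean_meth = 0.5,
        het_level = if (age == "young") 0.2 else het_o[i],
        missing_rate = 0.2,
        seed = seed * 100000L + i * 13L + (age == "old") * 7L)
      region_het_record(simulate_region(spec, sprintf("g%04d", i)))
    }))
  })
  names(recs) <- c("young", "old")
  ny <- normalise_heterogeneity(recs$young, window = norm_window, min_records = 20)
  no <- normalise_heterogeneity(recs$old, window = norm_window, min_records = 20)
  common <- intersect(ny$region_id, no$region_id)
  dz <- delta_het_zscore(ny[region_id %in% common], no[region_id %in% common],
                         window = z_window)
  data.table::setnames(dz, "region_id", "gene_id")

  disp_o <- rep(0.1, n_prom)
  # decoupled control: dispersion inflation hits a disjoint gene set, so
  # any stratum contrast is spurious
  target <- if (coupled) seq_len(n_coupled) else seq_len(n_coupled) + n_coupled
  stopifnot(max(target) <= n_prom)
  disp_o[target] <- 0.4
  mean_grid <- exp(seq(log(30), log(300), length.out = n_prom))
  mean_grid <- mean_grid[(seq_len(n_prom) * 17L) %% n_prom + 1L]
  mk <- function(disp, s) normalise_rpm(simulate_expression(sim_expr_spec(
    n_genes = n_prom, n_cells = 80, mean_grid = mean_grid, dispersion = disp,
    dropout_logit_params = c(3, 1), seed = s)))
  dm_y <- distance_to_median(mk(rep(0.1, n_prom), seed * 31L + 1L),
                             min_mean = 10, window = 40)
  dm_o <- distance_to_median(mk(disp_o, seed * 31L + 2L),
                             min_mean = 10, window = 40)
  list(delta_meth = dz, dm_young = dm_y, dm_old = dm_o,
       coupled_genes = sprintf("g%04d", seq_len(n_coupled)))
}
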