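#' Specification of a simulated methylation region
#'
#' Parameters of the template/stochastic mixture used to generate one
#' region's cells x CpG call matrix. A shared template state is drawn per
#' site; each cell either copies the template or (with probability
#' `het_level`) redraws the state independently, so `het_level` tunes
#' cell-to-cell heterogeneity monotonically while `mean_meth` fixes the
#' marginal methylation level — the two are controlled independently, which
#' is the property the downstream mean-methylation normalisation assumes.
#'
#' Defaults mirror the scale of the analysed data: 35 cells per individual
#' (the per-individual cell count after depth equalisation), ~30 CpGs for a
#' ~2 kb region, 50% global methylation, and heavy (50%) missingness
#' typical of single-cell bisulfite coverage.
#'
#' @param n_cells,n_cpgs Matrix dimensions.
#' @param mean_meth Marginal methylation probability in `[0, 1]`.
#' @param het_level Mixing weight of the independent component in `[0, 1]`.
#' @param missing_rate Per-entry missing-completely-at-random probability
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `SimMethRegionSpec` list.
#' @export
sim_meth_region_spec <- function(n_cells = 35, n_cpgs = 30, mean_meth = 0.5,
                                 het_level = 0.5, missing_rate = 0.5,
                                 seed = 1L) {
  stopifnot(n_cells >= 1, n_cpgs >= 1,
            mean_meth >= 0, mean_meth <= 1,
            het_level >= 0, het_level <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_cells = as.integer(n_cells), n_cpgs = as.integer(n_cpgs),
                 mean_meth = mean_meth, het_level = het_level,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "SimMethRegionSpec")
}

#' Simulate one region call matrix
#'
#' Draws from the template/stochastic mixture described in
#' [sim_meth_region_spec()]: template per site ~ Bernoulli(`mean_meth`);
#' each cell x site entry is resampled independently from the same
#' Bernoulli with probability `het_level`, otherwise copies the template;
#' entries are then masked missing independently with `missing_rate`.
#' Bit-identical output for the same spec.
#'
#' @param spec A [sim_meth_region_spec()].
#' @param region_id Identifier for the returned matrix.
#' @return A [RegionCallMatrix].
#' @export
simulate_region <- function(spec, region_id = "sim_region") {
  stopifnot(inherits(spec, "SimMethRegionSpec"))
  with_seed(spec$seed, {
    template <- rbinom(spec$n_cpgs, 1L, spec$mean_meth)
    n <- spec$n_cells * spec$n_cpgs
    resample <- matrix(runif(n) < spec$het_level, spec$n_cells, spec$n_cpgs)
    indep <- matrix(rbinom(n, 1L, spec$mean_meth), spec$n_cells, spec$n_cpgs)
    states <- matrix(rep(template, each = spec$n_cells),
                     spec$n_cells, spec$n_cpgs)
    states[resample] <- indep[resample]
    if (spec$missing_rate > 0) {
      states[matrix(runif(n) < spec$missing_rate, spec$n_cells, spec$n_cpgs)] <- NA_real_
    }
    RegionCallMatrix(region_id, states)
  })
}

#' Simulate matched young/old single-cell methylome cohorts
#'
#' Builds, for each region class, `n_regions` independent regions per
#' individual and age from the class's spec, converts them to per-cell
#' methylomes (one read per covered CpG), and lays regions end to end on a
#' synthetic chromosome. Age-dependent shifts are expressed by giving the
#' old specs different `mean_meth` / `het_level` than the young ones — e.g.
#' LINE-1-like classes gain methylation and lose heterogeneity with age
#' while Polycomb-target-like (H3K27me3) classes gain heterogeneity.
#'
#' @param young_specs,old_specs Named lists (one entry per region class) of
#'   [sim_meth_region_spec()] templates; the two lists must share names.
#'   Per-region seeds are derived from each spec's seed.
#' @param region_classes Named integer vector: regions per class.
#' @param n_individuals Individuals per age group; default 2 (the study
#'   design); each individual gets independent draws of every region.
#' @param age_weeks_young,age_weeks_old Chronological ages attached to the
#'   cells; defaults 7 and 115 weeks.
#' @param region_size Genomic span allotted to each region (bp).
#' @return A list with `cells_young`, `cells_old` (lists of
#'   [CellMethylome]) and `regions` (a [region_table()]).
#' @export
simulate_cohorts <- function(young_specs, old_specs, region_classes,
                             n_individuals = 2,
                             age_weeks_young = 7, age_weeks_old = 115,
                             region_size = 2000L) {
  if (!identical(sort(names(young_specs)), sort(names(old_specs))) ||
      !all(names(region_classes) %in% names(young_specs))) {
    stop("young_specs, old_specs and region_classes must cover the same classes")
  }
  classes <- names(region_classes)
  n_regions_total <- sum(region_classes)
  regions <- region_table(
    chrom = "chrSim",
    start = (seq_len(n_regions_total) - 1L) * region_size,
    end = seq_len(n_regions_total) * region_size,
    region_id = sprintf("r%04d", seq_len(n_regions_total)),
    region_class = rep(classes, region_classes)
  )

  build_age <- function(specs, age_group, age_weeks) {
    cells_calls <- NULL
    for (indiv in seq_len(n_individuals)) {
      indiv_id <- sprintf("%s%d", toupper(substr(age_group, 1, 1)), indiv)
      for (ri in seq_len(n_regions_total)) {
        cls <- regions$region_class[ri]
        spec <- specs[[cls]]
        spec$seed <- spec$seed + 7919L * ri + 104729L * indiv +
          1000003L * (age_group == "old")
        rcm <- simulate_region(spec, region_id = regions$region_id[ri])
        ## CpGs evenly spaced inside the region (1-based coverage coords)
        pos <- regions$start[ri] +
          round(seq(1, region_size - 1, length.out = spec$n_cpgs))
        st <- rcm$states
        idx <- which(!is.na(st), arr.ind = TRUE)
        if (nrow(idx)) {
          cells_calls <- rbind(cells_calls, data.table(
            indiv_id = indiv_id,
            cell = idx[, 1],
            chrom = "chrSim",
            pos = as.integer(pos[idx[, 2]]),
            n_meth = as.integer(st[idx]),
            n_unmeth = 1L - as.integer(st[idx])
          ))
        }
      }
    }
    cells_calls <- as.data.table(cells_calls)
    out <- list()
    for (key in unique(cells_calls[, paste(indiv_id, cell, sep = "_c")])) {
      parts <- cells_calls[paste(indiv_id, cell, sep = "_c") == key]
      out[[key]] <- CellMethylome(
        cell_id = key, calls = parts[, .(chrom, pos, n_meth, n_unmeth)],
        individual_id = parts$indiv_id[1], age_group = age_group,
        age_weeks = age_weeks,
        n_alignments = nrow(parts))
    }
    out
  }

  list(cells_young = build_age(young_specs, "young", age_weeks_young),
       cells_old = build_age(old_specs, "old", age_weeks_old),
       regions = regions)
}

#' Specification of a simulated expression matrix
#'
#' Negative-binomial counts with a gene-specific mean and overdispersion,
#' thinned by a Bernoulli detection step whose probability is logistic in
#' the log mean — the standard mean-variance and dropout structure of
#' full-length scRNA-seq. Defaults emulate the analysed data's scale: a few
#' thousand genes spanning three orders of magnitude in expression with
#' moderate overdispersion.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param mean_grid Per-gene expected counts (recycled to `n_genes`);
#'   default log-spaced on `[2, 500]`.
#' @param dispersion Per-gene NB overdispersion (variance = mu + disp *
#'   mu^2), scalar or length `n_genes`; default 0.1.
#' @param dropout_logit_params `c(intercept, slope)` of detection
#'   probability `plogis(intercept + slope * log(mean))`; default `c(0, 1)`
#'   (detection ~0.88 at mean 2, ~1 at mean 50).
#' @param total_offset Reads mapped outside the quantified gene set, added
#'   to each cell's column sum to form `mapped_total`; default 1e5.
#' @param seed Integer seed.
#' @return A `SimExprSpec` list.
#' @export
sim_expr_spec <- function(n_genes = 2000, n_cells = 200, mean_grid = NULL,
                          dispersion = 0.1, dropout_logit_params = c(0, 1),
                          total_offset = 1e5, seed = 1L) {
  stopifnot(all(dispersion > 0))
  if (is.null(mean_grid)) {
    mean_grid <- exp(seq(log(2), log(500), length.out = n_genes))
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 mean_grid = rep_len(mean_grid, n_genes),
                 dispersion = rep_len(dispersion, n_genes),
                 dropout_logit_params = dropout_logit_params,
                 total_offset = total_offset, seed = as.integer(seed)),
            class = "SimExprSpec")
}

#' Simulate a gene-by-cell count matrix
#'
#' @param spec A [sim_expr_spec()].
#' @param cell_prefix Prefix for generated cell ids.
#' @return An [ExpressionMatrix]; deterministic given the spec seed.
#' @export
simulate_expression <- function(spec, cell_prefix = "cell") {
  stopifnot(inherits(spec, "SimExprSpec"))
  with_seed(spec$seed, {
    mu <- spec$mean_grid
    size <- 1 / spec$dispersion
    counts <- matrix(rnbinom(spec$n_genes * spec$n_cells,
                             mu = rep(mu, spec$n_cells),
                             size = rep(size, spec$n_cells)),
                     nrow = spec$n_genes, ncol = spec$n_cells)
    p_detect <- stats::plogis(spec$dropout_logit_params[1] +
                                spec$dropout_logit_params[2] * log(mu))
    detected <- matrix(runif(spec$n_genes * spec$n_cells) <
                         rep(p_detect, spec$n_cells),
                       nrow = spec$n_genes)
    counts[!detected] <- 0L
    dimnames(counts) <- list(sprintf("g%04d", seq_len(spec$n_genes)),
                             sprintf("%s%03d", cell_prefix, seq_len(spec$n_cells)))
    mito <- runif(spec$n_cells, 0.01, 0.08)
    ExpressionMatrix(counts,
                     mapped_total = colSums(counts) + spec$total_offset,
                     mito_fraction = mito)
  })
}

#' Specification of a simulated clock training corpus
#'
#' Pseudo-bulk methylation profiles whose causal sites drift linearly with
#' chronological age. Site-level truth is
#' `clip(base + effect * age + Normal(0, noise_sd), 0, 1)`; observed
#' fractions are binomial draws at `coverage_depth`. Non-causal sites have
#' an age-independent base level. Defaults reflect a desk-scale training
#' corpus: 140 samples spanning mouse ages 2-40 weeks, 500 sites of which
#' 50 drift at 0.015 methylation/week (random sign).
#'
#' @param n_samples Number of training samples.
#' @param ages_weeks Sample ages; default evenly spaced on `[2, 40]`.
#' @param n_sites,n_causal Total and age-responsive site counts.
#' @param effect_size Absolute methylation change per week at causal sites;
#'   scalar or length `n_causal`. Signs are drawn at random.
#' @param noise_sd Site-level Gaussian noise s.d.
#' @param coverage_depth Binomial depth per site; `Inf` returns the exact
#'   fractions.
#' @param seed Integer seed.
#' @return A `SimClockSpec` list.
#' @export
sim_clock_spec <- function(n_samples = 140, ages_weeks = NULL, n_sites = 500,
                           n_causal = 50, effect_size = 0.015,
                           noise_sd = 0.02, coverage_depth = 20, seed = 1L) {
  stopifnot(n_causal <= n_sites, all(effect_size > 0), noise_sd >= 0,
            coverage_depth > 0)
  if (is.null(ages_weeks)) ages_weeks <- seq(2, 40, length.out = n_samples)
  stopifnot(length(ages_weeks) == n_samples, all(ages_weeks > 0))
  structure(list(n_samples = as.integer(n_samples), ages_weeks = ages_weeks,
                 n_sites = as.integer(n_sites), n_causal = as.integer(n_causal),
                 effect_size = rep_len(effect_size, max(n_causal, 1L)),
                 noise_sd = noise_sd, coverage_depth = coverage_depth,
                 seed = as.integer(seed)),
            class = "SimClockSpec")
}

#' Simulate clock training data
#'
#' @param spec A [sim_clock_spec()].
#' @return A list: `methylation` (samples x sites observed fractions),
#'   `ages` (weeks), `sites` (data.table with `chrom`, `pos`, `causal`,
#'   `slope`, `intercept`), `n_meth` and `depth` matrices (absent when
#'   `coverage_depth` is infinite).
#' @export
simulate_clock_data <- function(spec) {
  stopifnot(inherits(spec, "SimClockSpec"))
  with_seed(spec$seed, {
    max_age <- max(spec$ages_weeks)
    slope <- numeric(spec$n_sites)
    intercept <- runif(spec$n_sites, 0.05, 0.95)
    if (spec$n_causal > 0) {
      causal_idx <- seq_len(spec$n_causal)
      sgn <- sample(c(-1, 1), spec$n_causal, replace = TRUE)
      slope[causal_idx] <- sgn * spec$effect_size[seq_len(spec$n_causal)]
      ## keep base + slope * age inside (0.02, 0.98) over the age range
      span <- abs(slope[causal_idx]) * max_age
      lo <- ifelse(sgn > 0, 0.02, 0.02 + span)
      hi <- ifelse(sgn > 0, 0.98 - span, 0.98)
      intercept[causal_idx] <- lo + runif(spec$n_causal) * pmax(hi - lo, 0)
    }
    truth <- outer(spec$ages_weeks, slope) +
      matrix(intercept, spec$n_samples, spec$n_sites, byrow = TRUE)
    if (spec$noise_sd > 0) {
      truth <- truth + matrix(rnorm(length(truth), 0, spec$noise_sd),
                              nrow = spec$n_samples)
    }
    truth <- pmin(pmax(truth, 0), 1)
    sites <- data.table(chrom = "chrSim",
                        pos = seq_len(spec$n_sites) * 1000L,
                        causal = seq_len(spec$n_sites) <= spec$n_causal,
                        slope = slope, intercept = intercept)
    site_names <- paste0("chrSim:", sites$pos)
    if (is.finite(spec$coverage_depth)) {
      depth <- round(spec$coverage_depth)
      n_meth <- matrix(rbinom(length(truth), depth, truth),
                       nrow = spec$n_samples)
      observed <- n_meth / depth
      dimnames(observed) <- list(sprintf("s%03d", seq_len(spec$n_samples)),
                                 site_names)
      dimnames(n_meth) <- dimnames(observed)
      list(methylation = observed, ages = spec$ages_weeks, sites = sites,
           n_meth = n_meth,
           depth = matrix(depth, spec$n_samples, spec$n_sites,
                          dimnames = dimnames(observed)))
    } else {
      dimnames(truth) <- list(sprintf("s%03d", seq_len(spec$n_samples)),
                              site_names)
      list(methylation = truth, ages = spec$ages_weeks, sites = sites)
    }
  })
}
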