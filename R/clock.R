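## Calls of a CellMethylome (or a bare calls table) as a keyed site table.
site_table <- function(x) {
  calls <- if (inherits(x, "CellMethylome")) x$calls else as.data.table(x)
  calls[, .(chrom, pos, n_meth, n_unmeth, depth = n_meth + n_unmeth)]
}

#' Select the clock CpG panel
#'
#' Three-stage filter defining the sites an age model can be trained and
#' evaluated on: (1) keep sites covered in at least `min_sample_frac` of
#' the training samples; (2) remove sites not covered `min_target_depth`x
#' in every target pseudobulk; (3) remove training samples that do not have
#' 100% coverage of the remaining panel.
#'
#' @param training_sets List of training samples ([CellMethylome] or call
#'   tables with `chrom`, `pos`, `n_meth`, `n_unmeth`), at least 2.
#' @param targets List of target pseudobulk samples, at least 1.
#' @param min_sample_frac Stage-1 fraction; default 0.70 ("at least 70%"
#'   is inclusive).
#' @param min_target_depth Stage-2 depth; default 5.
#' @return List: `panel` (`data.table` of `chrom`, `pos`, `site` label and
#'   `n_training_covered`), `retained_training` (indices into
#'   `training_sets`), `n_dropped_samples`.
#' @export
select_sites <- function(training_sets, targets, min_sample_frac = 0.70,
                         min_target_depth = 5) {
  stopifnot(length(training_sets) >= 2, length(targets) >= 1)
  train <- lapply(training_sets, site_table)
  n_train <- length(train)
  cov_counts <- rbindlist(lapply(train, function(s) s[, .(chrom, pos)]))
  cov_counts <- cov_counts[, .(n_covered = .N), by = .(chrom, pos)]
  panel <- cov_counts[n_covered >= min_sample_frac * n_train]
  ## stage 2: at least min_target_depth in every target pseudobulk
  for (tg in targets) {
    tt <- site_table(tg)[depth >= min_target_depth, .(chrom, pos)]
    panel <- panel[tt, on = c("chrom", "pos"), nomatch = NULL]
  }
  if (nrow(panel) == 0) {
    stop("no site satisfies the coverage requirements; relax min_sample_frac ",
         "or min_target_depth")
  }
  ## stage 3: training samples must cover the full panel
  retained <- which(vapply(train, function(s) {
    nrow(panel[s[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]) ==
      nrow(panel)
  }, logical(1)))
  if (length(retained) < 2) {
    stop("fewer than 2 training samples cover the full panel")
  }
  setorder(panel, chrom, pos)
  panel[, site := paste0(chrom, ":", pos)]
  list(panel = panel[, .(chrom, pos, site, n_training_covered = n_covered)],
       retained_training = retained,
       n_dropped_samples = n_train - length(retained))
}

#' Bin methylation fractions
#'
#' Rounds methylation values to the nearest multiple of `bin_width`
#' (half-way ties round up), discarding read-depth information that would
#' otherwise leak into the methylation values. With the default width of
#' 0.2 the output takes values in {0, 0.2, 0.4, 0.6, 0.8, 1}.
#'
#' @param value Numeric in `[0, 1]` (vector or matrix).
#' @param bin_width Default 0.2; `0` disables binning.
#' @return Binned values with the input's shape.
#' @export
bin_methylation <- function(value, bin_width = 0.2) {
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    stop("methylation values must lie in [0, 1]")
  }
  if (bin_width == 0) return(value)
  ## small eps guards the half-way ties against floating-point ratios
  out <- floor(value / bin_width + 0.5 + 1e-9) * bin_width
  pmin(out, 1)
}

#' Fit the binned-methylation age clock
#'
#' Penalised linear regression (elastic net) of chronological age in weeks
#' on binned site methylation. The mixing parameter is chosen over
#' `alpha_grid` and the penalty by `cv_folds`-fold cross-validation, with
#' fold assignment fixed by `seed` so the fit is reproducible.
#'
#' @param methylation Samples x sites matrix of methylation fractions in
#'   `[0, 1]`, with site column names.
#' @param ages Chronological ages in weeks, one per sample.
#' @param bin_width Binning applied to the inputs (and later to prediction
#'   inputs); default 0.2.
#' @param alpha_grid Elastic-net mixing values tried; default
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param cv_folds Default 10.
#' @param seed Integer seed.
#' @return A `ClockModel`: `sites`, `coefficients` (named, zero entries
#'   kept), `intercept`, `bin_width`, `alpha`, `lambda`, and training
#'   metadata.
#' @export
fit_clock <- function(methylation, ages, bin_width = 0.2,
                      alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                      cv_folds = 10, seed = 1L) {
  stopifnot(nrow(methylation) == length(ages))
  if (length(unique(ages)) < 2) stop("training ages are constant; cannot fit")
  if (is.null(colnames(methylation))) {
    colnames(methylation) <- paste0("site_", seq_len(ncol(methylation)))
  }
  x <- bin_methylation(methylation, bin_width)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), nrow(x)))
    fits <- lapply(alpha_grid, function(a) {
      glmnet::cv.glmnet(x, ages, alpha = a, foldid = foldid,
                        family = "gaussian", standardize = TRUE)
    })
    cv_err <- vapply(fits, function(f) min(f$cvm), numeric(1))
    best <- which.min(cv_err)
    fit <- fits[[best]]
    beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
    structure(
      list(sites = colnames(x),
           coefficients = setNames(beta[-1], colnames(x)),
           intercept = beta[1],
           bin_width = bin_width,
           alpha = alpha_grid[best],
           lambda = fit$lambda.min,
           cv_error = cv_err[best],
           n_samples = nrow(x),
           age_range_weeks = range(ages)),
      class = "ClockModel")
  })
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf(paste0("<ClockModel> %d sites (%d non-zero), alpha = %.2f, ",
                     "lambda = %.4g, trained on %d samples (%.0f-%.0f wk)\n"),
              length(x$sites), sum(x$coefficients != 0), x$alpha, x$lambda,
              x$n_samples, x$age_range_weeks[1], x$age_range_weeks[2]))
  invisible(x)
}

#' Predict epigenetic age
#'
#' Applies the clock's linear score to binned methylation values. Input is
#' either a named vector / samples x sites matrix of methylation
#' fractions, or a pseudobulk [CellMethylome] whose per-site fractions are
#' computed from the summed calls; every model site must be present.
#'
#' @param model A [fit_clock()] model.
#' @param sample Methylation input (see above).
#' @return `data.table` with `sample_id`, `predicted_age_weeks`,
#'   `n_sites_used`.
#' @export
predict_age <- function(model, sample) {
  stopifnot(inherits(model, "ClockModel"))
  if (inherits(sample, "CellMethylome")) {
    st <- site_table(sample)
    st[, site := paste0(chrom, ":", pos)]
    frac <- setNames(st$n_meth / st$depth, st$site)
    ids <- sample$cell_id
    mat <- matrix(frac[model$sites], nrow = 1,
                  dimnames = list(ids, model$sites))
  } else if (is.null(dim(sample))) {
    vals <- if (is.null(names(sample))) {
      if (length(sample) != length(model$sites)) {
        stop("unnamed methylation vector must match the panel length")
      }
      sample
    } else sample[model$sites]
    mat <- matrix(vals, nrow = 1, dimnames = list("sample_1", model$sites))
  } else {
    missing_sites <- setdiff(model$sites, colnames(sample))
    if (length(missing_sites)) {
      stop("sample lacks clock sites: ",
           paste(utils::head(missing_sites, 5), collapse = ", "))
    }
    mat <- sample[, model$sites, drop = FALSE]
    if (is.null(rownames(mat))) rownames(mat) <- paste0("sample_", seq_len(nrow(mat)))
  }
  if (anyNA(mat)) {
    bad <- model$sites[colSums(is.na(mat)) > 0]
    stop("sample lacks clock sites: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  binned <- bin_methylation(mat, model$bin_width)
  pred <- drop(binned %*% model$coefficients) + model$intercept
  data.table(sample_id = rownames(mat),
             predicted_age_weeks = as.numeric(pred),
             n_sites_used = length(model$sites))
}

#' Cell-drop permutation ages
#'
#' Quantifies how much the predicted age of an individual's pseudobulk
#' depends on the particular cells captured: in each permutation a random
#' `drop_frac` of the cells is removed (round half up, at least one cell),
#' the remainder re-aggregated, and age predicted — but only when every
#' clock site still reaches `min_site_depth`x coverage; shallower
#' permutations are discarded.
#'
#' @param model A [fit_clock()] model.
#' @param cells List of [CellMethylome] from one individual.
#' @param drop_frac Fraction of cells removed per permutation; default 0.05.
#' @param n_perm Default 100.
#' @param min_site_depth Default 4.
#' @param seed Integer seed.
#' @return `data.table` of retained permutations (`perm`,
#'   `predicted_age_weeks`, `n_sites_used`); the number discarded is in
#'   attribute `n_discarded`. Errors if no permutation is retained.
#' @export
permutation_ages <- function(model, cells, drop_frac = 0.05, n_perm = 100,
                             min_site_depth = 4, seed = 1L) {
  stopifnot(inherits(model, "ClockModel"), length(cells) >= 2)
  n_cells <- length(cells)
  n_drop <- max(1L, as.integer(round_half_up(drop_frac * n_cells)))
  ## per-cell counts restricted to panel sites, so each permutation is a
  ## column-sum over retained cells
  panel <- data.table(site = model$sites)
  per_cell <- lapply(cells, function(cm) {
    st <- site_table(cm)
    st[, site := paste0(chrom, ":", pos)]
    st <- st[panel, on = "site"]
    list(n_meth = ifelse(is.na(st$n_meth), 0, st$n_meth),
         depth = ifelse(is.na(st$depth), 0, st$depth))
  })
  meth_mat <- vapply(per_cell, `[[`, numeric(nrow(panel)), "n_meth")
  depth_mat <- vapply(per_cell, `[[`, numeric(nrow(panel)), "depth")
  with_seed(seed, {
    out <- vector("list", n_perm)
    discarded <- 0L
    for (p in seq_len(n_perm)) {
      keep <- setdiff(seq_len(n_cells), sample(n_cells, n_drop))
      depth <- rowSums(depth_mat[, keep, drop = FALSE])
      if (any(depth < min_site_depth)) {
        discarded <- discarded + 1L
        next
      }
      frac <- rowSums(meth_mat[, keep, drop = FALSE]) / depth
      names(frac) <- model$sites
      pred <- predict_age(model, frac)
      out[[p]] <- data.table(perm = p,
                             predicted_age_weeks = pred$predicted_age_weeks,
                             n_sites_used = pred$n_sites_used)
    }
    res <- rbindlist(out)
    if (nrow(res) == 0) {
      stop("no permutation reached ", min_site_depth,
           "x coverage at every clock site")
    }
    data.table::setattr(res, "n_discarded", discarded)
    data.table::setattr(res, "n_dropped_cells", n_drop)
    res[]
  })
}

#' Serialise / restore a clock model
#'
#' The model is written as a JSON document (sites, coefficients,
#' intercept, bin width, training metadata).
#'
#' @param model A `ClockModel`.
#' @param path Output path.
#' @return `path` (write) or the restored `ClockModel` (read).
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "ClockModel"))
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)  # keep site names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  structure(obj, class = "ClockModel")
}
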