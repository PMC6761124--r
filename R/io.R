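#' Read a Bismark-style per-cell coverage file
#'
#' Parses the coverage dialect emitted by bisulfite callers: one line per
#' CpG with `chrom pos [pct] n_meth n_unmeth`, whitespace- or tab-separated.
#' Positions are 1-based. Duplicate positions are merged by summing counts;
#' no binarisation is applied here, raw counts are kept.
#'
#' @param path File path.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @param merge_strands If `TRUE`, calls at `pos` and `pos + 1` are treated
#'   as the two strands of one symmetric CpG and merged onto the lower
#'   coordinate. Default `FALSE`: input is assumed strand-collapsed already.
#' @param ... Passed to [CellMethylome()] (`individual_id`, `age_group`,
#'   `age_weeks`, `n_alignments`).
#' @return A [CellMethylome]. An empty file yields a methylome with zero
#'   calls and a warning.
#' @export
read_cell_coverage <- function(path, cell_id = NULL, merge_strands = FALSE, ...) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (is.null(cell_id)) {
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty coverage file: ", path)
    return(CellMethylome(cell_id, data.table(
      chrom = character(), pos = integer(),
      n_meth = integer(), n_unmeth = integer()), ...))
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(4L, 5L)))
  if (length(bad)) {
    stop(sprintf("malformed coverage line %d in %s: expected 4 or 5 fields, got %d",
                 bad[1], path, nf[bad[1]]))
  }
  has_pct <- nf == 5L
  pos     <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  n_meth  <- suppressWarnings(as.integer(mapply(function(f, p) f[[if (p) 4L else 3L]],
                                                fields, has_pct)))
  n_unmeth <- suppressWarnings(as.integer(mapply(function(f, p) f[[if (p) 5L else 4L]],
                                                 fields, has_pct)))
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad)) {
    stop(sprintf("malformed coverage line %d in %s: non-numeric field", bad[1], path))
  }
  calls <- data.table(chrom = vapply(fields, `[`, "", 1L), pos = pos,
                      n_meth = n_meth, n_unmeth = n_unmeth)
  if (merge_strands) {
    ## collapse symmetric CpG strand pairs (pos, pos + 1) onto the minus
    ## coordinate of the pair
    setorder(calls, chrom, pos)
    calls[, anchor := pos]
    calls[, prev_pos := data.table::shift(pos), by = chrom]
    calls[!is.na(prev_pos) & pos == prev_pos + 1L, anchor := prev_pos]
    calls <- calls[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                   by = .(chrom, pos = anchor)]
  }
  CellMethylome(cell_id, calls, ...)
}

#' Write a methylome back to coverage format
#'
#' Writes `chrom pos pct n_meth n_unmeth` tab-separated lines readable by
#' [read_cell_coverage()]; write-then-read reproduces the calls exactly.
#'
#' @param cell A [CellMethylome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_coverage <- function(cell, path) {
  stopifnot(inherits(cell, "CellMethylome"))
  out <- copy(cell$calls)
  out[, pct := round(100 * n_meth / (n_meth + n_unmeth), 6)]
  data.table::fwrite(out[, .(chrom, pos, pct, n_meth, n_unmeth)], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ region file
#'
#' Columns: chrom, start (0-based), end (exclusive), optional name and
#' class. Missing names become `region_<i>`.
#'
#' @param path BED file path.
#' @return A region `data.table` as from [region_table()].
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns")
  ids <- if (ncol(bed) >= 4) as.character(bed[[4]]) else paste0("region_", seq_len(nrow(bed)))
  cls <- if (ncol(bed) >= 5) as.character(bed[[5]]) else NA_character_
  region_table(bed[[1]], bed[[2]], bed[[3]], ids, cls)
}

#' Read a sample sheet
#'
#' Tab- or comma-separated table with at least `cell_id`; recognised
#' optional columns are `individual_id`, `age_group`, `age_weeks`,
#' `n_alignments`, `mapped_total`, `mito_fraction`.
#'
#' @param path File path.
#' @return A `data.table`, one row per cell.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  ss <- data.table::fread(path)
  if (!"cell_id" %in% names(ss)) stop("sample sheet must have a cell_id column")
  if (anyDuplicated(ss$cell_id)) stop("duplicated cell_id in sample sheet")
  ss[]
}

#' Read a genes-by-cells count table
#'
#' Plain TSV with gene ids in the first column and one column per cell.
#'
#' @param path File path.
#' @param sample_sheet Optional table from [read_sample_sheet()] supplying
#'   `mapped_total` and `mito_fraction` per cell; cells absent from the
#'   sheet get column-sum totals.
#' @return An [ExpressionMatrix].
#' @export
read_expression_tsv <- function(path, sample_sheet = NULL) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- data.table::fread(path)
  genes <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, with = FALSE])
  rownames(counts) <- genes
  mapped_total <- NULL
  mito_fraction <- NULL
  if (!is.null(sample_sheet)) {
    idx <- match(colnames(counts), sample_sheet$cell_id)
    if ("mapped_total" %in% names(sample_sheet)) {
      mapped_total <- sample_sheet$mapped_total[idx]
      mapped_total[is.na(mapped_total)] <- colSums(counts)[is.na(mapped_total)]
    }
    if ("mito_fraction" %in% names(sample_sheet)) {
      mito_fraction <- sample_sheet$mito_fraction[idx]
    }
  }
  ExpressionMatrix(counts, mapped_total = mapped_total,
                   mito_fraction = mito_fraction,
                   cell_meta = if (is.null(sample_sheet)) NULL else
                     sample_sheet[match(colnames(counts), cell_id)])
}

#' Build the region call matrix for one region
#'
#' Collects, across cells, every CpG position covered by at least one cell
#' inside the region's 0-based half-open interval (coverage positions are
#' 1-based, so a position `p` is inside iff `start < p <= end`), and
#' binarises each cell's call at each site: 1 if the methylated read
#' fraction is `>= binarise_threshold` (round half up), 0 otherwise, `NA`
#' where the cell has no coverage.
#'
#' @param cells List of [CellMethylome] objects (at least one).
#' @param region One-row region as from [region_table()], or a list with
#'   `chrom`, `start`, `end`, `region_id`.
#' @param binarise_threshold Methylated-fraction threshold in `(0, 1)`;
#'   default 0.5. Calls exactly at the threshold are set to 1.
#' @return A [RegionCallMatrix]; a region covering no CpG in any cell
#'   yields a matrix with zero columns.
#' @export
build_region_matrix <- function(cells, region, binarise_threshold = 0.5) {
  if (length(cells) == 0) stop("build_region_matrix needs at least one cell")
  stopifnot(binarise_threshold > 0, binarise_threshold < 1)
  region <- as.list(as.data.table(region)[1])
  cell_ids <- vapply(cells, function(x) x$cell_id, "")
  sub <- lapply(cells, function(cm) {
    cm$calls[chrom == region$chrom & pos > region$start & pos <= region$end]
  })
  sites <- sort(unique(unlist(lapply(sub, `[[`, "pos"))))
  states <- matrix(NA_real_, nrow = length(cells), ncol = length(sites),
                   dimnames = list(cell_ids, sites))
  for (i in seq_along(sub)) {
    s <- sub[[i]]
    if (nrow(s)) {
      frac <- s$n_meth / (s$n_meth + s$n_unmeth)
      states[i, match(s$pos, sites)] <- as.numeric(frac >= binarise_threshold)
    }
  }
  RegionCallMatrix(region$region_id, states, cell_ids = cell_ids,
                   site_positions = sites)
}

#' Aggregate single cells to a pseudobulk methylome
#'
#' Sums methylated and unmethylated read counts per CpG position across
#' cells — the aggregation used before epigenetic-age prediction. The
#' result inherits the (single) individual's annotation.
#'
#' @param cells List of [CellMethylome] objects from one individual.
#' @param id Identifier for the merged sample; defaults to the
#'   individual id.
#' @param allow_mixed Set `TRUE` to permit cells from several individuals
#'   (annotation fields then become `NA`).
#' @return A [CellMethylome] whose counts are per-site sums.
#' @export
pseudobulk <- function(cells, id = NULL, allow_mixed = FALSE) {
  if (length(cells) == 0) stop("pseudobulk needs at least one cell")
  indiv <- unique(vapply(cells, function(x) as.character(x$individual_id), ""))
  if (length(indiv) > 1 && !allow_mixed) {
    stop("cells come from multiple individuals (",
         paste(indiv, collapse = ", "),
         "); pass allow_mixed = TRUE to override")
  }
  calls <- rbindlist(lapply(cells, `[[`, "calls"))
  calls <- calls[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                 by = .(chrom, pos)]
  mixed <- length(indiv) > 1
  CellMethylome(
    cell_id = if (is.null(id)) paste0(indiv[1], "_pseudobulk") else id,
    calls = calls,
    individual_id = if (mixed) NA_character_ else indiv[1],
    age_group = if (mixed) NA_character_ else cells[[1]]$age_group,
    age_weeks = if (mixed) NA_real_ else cells[[1]]$age_weeks,
    n_alignments = sum(vapply(cells, function(x) {
      if (is.na(x$n_alignments)) 0L else as.integer(x$n_alignments)
    }, integer(1)))
  )
}
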