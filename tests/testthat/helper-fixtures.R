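# Small fixtures built in code.

# A CellMethylome from a compact spec: positions and counts on one
# chromosome.
make_cell <- function(cell_id, pos, n_meth, n_unmeth, chrom = "chr1", ...) {
  CellMethylome(cell_id,
                data.frame(chrom = chrom, pos = pos,
                           n_meth = n_meth, n_unmeth = n_unmeth),
                ...)
}

# A list of cells with single-read calls at the given sites taken from a
# binary states matrix (rows = cells); NA entries are uncovered.
cells_from_states <- function(states, pos, chrom = "chr1",
                              individual_id = "I1", prefix = "c", ...) {
  lapply(seq_len(nrow(states)), function(i) {
    covered <- which(!is.na(states[i, ]))
    make_cell(sprintf("%s%02d", prefix, i), pos[covered],
              n_meth = states[i, covered],
              n_unmeth = 1 - states[i, covered],
              chrom = chrom, individual_id = individual_id, ...)
  })
}

# An ExpressionMatrix with explicit per-cell metrics.
make_expr <- function(counts, mapped_total = NULL, mito = NULL) {
  ExpressionMatrix(counts, mapped_total = mapped_total, mito_fraction = mito)
}

# Random {0,1,NA} call matrix.
random_states <- function(n_cells, n_sites, missing_rate = 0) {
  m <- matrix(rbinom(n_cells * n_sites, 1, 0.5), n_cells, n_sites)
  if (missing_rate > 0) {
    m[matrix(runif(n_cells * n_sites) < missing_rate, n_cells, n_sites)] <- NA
  }
  m
}
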