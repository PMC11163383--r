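# Shared builders for small in-code fixtures.

edge_df <- function(a, b) {
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

# expression matrix from a named list of numeric series
expr_mat <- function(series) {
  m <- do.call(rbind, series)
  rownames(m) <- names(series)
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}

# mhpin with given edges, everything co-active at time 1 (so every edge and
# clique passes the spatiotemporal checks), optional RNA edges
toy_mhpin <- function(edges, proteins = NULL, rna_edges = NULL) {
  if (is.null(proteins))
    proteins <- sort(unique(c(edges$protein_a, edges$protein_b)))
  expr <- expr_mat(stats::setNames(
    rep(list(c(5, 5, 9)), length(proteins)), proteins))
  act <- compute_activity(expr)
  build_mhpin(edges, act, NULL, rna_edges)
}

toy_activity <- function(proteins, times_list) {
  expr <- expr_mat(stats::setNames(rep(list(rep(1, 4)), length(proteins)),
                                   proteins))
  act <- compute_activity(expr)
  act$active_times <- stats::setNames(times_list, proteins)
  act
}

random_complexes <- function(n, universe, max_size = 10) {
  lapply(seq_len(n), function(i)
    sample(universe, sample(seq(2, max_size), 1)))
}

# brute-force softmax used as an oracle
softmax_oracle <- function(x) exp(x) / sum(exp(x))
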