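#' Per-protein activity threshold
#'
#' Threshold separating active from inactive expression for one protein,
#' computed from the mean `u` and standard deviation `sigma` of its
#' time-course:
#' \deqn{u + k\,\sigma\,(1 - 1/(1 + \sigma^2))}
#' The variance-dependent damping keeps the threshold close to the mean for
#' stably expressed proteins (at `sigma = 0` the threshold is exactly the
#' mean) while pushing it upward for noisy ones.
#'
#' @param u mean expression (vectorized)
#' @param sigma standard deviation of expression, must be `>= 0`
#' @param k stringency multiplier; larger `k` marks fewer time points active.
#'   Default 1.
#' @return numeric threshold(s)
#' @export
active_threshold <- function(u, sigma, k = 1) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  u + k * sigma * (1 - 1 / (1 + sigma^2))
}

#' Per-protein activity profiles from a time-course expression matrix
#'
#' For each protein, computes the mean, sample standard deviation, the
#' [active_threshold()], and the set of active time points: those whose
#' expression value is at least the threshold (`>=`, so a constant series is
#' active at every point).
#'
#' @param expr numeric matrix, proteins x T, rownames = protein IDs
#' @param k stringency multiplier passed to [active_threshold()]
#' @return object of class `activity_profile`: list with numeric vectors
#'   `u`, `sigma`, `threshold` (named by protein) and `active_times`, a named
#'   list of integer vectors in `1..T`
#' @export
compute_activity <- function(expr, k = 1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  u <- rowMeans(expr)
  sigma <- apply(expr, 1L, stats::sd)
  sigma[is.na(sigma)] <- 0 # T = 1
  thr <- active_threshold(u, sigma, k)
  active <- lapply(seq_len(nrow(expr)), function(i)
    unname(which(expr[i, ] >= thr[[i]])))
  names(active) <- rownames(expr)
  structure(list(u = u, sigma = sigma, threshold = thr,
                 active_times = active, T = ncol(expr), k = k),
            class = "activity_profile")
}

active_times_of <- function(activity, protein) {
  if (is.null(activity)) return(integer(0))
  at <- activity$active_times[[protein]]
  if (is.null(at)) integer(0) else at
}

locations_of <- function(localization, protein) {
  if (is.null(localization)) return(character(0))
  lc <- localization[[protein]]
  if (is.null(lc)) character(0) else lc
}

#' Select regulator RNA partners for each protein
#'
#' For every protein, keeps the RNAs whose association score is strictly
#' greater than the mean of that protein's own recorded scores. A protein
#' with a single recorded association (or all-equal scores) gets no partner,
#' since nothing exceeds its own mean.
#'
#' @param assoc data.frame with columns `rna`, `protein`, `score`
#' @return data.frame (`rna`, `protein`, `score`) of retained bipartite edges
#' @export
select_rna_partners <- function(assoc) {
  stopifnot(all(c("rna", "protein", "score") %in% colnames(assoc)))
  if (nrow(assoc) == 0L)
    return(data.frame(rna = character(0), protein = character(0),
                      score = numeric(0)))
  mu <- stats::ave(assoc$score, assoc$protein, FUN = mean)
  out <- assoc[assoc$score > mu, c("rna", "protein", "score"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the multiplex heterogeneous protein information network
#'
#' Filters the PPI edge list by spatiotemporal evidence: an edge is retained
#' iff its endpoints share at least one active time point OR at least one
#' subcellular compartment. Retained edges are annotated with both
#' intersection sets; selected RNA-protein bipartite edges are attached as a
#' distinct interaction type.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`
#' @param activity an `activity_profile` from [compute_activity()], or `NULL`
#' @param localization named list protein -> compartments, or `NULL`
#' @param rna_edges data.frame (`rna`, `protein`, `score`) from
#'   [select_rna_partners()], or `NULL`
#' @param filter if `FALSE`, skip the spatiotemporal filter and keep every
#'   edge (annotations are still computed); used for ablation runs
#' @return object of class `mhpin`: protein and RNA node sets, annotated
#'   retained edges, bipartite edges, and counts of removed edges
#' @export
build_mhpin <- function(edges, activity = NULL, localization = NULL,
                        rna_edges = NULL, filter = TRUE) {
  stopifnot(all(c("protein_a", "protein_b") %in% colnames(edges)))
  n <- nrow(edges)
  co_time <- vector("list", n)
  co_loc <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    a <- edges$protein_a[[i]]; b <- edges$protein_b[[i]]
    ct <- intersect(active_times_of(activity, a), active_times_of(activity, b))
    cl <- intersect(locations_of(localization, a), locations_of(localization, b))
    co_time[[i]] <- ct
    co_loc[[i]] <- cl
    keep[[i]] <- length(ct) > 0L || length(cl) > 0L
  }
  if (!filter) keep <- rep(TRUE, n)
  kept <- edges[keep, c("protein_a", "protein_b"), drop = FALSE]
  kept$co_time <- co_time[keep]
  kept$co_loc <- co_loc[keep]
  rownames(kept) <- NULL
  if (is.null(rna_edges))
    rna_edges <- data.frame(rna = character(0), protein = character(0),
                            score = numeric(0))
  proteins <- sort(unique(c(edges$protein_a, edges$protein_b,
                            rna_edges$protein)))
  rnas <- sort(unique(rna_edges$rna))
  if (nrow(kept) == 0L)
    message("build_mhpin: no PPI edge survived the spatiotemporal filter")
  structure(list(proteins = proteins, rnas = rnas, edges = kept,
                 rna_edges = rna_edges,
                 n_removed = n - nrow(kept), filtered = filter),
            class = "mhpin")
}

#' @export
print.mhpin <- function(x, ...) {
  cat(sprintf(
    "mhpin: %d proteins, %d RNAs, %d retained PPI edges (%d removed), %d RNA-protein edges\n",
    length(x$proteins), length(x$rnas), nrow(x$edges), x$n_removed,
    nrow(x$rna_edges)))
  invisible(x)
}

#' Build the stack of basic spatiotemporal interaction patterns
#'
#' Decomposes the retained PPI edges into binary adjacency layers: one
#' single-time pattern `T_i` per time point, one single-space pattern `S_j`
#' per compartment, and one overlap pattern `T_i&S_j` per time-compartment
#' combination, an edge entering `T_i&S_j` iff it is co-active at `T_i` and
#' co-located at `S_j`. All-zero layers are dropped (a zero matrix carries no
#' interaction). Layer order is deterministic: single-time ascending, then
#' single-space in compartment-vocabulary order, then overlaps time-major.
#'
#' @param mhpin an `mhpin` from [build_mhpin()]
#' @param space_vocab optional character vector fixing the compartment order;
#'   defaults to the sorted compartments observed on retained edges
#' @return object of class `pattern_stack`: named list `mats` of sparse
#'   binary symmetric matrices over the protein node set, `labels`, `M`,
#'   `proteins`, `space_vocab`
#' @export
build_patterns <- function(mhpin, space_vocab = NULL) {
  stopifnot(inherits(mhpin, "mhpin"))
  proteins <- mhpin$proteins
  np <- length(proteins)
  idx <- stats::setNames(seq_len(np), proteins)
  ed <- mhpin$edges
  times <- sort(unique(unlist(ed$co_time)))
  if (is.null(space_vocab))
    space_vocab <- sort(unique(unlist(ed$co_loc)))
  locs <- space_vocab[space_vocab %in% unique(unlist(ed$co_loc))]
  sidx <- match(locs, space_vocab)

  triplets <- list() # label -> list(i = ..., j = ...)
  add_entry <- function(lbl, i, j) {
    cur <- triplets[[lbl]]
    if (is.null(cur)) cur <- list(i = integer(0), j = integer(0))
    cur$i <- c(cur$i, i); cur$j <- c(cur$j, j)
    triplets[[lbl]] <<- cur
  }
  for (e in seq_len(nrow(ed))) {
    i <- idx[[ed$protein_a[[e]]]]; j <- idx[[ed$protein_b[[e]]]]
    ct <- ed$co_time[[e]]; cl <- ed$co_loc[[e]]
    for (t in ct) add_entry(paste0("T", t), i, j)
    for (s in cl) add_entry(paste0("S", match(s, space_vocab)), i, j)
    for (t in ct) for (s in cl)
      add_entry(paste0("T", t, "&S", match(s, space_vocab)), i, j)
  }
  overlap_labels <- if (length(times) && length(sidx))
    as.vector(t(outer(times, sidx, function(t, s) paste0("T", t, "&S", s))))
  else character(0)
  labels <- c(paste0("T", times), paste0("S", sidx), overlap_labels)
  labels <- labels[labels %in% names(triplets)]
  mats <- lapply(labels, function(lbl) {
    tr <- triplets[[lbl]]
    m <- Matrix::sparseMatrix(i = c(tr$i, tr$j), j = c(tr$j, tr$i), x = 1,
                              dims = c(np, np),
                              dimnames = list(proteins, proteins))
    m@x[] <- 1 # collapse duplicate triplets to binary
    m
  })
  names(mats) <- labels
  structure(list(mats = mats, labels = labels, M = length(labels),
                 proteins = proteins, space_vocab = space_vocab),
            class = "pattern_stack")
}

#' @export
print.pattern_stack <- function(x, ...) {
  cat(sprintf("pattern_stack: M = %d layers over %d proteins\n",
              x$M, length(x$proteins)))
  invisible(x)
}
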