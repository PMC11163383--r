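#' Reweight the protein interaction network by embedding similarity
#'
#' Assigns each existing PIN edge the cosine similarity of its endpoint
#' embeddings; non-edges keep weight zero. The result measures interaction
#' tightness: noisy edges between unrelated proteins get low or negative
#' weight.
#'
#' @param Z a `final_embedding` or a numeric matrix with protein rownames
#' @param pin data.frame of edges (`protein_a`, `protein_b`), e.g.
#'   `mhpin$edges`
#' @return object of class `reweighted_pin`: sparse symmetric weight matrix
#'   `w` and the protein order
#' @export
reweight_pin <- function(Z, pin) {
  if (inherits(Z, "final_embedding")) Z <- Z$Z
  stopifnot(is.matrix(Z), !is.null(rownames(Z)))
  prots <- unique(c(pin$protein_a, pin$protein_b))
  missing <- setdiff(prots, rownames(Z))
  if (length(missing))
    stop("no embedding for protein(s): ", paste(missing, collapse = ", "))
  proteins <- rownames(Z)
  n <- length(proteins)
  ia <- match(pin$protein_a, proteins)
  ib <- match(pin$protein_b, proteins)
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm[c(ia, ib)] == 0))
    stop("zero-norm embedding row; cosine similarity undefined")
  Zn <- Z / nrm
  wv <- rowSums(Zn[ia, , drop = FALSE] * Zn[ib, , drop = FALSE])
  w <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(wv, wv),
                            dims = c(n, n),
                            dimnames = list(proteins, proteins))
  structure(list(w = w, proteins = proteins), class = "reweighted_pin")
}

weight_lookup <- function(w) {
  if (inherits(w, "reweighted_pin")) w$w else w
}

#' Density score of a candidate core
#'
#' Sum of the reweighted-PIN edge weights over all unordered pairs within
#' the core (each pair counted once).
#'
#' @param core character vector of protein IDs, length >= 2
#' @param w a `reweighted_pin` (or weight matrix with dimnames)
#' @return scalar density score
#' @export
density_score <- function(core, w) {
  stopifnot(length(core) >= 2L)
  m <- weight_lookup(w)
  sum(m[core, core]) / 2
}

#' Adhesion score of a protein to a core
#'
#' Mean reweighted edge weight from `p` into the core:
#' \eqn{ah(p, C) = \sum_{q \in C} w_{pq} / |C|}. `p` must not belong to the
#' core.
#'
#' @param p protein ID
#' @param core character vector of core protein IDs
#' @param w a `reweighted_pin`
#' @return scalar adhesion score
#' @export
adhesion_score <- function(p, core, w) {
  if (p %in% core) stop("protein ", p, " is part of the core")
  m <- weight_lookup(w)
  sum(m[p, core]) / length(core)
}

core_key <- function(members) paste(sort(members), collapse = "\r")

# deterministic candidate ordering: by descending density, then larger
# size, then lexicographically smallest member string
order_candidates <- function(cands, scores) {
  sizes <- lengths(cands)
  keys <- vapply(cands, core_key, character(1))
  order(-scores, -sizes, keys)
}

has_st_witness <- function(members, activity, localization) {
  ct <- Reduce(intersect, lapply(members, function(p)
    active_times_of(activity, p)))
  if (length(ct) > 0L) return(TRUE)
  cl <- Reduce(intersect, lapply(members, function(p)
    locations_of(localization, p)))
  length(cl) > 0L
}

#' Mine protein-complex cores from the reweighted network
#'
#' Two-stage core generation: (1) enumerate maximal cliques of size >= 3 on
#' the graph of positive-weight edges and keep those whose members share at
#' least one active time point or one compartment (candidate cores);
#' (2) score candidates by [density_score()] and sort descending; (3) move
#' the top candidate into the seed set; (4) every remaining candidate
#' overlapping it is deleted if its non-overlapping part has fewer than 3
#' proteins, otherwise replaced by that non-overlapping part (which must
#' still carry a spatiotemporal witness and is re-scored); (5) repeat until
#' no candidate remains. Ties are broken deterministically (larger size,
#' then lexicographically smallest member set), so the output is invariant
#' to input edge order.
#'
#' @param w a `reweighted_pin`
#' @param activity an `activity_profile` (or `NULL`)
#' @param localization named list protein -> compartments (or `NULL`)
#' @param min_size minimum core size (default 3)
#' @return object of class `core_set`: list of cores in extraction order,
#'   each with `members` and `d_s`
#' @export
mine_cores <- function(w, activity = NULL, localization = NULL,
                       min_size = 3L) {
  m <- weight_lookup(w)
  pos <- (m > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(pos, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g, min = min_size)
  cands <- lapply(cliques, function(cl) sort(names(cl)))
  cands <- cands[vapply(cands, has_st_witness, logical(1),
                        activity, localization)]
  cands <- cands[!duplicated(vapply(cands, core_key, character(1)))]
  if (length(cands) == 0L) {
    message("mine_cores: no candidate core of size >= ", min_size)
    return(structure(list(cores = list()), class = "core_set"))
  }
  seeds <- list()
  while (length(cands) > 0L) {
    scores <- vapply(cands, density_score, numeric(1), w = m)
    ord <- order_candidates(cands, scores)
    cands <- cands[ord]; scores <- scores[ord]
    top <- cands[[1L]]
    seeds[[length(seeds) + 1L]] <- list(members = top, d_s = scores[[1L]])
    cands <- cands[-1L]
    if (length(cands) == 0L) break
    updated <- list()
    for (cc in cands) {
      ov <- intersect(cc, top)
      if (length(ov) == 0L) {
        updated[[length(updated) + 1L]] <- cc
      } else {
        rest <- setdiff(cc, top)
        if (length(rest) >= min_size &&
            has_st_witness(rest, activity, localization))
          updated[[length(updated) + 1L]] <- sort(rest)
      }
    }
    cands <- updated[!duplicated(vapply(updated, core_key, character(1)))]
  }
  structure(list(cores = seeds), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d cores\n", length(x$cores)))
  invisible(x)
}

#' Identify protein complexes (core-attachment strategy)
#'
#' End stage of the pipeline: reweights the PIN by embedding similarity,
#' mines cores with [mine_cores()], then attaches to each core every
#' non-core protein that has at least one PIN edge into the core and whose
#' [adhesion_score()] exceeds `lambda` (strict `>`). Complexes identical as
#' sets after attachment are deduplicated, keeping the first.
#'
#' @param Z a `final_embedding` (or embedding matrix with rownames)
#' @param pin edge data.frame (`protein_a`, `protein_b`)
#' @param activity an `activity_profile` (or `NULL`)
#' @param localization named list protein -> compartments (or `NULL`)
#' @param lambda attachment threshold in `[0, 1]` (default 0.4)
#' @param min_size minimum core size
#' @return a [complex_set] with the per-complex core subsets recorded
#' @export
identify_complexes <- function(Z, pin, activity = NULL, localization = NULL,
                               lambda = 0.4, min_size = 3L) {
  stopifnot(lambda >= 0, lambda <= 1)
  w <- reweight_pin(Z, pin)
  cores <- mine_cores(w, activity, localization, min_size)
  if (length(cores$cores) == 0L)
    return(structure(list(complexes = list(), cores = list()),
                     class = "complex_set"))
  nbrs <- split(c(pin$protein_b, pin$protein_a),
                c(pin$protein_a, pin$protein_b))
  complexes <- list(); kept_cores <- list()
  for (co in cores$cores) {
    members <- co$members
    cand <- setdiff(unique(unlist(nbrs[members], use.names = FALSE)), members)
    att <- character(0)
    for (p in cand)
      if (adhesion_score(p, members, w) > lambda) att <- c(att, p)
    complexes[[length(complexes) + 1L]] <- c(members, sort(att))
    kept_cores[[length(kept_cores) + 1L]] <- members
  }
  keys <- vapply(complexes, core_key, character(1))
  keep <- !duplicated(keys)
  complex_set(complexes[keep], cores = kept_cores[keep])
}
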