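softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Wide-domain weighted adjacency
#'
#' Convex combination of the basic spatiotemporal pattern layers,
#' \eqn{\tilde A_{Wd} = \sum_i \alpha_i \bar A_i}, with the raw weight vector
#' `alpha` passed through a softmax so the combination stays bounded and
#' nonnegative. With learnable `alpha` this lets training discover which
#' spatiotemporal scenarios matter.
#'
#' @param patterns a `pattern_stack` from [build_patterns()]
#' @param alpha numeric vector of length `M` (raw, pre-softmax weights)
#' @return sparse symmetric nonnegative matrix (class from Matrix)
#' @export
wide_domain_adjacency <- function(patterns, alpha) {
  stopifnot(inherits(patterns, "pattern_stack"))
  if (length(alpha) != patterns$M)
    stop(sprintf("alpha has length %d but there are %d patterns",
                 length(alpha), patterns$M))
  a <- softmax(alpha)
  out <- NULL
  for (i in seq_len(patterns$M)) {
    term <- a[[i]] * patterns$mats[[i]]
    out <- if (is.null(out)) term else out + term
  }
  out
}

#' Per-pattern degree profile
#'
#' Row `p` records, for each pattern layer, the number of interaction
#' partners of protein `p` in that layer; proteins with similar profiles play
#' similar structural roles across spatiotemporal scenarios.
#'
#' @param patterns a `pattern_stack`
#' @return integer matrix, proteins x M, column names = pattern labels
#' @export
degree_profile <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_stack"))
  D <- vapply(patterns$mats, function(m) Matrix::rowSums(m),
              numeric(length(patterns$proteins)))
  D <- matrix(D, nrow = length(patterns$proteins),
              dimnames = list(patterns$proteins, patterns$labels))
  D
}

#' Deep-domain weighted adjacency
#'
#' Role-similarity adjacency from degree profiles: columns of `D` are scaled
#' by `sigmoid(epsilon)`, the Gram matrix `D D'` is formed, its diagonal
#' zeroed, and the result symmetrically degree-normalized
#' (\eqn{\Lambda^{-1/2} S \Lambda^{-1/2}}, all-zero rows mapping to zero
#' rows). Higher entries mean closer structural roles.
#'
#' @param profile degree-profile matrix from [degree_profile()]
#' @param epsilon numeric vector of length `M` (raw, pre-sigmoid column
#'   weights); default 0 gives uniform weight 0.5 on every pattern
#' @return dense symmetric nonnegative matrix with zero diagonal
#' @export
deep_domain_adjacency <- function(profile, epsilon = rep(0, ncol(profile))) {
  stopifnot(is.matrix(profile), length(epsilon) == ncol(profile))
  Dw <- sweep(profile, 2L, sigmoid(epsilon), `*`)
  S <- Dw %*% t(Dw)
  diag(S) <- 0
  r <- rowSums(S)
  s <- ifelse(r > 0, 1 / sqrt(r), 0)
  out <- S * outer(s, s)
  dimnames(out) <- dimnames(S)
  out
}

#' Sparsify a dense adjacency to its strongest entries
#'
#' Keeps, per row, the `k` largest strictly positive entries, then
#' re-symmetrizes by union (an entry survives if it is top-k in either
#' endpoint's row). Used to turn the dense deep-domain adjacency into a
#' neighbor graph of tractable degree.
#'
#' @param adj dense symmetric matrix
#' @param k neighbors kept per row (default 10)
#' @return sparse symmetric matrix
#' @export
sparsify_topk <- function(adj, k = 10) {
  n <- nrow(adj)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ri <- adj[i, ]
    pos <- which(ri > 0)
    if (length(pos) > k)
      pos <- pos[order(ri[pos], decreasing = TRUE)[seq_len(k)]]
    keep[i, pos] <- TRUE
  }
  keep <- keep | t(keep)
  out <- Matrix::Matrix(adj * keep, sparse = TRUE)
  dimnames(out) <- dimnames(adj)
  out
}
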