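#' Node-level attention aggregation over one neighbor type
#'
#' Aggregates the (projected) features of a target node's neighbors of a
#' single type with attention weights. The logit for neighbor `q` is
#' \eqn{b_q = \mu^\top [h_p \| h_q]} passed through a LeakyReLU; when edge
#' weights are supplied they enter additively on the logit as `log(w)`,
#' preserving the softmax form while letting pattern strength matter.
#' The output is `elu(sum_q beta_q H_q)`.
#'
#' @param h_p target node feature, length-d vector
#' @param H_nb neighbor feature matrix, one row per neighbor (may have 0 rows)
#' @param mu attention vector of length `2d`
#' @param weights optional positive edge weights, one per neighbor
#' @param slope LeakyReLU negative slope (default 0.2)
#' @return list with `embedding` (length-d vector) and `beta` (attention
#'   weights summing to 1); an empty neighborhood yields a zero embedding
#' @export
node_level_attention <- function(h_p, H_nb, mu, weights = NULL, slope = 0.2) {
  d <- length(h_p)
  if (is.null(dim(H_nb))) H_nb <- matrix(H_nb, ncol = d)
  if (nrow(H_nb) == 0L)
    return(list(embedding = numeric(d), beta = numeric(0)))
  stopifnot(ncol(H_nb) == d, length(mu) == 2L * d)
  logits <- apply(H_nb, 1L, function(h_q) sum(mu * c(h_p, h_q)))
  logits <- ifelse(logits > 0, logits, slope * logits)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(H_nb), all(weights > 0))
    logits <- logits + log(weights)
  }
  beta <- softmax(logits)
  z <- colSums(beta * H_nb)
  list(embedding = ifelse(z > 0, z, exp(pmin(z, 0)) - 1), beta = beta)
}

#' Type-level (semantic) attention over per-type embeddings
#'
#' Scores each neighbor type by \eqn{w_\phi = \frac{1}{n}\sum_i \mu^\top
#' \tanh(W z_i^\phi + b)} (averaged over all protein nodes), softmax-weights
#' the types, and returns the weighted sum of the per-type embedding
#' matrices.
#'
#' @param z_list list of n x d embedding matrices, one per type
#' @param W d x d transform
#' @param b length-d bias
#' @param mu length-d type attention vector
#' @return list with `embedding` (n x d) and `gamma` (type weights, sum 1)
#' @export
type_level_attention <- function(z_list, W, b, mu) {
  stopifnot(length(z_list) >= 1L)
  if (length(z_list) == 1L)
    return(list(embedding = z_list[[1L]], gamma = 1))
  w <- vapply(z_list, function(z)
    mean(tanh(sweep(z %*% W, 2L, b, `+`)) %*% mu), numeric(1))
  gamma <- softmax(w)
  out <- Reduce(`+`, Map(`*`, gamma, z_list))
  list(embedding = out, gamma = gamma)
}

#' Single-layer symmetric-normalized graph convolution
#'
#' One meta-path-specific convolution layer with self term:
#' \eqn{z_p = \frac{1}{d_p+1} h_p + \sum_{q \in N_p}
#' \frac{1}{\sqrt{(d_p+1)(d_q+1)}} h_q}, where degrees are taken on the
#' meta-path neighbor graph. Isolated nodes keep their own features.
#'
#' @param adj symmetric binary adjacency (base or Matrix), n x n
#' @param H feature matrix, n x d
#' @return n x d convolved features
#' @export
metapath_gcn <- function(adj, H) {
  adj <- as.matrix(adj)
  stopifnot(nrow(adj) == ncol(adj), nrow(adj) == nrow(H))
  deg <- rowSums(adj != 0)
  s <- 1 / sqrt(deg + 1)
  out <- s * ((adj != 0) %*% (s * H)) + H / (deg + 1)
  dimnames(out) <- dimnames(H)
  out
}

#' Fuse per-meta-path embeddings by semantic attention
#'
#' Same machinery as [type_level_attention()], applied across meta-path types
#' (with its own learned parameters in training): the result is a convex
#' combination of the per-path embedding matrices.
#'
#' @inheritParams type_level_attention
#' @return list with `embedding` (n x d) and `theta` (path weights, sum 1)
#' @export
metapath_fusion <- function(z_list, W, b, mu) {
  out <- type_level_attention(z_list, W, b, mu)
  names(out) <- c("embedding", "theta")
  out
}

# ---- meta-path neighbor graphs -------------------------------------------

# protein-protein-protein: two-hop closure of a protein adjacency (diagonal
# removed); protein-RNA-protein: proteins sharing at least one RNA partner.
metapath_graphs <- function(adj, bip = NULL) {
  B <- (as.matrix(adj) != 0) * 1
  A2 <- (B %*% B > 0) * 1
  diag(A2) <- 0
  out <- list(ppp = A2)
  if (!is.null(bip) && ncol(bip) > 0L && sum(bip) > 0) {
    P <- (as.matrix(bip) != 0) * 1
    A <- (P %*% t(P) > 0) * 1
    diag(A) <- 0
    out$prp <- A
  }
  out
}

# GCN operator (constant matrix N with N H == metapath_gcn(adj, H))
gcn_operator <- function(adj) {
  A <- (as.matrix(adj) != 0) * 1
  deg <- rowSums(A)
  s <- 1 / sqrt(deg + 1)
  N <- A * outer(s, s)
  diag(N) <- diag(N) + s^2
  N
}

# ---- encoder parameters and full forward ----------------------------------

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize dual-view aggregator parameters
#'
#' One parameter set per interaction pattern aggregator (wide, deep): type
#' projections, node-level attention vectors for the protein and RNA
#' neighbor types, and two semantic-attention parameter triples (first-order
#' types; meta-paths). Drawn from scaled normal distributions; seed the RNG
#' before calling for reproducibility.
#'
#' @param h input feature dimension
#' @param d hidden/output embedding dimension
#' @return named list of parameter matrices/vectors
#' @export
init_encoder_params <- function(h, d) {
  list(
    W_P = glorot(h, d), W_R = glorot(h, d),
    mu_p = glorot(2L * d, 1L), mu_r = glorot(2L * d, 1L),
    Wt = glorot(d, d), bt = matrix(0, 1L, d), mut = glorot(d, 1L),
    Wm = glorot(d, d), bm = matrix(0, 1L, d), mum = glorot(d, 1L)
  )
}

# Tape forward of one aggregator. topo holds the (fixed or per-epoch)
# topology: protein-edge endpoints, optional RNA edges, GCN operators.
# X_P/X_R and prm entries are tape nodes; pe_w is a tape node of positive
# edge weights or NULL. Returns nodes Z_stra, Z_mp, Z_pat.
enc_forward <- function(ctx, X_P, X_R, prm, topo, slope = 0.2) {
  H_P <- ad_matmul(ctx, X_P, prm$W_P)
  H_R <- if (!is.null(X_R)) ad_matmul(ctx, X_R, prm$W_R)
  nP <- nrow(H_P$v)
  d <- ncol(H_P$v)

  attn_type <- function(H_src, tgt, src, mu, wnode) {
    Ht <- ad_rows(ctx, H_P, tgt)
    Hs <- ad_rows(ctx, H_src, src)
    l <- ad_leakyrelu(ctx, ad_matmul(ctx, ad_cbind(ctx, Ht, Hs), mu), slope)
    if (!is.null(wnode)) l <- ad_add(ctx, l, ad_log(ctx, wnode))
    beta <- ad_segment_softmax(ctx, l, tgt)
    ad_elu(ctx, ad_scatter(ctx, ad_rowscale(ctx, Hs, beta), tgt, nP))
  }

  z_prot <- if (length(topo$pe_tgt))
    attn_type(H_P, topo$pe_tgt, topo$pe_src, prm$mu_p, topo$pe_w)
  else ad_const(ctx, matrix(0, nP, d))
  z_rna <- if (length(topo$re_tgt))
    attn_type(H_R, topo$re_tgt, topo$re_src, prm$mu_r, NULL)

  fuse <- function(zl, W, b, mu) {
    if (length(zl) == 1L) return(zl[[1L]])
    sc <- lapply(zl, function(z)
      ad_mean(ctx, ad_matmul(ctx,
        ad_tanh(ctx, ad_addvec(ctx, ad_matmul(ctx, z, W), b)), mu)))
    gam <- ad_softmax(ctx, ad_vstack(ctx, sc))
    out <- NULL
    for (k in seq_along(zl)) {
      term <- ad_scalmul(ctx, ad_get(ctx, gam, k), zl[[k]])
      out <- if (is.null(out)) term else ad_add(ctx, out, term)
    }
    out
  }

  Z_stra <- fuse(c(list(z_prot), if (!is.null(z_rna)) list(z_rna)),
                 prm$Wt, prm$bt, prm$mut)

  z_paths <- list(ad_matmul(ctx, ad_const(ctx, topo$N_ppp), H_P))
  if (!is.null(topo$N_prp))
    z_paths <- c(z_paths, list(ad_matmul(ctx, ad_const(ctx, topo$N_prp), H_P)))
  Z_mp <- fuse(z_paths, prm$Wm, prm$bm, prm$mum)

  list(Z_stra = Z_stra, Z_mp = Z_mp,
       Z_pat = ad_scale(ctx, ad_add(ctx, Z_stra, Z_mp), 0.5))
}

# Build the topology inputs for one aggregator from a (sparse) weighted
# protein adjacency and the RNA bipartite edges. wnode_fn(ij) must return a
# tape node of the adjacency entries at the E x 2 index matrix ij (or NULL
# for constant weights).
enc_topology <- function(adj, proteins, rnas, rna_edges, ctx = NULL,
                         wnode = NULL) {
  Adense <- as.matrix(adj)
  nz <- which(Adense > 0, arr.ind = TRUE)
  topo <- list(pe_tgt = as.integer(nz[, 1L]), pe_src = as.integer(nz[, 2L]),
               pe_w = wnode)
  bip <- NULL
  if (!is.null(rna_edges) && nrow(rna_edges) > 0L && length(rnas) > 0L) {
    pi <- match(rna_edges$protein, proteins)
    ri <- match(rna_edges$rna, rnas)
    ok <- !is.na(pi) & !is.na(ri)
    topo$re_tgt <- pi[ok]
    topo$re_src <- ri[ok]
    bip <- matrix(0, length(proteins), length(rnas))
    bip[cbind(pi[ok], ri[ok])] <- 1
  } else {
    topo$re_tgt <- integer(0)
    topo$re_src <- integer(0)
  }
  mg <- metapath_graphs(Adense, bip)
  topo$N_ppp <- gcn_operator(mg$ppp)
  topo$N_prp <- if (!is.null(mg$prp)) gcn_operator(mg$prp)
  topo$nz <- nz
  topo
}

#' Encode one interaction pattern with the dual-view aggregator
#'
#' Runs the full aggregator forward for a single pattern adjacency: the
#' first-order view attends over protein neighbors (nonzero entries of the
#' adjacency, weights on the logits) and RNA partners, then weighs the two
#' neighbor types by semantic attention; the meta-path view convolves over
#' the protein-protein-protein (two-hop) and protein-RNA-protein
#' (shared-regulator) neighbor graphs and fuses them the same way. Without
#' RNA edges both views reduce to their protein-only branch.
#'
#' @param adjacency symmetric nonnegative protein-protein matrix (wide- or
#'   deep-domain), rows/cols ordered as `mhpin$proteins`
#' @param mhpin an `mhpin` (supplies RNA bipartite edges and node order)
#' @param features matrix with one row per node, proteins first then RNAs
#'   (rownames = `c(mhpin$proteins, mhpin$rnas)`)
#' @param params parameter list from [init_encoder_params()]
#' @param slope LeakyReLU slope
#' @return list of matrices `Z_stra`, `Z_mp`, `Z_pattern` (each
#'   `|proteins| x d`), with `Z_pattern = (Z_stra + Z_mp) / 2`
#' @export
encode_pattern <- function(adjacency, mhpin, features, params, slope = 0.2) {
  proteins <- mhpin$proteins
  rnas <- mhpin$rnas
  stopifnot(nrow(features) == length(proteins) + length(rnas))
  ctx <- ad_ctx()
  nP <- length(proteins)
  X_P <- ad_const(ctx, features[seq_len(nP), , drop = FALSE])
  X_R <- if (length(rnas))
    ad_const(ctx, features[nP + seq_along(rnas), , drop = FALSE])
  Anode <- ad_const(ctx, as.matrix(adjacency))
  topo <- enc_topology(adjacency, proteins, rnas, mhpin$rna_edges)
  if (nrow(topo$nz) > 0L)
    topo$pe_w <- ad_gather_elems(ctx, Anode, topo$nz)
  prm <- lapply(params, function(p) ad_const(ctx, p))
  out <- enc_forward(ctx, X_P, X_R, prm, topo, slope)
  res <- list(Z_stra = out$Z_stra$v, Z_mp = out$Z_mp$v,
              Z_pattern = out$Z_pat$v)
  for (nm in names(res)) rownames(res[[nm]]) <- proteins
  res
}
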