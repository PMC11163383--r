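elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

test_that("node-level attention matches a brute-force softmax oracle", {
  set.seed(21)
  d <- 4
  h_p <- rnorm(d)
  mu <- rnorm(2 * d)

  # single neighbor: beta = 1, output elu(H_q)
  Hq <- matrix(rnorm(d), 1)
  out <- node_level_attention(h_p, Hq, mu)
  expect_equal(out$beta, 1)
  expect_equal(out$embedding, elu(as.vector(Hq)))

  # two identical neighbors: symmetric attention
  Hq2 <- rbind(Hq, Hq)
  out2 <- node_level_attention(h_p, Hq2, mu)
  expect_equal(unname(out2$beta), c(0.5, 0.5))

  # three random neighbors: oracle softmax of leaky-relu logits
  H3 <- matrix(rnorm(3 * d), 3)
  out3 <- node_level_attention(h_p, H3, mu)
  logits <- apply(H3, 1, function(hq) {
    b <- sum(mu * c(h_p, hq))
    ifelse(b > 0, b, 0.2 * b)
  })
  expect_equal(unname(out3$beta), unname(softmax_oracle(logits)),
               tolerance = 1e-12)
  expect_equal(out3$embedding,
               elu(colSums(softmax_oracle(logits) * H3)), tolerance = 1e-12)
  expect_equal(sum(out3$beta), 1, tolerance = 1e-6)

  # edge weights shift the logits additively in log space
  wts <- c(2, 1, 1)
  outw <- node_level_attention(h_p, H3, mu, weights = wts)
  expect_equal(unname(outw$beta),
               unname(softmax_oracle(logits + log(wts))), tolerance = 1e-12)

  # empty neighborhood yields a zero embedding, not an error
  out0 <- node_level_attention(h_p, matrix(numeric(0), 0, d), mu)
  expect_equal(out0$embedding, numeric(d))
})

test_that("type-level attention is a softmax-weighted convex combination", {
  set.seed(22)
  n <- 5; d <- 3
  W <- matrix(rnorm(d * d), d); b <- rnorm(d); mu <- rnorm(d)
  z1 <- matrix(rnorm(n * d), n)
  # single type: identity
  expect_equal(type_level_attention(list(z1), W, b, mu)$embedding, z1)
  # identical types: gamma = 0.5 each, output unchanged
  out <- type_level_attention(list(z1, z1), W, b, mu)
  expect_equal(unname(out$gamma), c(0.5, 0.5))
  expect_equal(out$embedding, z1, tolerance = 1e-12)
  # random types: weights match the brute-force oracle and sum to 1
  z2 <- matrix(rnorm(n * d), n)
  out2 <- type_level_attention(list(z1, z2), W, b, mu)
  w_or <- sapply(list(z1, z2), function(z)
    mean(tanh(sweep(z %*% W, 2, b, `+`)) %*% mu))
  g_or <- softmax_oracle(w_or)
  expect_equal(unname(out2$gamma), unname(g_or), tolerance = 1e-12)
  expect_equal(out2$embedding, g_or[1] * z1 + g_or[2] * z2, tolerance = 1e-12)
  expect_equal(sum(out2$gamma), 1, tolerance = 1e-6)
})

test_that("single-layer convolution matches dense evaluation of the normalized operator", {
  set.seed(23)
  d <- 3
  # isolated node keeps its own features
  H1 <- matrix(rnorm(d), 1)
  expect_equal(metapath_gcn(matrix(0, 1, 1), H1), H1)
  # connected pair, both degree 1: average of the two features
  H2 <- matrix(rnorm(2 * d), 2)
  A2 <- rbind(c(0, 1), c(1, 0))
  expect_equal(metapath_gcn(A2, H2)[1, ], (H2[1, ] + H2[2, ]) / 2,
               tolerance = 1e-12)
  # star graph: brute-force evaluation of the per-node formula
  n <- 6
  A <- matrix(0, n, n); A[1, 2:n] <- 1; A[2:n, 1] <- 1
  H <- matrix(rnorm(n * d), n)
  Z <- metapath_gcn(A, H)
  deg <- rowSums(A)
  oracle <- t(sapply(seq_len(n), function(p) {
    z <- H[p, ] / (deg[p] + 1)
    for (q in which(A[p, ] == 1))
      z <- z + H[q, ] / sqrt((deg[p] + 1) * (deg[q] + 1))
    z
  }))
  expect_equal(Z, oracle, tolerance = 1e-12)
  # random graph <= 20 nodes: same identity
  n <- 15
  A <- matrix(rbinom(n * n, 1, 0.3), n); A <- pmax(A, t(A)); diag(A) <- 0
  H <- matrix(rnorm(n * d), n)
  deg <- rowSums(A)
  s <- 1 / sqrt(deg + 1)
  dense <- (A * outer(s, s) + diag(s^2)) %*% H
  expect_equal(metapath_gcn(A, H), dense, tolerance = 1e-12)
})

test_that("meta-path fusion returns a convex combination with weights summing to 1", {
  set.seed(24)
  n <- 4; d <- 3
  W <- matrix(rnorm(d * d), d); b <- rnorm(d); mu <- rnorm(d)
  z1 <- matrix(rnorm(n * d), n); z2 <- matrix(rnorm(n * d), n)
  expect_equal(metapath_fusion(list(z1), W, b, mu)$embedding, z1)
  same <- metapath_fusion(list(z2, z2), W, b, mu)
  expect_equal(same$embedding, z2, tolerance = 1e-12)
  out <- metapath_fusion(list(z1, z2), W, b, mu)
  expect_equal(sum(out$theta), 1, tolerance = 1e-6)
  lo <- pmin(z1, z2); hi <- pmax(z1, z2)
  expect_true(all(out$embedding >= lo - 1e-12 & out$embedding <= hi + 1e-12))
})

test_that("encode_pattern composes the two views over the heterogeneous network", {
  set.seed(25)
  act <- toy_activity(c("A", "B", "C", "D"), rep(list(1L), 4))
  edges <- edge_df(c("A", "B", "C"), c("B", "C", "A")) # triangle + D isolated
  # two proteins share an RNA but no PPI edge
  rna <- data.frame(rna = c("r1", "r1"), protein = c("A", "D"),
                    score = c(0.9, 0.9))
  mh <- build_mhpin(edges, act, NULL, rna)
  pats <- build_patterns(mh)
  adj <- wide_domain_adjacency(pats, rep(0, pats$M))
  h <- 5; d <- 4
  X <- matrix(rnorm((length(mh$proteins) + length(mh$rnas)) * h), ncol = h)
  prm <- init_encoder_params(h, d)
  out <- encode_pattern(adj, mh, X, prm)
  expect_equal(dim(out$Z_stra), c(4L, d))
  expect_equal(out$Z_pattern, (out$Z_stra + out$Z_mp) / 2, tolerance = 1e-12)

  # P-R-P meta-path connects the RNA-sharing pair A-D
  bip <- matrix(0, 4, 1, dimnames = list(mh$proteins, "r1"))
  bip[c("A", "D"), 1] <- 1
  mg <- stcomplex:::metapath_graphs(as.matrix(adj), bip)
  expect_equal(mg$prp["A", "D"], 1)
  expect_equal(sum(mg$prp), 2)
  # P-P-P graph equals the triangle's two-hop closure (oracle: path enumeration)
  B <- (as.matrix(adj) != 0) * 1
  two_hop <- (B %*% B > 0) * 1; diag(two_hop) <- 0
  expect_equal(mg$ppp, two_hop)

  # without RNA edges the first-order view reduces to the protein type
  mh0 <- build_mhpin(edges, act, NULL)
  pats0 <- build_patterns(mh0)
  adj0 <- wide_domain_adjacency(pats0, rep(0, pats0$M))
  X0 <- X[seq_along(mh0$proteins), , drop = FALSE]
  out0 <- encode_pattern(adj0, mh0, X0, prm)
  H_P <- X0 %*% prm$W_P
  z_oracle <- t(sapply(seq_len(nrow(H_P)), function(p) {
    nb <- which(as.matrix(adj0)[p, ] > 0)
    node_level_attention(H_P[p, ], H_P[nb, , drop = FALSE],
                         as.vector(prm$mu_p),
                         weights = as.matrix(adj0)[p, nb])$embedding
  }))
  expect_equal(unname(out0$Z_stra), unname(z_oracle), tolerance = 1e-10)
})

test_that("permuting node labels permutes embeddings identically", {
  set.seed(26)
  n <- 6
  prot <- sprintf("P%d", 1:n)
  act <- toy_activity(prot, rep(list(1L), n))
  prs <- t(combn(prot, 2))
  prs <- prs[runif(nrow(prs)) < 0.5, , drop = FALSE]
  mh <- build_mhpin(edge_df(prs[, 1], prs[, 2]), act, NULL)
  pats <- build_patterns(mh)
  adj <- as.matrix(wide_domain_adjacency(pats, rep(0, pats$M)))
  h <- 4; d <- 3
  X <- matrix(rnorm(length(mh$proteins) * h), ncol = h,
              dimnames = list(mh$proteins, NULL))
  prm <- init_encoder_params(h, d)
  out <- encode_pattern(adj, mh, X, prm)

  perm <- sample(length(mh$proteins))
  mh2 <- mh
  mh2$proteins <- mh$proteins[perm]
  adj2 <- adj[perm, perm]
  out2 <- encode_pattern(adj2, mh2, X[perm, , drop = FALSE], prm)
  expect_equal(out2$Z_pattern, out$Z_pattern[perm, ], tolerance = 1e-10)
})
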