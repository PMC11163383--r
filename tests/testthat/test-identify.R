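embed_from <- function(vecs) {
  Z <- do.call(rbind, vecs)
  rownames(Z) <- names(vecs)
  Z
}

test_that("reweighting assigns cosine similarity on edges and zero elsewhere", {
  Z <- embed_from(list(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(1, 1)))
  pin <- edge_df(c("A", "A"), c("B", "C"))
  w <- reweight_pin(Z, pin)
  expect_equal(w$w["A", "B"], 1)           # identical embeddings
  expect_equal(w$w["A", "C"], 0)           # orthogonal embeddings
  expect_equal(w$w["A", "D"], 0)           # similar but not an edge
  expect_equal(as.matrix(w$w), t(as.matrix(w$w)))
  expect_error(reweight_pin(Z, edge_df("A", "Zmissing")), "Zmissing")
})

test_that("density score sums each unordered pair once", {
  n <- 4
  W <- matrix(0.5, n, n); diag(W) <- 0
  dimnames(W) <- list(LETTERS[1:n], LETTERS[1:n])
  expect_equal(density_score(c("A", "B", "C"), W), 1.5) # 3 pairs x 0.5
  W0 <- W * 0
  expect_equal(density_score(c("A", "B", "C"), W0), 0)
  # random cores <= 6 nodes vs brute-force pair enumeration
  set.seed(51)
  for (rep in 1:20) {
    m <- sample(3:6, 1)
    Wr <- matrix(runif(m * m, -1, 1), m); Wr <- (Wr + t(Wr)) / 2
    diag(Wr) <- 0
    ids <- sprintf("N%d", 1:m)
    dimnames(Wr) <- list(ids, ids)
    prs <- t(combn(ids, 2))
    oracle <- sum(apply(prs, 1, function(x) Wr[x[1], x[2]]))
    expect_equal(density_score(ids, Wr), oracle, tolerance = 1e-12)
  }
})

test_that("adhesion score is the mean edge weight into the core", {
  W <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  W["D", "A"] <- W["A", "D"] <- 0.6
  W["D", "B"] <- W["B", "D"] <- 0.6
  core <- c("A", "B", "C")
  expect_equal(adhesion_score("D", core, W), 0.4) # 1.2 / 3
  W2 <- W * 0
  expect_equal(adhesion_score("D", core, W2), 0)
  W3 <- matrix(1, 4, 4, dimnames = dimnames(W)); diag(W3) <- 0
  expect_equal(adhesion_score("D", core, W3), 1)
  expect_error(adhesion_score("A", core, W), "part of the core")
})

two_triangle_pin <- function(w_strong = 0.9, w_weak = 0.5) {
  # two vertex-disjoint triangles with different densities
  ids <- c("A", "B", "C", "D", "E", "F")
  W <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (pr in list(c("A", "B"), c("B", "C"), c("A", "C")))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- w_strong
  for (pr in list(c("D", "E"), c("E", "F"), c("D", "F")))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- w_weak
  W
}

test_that("two disjoint triangles are both extracted as cores, densest first", {
  W <- two_triangle_pin()
  act <- toy_activity(LETTERS[1:6], rep(list(1L), 6))
  cores <- mine_cores(W, act, NULL)
  expect_length(cores$cores, 2L)
  expect_setequal(cores$cores[[1]]$members, c("A", "B", "C"))
  expect_setequal(cores$cores[[2]]$members, c("D", "E", "F"))
  expect_equal(cores$cores[[1]]$d_s, 2.7)
  expect_equal(cores$cores[[2]]$d_s, 1.5)
})

test_that("a weaker candidate overlapping the seed in all but 2 nodes is deleted", {
  # clique ABCD (strong) and clique BCDE (weaker via lower weights on E):
  # after ABCD is seeded, BCDE \ ABCD = {E} has < 3 nodes -> deleted
  ids <- c("A", "B", "C", "D", "E")
  W <- matrix(0, 5, 5, dimnames = list(ids, ids))
  for (pr in combn(c("A", "B", "C", "D"), 2, simplify = FALSE))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- 0.9
  for (x in c("B", "C", "D"))
    W[x, "E"] <- W["E", x] <- 0.1
  act <- toy_activity(ids, rep(list(1L), 5))
  cores <- mine_cores(W, act, NULL)
  expect_length(cores$cores, 1L)
  expect_setequal(cores$cores[[1]]$members, c("A", "B", "C", "D"))
})

test_that("larger overlapping candidates survive as their non-overlapping remnant", {
  # strong triangle ABC; weaker clique on {C,D,E,F,G}: remnant {D,E,F,G}
  ids <- c("A", "B", "C", "D", "E", "F", "G")
  W <- matrix(0, 7, 7, dimnames = list(ids, ids))
  for (pr in combn(c("A", "B", "C"), 2, simplify = FALSE))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- 0.95
  for (pr in combn(c("C", "D", "E", "F", "G"), 2, simplify = FALSE))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- 0.2
  act <- toy_activity(ids, rep(list(1L), 7))
  cores <- mine_cores(W, act, NULL)
  expect_setequal(cores$cores[[1]]$members, c("A", "B", "C"))
  expect_true(any(vapply(cores$cores, function(co)
    setequal(co$members, c("D", "E", "F", "G")), logical(1))))
})

test_that("cliques without a shared time or compartment are excluded", {
  W <- two_triangle_pin()
  # first triangle shares time 1; second shares nothing
  act <- toy_activity(LETTERS[1:6],
                      list(1L, 1L, 1L, 2L, 3L, 4L))
  expect_message(cores <- mine_cores(W[4:6, 4:6], act, NULL), "no candidate")
  expect_length(cores$cores, 0L)
  cores2 <- mine_cores(W, act, NULL)
  expect_length(cores2$cores, 1L)
  expect_setequal(cores2$cores[[1]]$members, c("A", "B", "C"))
  # a shared compartment alone is also a valid witness
  loc <- stats::setNames(rep(list("vacuole"), 6), LETTERS[1:6])
  cores3 <- mine_cores(W, act, loc)
  expect_length(cores3$cores, 2L)
})

test_that("core mining is invariant to input edge order", {
  set.seed(52)
  n <- 10
  ids <- sprintf("P%02d", 1:n)
  W <- matrix(runif(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
  W[W < 0.4] <- 0
  dimnames(W) <- list(ids, ids)
  act <- toy_activity(ids, rep(list(1L), n))
  c1 <- mine_cores(W, act, NULL)
  perm <- sample(n)
  Wp <- W[perm, perm]
  c2 <- mine_cores(Wp, act, NULL)
  expect_equal(lapply(c1$cores, function(x) x$members),
               lapply(c2$cores, function(x) x$members))
})

test_that("attachment joins complexes only above the adhesion threshold", {
  # planted core ABC plus a satellite S with strong edges into it
  Z <- embed_from(list(A = c(1, 0.1), B = c(1, 0.15), C = c(1, 0.05),
                       S = c(1, 0.35), X = c(-1, 1)))
  pin <- edge_df(c("A", "B", "A", "S", "S", "X"),
                 c("B", "C", "C", "A", "B", "A"))
  act <- toy_activity(c("A", "B", "C", "S", "X"), rep(list(1L), 5))
  # lambda = 0.4: satellite's mean cosine into the core ~ 2/3 of ~1 > 0.4
  cx <- identify_complexes(Z, pin, act, NULL, lambda = 0.4)
  expect_length(cx, 1L)
  expect_setequal(cx$complexes[[1]], c("A", "B", "C", "S"))
  expect_setequal(cx$cores[[1]], c("A", "B", "C"))
  # lambda = 1: cosine <= 1 and the strict > bars every attachment
  cx1 <- identify_complexes(Z, pin, act, NULL, lambda = 1)
  expect_setequal(cx1$complexes[[1]], c("A", "B", "C"))
  # lambda = 0: one positive-weight edge into the core suffices
  cx0 <- identify_complexes(Z, pin, act, NULL, lambda = 0)
  expect_true("S" %in% cx0$complexes[[1]])
})

test_that("every output complex re-checks: core >= 3 and attachments above lambda", {
  set.seed(53)
  n <- 24
  ids <- sprintf("P%02d", 1:n)
  Z <- matrix(rnorm(n * 6), n, dimnames = list(ids, NULL))
  prs <- t(combn(ids, 2))
  prs <- prs[runif(nrow(prs)) < 0.25, , drop = FALSE]
  pin <- edge_df(prs[, 1], prs[, 2])
  act <- toy_activity(ids, rep(list(1L), n))
  lambda <- 0.2
  cx <- identify_complexes(Z, pin, act, NULL, lambda = lambda)
  if (length(cx) > 0L) {
    w <- reweight_pin(Z, pin)
    for (i in seq_along(cx$complexes)) {
      core <- cx$cores[[i]]
      expect_gte(length(core), 3L)
      for (p in setdiff(cx$complexes[[i]], core))
        expect_gt(adhesion_score(p, core, w), lambda)
    }
    keys <- vapply(cx$complexes, function(x) paste(sort(x), collapse = " "),
                   character(1))
    expect_false(any(duplicated(keys)))
  }
})
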