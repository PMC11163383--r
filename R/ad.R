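# Minimal eager reverse-mode automatic differentiation over dense matrices.
# Every op computes its value immediately and records a backward closure on
# the tape; backward() walks the tape in reverse (creation order is a valid
# topological order). Values are plain base-R matrices; scalars are 1x1.
# Gradients are checked against central finite differences in the tests.

ad_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- vector("list", 256L)
  ctx$n <- 0L
  ctx
}

ad_node <- function(ctx, value, back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$back <- back
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$tape)) length(ctx$tape) <- 2L * length(ctx$tape)
  ctx$tape[[ctx$n]] <- nd
  nd
}

ad_accum <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

ad_const <- function(ctx, v) ad_node(ctx, as.matrix(v))
ad_param <- ad_const # params are leaves too; their $g is read after backward

ad_backward <- function(ctx, loss) {
  stopifnot(length(loss$v) == 1L)
  loss$g <- matrix(1, 1, 1)
  for (i in rev(seq_len(ctx$n))) {
    nd <- ctx$tape[[i]]
    if (!is.null(nd$g) && !is.null(nd$back)) nd$back(nd$g)
  }
  invisible(NULL)
}

ad_matmul <- function(ctx, A, B) {
  v <- A$v %*% B$v
  ad_node(ctx, v, function(g) {
    ad_accum(A, g %*% t(B$v))
    ad_accum(B, t(A$v) %*% g)
  })
}

ad_t <- function(ctx, A)
  ad_node(ctx, t(A$v), function(g) ad_accum(A, t(g)))

ad_add <- function(ctx, A, B) {
  stopifnot(all(dim(A$v) == dim(B$v)))
  ad_node(ctx, A$v + B$v, function(g) { ad_accum(A, g); ad_accum(B, g) })
}

ad_sub <- function(ctx, A, B)
  ad_node(ctx, A$v - B$v, function(g) { ad_accum(A, g); ad_accum(B, -g) })

ad_mul <- function(ctx, A, B) {
  stopifnot(all(dim(A$v) == dim(B$v)))
  ad_node(ctx, A$v * B$v, function(g) {
    ad_accum(A, g * B$v)
    ad_accum(B, g * A$v)
  })
}

ad_scale <- function(ctx, A, s) # s plain numeric constant
  ad_node(ctx, A$v * s, function(g) ad_accum(A, g * s))

ad_addvec <- function(ctx, A, b) { # b is 1 x d, broadcast over rows of A
  stopifnot(ncol(A$v) == ncol(b$v), nrow(b$v) == 1L)
  ad_node(ctx, sweep(A$v, 2L, as.vector(b$v), `+`), function(g) {
    ad_accum(A, g)
    ad_accum(b, matrix(colSums(g), 1L))
  })
}

ad_rows <- function(ctx, A, idx) {
  ad_node(ctx, A$v[idx, , drop = FALSE], function(g) {
    acc <- matrix(0, nrow(A$v), ncol(A$v))
    rs <- rowsum(g, group = idx)
    acc[as.integer(rownames(rs)), ] <- rs
    ad_accum(A, acc)
  })
}

ad_scatter <- function(ctx, Vals, idx, n) { # scatter-add rows of Vals into n rows
  out <- matrix(0, n, ncol(Vals$v))
  rs <- rowsum(Vals$v, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  ad_node(ctx, out, function(g) ad_accum(Vals, g[idx, , drop = FALSE]))
}

ad_cbind <- function(ctx, A, B) {
  ka <- ncol(A$v)
  ad_node(ctx, cbind(A$v, B$v), function(g) {
    ad_accum(A, g[, seq_len(ka), drop = FALSE])
    ad_accum(B, g[, -seq_len(ka), drop = FALSE])
  })
}

ad_rowscale <- function(ctx, A, s) { # s is m x 1, scales rows
  sv <- as.vector(s$v)
  ad_node(ctx, A$v * sv, function(g) {
    ad_accum(A, g * sv)
    ad_accum(s, matrix(rowSums(g * A$v), ncol = 1L))
  })
}

ad_colscale <- function(ctx, A, s) { # s is d x 1, scales columns
  sv <- as.vector(s$v)
  ad_node(ctx, sweep(A$v, 2L, sv, `*`), function(g) {
    ad_accum(A, sweep(g, 2L, sv, `*`))
    ad_accum(s, matrix(colSums(g * A$v), ncol = 1L))
  })
}

ad_tanh <- function(ctx, A) {
  v <- tanh(A$v)
  ad_node(ctx, v, function(g) ad_accum(A, g * (1 - v^2)))
}

ad_elu <- function(ctx, A) {
  v <- A$v
  neg <- v < 0
  v[neg] <- exp(v[neg]) - 1
  ad_node(ctx, v, function(g) {
    d <- g
    d[neg] <- d[neg] * (v[neg] + 1)
    ad_accum(A, d)
  })
}

ad_leakyrelu <- function(ctx, A, slope = 0.2) {
  v <- A$v
  neg <- v < 0
  v[neg] <- slope * v[neg]
  ad_node(ctx, v, function(g) {
    d <- g
    d[neg] <- d[neg] * slope
    ad_accum(A, d)
  })
}

ad_sigmoid <- function(ctx, A) {
  v <- 1 / (1 + exp(-A$v))
  ad_node(ctx, v, function(g) ad_accum(A, g * v * (1 - v)))
}

ad_log <- function(ctx, A) {
  stopifnot(all(A$v > 0))
  ad_node(ctx, log(A$v), function(g) ad_accum(A, g / A$v))
}

ad_sum <- function(ctx, A)
  ad_node(ctx, matrix(sum(A$v), 1, 1),
          function(g) ad_accum(A, matrix(g[1L], nrow(A$v), ncol(A$v))))

ad_mean <- function(ctx, A) {
  n <- length(A$v)
  ad_node(ctx, matrix(mean(A$v), 1, 1),
          function(g) ad_accum(A, matrix(g[1L] / n, nrow(A$v), ncol(A$v))))
}

ad_softmax <- function(ctx, x) { # x is K x 1
  v <- matrix(softmax(as.vector(x$v)), ncol = 1L)
  ad_node(ctx, v, function(g) {
    ad_accum(x, v * (g - sum(g * v)))
  })
}

ad_segment_softmax <- function(ctx, x, groups) { # x is E x 1
  xv <- as.vector(x$v)
  gm <- vapply(split(xv, groups), max, numeric(1))
  gidx <- match(as.character(groups), names(gm))
  ex <- exp(xv - gm[gidx])
  den <- rowsum(ex, group = groups)
  didx <- match(as.character(groups), rownames(den))
  v <- matrix(ex / den[didx], ncol = 1L)
  ad_node(ctx, v, function(g) {
    s <- rowsum(as.vector(g) * as.vector(v), group = groups)
    ad_accum(x, v * (g - matrix(s[didx], ncol = 1L)))
  })
}

ad_rownorm <- function(ctx, A, tol = 1e-12) {
  nrm <- sqrt(rowSums(A$v^2))
  safe <- ifelse(nrm > tol, nrm, 1)
  v <- A$v / safe
  v[nrm <= tol, ] <- 0
  ad_node(ctx, v, function(g) {
    dot <- rowSums(g * v)
    dx <- (g - dot * v) / safe
    dx[nrm <= tol, ] <- 0
    ad_accum(A, dx)
  })
}

ad_row_logsumexp <- function(ctx, S) {
  m <- apply(S$v, 1L, max)
  lse <- m + log(rowSums(exp(S$v - m)))
  v <- matrix(lse, ncol = 1L)
  ad_node(ctx, v, function(g) {
    ad_accum(S, as.vector(g) * exp(S$v - lse))
  })
}

ad_diag <- function(ctx, S)
  ad_node(ctx, matrix(diag(S$v), ncol = 1L), function(g) {
    acc <- matrix(0, nrow(S$v), ncol(S$v))
    diag(acc) <- as.vector(g)
    ad_accum(S, acc)
  })

ad_get <- function(ctx, x, i)
  ad_node(ctx, matrix(x$v[i, 1L], 1, 1), function(g) {
    acc <- matrix(0, nrow(x$v), 1L)
    acc[i, 1L] <- g[1L]
    ad_accum(x, acc)
  })

ad_vstack <- function(ctx, scalars) {
  ad_node(ctx, matrix(vapply(scalars, function(s) s$v[1L], numeric(1)),
                      ncol = 1L),
          function(g) for (k in seq_along(scalars))
            ad_accum(scalars[[k]], matrix(g[k, 1L], 1, 1)))
}

ad_scalmul <- function(ctx, s, A) { # s is 1x1 node
  sv <- s$v[1L]
  ad_node(ctx, sv * A$v, function(g) {
    ad_accum(s, matrix(sum(g * A$v), 1, 1))
    ad_accum(A, sv * g)
  })
}

ad_gather_elems <- function(ctx, A, ij) { # ij: E x 2 index matrix, unique pairs
  ad_node(ctx, matrix(A$v[ij], ncol = 1L), function(g) {
    acc <- matrix(0, nrow(A$v), ncol(A$v))
    acc[ij] <- as.vector(g)
    ad_accum(A, acc)
  })
}

ad_invsqrt_guard <- function(ctx, r, tol = 1e-12) { # r: n x 1, >= 0
  rv <- as.vector(r$v)
  v <- matrix(ifelse(rv > tol, 1 / sqrt(pmax(rv, tol)), 0), ncol = 1L)
  ad_node(ctx, v, function(g) {
    dr <- ifelse(rv > tol, -0.5 * pmax(rv, tol)^(-1.5), 0)
    ad_accum(r, g * matrix(dr, ncol = 1L))
  })
}

# InfoNCE-style contrastive loss node over cosine similarities; zero-norm
# rows contribute a flat (zero-gradient) term rather than erroring, which is
# what training needs for isolated nodes. The exported loss functions in
# train.R enforce the strict nonzero-norm contract.
ad_infonce <- function(ctx, Za, Zb, tau) {
  Zan <- ad_rownorm(ctx, Za)
  Zbn <- ad_rownorm(ctx, Zb)
  S <- ad_scale(ctx, ad_matmul(ctx, Zan, ad_t(ctx, Zbn)), 1 / tau)
  lse <- ad_row_logsumexp(ctx, S)
  dg <- ad_diag(ctx, S)
  ad_sum(ctx, ad_sub(ctx, lse, dg))
}
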