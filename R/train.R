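infonce_value <- function(Za, Zb, tau, label) {
  stopifnot(all(dim(Za) == dim(Zb)))
  if (tau <= 0) stop("temperature must be > 0")
  na <- sqrt(rowSums(Za^2)); nb <- sqrt(rowSums(Zb^2))
  if (any(na == 0) || any(nb == 0))
    stop(label, ": zero-norm embedding row, cosine similarity undefined")
  S <- (Za / na) %*% t(Zb / nb) / tau
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  sum(lse - diag(as.matrix(S)))
}

#' Inter-view contrastive loss
#'
#' InfoNCE loss between the first-order-neighbor and meta-path view
#' embeddings of the same aggregator. For each protein the positive pair is
#' the same protein in the other view; the denominator runs over all
#' proteins of the other view (the positive included). Similarity is cosine,
#' scaled by the temperature.
#'
#' @param Z_a,Z_b n x d embedding matrices (same shape)
#' @param tau temperature, `> 0` (default 0.5)
#' @return scalar loss (0 for a single protein; `n log n` when all rows are
#'   identical)
#' @export
view_contrast_loss <- function(Z_a, Z_b, tau = 0.5)
  infonce_value(Z_a, Z_b, tau, "view_contrast_loss")

#' Inter-pattern contrastive loss
#'
#' Same contract as [view_contrast_loss()], applied between the wide-domain
#' and deep-domain pattern embeddings.
#'
#' @inheritParams view_contrast_loss
#' @export
pattern_contrast_loss <- function(Z_a, Z_b, tau = 0.5)
  infonce_value(Z_a, Z_b, tau, "pattern_contrast_loss")

adam_step <- function(theta, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    theta[[nm]] <- theta[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(theta = theta, state = state)
}

# One full forward pass; returns loss node and embedding nodes.
# wide_fix: precomputed fixed topology pieces; deep topology is rebuilt from
# the current epsilon (the adjacency sits inside the differentiable graph).
joint_forward <- function(ctx, theta, consts, cfg, dropout_mask = NULL) {
  nP <- consts$nP
  Xn <- ad_param(ctx, theta$X)
  if (!is.null(dropout_mask))
    Xn <- ad_mul(ctx, Xn, ad_const(ctx, dropout_mask))
  X_P <- ad_rows(ctx, Xn, seq_len(nP))
  X_R <- if (consts$nR > 0L)
    ad_rows(ctx, Xn, nP + seq_len(consts$nR))

  # wide-domain adjacency: softmax(alpha)-weighted pattern sum on the fixed
  # union support
  alpha_n <- ad_param(ctx, theta$alpha)
  alpha_s <- ad_softmax(ctx, alpha_n)
  topo_w <- consts$topo_wide
  if (nrow(consts$memb) > 0L)
    topo_w$pe_w <- ad_matmul(ctx, ad_const(ctx, consts$memb), alpha_s)

  # deep-domain adjacency from degree profiles and sigmoid(epsilon)
  eps_n <- ad_param(ctx, theta$eps)
  eps_s <- ad_sigmoid(ctx, eps_n)
  Dw <- ad_colscale(ctx, ad_const(ctx, consts$D), eps_s)
  S <- ad_matmul(ctx, Dw, ad_t(ctx, Dw))
  S0 <- ad_mul(ctx, S, ad_const(ctx, consts$offdiag))
  r <- ad_matmul(ctx, S0, ad_const(ctx, matrix(1, nP, 1L)))
  sc <- ad_invsqrt_guard(ctx, r)
  Adeep <- ad_mul(ctx, S0, ad_matmul(ctx, sc, ad_t(ctx, sc)))

  Asp <- sparsify_topk(Adeep$v, cfg$topk)
  topo_d <- enc_topology(Asp, consts$proteins, consts$rnas, consts$rna_edges)
  topo_d$N_prp <- consts$topo_wide$N_prp # shared-RNA graph is topology-fixed
  if (nrow(topo_d$nz) > 0L)
    topo_d$pe_w <- ad_gather_elems(ctx, Adeep, topo_d$nz)

  prm_w <- lapply(theta[grep("^wide\\.", names(theta))],
                  function(p) ad_param(ctx, p))
  names(prm_w) <- sub("^wide\\.", "", names(prm_w))
  prm_d <- lapply(theta[grep("^deep\\.", names(theta))],
                  function(p) ad_param(ctx, p))
  names(prm_d) <- sub("^deep\\.", "", names(prm_d))

  ew <- enc_forward(ctx, X_P, X_R, prm_w, topo_w, cfg$slope)
  ed <- enc_forward(ctx, X_P, X_R, prm_d, topo_d, cfg$slope)

  loss <- ad_add(ctx,
    ad_add(ctx,
      ad_infonce(ctx, ew$Z_stra, ew$Z_mp, cfg$tau_stru),
      ad_infonce(ctx, ed$Z_stra, ed$Z_mp, cfg$tau_stru)),
    ad_infonce(ctx, ew$Z_pat, ed$Z_pat, cfg$tau_pat))

  list(loss = loss, Zw = ew$Z_pat, Zd = ed$Z_pat,
       params = c(list(X = Xn, alpha = alpha_n, eps = eps_n),
                  stats::setNames(prm_w, paste0("wide.", names(prm_w))),
                  stats::setNames(prm_d, paste0("deep.", names(prm_d)))))
}

#' Train protein embeddings on the multiplex heterogeneous network
#'
#' Jointly optimizes the pattern weights (alpha, epsilon), the learnable
#' node features and both dual-view aggregators by Adam gradient descent on
#' the joint contrastive objective: one inter-view loss per aggregator
#' (first-order vs meta-path view) plus the inter-pattern loss (wide vs deep
#' embedding). Both adjacencies are rebuilt from the current weights at
#' every step. Returns the final embedding
#' `Z = (Z_wide + Z_deep) / 2`, computed without dropout.
#'
#' @param mhpin an `mhpin` from [build_mhpin()]
#' @param patterns a `pattern_stack` from [build_patterns()]
#' @param d embedding dimension (default 128)
#' @param h input feature dimension of the learnable node features
#' @param tau_stru,tau_pat contrastive temperatures
#' @param lr Adam learning rate
#' @param epochs maximum training epochs
#' @param patience early-stop patience: training stops when the best loss
#'   has not improved by more than `tol` for this many epochs
#' @param tol minimum loss improvement counted as progress
#' @param dropout feature dropout rate during training
#' @param topk neighbors kept per row when sparsifying the dense deep-domain
#'   adjacency
#' @param slope LeakyReLU negative slope in the attention logits
#' @param seed RNG seed fixing initialization and dropout; a fixed seed
#'   makes the run exactly reproducible
#' @param verbose print the loss every 25 epochs
#' @return object of class `final_embedding`: `Z`, `Z_wide`, `Z_deep`
#'   (rownames = proteins), `loss_history`, `alpha`, `epsilon`, `config`
#' @export
train_embeddings <- function(mhpin, patterns, d = 128, h = 64,
                             tau_stru = 0.5, tau_pat = 0.5, lr = 5e-3,
                             epochs = 400, patience = 50, tol = 1e-4,
                             dropout = 0.3, topk = 10, slope = 0.2,
                             seed = 1, verbose = FALSE) {
  stopifnot(inherits(mhpin, "mhpin"), inherits(patterns, "pattern_stack"))
  if (patterns$M == 0L) stop("empty pattern stack: nothing to train on")
  stopifnot(identical(mhpin$proteins, patterns$proteins))
  cfg <- list(d = d, h = h, tau_stru = tau_stru, tau_pat = tau_pat, lr = lr,
              epochs = epochs, patience = patience, tol = tol,
              dropout = dropout, topk = topk, slope = slope, seed = seed)
  set.seed(seed)
  proteins <- mhpin$proteins
  rnas <- mhpin$rnas
  nP <- length(proteins); nR <- length(rnas)

  # fixed pieces: union support of the wide adjacency with per-pattern
  # membership, degree profiles, wide/meta-path topologies
  union_adj <- Reduce(`+`, patterns$mats)
  nzw <- which(as.matrix(union_adj) > 0, arr.ind = TRUE)
  memb <- if (nrow(nzw) > 0L)
    vapply(patterns$mats, function(m) as.matrix(m)[nzw], numeric(nrow(nzw)))
  else matrix(0, 0L, patterns$M)
  memb <- matrix(memb, nrow = nrow(nzw))
  topo_wide <- enc_topology(union_adj, proteins, rnas, mhpin$rna_edges)
  consts <- list(nP = nP, nR = nR, proteins = proteins, rnas = rnas,
                 rna_edges = mhpin$rna_edges, memb = memb,
                 topo_wide = topo_wide, D = degree_profile(patterns),
                 offdiag = 1 - diag(nP))

  pw <- init_encoder_params(h, d)
  pd <- init_encoder_params(h, d)
  theta <- c(list(X = glorot(nP + nR, h),
                  alpha = matrix(0, patterns$M, 1L),
                  eps = matrix(0, patterns$M, 1L)),
             stats::setNames(pw, paste0("wide.", names(pw))),
             stats::setNames(pd, paste0("deep.", names(pd))))

  state <- list(t = 0L,
                m = lapply(theta, function(p) p * 0),
                v = lapply(theta, function(p) p * 0))
  history <- numeric(0)
  best <- Inf; wait <- 0L
  for (ep in seq_len(epochs)) {
    mask <- NULL
    if (dropout > 0) {
      keep <- matrix(stats::rbinom((nP + nR) * h, 1L, 1 - dropout),
                     nP + nR, h)
      mask <- keep / (1 - dropout)
    }
    ctx <- ad_ctx()
    fw <- joint_forward(ctx, theta, consts, cfg, mask)
    lv <- fw$loss$v[1L]
    if (!is.finite(lv))
      stop(sprintf("training diverged at epoch %d (loss = %g); ",
                   ep, lv),
           "try a smaller learning rate or temperature")
    history <- c(history, lv)
    ad_backward(ctx, fw$loss)
    grads <- lapply(fw$params, function(nd) nd$g)
    upd <- adam_step(theta, grads, state, lr)
    theta <- upd$theta; state <- upd$state
    if (verbose && ep %% 25L == 0L)
      message(sprintf("epoch %4d  loss %.4f", ep, lv))
    if (lv < best - tol) { best <- lv; wait <- 0L } else wait <- wait + 1L
    if (wait >= patience) break
  }

  ctx <- ad_ctx()
  fw <- joint_forward(ctx, theta, consts, cfg, NULL)
  Zw <- fw$Zw$v; Zd <- fw$Zd$v
  Z <- 0.5 * (Zw + Zd)
  rownames(Z) <- rownames(Zw) <- rownames(Zd) <- proteins
  structure(list(Z = Z, Z_wide = Zw, Z_deep = Zd,
                 loss_history = history, epochs_run = length(history),
                 alpha = softmax(as.vector(theta$alpha)),
                 epsilon = sigmoid(as.vector(theta$eps)),
                 config = cfg),
            class = "final_embedding")
}

#' @export
print.final_embedding <- function(x, ...) {
  cat(sprintf(
    "final_embedding: %d proteins x %d dims; %d epochs, loss %.4f -> %.4f\n",
    nrow(x$Z), ncol(x$Z), x$epochs_run,
    x$loss_history[1L], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Write embeddings as a TSV table
#'
#' @param embedding a `final_embedding` (or plain matrix with rownames)
#' @param path output path; columns `protein`, `v1` ... `vd`
#' @export
write_embeddings <- function(embedding, path) {
  Z <- if (inherits(embedding, "final_embedding")) embedding$Z else embedding
  df <- data.frame(protein = rownames(Z), Z, check.names = FALSE)
  colnames(df) <- c("protein", paste0("v", seq_len(ncol(Z))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
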