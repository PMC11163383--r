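#' Run the full identification pipeline
#'
#' Build -> embed -> identify (-> evaluate): computes activity profiles,
#' selects RNA partners, constructs the multiplex heterogeneous network and
#' its spatiotemporal pattern stack, trains the contrastive dual-view
#' embeddings, reweights the network and mines core-attachment complexes.
#' If a gold-standard set is supplied the predictions are scored against it.
#'
#' @param tables list with `ppi` (edge data.frame), `expression` (matrix or
#'   `NULL`), `localization` (named list or localization data.frame), and
#'   `rna_assoc` (data.frame or `NULL`) — either from [read_tables()] or a
#'   `sim_bundle`
#' @param gold optional [complex_set] to evaluate against
#' @param k activity threshold multiplier (default 1)
#' @param lambda attachment threshold (default 0.4)
#' @param filter apply the spatiotemporal edge filter (set `FALSE` for
#'   ablation runs that accept every edge)
#' @param omega match threshold for evaluation
#' @param ... further arguments to [train_embeddings()] (`d`, `epochs`,
#'   `seed`, ...)
#' @return list: `mhpin`, `patterns`, `embedding`, `complexes`, `activity`,
#'   and `metrics` when `gold` was given
#' @export
run_pipeline <- function(tables, gold = NULL, k = 1, lambda = 0.4,
                         filter = TRUE, omega = 0.25, ...) {
  loc <- tables$localization
  if (is.data.frame(loc))
    loc <- lapply(split(loc$compartment, loc$protein), unique)
  act <- if (!is.null(tables$expression))
    compute_activity(tables$expression, k = k)
  rna <- if (!is.null(tables$rna_assoc))
    select_rna_partners(tables$rna_assoc)
  mh <- build_mhpin(tables$ppi, act, loc, rna, filter = filter)
  pats <- build_patterns(mh)
  emb <- train_embeddings(mh, pats, ...)
  cx <- identify_complexes(emb, mh$edges, act, loc, lambda = lambda)
  out <- list(mhpin = mh, patterns = pats, embedding = emb, complexes = cx,
              activity = act)
  if (!is.null(gold) && length(cx$complexes) > 0L)
    out$metrics <- evaluate_complexes(cx, gold, omega = omega)
  out
}
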