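#' Neighborhood affinity between two complexes
#'
#' \eqn{NA(p, b) = |V_p \cap V_b|^2 / (|V_p| \times |V_b|)}: 1 iff the two
#' protein sets are equal, 0 iff disjoint, symmetric in its arguments.
#'
#' @param p,b nonempty character vectors of protein IDs
#' @return affinity in `[0, 1]`
#' @export
na_score <- function(p, b) {
  p <- unique(p); b <- unique(b)
  if (length(p) == 0L || length(b) == 0L)
    stop("na_score: complexes must be nonempty")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

na_matrix <- function(P, B) {
  outer(seq_along(P), seq_along(B),
        Vectorize(function(i, j) na_score(P[[i]], B[[j]])))
}

overlap_matrix <- function(P, B) {
  outer(seq_along(P), seq_along(B),
        Vectorize(function(i, j) length(intersect(P[[i]], B[[j]]))))
}

as_complex_list <- function(x) {
  if (inherits(x, "complex_set")) x$complexes else x
}

#' Precision, recall and F-score of identified complexes
#'
#' A predicted complex counts as matched if its neighborhood affinity with
#' some gold-standard complex reaches `omega` (`NA >= omega`, default 0.25),
#' and symmetrically for gold complexes. Precision = matched predictions /
#' predictions; recall = matched gold complexes / gold complexes; F is their
#' harmonic mean (0 when both are 0).
#'
#' @param P identified complexes ([complex_set] or list of ID vectors)
#' @param B gold-standard complexes
#' @param omega match threshold (default 0.25)
#' @return list: `n_cp`, `n_cb`, `precision`, `recall`, `f_score`, `na`
#'   (the all-pairs affinity matrix)
#' @export
precision_recall_f <- function(P, B, omega = 0.25) {
  P <- as_complex_list(P); B <- as_complex_list(B)
  stopifnot(length(P) >= 1L, length(B) >= 1L)
  na <- na_matrix(P, B)
  n_cp <- sum(apply(na >= omega, 1L, any))
  n_cb <- sum(apply(na >= omega, 2L, any))
  precision <- n_cp / length(P)
  recall <- n_cb / length(B)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(n_cp = n_cp, n_cb = n_cb, precision = precision, recall = recall,
       f_score = f, na = na)
}

#' Clustering sensitivity, positive predictive value and accuracy
#'
#' Computed from the complex-complex overlap matrix `T[b, p] = |b `
#' intersect ` p|`: Sn sums the best prediction overlap per gold complex
#' over total gold proteins; PPV sums the best gold overlap per prediction
#' over all overlaps; Acc is their geometric mean. A zero PPV denominator
#' (no overlap anywhere) yields PPV = 0.
#'
#' @inheritParams precision_recall_f
#' @return list: `sn`, `ppv`, `acc`
#' @export
sn_ppv_acc <- function(P, B) {
  P <- as_complex_list(P); B <- as_complex_list(B)
  stopifnot(length(P) >= 1L, length(B) >= 1L)
  Tm <- t(overlap_matrix(P, B)) # rows = gold b, cols = predicted p
  sn <- sum(apply(Tm, 1L, max)) / sum(lengths(lapply(B, unique)))
  den <- sum(Tm)
  ppv <- if (den == 0) 0 else sum(apply(Tm, 2L, max)) / den
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Full evaluation report
#'
#' Combines [precision_recall_f()] and [sn_ppv_acc()] and reports the
#' composite score `f_score + acc` used to rank methods on both overarching
#' criteria at once.
#'
#' @inheritParams precision_recall_f
#' @return list with all metric fields plus `composite`
#' @export
evaluate_complexes <- function(P, B, omega = 0.25) {
  a <- precision_recall_f(P, B, omega)
  b <- sn_ppv_acc(P, B)
  c(a[c("n_cp", "n_cb", "precision", "recall", "f_score")], b,
    list(composite = a$f_score + b$acc, omega = omega))
}

#' Hypergeometric enrichment P-value of a complex in a functional group
#'
#' Upper-tail probability that a complex of `complex_size` proteins drawn
#' from a universe of `universe` proteins contains at least `overlap`
#' members of a functional group of `group_size`:
#' \deqn{P = 1 - \sum_{i=0}^{k-1} \binom{|F|}{i}\binom{|V|-|F|}{|p|-i} /
#' \binom{|V|}{|p|}.}
#' Values below the conventional 0.01 cutoff are considered biologically
#' significant. Evaluated in log space via the hypergeometric distribution
#' for numerical stability.
#'
#' @param complex_size number of proteins in the complex (`|p|`)
#' @param group_size number of proteins annotated to the group (`|F|`)
#' @param overlap observed number of complex proteins in the group (`k`)
#' @param universe total number of proteins in the network (`|V|`)
#' @return P-value in `[0, 1]` (1 when `overlap = 0`)
#' @export
enrichment_pvalue <- function(complex_size, group_size, overlap, universe) {
  if (overlap > min(complex_size, group_size) || group_size > universe ||
      complex_size > universe || overlap < 0)
    stop("inconsistent counts for enrichment_pvalue")
  stats::phyper(overlap - 1, group_size, universe - group_size,
                complex_size, lower.tail = FALSE)
}

#' Mismatch count between an identified and a gold-standard complex
#'
#' The larger of (proteins identified but absent from the gold complex) and
#' (gold proteins missed by the identification):
#' `max(|I \ G|, |G \ I|)`. This convention is an inference from worked
#' matching examples, not a published definition; it is the unique simple
#' rule consistent with all of them.
#'
#' @param identified,gold nonempty character vectors of protein IDs
#' @return nonnegative integer
#' @export
mismatch_count <- function(identified, gold) {
  identified <- unique(identified); gold <- unique(gold)
  stopifnot(length(identified) > 0L, length(gold) > 0L)
  max(length(setdiff(identified, gold)), length(setdiff(gold, identified)))
}

#' Worked matching examples
#'
#' Loads the bundled worked examples of matched-but-not-identical complexes:
#' three curated yeast gold-standard complexes (the glucose-induced
#' degradation complex among them), each paired with three method
#' identifications, together with the published mismatch counts they should
#' reproduce under [mismatch_count()].
#'
#' @return data.frame with columns `gold_id`, `set`, `mismatch` (NA for the
#'   gold rows) and a list-column `members`
#' @export
matched_examples <- function() {
  path <- system.file("extdata", "matched_complex_examples.tsv",
                      package = "stcomplex", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$members <- strsplit(df$members, " ", fixed = TRUE)
  df$mismatch <- suppressWarnings(as.integer(df$mismatch))
  df
}
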