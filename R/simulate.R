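yeast_compartments <- c(
  "extracellular_space", "nucleus", "mitochondrion", "endosome", "vacuole",
  "peroxisome", "endoplasmic_reticulum", "golgi_apparatus", "cytosol",
  "cytoskeleton", "plasma_membrane")

#' Default synthetic benchmark configuration
#'
#' Study conditions mirroring a yeast-scale setting at desk size: 12
#' metabolic-cycle time points, the 11 canonical subcellular compartments,
#' planted core-attachment complexes whose members share an active
#' expression window and a home compartment, regulator RNAs per complex
#' linked with high association scores, and sparse background noise edges.
#'
#' @param n_proteins,n_complexes network and truth sizes
#' @param core_size_range,attachment_range per-complex core and attachment
#'   count ranges (inclusive)
#' @param p_core within-core edge probability
#' @param p_background background edge probability between any pair not
#'   already connected
#' @param T number of expression time points
#' @param n_compartments number of compartments (first `n` of the canonical
#'   vocabulary)
#' @param window active-window length per complex (time points)
#' @param baseline,amplitude,noise_sd expression model: active-window values
#'   are `baseline + amplitude + noise`, off-window `baseline + noise`
#' @param n_rnas,rnas_per_complex RNA pool and per-complex regulator count
#' @param seed RNG seed fixing every random draw
#' @return named list (class `sim_config`)
#' @export
sim_config <- function(n_proteins = 300, n_complexes = 20,
                       core_size_range = c(3, 6), attachment_range = c(0, 3),
                       p_core = 0.9, p_background = 0.02, T = 12,
                       n_compartments = 11, window = 4, baseline = 5,
                       amplitude = 3, noise_sd = 0.3, n_rnas = 60,
                       rnas_per_complex = 2, seed = 42) {
  cfg <- as.list(environment())
  stopifnot(cfg$p_core >= 0, cfg$p_core <= 1,
            cfg$p_background >= 0, cfg$p_background <= 1,
            cfg$core_size_range[1] >= 3,
            cfg$window >= 1, cfg$window <= cfg$T,
            cfg$n_compartments >= 1,
            cfg$n_compartments <= length(yeast_compartments))
  if (cfg$core_size_range[2] + cfg$attachment_range[2] > cfg$n_proteins)
    stop("infeasible config: complexes larger than the protein pool")
  if (cfg$n_complexes * (cfg$core_size_range[2] + cfg$attachment_range[2]) >
      cfg$n_proteins)
    stop("infeasible config: not enough proteins for disjoint complexes")
  structure(cfg, class = "sim_config")
}

rand_int <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}

#' Generate a seeded synthetic benchmark with planted complexes
#'
#' Plants `n_complexes` disjoint core-attachment complexes: cores are dense
#' subgraphs (edge probability `p_core`), each attachment connects to at
#' least half of the core; complex members share an active time window
#' (expression raised by `amplitude` inside it) and a common home
#' compartment; each complex gets regulator RNAs linked to its members with
#' high scores plus low-score decoy associations so partner selection is
#' informative. Background proteins follow their own random expression
#' windows and compartments, and background edges are added at
#' `p_background`. All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list (class `sim_bundle`): `ppi`, `expression`, `localization`
#'   (data.frame form), `rna_assoc`, `truth` (a [complex_set] with cores),
#'   `config`
#' @export
generate_benchmark <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  compartments <- yeast_compartments[seq_len(cfg$n_compartments)]
  pool <- sample(proteins)
  nxt <- 1L
  take <- function(n) {
    out <- pool[nxt:(nxt + n - 1L)]
    nxt <<- nxt + n
    out
  }

  truth <- list(); cores <- list()
  edges_a <- character(0); edges_b <- character(0)
  home <- character(0); windows <- list(); members_all <- character(0)
  loc_p <- character(0); loc_c <- character(0)
  complex_rnas <- list()
  rnas <- sprintf("R%03d", seq_len(cfg$n_rnas))
  rna_pool <- sample(rnas)

  for (ci in seq_len(cfg$n_complexes)) {
    core_n <- rand_int(cfg$core_size_range[1], cfg$core_size_range[2])
    att_n <- rand_int(cfg$attachment_range[1], cfg$attachment_range[2])
    core <- take(core_n)
    atts <- if (att_n > 0) take(att_n) else character(0)
    members <- c(core, atts)
    truth[[ci]] <- members; cores[[ci]] <- core
    members_all <- c(members_all, members)
    # dense core
    prs <- utils::combn(core, 2L)
    keep <- stats::runif(ncol(prs)) < cfg$p_core
    edges_a <- c(edges_a, prs[1L, keep]); edges_b <- c(edges_b, prs[2L, keep])
    # attachments wired to at least half the core
    for (a in atts) {
      k <- rand_int(ceiling(core_n / 2), core_n)
      tgt <- sample(core, k)
      edges_a <- c(edges_a, rep(a, k)); edges_b <- c(edges_b, tgt)
    }
    # shared compartment and active window
    hc <- sample(compartments, 1L)
    loc_p <- c(loc_p, members); loc_c <- c(loc_c, rep(hc, length(members)))
    w0 <- rand_int(1L, cfg$T - cfg$window + 1L)
    for (mb in members) windows[[mb]] <- w0:(w0 + cfg$window - 1L)
    complex_rnas[[ci]] <- rna_pool[((ci - 1L) * cfg$rnas_per_complex) %%
                                     cfg$n_rnas + seq_len(cfg$rnas_per_complex)]
  }

  background <- setdiff(proteins, members_all)
  for (bp in background) {
    w0 <- rand_int(1L, cfg$T - cfg$window + 1L)
    windows[[bp]] <- w0:(w0 + cfg$window - 1L)
    nc <- rand_int(1L, 2L)
    loc_p <- c(loc_p, rep(bp, nc))
    loc_c <- c(loc_c, sample(compartments, nc))
  }
  # occasional secondary compartment for complex members
  extra <- members_all[stats::runif(length(members_all)) < 0.3]
  if (length(extra)) {
    loc_p <- c(loc_p, extra)
    loc_c <- c(loc_c, sample(compartments, length(extra), replace = TRUE))
  }

  # background edges over pairs not already present
  key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  existing <- unique(key(edges_a, edges_b))
  n_bg <- stats::rbinom(1L, choose(cfg$n_proteins, 2L) - length(existing),
                        cfg$p_background)
  if (n_bg > 0) {
    got <- character(0); tries <- 0L
    while (length(got) < n_bg && tries < 50L) {
      a <- sample(proteins, n_bg, replace = TRUE)
      b <- sample(proteins, n_bg, replace = TRUE)
      ok <- a != b & !(key(a, b) %in% c(existing, got))
      new <- unique(key(a, b)[ok])
      pick <- utils::head(new, n_bg - length(got))
      got <- c(got, pick)
      tries <- tries + 1L
    }
    sp <- strsplit(got, " ", fixed = TRUE)
    edges_a <- c(edges_a, vapply(sp, `[`, character(1), 1L))
    edges_b <- c(edges_b, vapply(sp, `[`, character(1), 2L))
  }

  # expression: baseline + window amplitude + noise
  expr <- matrix(cfg$baseline, cfg$n_proteins, cfg$T,
                 dimnames = list(proteins, paste0("t", seq_len(cfg$T))))
  for (p in proteins) expr[p, windows[[p]]] <- expr[p, windows[[p]]] +
    cfg$amplitude
  expr <- expr + matrix(stats::rnorm(length(expr), sd = cfg$noise_sd),
                        nrow(expr), ncol(expr))

  # RNA associations: per-complex regulators with high scores; per-protein
  # decoys with low scores so each protein's own mean is informative
  ra_rna <- character(0); ra_prot <- character(0); ra_score <- numeric(0)
  for (ci in seq_len(cfg$n_complexes)) {
    for (rn in complex_rnas[[ci]]) {
      mb <- truth[[ci]]
      ra_rna <- c(ra_rna, rep(rn, length(mb)))
      ra_prot <- c(ra_prot, mb)
      ra_score <- c(ra_score, stats::runif(length(mb), 0.7, 0.95))
    }
  }
  for (p in proteins) {
    dec <- sample(rnas, 3L)
    ra_rna <- c(ra_rna, dec)
    ra_prot <- c(ra_prot, rep(p, 3L))
    ra_score <- c(ra_score, stats::runif(3L, 0.05, 0.3))
  }
  rk <- paste(ra_rna, ra_prot)
  keep <- !duplicated(rk)

  structure(list(
    ppi = data.frame(protein_a = edges_a, protein_b = edges_b,
                     stringsAsFactors = FALSE),
    expression = expr,
    localization = data.frame(protein = loc_p, compartment = loc_c,
                              stringsAsFactors = FALSE),
    rna_assoc = data.frame(rna = ra_rna[keep], protein = ra_prot[keep],
                           score = ra_score[keep], stringsAsFactors = FALSE),
    truth = complex_set(truth, cores = cores),
    config = cfg), class = "sim_bundle")
}

#' Write a synthetic bundle to the on-disk input formats
#'
#' Emits `ppi.tsv`, `expression.tsv`, `localization.tsv`, `rna_assoc.tsv`
#' and `truth_complexes.txt` into a directory, in the exact dialects the
#' readers expect.
#'
#' @param bundle a `sim_bundle` from [generate_benchmark()]
#' @param dir output directory (created if absent)
#' @return named vector of file paths, invisibly
#' @export
write_benchmark <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(bundle$ppi, "ppi.tsv")
  edf <- data.frame(protein = rownames(bundle$expression),
                    bundle$expression, check.names = FALSE)
  wt(edf, "expression.tsv")
  wt(bundle$localization, "localization.tsv")
  wt(data.frame(rna = bundle$rna_assoc$rna,
                protein = bundle$rna_assoc$protein,
                score = format(bundle$rna_assoc$score, digits = 15)),
     "rna_assoc.tsv")
  write_complexes(bundle$truth, p("truth_complexes.txt"))
  invisible(c(ppi = p("ppi.tsv"), expression = p("expression.tsv"),
              localization = p("localization.tsv"),
              rna_assoc = p("rna_assoc.tsv"),
              truth = p("truth_complexes.txt")))
}

#' Summarize a synthetic bundle against its own ground truth
#'
#' Reports the realized within-core edge density, the fraction of edges
#' falling inside planted complexes, and the fraction of within-core edges
#' that survive the spatiotemporal co-activity/co-location filter when run
#' through the real pipeline front end.
#'
#' @param bundle a `sim_bundle`
#' @param k activity threshold multiplier used for the survival check
#' @return list of summary statistics
#' @export
summarize_truth <- function(bundle, k = 1) {
  stopifnot(inherits(bundle, "sim_bundle"))
  cores <- bundle$truth$cores
  members <- bundle$truth$complexes
  key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  ek <- key(bundle$ppi$protein_a, bundle$ppi$protein_b)
  core_pairs <- unlist(lapply(cores, function(co)
    apply(utils::combn(co, 2L), 2L, function(x) key(x[1], x[2]))))
  within_core_density <- mean(core_pairs %in% ek)
  in_complex <- unlist(lapply(members, function(mb) {
    prs <- utils::combn(mb, 2L)
    key(prs[1L, ], prs[2L, ])
  }))
  frac_edges_within <- mean(ek %in% in_complex)

  act <- compute_activity(bundle$expression, k = k)
  loc <- lapply(split(bundle$localization$compartment,
                      bundle$localization$protein), unique)
  core_edges <- bundle$ppi[ek %in% core_pairs, , drop = FALSE]
  mh <- build_mhpin(core_edges, act, loc)
  survival <- if (nrow(core_edges)) nrow(mh$edges) / nrow(core_edges) else NA
  list(within_core_density = within_core_density,
       frac_edges_within_complexes = frac_edges_within,
       core_edge_filter_survival = survival,
       n_edges = nrow(bundle$ppi),
       n_complex_proteins = length(unique(unlist(members))))
}
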