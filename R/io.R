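#' Complex set container
#'
#' An ordered collection of protein complexes. Each complex is a character
#' vector of unique protein identifiers; identifiers are opaque,
#' case-sensitive strings. An optional per-complex core subset (the densely
#' connected part of a core-attachment structure) may be attached.
#'
#' @param complexes list of character vectors, each nonempty
#' @param cores optional list of character vectors, parallel to `complexes`;
#'   each core must be a subset of its complex
#' @return an object of class `complex_set`
#' @export
complex_set <- function(complexes, cores = NULL) {
  stopifnot(is.list(complexes))
  complexes <- lapply(complexes, function(x) {
    x <- as.character(x)
    x <- x[!duplicated(x)]
    if (length(x) == 0L) stop("complexes must be nonempty")
    x
  })
  if (!is.null(cores)) {
    stopifnot(length(cores) == length(complexes))
    ok <- mapply(function(co, cx) all(co %in% cx), cores, complexes)
    if (length(ok) && !all(ok)) stop("each core must be a subset of its complex")
  }
  structure(list(complexes = complexes, cores = cores),
            class = "complex_set")
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' @export
print.complex_set <- function(x, ...) {
  sizes <- lengths(x$complexes)
  cat(sprintf("complex_set: %d complexes (sizes %s)\n",
              length(sizes),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Read a complex file
#'
#' One complex per nonblank line, whitespace-separated protein IDs (the
#' de-facto interchange format of complex benchmarks). Duplicate proteins
#' within a line are collapsed; line order is preserved.
#'
#' @param path path to a complex file
#' @return a [complex_set]
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("cannot read complex file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty complex file: ", path)
    return(structure(list(complexes = list(), cores = NULL),
                     class = "complex_set"))
  }
  complex_set(lapply(strsplit(lines, "\\s+"), unique))
}

#' Write a complex file
#'
#' Inverse of [read_complexes()]: `read_complexes(write_complexes(x, p))`
#' recovers `x` up to within-complex ordering.
#'
#' @param complexes a [complex_set] or plain list of character vectors
#' @param path output path
#' @export
write_complexes <- function(complexes, path) {
  if (inherits(complexes, "complex_set")) complexes <- complexes$complexes
  writeLines(vapply(complexes, paste, character(1), collapse = " "), path)
  invisible(path)
}

read_tsv_strict <- function(path, expect_cols) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(expect_cols, colnames(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  df
}

#' Read a PPI edge list
#'
#' Tab-separated, header `protein_a`/`protein_b`, undirected. Self-loops and
#' duplicate edges (in either orientation) are removed; the number removed is
#' recorded in the `"report"` attribute so no row is dropped silently.
#'
#' @param path path to `ppi.tsv`
#' @return data.frame with columns `protein_a`, `protein_b`
#' @export
read_ppi <- function(path) {
  df <- read_tsv_strict(path, c("protein_a", "protein_b"))
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  bad <- !nzchar(df$protein_a) | !nzchar(df$protein_b) |
    is.na(df$protein_a) | is.na(df$protein_b)
  if (any(bad)) stop(sprintf("%s: empty protein id at line(s) %s",
                             path, paste(which(bad) + 1L, collapse = ",")))
  n0 <- nrow(df)
  self <- df$protein_a == df$protein_b
  df <- df[!self, , drop = FALSE]
  key <- ifelse(df$protein_a < df$protein_b,
                paste(df$protein_a, df$protein_b),
                paste(df$protein_b, df$protein_a))
  dup <- duplicated(key)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "report") <- list(n_input = n0, n_self_loops = sum(self),
                             n_duplicates = sum(dup), n_kept = nrow(df))
  df
}

#' Read a time-course expression table
#'
#' Tab-separated, first column `protein`, then one column per time point
#' (`t1` ... `tT`). All rows must have the same number of time points and
#' protein IDs must be unique.
#'
#' @param path path to `expression.tsv`
#' @return numeric matrix, proteins x T, with protein IDs as rownames
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path, "protein")
  if (ncol(df) < 2L) stop(path, ": expression table needs >= 1 time column")
  ids <- as.character(df$protein)
  if (anyDuplicated(ids)) stop(path, ": duplicate protein ids in expression table")
  vals <- df[, setdiff(colnames(df), "protein"), drop = FALSE]
  m <- as.matrix(vals)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))
    stop(sprintf("%s: non-numeric or missing expression value(s) at line(s) %s",
                 path, paste(bad + 1L, collapse = ",")))
  }
  rownames(m) <- ids
  m
}

#' Read a subcellular localization table
#'
#' Tab-separated, columns `protein` and `compartment`, one row per
#' assignment (a protein localized to two compartments occupies two rows).
#'
#' @param path path to `localization.tsv`
#' @return named list: protein ID -> character vector of compartment labels
#' @export
read_localization <- function(path) {
  df <- read_tsv_strict(path, c("protein", "compartment"))
  df$protein <- as.character(df$protein)
  df$compartment <- as.character(df$compartment)
  bad <- !nzchar(df$compartment) | is.na(df$compartment)
  if (any(bad)) stop(sprintf("%s: empty compartment label at line(s) %s",
                             path, paste(which(bad) + 1L, collapse = ",")))
  lapply(split(df$compartment, df$protein), unique)
}

#' Read an RNA-protein association table
#'
#' Tab-separated, columns `rna`, `protein`, `score`. Scores emulate
#' RNA-protein correlation coefficients; duplicate (rna, protein) pairs and
#' non-finite scores are rejected.
#'
#' @param path path to `rna_assoc.tsv`
#' @return data.frame with columns `rna`, `protein`, `score`
#' @export
read_rna_assoc <- function(path) {
  df <- read_tsv_strict(path, c("rna", "protein", "score"))
  df$rna <- as.character(df$rna)
  df$protein <- as.character(df$protein)
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score)))
    stop(sprintf("%s: non-finite score at line(s) %s", path,
                 paste(which(!is.finite(df$score)) + 1L, collapse = ",")))
  key <- paste(df$rna, df$protein)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (rna, protein) pair at line(s) %s", path,
                 paste(which(duplicated(key)) + 1L, collapse = ",")))
  rownames(df) <- NULL
  df
}

#' Read the full input bundle
#'
#' Reads the PPI edge list, expression, localization and RNA-association
#' tables and cross-checks them. Proteins appearing only in auxiliary tables
#' (never in the PPI network) are retained but flagged in the parse report.
#'
#' @param paths named list with elements `ppi`, `expression`, `localization`,
#'   `rna_assoc` (the last three optional, `NULL` to skip)
#' @return list with elements `ppi`, `expression`, `localization`,
#'   `rna_assoc`, and `report` (row counts, removed edges, flagged proteins)
#' @export
read_tables <- function(paths) {
  stopifnot(is.list(paths), !is.null(paths$ppi))
  ppi <- read_ppi(paths$ppi)
  expr <- if (!is.null(paths$expression)) read_expression(paths$expression)
  loc <- if (!is.null(paths$localization)) read_localization(paths$localization)
  rna <- if (!is.null(paths$rna_assoc)) read_rna_assoc(paths$rna_assoc)
  pin_proteins <- unique(c(ppi$protein_a, ppi$protein_b))
  aux <- unique(c(if (!is.null(expr)) rownames(expr),
                  if (!is.null(loc)) names(loc),
                  if (!is.null(rna)) rna$protein))
  flagged <- setdiff(aux, pin_proteins)
  report <- c(attr(ppi, "report"),
              list(n_pin_proteins = length(pin_proteins),
                   flagged_aux_only = flagged))
  list(ppi = ppi, expression = expr, localization = loc, rna_assoc = rna,
       report = report)
}
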