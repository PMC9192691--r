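# Correlation-augmented over-representation analysis against a
# measured-protein background.

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.  Gene symbols
#' are uppercased; duplicate set names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_config("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    warning(sprintf("skipping %d malformed GMT line(s)", sum(bad)))
    parts <- parts[!bad]
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop_config("duplicate gene-set names in %s", path)
  db <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(db) <- nm
  attr(db, "description") <- vapply(parts, `[[`, character(1), 2)
  db
}

#' Write a gene-set list to GMT
#' @param db Named list of character vectors.
#' @param path Output path.
#' @param description Optional vector of descriptions (defaults to names).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(db, path, description = names(db)) {
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(db), description, db)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Augment a protein query with high-correlation partners
#'
#' Adds every measured protein whose absolute Spearman correlation with at
#' least one selected protein strictly exceeds `rho_threshold` (default
#' 0.80).  Self-pairs are excluded; the boundary value is not added.
#'
#' @param selected Character vector of selected protein identifiers.
#' @param matrix Protein matrix (observations x proteins) on which
#'   correlations are computed.
#' @param rho_threshold Strict absolute-correlation threshold.
#' @return Character vector: the selection plus its partners, with an
#'   attribute `added` naming the augmentation.
#' @export
augment_query <- function(selected, matrix, rho_threshold = 0.80) {
  if (!length(selected)) return(character(0))
  missing <- setdiff(selected, colnames(matrix))
  if (length(missing)) {
    stop_config("selected proteins absent from matrix: %s",
                paste(missing, collapse = ", "))
  }
  others <- setdiff(colnames(matrix), selected)
  added <- character(0)
  if (length(others)) {
    rho <- suppressWarnings(
      cor(matrix[, others, drop = FALSE],
          matrix[, selected, drop = FALSE], method = "spearman"))
    best <- apply(abs(rho), 1, max, na.rm = TRUE)
    added <- others[is.finite(best) & best > rho_threshold]
  }
  out <- unique(c(selected, added))
  attr(out, "added") <- added
  out
}

#' One-sided hypergeometric over-representation p-value
#'
#' `P(X >= overlap)` where `X ~ Hypergeometric(background_n, set_n,
#' query_n)`: the chance of drawing at least `overlap` set members in a
#' query of size `query_n` sampled without replacement from the background.
#'
#' @param overlap Observed overlap count.
#' @param query_n Query size.
#' @param set_n Effective gene-set size (already intersected with the
#'   background).
#' @param background_n Background universe size.
#' @return The upper-tail p-value in (0, 1].
#' @export
hypergeom_test <- function(overlap, query_n, set_n, background_n) {
  if (overlap < 0 || set_n < 0 || query_n < 0 ||
      set_n > background_n || query_n > background_n ||
      overlap > min(query_n, set_n)) {
    stop_config("inconsistent counts: overlap %s, query %s, set %s, background %s",
                overlap, query_n, set_n, background_n)
  }
  phyper(overlap - 1, set_n, background_n - set_n, query_n,
         lower.tail = FALSE)
}

#' Over-representation analysis of a query against a gene-set database
#'
#' Every set is intersected with the background before testing (the
#' background is the measured-protein universe, not the whole genome).
#' Query genes absent from the background are ignored with a logged count.
#' Results are sorted by p-value; significance is raw p < 0.05.
#'
#' @param query Character vector of gene/protein identifiers.
#' @param db Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the measured universe.
#' @param alpha Significance cutoff (default 0.05).
#' @return Data frame: set, overlap, query_n, set_n (effective),
#'   background_n, p, significant; attribute `n_query_dropped`.
#' @export
enrich <- function(query, db, background, alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) stop_config("empty background")
  query0 <- unique(query)
  query <- intersect(query0, background)
  n_dropped <- length(query0) - length(query)
  if (n_dropped > 0) {
    warning(sprintf("%d query gene(s) absent from background ignored",
                    n_dropped))
  }
  N <- length(background); q <- length(query)
  rows <- lapply(names(db), function(nm) {
    eff <- intersect(db[[nm]], background)
    ov <- length(intersect(query, eff))
    p <- if (length(eff) == 0) 1 else hypergeom_test(ov, q, length(eff), N)
    data.frame(set = nm, overlap = ov, query_n = q, set_n = length(eff),
               background_n = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- n_dropped
  out
}

#' Partition significant pathways into shared and timepoint-specific
#'
#' @param resA,resB [enrich()] results computed on the same database and
#'   background.
#' @return List with `shared`, `a_only`, `b_only` set-name vectors.
#' @export
compare_timepoints <- function(resA, resB) {
  sa <- resA$set[resA$significant]
  sb <- resB$set[resB$significant]
  list(shared = sort(intersect(sa, sb)),
       a_only = sort(setdiff(sa, sb)),
       b_only = sort(setdiff(sb, sa)))
}
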