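#' Network proximity measures between a herb gene set and a disease module
#'
#' Three measures quantify how close a herb's target genes `H` (h_1..h_N) lie
#' to a disease's genes `D` (d_1..d_M) in the interactome; lower values
#' predict stronger association.
#'
#' * **ASP** (average shortest path length): the mean of `spl(h_n, d_m)` over
#'   all N x M gene pairs.
#' * **ACP** (average closest path length): for each herb gene, only the
#'   distance to its *nearest* disease gene counts; the mean over the N herb
#'   genes. A herb gene need not be close to every disease gene.
#' * **WACP** (weighted average closest path length): as ACP, but each herb
#'   gene's closest distance is multiplied by `1/w_n`, where `w_n` is the
#'   number of compounds in the herb targeting that gene. Genes hit by many
#'   compounds are treated as more strongly perturbed, pulling the score
#'   down. With all weights equal to 1, WACP reduces to ACP, and for any
#'   inputs `WACP <= ACP <= ASP`.
#'
#' Genes absent from the oracle's interactome are dropped before scoring, and
#' the denominators use the restricted counts. If either restricted set is
#' empty the score is undefined and `NA` is returned (with attribute
#' `n_herb_genes_used` / `n_disease_genes_used` still reporting the counts).
#'
#' @param H Character vector of herb gene identifiers.
#' @param D Character vector of disease gene identifiers.
#' @param H_weights Named positive numeric vector: herb genes -> compound
#'   multiplicity weights (names are the gene set, values `w_n >= 1`).
#' @param oracle A [distance_oracle()].
#' @return A numeric scalar (or `NA_real_` when undefined) with attributes
#'   `n_herb_genes_used` and `n_disease_genes_used`.
#' @seealso [score_all_pairs()] to score every herb-disease pair at once.
#' @name proximity_measures
NULL

restrict_to_graph <- function(genes, oracle) {
  unique(genes[genes %in% oracle_nodes(oracle)])
}

proximity_value <- function(value, n_h, n_d) {
  structure(value, n_herb_genes_used = n_h, n_disease_genes_used = n_d)
}

#' @rdname proximity_measures
#' @export
asp <- function(H, D, oracle) {
  H <- restrict_to_graph(H, oracle)
  D <- restrict_to_graph(D, oracle)
  if (length(H) == 0 || length(D) == 0) {
    return(proximity_value(NA_real_, length(H), length(D)))
  }
  d <- oracle_distances(oracle, H, D)
  proximity_value(mean(d), length(H), length(D))
}

#' @rdname proximity_measures
#' @export
acp <- function(H, D, oracle) {
  H <- restrict_to_graph(H, oracle)
  D <- restrict_to_graph(D, oracle)
  if (length(H) == 0 || length(D) == 0) {
    return(proximity_value(NA_real_, length(H), length(D)))
  }
  d <- oracle_distances(oracle, H, D)
  proximity_value(mean(apply(d, 1, min)), length(H), length(D))
}

#' @rdname proximity_measures
#' @export
wacp <- function(H_weights, D, oracle) {
  if (is.null(names(H_weights)) || any(!nzchar(names(H_weights)))) {
    stop("H_weights must be a named vector (names = herb genes)",
         call. = FALSE)
  }
  if (any(H_weights <= 0) || anyNA(H_weights)) {
    stop("all weights must be positive", call. = FALSE)
  }
  keep <- names(H_weights) %in% oracle_nodes(oracle)
  H_weights <- H_weights[keep]
  D <- restrict_to_graph(D, oracle)
  if (length(H_weights) == 0 || length(D) == 0) {
    return(proximity_value(NA_real_, length(H_weights), length(D)))
  }
  d <- oracle_distances(oracle, names(H_weights), D)
  closest <- apply(d, 1, min)
  proximity_value(mean(closest / as.numeric(H_weights)),
                  length(H_weights), length(D))
}

#' Score every herb-disease pair with one proximity measure
#'
#' Applies [asp()], [acp()] or [wacp()] to all herb x disease combinations,
#' restricting gene sets to interactome nodes. Distances are batch-computed
#' once for the union of in-graph herb genes against the union of in-graph
#' disease genes, then sliced per pair, which is equivalent to (and tested
#' against) cell-by-cell calls of the single-pair functions.
#'
#' @param herbs Named list of `herb_profile` objects ([build_herb_profiles()]).
#' @param diseases Named list of `disease_profile` objects
#'   ([build_disease_profiles()]).
#' @param oracle A [distance_oracle()].
#' @param measure `"WACP"` (default), `"ACP"` or `"ASP"`.
#' @return A `score_matrix`: numeric matrix (herbs x diseases, dimnames set)
#'   with `NA` for undefined cells, and attributes `measure`,
#'   `n_herb_genes_used` (named vector), `n_disease_genes_used` (named
#'   vector).
#' @export
score_all_pairs <- function(herbs, diseases, oracle,
                            measure = c("WACP", "ACP", "ASP")) {
  measure <- match.arg(measure)
  stopifnot(length(herbs) > 0, length(diseases) > 0)
  herb_ids <- vapply(herbs, function(h) h$herb_id, character(1))
  disease_ids <- vapply(diseases, function(d) d$disease_id, character(1))

  nodes <- oracle_nodes(oracle)
  h_genes <- lapply(herbs, function(h) {
    w <- h$gene_weights
    w[names(w) %in% nodes]
  })
  d_genes <- lapply(diseases, function(d) unique(d$genes[d$genes %in% nodes]))

  all_h <- unique(unlist(lapply(h_genes, names), use.names = FALSE))
  all_d <- unique(unlist(d_genes, use.names = FALSE))
  if (length(all_h) == 0 || length(all_d) == 0) {
    stop("no herb or disease genes map onto the interactome", call. = FALSE)
  }
  big <- oracle_distances(oracle, all_h, all_d)

  scores <- matrix(NA_real_, length(herbs), length(diseases),
                   dimnames = list(herb_ids, disease_ids))
  for (i in seq_along(herbs)) {
    w <- h_genes[[i]]
    if (length(w) == 0) next
    rows <- big[names(w), , drop = FALSE]
    for (j in seq_along(diseases)) {
      dg <- d_genes[[j]]
      if (length(dg) == 0) next
      d <- rows[, dg, drop = FALSE]
      scores[i, j] <- switch(measure,
        ASP = mean(d),
        ACP = mean(apply(d, 1, min)),
        WACP = mean(apply(d, 1, min) / as.numeric(w)))
    }
  }
  n_undef <- sum(is.na(scores))
  if (n_undef > 0) {
    message(sprintf("score_all_pairs: %d of %d cells undefined (empty in-graph gene set)",
                    n_undef, length(scores)))
  }
  structure(scores,
            measure = measure,
            n_herb_genes_used = stats::setNames(lengths(h_genes), herb_ids),
            n_disease_genes_used = stats::setNames(lengths(d_genes),
                                                   disease_ids),
            class = c("score_matrix", "matrix", "array"))
}

#' Write a score matrix as long-format TSV
#'
#' Columns: `herb`, `disease`, `measure`, `value`, `n_herb_genes`,
#' `n_disease_genes`; undefined cells are written as `NA`.
#'
#' @param scores A `score_matrix` from [score_all_pairs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  stopifnot(inherits(scores, "score_matrix"))
  long <- data.frame(
    herb = rep(rownames(scores), times = ncol(scores)),
    disease = rep(colnames(scores), each = nrow(scores)),
    measure = attr(scores, "measure"),
    value = as.vector(scores),
    n_herb_genes = rep(unname(attr(scores, "n_herb_genes_used")),
                       times = ncol(scores)),
    n_disease_genes = rep(unname(attr(scores, "n_disease_genes_used")),
                          each = nrow(scores)),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
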