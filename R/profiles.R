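#' Build disease gene-set profiles
#'
#' Groups an (evidence-filtered) disease-gene table into one profile per
#' disease. A disease profile is its set of associated genes, the disease
#' module searched for in the interactome.
#'
#' @param disease_gene An `association_table` with `relation_kind`
#'   `"disease_gene"`, already evidence-filtered by the caller.
#' @return A named list of `disease_profile` objects, each a list with
#'   elements `disease_id` and `genes` (character vector, unique). The sum of
#'   profile sizes equals the number of table records.
#' @export
build_disease_profiles <- function(disease_gene) {
  stopifnot(inherits(disease_gene, "association_table"))
  if (!identical(attr(disease_gene, "relation_kind"), "disease_gene")) {
    stop("expected a disease_gene association table", call. = FALSE)
  }
  if (nrow(disease_gene) == 0) return(structure(list(), names = character(0)))
  by_disease <- split(disease_gene$object, disease_gene$subject)
  out <- lapply(names(by_disease), function(d) {
    structure(list(disease_id = d, genes = unique(by_disease[[d]])),
              class = "disease_profile")
  })
  names(out) <- names(by_disease)
  out
}

#' @export
print.disease_profile <- function(x, ...) {
  cat(sprintf("<disease_profile> %s: %d gene(s)\n", x$disease_id,
              length(x$genes)))
  invisible(x)
}

#' Build herb gene-set profiles with compound-multiplicity weights
#'
#' A herb's gene set is the union of the target genes of its compounds; each
#' gene carries a weight, the number of the herb's compounds that target it.
#' These weights encode the multi-compound multi-target character of herbs
#' and later down-weight (divide) closest-path distances in the WACP measure.
#' Herbs whose compounds collectively target no genes are dropped with a
#' warning, mirroring the restriction to herbs with at least one annotated
#' compound.
#'
#' @param herb_compound `association_table` (`"herb_compound"`), filtered.
#' @param compound_gene `association_table` (`"compound_gene"`), filtered.
#' @return A named list of `herb_profile` objects: lists with `herb_id`,
#'   `compounds` (character vector) and `gene_weights` (named integer vector;
#'   names are the herb's genes, values the compound counts).
#' @export
build_herb_profiles <- function(herb_compound, compound_gene) {
  stopifnot(inherits(herb_compound, "association_table"),
            inherits(compound_gene, "association_table"))
  if (!identical(attr(herb_compound, "relation_kind"), "herb_compound") ||
      !identical(attr(compound_gene, "relation_kind"), "compound_gene")) {
    stop("expected herb_compound and compound_gene association tables",
         call. = FALSE)
  }
  if (nrow(herb_compound) == 0) return(structure(list(), names = character(0)))
  targets <- split(compound_gene$object, compound_gene$subject)
  by_herb <- split(herb_compound$object, herb_compound$subject)

  out <- lapply(names(by_herb), function(h) {
    comps <- unique(by_herb[[h]])
    hit <- unlist(targets[intersect(comps, names(targets))],
                  use.names = FALSE)
    if (length(hit) == 0) return(NULL)
    w <- table(hit)
    structure(list(herb_id = h,
                   compounds = comps,
                   gene_weights = stats::setNames(as.integer(w), names(w))),
              class = "herb_profile")
  })
  names(out) <- names(by_herb)
  empty <- vapply(out, is.null, logical(1))
  if (any(empty)) {
    warning(sprintf("dropped %d herb(s) whose compounds target no genes",
                    sum(empty)), call. = FALSE)
    out <- out[!empty]
  }
  out
}

#' @export
print.herb_profile <- function(x, ...) {
  cat(sprintf("<herb_profile> %s: %d compound(s), %d target gene(s), max weight %d\n",
              x$herb_id, length(x$compounds), length(x$gene_weights),
              max(x$gene_weights)))
  invisible(x)
}
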