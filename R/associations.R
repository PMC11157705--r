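#' Construct an association table
#'
#' An association table holds evidence-annotated subject -> object links
#' (e.g. disease -> gene, herb -> compound) pooled from several source
#' databases. Duplicate (subject, object) pairs are merged by unioning their
#' source-label sets, so each pair appears exactly once.
#'
#' @param subject Character vector of subject identifiers.
#' @param object Character vector of object identifiers (same length).
#' @param sources List of character vectors, one per record: the source
#'   databases carrying that record. Labels are case-sensitive opaque strings.
#' @param relation_kind One of `"disease_gene"`, `"herb_compound"`,
#'   `"compound_gene"`, `"herb_disease"`.
#' @return A data frame of class `association_table` with columns `subject`,
#'   `object` and the list-column `sources`, plus a `relation_kind` attribute.
#' @examples
#' association_table(c("d1", "d1"), c("g1", "g1"),
#'                   list("CTD", "OMIM"), "disease_gene")
#' @export
association_table <- function(subject, object, sources, relation_kind) {
  relation_kind <- match.arg(relation_kind, relation_kinds())
  subject <- as.character(subject)
  object <- as.character(object)
  if (length(subject) != length(object)) {
    stop("subject and object must have the same length", call. = FALSE)
  }
  if (!is.list(sources)) sources <- as.list(sources)
  sources <- rep_len(sources, length(subject))
  sources <- lapply(sources, function(s) unique(as.character(s)))

  if (any(!nzchar(subject)) || any(!nzchar(object)) ||
      anyNA(subject) || anyNA(object)) {
    stop("identifiers must be non-empty strings", call. = FALSE)
  }
  bad <- vapply(sources, function(s) length(s) == 0L || any(!nzchar(s)),
                logical(1))
  if (any(bad)) {
    stop(sprintf("%d record(s) have an empty sources field", sum(bad)),
         call. = FALSE)
  }

  # merge duplicate pairs, unioning evidence; keyed so row order is irrelevant
  key <- paste(subject, object, sep = "\r")
  if (anyDuplicated(key)) {
    merged <- lapply(split(sources, key), function(s) unique(unlist(s)))
    first <- !duplicated(key)
    subject <- subject[first]
    object <- object[first]
    key <- key[first]
    sources <- merged[key]
  }
  ord <- order(subject, object)
  out <- data.frame(subject = subject[ord], object = object[ord],
                    stringsAsFactors = FALSE)
  out$sources <- unname(sources[ord])
  attr(out, "relation_kind") <- relation_kind
  class(out) <- c("association_table", "data.frame")
  out
}

relation_kinds <- function() {
  c("disease_gene", "herb_compound", "compound_gene", "herb_disease")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %s: %d record(s), %d subject(s), %d object(s)\n",
              attr(x, "relation_kind"), nrow(x),
              length(unique(x$subject)), length(unique(x$object))))
  if (nrow(x) > 0) {
    show <- utils::head(x, 6L)
    lab <- vapply(show$sources, paste, character(1), collapse = ",")
    print(data.frame(subject = show$subject, object = show$object,
                     sources = lab, stringsAsFactors = FALSE))
    if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Load an association table from TSV
#'
#' Reads a tab-separated file with header columns `subject`, `object`,
#' `sources`. The sources field is a list of database labels separated by
#' `|` or `,`. Lines starting with `#` are ignored. Duplicate
#' (subject, object) rows are merged by unioning their source sets, so the
#' result does not depend on row order.
#'
#' @param path Path to the TSV file.
#' @param relation_kind Relation the table encodes; see [association_table()].
#' @return An `association_table`.
#' @export
load_association_table <- function(path, relation_kind) {
  relation_kind <- match.arg(relation_kind, relation_kinds())
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("subject", "object", "sources")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    stop(sprintf("%s: empty association table", path), call. = FALSE)
  }
  sources <- strsplit(raw$sources, "[|,]")
  sources <- lapply(sources, function(s) trimws(s[nzchar(trimws(s))]))
  association_table(raw$subject, raw$object, sources, relation_kind)
}

#' Keep associations supported by multiple databases
#'
#' Retains the records whose evidence spans at least `min_sources` distinct
#' source databases. Distinct labels are counted, not record multiplicity.
#' The operation is idempotent, and `min_sources = 1` is the identity on any
#' loaded table.
#'
#' @param table An `association_table`.
#' @param min_sources Minimum number of distinct source databases (default 2,
#'   the conventional reliability filter).
#' @return The filtered `association_table` (possibly with zero records).
#' @export
filter_by_evidence <- function(table, min_sources = 2L) {
  stopifnot(inherits(table, "association_table"))
  min_sources <- as.integer(min_sources)
  if (is.na(min_sources) || min_sources < 1L) {
    stop("min_sources must be a positive integer", call. = FALSE)
  }
  keep <- lengths(table$sources) >= min_sources
  out <- table[keep, , drop = FALSE]
  attr(out, "relation_kind") <- attr(table, "relation_kind")
  class(out) <- c("association_table", "data.frame")
  out
}
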