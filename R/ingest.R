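#' Protein entries and the transaction database
#'
#' A protein entry couples an accession with its taxonomic lineage, its
#' InterPro signature identifiers and its evidenced pathway annotations.
#' Entries are the unit of ingestion; each entry later becomes one
#' transaction of namespaced items (`TAXON:`, `IPR:`, `PATHWAY:`) for rule
#' mining.
#'
#' @param accession non-empty accession string.
#' @param lineage character vector of taxon names, most general first (may
#'   be empty).
#' @param interpro character vector of InterPro ids (`IPR` + 6 digits);
#'   duplicates are removed.
#' @param pathways list of pathway annotations, each created by
#'   [pathway_annotation()].
#' @return a `protein_entry` object.
#' @seealso [build_transactions()], [filter_by_evidence()]
#' @export
protein_entry <- function(accession, lineage = character(),
                          interpro = character(), pathways = list()) {
  if (length(accession) != 1L || is.na(accession) || !nzchar(accession))
    stop("accession must be a non-empty string")
  interpro <- unique(as.character(interpro))
  bad <- interpro[!grepl("^IPR[0-9]{6}$", interpro)]
  if (length(bad))
    stop("malformed InterPro id(s): ", paste(bad, collapse = ", "))
  stopifnot(is.list(pathways))
  lineage <- vapply(as.character(lineage), normalize_ws, "",
                    USE.NAMES = FALSE)
  structure(list(accession = accession, lineage = lineage,
                 interpro = interpro, pathways = pathways),
            class = "protein_entry")
}

#' @rdname protein_entry
#' @param label pathway label string (parsed and canonicalised) or a
#'   `pathway_label` object.
#' @param evidence character vector of ECO evidence codes
#'   (`ECO:` + 7 digits). May be empty for unannotated application-mode
#'   input.
#' @export
pathway_annotation <- function(label, evidence = character()) {
  if (!inherits(label, "pathway_label")) label <- parse_pathway_label(label)
  evidence <- unique(as.character(evidence))
  bad <- evidence[!grepl("^ECO:[0-9]{7}$", evidence)]
  if (length(bad))
    stop("malformed ECO code(s): ", paste(bad, collapse = ", "))
  structure(list(label = label, evidence = evidence),
            class = "pathway_annotation")
}

#' @export
print.protein_entry <- function(x, ...) {
  cat("<protein_entry> ", x$accession, ": ", length(x$lineage),
      " lineage nodes, ", length(x$interpro), " InterPro ids, ",
      length(x$pathways), " pathway annotation(s)\n", sep = "")
  invisible(x)
}

#' ECO codes accepted as manual assertion evidence
#'
#' The six Evidence and Conclusion Ontology codes that mark manually
#' curated pathway annotations: experimental evidence, non-traceable
#' author statement, curator inference, sequence similarity, sequence
#' model, and combinatorial evidence.
#'
#' @return character vector of six ECO codes.
#' @export
manual_assertion_codes <- function() {
  c("ECO:0000269", "ECO:0000303", "ECO:0000305",
    "ECO:0000250", "ECO:0000255", "ECO:0000244")
}

#' Filter entries to manually asserted pathway annotations
#'
#' Keeps each pathway annotation only if its evidence set intersects the
#' allowed codes; entries left with no pathway annotation are removed
#' (learning mode).
#'
#' @param entries list of `protein_entry` objects.
#' @param allowed set of admissible ECO codes; defaults to
#'   [manual_assertion_codes()].
#' @param drop_unannotated remove entries with zero surviving pathway
#'   annotations (default `TRUE`; set `FALSE` in application mode).
#' @return filtered list of `protein_entry` objects.
#' @export
filter_by_evidence <- function(entries, allowed = manual_assertion_codes(),
                               drop_unannotated = TRUE) {
  out <- lapply(entries, function(e) {
    keep <- vapply(e$pathways,
                   function(p) length(intersect(p$evidence, allowed)) > 0L,
                   logical(1))
    e$pathways <- e$pathways[keep]
    e
  })
  if (drop_unannotated)
    out <- out[vapply(out, function(e) length(e$pathways) > 0L, logical(1))]
  out
}

#' Build the transaction database
#'
#' Maps each entry to one transaction of canonical namespaced items: one
#' `TAXON:<name>` item per lineage node, one `IPR:<id>` item per InterPro
#' signature, one `PATHWAY:<canonical label>` item per pathway annotation
#' (the full label string, step suffix included). Items within a
#' transaction are deduplicated.
#'
#' @param entries list of `protein_entry` objects (already
#'   evidence-filtered in learning mode).
#' @return a `transaction_db`: list with `transactions` (named list of
#'   character item vectors, names = accessions) and `N` (transaction
#'   count).
#' @export
build_transactions <- function(entries) {
  acc <- vapply(entries, function(e) e$accession, "")
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  tx <- lapply(entries, function(e) {
    items <- c(
      if (length(e$lineage)) paste0("TAXON:", e$lineage),
      if (length(e$interpro)) paste0("IPR:", e$interpro),
      vapply(e$pathways,
             function(p) paste0("PATHWAY:", render_pathway_label(p$label)),
             "")
    )
    unique(items)
  })
  names(tx) <- acc
  structure(list(transactions = tx, N = length(tx)), class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  n_items <- length(unique(unlist(x$transactions, use.names = FALSE)))
  cat("<transaction_db> ", x$N, " transactions, ", n_items,
      " distinct items\n", sep = "")
  invisible(x)
}

#' Reference pathway set
#'
#' The evaluation universe: pathway items present in at least `min_count`
#' transactions.
#'
#' @param db a `transaction_db`.
#' @param min_count minimum number of carrying transactions (default 20).
#' @return character vector of `PATHWAY:` items, sorted.
#' @export
reference_pathways <- function(db, min_count = 20L) {
  stopifnot(inherits(db, "transaction_db"), min_count >= 1L)
  counts <- item_counts(db, "PATHWAY")
  sort(names(counts)[counts >= min_count])
}

# occurrence count per distinct item, optionally restricted to a namespace
item_counts <- function(db, namespace = NULL) {
  all_items <- unlist(db$transactions, use.names = FALSE)
  if (!is.null(namespace))
    all_items <- all_items[startsWith(all_items, paste0(namespace, ":"))]
  if (!length(all_items)) return(integer())
  tab <- table(all_items)
  stats::setNames(as.integer(tab), names(tab))
}

# split a canonical item into namespace and value
item_namespace <- function(items) sub(":.*$", "", items)

# attribute items are TAXON/IPR; PATHWAY items are targets
is_attribute_item <- function(items) !startsWith(items, "PATHWAY:")
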