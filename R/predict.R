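#' Apply prediction models to a transaction database
#'
#' A model fires on an entry when the antecedent of at least one of its
#' clauses is contained in the entry's attribute items (`TAXON:`/`IPR:`;
#' any `PATHWAY:` items the transaction carries are ignored, so annotated
#' and unannotated entries are handled identically). Each (entry, pathway)
#' pair yields at most one prediction; `best_distance` is the minimum
#' distance over firing clauses and the prediction score is
#' `2 - best_distance` (higher is better; any firing clause scores > 0,
#' non-predictions implicitly score 0).
#'
#' @param models a `prediction_models` object.
#' @param db a `transaction_db` (transactions may lack pathway items).
#' @return data.frame with columns `accession`, `pathway`,
#'   `best_distance`, `score`, `n_firing_clauses`.
#' @export
apply_models <- function(models, db) {
  stopifnot(inherits(db, "transaction_db"))
  acc_out <- character(); pw_out <- character()
  dist_out <- numeric(); nfire_out <- integer()
  for (acc in names(db$transactions)) {
    attrs <- db$transactions[[acc]]
    attrs <- attrs[is_attribute_item(attrs)]
    for (m in models) {
      firing <- vapply(m$clauses,
                       function(cl) all(cl$antecedent %in% attrs),
                       logical(1))
      if (!any(firing)) next
      acc_out <- c(acc_out, acc)
      pw_out <- c(pw_out, m$consequent)
      dist_out <- c(dist_out,
                    min(vapply(m$clauses[firing],
                               function(cl) cl$distance, numeric(1))))
      nfire_out <- c(nfire_out, sum(firing))
    }
  }
  data.frame(accession = acc_out, pathway = pw_out,
             best_distance = dist_out, score = 2 - dist_out,
             n_firing_clauses = nfire_out, stringsAsFactors = FALSE)
}

#' Write predictions to TSV
#'
#' Columns: `accession`, `pathway`, `best_distance`, `score`,
#' `n_firing_clauses`.
#'
#' @param predictions output of [apply_models()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  df <- predictions
  df$best_distance <- fmt_num(df$best_distance)
  df$score <- fmt_num(df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare a prediction set against another system's annotations
#'
#' Each of our predictions is classified against the other system's
#' annotations for the same entry: `identical` if any annotation matches
#' the predicted pathway exactly (canonical strings equal), otherwise
#' `similar` if any annotation is hierarchically more general or more
#' specific (see [compare_pathway_labels()]), otherwise `distinct`.
#' Predictions for entries the other system did not annotate at all are
#' counted as `novel`.
#'
#' @param ours data.frame with columns `accession`, `pathway` (our
#'   predictions; pathway strings may carry the `PATHWAY:` namespace
#'   prefix, which is stripped before label comparison).
#' @param theirs data.frame with columns `accession`, `pathway` (the other
#'   system's annotations).
#' @return named list of counts: `identical`, `similar`, `distinct`,
#'   `novel`.
#' @export
compare_prediction_sets <- function(ours, theirs) {
  strip_ns <- function(x) sub("^PATHWAY:", "", x)
  theirs_by_entry <- split(strip_ns(theirs$pathway), theirs$accession)
  counts <- c(identical = 0L, similar = 0L, distinct = 0L, novel = 0L)
  for (i in seq_len(nrow(ours))) {
    acc <- ours$accession[i]
    mine <- strip_ns(ours$pathway[i])
    ref <- theirs_by_entry[[acc]]
    if (is.null(ref)) {
      counts["novel"] <- counts["novel"] + 1L
      next
    }
    cmp <- vapply(ref, function(r) compare_pathway_labels(mine, r), "")
    cat_i <- if (any(cmp == "identical")) "identical"
             else if (any(cmp == "similar")) "similar"
             else "distinct"
    counts[cat_i] <- counts[cat_i] + 1L
  }
  as.list(counts)
}
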