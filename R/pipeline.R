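#' End-to-end learning pipeline
#'
#' Convenience wrapper chaining the learning stages on an annotated entry
#' collection: evidence filtering, transaction building, frequent
#' antecedent mining, rule derivation and scoring, skyline selection, and
#' model aggregation.
#'
#' @param entries list of `protein_entry` objects (unfiltered).
#' @param min_support_abs minimum absolute antecedent support (default
#'   20).
#' @param min_conf minimum rule confidence (default 1.0).
#' @param max_size maximum antecedent size (default 4).
#' @param allowed_evidence ECO codes accepted as manual assertion;
#'   defaults to [manual_assertion_codes()].
#' @param verbose emit per-stage counts via `message()`.
#' @return list with `db` (the `transaction_db`), `rules` (mined
#'   `rule_set`), `representatives` (selected subset), `models`
#'   (`prediction_models`).
#' @export
learn_models <- function(entries, min_support_abs = 20L, min_conf = 1.0,
                         max_size = 4L,
                         allowed_evidence = manual_assertion_codes(),
                         verbose = FALSE) {
  kept <- filter_by_evidence(entries, allowed_evidence)
  if (verbose)
    message("entries kept after evidence filter: ", length(kept), " / ",
            length(entries))
  if (!length(kept)) stop("no entries left after evidence filtering")
  db <- build_transactions(kept)
  frequent <- mine_frequent_antecedents(db, min_support_abs, max_size)
  rules <- derive_rules(db, frequent, min_conf)
  if (verbose) message("rules mined: ", nrow(rules))
  reps <- select_representatives(rules)
  if (verbose) message("representative rules: ", nrow(reps))
  models <- aggregate_models(reps)
  if (verbose) message("prediction models: ", length(models))
  list(db = db, rules = rules, representatives = reps, models = models)
}
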