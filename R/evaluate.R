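#' Pair-level confusion matrix
#'
#' Confusion counting runs over every (protein, reference pathway) pair:
#' a pair both predicted and annotated is a true positive; predicted but
#' not annotated, a false positive; annotated but not predicted, a false
#' negative; neither, a true negative. Predictions and annotations outside
#' the protein set or the reference pathway set are ignored, so
#' `TP + FP + FN + TN = |proteins| * |reference|` always holds.
#'
#' @param predictions data.frame with columns `accession`, `pathway`.
#' @param annotations data.frame with columns `accession`, `pathway`
#'   (the known pathway memberships).
#' @param proteins character vector of accessions defining the pair
#'   universe.
#' @param reference character vector of reference pathway items (see
#'   [reference_pathways()]).
#' @return named list with integer fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_matrix <- function(predictions, annotations, proteins, reference) {
  if (!length(reference)) stop("reference pathway set is empty")
  proteins <- unique(proteins)
  reference <- unique(reference)
  pair_key <- function(df) {
    keep <- df$accession %in% proteins & df$pathway %in% reference
    unique(paste(df$accession[keep], df$pathway[keep], sep = "\r"))
  }
  pred <- pair_key(predictions)
  ann <- pair_key(annotations)
  TP <- length(intersect(pred, ann))
  FP <- length(setdiff(pred, ann))
  FN <- length(setdiff(ann, pred))
  total <- length(proteins) * length(reference)
  list(TP = TP, FP = FP, FN = FN, TN = total - TP - FP - FN)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f1 = 2*P*R/(P+R)`. Degenerate denominators follow the no-error
#' convention: a 0/0 precision or recall is 1 (no mistakes were made);
#' F1 is 0 when `P + R = 0`.
#'
#' @param cm list with fields `TP`, `FP`, `FN`, `TN` (fractional counts
#'   from fold averaging are accepted).
#' @return a ratio in `[0, 1]`.
#' @export
precision <- function(cm) {
  if (cm$TP + cm$FP == 0) return(1)
  cm$TP / (cm$TP + cm$FP)
}

#' @rdname precision
#' @export
recall <- function(cm) {
  if (cm$TP + cm$FN == 0) return(1)
  cm$TP / (cm$TP + cm$FN)
}

#' @rdname precision
#' @export
f1_score <- function(cm) {
  p <- precision(cm); r <- recall(cm)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Truncate to three decimals
#'
#' Reported metric values are truncated (not rounded) to three decimal
#' places.
#'
#' @param x numeric vector.
#' @return truncated values.
#' @export
truncate3 <- function(x) trunc(x * 1000) / 1000

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' tie correction: `(concordant + ties/2) / (n_pos * n_neg)`, evaluated
#' via average ranks. Equal to the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical (or 0/1) true labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC requires both positive and negative labels")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs `runs` rounds of `k`-fold cross-validation over the transaction
#' database. In each round the transactions are partitioned uniformly at
#' random into `k` folds of size differing by at most one; for each fold,
#' rules are mined, selected and aggregated on the other `k - 1` folds
#' and the resulting models are applied to the held-out fold. Confusion is
#' counted pair-wise against the reference pathway set computed once on
#' the full database. Fold confusion matrices are averaged (cell-wise
#' mean) per run; the global matrix is the mean of the run matrices with
#' a deviation of half the absolute difference between the two runs (for
#' `runs == 2`; more generally half the range). Precision, recall, F1 are
#' computed from the averaged matrices; AUC is averaged over folds, each
#' fold's AUC taken over all (held-out protein, reference pathway) pairs
#' with score `2 - best_distance` (0 when no clause fires).
#'
#' The second and later runs use seeds derived from `seed` (`seed + run -
#' 1`) so that each run splits the data differently but the whole report
#' is reproducible.
#'
#' @param db a `transaction_db` of annotated entries.
#' @param k number of folds (default 5; must be >= 2).
#' @param runs number of rounds (default 2).
#' @param seed integer seed for the fold splits.
#' @param min_support_abs,min_conf,max_size mining parameters (defaults
#'   20, 1.0, 4).
#' @param ref_min_count reference-set threshold (default 20).
#' @return an `evaluation_report`: list with `folds` (per run, per fold
#'   matrices and metrics), `runs` (per-run averaged matrices and
#'   metrics), `global` (means and deviations), and `params`.
#' @export
cross_validate <- function(db, k = 5L, runs = 2L, seed = 1L,
                           min_support_abs = 20L, min_conf = 1.0,
                           max_size = 4L, ref_min_count = 20L) {
  stopifnot(inherits(db, "transaction_db"))
  if (k < 2L) stop("cross-validation requires k >= 2")
  if (db$N < k) stop("database too small for ", k, " folds")
  reference <- reference_pathways(db, ref_min_count)
  if (!length(reference))
    stop("reference pathway set is empty at min_count = ", ref_min_count)
  accs <- names(db$transactions)

  annotations_of <- function(ids) {
    pw <- lapply(db$transactions[ids],
                 function(tx) tx[startsWith(tx, "PATHWAY:")])
    data.frame(accession = rep(ids, lengths(pw)),
               pathway = unlist(pw, use.names = FALSE) %||% character(),
               stringsAsFactors = FALSE)
  }

  run_results <- vector("list", runs)
  fold_results <- vector("list", runs)
  for (run in seq_len(runs)) {
    fold_of <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed + run - 1L)
      sample(rep(seq_len(k), length.out = db$N))
    })
    per_fold <- vector("list", k)
    for (f in seq_len(k)) {
      train_ids <- accs[fold_of != f]
      test_ids <- accs[fold_of == f]
      train_db <- structure(list(transactions = db$transactions[train_ids],
                                 N = length(train_ids)),
                            class = "transaction_db")
      frequent <- mine_frequent_antecedents(train_db, min_support_abs,
                                            max_size)
      rules <- derive_rules(train_db, frequent, min_conf)
      reps <- select_representatives(rules)
      models <- aggregate_models(reps)
      test_db <- structure(list(transactions = db$transactions[test_ids],
                                N = length(test_ids)),
                           class = "transaction_db")
      preds <- apply_models(models, test_db)
      ann <- annotations_of(test_ids)
      cm <- confusion_matrix(preds, ann, test_ids, reference)
      auc <- fold_auc(preds, ann, test_ids, reference)
      per_fold[[f]] <- list(
        cm = cm, auc = auc,
        n_rules = nrow(rules), n_representatives = nrow(reps),
        n_models = length(models))
    }
    fold_results[[run]] <- per_fold
    avg_cm <- lapply(stats::setNames(nm = c("TP", "FP", "FN", "TN")),
                     function(f_) mean(vapply(per_fold,
                                              function(x) x$cm[[f_]],
                                              numeric(1))))
    aucs <- vapply(per_fold, function(x) x$auc, numeric(1))
    run_results[[run]] <- list(
      cm = avg_cm,
      precision = precision(avg_cm), recall = recall(avg_cm),
      f1 = f1_score(avg_cm), auc = mean(aucs, na.rm = TRUE))
  }

  half_range <- function(v) (max(v) - min(v)) / 2
  global <- list()
  for (f_ in c("TP", "FP", "FN", "TN")) {
    v <- vapply(run_results, function(x) x$cm[[f_]], numeric(1))
    global[[f_]] <- mean(v)
    global[[paste0(f_, "_dev")]] <- half_range(v)
  }
  for (mname in c("precision", "recall", "f1", "auc")) {
    v <- vapply(run_results, function(x) x[[mname]], numeric(1))
    global[[mname]] <- mean(v)
    global[[paste0(mname, "_dev")]] <- half_range(v)
  }
  structure(list(folds = fold_results, runs = run_results, global = global,
                 params = list(k = k, runs = runs, seed = seed,
                               min_support_abs = min_support_abs,
                               min_conf = min_conf, max_size = max_size,
                               ref_min_count = ref_min_count,
                               n_reference = length(reference))),
            class = "evaluation_report")
}

# AUC over all (held-out protein, reference pathway) pairs;
# NA when the fold has a single class
fold_auc <- function(preds, ann, proteins, reference) {
  pairs <- expand.grid(accession = proteins, pathway = reference,
                       stringsAsFactors = FALSE)
  key <- paste(pairs$accession, pairs$pathway, sep = "\r")
  score <- stats::setNames(rep(0, length(key)), key)
  if (nrow(preds)) {
    pk <- paste(preds$accession, preds$pathway, sep = "\r")
    keep <- pk %in% key
    score[pk[keep]] <- preds$score[keep]
  }
  label <- key %in% paste(ann$accession, ann$pathway, sep = "\r")
  if (all(label) || !any(label)) return(NA_real_)
  auc_rank(unname(score), label)
}

#' @export
print.evaluation_report <- function(x, ...) {
  g <- x$global
  cat("<evaluation_report> ", x$params$runs, " run(s) x ", x$params$k,
      "-fold CV (seed ", x$params$seed, ")\n", sep = "")
  cat(sprintf("  TP %.1f±%.1f  FP %.1f±%.1f  FN %.1f±%.1f  TN %.1f±%.1f\n",
              g$TP, g$TP_dev, g$FP, g$FP_dev, g$FN, g$FN_dev, g$TN,
              g$TN_dev))
  cat(sprintf(
    "  precision %.3f  recall %.3f  F1 %.3f  AUC %.3f (truncated)\n",
    truncate3(g$precision), truncate3(g$recall), truncate3(g$f1),
    truncate3(g$auc)))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Serialises fold- and run-level confusion matrices, global means with
#' deviations, and the parameters used.
#'
#' @param report an `evaluation_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  doc <- list(
    params = report$params,
    runs = lapply(report$runs, function(r) {
      list(confusion = r$cm,
           precision = r$precision, recall = r$recall, f1 = r$f1,
           auc = r$auc)
    }),
    folds = lapply(report$folds, function(run) {
      lapply(run, function(f) {
        list(confusion = f$cm, auc = f$auc, n_rules = f$n_rules,
             n_representatives = f$n_representatives,
             n_models = f$n_models)
      })
    }),
    global = report$global)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}
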