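#' Support of an itemset
#'
#' Number of transactions whose item set contains every item of `items`;
#' the empty itemset has support `N`, the size of the database.
#'
#' @param db a `transaction_db`.
#' @param items character vector of canonical items (may be empty).
#' @return integer count.
#' @export
itemset_support <- function(db, items) {
  stopifnot(inherits(db, "transaction_db"))
  if (!length(items)) return(db$N)
  sum(vapply(db$transactions, function(tx) all(items %in% tx), logical(1)))
}

#' Mine frequent attribute antecedents
#'
#' Level-wise Apriori over the attribute items (`TAXON:`/`IPR:` namespaces
#' only; pathway items are never candidates). Returns every attribute
#' itemset of size 1..`max_size` whose absolute support meets
#' `min_support_abs`, in deterministic order (by size, then
#' lexicographically on the sorted canonical items).
#'
#' Candidate generation is the classic join of frequent (k-1)-itemsets
#' sharing a (k-2)-prefix followed by subset pruning; antecedent-support
#' antimonotonicity guarantees completeness.
#'
#' @param db a `transaction_db`.
#' @param min_support_abs minimum absolute support (default 20
#'   transactions).
#' @param max_size maximum antecedent size (default 4).
#' @return data.frame with list-column `items` (sorted canonical item
#'   vectors), `size`, and `support_abs`.
#' @export
mine_frequent_antecedents <- function(db, min_support_abs = 20L,
                                      max_size = 4L) {
  stopifnot(inherits(db, "transaction_db"),
            min_support_abs >= 1L, max_size >= 1L)
  if (db$N == 0L) stop("cannot mine an empty transaction database")

  counts <- item_counts(db)
  counts <- counts[is_attribute_item(names(counts))]
  freq1 <- sort(names(counts)[counts >= min_support_abs])
  empty <- data.frame(size = integer(), support_abs = integer())
  empty$items <- list()
  if (!length(freq1)) return(empty[, c("items", "size", "support_abs")])

  # transaction x item incidence over frequent singletons
  M <- vapply(freq1,
              function(it) vapply(db$transactions, function(tx) it %in% tx,
                                  logical(1)),
              logical(db$N))
  M <- matrix(M, nrow = db$N, dimnames = list(NULL, freq1))

  support_of <- function(cols) {
    sum(rowSums(M[, cols, drop = FALSE]) == length(cols))
  }

  levels_items <- list(as.list(freq1))
  levels_supp <- list(unname(counts[freq1]))
  k <- 1L
  while (k < max_size && length(levels_items[[k]]) > 1L) {
    prev <- levels_items[[k]]
    prev_keys <- vapply(prev, paste, "", collapse = "\r")
    cand <- list()
    # join step: pairs sharing the first k-1 items (items kept sorted)
    pref <- vapply(prev, function(s) paste(s[-length(s)], collapse = "\r"), "")
    for (g in split(seq_along(prev), pref)) {
      if (length(g) < 2L) next
      for (i in seq_len(length(g) - 1L)) for (j in (i + 1L):length(g)) {
        a <- prev[[g[i]]]; b <- prev[[g[j]]]
        new <- sort(unique(c(a, b)))
        if (length(new) != k + 1L) next
        # prune: all k-subsets must be frequent
        ok <- all(vapply(seq_along(new), function(d)
          paste(new[-d], collapse = "\r") %in% prev_keys, logical(1)))
        if (ok) cand[[length(cand) + 1L]] <- new
      }
    }
    if (!length(cand)) break
    cand <- unique(cand)
    supp <- vapply(cand, support_of, integer(1))
    keep <- supp >= min_support_abs
    if (!any(keep)) break
    levels_items[[k + 1L]] <- cand[keep]
    levels_supp[[k + 1L]] <- supp[keep]
    k <- k + 1L
  }

  items <- do.call(c, levels_items)
  supp <- unlist(levels_supp)
  size <- lengths(items)
  key <- vapply(items, paste, "", collapse = "\r")
  ord <- order(size, key, method = "radix")
  out <- data.frame(size = size[ord], support_abs = as.integer(supp[ord]))
  out$items <- items[ord]
  out[, c("items", "size", "support_abs")]
}

#' Derive class-association rules from frequent antecedents
#'
#' For every frequent attribute antecedent X and every pathway item Y
#' co-occurring with it, emits the rule X => Y when its confidence
#' supp(X u Y)/supp(X) reaches `min_conf`. Rule support follows the
#' antecedent-support convention: `support_abs = supp(X)`,
#' `support_rel = supp(X)/N`. Lift and the G-test p-value are computed from
#' the 2x2 contingency table of X and Y, and each rule is scored with its
#' normalized metric vector and Euclidean distance to the ideal point (see
#' [normalize_metrics()] and [ideal_distance()]).
#'
#' @param db a `transaction_db`.
#' @param frequent output of [mine_frequent_antecedents()].
#' @param min_conf minimum confidence in (0, 1]; default 1.0 (only exact
#'   rules are kept).
#' @return a `rule_set`: data.frame with columns `consequent`,
#'   list-column `antecedent`, `support_abs`, `support_rel`, `confidence`,
#'   `lift`, `p_value`, `m_support`, `m_confidence`, `m_lift`, `m_p`,
#'   `distance`.
#' @export
derive_rules <- function(db, frequent, min_conf = 1.0) {
  stopifnot(inherits(db, "transaction_db"),
            min_conf > 0, min_conf <= 1)
  N <- db$N
  pw_counts <- item_counts(db, "PATHWAY")
  pathways <- sort(names(pw_counts))

  cols <- list(consequent = character(), antecedent = list(),
               support_abs = integer(), support_rel = numeric(),
               confidence = numeric(), lift = numeric(),
               p_value = numeric())
  if (length(pathways) && nrow(frequent)) {
    # incidence of pathway items over transactions
    P <- vapply(pathways,
                function(it) vapply(db$transactions,
                                    function(tx) it %in% tx, logical(1)),
                logical(N))
    P <- matrix(P, nrow = N, dimnames = list(NULL, pathways))
    for (r in seq_len(nrow(frequent))) {
      X <- frequent$items[[r]]
      sX <- frequent$support_abs[r]
      rows <- vapply(db$transactions, function(tx) all(X %in% tx), logical(1))
      sXY <- colSums(P[rows, , drop = FALSE])
      for (y in pathways[sXY > 0]) {
        a <- sXY[[y]]
        conf <- a / sX
        if (conf < min_conf - 1e-12) next
        sY <- pw_counts[[y]]
        lift <- conf * N / sY
        p <- g_test_p_value(a = a, b = sX - a, c = sY - a,
                            d = N - sX - sY + a)
        cols$consequent <- c(cols$consequent, y)
        cols$antecedent <- c(cols$antecedent, list(X))
        cols$support_abs <- c(cols$support_abs, sX)
        cols$support_rel <- c(cols$support_rel, sX / N)
        cols$confidence <- c(cols$confidence, conf)
        cols$lift <- c(cols$lift, lift)
        cols$p_value <- c(cols$p_value, p)
      }
    }
  }
  rules <- data.frame(consequent = cols$consequent,
                      support_abs = cols$support_abs,
                      support_rel = cols$support_rel,
                      confidence = cols$confidence,
                      lift = cols$lift, p_value = cols$p_value,
                      stringsAsFactors = FALSE)
  rules$antecedent <- cols$antecedent
  rules <- rules[, c("consequent", "antecedent", "support_abs",
                     "support_rel", "confidence", "lift", "p_value")]
  rules <- score_rules(rules, N)
  # deterministic order: consequent, then antecedent key
  ord <- order(rules$consequent, antecedent_keys(rules), method = "radix")
  rules <- rules[ord, , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("rule_set", "data.frame")
  rules
}

antecedent_keys <- function(rules) {
  vapply(rules$antecedent, function(x) paste(sort(x), collapse = "\r"), "")
}

#' Write / read a mined-rule TSV dump
#'
#' Columns: `consequent`, `antecedent` (`";"`-joined canonical items),
#' `support_abs`, `support_rel`, `confidence`, `lift`, `p_value`.
#'
#' @param rules a `rule_set`.
#' @param path file path.
#' @return `write_rules_tsv()` returns `path` invisibly; `read_rules_tsv()`
#'   returns a `rule_set` (re-scored from the raw metric columns).
#' @export
write_rules_tsv <- function(rules, path) {
  df <- data.frame(
    consequent = rules$consequent,
    antecedent = vapply(rules$antecedent, paste, "", collapse = ";"),
    support_abs = rules$support_abs,
    support_rel = fmt_num(rules$support_rel),
    confidence = fmt_num(rules$confidence),
    lift = fmt_num(rules$lift),
    p_value = fmt_num(rules$p_value),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @param N transaction count used to re-normalise the metric vector.
#' @export
read_rules_tsv <- function(path, N) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character")
  rules <- data.frame(consequent = df$consequent,
                      support_abs = as.integer(df$support_abs),
                      support_rel = as.numeric(df$support_rel),
                      confidence = as.numeric(df$confidence),
                      lift = as.numeric(df$lift),
                      p_value = as.numeric(df$p_value),
                      stringsAsFactors = FALSE)
  rules$antecedent <- lapply(strsplit(df$antecedent, ";", fixed = TRUE),
                             trimws)
  rules <- rules[, c("consequent", "antecedent", "support_abs",
                     "support_rel", "confidence", "lift", "p_value")]
  rules <- score_rules(rules, N)
  class(rules) <- c("rule_set", "data.frame")
  rules
}

# shortest decimal text that round-trips the double
fmt_num <- function(x) vapply(x, function(v) format(v, digits = 17), "")
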