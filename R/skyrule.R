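#' Comparability and dominance between rules
#'
#' Two rules are *comparable* when they predict the same consequent and
#' their antecedents share at least one item; comparability is the
#' semantic precondition for dominance. Rule 1 *dominates* rule 2 when its
#' normalised metric vector is componentwise greater than or equal to rule
#' 2's with strict inequality in at least one component (the standard
#' Pareto convention).
#'
#' @param rules a `rule_set` (see [derive_rules()]).
#' @param i,j row indices into `rules`.
#' @return logical.
#' @export
rules_comparable <- function(rules, i, j) {
  rules$consequent[i] == rules$consequent[j] &&
    length(intersect(rules$antecedent[[i]], rules$antecedent[[j]])) > 0L
}

#' @rdname rules_comparable
#' @export
rule_dominates <- function(rules, i, j) {
  mi <- metric_matrix(rules)[i, ]
  mj <- metric_matrix(rules)[j, ]
  all(mi >= mj) && any(mi > mj)
}

metric_matrix <- function(rules) {
  as.matrix(rules[, c("m_support", "m_confidence", "m_lift", "m_p")])
}

#' Select representative rules (skyline filtering)
#'
#' Two-stage skyline selection so that only undominated and incomparable
#' rules are left. First, every rule dominated by some comparable rule is
#' removed (dominance is only meaningful between comparable rules).
#' Second, representatives are drawn iteratively: the surviving candidate
#' closest to the normalised ideal point is selected -- it is provably
#' undominated within its comparability class -- and every remaining
#' candidate comparable to it is discarded, until no candidates remain.
#' The representatives are pairwise incomparable and each is undominated
#' by any input rule comparable to it.
#'
#' The dominance pre-filter is required for that guarantee: comparability
#' is not transitive, so the bare iterative procedure could otherwise
#' select a rule whose comparable dominator was discarded in an earlier
#' round.
#'
#' Ties on distance are broken lexicographically on the consequent string,
#' then on the sorted antecedent items, making the selection invariant to
#' input order.
#'
#' @param rules a `rule_set` with metrics and distances populated.
#' @return the selected subset, a `rule_set`, in selection order
#'   (ascending distance).
#' @export
select_representatives <- function(rules) {
  stopifnot(inherits(rules, "data.frame"))
  n <- nrow(rules)
  if (n == 0L) return(rules)
  if (any(!is.finite(rules$distance)))
    stop("rule distances must be finite")
  keys <- antecedent_keys(rules)
  if (anyDuplicated(paste(rules$consequent, keys, sep = "\r")))
    stop("candidate set contains duplicate rules")
  M <- metric_matrix(rules)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && rules_comparable(rules, i, j) &&
          all(M[j, ] >= M[i, ]) && any(M[j, ] > M[i, ])) {
        alive[i] <- FALSE
        break
      }
    }
  }
  ord <- order(rules$distance, rules$consequent, keys, method = "radix")
  selected <- integer()
  for (i in ord) {
    if (!alive[i]) next
    selected <- c(selected, i)
    for (j in which(alive)) {
      if (rules_comparable(rules, i, j)) alive[j] <- FALSE
    }
  }
  out <- rules[selected, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(rules)
  out
}
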