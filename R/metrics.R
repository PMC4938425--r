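#' Rule-quality metrics
#'
#' Confidence and lift of a class-association rule X => Y over a
#' transaction database: `conf = supp(X u Y) / supp(X)` and
#' `lift = conf / (supp(Y)/N)`, where N is the number of transactions. A
#' lift of 1 means antecedent and consequent are statistically independent.
#'
#' @param db a `transaction_db`.
#' @param X character vector of attribute items (the antecedent).
#' @param Y single pathway item (the consequent).
#' @return a ratio.
#' @export
rule_confidence <- function(db, X, Y) {
  sX <- itemset_support(db, X)
  if (sX == 0L) stop("confidence undefined: antecedent has zero support")
  itemset_support(db, c(X, Y)) / sX
}

#' @rdname rule_confidence
#' @export
rule_lift <- function(db, X, Y) {
  sY <- itemset_support(db, Y)
  if (sY == 0L) stop("lift undefined: consequent has zero support")
  rule_confidence(db, X, Y) / (sY / db$N)
}

#' G-test p-value for a 2x2 contingency table
#'
#' Likelihood-ratio test of independence between antecedent and consequent
#' occurrence. The statistic is `G = 2 * sum(O * ln(O/E))` over the four
#' cells, with expectations E from the margins under independence and the
#' convention `0 * ln(0) = 0`. Under independence G is asymptotically
#' chi-square distributed with 1 degree of freedom; the p-value is the
#' upper-tail probability. A table with a zero row or column margin
#' carries no evidence of association and yields p = 1.
#'
#' @param a count of transactions with both X and Y.
#' @param b count with X but not Y.
#' @param c count with Y but not X.
#' @param d count with neither.
#' @return p-value in `[0, 1]`.
#' @examples
#' g_test_p_value(5, 5, 5, 5)    # exact independence: p = 1
#' g_test_p_value(10, 0, 0, 10)  # G = 40*log(2), p ~ 1.4e-7
#' @export
g_test_p_value <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  N <- a + b + c + d
  if (N == 0) stop("empty contingency table")
  O <- c(a, b, c, d)
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) return(1)
  # O/E written as O*N/(row*col): exact 1 (hence exact G = 0) at integer
  # independence, where E = row*col/N would round
  margins <- c(row1 * col1, row1 * col2, row2 * col1, row2 * col2)
  terms <- ifelse(O > 0, O * log(O * N / margins), 0)
  G <- 2 * sum(terms)
  G <- max(G, 0)  # guard tiny negative rounding near independence
  stats::pchisq(G, df = 1, lower.tail = FALSE)
}

#' Normalised metric vector and distance to the ideal point
#'
#' Each rule is scored on the unit hypercube by the vector
#' `(support_rel, confidence, lift/N, 1 - p_value)`, every component
#' clamped to `[0, 1]`. The ideal rule scores 1.0 on all four metrics;
#' rule quality is summarised by the Euclidean distance to that ideal
#' point, `sqrt(sum((1 - m_k)^2))`, which ranges from 0 (ideal) to 2.
#'
#' The lift normaliser is N: for a confidence-1 rule,
#' `lift = N / supp(Y)` and the normalised lift is `1 / supp_abs(Y)`, the
#' reciprocal of the consequent's absolute support.
#'
#' @param support_rel relative antecedent support in `[0, 1]`.
#' @param confidence rule confidence in `[0, 1]`.
#' @param lift raw lift (> 0).
#' @param p_value G-test p-value in `[0, 1]`.
#' @param N transaction count (the lift normaliser).
#' @return `normalize_metrics()` returns a numeric vector
#'   `(m_support, m_confidence, m_lift, m_p)`.
#' @export
normalize_metrics <- function(support_rel, confidence, lift, p_value, N) {
  clamp01(c(m_support = support_rel, m_confidence = confidence,
            m_lift = lift / N, m_p = 1 - p_value))
}

#' @rdname normalize_metrics
#' @param m numeric vector of four normalised metric components.
#' @return `ideal_distance()` returns the distance in `[0, 2]`.
#' @examples
#' ideal_distance(c(1, 1, 1, 1))  # 0
#' ideal_distance(c(0, 0, 0, 0))  # 2
#' @export
ideal_distance <- function(m) {
  stopifnot(is.numeric(m), length(m) == 4L, all(m >= 0), all(m <= 1))
  sqrt(sum((1 - m)^2))
}

# attach m_* columns and distance to a raw rule data.frame
score_rules <- function(rules, N) {
  n <- nrow(rules)
  m <- matrix(0, nrow = n, ncol = 4,
              dimnames = list(NULL,
                              c("m_support", "m_confidence", "m_lift", "m_p")))
  if (n) {
    m[, "m_support"] <- clamp01(rules$support_rel)
    m[, "m_confidence"] <- clamp01(rules$confidence)
    m[, "m_lift"] <- clamp01(rules$lift / N)
    m[, "m_p"] <- clamp01(1 - rules$p_value)
  }
  rules$m_support <- m[, "m_support"]
  rules$m_confidence <- m[, "m_confidence"]
  rules$m_lift <- m[, "m_lift"]
  rules$m_p <- m[, "m_p"]
  rules$distance <- if (n) sqrt(rowSums((1 - m)^2)) else numeric()
  rules
}

clamp01 <- function(x) pmin(1, pmax(0, x))
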