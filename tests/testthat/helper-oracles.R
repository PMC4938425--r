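# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# random transaction database over small item pools
random_db <- function(seed, n_tx = 30, n_attr = 8, n_pw = 3,
                      attr_rate = 0.3, pw_rate = 0.3) {
  set.seed(seed)
  attrs <- c(sprintf("IPR:IPR%06d", seq_len(ceiling(n_attr / 2))),
             sprintf("TAXON:Taxon%d", seq_len(floor(n_attr / 2))))
  pws <- sprintf("PATHWAY:Pathway %d", seq_len(n_pw))
  tx <- lapply(seq_len(n_tx), function(i) {
    c(attrs[runif(length(attrs)) < attr_rate],
      pws[runif(length(pws)) < pw_rate])
  })
  names(tx) <- sprintf("ACC%04d", seq_len(n_tx))
  structure(list(transactions = tx, N = n_tx), class = "transaction_db")
}

# plain scan support count
oracle_support <- function(db, items) {
  if (!length(items)) return(db$N)
  sum(vapply(db$transactions, function(t) all(items %in% t), logical(1)))
}

# exhaustive power-set enumeration of frequent attribute itemsets
oracle_frequent <- function(db, min_support, max_size) {
  univ <- sort(unique(unlist(db$transactions, use.names = FALSE)))
  univ <- univ[!startsWith(univ, "PATHWAY:")]
  out <- list()
  for (k in seq_len(min(max_size, length(univ)))) {
    for (comb in utils::combn(univ, k, simplify = FALSE)) {
      s <- oracle_support(db, comb)
      if (s >= min_support)
        out[[length(out) + 1L]] <- list(items = sort(comb), support = s)
    }
  }
  out
}

# exhaustive (antecedent, pathway) rule enumeration
oracle_rules <- function(db, min_support, max_size, min_conf) {
  freq <- oracle_frequent(db, min_support, max_size)
  pws <- sort(unique(unlist(db$transactions, use.names = FALSE)))
  pws <- pws[startsWith(pws, "PATHWAY:")]
  out <- list()
  for (f in freq) {
    for (y in pws) {
      sxy <- oracle_support(db, c(f$items, y))
      if (sxy == 0) next
      conf <- sxy / f$support
      if (conf >= min_conf - 1e-12)
        out[[length(out) + 1L]] <- list(antecedent = f$items, consequent = y,
                                        support = f$support,
                                        confidence = conf)
    }
  }
  out
}

rule_key <- function(antecedent, consequent) {
  paste(consequent, paste(sort(antecedent), collapse = ";"), sep = " <= ")
}

# independent log-likelihood-ratio G-test via the entropy decomposition
# G = 2*(sum O ln O - sum row ln row - sum col ln col + N ln N)
oracle_g_p <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  if (a * N == r1 * c1) return(1)  # exact independence: G is exactly 0
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  G <- 2 * (sum(xlx(c(a, b, c, d))) - xlx(r1) - xlx(r2) - xlx(c1) -
              xlx(c2) + xlx(N))
  pchisq(max(G, 0), df = 1, lower.tail = FALSE)
}

# independent two-stage skyline selection over a plain list of rules;
# each rule: list(antecedent, consequent, m (length-4), distance)
oracle_skyline <- function(rules) {
  comp <- function(r, s) r$consequent == s$consequent &&
    length(intersect(r$antecedent, s$antecedent)) > 0
  dominated <- vapply(rules, function(r) {
    any(vapply(rules, function(s) {
      comp(r, s) && all(s$m >= r$m) && any(s$m > r$m)
    }, logical(1)))
  }, logical(1))
  chosen <- list()
  pool <- rules[!dominated]
  while (length(pool)) {
    ds <- vapply(pool, function(r) r$distance, numeric(1))
    cs <- vapply(pool, function(r) r$consequent, "")
    as <- vapply(pool, function(r) paste(sort(r$antecedent),
                                         collapse = "\r"), "")
    i <- order(ds, cs, as, method = "radix")[1]
    pick <- pool[[i]]
    chosen[[length(chosen) + 1L]] <- pick
    pool <- Filter(function(r) !comp(r, pick), pool)
  }
  chosen
}

# exhaustive pairwise AUC: (concordant + half ties) / (pos * neg)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# random candidate rule_set for skyline tests
random_rule_set <- function(seed, n_rules = 20, n_items = 6, n_cons = 3) {
  set.seed(seed)
  items <- sprintf("IPR:IPR%06d", seq_len(n_items))
  cons <- sprintf("PATHWAY:Pathway %d", seq_len(n_cons))
  seen <- character()
  rows <- list()
  while (length(rows) < n_rules) {
    ante <- sort(sample(items, sample(1:3, 1)))
    y <- sample(cons, 1)
    k <- rule_key(ante, y)
    if (k %in% seen) next
    seen <- c(seen, k)
    m <- round(runif(4), 2)
    rows[[length(rows) + 1L]] <- list(antecedent = ante, consequent = y,
                                      m = m)
  }
  rules <- data.frame(
    consequent = vapply(rows, function(r) r$consequent, ""),
    support_abs = 1L, support_rel = vapply(rows, function(r) r$m[1], 0),
    confidence = vapply(rows, function(r) r$m[2], 0),
    lift = 1, p_value = vapply(rows, function(r) 1 - r$m[4], 0),
    m_support = vapply(rows, function(r) r$m[1], 0),
    m_confidence = vapply(rows, function(r) r$m[2], 0),
    m_lift = vapply(rows, function(r) r$m[3], 0),
    m_p = vapply(rows, function(r) r$m[4], 0),
    stringsAsFactors = FALSE)
  rules$antecedent <- lapply(rows, function(r) r$antecedent)
  m <- as.matrix(rules[, c("m_support", "m_confidence", "m_lift", "m_p")])
  rules$distance <- sqrt(rowSums((1 - m)^2))
  class(rules) <- c("rule_set", "data.frame")
  rules
}

# rule_set -> plain list form used by oracle_skyline
as_oracle_rules <- function(rules) {
  lapply(seq_len(nrow(rules)), function(i) {
    list(antecedent = rules$antecedent[[i]],
         consequent = rules$consequent[i],
         m = unlist(rules[i, c("m_support", "m_confidence", "m_lift",
                               "m_p")]),
         distance = rules$distance[i])
  })
}

# concatenate two rule_sets (keeping the list-column)
rbind_rules <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("rule_set", "data.frame")
  out
}
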