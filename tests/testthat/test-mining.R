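test_that("itemset support matches a brute-force scan, supp(empty) = N", {
  db <- random_db(11, n_tx = 5, n_attr = 4, n_pw = 2)
  expect_equal(itemset_support(db, character()), 5L)
  items <- unique(unlist(db$transactions))
  for (it in items)
    expect_equal(itemset_support(db, it), oracle_support(db, it))
  # anti-monotonicity checked exhaustively on tiny DBs
  for (seed in 1:5) {
    db2 <- random_db(seed, n_tx = 8, n_attr = 4, n_pw = 1)
    univ <- sort(unique(unlist(db2$transactions)))
    subsets <- unlist(lapply(1:min(3, length(univ)), function(k)
      utils::combn(univ, k, simplify = FALSE)), recursive = FALSE)
    for (s in subsets) {
      supp_s <- itemset_support(db2, s)
      for (extra in setdiff(univ, s))
        expect_lte(itemset_support(db2, c(s, extra)), supp_s)
    }
  }
})

test_that("frequent antecedent mining equals exhaustive enumeration", {
  for (seed in c(1, 7, 42, 99)) {
    db <- random_db(seed, n_tx = 50, n_attr = 10, n_pw = 3,
                    attr_rate = 0.35)
    for (ms in c(5, 12, 20)) {
      mined <- mine_frequent_antecedents(db, min_support_abs = ms,
                                         max_size = 4)
      brute <- oracle_frequent(db, ms, 4)
      mined_keys <- vapply(mined$items, paste, "", collapse = ";")
      brute_keys <- vapply(brute, function(f) paste(f$items,
                                                    collapse = ";"), "")
      expect_setequal(mined_keys, brute_keys)
      sup <- setNames(vapply(brute, function(f) f$support, 0), brute_keys)
      expect_equal(mined$support_abs, unname(sup[mined_keys]))
    }
  }
})

test_that("mining respects thresholds, candidate namespaces and determinism", {
  # boundary: item occurring exactly at threshold is reported
  tx <- c(rep(list(c("IPR:IPR000001", "PATHWAY:P")), 20),
          rep(list(c("TAXON:Other", "PATHWAY:P")), 5))
  names(tx) <- sprintf("A%02d", seq_along(tx))
  db <- structure(list(transactions = tx, N = length(tx)),
                  class = "transaction_db")
  got <- mine_frequent_antecedents(db, 20, 4)
  expect_equal(got$items, list("IPR:IPR000001"))
  expect_equal(got$support_abs, 20L)
  # pathway items never become candidates even when frequent
  expect_false(any(grepl("^PATHWAY:",
                         unlist(mine_frequent_antecedents(db, 1, 4)$items))))
  # empty candidate universe
  tx2 <- rep(list("PATHWAY:P"), 5)
  names(tx2) <- paste0("B", 1:5)
  db2 <- structure(list(transactions = tx2, N = 5L),
                   class = "transaction_db")
  expect_equal(nrow(mine_frequent_antecedents(db2, 1, 3)), 0L)
  # empty DB errors
  db0 <- structure(list(transactions = list(), N = 0L),
                   class = "transaction_db")
  expect_error(mine_frequent_antecedents(db0, 1, 1), "empty")
  # invariance to transaction order
  db3 <- random_db(5, n_tx = 40, n_attr = 8)
  perm <- sample(seq_len(db3$N))
  db3p <- structure(list(transactions = db3$transactions[perm], N = db3$N),
                    class = "transaction_db")
  expect_equal(mine_frequent_antecedents(db3, 8, 3),
               mine_frequent_antecedents(db3p, 8, 3))
})

test_that("rule derivation equals brute-force enumeration and obeys min_conf", {
  for (seed in c(3, 21, 77)) {
    db <- random_db(seed, n_tx = 40, n_attr = 8, n_pw = 3, pw_rate = 0.4)
    for (mc in c(1.0, 0.7)) {
      freq <- mine_frequent_antecedents(db, 5, 3)
      rules <- derive_rules(db, freq, min_conf = mc)
      brute <- oracle_rules(db, 5, 3, mc)
      expect_setequal(
        mapply(rule_key, rules$antecedent, rules$consequent),
        vapply(brute, function(r) rule_key(r$antecedent, r$consequent), ""))
      expect_true(all(rules$confidence >= mc - 1e-12))
      # support fields use the antecedent-support convention
      for (i in seq_len(nrow(rules))) {
        expect_equal(rules$support_abs[i],
                     oracle_support(db, rules$antecedent[[i]]))
      }
      expect_equal(rules$support_rel, rules$support_abs / db$N)
    }
  }
})

test_that("exact-confidence rules have supp(XuY) == supp(X) and lift N/supp(Y)", {
  db <- random_db(31, n_tx = 40, n_attr = 6, n_pw = 2, pw_rate = 0.5)
  rules <- derive_rules(db, mine_frequent_antecedents(db, 4, 3),
                        min_conf = 1.0)
  expect_gt(nrow(rules), 0)
  for (i in seq_len(nrow(rules))) {
    X <- rules$antecedent[[i]]; Y <- rules$consequent[i]
    expect_identical(oracle_support(db, c(X, Y)), oracle_support(db, X))
    sY <- oracle_support(db, Y)
    expect_equal(rules$lift[i], db$N / sY)
    expect_equal(rules$m_lift[i], 1 / sY)
  }
})

test_that("confidence threshold boundary: 19/20 is rejected at min_conf 1", {
  tx <- c(rep(list(c("IPR:IPR000001", "PATHWAY:Y")), 19),
          list(c("IPR:IPR000001", "PATHWAY:Z")),
          rep(list(c("TAXON:Pad", "PATHWAY:Y")), 10))
  names(tx) <- sprintf("T%02d", seq_along(tx))
  db <- structure(list(transactions = tx, N = length(tx)),
                  class = "transaction_db")
  freq <- mine_frequent_antecedents(db, 20, 2)
  rules <- derive_rules(db, freq, min_conf = 1.0)
  expect_false("PATHWAY:Y" %in%
                 rules$consequent[vapply(rules$antecedent, identical,
                                         TRUE, "IPR:IPR000001")])
  rules95 <- derive_rules(db, freq, min_conf = 0.95)
  idx <- which(rules95$consequent == "PATHWAY:Y" &
                 vapply(rules95$antecedent, identical, TRUE,
                        "IPR:IPR000001"))
  expect_length(idx, 1L)
  expect_equal(rules95$confidence[idx], 0.95)
})

test_that("mined-rule TSV dump round-trips", {
  db <- random_db(8, n_tx = 40, n_attr = 6, n_pw = 2, pw_rate = 0.5)
  rules <- derive_rules(db, mine_frequent_antecedents(db, 4, 3), 0.8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules_tsv(rules, path)
  back <- read_rules_tsv(path, N = db$N)
  expect_equal(back$consequent, rules$consequent)
  expect_equal(back$antecedent, rules$antecedent)
  expect_equal(back$support_abs, rules$support_abs)
  expect_equal(back$confidence, rules$confidence)
  expect_equal(back$lift, rules$lift)
  expect_equal(back$p_value, rules$p_value)
  expect_equal(back$distance, rules$distance)
})
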