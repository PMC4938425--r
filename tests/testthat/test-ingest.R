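entry_with <- function(acc, pathways) {
  protein_entry(acc, lineage = c("Bacteria", "Proteobacteria"),
                interpro = "IPR000001", pathways = pathways)
}

test_that("evidence filter keeps manual assertions per annotation", {
  e1 <- entry_with("A1", list(pathway_annotation("P one", "ECO:0000269")))
  e2 <- entry_with("A2", list(pathway_annotation("P two", "ECO:0000501")))
  e3 <- entry_with("A3", list(
    pathway_annotation("P one", "ECO:0000250"),
    pathway_annotation("P two", "ECO:0000501")))
  out <- filter_by_evidence(list(e1, e2, e3))
  expect_equal(vapply(out, function(e) e$accession, ""), c("A1", "A3"))
  expect_identical(out[[1]]$pathways, e1$pathways)   # retained unchanged
  expect_length(out[[2]]$pathways, 1L)               # only the manual one
  expect_equal(render_pathway_label(out[[2]]$pathways[[1]]$label), "P one")
  # application mode keeps unannotated entries
  out2 <- filter_by_evidence(list(e2), drop_unannotated = FALSE)
  expect_length(out2, 1L)
  expect_length(out2[[1]]$pathways, 0L)
  # empty output is permitted
  expect_length(filter_by_evidence(list(e2)), 0L)
})

test_that("worked-example entries map to the expected 14-item transactions", {
  db <- build_transactions(worked_example_entries())
  expect_equal(db$N, 2L)
  q8 <- db$transactions[["Q8TRZ4"]]
  expect_length(q8, 14L)
  expect_setequal(q8, c(
    "PATHWAY:One-carbon metabolism; methanogenesis from acetate",
    paste0("TAXON:", c("Archaea", "Euryarchaeota", "Methanomicrobia",
                       "Methanosarcinales", "Methanosarcinaceae",
                       "Methanosarcina")),
    paste0("IPR:", c("IPR017896", "IPR017900", "IPR004460", "IPR004137",
                     "IPR009051", "IPR011254", "IPR016099"))))
  p18 <- db$transactions[["P18335"]]
  expect_length(p18, 14L)
  expect_equal(sum(startsWith(p18, "PATHWAY:")), 2L)
  expect_true(paste0("PATHWAY:Amino-acid biosynthesis; L-arginine ",
                     "biosynthesis; N(2)-acetyl-L-ornithine from ",
                     "L-glutamate: step 4/4") %in% p18)
})

test_that("transaction building rejects duplicates, keeps attribute-free entries", {
  e <- worked_example_entries()
  expect_error(build_transactions(c(e, e[1])), "duplicate accession")
  bare <- protein_entry("B1",
                        pathways = list(pathway_annotation("P", "ECO:0000269")))
  db <- build_transactions(list(e[[1]], bare))
  expect_equal(db$N, 2L)  # counts in N even with no attributes
  expect_equal(db$transactions[["B1"]], "PATHWAY:P")
  # entry with no InterPro ids: TAXON + PATHWAY items only
  no_ipr <- protein_entry("C1", lineage = "Bacteria",
                          pathways = list(pathway_annotation("P", "ECO:0000269")))
  tx <- build_transactions(list(no_ipr))$transactions[["C1"]]
  expect_setequal(tx, c("TAXON:Bacteria", "PATHWAY:P"))
})

test_that("reference pathway set applies the at-least-min-count boundary", {
  mk <- function(n, label) lapply(seq_len(n), function(i)
    entry_with(paste0(label, i),
               list(pathway_annotation(label, "ECO:0000269"))))
  db <- build_transactions(c(mk(20, "Exactly twenty"), mk(19, "Nineteen")))
  ref <- reference_pathways(db, 20)
  expect_identical(ref, "PATHWAY:Exactly twenty")
  # brute-force count oracle on a randomized synthetic DB
  db2 <- random_db(401, n_tx = 200, n_attr = 6, n_pw = 5, pw_rate = 0.12)
  for (mc in c(1, 10, 20, 35)) {
    pws <- unique(unlist(db2$transactions))
    pws <- sort(pws[startsWith(pws, "PATHWAY:")])
    brute <- pws[vapply(pws, function(p) oracle_support(db2, p),
                        0) >= mc]
    expect_identical(reference_pathways(db2, mc), brute)
  }
  # monotone non-increasing in min_count
  sizes <- vapply(1:40, function(mc) length(reference_pathways(db2, mc)), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("entries TSV dialect round-trips, evidence braces optional", {
  path <- withr::local_tempfile(fileext = ".tsv")
  entries <- c(worked_example_entries(),
               list(protein_entry("NOEV1", lineage = "Bacteria",
                                  interpro = "IPR000007",
                                  pathways = list(pathway_annotation("P; Q")))))
  write_entries_tsv(entries, path)
  back <- read_entries_tsv(path)
  expect_equal(length(back), 3L)
  for (i in seq_along(entries)) {
    expect_equal(back[[i]]$accession, entries[[i]]$accession)
    expect_equal(back[[i]]$lineage, entries[[i]]$lineage)
    expect_equal(back[[i]]$interpro, entries[[i]]$interpro)
    expect_equal(
      lapply(back[[i]]$pathways,
             function(p) list(render_pathway_label(p$label), p$evidence)),
      lapply(entries[[i]]$pathways,
             function(p) list(render_pathway_label(p$label), p$evidence)))
  }
  # identical transactions either way
  expect_equal(build_transactions(back), build_transactions(entries))
})

test_that("UniProt flat-file subset parser reads AC/OC/DR/CC blocks", {
  txt <- c(
    "ID   ARGD_ECOLI              Reviewed;         406 AA.",
    "AC   P18335; Q2M6Y1;",
    "OC   Bacteria; Proteobacteria; Gammaproteobacteria; Enterobacteriales;",
    "OC   Enterobacteriaceae; Escherichia.",
    "DR   InterPro; IPR017652; Ace_aminotran_succ.",
    "DR   InterPro; IPR004636; AcOrn/SuccOrn_fam.",
    "DR   Pfam; PF00202; Aminotran_3; 1.",
    "CC   -!- FUNCTION: Catalyzes the transamination step.",
    "CC   -!- PATHWAY: Amino-acid biosynthesis; L-arginine biosynthesis;",
    "CC       N(2)-acetyl-L-ornithine from L-glutamate: step 4/4.",
    "CC       {ECO:0000269|PubMed:2198024, ECO:0000305}.",
    "CC   -!- PATHWAY: Amino-acid biosynthesis; L-lysine biosynthesis via",
    "CC       DAP pathway; LL-2, 6-diaminopimelate from",
    "CC       (S)-tetrahydrodipicolinate (succinylase route): step 2/3.",
    "CC       {ECO:0000250}.",
    "//",
    "ID   NOPW_TEST               Unreviewed;       100 AA.",
    "AC   X99999;",
    "OC   Bacteria.",
    "//")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, path)
  entries <- read_uniprot_txt(path)
  expect_length(entries, 2L)
  e <- entries[[1]]
  expect_equal(e$accession, "P18335")
  expect_equal(e$lineage[1], "Bacteria")
  expect_length(e$lineage, 6L)
  expect_setequal(e$interpro, c("IPR017652", "IPR004636"))
  expect_length(e$pathways, 2L)
  expect_equal(
    render_pathway_label(e$pathways[[1]]$label),
    paste0("Amino-acid biosynthesis; L-arginine biosynthesis; ",
           "N(2)-acetyl-L-ornithine from L-glutamate: step 4/4"))
  # source cross-refs after "|" ignored, both codes captured
  expect_setequal(e$pathways[[1]]$evidence, c("ECO:0000269", "ECO:0000305"))
  expect_equal(e$pathways[[2]]$evidence, "ECO:0000250")
  expect_equal(entries[[2]]$accession, "X99999")
  expect_length(entries[[2]]$pathways, 0L)
})
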