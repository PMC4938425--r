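#' Specify a synthetic entry collection with planted rule structure
#'
#' The generator emulates the statistical structure the mining stage
#' assumes: a set of *planted rules* (attribute itemset => pathway) whose
#' carrier entries hold the full antecedent, background entries carrying
#' only lineage and noise signatures, and optional multi-pathway
#' annotations. A planted rule with contamination 0 is recoverable at
#' confidence exactly 1; contamination `c` leaves a fraction `c` of the
#' carriers without the pathway annotation (they receive a decoy pathway
#' instead so that the learning-mode evidence filter does not remove them
#' and restore the confidence to 1).
#'
#' @param n_entries total number of entries to generate.
#' @param planted list of planted rules from [planted_rule()].
#' @param n_noise_taxa number of distinct background leaf clades (0 means
#'   every entry shares one fixed lineage).
#' @param n_noise_ipr size of the background InterPro vocabulary; noise
#'   ids are drawn from a range disjoint from any sensible planted
#'   antecedent (`IPR9xxxxx`).
#' @param noise_item_rate per-item inclusion probability of each noise
#'   InterPro id, in `[0, 1]`.
#' @param multi_pathway_rate probability that a pathway-annotated carrier
#'   gains a second, decoy pathway annotation.
#' @param lineage_depth number of lineage nodes per entry (default 6).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_entries, planted = list(), n_noise_taxa = 0L,
                           n_noise_ipr = 0L, noise_item_rate = 0,
                           multi_pathway_rate = 0, lineage_depth = 6L,
                           seed = 1L) {
  stopifnot(n_entries >= 1L, n_noise_taxa >= 0L, n_noise_ipr >= 0L,
            noise_item_rate >= 0, noise_item_rate <= 1,
            multi_pathway_rate >= 0, multi_pathway_rate <= 1,
            lineage_depth >= 1L)
  carriers <- sum(vapply(planted, function(p) p$carrier_count, integer(1)))
  if (carriers > n_entries)
    stop("infeasible spec: planted carrier counts (", carriers,
         ") exceed n_entries (", n_entries, ")")
  structure(list(n_entries = as.integer(n_entries), planted = planted,
                 n_noise_taxa = as.integer(n_noise_taxa),
                 n_noise_ipr = as.integer(n_noise_ipr),
                 noise_item_rate = noise_item_rate,
                 multi_pathway_rate = multi_pathway_rate,
                 lineage_depth = as.integer(lineage_depth),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param antecedent character vector of attribute items (canonical
#'   `IPR:`/`TAXON:` form). `TAXON:` members are appended to each
#'   carrier's lineage.
#' @param pathway pathway label string (without namespace prefix).
#' @param carrier_count number of entries carrying the full antecedent.
#' @param contamination fraction of carriers *not* annotated with the
#'   pathway, in `[0, 1)`; 0 plants the rule at confidence exactly 1.
#' @export
planted_rule <- function(antecedent, pathway, carrier_count,
                         contamination = 0) {
  stopifnot(length(antecedent) >= 1L, carrier_count >= 1L,
            contamination >= 0, contamination < 1)
  ns <- item_namespace(antecedent)
  if (!all(ns %in% c("IPR", "TAXON")))
    stop("planted antecedents may contain only IPR:/TAXON: items")
  list(antecedent = unique(antecedent), pathway = pathway,
       carrier_count = as.integer(carrier_count),
       contamination = contamination)
}

#' Generate synthetic protein entries
#'
#' Produces exactly `spec$n_entries` entries. For each planted rule,
#' `carrier_count` entries carry the full antecedent, of which
#' `ceiling((1 - contamination) * carrier_count)` are annotated with the
#' planted pathway (evidence `ECO:0000269`); contaminated carriers are
#' annotated with a decoy pathway instead. Background (non-carrier)
#' entries carry a lineage and independent noise InterPro items at
#' `noise_item_rate` and never contain a planted antecedent in full (the
#' noise vocabulary is disjoint from planted items by construction);
#' they carry no pathway annotation. Output is deterministic given the
#' spec seed and leaves the caller's RNG state untouched.
#'
#' @param spec a `synthetic_spec`.
#' @return list of `protein_entry` objects.
#' @export
generate_entries <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_entries
  # synthetic taxonomy: shared root chain, optional leaf clades
  base_lineage <- function(clade) {
    ranks <- c("Bacteria", "Phylum", "Class", "Order", "Family", "Genus",
               "Species", "Strain")
    depth <- spec$lineage_depth
    nodes <- ranks[seq_len(min(depth, length(ranks)))]
    if (length(nodes) < depth)
      nodes <- c(nodes, paste0("Subtaxon", seq_len(depth - length(nodes))))
    if (clade > 0L && depth >= 2L)
      nodes[-1] <- paste0(nodes[-1], "_", clade)
    nodes
  }
  clades <- if (spec$n_noise_taxa > 0L)
    sample.int(spec$n_noise_taxa, n, replace = TRUE) else rep(0L, n)

  noise_vocab <- if (spec$n_noise_ipr > 0L)
    sprintf("IPR9%05d", seq_len(spec$n_noise_ipr)) else character()
  decoys <- sprintf("Background metabolism; decoy pathway %d", 1:5)

  # disjoint carrier blocks in a random order
  idx <- sample.int(n)
  pos <- 1L
  role <- vector("list", n)  # NULL = background, else planted-rule record
  for (p in spec$planted) {
    ids <- idx[pos:(pos + p$carrier_count - 1L)]
    pos <- pos + p$carrier_count
    n_ann <- ceiling((1 - p$contamination) * p$carrier_count)
    annotated <- ids[seq_len(n_ann)]
    for (i in ids)
      role[[i]] <- list(rule = p, annotated = i %in% annotated)
  }

  entries <- vector("list", n)
  for (i in seq_len(n)) {
    lineage <- base_lineage(clades[i])
    ipr <- noise_vocab[stats::runif(length(noise_vocab)) <
                         spec$noise_item_rate]
    pathways <- list()
    r <- role[[i]]
    if (!is.null(r)) {
      ante <- r$rule$antecedent
      ipr <- unique(c(sub("^IPR:", "", ante[startsWith(ante, "IPR:")]), ipr))
      extra_taxa <- sub("^TAXON:", "", ante[startsWith(ante, "TAXON:")])
      lineage <- unique(c(lineage, extra_taxa))
      if (r$annotated) {
        pathways <- list(pathway_annotation(r$rule$pathway, "ECO:0000269"))
        if (stats::runif(1) < spec$multi_pathway_rate)
          pathways <- c(pathways,
                        list(pathway_annotation(sample(decoys, 1L),
                                                "ECO:0000269")))
      } else {
        # contaminated carrier: annotated, but not with the planted pathway
        pathways <- list(pathway_annotation(sample(decoys, 1L),
                                            "ECO:0000269"))
      }
    }
    entries[[i]] <- protein_entry(sprintf("SYN%05d", i), lineage, ipr,
                                  pathways)
  }
  entries
}

#' Worked-example entries
#'
#' Two real annotated prokaryotic proteins used throughout the
#' documentation and tests: the acetyl-CoA decarbonylase/synthase complex
#' subunit Q8TRZ4 (a methanogenic archaeon, one pathway, seven InterPro
#' signatures) and the bifunctional aminotransferase P18335 (an
#' enterobacterium, two pathway annotations with step indicators, six
#' signatures). Each maps to a 14-item transaction.
#'
#' @return list of two `protein_entry` objects.
#' @export
worked_example_entries <- function() {
  list(
    protein_entry(
      "Q8TRZ4",
      lineage = c("Archaea", "Euryarchaeota", "Methanomicrobia",
                  "Methanosarcinales", "Methanosarcinaceae",
                  "Methanosarcina"),
      interpro = c("IPR017896", "IPR017900", "IPR004460", "IPR004137",
                   "IPR009051", "IPR011254", "IPR016099"),
      pathways = list(pathway_annotation(
        "One-carbon metabolism; methanogenesis from acetate",
        "ECO:0000269"))),
    protein_entry(
      "P18335",
      lineage = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                  "Enterobacteriales", "Enterobacteriaceae", "Escherichia"),
      interpro = c("IPR017652", "IPR004636", "IPR005814", "IPR015424",
                   "IPR015421", "IPR015422"),
      pathways = list(
        pathway_annotation(
          paste0("Amino-acid biosynthesis; L-arginine biosynthesis; ",
                 "N(2)-acetyl-L-ornithine from L-glutamate: step 4/4"),
          "ECO:0000269"),
        pathway_annotation(
          paste0("Amino-acid biosynthesis; L-lysine biosynthesis via DAP ",
                 "pathway; LL-2, 6-diaminopimelate from ",
                 "(S)-tetrahydrodipicolinate (succinylase route): step 2/3"),
          "ECO:0000269")))
  )
}
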