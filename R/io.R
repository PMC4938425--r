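#' Read and write the entries TSV dialect
#'
#' The primary interchange format is a UTF-8, tab-separated file with a
#' header row and columns:
#' \describe{
#'   \item{accession}{entry accession, unique within the file}
#'   \item{lineage}{`";"`-separated taxon names, most general first (may be
#'     empty)}
#'   \item{interpro}{`";"`-separated InterPro ids (may be empty)}
#'   \item{pathways}{`"|"`-separated records; each record is
#'     `<pathway string>{ECO:xxxxxxx;ECO:...}` -- the evidence braces are
#'     optional in application mode}
#' }
#'
#' @param path file path.
#' @return `read_entries_tsv()` returns a list of `protein_entry` objects.
#' @export
read_entries_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), encoding = "UTF-8")
  need <- c("accession", "lineage", "interpro", "pathways")
  if (!all(need %in% names(df)))
    stop("entries TSV is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    protein_entry(
      accession = df$accession[i],
      lineage   = split_field(df$lineage[i]),
      interpro  = split_field(df$interpro[i]),
      pathways  = lapply(split_field(df$pathways[i], "|"),
                         parse_pathway_record)
    )
  })
  acc <- vapply(entries, function(e) e$accession, "")
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  entries
}

#' @rdname read_entries_tsv
#' @param entries list of `protein_entry` objects.
#' @return `write_entries_tsv()` returns `path` invisibly.
#' @export
write_entries_tsv <- function(entries, path) {
  rows <- vapply(entries, function(e) {
    recs <- vapply(e$pathways, function(p) {
      s <- render_pathway_label(p$label)
      if (length(p$evidence))
        s <- paste0(s, "{", paste(p$evidence, collapse = ";"), "}")
      s
    }, "")
    paste(e$accession,
          paste(e$lineage, collapse = ";"),
          paste(e$interpro, collapse = ";"),
          paste(recs, collapse = "|"),
          sep = "\t")
  }, "")
  writeLines(c("accession\tlineage\tinterpro\tpathways", rows), path,
             useBytes = TRUE)
  invisible(path)
}

split_field <- function(s, sep = ";") {
  if (is.na(s) || !nzchar(trimws(s))) return(character())
  parts <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

# "<pathway>{ECO:...;ECO:...}" -> pathway_annotation (braces optional)
parse_pathway_record <- function(rec) {
  rec <- trimws(rec)
  brace <- regmatches(rec, regexpr("\\{[^{}]*\\}$", rec))
  if (length(brace) == 1L) {
    ev <- split_field(substr(brace, 2L, nchar(brace) - 1L))
    label <- trimws(substr(rec, 1L, nchar(rec) - nchar(brace)))
  } else {
    ev <- character()
    label <- rec
  }
  pathway_annotation(label, ev)
}

#' Read a subset of the UniProtKB flat text format
#'
#' Parses only the line types the pipeline needs: `AC` (first token before
#' `";"` of the first AC line), `OC` (lineage; lines concatenated,
#' `";"`-separated, terminal `"."` stripped), `DR   InterPro; IPRxxxxxx;`
#' cross-references, and `CC   -!- PATHWAY:` comment blocks (continuation
#' lines joined by a single space; evidence codes read from `{ECO:...}`
#' suffixes, with source cross-references after `"|"` inside a code
#' ignored; multiple records inside one block split on `". PATHWAY:"`
#' boundaries). Entries are terminated by `"//"` lines.
#'
#' @param path file path.
#' @return list of `protein_entry` objects.
#' @export
read_uniprot_txt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ends <- grep("^//", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  entries <- list()
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:ends[k]]
    if (!any(grepl("^AC   ", block))) next
    entries[[length(entries) + 1L]] <- parse_uniprot_block(block)
  }
  entries
}

parse_uniprot_block <- function(block) {
  ac_line <- grep("^AC   ", block, value = TRUE)[1]
  accession <- trimws(strsplit(sub("^AC   ", "", ac_line), ";")[[1]][1])

  oc <- paste(sub("^OC   ", "", grep("^OC   ", block, value = TRUE)),
              collapse = " ")
  oc <- sub("\\.\\s*$", "", oc)
  lineage <- if (nzchar(trimws(oc))) split_field(oc) else character()

  dr <- grep("^DR   InterPro;", block, value = TRUE)
  interpro <- sub("^DR   InterPro;\\s*(IPR[0-9]{6});.*$", "\\1", dr)

  pathways <- parse_uniprot_pathway_cc(block)
  protein_entry(accession, lineage, interpro, pathways)
}

parse_uniprot_pathway_cc <- function(block) {
  cc <- grep("^CC   ", block)
  if (!length(cc)) return(list())
  txt <- sub("^CC   ", "", block[cc])
  # group CC lines into topic blocks starting at "-!- "
  starts <- grep("^-!- ", txt)
  if (!length(starts)) return(list())
  bounds <- c(starts, length(txt) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    chunk <- txt[bounds[i]:(bounds[i + 1L] - 1L)]
    if (!grepl("^-!- PATHWAY:", chunk[1])) next
    joined <- paste(trimws(chunk), collapse = " ")
    joined <- sub("^-!- PATHWAY:\\s*", "", joined)
    # one CC block may chain several records: ". PATHWAY: " boundaries
    recs <- strsplit(joined, "\\.\\s+PATHWAY:\\s*")[[1]]
    for (rec in recs) {
      ev <- character()
      braces <- regmatches(rec, gregexpr("\\{[^}]*\\}", rec))[[1]]
      if (length(braces)) {
        ev <- unlist(regmatches(braces, gregexpr("ECO:[0-9]{7}", braces)))
        rec <- gsub("\\{[^}]*\\}", "", rec)
      }
      # drop the record's closing period(s), incl. one orphaned by an
      # evidence group that preceded it
      rec <- gsub("[[:space:].]+$", "", trimws(rec))
      if (nzchar(rec))
        out[[length(out) + 1L]] <- pathway_annotation(rec, unique(ev))
    }
  }
  out
}
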