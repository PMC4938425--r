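#' Hierarchical pathway labels
#'
#' Metabolic pathway annotations are structured strings of up to three
#' hierarchy levels (super-pathway, pathway, sub-pathway) separated by
#' semicolons, optionally ending in a step indicator `": step i/n"` on the
#' last level, e.g.
#' `"Amino-acid biosynthesis; L-tryptophan biosynthesis; L-tryptophan from
#' chorismate: step 1/5"`.
#'
#' @param text a single pathway string.
#' @return `parse_pathway_label()` returns a `pathway_label` object: a list
#'   with `levels` (character vector of 1-3 trimmed level names),
#'   `step_index` and `step_total` (integers, or `NA` when the label carries
#'   no step indicator).
#' @examples
#' lab <- parse_pathway_label(
#'   "Amino-acid biosynthesis; L-tryptophan biosynthesis; L-tryptophan from chorismate: step 1/5")
#' lab$levels
#' lab$step_index
#' render_pathway_label(lab)
#' @export
parse_pathway_label <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("pathway label text must be a single non-empty string")
  segs <- strsplit(text, ";", fixed = TRUE)[[1]]
  segs <- vapply(segs, normalize_ws, "", USE.NAMES = FALSE)
  step_index <- NA_integer_
  step_total <- NA_integer_
  last <- segs[length(segs)]
  if (grepl(":\\s*step\\b", last, ignore.case = TRUE)) {
    m <- regmatches(last,
      regexec("^(.*?)\\s*:\\s*step\\s+([0-9]+)\\s*/\\s*([0-9]+)\\s*$", last,
              ignore.case = TRUE))[[1]]
    if (length(m) == 0L)
      stop("malformed step suffix in pathway label: '", text, "'")
    segs[length(segs)] <- normalize_ws(m[2])
    step_index <- as.integer(m[3])
    step_total <- as.integer(m[4])
    if (step_index < 1L || step_index > step_total)
      stop("step index out of range in pathway label: '", text, "'")
  }
  if (length(segs) > 3L)
    stop("pathway label has more than 3 levels: '", text, "'")
  if (any(!nzchar(segs)))
    stop("pathway label contains an empty level: '", text, "'")
  structure(list(levels = segs, step_index = step_index,
                 step_total = step_total),
            class = "pathway_label")
}

#' @rdname parse_pathway_label
#' @param label a `pathway_label` object.
#' @return `render_pathway_label()` returns the canonical string form;
#'   `render(parse(s))` is the canonical form of `s`.
#' @export
render_pathway_label <- function(label) {
  stopifnot(inherits(label, "pathway_label"))
  out <- paste(label$levels, collapse = "; ")
  if (!is.na(label$step_index))
    out <- sprintf("%s: step %d/%d", out, label$step_index, label$step_total)
  out
}

#' @export
format.pathway_label <- function(x, ...) render_pathway_label(x)

#' @export
print.pathway_label <- function(x, ...) {
  cat("<pathway_label> ", render_pathway_label(x), "\n", sep = "")
  invisible(x)
}

#' @rdname parse_pathway_label
#' @return `canonical_pathway()` returns the canonicalised string
#'   (whitespace-normalised levels joined by `"; "`, step suffix preserved).
#' @export
canonical_pathway <- function(text) {
  vapply(text, function(s) render_pathway_label(parse_pathway_label(s)), "",
         USE.NAMES = FALSE)
}

#' Compare two pathway labels hierarchically
#'
#' Classifies the relationship between two pathway labels:
#' `"identical"` when their canonical strings are equal; `"similar"` when
#' one label's level list is a strict prefix of the other's (steps ignored),
#' or the level lists are equal and exactly one side carries a step
#' indicator -- i.e. one annotation is a more general or more specific form
#' of the other; `"distinct"` otherwise.
#'
#' @param a,b pathway label strings or `pathway_label` objects.
#' @return one of `"identical"`, `"similar"`, `"distinct"`.
#' @examples
#' compare_pathway_labels("A; B", "A; B; C: step 1/2")  # similar
#' compare_pathway_labels("A; B", "A; D")               # distinct
#' @export
compare_pathway_labels <- function(a, b) {
  if (!inherits(a, "pathway_label")) a <- parse_pathway_label(a)
  if (!inherits(b, "pathway_label")) b <- parse_pathway_label(b)
  if (identical(render_pathway_label(a), render_pathway_label(b)))
    return("identical")
  la <- a$levels; lb <- b$levels
  na <- length(la); nb <- length(lb)
  if (identical(la, lb)) {
    # same levels, unequal canonical strings: step indicators differ
    if (xor(is.na(a$step_index), is.na(b$step_index))) return("similar")
    return("distinct")
  }
  if (na < nb && identical(la, lb[seq_len(na)])) return("similar")
  if (nb < na && identical(lb, la[seq_len(nb)])) return("similar")
  "distinct"
}

# trim ends and collapse internal whitespace runs to a single space
normalize_ws <- function(s) gsub("[[:space:]]+", " ", trimws(s))
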