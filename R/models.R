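#' Aggregate representative rules into prediction models
#'
#' Representative rules sharing a consequent are merged into one
#' disjunctive prediction model: `A => C` and `B => C` become
#' `A OR B => C`. Each representative contributes one clause holding its
#' antecedent, its normalised metric vector and its distance to the ideal
#' point; clauses are ordered by ascending distance (ties broken on the
#' sorted antecedent items). The input must be pairwise incomparable, as
#' produced by [select_representatives()].
#'
#' @param representatives a `rule_set` of pairwise-incomparable rules.
#' @return a `prediction_models` object: list of models, each a list with
#'   `consequent` (pathway item string) and `clauses` (list of clauses
#'   with `antecedent`, `support`, `confidence`, `lift_norm`, `p_norm`,
#'   `distance`). Models are ordered by consequent.
#' @export
aggregate_models <- function(representatives) {
  r <- representatives
  n <- nrow(r)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (rules_comparable(r, i, j))
        stop("representatives must be pairwise incomparable; rows ", i,
             " and ", j, " are comparable")
    }
  }
  keys <- if (n) antecedent_keys(r) else character()
  models <- lapply(sort(unique(r$consequent)), function(cons) {
    idx <- which(r$consequent == cons)
    idx <- idx[order(r$distance[idx], keys[idx], method = "radix")]
    clauses <- lapply(idx, function(i) {
      list(antecedent = sort(r$antecedent[[i]]),
           support = r$m_support[i],
           confidence = r$m_confidence[i],
           lift_norm = r$m_lift[i],
           p_norm = r$m_p[i],
           distance = r$distance[i])
    })
    structure(list(consequent = cons, clauses = clauses),
              class = "prediction_model")
  })
  structure(models, class = "prediction_models")
}

#' @export
print.prediction_models <- function(x, ...) {
  cat("<prediction_models> ", length(x), " model(s), ",
      sum(vapply(x, function(m) length(m$clauses), integer(1))),
      " clause(s)\n", sep = "")
  invisible(x)
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(render_model(x), sep = "\n")
  invisible(x)
}

#' Human-readable model rendering
#'
#' A model renders as a block:
#' \preformatted{
#' [PREDICT] PATHWAY:...
#' [IF] [item, item] support-confidence-lift-p -> distance
#' OR [item] ... -> distance
#' [END]
#' }
#' Metric components are printed at full precision, joined by en dashes;
#' the arrow before the distance is a rightwards arrow. `parse_models_text`
#' accepts both en dash and plain hyphen as the metric separator, so that
#' render -> parse -> render is a fixed point.
#'
#' @param model a `prediction_model`.
#' @return `render_model()` returns a character vector of lines;
#'   `render_models()` concatenates all models.
#' @export
render_model <- function(model) {
  lines <- paste0("[PREDICT] ", model$consequent)
  for (k in seq_along(model$clauses)) {
    cl <- model$clauses[[k]]
    prefix <- if (k == 1L) "[IF]" else "OR"
    metrics <- paste(fmt_num(c(cl$support, cl$confidence, cl$lift_norm,
                               cl$p_norm)),
                     collapse = "–")
    lines <- c(lines, sprintf("%s [%s] %s → %s", prefix,
                              paste(cl$antecedent, collapse = ", "),
                              metrics, fmt_num(cl$distance)))
  }
  c(lines, "[END]")
}

#' @rdname render_model
#' @param models a `prediction_models` object.
#' @export
render_models <- function(models) {
  unlist(lapply(models, render_model), use.names = FALSE)
}

#' @rdname render_model
#' @param lines character vector of rendered lines (or a file's contents).
#' @export
parse_models_text <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  models <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "[PREDICT] ")) {
      cur <- list(consequent = sub("^\\[PREDICT\\] ", "", ln),
                  clauses = list())
    } else if (startsWith(ln, "[IF] ") || startsWith(ln, "OR ")) {
      if (is.null(cur)) stop("clause line outside a model block: ", ln)
      body <- sub("^(\\[IF\\]|OR) ", "", ln)
      m <- regexec("^\\[([^]]*)\\]\\s+(.*?)\\s+(→|->)\\s+(\\S+)$",
                   body)[[1]]
      g <- regmatches(body, list(m))[[1]]
      if (length(g) == 0L) stop("malformed clause line: ", ln)
      ante <- trimws(strsplit(g[2], ",", fixed = TRUE)[[1]])
      parts <- strsplit(g[3], "–", fixed = TRUE)[[1]]
      if (length(parts) != 4L)
        parts <- strsplit(g[3], "(?<![eE])-", perl = TRUE)[[1]]
      if (length(parts) != 4L)
        stop("expected 4 metric components in clause line: ", ln)
      v <- as.numeric(parts)
      cur$clauses[[length(cur$clauses) + 1L]] <-
        list(antecedent = ante, support = v[1], confidence = v[2],
             lift_norm = v[3], p_norm = v[4], distance = as.numeric(g[5]))
    } else if (ln == "[END]") {
      if (is.null(cur)) stop("[END] without a model block")
      models[[length(models) + 1L]] <- structure(cur,
                                                 class = "prediction_model")
      cur <- NULL
    } else {
      stop("unrecognised model line: ", ln)
    }
  }
  if (!is.null(cur)) stop("unterminated model block: ", cur$consequent)
  structure(models, class = "prediction_models")
}

#' Serialise prediction models to JSON
#'
#' Document layout:
#' `{"models": [{"consequent": str, "clauses": [{"antecedent": [str],
#' "support": num, "confidence": num, "lift_norm": num, "p_norm": num,
#' "distance": num}]}], "meta": {...}}`.
#' Numbers are written at full precision so that distances survive a
#' write/read cycle bit-for-bit. `read_models()` validates the document
#' structure and reports the JSON-pointer location of the first offending
#' element.
#'
#' @param models a `prediction_models` object.
#' @param path file path.
#' @param meta optional named list stored under `"meta"`.
#' @return `write_models()` returns `path` invisibly; `read_models()`
#'   returns a `prediction_models` object.
#' @export
write_models <- function(models, path, meta = list()) {
  doc <- list(
    models = lapply(models, function(m) {
      list(consequent = m$consequent,
           clauses = lapply(m$clauses, function(cl) {
             list(antecedent = as.list(cl$antecedent),
                  support = cl$support, confidence = cl$confidence,
                  lift_norm = cl$lift_norm, p_norm = cl$p_norm,
                  distance = cl$distance)
           }))
    }),
    meta = meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$models))
    stop("invalid models document at /: missing 'models'")
  num_fields <- c("support", "confidence", "lift_norm", "p_norm", "distance")
  models <- lapply(seq_along(doc$models), function(i) {
    m <- doc$models[[i]]
    here <- sprintf("/models/%d", i - 1L)
    if (!is.character(m$consequent %||% NULL) || !nzchar(m$consequent))
      stop("invalid models document at ", here, ": missing 'consequent'")
    if (!is.list(m$clauses %||% NULL) || !length(m$clauses))
      stop("invalid models document at ", here, ": missing 'clauses'")
    clauses <- lapply(seq_along(m$clauses), function(k) {
      cl <- m$clauses[[k]]
      where <- sprintf("%s/clauses/%d", here, k - 1L)
      ante <- cl$antecedent %||% NULL
      if (is.null(ante) || !length(ante))
        stop("invalid models document at ", where, ": missing 'antecedent'")
      for (f in num_fields) {
        if (!is.numeric(cl[[f]] %||% NULL))
          stop("invalid models document at ", where, ": missing '", f, "'")
      }
      list(antecedent = as.character(unlist(ante)),
           support = cl$support, confidence = cl$confidence,
           lift_norm = cl$lift_norm, p_norm = cl$p_norm,
           distance = cl$distance)
    })
    structure(list(consequent = m$consequent, clauses = clauses),
              class = "prediction_model")
  })
  structure(models, class = "prediction_models")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
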