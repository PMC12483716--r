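# Predictor schema: declares every predictor's level (person / item /
# person-by-item), kind (continuous / nominal), and category coding.

#' Declare the predictor layout of a person-by-item table
#'
#' A schema lists every predictor column with its level of variation and
#' measurement kind.  Person-level predictors must be constant within each
#' person, item-level predictors constant within each item; this is validated
#' when a table is loaded.  Nominal predictors carry an ordered category set
#' and a reference category used for dummy coding in the item response model
#' design (forests keep them as unordered factors instead).
#'
#' @param predictors a list of entries, each a list with elements
#'   `name` (string), `level` (one of `"person"`, `"item"`,
#'   `"person_by_item"`), `kind` (`"continuous"` or `"nominal"`), and for
#'   nominal predictors `categories` (character vector, length >= 2) and
#'   optionally `reference` (defaults to the first category in sorted order).
#' @return an object of class `eirmrf_schema`.
#' @export
#' @examples
#' sch <- predictor_schema(list(
#'   list(name = "x1", level = "person", kind = "continuous"),
#'   list(name = "g", level = "item", kind = "nominal",
#'        categories = c("a", "b", "c"))
#' ))
predictor_schema <- function(predictors) {
  if (!is.list(predictors) || length(predictors) == 0) {
    stop_eirmrf("'predictors' must be a non-empty list", "schema_error")
  }
  entries <- lapply(predictors, function(p) {
    if (is.null(p$name) || is.null(p$level) || is.null(p$kind)) {
      stop_eirmrf("each predictor needs 'name', 'level' and 'kind'", "schema_error")
    }
    level <- match.arg(p$level, c("person", "item", "person_by_item"))
    kind <- match.arg(p$kind, c("continuous", "nominal"))
    categories <- NULL
    reference <- NULL
    if (kind == "nominal") {
      categories <- as.character(p$categories)
      if (length(categories) < 2 || anyDuplicated(categories)) {
        stop_eirmrf(
          sprintf("nominal predictor '%s' needs >= 2 distinct categories", p$name),
          "schema_error"
        )
      }
      reference <- as.character(p$reference %||% sort(categories)[1])
      if (!reference %in% categories) {
        stop_eirmrf(
          sprintf("reference category of '%s' is not among its categories", p$name),
          "schema_error"
        )
      }
    }
    list(
      name = as.character(p$name), level = level, kind = kind,
      categories = categories, reference = reference
    )
  })
  names(entries) <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(names(entries))) {
    stop_eirmrf("predictor names must be unique", "schema_error")
  }
  structure(list(predictors = entries), class = "eirmrf_schema")
}

#' @export
print.eirmrf_schema <- function(x, ...) {
  cat("Predictor schema:", length(x$predictors), "predictors\n")
  for (p in x$predictors) {
    cat(
      sprintf(
        "  %-16s %-14s %-10s%s\n", p$name, p$level, p$kind,
        if (p$kind == "nominal") {
          sprintf(" {%s} ref=%s", paste(p$categories, collapse = ","), p$reference)
        } else ""
      )
    )
  }
  invisible(x)
}

schema_names <- function(schema) names(schema$predictors)

schema_subset <- function(schema, level = NULL, kind = NULL) {
  keep <- vapply(schema$predictors, function(p) {
    (is.null(level) || p$level %in% level) && (is.null(kind) || p$kind %in% kind)
  }, logical(1))
  names(schema$predictors)[keep]
}

#' Read a predictor schema from a YAML or JSON file
#'
#' The file holds a list of predictor entries in the same shape accepted by
#' [predictor_schema()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `eirmrf_schema`.
#' @export
read_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_eirmrf("the 'yaml' package is required to read YAML schemas", "schema_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  predictor_schema(raw)
}
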