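# Ingestion, validation, preprocessing and encoding of long-format
# person-by-item response tables.

#' Load and validate a long-format person-by-item table
#'
#' Each row is one (person, item) pair with a binary response.  Rows with any
#' missing value among the id, response or schema columns are listwise
#' deleted.  Person-level predictors must be constant within each person and
#' item-level predictors within each item; duplicated (person, item) pairs
#' are rejected.
#'
#' @param source a data frame, or a path to a CSV file with a header.
#'   Required columns: `person_id`, `item_id`, `response`, plus one column
#'   per schema predictor.
#' @param schema an [predictor_schema()] object.
#' @return a `response_table`: a data frame with columns `person_id`,
#'   `item_id`, `y` and the predictors (nominal ones as factors with the
#'   schema's category set), with attributes `schema`, `n_persons`,
#'   `n_items`.
#' @export
load_long_table <- function(source, schema) {
  stopifnot(inherits(schema, "eirmrf_schema"))
  df <- if (is.character(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE)
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }
  need <- c("person_id", "item_id", "response", schema_names(schema))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_eirmrf(
      paste("missing required columns:", paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  df <- df[, need, drop = FALSE]

  # listwise deletion before any domain checks on retained rows
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop_eirmrf("no complete rows after listwise deletion", "value_error")

  if (!all(df$response %in% c(0, 1))) {
    stop_eirmrf("response values must be 0 or 1", "value_error")
  }

  out <- data.frame(
    person_id = as.character(df$person_id),
    item_id = as.character(df$item_id),
    y = as.integer(df$response),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out[, c("person_id", "item_id")])) {
    stop_eirmrf("duplicated (person_id, item_id) pairs", "value_error")
  }

  for (p in schema$predictors) {
    v <- df[[p$name]]
    if (p$kind == "nominal") {
      v <- as.character(v)
      bad <- setdiff(unique(v), p$categories)
      if (length(bad)) {
        stop_eirmrf(
          sprintf("predictor '%s' has categories outside the schema: %s",
                  p$name, paste(bad, collapse = ", ")),
          "encoding_error"
        )
      }
      v <- factor(v, levels = p$categories)
    } else {
      v <- as.numeric(v)
    }
    out[[p$name]] <- v
    # within-cluster constancy
    if (p$level %in% c("person", "item")) {
      by <- if (p$level == "person") out$person_id else out$item_id
      n_distinct <- tapply(as.character(v), by, function(z) length(unique(z)))
      if (any(n_distinct > 1)) {
        stop_eirmrf(
          sprintf("%s-level predictor '%s' varies within a %s",
                  p$level, p$name, p$level),
          "consistency_error"
        )
      }
    }
  }

  structure(
    out,
    schema = schema,
    n_persons = length(unique(out$person_id)),
    n_items = length(unique(out$item_id)),
    class = c("response_table", "data.frame")
  )
}

#' Write a response table to CSV
#'
#' Inverse of [load_long_table()]: the written file, re-read with the same
#' schema, reproduces the table exactly.
#'
#' @param table a `response_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  df <- as.data.frame(table)
  names(df)[names(df) == "y"] <- "response"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Preprocess a response table
#'
#' Mean-centers continuous predictors (training means are stored so held-out
#' rows can be transformed consistently), drops near-zero-variance
#' predictors, and reports the pairwise predictor correlation summary
#' (median and interquartile range).
#'
#' @param table a `response_table` from [load_long_table()].
#' @param center logical; mean-center continuous predictors (default `TRUE`).
#' @param nzv_freq_ratio frequency ratio of the most to the second most
#'   common value above which a predictor is a near-zero-variance candidate
#'   (default 19, i.e. 95/5).
#' @param nzv_unique_frac unique-value fraction below which a candidate is
#'   dropped (default 0.10).  Both conditions must hold for a drop; a
#'   predictor with a single distinct value is always dropped.
#' @return a `prepared_data` object: list with elements `table` (transformed
#'   response table), `schema` (retained predictors), `centers` (named means
#'   used for centering), `dropped` (near-zero-variance report), and
#'   `correlation` (median / IQR of pairwise correlations, computed over
#'   numerically coded predictors; cross-level pairs are reported separately
#'   because a fully crossed design forces them to zero).
#' @export
preprocess <- function(table, center = TRUE, nzv_freq_ratio = 19,
                       nzv_unique_frac = 0.10) {
  stopifnot(inherits(table, "response_table"))
  schema <- attr(table, "schema")
  nms <- schema_names(schema)

  dropped <- data.frame(
    predictor = character(0), freq_ratio = numeric(0),
    unique_frac = numeric(0), stringsAsFactors = FALSE
  )
  keep <- character(0)
  for (nm in nms) {
    v <- table[[nm]]
    tab <- sort(table(as.character(v)), decreasing = TRUE)
    fr <- if (length(tab) >= 2) tab[[1]] / tab[[2]] else Inf
    uf <- length(tab) / length(v)
    if ((fr > nzv_freq_ratio && uf < nzv_unique_frac) || length(tab) < 2) {
      dropped <- rbind(dropped, data.frame(
        predictor = nm, freq_ratio = fr, unique_frac = uf,
        stringsAsFactors = FALSE
      ))
    } else {
      keep <- c(keep, nm)
    }
  }
  if (length(keep) == 0) {
    stop_eirmrf("all predictors were dropped by the near-zero-variance screen",
                "empty_feature_error")
  }

  retained_schema <- predictor_schema(
    unname(lapply(schema$predictors[keep], function(p) {
      list(name = p$name, level = p$level, kind = p$kind,
           categories = p$categories, reference = p$reference)
    }))
  )

  out <- table[, c("person_id", "item_id", "y", keep), drop = FALSE]
  centers <- numeric(0)
  if (center) {
    for (nm in schema_subset(retained_schema, kind = "continuous")) {
      m <- mean(out[[nm]])
      out[[nm]] <- out[[nm]] - m
      centers[nm] <- m
    }
  }

  correlation <- correlation_summary(out, retained_schema)

  prepared <- list(
    table = structure(out,
      schema = retained_schema,
      n_persons = length(unique(out$person_id)),
      n_items = length(unique(out$item_id)),
      class = c("response_table", "data.frame")
    ),
    schema = retained_schema,
    centers = centers,
    dropped = dropped,
    correlation = correlation
  )
  class(prepared) <- "prepared_data"
  prepared
}

# Pairwise correlations over integer-coded predictors. Within-level pairs are
# the informative ones; in a fully crossed design the long-format sample
# correlation between a person-level and an item-level predictor is 0 by
# construction.
correlation_summary <- function(table, schema) {
  nms <- schema_names(schema)
  if (length(nms) < 2) {
    return(list(median = NA_real_, iqr = NA_real_, n_pairs = 0L,
                median_all = NA_real_, high_pairs = character(0)))
  }
  num <- sapply(nms, function(nm) as.numeric(table[[nm]]))
  cm <- suppressWarnings(stats::cor(num))
  lv <- vapply(schema$predictors[nms], `[[`, "", "level")
  same_level <- outer(lv, lv, `==`)
  ut <- upper.tri(cm)
  within <- cm[ut & same_level]
  within <- within[is.finite(within)]
  all_pairs <- cm[ut]
  all_pairs <- all_pairs[is.finite(all_pairs)]
  idx <- which(ut & abs(cm) > 0.9, arr.ind = TRUE)
  high <- if (nrow(idx)) paste(nms[idx[, 1]], nms[idx[, 2]], sep = ":") else character(0)
  list(
    median = stats::median(within),
    iqr = stats::IQR(within),
    n_pairs = length(within),
    median_all = stats::median(all_pairs),
    high_pairs = high
  )
}

#' @export
print.prepared_data <- function(x, ...) {
  cat("Prepared person-by-item data:",
      nrow(x$table), "rows,",
      attr(x$table, "n_persons"), "persons x",
      attr(x$table, "n_items"), "items\n")
  cat("  predictors retained:", length(x$schema$predictors),
      " dropped:", nrow(x$dropped), "\n")
  cat(sprintf("  pairwise correlation median %.3f (IQR %.3f)\n",
              x$correlation$median, x$correlation$iqr))
  invisible(x)
}

#' Export the preprocessing report as JSON
#'
#' Drops, centering offsets and the predictor-correlation summary of a
#' [preprocess()] result.
#'
#' @param prepared a `prepared_data` object.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
preprocess_report_json <- function(prepared, path = NULL) {
  stopifnot(inherits(prepared, "prepared_data"))
  out <- list(
    n_rows = nrow(prepared$table),
    n_persons = attr(prepared$table, "n_persons"),
    n_items = attr(prepared$table, "n_items"),
    dropped = prepared$dropped,
    centers = as.list(prepared$centers),
    correlation = prepared$correlation
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Encode prepared data as a feature matrix
#'
#' Two encodings are supported.  `mode = "eirm"` produces an intercept plus
#' dummy columns (one per non-reference category of each nominal predictor)
#' suitable for the logistic mixed model.  `mode = "forest"` keeps one column
#' per predictor, with nominal predictors as unordered factors, the encoding
#' a random forest splits on by category membership.
#'
#' @param prepared a `prepared_data` object.
#' @param mode `"eirm"` or `"forest"`.
#' @param newdata optional data frame of rows to encode under the training
#'   schema and centering offsets (defaults to the prepared table).
#' @return for `"eirm"`, a numeric matrix with an `(Intercept)` column and
#'   attribute `columns`; for `"forest"`, a data frame of features.
#' @export
encode <- function(prepared, mode = c("eirm", "forest"), newdata = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(prepared, "prepared_data"))
  schema <- prepared$schema
  df <- if (is.null(newdata)) {
    as.data.frame(prepared$table)
  } else {
    transform_newdata(prepared, newdata)
  }
  nms <- schema_names(schema)
  if (mode == "forest") {
    out <- df[, nms, drop = FALSE]
    return(out)
  }
  cols <- list(`(Intercept)` = rep(1, nrow(df)))
  for (p in schema$predictors) {
    v <- df[[p$name]]
    if (p$kind == "continuous") {
      cols[[p$name]] <- as.numeric(v)
    } else {
      # dummies span only the categories observed in the prepared table;
      # an unobserved category would give an all-zero (rank-deficient)
      # column.  If the reference itself is unobserved, the first observed
      # category takes its place as the baseline.
      observed <- unique(as.character(prepared$table[[p$name]]))
      ref <- if (p$reference %in% observed) p$reference else sort(observed)[1]
      for (cat in setdiff(intersect(p$categories, observed), ref)) {
        cols[[paste0(p$name, ".", cat)]] <- as.numeric(v == cat)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "columns") <- names(cols)
  X
}

# Apply schema typing and stored centering to new rows.
transform_newdata <- function(prepared, newdata) {
  schema <- prepared$schema
  df <- as.data.frame(newdata, stringsAsFactors = FALSE)
  for (p in schema$predictors) {
    if (!p$name %in% names(df)) {
      stop_eirmrf(sprintf("newdata lacks predictor '%s'", p$name), "encoding_error")
    }
    v <- df[[p$name]]
    if (p$kind == "nominal") {
      v <- as.character(v)
      bad <- setdiff(unique(v[!is.na(v)]), p$categories)
      if (length(bad)) {
        stop_eirmrf(
          sprintf("unseen category in '%s': %s", p$name, paste(bad, collapse = ", ")),
          "encoding_error"
        )
      }
      df[[p$name]] <- factor(v, levels = p$categories)
    } else {
      v <- as.numeric(v)
      if (p$name %in% names(prepared$centers)) {
        v <- v - prepared$centers[[p$name]]
      }
      df[[p$name]] <- v
    }
  }
  df
}
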