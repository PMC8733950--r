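#' Write a divergence report to JSON (and optionally TSV)
#'
#' Serializes a [compare_clades()] report as a JSON document with
#' deterministic key order, plot-ready arrays (the two branch-length samples
#' for a boxplot, the Venn counts) and, for every test, a `p_display` string
#' that shows `"< 1e-15"` when the p-value is below representable precision.
#' The document conforms to the JSON schema shipped at
#' `system.file("extdata", "report-schema.json", package = "cladediv")`.
#'
#' @param report A `divergence_report`.
#' @param path Output path for the JSON document.
#' @param tsv Optional path for a flat one-row-per-test TSV summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tsv = NULL) {
  stopifnot(inherits(report, "divergence_report"))
  doc <- report_to_list(report)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(tsv)) {
    utils::write.table(report_tsv(report), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

report_to_list <- function(report) {
  tests <- lapply(unname(report$tests), function(t) {
    if (inherits(t, "divergence_test_error"))
      list(name = t$test, error = t$error)
    else
      list(name = t$test,
           statistic = t$statistic,
           df = if (is.na(t$df)) NULL else t$df,
           p_value = t$p_value,
           p_display = format_p(t$p_value),
           n1 = t$n1, n2 = t$n2,
           method = if (is.na(t$method)) NULL else t$method)
  })
  species <- if (is.null(report$species)) NULL else {
    s <- report$species
    list(common = s$common, unique_a = s$unique_a, unique_b = s$unique_b,
         relation = s$relation,
         common_species = as.list(s$common_species),
         unique_a_species = as.list(s$unique_a_species),
         unique_b_species = as.list(s$unique_b_species))
  }
  strip_na <- function(cl) {
    cl$n_species <- if (is.na(cl$n_species)) NULL else cl$n_species
    cl
  }
  list(clades = list(a = strip_na(report$clades$a),
                     b = strip_na(report$clades$b)),
       tests = tests,
       species = species,
       samples = list(a = as.numeric(report$samples$a),
                      b = as.numeric(report$samples$b)),
       provenance = report$provenance)
}

report_tsv <- function(report) {
  rows <- lapply(report$tests, function(t) {
    if (inherits(t, "divergence_test_error"))
      data.frame(test = t$test, statistic = NA_real_, df = NA_real_,
                 p_value = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
                 note = t$error)
    else
      data.frame(test = t$test, statistic = t$statistic, df = t$df,
                 p_value = t$p_value, n1 = t$n1, n2 = t$n2,
                 note = ifelse(is.na(t$method), "", t$method))
  })
  do.call(rbind, rows)
}

#' Read back a JSON report
#' @param path Path to a JSON document written by [write_report()].
#' @return The report as a plain list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Check a report document against the shipped schema
#'
#' A light structural validator covering the subset of JSON Schema the
#' shipped schema uses (`type`, `required`, `properties`, `items`, `enum`).
#'
#' @param doc A list as returned by [read_report()].
#' @param schema_path Path to the schema; defaults to the shipped one.
#' @return `TRUE` if valid, otherwise an error describing the first violation.
#' @export
validate_report <- function(doc,
                            schema_path = system.file("extdata",
                                                      "report-schema.json",
                                                      package = "cladediv")) {
  schema <- jsonlite::read_json(schema_path)
  check_schema(doc, schema, "$")
  TRUE
}

check_schema <- function(x, schema, where) {
  type <- schema$type
  if (!is.null(type)) {
    ok <- switch(type,
      object  = is.list(x),
      array   = is.list(x) || is.vector(x),
      number  = is.numeric(x),
      integer = is.numeric(x) && all(x == round(x)),
      string  = is.character(x),
      boolean = is.logical(x),
      `null`  = is.null(x),
      TRUE)
    if (!ok) stop("schema violation at ", where, ": expected ", type,
                  call. = FALSE)
  }
  if (!is.null(schema$enum) && !(x %in% unlist(schema$enum)))
    stop("schema violation at ", where, ": value not in enum", call. = FALSE)
  if (!is.null(schema$required)) {
    miss <- setdiff(unlist(schema$required), names(x))
    if (length(miss) > 0L)
      stop("schema violation at ", where, ": missing required key(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(schema$properties)) {
    for (nm in intersect(names(schema$properties), names(x))) {
      if (is.null(x[[nm]])) next
      check_schema(x[[nm]], schema$properties[[nm]], paste0(where, ".", nm))
    }
  }
  if (!is.null(schema$items)) {
    if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
    if (is.list(x)) {
      for (i in seq_along(x))
        check_schema(x[[i]], schema$items, paste0(where, "[", i, "]"))
    } else if (length(x) > 0L) {
      # atomic array: a vectorized type check covers every element
      check_schema(x, schema$items, paste0(where, "[]"))
    }
  }
  invisible(TRUE)
}
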