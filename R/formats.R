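#' @importFrom jsonlite fromJSON toJSON
#' @importFrom xml2 read_xml xml_name xml_find_all xml_find_first xml_text
#'   xml_new_root xml_add_child
NULL

# ---- numeric formatting -----------------------------------------------------

# Shortest decimal representation that round-trips to the same double.
# Canonical writers depend on this for byte-stable output.
format_coord <- function(x) {
  vapply(x, function(v) {
    if (v == floor(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

issues_of <- function(x) {
  iss <- attr(x, "issues")
  if (is.null(iss)) no_issues() else iss
}

#' Issues attached to a parsed object
#'
#' Readers never lose information silently: normalisations performed while
#' parsing (e.g. shifting one-based class values down) are recorded as
#' warning issues attached to the returned object.
#'
#' @param x An object returned by [read_dataset()] or [read_information()].
#' @return A data frame of issues; zero rows when parsing was literal.
#' @export
issues <- function(x) issues_of(x)

# ---- detection --------------------------------------------------------------

split_lines <- function(text) {
  lines <- strsplit(gsub("\r\n", "\n", text), "\n", fixed = TRUE)[[1]]
  # ignore blank trailing lines only
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  lines
}

csv_fields <- function(line) trimws(strsplit(line, ",", fixed = TRUE)[[1]])

#' Detect the dialect and family of a raw document
#'
#' JSON and XML documents are classified by their root token (`dataset` or
#' `information`). CSV carries no root: a CSV is a dataset iff every row
#' has exactly three numeric fields, and an information file otherwise. A
#' three-column all-integer CSV is valid under both readings, so it is
#' rejected as ambiguous unless the caller forces the family — the
#' function never guesses silently.
#'
#' @param raw_text Document text (non-empty).
#' @param family Optional `"dataset"` or `"information"` to force the CSV
#'   family (and to assert the family of structured dialects).
#' @return A list with elements `dialect` (`"json"`, `"xml"` or `"csv"`)
#'   and `family` (`"dataset"` or `"information"`).
#' @export
#' @examples
#' detect_format('{"dataset": {"points": [[0,0,0]]}}')
detect_format <- function(raw_text, family = NULL) {
  stopifnot(is.character(raw_text), length(raw_text) == 1)
  trimmed <- trimws(raw_text)
  if (!nzchar(trimmed)) {
    stop_issue("UNRECOGNISED_FORMAT", "empty input")
  }
  first <- substr(trimmed, 1, 1)
  if (first == "{") {
    obj <- tryCatch(fromJSON(raw_text, simplifyVector = FALSE),
                    error = function(e) stop_issue("SYNTAX_ERROR",
                      paste("invalid JSON:", conditionMessage(e))))
    root <- names(obj)
    fam <- if ("dataset" %in% root) "dataset"
           else if ("information" %in% root) "information"
           else stop_issue("UNRECOGNISED_FORMAT",
                           "JSON root is neither 'dataset' nor 'information'")
    check_family(fam, family)
    return(list(dialect = "json", family = fam))
  }
  if (first == "<") {
    doc <- tryCatch(read_xml(raw_text),
                    error = function(e) stop_issue("SYNTAX_ERROR",
                      paste("invalid XML:", conditionMessage(e))))
    root <- xml_name(doc)
    fam <- switch(root, dataset = "dataset", information = "information",
                  stop_issue("UNRECOGNISED_FORMAT",
                             sprintf("XML root '<%s>' is not recognised", root)))
    check_family(fam, family)
    return(list(dialect = "xml", family = fam))
  }
  # CSV: no structural root
  lines <- split_lines(raw_text)
  if (length(lines) == 0) stop_issue("UNRECOGNISED_FORMAT", "empty input")
  rows <- lapply(lines, csv_fields)
  nums <- suppressWarnings(lapply(rows, as.numeric))
  if (any(vapply(nums, anyNA, logical(1)))) {
    stop_issue("UNRECOGNISED_FORMAT", "CSV contains non-numeric fields")
  }
  if (!is.null(family)) {
    return(list(dialect = "csv", family = match.arg(family,
                c("dataset", "information"))))
  }
  three_col <- all(vapply(rows, length, integer(1)) == 3L)
  if (three_col) {
    all_int <- all(vapply(nums, function(v) all(v == floor(v)), logical(1)))
    if (all_int) {
      stop_issue("AMBIGUOUS_CSV_FAMILY",
                 paste("a 3-column all-integer CSV is valid as either family;",
                       "pass family explicitly"))
    }
    return(list(dialect = "csv", family = "dataset"))
  }
  list(dialect = "csv", family = "information")
}

# Syntactic dialect sniff for readers whose family is already known from
# the call: a leading '{' is JSON, '<' is XML, anything else CSV. The
# full classifier (detect_format) additionally resolves the family.
sniff_dialect <- function(raw_text) {
  trimmed <- trimws(raw_text)
  if (!nzchar(trimmed)) stop_issue("UNRECOGNISED_FORMAT", "empty input")
  switch(substr(trimmed, 1, 1), "{" = "json", "<" = "xml", "csv")
}

check_family <- function(found, forced) {
  if (!is.null(forced) && !identical(found, match.arg(forced,
      c("dataset", "information")))) {
    stop_issue("UNRECOGNISED_FORMAT",
               sprintf("document is a %s file, but family '%s' was forced",
                       found, forced))
  }
  invisible(found)
}

# ---- dataset readers --------------------------------------------------------

#' Read a dataset document
#'
#' Parses one of the three dialects into a [pw_dataset()]. The `chain`
#' flag defaults to `FALSE` when absent. CSV cannot express a name or the
#' chain flag, so CSV parses always yield the default name `"dataset"` and
#' `chain = FALSE`.
#'
#' @param raw_text Document text.
#' @param dialect `"json"`, `"xml"` or `"csv"`; `NULL` to auto-detect.
#' @return A [pw_dataset()] with `source_dialect` set; any parse-time
#'   normalisations are retrievable with [issues()].
#' @export
#' @examples
#' read_dataset('{"dataset": {"name": "demo", "points": [[0,0,0],[1,1,1]]}}')
read_dataset <- function(raw_text, dialect = NULL) {
  if (is.null(dialect)) dialect <- sniff_dialect(raw_text)
  dialect <- match.arg(dialect, c("json", "xml", "csv"))
  switch(dialect,
         json = read_dataset_json(raw_text),
         xml  = read_dataset_xml(raw_text),
         csv  = read_dataset_csv(raw_text))
}

parse_point_list <- function(pts, locus_fmt = "point %d") {
  if (length(pts) == 0) stop_issue("EMPTY_DATASET", "no points defined")
  mat <- matrix(NA_real_, nrow = length(pts), ncol = 3)
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    if (length(p) != 3) {
      stop_issue("BAD_ARITY",
                 sprintf("point has %d coordinates, expected 3", length(p)),
                 locus = sprintf(locus_fmt, i))
    }
    v <- suppressWarnings(as.numeric(unlist(p, use.names = FALSE)))
    if (length(v) != 3 || anyNA(v) || !all(is.finite(v))) {
      stop_issue("BAD_COORDINATE", "non-numeric or non-finite coordinate",
                 locus = sprintf(locus_fmt, i))
    }
    mat[i, ] <- v
  }
  mat
}

read_dataset_json <- function(raw_text) {
  obj <- tryCatch(fromJSON(raw_text, simplifyVector = FALSE),
                  error = function(e) stop_issue("SYNTAX_ERROR",
                    paste("invalid JSON:", conditionMessage(e))))
  if (!is.list(obj) || !"dataset" %in% names(obj)) {
    stop_issue("MISSING_ROOT", "expected a root object called 'dataset'")
  }
  root <- obj$dataset
  name <- if (!is.null(root$name)) as.character(root$name[[1]]) else "dataset"
  chain <- FALSE
  if (!is.null(root$chain)) {
    if (!is.logical(root$chain) || length(root$chain) != 1 || is.na(root$chain)) {
      stop_issue("BAD_BOOLEAN", "'chain' must be the JSON literal true or false")
    }
    chain <- root$chain
  }
  if (is.null(root$points)) {
    stop_issue("MISSING_ROOT", "dataset lacks the 'points' property")
  }
  mat <- parse_point_list(root$points)
  pw_dataset(mat, name = name, chain = chain, source_dialect = "json")
}

parse_xml_doc <- function(raw_text, root_name) {
  doc <- tryCatch(read_xml(raw_text),
                  error = function(e) stop_issue("SYNTAX_ERROR",
                    paste("invalid XML:", conditionMessage(e))))
  if (xml_name(doc) != root_name) {
    stop_issue("MISSING_ROOT",
               sprintf("expected a root element named '<%s>'", root_name))
  }
  doc
}

xml_bool <- function(text) {
  low <- tolower(trimws(text))
  if (low == "true") return(TRUE)
  if (low == "false") return(FALSE)
  stop_issue("BAD_BOOLEAN", sprintf("'%s' is not 'true' or 'false'", text))
}

read_dataset_xml <- function(raw_text) {
  doc <- parse_xml_doc(raw_text, "dataset")
  name_node <- xml_find_first(doc, "./name")
  name <- if (inherits(name_node, "xml_missing")) "dataset" else xml_text(name_node)
  chain_node <- xml_find_first(doc, "./chain")
  chain <- if (inherits(chain_node, "xml_missing")) FALSE
           else xml_bool(xml_text(chain_node))
  pts <- xml_find_all(doc, "./points/point")
  if (length(pts) == 0) stop_issue("EMPTY_DATASET", "no <point> elements")
  mat <- matrix(NA_real_, nrow = length(pts), ncol = 3)
  for (i in seq_along(pts)) {
    coords <- vapply(c("x", "y", "z"), function(ax) {
      node <- xml_find_first(pts[[i]], paste0("./", ax))
      if (inherits(node, "xml_missing")) NA_character_ else xml_text(node)
    }, character(1))
    if (anyNA(coords)) {
      stop_issue("BAD_ARITY", "point lacks an <x>, <y> or <z> child",
                 locus = sprintf("point %d", i))
    }
    v <- suppressWarnings(as.numeric(coords))
    if (anyNA(v) || !all(is.finite(v))) {
      stop_issue("BAD_COORDINATE", "non-numeric or non-finite coordinate",
                 locus = sprintf("point %d", i))
    }
    mat[i, ] <- v
  }
  pw_dataset(mat, name = name, chain = chain, source_dialect = "xml")
}

read_dataset_csv <- function(raw_text) {
  lines <- split_lines(raw_text)
  if (length(lines) == 0) stop_issue("EMPTY_DATASET", "no points defined")
  mat <- matrix(NA_real_, nrow = length(lines), ncol = 3)
  for (i in seq_along(lines)) {
    fields <- csv_fields(lines[i])
    if (length(fields) != 3) {
      stop_issue("BAD_ARITY",
                 sprintf("line has %d fields, expected 3", length(fields)),
                 locus = sprintf("line %d", i))
    }
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v) || !all(is.finite(v))) {
      stop_issue("BAD_COORDINATE", "non-numeric or non-finite coordinate",
                 locus = sprintf("line %d", i))
    }
    mat[i, ] <- v
  }
  pw_dataset(mat, name = "dataset", chain = FALSE, source_dialect = "csv")
}

# ---- information readers ----------------------------------------------------

# Map raw class identifiers to canonical 0-based form. Two conventions are
# accepted: values already in [0, k-1], or values occupying exactly {1..k}
# (shifted down with a warning). Anything else is an error unless repair
# mode raises num_classes to cover the observed maximum.
canonicalise_values <- function(vals, num_classes, repair = FALSE, locus = "") {
  iss <- no_issues()
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals != floor(vals))) {
    stop_issue("VALUE_OUT_OF_RANGE", "class values must be integers",
               locus = locus)
  }
  vals <- as.integer(vals)
  k <- if (is.null(num_classes)) length(unique(vals)) else as.integer(num_classes)
  if (is.na(k) || k < 1) {
    stop_issue("VALUE_OUT_OF_RANGE", "numClass must be a positive integer",
               locus = locus)
  }
  if (all(vals >= 0L & vals < k)) {
    return(list(values = vals, num_classes = k, issues = iss))
  }
  if (setequal(unique(vals), seq_len(k))) {
    iss <- rbind(iss, validation_issue(
      "ONE_BASED_NORMALISED",
      sprintf("values occupied {1..%d}; shifted to 0-based", k),
      locus = locus))
    return(list(values = vals - 1L, num_classes = k, issues = iss))
  }
  if (repair && all(vals >= 0L)) {
    k2 <- max(vals) + 1L
    iss <- rbind(iss, validation_issue(
      "NUM_CLASSES_RAISED",
      sprintf("num_classes raised from %d to %d to cover observed values", k, k2),
      locus = locus))
    return(list(values = vals, num_classes = k2, issues = iss))
  }
  stop_issue("VALUE_OUT_OF_RANGE",
             sprintf("values not mappable into [0, %d]", k - 1L),
             locus = locus)
}

#' Read an information-layer document
#'
#' Parses one of the three dialects into a [pw_infofile()]. JSON and XML
#' files declare `numClass` per layer; CSV cannot, so each column's class
#' count is inferred as its number of distinct values, and CSV layers have
#' no name or labels. Raw class identifiers are normalised to canonical
#' 0-based integers: a file whose values occupy exactly `{1..numClass}`
#' is treated as one-based and shifted down with an `ONE_BASED_NORMALISED`
#' warning (see [issues()]).
#'
#' @param raw_text Document text.
#' @param dialect `"json"`, `"xml"` or `"csv"`; `NULL` to auto-detect.
#' @param repair If `TRUE`, values exceeding the declared class count raise
#'   `num_classes` to `max + 1` with a `NUM_CLASSES_RAISED` warning instead
#'   of failing. Strict by default.
#' @return A [pw_infofile()].
#' @export
read_information <- function(raw_text, dialect = NULL, repair = FALSE) {
  if (is.null(dialect)) dialect <- sniff_dialect(raw_text)
  dialect <- match.arg(dialect, c("json", "xml", "csv"))
  switch(dialect,
         json = read_information_json(raw_text, repair),
         xml  = read_information_xml(raw_text, repair),
         csv  = read_information_csv(raw_text, repair))
}

build_layer <- function(raw_values, num_classes, name, labels, repair, locus) {
  canon <- canonicalise_values(raw_values, num_classes, repair, locus)
  if (!is.null(labels) && length(labels) != canon$num_classes) {
    stop_issue("LABEL_COUNT_MISMATCH",
               sprintf("%d labels for %d classes", length(labels),
                       canon$num_classes),
               locus = locus)
  }
  list(layer = pw_layer(canon$values, canon$num_classes, name = name,
                        labels = labels),
       issues = canon$issues)
}

assemble_infofile <- function(parts, dialect) {
  layers <- lapply(parts, `[[`, "layer")
  iss <- do.call(rbind, c(list(no_issues()), lapply(parts, `[[`, "issues")))
  lens <- vapply(layers, function(l) length(l$values), integer(1))
  if (length(unique(lens)) != 1) {
    stop_issue("RAGGED_LAYERS",
               paste("layer lengths differ:", paste(lens, collapse = ", ")))
  }
  info <- pw_infofile(layers, source_dialect = dialect)
  attr(info, "issues") <- iss
  info
}

read_information_json <- function(raw_text, repair = FALSE) {
  obj <- tryCatch(fromJSON(raw_text, simplifyVector = FALSE),
                  error = function(e) stop_issue("SYNTAX_ERROR",
                    paste("invalid JSON:", conditionMessage(e))))
  if (!is.list(obj) || !"information" %in% names(obj)) {
    stop_issue("MISSING_ROOT", "expected a root object called 'information'")
  }
  sets <- obj$information
  if (!is.list(sets) || length(sets) == 0) {
    stop_issue("EMPTY_INFORMATION", "information file defines no layers")
  }
  parts <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    locus <- sprintf("layer %d", i)
    if (is.null(s$values) || length(s$values) == 0) {
      stop_issue("VALUE_OUT_OF_RANGE", "layer lacks 'values'", locus = locus)
    }
    vals <- suppressWarnings(as.numeric(unlist(s$values, use.names = FALSE)))
    name <- if (!is.null(s$name)) as.character(s$name[[1]]) else NULL
    labels <- if (!is.null(s$labels)) {
      as.character(unlist(s$labels, use.names = FALSE))
    } else NULL
    k <- if (!is.null(s$numClass)) suppressWarnings(as.numeric(s$numClass[[1]]))
         else NULL
    build_layer(vals, k, name, labels, repair, locus)
  })
  assemble_infofile(parts, "json")
}

read_information_xml <- function(raw_text, repair = FALSE) {
  doc <- parse_xml_doc(raw_text, "information")
  sets <- xml_find_all(doc, "./set")
  if (length(sets) == 0) {
    stop_issue("EMPTY_INFORMATION", "information file defines no <set> layers")
  }
  parts <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    locus <- sprintf("layer %d", i)
    value_nodes <- xml_find_all(s, "./values/value")
    if (length(value_nodes) == 0) {
      stop_issue("VALUE_OUT_OF_RANGE", "layer lacks <values>", locus = locus)
    }
    vals <- suppressWarnings(as.numeric(xml_text(value_nodes)))
    name_node <- xml_find_first(s, "./name")
    name <- if (inherits(name_node, "xml_missing")) NULL else xml_text(name_node)
    label_nodes <- xml_find_all(s, "./labels/label")
    labels <- if (length(label_nodes) > 0) xml_text(label_nodes) else NULL
    k_node <- xml_find_first(s, "./numClass")
    k <- if (inherits(k_node, "xml_missing")) NULL
         else suppressWarnings(as.numeric(xml_text(k_node)))
    build_layer(vals, k, name, labels, repair, locus)
  })
  assemble_infofile(parts, "xml")
}

read_information_csv <- function(raw_text, repair = FALSE) {
  lines <- split_lines(raw_text)
  if (length(lines) == 0) {
    stop_issue("EMPTY_INFORMATION", "information file defines no layers")
  }
  rows <- lapply(lines, csv_fields)
  widths <- vapply(rows, length, integer(1))
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop_issue("RAGGED_LAYERS",
               sprintf("line has %d fields, expected %d", widths[bad], widths[1]),
               locus = sprintf("line %d", bad))
  }
  ncols <- widths[1]
  parts <- lapply(seq_len(ncols), function(j) {
    col <- vapply(rows, `[[`, character(1), j)
    vals <- suppressWarnings(as.numeric(col))
    if (anyNA(vals)) {
      stop_issue("VALUE_OUT_OF_RANGE", "non-numeric class value",
                 locus = sprintf("column %d", j))
    }
    # CSV cannot declare numClass: infer as the count of distinct values
    build_layer(vals, NULL, NULL, NULL, repair, sprintf("column %d", j))
  })
  assemble_infofile(parts, "csv")
}

# ---- writers ----------------------------------------------------------------

json_string <- function(x) {
  as.character(toJSON(x, auto_unbox = TRUE))
}

#' Write a dataset document
#'
#' Serialises to the canonical form of the requested dialect. The output
#' is byte-stable: writing the same dataset twice yields identical text,
#' and numbers use the shortest decimal representation that round-trips.
#' CSV cannot express the dataset name or the chain flag; emitting either
#' produces `LOSSY_CSV` warnings, never silent loss.
#'
#' @param ds A [pw_dataset()].
#' @param dialect `"json"`, `"xml"` or `"csv"`.
#' @return A list with `text` (the document) and `issues` (a data frame of
#'   lossiness warnings; zero rows for JSON and XML).
#' @export
#' @examples
#' ds <- pw_dataset(rbind(c(0, 0, 0), c(1, 2, 3)), name = "demo")
#' cat(write_dataset(ds, "json")$text)
write_dataset <- function(ds, dialect) {
  stopifnot(inherits(ds, "pw_dataset"))
  dialect <- match.arg(dialect, c("json", "xml", "csv"))
  switch(dialect,
         json = write_dataset_json(ds),
         xml  = write_dataset_xml(ds),
         csv  = write_dataset_csv(ds))
}

write_dataset_json <- function(ds) {
  pts <- apply(ds$points, 1, function(p)
    paste0("      [", paste(format_coord(p), collapse = ", "), "]"))
  text <- paste0(
    "{\n  \"dataset\": {\n",
    "    \"name\": ", json_string(ds$name), ",\n",
    "    \"chain\": ", if (ds$chain) "true" else "false", ",\n",
    "    \"points\": [\n",
    paste(pts, collapse = ",\n"), "\n",
    "    ]\n  }\n}\n")
  list(text = text, issues = no_issues())
}

write_dataset_xml <- function(ds) {
  doc <- xml_new_root("dataset")
  xml_add_child(doc, "name", ds$name)
  xml_add_child(doc, "chain", if (ds$chain) "true" else "false")
  pts_node <- xml_add_child(doc, "points")
  coords <- matrix(format_coord(ds$points), ncol = 3)
  for (i in seq_len(nrow(coords))) {
    p <- xml_add_child(pts_node, "point")
    xml_add_child(p, "x", coords[i, 1])
    xml_add_child(p, "y", coords[i, 2])
    xml_add_child(p, "z", coords[i, 3])
  }
  list(text = paste0(as.character(doc), ""), issues = no_issues())
}

write_dataset_csv <- function(ds) {
  iss <- no_issues()
  if (ds$name != "dataset") {
    iss <- rbind(iss, validation_issue(
      "LOSSY_CSV", sprintf("dataset name '%s' cannot be expressed in CSV", ds$name)))
  }
  if (ds$chain) {
    iss <- rbind(iss, validation_issue(
      "LOSSY_CSV", "chain flag cannot be expressed in CSV; points become particles"))
  }
  rows <- apply(ds$points, 1, function(p) paste(format_coord(p), collapse = ","))
  list(text = paste0(paste(rows, collapse = "\n"), "\n"), issues = iss)
}

#' Write an information-layer document
#'
#' Serialises to the canonical form of the requested dialect; byte-stable
#' like [write_dataset()]. CSV emits one column per layer and cannot carry
#' layer names, labels or a declared class count; every such dropped field
#' yields a `LOSSY_CSV` warning. Because a CSV reader infers the class
#' count from the distinct values present, classes are renumbered to a
#' contiguous 0-based range on CSV output when necessary (again with a
#' warning) so that the emitted text re-parses.
#'
#' @param info A [pw_infofile()] or single [pw_layer()].
#' @param dialect `"json"`, `"xml"` or `"csv"`.
#' @return A list with `text` and `issues`, as in [write_dataset()].
#' @export
write_information <- function(info, dialect) {
  if (inherits(info, "pw_layer")) info <- pw_infofile(list(info))
  stopifnot(inherits(info, "pw_infofile"))
  dialect <- match.arg(dialect, c("json", "xml", "csv"))
  switch(dialect,
         json = write_information_json(info),
         xml  = write_information_xml(info),
         csv  = write_information_csv(info))
}

write_information_json <- function(info) {
  blocks <- vapply(info$layers, function(l) {
    fields <- character()
    if (!is.null(l$name)) {
      fields <- c(fields, paste0("      \"name\": ", json_string(l$name)))
    }
    fields <- c(fields, paste0("      \"numClass\": ", l$num_classes))
    if (!is.null(l$labels)) {
      fields <- c(fields, paste0("      \"labels\": [",
        paste(vapply(l$labels, json_string, character(1)), collapse = ", "), "]"))
    }
    fields <- c(fields, paste0("      \"values\": [",
      paste(l$values, collapse = ", "), "]"))
    paste0("    {\n", paste(fields, collapse = ",\n"), "\n    }")
  }, character(1))
  text <- paste0("{\n  \"information\": [\n",
                 paste(blocks, collapse = ",\n"),
                 "\n  ]\n}\n")
  list(text = text, issues = no_issues())
}

write_information_xml <- function(info) {
  doc <- xml_new_root("information")
  for (l in info$layers) {
    s <- xml_add_child(doc, "set")
    if (!is.null(l$name)) xml_add_child(s, "name", l$name)
    xml_add_child(s, "numClass", as.character(l$num_classes))
    if (!is.null(l$labels)) {
      labels_node <- xml_add_child(s, "labels")
      for (lb in l$labels) xml_add_child(labels_node, "label", lb)
    }
    values_node <- xml_add_child(s, "values")
    for (v in l$values) xml_add_child(values_node, "value", as.character(v))
  }
  list(text = as.character(doc), issues = no_issues())
}

write_information_csv <- function(info) {
  iss <- no_issues()
  cols <- vector("list", length(info$layers))
  for (i in seq_along(info$layers)) {
    l <- info$layers[[i]]
    locus <- sprintf("layer %d", i)
    if (!is.null(l$name)) {
      iss <- rbind(iss, validation_issue(
        "LOSSY_CSV", sprintf("layer name '%s' cannot be expressed in CSV", l$name),
        locus = locus))
    }
    if (!is.null(l$labels)) {
      iss <- rbind(iss, validation_issue(
        "LOSSY_CSV", "class labels cannot be expressed in CSV", locus = locus))
    }
    vals <- l$values
    present <- sort(unique(vals))
    if (!identical(present, seq_along(present) - 1L)) {
      # contiguity required so a reader's distinct-count inference holds
      vals <- match(vals, present) - 1L
      iss <- rbind(iss, validation_issue(
        "LOSSY_CSV",
        "classes renumbered to a contiguous 0-based range for CSV",
        locus = locus))
    } else if (l$num_classes > length(present)) {
      iss <- rbind(iss, validation_issue(
        "LOSSY_CSV",
        sprintf("declared class count %d collapses to %d observed classes in CSV",
                l$num_classes, length(present)),
        locus = locus))
    }
    cols[[i]] <- vals
  }
  mat <- do.call(cbind, cols)
  rows <- apply(mat, 1, paste, collapse = ",")
  list(text = paste0(paste(rows, collapse = "\n"), "\n"), issues = iss)
}

# ---- conversion -------------------------------------------------------------

#' Convert a document between dialects
#'
#' Detects the input, parses it and re-serialises in the requested
#' dialect. Semantics are preserved exactly for JSON and XML; conversions
#' to CSV lose the fields CSV cannot express, each loss reported as a
#' `LOSSY_CSV` warning in the returned issues.
#'
#' @param raw_text Input document text.
#' @param out_dialect Target dialect: `"json"`, `"xml"` or `"csv"`.
#' @param family Optional family override for ambiguous CSV inputs.
#' @param repair Passed to [read_information()].
#' @return A list with `text`, `issues` (read- and write-side combined),
#'   `family` and `from_dialect`.
#' @export
#' @examples
#' ex <- worked_example()
#' xml <- convert(write_dataset(ex$dataset, "json")$text, "xml")
#' cat(xml$text)
convert <- function(raw_text, out_dialect, family = NULL, repair = FALSE) {
  out_dialect <- match.arg(out_dialect, c("json", "xml", "csv"))
  det <- detect_format(raw_text, family = family)
  if (det$family == "dataset") {
    obj <- read_dataset(raw_text, det$dialect)
    out <- write_dataset(obj, out_dialect)
  } else {
    obj <- read_information(raw_text, det$dialect, repair = repair)
    out <- write_information(obj, out_dialect)
  }
  list(text = out$text, issues = rbind(issues_of(obj), out$issues),
       family = det$family, from_dialect = det$dialect)
}
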