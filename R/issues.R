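#' Catalogue of validation issue codes
#'
#' Every error or warning produced while parsing, writing, converting or
#' cross-validating files carries a short machine token drawn from this
#' closed catalogue. Codes are stable API: scripted callers may dispatch on
#' them.
#'
#' @return A data frame with columns `code`, `severity` (`"error"` or
#'   `"warning"`) and `description`.
#' @export
#' @examples
#' issue_catalogue()
issue_catalogue <- function() {
  rbind(
    data.frame(code = "UNRECOGNISED_FORMAT", severity = "error",
               description = "input matches none of the known dialects/families"),
    data.frame(code = "AMBIGUOUS_CSV_FAMILY", severity = "error",
               description = "3-column all-integer CSV; family must be forced by the caller"),
    data.frame(code = "SYNTAX_ERROR", severity = "error",
               description = "document is not well-formed in its dialect"),
    data.frame(code = "MISSING_ROOT", severity = "error",
               description = "expected root object/element absent"),
    data.frame(code = "EMPTY_DATASET", severity = "error",
               description = "dataset holds no points"),
    data.frame(code = "BAD_COORDINATE", severity = "error",
               description = "coordinate is non-numeric or non-finite"),
    data.frame(code = "BAD_ARITY", severity = "error",
               description = "a point does not have exactly three coordinates"),
    data.frame(code = "BAD_BOOLEAN", severity = "error",
               description = "chain flag is not 'true' or 'false'"),
    data.frame(code = "EMPTY_INFORMATION", severity = "error",
               description = "information file defines zero layers"),
    data.frame(code = "RAGGED_LAYERS", severity = "error",
               description = "layers in one file have unequal values lengths"),
    data.frame(code = "VALUE_OUT_OF_RANGE", severity = "error",
               description = "class value not mappable into [0, num_classes-1]"),
    data.frame(code = "LABEL_COUNT_MISMATCH", severity = "error",
               description = "labels length differs from declared class count"),
    data.frame(code = "LENGTH_MISMATCH", severity = "error",
               description = "layer values length differs from dataset point count"),
    data.frame(code = "LOSSY_CSV", severity = "warning",
               description = "field cannot be expressed in CSV and was dropped"),
    data.frame(code = "ONE_BASED_NORMALISED", severity = "warning",
               description = "values occupied {1..num_classes}; shifted to 0-based"),
    data.frame(code = "NUM_CLASSES_RAISED", severity = "warning",
               description = "repair mode raised num_classes to cover observed values"),
    data.frame(code = "EMPTY_CLASS", severity = "warning",
               description = "declared class has no member points"),
    data.frame(code = "WORLD_LIMIT", severity = "error",
               description = "a scene holds at most four worlds"),
    data.frame(code = "INVALID_PAIR", severity = "error",
               description = "layer failed cross-validation against its dataset"),
    data.frame(code = "EMPTY_SCENE", severity = "error",
               description = "no world has a bound dataset"),
    data.frame(code = "BAD_COLUMN", severity = "error",
               description = "column selector does not resolve"),
    data.frame(code = "NO_CA_ATOMS", severity = "error",
               description = "no C-alpha ATOM records found"),
    data.frame(code = "CHAIN_NOT_FOUND", severity = "error",
               description = "requested PDB chain identifier absent"),
    data.frame(code = "IO_ERROR", severity = "error",
               description = "file could not be read or written")
  )
}

#' Construct a validation issue record
#'
#' @param code Machine token from [issue_catalogue()].
#' @param message Human-readable description of this occurrence.
#' @param severity `"error"` or `"warning"`; defaults to the catalogue entry.
#' @param locus File/record position (e.g. `"line 3"`, `"layer 2"`), or `""`.
#' @return One-row data frame with columns `severity`, `code`, `message`,
#'   `locus`.
#' @export
validation_issue <- function(code, message, severity = NULL, locus = "") {
  cat <- issue_catalogue()
  if (!code %in% cat$code) {
    stop("unknown issue code: ", code)
  }
  if (is.null(severity)) severity <- cat$severity[cat$code == code]
  data.frame(severity = severity, code = code, message = message,
             locus = locus, stringsAsFactors = FALSE)
}

#' @rdname validation_issue
#' @export
no_issues <- function() {
  data.frame(severity = character(), code = character(),
             message = character(), locus = character(),
             stringsAsFactors = FALSE)
}

# Raise a classed condition carrying a structured issue. Callers can
# dispatch on class "pointworlds_error" and read conditionCall-free fields.
stop_issue <- function(code, message, locus = "") {
  issue <- validation_issue(code, message, severity = "error", locus = locus)
  cond <- structure(
    class = c(paste0("pointworlds_error_", code),
              "pointworlds_error", "error", "condition"),
    list(message = sprintf("[%s] %s%s", code, message,
                           if (nzchar(locus)) paste0(" (", locus, ")") else ""),
         call = sys.call(-1), issue = issue, code = code)
  )
  stop(cond)
}

#' Extract the machine code from a pointworlds error condition
#'
#' @param e A condition object caught with `tryCatch()`.
#' @return The issue code string, or `NA_character_` for foreign conditions.
#' @export
issue_code <- function(e) {
  if (inherits(e, "pointworlds_error")) e$code else NA_character_
}
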