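#' Import a delimited coordinate table as a dataset
#'
#' Turns tabular output from upstream analyses (e.g. the first three
#' principal-component scores of a PCA) into a dataset. Columns are
#' selected by header name or 1-based position; row order is preserved
#' and the result is a particle (non-chained) dataset.
#'
#' @param table Delimited text, or a path to a file when `is_path = TRUE`.
#' @param x_col,y_col,z_col Column selectors: header names (character) or
#'   1-based indices (numeric). The three selectors must be distinct.
#' @param name Dataset name.
#' @param sep Field separator (default comma; use `"\t"` for TSV).
#' @param header Whether the first row is a header; defaults to `TRUE`
#'   when any selector is a character name.
#' @param is_path Treat `table` as a file path.
#' @return A [pw_dataset()].
#' @export
#' @examples
#' txt <- "PC1,PC2,PC3\n1,2,3\n4,5,6"
#' table_to_dataset(txt, "PC1", "PC2", "PC3", name = "pca scores")
table_to_dataset <- function(table, x_col, y_col, z_col, name = "dataset",
                             sep = ",", header = NULL, is_path = FALSE) {
  sel <- list(x_col, y_col, z_col)
  if (is.null(header)) header <- any(vapply(sel, is.character, logical(1)))
  if (is_path) table <- read_text(table)
  df <- tryCatch(
    utils::read.table(text = table, sep = sep, header = header,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = ""),
    error = function(e) stop_issue("SYNTAX_ERROR",
      paste("cannot parse table:", conditionMessage(e))))
  cols <- vapply(sel, function(s) resolve_column(df, s), integer(1))
  if (anyDuplicated(cols)) {
    stop_issue("BAD_COLUMN", "x, y and z selectors must name distinct columns")
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = 3)
  for (j in 1:3) {
    raw <- df[[cols[j]]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop_issue("BAD_COORDINATE",
                 sprintf("non-numeric cell '%s' in column %d", raw[bad[1]], cols[j]),
                 locus = sprintf("row %d", bad[1]))
    }
    mat[, j] <- v
  }
  pw_dataset(mat, name = name, chain = FALSE)
}

resolve_column <- function(df, selector) {
  if (is.numeric(selector)) {
    selector <- as.integer(selector)
    if (selector < 1 || selector > ncol(df)) {
      stop_issue("BAD_COLUMN", sprintf("no column %d (table has %d)",
                                       selector, ncol(df)))
    }
    return(selector)
  }
  idx <- which(names(df) == selector)
  if (length(idx) != 1) {
    stop_issue("BAD_COLUMN", sprintf("no column named '%s'", selector))
  }
  idx
}

#' Convert a categorical label vector into an information layer
#'
#' Cluster assignments (factor, character or integer labels) become a
#' canonical layer: classes are numbered by first appearance, so class 0
#' is the first label seen, and the original category names become the
#' layer's class labels.
#'
#' @param labels Non-empty vector of categorical values.
#' @param name Optional layer name.
#' @return A [pw_layer()] whose class labels are the distinct input
#'   labels in first-appearance order.
#' @export
#' @examples
#' labels_to_layer(c("A", "A", "B"))
labels_to_layer <- function(labels, name = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  stopifnot(length(labels) >= 1, !anyNA(labels))
  labels <- as.character(labels)
  uniq <- unique(labels)
  pw_layer(match(labels, uniq) - 1L, num_classes = length(uniq),
           name = name, labels = uniq)
}

#' Import a PDB structure as a chained backbone dataset
#'
#' Extracts the C-alpha trace of one chain from PDB-format text: `ATOM`
#' records with atom name `CA`, first alternate location only, first
#' model only, in residue order. The result is a chained dataset, drawn
#' as a polyline through the backbone.
#'
#' @param pdb_text PDB-format text (or a path when `is_path = TRUE`).
#' @param chain_id Chain identifier; `NULL` selects the first chain that
#'   has C-alpha atoms.
#' @param name Dataset name; defaults to `"pdb <chain>"`.
#' @param is_path Treat `pdb_text` as a file path.
#' @return A [pw_dataset()] with `chain = TRUE`.
#' @export
pdb_to_chain_dataset <- function(pdb_text, chain_id = NULL, name = NULL,
                                 is_path = FALSE) {
  path <- if (is_path) pdb_text else {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(pdb_text, tmp)
    tmp
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_issue("SYNTAX_ERROR",
      paste("cannot parse PDB:", conditionMessage(e))))
  atoms <- pdb$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop_issue("NO_CA_ATOMS", "no C-alpha ATOM records found")
  if (is.null(chain_id)) {
    chain_id <- ca$chain[1]
  } else if (!chain_id %in% ca$chain) {
    stop_issue("CHAIN_NOT_FOUND",
               sprintf("chain '%s' not present (chains: %s)", chain_id,
                       paste(unique(ca$chain), collapse = ", ")))
  }
  ca <- ca[ca$chain == chain_id, , drop = FALSE]
  # first altloc per residue: keep the first CA record for each residue key
  key <- paste(ca$resno, ca$insert)
  ca <- ca[!duplicated(key), , drop = FALSE]
  pw_dataset(as.matrix(ca[, c("x", "y", "z")]),
             name = name %||% paste("pdb chain", chain_id),
             chain = TRUE)
}
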