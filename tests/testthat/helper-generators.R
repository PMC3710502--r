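# Random-object generators for property-style tests. All callers set a
# seed; nothing here consumes randomness beyond stats RNG.

random_dataset <- function(n = sample(1:25, 1)) {
  # mixed magnitudes and precisions exercise the shortest-round-trip writer
  pts <- matrix(signif(stats::runif(n * 3, -1, 1) *
                         10^sample(-3:3, n * 3, replace = TRUE),
                       sample(1:10, n * 3, replace = TRUE)),
                ncol = 3)
  pw_dataset(pts,
             name = paste0("ds-", paste(sample(letters, 6), collapse = "")),
             chain = sample(c(TRUE, FALSE), 1))
}

random_layer <- function(n) {
  k <- sample(1:min(6, n + 2), 1)
  vals <- c(seq_len(min(k, n)) - 1L,
            sample(0:(k - 1), max(0, n - k), replace = TRUE))[seq_len(n)]
  labelled <- sample(c(TRUE, FALSE), 1)
  pw_layer(vals, num_classes = k,
           name = if (sample(c(TRUE, FALSE), 1))
             paste0("layer-", paste(sample(letters, 4), collapse = "")) else NULL,
           labels = if (labelled)
             paste0("class ", seq_len(k)) else NULL)
}

random_infofile <- function(n = sample(1:20, 1),
                            n_layers = sample(1:3, 1)) {
  pw_infofile(lapply(seq_len(n_layers), function(i) random_layer(n)))
}

# Fixed-format PDB text with CA atoms at the given coordinates.
make_pdb <- function(coords, chain = "A", altloc = " ",
                     extra_lines = character()) {
  coords <- as.matrix(coords)
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  CA %sALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, substr(altloc, 1, 1), chain, i,
            coords[i, 1], coords[i, 2], coords[i, 3], 1, 0)
  }, character(1))
  paste(c(lines, extra_lines, "END"), collapse = "\n")
}

expect_issue_error <- function(expr, code) {
  err <- tryCatch({ expr; NULL }, pointworlds_error = function(e) e)
  expect_false(is.null(err), label = paste("expected", code, "error"))
  if (!is.null(err)) expect_identical(issue_code(err), code)
  invisible(err)
}
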