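#' The minimal worked example: three points, two layers
#'
#' A 3-point particle dataset with injective coordinates (so order
#' preservation is observable) paired with an information file holding
#' two layers: the first puts the first two points together in one class
#' and the third point alone in a second class; the second puts each
#' point in its own class — the two partitions two different clustering
#' algorithms might produce.
#'
#' @return A list with elements `dataset` (a [pw_dataset()]) and
#'   `information` (a [pw_infofile()] of two layers). The pair validates
#'   cleanly.
#' @export
#' @examples
#' ex <- worked_example()
#' validate_pair(ex$dataset, ex$information)
worked_example <- function() {
  ds <- pw_dataset(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   name = "minimal example", chain = FALSE)
  layer_a <- pw_layer(c(0L, 0L, 1L), num_classes = 2,
                      name = "two clusters",
                      labels = c("pair", "singleton"))
  layer_b <- pw_layer(c(0L, 1L, 2L), num_classes = 3,
                      name = "all separate")
  list(dataset = ds, information = pw_infofile(list(layer_a, layer_b)))
}

#' Simulate a clustered 3D cell map
#'
#' Draws an isotropic Gaussian mixture: `k` cluster centers (given, or
#' sampled uniformly in the unit cube) each emitting `n_per_cluster`
#' points with coordinate-wise normal noise of standard deviation
#' `sigma`. This emulates a spatial map of cell-sized bins grouped into
#' expression clusters, and pairs every point with its generating
#' cluster as a ground-truth information layer. Deterministic given
#' `seed`; the caller's random-number state is left untouched.
#'
#' @param k Number of clusters (>= 1).
#' @param n_per_cluster Points per cluster (>= 1).
#' @param centers Optional k x 3 matrix of cluster centers; sampled in
#'   the unit cube when `NULL`.
#' @param sigma Isotropic noise standard deviation (>= 0; 0 puts every
#'   point exactly on its center).
#' @param seed Integer seed.
#' @param name Dataset name.
#' @return A list with `dataset` (N = `k * n_per_cluster` points, in
#'   cluster-major order), `layer` (true cluster index per point) and
#'   `centers`.
#' @export
#' @examples
#' sim <- simulate_clusters(k = 3, n_per_cluster = 10, sigma = 0.02, seed = 7)
#' validate_pair(sim$dataset, pw_infofile(list(sim$layer)))
simulate_clusters <- function(k = 3, n_per_cluster = 100, centers = NULL,
                              sigma = 0.05, seed = 1,
                              name = "simulated clusters") {
  stopifnot(k >= 1, n_per_cluster >= 1, sigma >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  if (is.null(centers)) {
    centers <- matrix(stats::runif(k * 3), ncol = 3)
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == k, ncol(centers) == 3)
  }
  n <- k * n_per_cluster
  noise <- matrix(stats::rnorm(n * 3, sd = sigma), ncol = 3)
  assign_idx <- rep(seq_len(k), each = n_per_cluster)
  pts <- centers[assign_idx, , drop = FALSE] + noise
  list(dataset = pw_dataset(pts, name = name, chain = FALSE),
       layer = pw_layer(assign_idx - 1L, num_classes = k,
                        name = "true clusters"),
       centers = centers)
}

#' Write the reference fixture suite to a directory
#'
#' Emits the worked example and a default cluster simulation in all three
#' dialects and both families, plus a corpus of deliberately corrupted
#' files, one planted defect each. A tab-separated manifest maps every
#' file to its family, dialect and the issue code parsing it must raise
#' (empty for clean files). Re-running with the same seed is
#' byte-identical.
#'
#' @param directory Output directory (created if needed).
#' @param k,n_per_cluster,sigma Cluster-simulation parameters, as in
#'   [simulate_clusters()].
#' @param seed Seed for the cluster simulation.
#' @return The manifest data frame (columns `file`, `family`, `dialect`,
#'   `expected_code`), invisibly written as `manifest.tsv`.
#' @export
emit_fixture_suite <- function(directory, k = 3, n_per_cluster = 100,
                               sigma = 0.05, seed = 1) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop_issue("IO_ERROR", paste("cannot create directory", directory))
  }
  manifest <- data.frame(file = character(), family = character(),
                         dialect = character(), expected_code = character(),
                         stringsAsFactors = FALSE)
  put <- function(fname, text, family, dialect, code = "") {
    con <- file(file.path(directory, fname), open = "wb")
    writeBin(charToRaw(text), con)
    close(con)
    manifest <<- rbind(manifest, data.frame(
      file = fname, family = family, dialect = dialect,
      expected_code = code, stringsAsFactors = FALSE))
  }

  ex <- worked_example()
  sim <- simulate_clusters(k = k, n_per_cluster = n_per_cluster,
                           sigma = sigma, seed = seed)
  for (d in c("json", "xml", "csv")) {
    put(paste0("worked_dataset.", d), write_dataset(ex$dataset, d)$text,
        "dataset", d)
    put(paste0("worked_information.", d),
        write_information(ex$information, d)$text, "information", d)
    put(paste0("clusters_dataset.", d), write_dataset(sim$dataset, d)$text,
        "dataset", d)
    put(paste0("clusters_information.", d),
        write_information(pw_infofile(list(sim$layer)), d)$text,
        "information", d)
  }

  for (i in seq_len(nrow(corrupted_corpus()))) {
    row <- corrupted_corpus()[i, ]
    put(row$file, row$text, row$family, row$dialect, row$expected_code)
  }

  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# One planted defect per file; the expected_code is what read_dataset /
# read_information must raise.
corrupted_corpus <- function() {
  rows <- list(
    list("bad_syntax.json", "dataset", "json", "SYNTAX_ERROR",
         '{"dataset": {"points": [[0,0,0]'),
    list("missing_root.json", "dataset", "json", "MISSING_ROOT",
         '{"data": {"points": [[0,0,0]]}}'),
    list("bad_coordinate.json", "dataset", "json", "BAD_COORDINATE",
         '{"dataset": {"points": [[0,0,"zero"]]}}'),
    list("bad_arity.json", "dataset", "json", "BAD_ARITY",
         '{"dataset": {"points": [[0,0,0],[1,1]]}}'),
    list("bad_boolean.json", "dataset", "json", "BAD_BOOLEAN",
         '{"dataset": {"chain": "maybe", "points": [[0,0,0]]}}'),
    list("bad_arity.csv", "dataset", "csv", "BAD_ARITY",
         "0,0,0\n1,1\n2,2,2\n"),
    list("bad_coordinate.csv", "dataset", "csv", "BAD_COORDINATE",
         "0,0,0\n1,x,1\n"),
    list("bad_boolean.xml", "dataset", "xml", "BAD_BOOLEAN",
         paste0("<dataset><chain>perhaps</chain><points>",
                "<point><x>0</x><y>0</y><z>0</z></point></points></dataset>")),
    list("bad_syntax.xml", "dataset", "xml", "SYNTAX_ERROR",
         "<dataset><points><point><x>0</x>"),
    list("missing_root.xml", "information", "xml", "MISSING_ROOT",
         "<info><set><numClass>1</numClass><values><value>0</value></values></set></info>"),
    list("bad_point_arity.xml", "dataset", "xml", "BAD_ARITY",
         paste0("<dataset><points><point><x>0</x><y>0</y></point>",
                "</points></dataset>")),
    list("empty_information.json", "information", "json", "EMPTY_INFORMATION",
         '{"information": []}'),
    list("ragged_layers.json", "information", "json", "RAGGED_LAYERS",
         paste0('{"information": [{"numClass": 1, "values": [0,0,0]},',
                '{"numClass": 1, "values": [0,0]}]}')),
    list("ragged_layers.csv", "information", "csv", "RAGGED_LAYERS",
         "0,1\n0\n1,1\n"),
    list("value_out_of_range.json", "information", "json", "VALUE_OUT_OF_RANGE",
         '{"information": [{"numClass": 2, "values": [0,1,5]}]}'),
    list("label_count_mismatch.json", "information", "json", "LABEL_COUNT_MISMATCH",
         paste0('{"information": [{"numClass": 2, "labels": ["a","b","c"],',
                ' "values": [0,1,0]}]}'))
  )
  data.frame(
    file = vapply(rows, `[[`, character(1), 1),
    family = vapply(rows, `[[`, character(1), 2),
    dialect = vapply(rows, `[[`, character(1), 3),
    expected_code = vapply(rows, `[[`, character(1), 4),
    text = vapply(rows, `[[`, character(1), 5),
    stringsAsFactors = FALSE)
}
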