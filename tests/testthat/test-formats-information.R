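worked_information_json <- function() {
  write_information(worked_example()$information, "json")$text
}

test_that("the two-layer worked example parses from JSON as specified", {
  info <- read_information(worked_information_json(), "json")
  expect_s3_class(info, "pw_infofile")
  expect_length(info$layers, 2)
  # first clustering: points 1,2 together, point 3 alone
  expect_equal(info$layers[[1]]$values, c(0L, 0L, 1L))
  expect_equal(info$layers[[1]]$num_classes, 2L)
  # second clustering: each point its own class
  expect_equal(info$layers[[2]]$values, c(0L, 1L, 2L))
  expect_equal(info$layers[[2]]$num_classes, 3L)
  expect_equal(nrow(issues(info)), 0)
})

test_that("CSV information columns infer their class count from distinct values", {
  info <- read_information("0\n0\n0\n", "csv")
  expect_length(info$layers, 1)
  expect_equal(info$layers[[1]]$num_classes, 1L)
  expect_equal(info$layers[[1]]$values, c(0L, 0L, 0L))
  expect_null(info$layers[[1]]$name)    # CSV cannot express names
  expect_null(info$layers[[1]]$labels)

  multi <- read_information("0,0\n0,1\n1,2\n", "csv")
  expect_equal(vapply(multi$layers, `[[`, integer(1), "num_classes"), c(2L, 3L))
})

test_that("one-based class values are normalised down with an explicit warning", {
  txt <- '{"information": [{"numClass": 2, "values": [1, 1, 2]}]}'
  info <- read_information(txt, "json")
  expect_equal(info$layers[[1]]$values, c(0L, 0L, 1L))
  expect_equal(issues(info)$code, "ONE_BASED_NORMALISED")

  # valid under the 0-based reading: taken literally, no shift
  amb <- read_information('{"information": [{"numClass": 3, "values": [1, 2, 1]}]}')
  expect_equal(amb$layers[[1]]$values, c(1L, 2L, 1L))
  expect_equal(nrow(issues(amb)), 0)
})

test_that("out-of-range values error strictly, or raise num_classes in repair mode", {
  txt <- '{"information": [{"numClass": 2, "values": [0, 1, 5]}]}'
  expect_issue_error(read_information(txt, "json"), "VALUE_OUT_OF_RANGE")
  rep <- read_information(txt, "json", repair = TRUE)
  expect_equal(rep$layers[[1]]$num_classes, 6L)
  expect_equal(issues(rep)$code, "NUM_CLASSES_RAISED")
  # negative values are never repairable
  expect_issue_error(
    read_information('{"information": [{"numClass": 2, "values": [-1, 0]}]}',
                     repair = TRUE),
    "VALUE_OUT_OF_RANGE")
})

test_that("structural information defects raise the precise catalogue code", {
  expect_issue_error(read_information('{"information": []}'), "EMPTY_INFORMATION")
  expect_issue_error(
    read_information('{"values": [0]}', "json"), "MISSING_ROOT")
  expect_issue_error(read_information(
    '{"information": [{"numClass":1,"values":[0,0]},{"numClass":1,"values":[0]}]}'),
    "RAGGED_LAYERS")
  expect_issue_error(read_information("0,1\n0\n", "csv"), "RAGGED_LAYERS")
  expect_issue_error(read_information(
    '{"information": [{"numClass":2,"labels":["a"],"values":[0,1]}]}'),
    "LABEL_COUNT_MISMATCH")
})

test_that("information files round-trip exactly through JSON and XML", {
  set.seed(202)
  for (rep in 1:40) {
    info <- random_infofile()
    for (d in c("json", "xml")) {
      out <- write_information(info, d)
      expect_equal(nrow(out$issues), 0)
      back <- read_information(out$text, d)
      for (i in seq_along(info$layers)) {
        expect_identical(back$layers[[i]]$values, info$layers[[i]]$values)
        expect_identical(back$layers[[i]]$num_classes, info$layers[[i]]$num_classes)
        expect_identical(back$layers[[i]]$name, info$layers[[i]]$name)
        expect_identical(back$layers[[i]]$labels, info$layers[[i]]$labels)
      }
      expect_identical(write_information(back, d)$text, out$text)
    }
  }
})

test_that("CSV information output re-parses, with every loss warned about", {
  set.seed(203)
  for (rep in 1:25) {
    info <- random_infofile()
    out <- write_information(info, "csv")
    lossy_fields <- sum(vapply(info$layers, function(l) {
      sum(!is.null(l$name), !is.null(l$labels))
    }, numeric(1)))
    expect_gte(nrow(out$issues), lossy_fields)
    back <- read_information(out$text, "csv")
    expect_length(back$layers, length(info$layers))
    for (i in seq_along(info$layers)) {
      # partition identity survives even if classes were renumbered
      a <- info$layers[[i]]$values
      b <- back$layers[[i]]$values
      expect_true(all(tapply(b, a, function(v) length(unique(v))) == 1))
      expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
    }
  }
})

test_that("sparse class numbering is renumbered for CSV with a warning", {
  info <- pw_infofile(list(pw_layer(c(0L, 2L, 0L), num_classes = 3)))
  out <- write_information(info, "csv")
  expect_true(any(out$issues$code == "LOSSY_CSV"))
  expect_equal(read_information(out$text, "csv")$layers[[1]]$values,
               c(0L, 1L, 0L))
})

test_that("pair validation flags length mismatches per layer and empty classes", {
  ex <- worked_example()
  expect_equal(nrow(validate_pair(ex$dataset, ex$information)), 0)

  long_layer <- pw_layer(c(0L, 0L, 1L, 1L), num_classes = 2)
  iss <- validate_pair(ex$dataset, pw_infofile(list(long_layer)))
  expect_equal(iss$code, "LENGTH_MISMATCH")
  expect_equal(iss$severity, "error")

  sparse <- pw_layer(c(0L, 0L, 0L), num_classes = 3)
  iss <- validate_pair(ex$dataset, pw_infofile(list(sparse)))
  expect_equal(iss$code, "EMPTY_CLASS")
  expect_equal(iss$severity, "warning")
})

# validate_pair must see ragged layers to count per-layer mismatches, so
# bypass the constructor's equal-length invariant for this corruption test.
pw_infofile_ragged_ok <- function(layers) {
  structure(list(layers = layers, source_dialect = NA_character_),
            class = "pw_infofile")
}

test_that("every corrupted layer of a pair yields exactly one mismatch error", {
  set.seed(204)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    ds <- random_dataset(n)
    n_layers <- sample(1:3, 1)
    corrupt <- sample(c(TRUE, FALSE), n_layers, replace = TRUE)
    layers <- lapply(seq_len(n_layers), function(i) {
      len <- if (corrupt[i]) n + sample(c(-1, 1, 2), 1) else n
      pw_layer(rep(0L, max(1, len)), num_classes = 1)
    })
    iss <- validate_pair(ds, pw_infofile_ragged_ok(layers))
    mism <- iss[iss$code == "LENGTH_MISMATCH", ]
    expect_equal(nrow(mism), sum(corrupt & vapply(layers, function(l)
      length(l$values) != n, logical(1))))
  }
})
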