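test_that("format detection identifies dialect and family by root token", {
  expect_equal(detect_format('{"dataset": {"points": [[0,0,0]]}}'),
               list(dialect = "json", family = "dataset"))
  expect_equal(detect_format('{"information": [{"numClass":1,"values":[0]}]}'),
               list(dialect = "json", family = "information"))
  expect_equal(
    detect_format("<information><set><numClass>1</numClass><values><value>0</value></values></set></information>"),
    list(dialect = "xml", family = "information"))
  expect_equal(detect_format("0.5,1.5,2\n1,2,3\n")$family, "dataset")
  expect_equal(detect_format("0,1\n1,0\n")$family, "information")
  expect_issue_error(detect_format(""), "UNRECOGNISED_FORMAT")
  expect_issue_error(detect_format("a,b,c\n"), "UNRECOGNISED_FORMAT")
})

test_that("three-column all-integer CSV is ambiguous until the family is forced", {
  txt <- "0,0,0\n1,0,0\n0,1,0\n"
  expect_issue_error(detect_format(txt), "AMBIGUOUS_CSV_FAMILY")
  expect_equal(detect_format(txt, family = "dataset")$family, "dataset")
  expect_equal(detect_format(txt, family = "information")$family, "information")
  # forcing a family that contradicts a structured root is refused
  expect_issue_error(
    detect_format('{"dataset": {"points": [[0,0,0]]}}', family = "information"),
    "UNRECOGNISED_FORMAT")
})

test_that("JSON dataset parsing honours defaults and preserves order", {
  ds <- read_dataset('{"dataset": {"name": "demo", "points": [[0,0,0],[1,2,3],[4,5,6]]}}')
  expect_s3_class(ds, "pw_dataset")
  expect_equal(n_points(ds), 3)
  expect_false(ds$chain)  # chain defaults to false when absent
  expect_equal(ds$name, "demo")
  expect_equal(ds$points[2, ], c(x = 1, y = 2, z = 3))
  expect_equal(ds$source_dialect, "json")

  one <- read_dataset('{"dataset": {"chain": true, "points": [[1,1,1]]}}')
  expect_true(one$chain)
  expect_equal(n_points(one), 1)  # a 1-point chain has zero segments
})

test_that("XML dataset parsing matches the JSON reading of the same content", {
  xml <- paste0("<dataset><name>demo</name><chain>TRUE</chain><points>",
                "<point><x>1</x><y>2</y><z>3</z></point>",
                "<point><x>-4.5</x><y>0</y><z>6e2</z></point>",
                "</points></dataset>")
  ds <- read_dataset(xml)
  expect_true(ds$chain)  # booleans are case-insensitive
  expect_equal(unname(ds$points), rbind(c(1, 2, 3), c(-4.5, 0, 600)))
  expect_issue_error(
    read_dataset("<dataset><chain>yes</chain><points><point><x>0</x><y>0</y><z>0</z></point></points></dataset>"),
    "BAD_BOOLEAN")
})

test_that("CSV dataset parsing trims fields, accepts CRLF, drops trailing blank", {
  ds <- read_dataset("1, 2 ,3\r\n4,5,6\r\n\r\n", dialect = "csv")
  expect_equal(unname(ds$points), rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(ds$name, "dataset")  # CSV cannot express a name
  expect_false(ds$chain)
})

test_that("malformed dataset documents raise the precise catalogue code", {
  cases <- list(
    list('{"dataset": {"points": [[0,0,0]', "SYNTAX_ERROR"),
    list('{"other": 1}', "MISSING_ROOT"),
    list('{"dataset": {"points": [[0,0,"a"]]}}', "BAD_COORDINATE"),
    list('{"dataset": {"points": [[0,0],[0,0,0]]}}', "BAD_ARITY"),
    list('{"dataset": {"points": []}}', "EMPTY_DATASET"),
    list('{"dataset": {"chain": "true", "points": [[0,0,0]]}}', "BAD_BOOLEAN"))
  for (cs in cases) expect_issue_error(read_dataset(cs[[1]], "json"), cs[[2]])
  expect_issue_error(read_dataset("1,2\n", "csv"), "BAD_ARITY")
  expect_issue_error(read_dataset("1,2,x\n", "csv"), "BAD_COORDINATE")
  err <- expect_issue_error(read_dataset("1,2,3\n4,5\n", "csv"), "BAD_ARITY")
  expect_equal(err$issue$locus, "line 2")
})

test_that("write/read round-trips preserve datasets exactly in every dialect", {
  set.seed(101)
  for (rep in 1:40) {
    ds <- random_dataset()
    for (d in c("json", "xml")) {
      out <- write_dataset(ds, d)
      expect_equal(nrow(out$issues), 0)
      back <- read_dataset(out$text, d)
      expect_identical(back$points, ds$points)
      expect_identical(back$name, ds$name)
      expect_identical(back$chain, ds$chain)
      # canonical writers are byte-stable
      expect_identical(write_dataset(back, d)$text, out$text)
    }
    out <- write_dataset(ds, "csv")
    back <- read_dataset(out$text, "csv")
    expect_identical(back$points, ds$points)  # coordinates survive CSV
  }
})

test_that("CSV emission of a named or chained dataset warns, never loses silently", {
  plain <- pw_dataset(rbind(c(0.5, 0, 0)), name = "dataset", chain = FALSE)
  expect_equal(nrow(write_dataset(plain, "csv")$issues), 0)

  named <- pw_dataset(rbind(c(0.5, 0, 0)), name = "my cells")
  iss <- write_dataset(named, "csv")$issues
  expect_equal(iss$code, "LOSSY_CSV")

  chained <- pw_dataset(rbind(c(0.5, 0, 0), c(1, 1, 1)), name = "bb", chain = TRUE)
  iss <- write_dataset(chained, "csv")$issues
  expect_equal(iss$code, c("LOSSY_CSV", "LOSSY_CSV"))

  lines <- strsplit(write_dataset(chained, "csv")$text, "\n")[[1]]
  expect_length(lines, 2)
  expect_true(all(lengths(strsplit(lines, ",")) == 3))
})

test_that("convert composes read and write across dialects", {
  ex <- worked_example()
  js <- write_dataset(ex$dataset, "json")$text
  xml <- convert(js, "xml")
  expect_equal(xml$from_dialect, "json")
  expect_equal(nrow(xml$issues), 0)
  # the XML and JSON documents carry the same information
  expect_identical(convert(xml$text, "json")$text, js)
  csv <- convert(js, "csv")
  expect_true(any(csv$issues$code == "LOSSY_CSV"))  # name dropped
})
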