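worked_scene <- function(n_worlds = 1, settings = scene_settings()) {
  ex <- worked_example()
  sc <- scene(settings)
  for (i in seq_len(n_worlds)) {
    sc <- add_world(sc)
    sc <- attach_dataset(sc, i, ex$dataset)
    sc <- attach_layer(sc, i, 1, ex$information, layer_index = 1)
  }
  sc
}

test_that("the worked example compiles to a shadow batch plus two class batches", {
  sc <- worked_scene()
  prims <- build_primitives(sc$worlds[[1]], sc$settings)
  expect_length(prims, 3)
  kinds <- vapply(prims, `[[`, character(1), "kind")
  expect_equal(kinds, rep("particles", 3))
  sizes <- vapply(prims, function(p) nrow(p$positions), integer(1))
  expect_equal(sizes, c(3L, 2L, 1L))  # all raw points, class 0 pair, class 1 singleton
  expect_equal(prims[[1]]$tag$class, "raw")
  expect_equal(prims[[1]]$opacity, sc$settings$raw_opacity)
  expect_equal(prims[[2]]$tag$class, 0)
})

test_that("hidden classes leave the shadow intact but contribute no colour", {
  sc <- worked_scene()
  sc <- set_class_display(sc, 1, 1, 0, visible = FALSE)
  sc <- set_class_display(sc, 1, 1, 1, visible = FALSE)
  prims <- build_primitives(sc$worlds[[1]], sc$settings)
  expect_length(prims, 1)
  expect_equal(prims[[1]]$tag$class, "raw")
  expect_equal(nrow(prims[[1]]$positions), 3)
})

test_that("chained datasets emit a polyline with exactly N-1 segments", {
  two <- pw_dataset(rbind(c(0, 0, 0), c(1, 1, 1)), name = "seg", chain = TRUE)
  sc <- attach_dataset(add_world(scene()), 1, two)
  prims <- build_primitives(sc$worlds[[1]], sc$settings)
  poly <- Filter(function(p) p$kind == "polyline", prims)
  expect_length(poly, 1)
  expect_equal(nrow(poly[[1]]$positions), 2)  # one segment

  one <- pw_dataset(rbind(c(0, 0, 0)), name = "pt", chain = TRUE)
  sc1 <- attach_dataset(add_world(scene()), 1, one)
  prims1 <- build_primitives(sc1$worlds[[1]], sc1$settings)
  expect_length(Filter(function(p) p$kind == "polyline", prims1), 0)
})

test_that("point conservation holds across random scenes with hidden classes", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    ds <- random_dataset(n)
    layer <- random_layer(n)
    sc <- attach_dataset(add_world(scene()), 1, ds)
    sc <- attach_layer(sc, 1, 1, layer)
    hidden <- which(sample(c(TRUE, FALSE), layer$num_classes, replace = TRUE))
    for (h in hidden) sc <- set_class_display(sc, 1, 1, h - 1L, visible = FALSE)
    prims <- build_primitives(sc$worlds[[1]], sc$settings)
    parts <- Filter(function(p) p$kind == "particles", prims)
    class_pts <- sum(vapply(parts[-1], function(p) nrow(p$positions), integer(1)))
    hidden_pts <- sum(layer$values %in% (hidden - 1L))
    expect_equal(class_pts + hidden_pts, n)            # conservation
    expect_equal(nrow(parts[[1]]$positions), n)        # shadow always complete
  }
})

test_that("documents are self-contained with a faithful data island", {
  sc <- worked_scene()
  html <- render_document(sc)
  expect_false(grepl("https?://|file://|ftp://", html))  # no external fetches
  island <- extract_data_island(html)
  expect_length(island$worlds, 1)
  prims <- island$worlds[[1]]$primitives
  expect_length(prims, 3)
  direct <- build_primitives(sc$worlds[[1]], sc$settings)
  for (i in seq_along(prims)) {
    got <- do.call(rbind, lapply(prims[[i]]$positions, unlist))
    expect_equal(got, unname(direct[[i]]$positions))
    expect_equal(unlist(prims[[i]]$colour), direct[[i]]$colour)
    expect_equal(prims[[i]]$opacity, direct[[i]]$opacity)
  }
})

test_that("a four-world scene renders four sub-views", {
  html <- render_document(worked_scene(4))
  island <- extract_data_island(html)
  expect_length(island$worlds, 4)
  expect_equal(vapply(island$worlds, `[[`, integer(1), "id"), 1:4)
  expect_equal(lengths(regmatches(html, gregexpr("class=\"world quad\"|'world quad'", html))), 1)
})

test_that("island round-trips are exact for random scenes", {
  set.seed(405)
  for (rep in 1:5) {
    n <- sample(2:30, 1)
    sc <- attach_dataset(add_world(scene()), 1, random_dataset(n))
    sc <- attach_layer(sc, 1, 1, random_layer(n))
    island <- extract_data_island(render_document(sc))
    direct <- build_primitives(sc$worlds[[1]], sc$settings)
    expect_length(island$worlds[[1]]$primitives, length(direct))
    for (i in seq_along(direct)) {
      got <- do.call(rbind, lapply(island$worlds[[1]]$primitives[[i]]$positions,
                                   unlist))
      expect_equal(got, unname(direct[[i]]$positions))
    }
  }
})

test_that("rendering an empty scene is refused", {
  expect_issue_error(render_document(scene()), "EMPTY_SCENE")
  expect_issue_error(render_document(add_world(scene())), "EMPTY_SCENE")
  expect_issue_error(render_static(add_world(scene()), tempfile()), "EMPTY_SCENE")
})

test_that("static rendering honours the requested pixel size", {
  skip_if_not_installed("png")
  f <- withr::local_tempfile(fileext = ".png")
  render_static(worked_scene(), f, width = 640, height = 480)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], c(480L, 640L))
})

test_that("static rendering is deterministic and keeps the shadow when all classes hide", {
  sc <- worked_scene()
  sc <- set_class_display(sc, 1, 1, 0, visible = FALSE)
  sc <- set_class_display(sc, 1, 1, 1, visible = FALSE)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_static(sc, f1, width = 200, height = 150)
  render_static(sc, f2, width = 200, height = 150)
  b1 <- readBin(f1, "raw", file.info(f1)$size)
  expect_identical(b1, readBin(f2, "raw", file.info(f2)$size))
  skip_if_not_installed("png")
  img <- png::readPNG(f1)
  expect_gt(length(unique(as.vector(img[, , 1]))), 1)  # shadow points drawn
})
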