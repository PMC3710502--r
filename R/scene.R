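#' Global display settings
#'
#' Settings apply to all worlds and all datasets of a scene: per-axis
#' scale factors, opacity and size for the raw (shadow) points and for the
#' coloured information-layer points, and whether to center the data
#' around the origin before display.
#'
#' @param axis_scale Positive length-3 numeric, multiplicative scale per
#'   axis (x, y, z).
#' @param raw_opacity,layer_opacity Opacities in (0, 1]. Raw points are
#'   faint by default so the coloured classes read on top of them.
#' @param raw_size,layer_size Positive marker sizes (renderer units).
#' @param center If `TRUE`, subtract each axis' bounding-box midpoint so
#'   the displayed extents are symmetric about 0; if `FALSE` coordinates
#'   are used as inputted.
#' @return An object of class `pw_settings`.
#' @export
scene_settings <- function(axis_scale = c(1, 1, 1),
                           raw_opacity = 0.15, layer_opacity = 0.9,
                           raw_size = 1, layer_size = 1,
                           center = FALSE) {
  axis_scale <- as.numeric(axis_scale)
  stopifnot(length(axis_scale) == 3, all(is.finite(axis_scale)),
            all(axis_scale > 0),
            raw_opacity > 0, raw_opacity <= 1,
            layer_opacity > 0, layer_opacity <= 1,
            raw_size > 0, layer_size > 0,
            is.logical(center), length(center) == 1, !is.na(center))
  structure(list(axis_scale = axis_scale,
                 raw_opacity = raw_opacity, layer_opacity = layer_opacity,
                 raw_size = raw_size, layer_size = layer_size,
                 center = center),
            class = "pw_settings")
}

#' Create an empty scene
#'
#' A scene holds up to four worlds (independent visualisation
#' sub-windows), each binding datasets with an optional active information
#' layer and per-class display control, plus one global [scene_settings()]
#' object.
#'
#' @param settings A [scene_settings()] object.
#' @return An object of class `pw_scene` with zero worlds.
#' @seealso [add_world()], [attach_dataset()], [attach_layer()]
#' @export
#' @examples
#' sc <- scene()
#' sc <- add_world(sc)
#' ex <- worked_example()
#' sc <- attach_dataset(sc, 1, ex$dataset)
#' sc <- attach_layer(sc, 1, "minimal example", ex$information$layers[[1]])
scene <- function(settings = scene_settings()) {
  stopifnot(inherits(settings, "pw_settings"))
  structure(list(worlds = list(), settings = settings,
                 display_memory = list()),
            class = "pw_scene")
}

#' @export
print.pw_scene <- function(x, ...) {
  cat(sprintf("<pw_scene> %d world(s)\n", length(x$worlds)))
  for (w in x$worlds) {
    cat(sprintf("  world %d: %d dataset binding(s)\n", w$id, length(w$bindings)))
  }
  invisible(x)
}

world_ids <- function(sc) vapply(sc$worlds, `[[`, integer(1), "id")

#' Add a world to a scene
#'
#' Scenes support at most four simultaneous worlds; the new world takes
#' the lowest free id in 1..4.
#'
#' @param sc A [scene()].
#' @return The scene with one more world.
#' @export
add_world <- function(sc) {
  stopifnot(inherits(sc, "pw_scene"))
  ids <- world_ids(sc)
  if (length(ids) >= 4) {
    stop_issue("WORLD_LIMIT", "a scene holds at most four worlds")
  }
  new_id <- setdiff(1:4, ids)[1]
  sc$worlds[[length(sc$worlds) + 1]] <- list(id = new_id, bindings = list())
  sc
}

#' Remove a world from a scene
#' @param sc A [scene()].
#' @param id World id in 1..4.
#' @return The scene without that world.
#' @export
remove_world <- function(sc, id) {
  ids <- world_ids(sc)
  keep <- ids != id
  if (all(keep)) stop("no world with id ", id)
  sc$worlds <- sc$worlds[keep]
  sc
}

world_index <- function(sc, id) {
  idx <- which(world_ids(sc) == id)
  if (length(idx) != 1) stop("no world with id ", id)
  idx
}

#' Bind a dataset to a world
#'
#' The dataset is shown as raw (shadow) points until an information layer
#' is attached with [attach_layer()].
#'
#' @param sc A [scene()].
#' @param world_id World id in 1..4.
#' @param ds A [pw_dataset()].
#' @return The updated scene.
#' @export
attach_dataset <- function(sc, world_id, ds) {
  stopifnot(inherits(sc, "pw_scene"), inherits(ds, "pw_dataset"))
  wi <- world_index(sc, world_id)
  sc$worlds[[wi]]$bindings[[length(sc$worlds[[wi]]$bindings) + 1]] <-
    list(dataset = ds, layer = NULL, display = NULL)
  sc
}

display_key <- function(ds_name, layer) {
  paste0(ds_name, "\r", if (is.null(layer$name)) "" else layer$name,
         "\r", layer$num_classes)
}

default_display <- function(k) {
  pal <- default_palette(k)
  data.frame(class = seq_len(k) - 1L, visible = TRUE,
             r = pal[, 1], g = pal[, 2], b = pal[, 3])
}

#' Attach an information layer to a bound dataset
#'
#' Validates the pair, then creates one display state (visible flag +
#' colour) per class, coloured from [default_palette()]. If the same
#' (dataset, layer) combination was attached and customised before,
#' previously customised display states are restored rather than reset.
#'
#' @param sc A [scene()].
#' @param world_id World id.
#' @param dataset Dataset selector within the world: name or position.
#' @param layer A [pw_layer()] (or a [pw_infofile()], in which case
#'   `layer_index` selects one of its layers).
#' @param layer_index Which layer of an information file to use.
#' @return The updated scene.
#' @export
attach_layer <- function(sc, world_id, dataset, layer, layer_index = 1) {
  stopifnot(inherits(sc, "pw_scene"))
  if (inherits(layer, "pw_infofile")) layer <- layer$layers[[layer_index]]
  stopifnot(inherits(layer, "pw_layer"))
  wi <- world_index(sc, world_id)
  bi <- binding_index(sc$worlds[[wi]], dataset)
  ds <- sc$worlds[[wi]]$bindings[[bi]]$dataset
  iss <- validate_pair(ds, pw_infofile(list(layer)))
  if (any(iss$severity == "error")) {
    stop_issue("INVALID_PAIR",
               paste("layer failed validation:",
                     paste(iss$code[iss$severity == "error"], collapse = ", ")))
  }
  key <- display_key(ds$name, layer)
  display <- sc$display_memory[[key]]
  if (is.null(display) || nrow(display) != layer$num_classes) {
    display <- default_display(layer$num_classes)
  }
  sc$worlds[[wi]]$bindings[[bi]]$layer <- layer
  sc$worlds[[wi]]$bindings[[bi]]$display <- display
  sc$display_memory[[key]] <- display
  sc
}

binding_index <- function(world, dataset) {
  if (is.numeric(dataset)) {
    stopifnot(dataset >= 1, dataset <= length(world$bindings))
    return(as.integer(dataset))
  }
  names_ <- vapply(world$bindings, function(b) b$dataset$name, character(1))
  idx <- which(names_ == dataset)
  if (length(idx) < 1) stop("no dataset named '", dataset, "' in world ", world$id)
  idx[1]
}

#' Change the display state of one class
#'
#' @param sc A [scene()].
#' @param world_id World id.
#' @param dataset Dataset selector (name or position within the world).
#' @param class_index 0-based class index.
#' @param visible Optional logical.
#' @param colour Optional RGB triple in \eqn{[0,1]^3}.
#' @return The updated scene; the customisation is remembered for future
#'   [attach_layer()] calls on the same (dataset, layer) pair.
#' @export
set_class_display <- function(sc, world_id, dataset, class_index,
                              visible = NULL, colour = NULL) {
  wi <- world_index(sc, world_id)
  bi <- binding_index(sc$worlds[[wi]], dataset)
  b <- sc$worlds[[wi]]$bindings[[bi]]
  if (is.null(b$display)) stop("no layer attached to this dataset")
  row <- which(b$display$class == class_index)
  if (length(row) != 1) stop("no class ", class_index)
  if (!is.null(visible)) b$display$visible[row] <- isTRUE(visible)
  if (!is.null(colour)) {
    colour <- as.numeric(colour)
    stopifnot(length(colour) == 3, all(is.finite(colour)),
              all(colour >= 0), all(colour <= 1))
    b$display[row, c("r", "g", "b")] <- colour
  }
  sc$worlds[[wi]]$bindings[[bi]] <- b
  sc$display_memory[[display_key(b$dataset$name, b$layer)]] <- b$display
  sc
}

#' Deterministic categorical palette
#'
#' `k` maximally hue-separated colours: evenly spaced hues at fixed
#' saturation and value, so `k = 2` gives complementary hues 180 degrees
#' apart. Pairwise distinct for `k <= 64`.
#'
#' @param k Number of colours (positive integer).
#' @return A `k` x 3 matrix of RGB components in `[0, 1]`.
#' @export
#' @examples
#' default_palette(3)
default_palette <- function(k) {
  stopifnot(k >= 1)
  hues <- (seq_len(k) - 1) / k
  cols <- grDevices::hsv(h = hues, s = 0.65, v = 0.9)
  t(grDevices::col2rgb(cols)) / 255
}

#' Apply global settings to coordinates
#'
#' Centering subtracts each axis' bounding-box midpoint (so the minimum
#' and maximum of every output axis are symmetric about 0), then each
#' axis is multiplied by its scale factor. With `center = FALSE` and unit
#' scales this is the identity.
#'
#' @param points N x 3 numeric matrix.
#' @param settings A [scene_settings()].
#' @return The transformed N x 3 matrix.
#' @export
#' @examples
#' apply_settings(rbind(c(0, 0, 0), c(2, 2, 2)),
#'                scene_settings(center = TRUE))
apply_settings <- function(points, settings) {
  stopifnot(inherits(settings, "pw_settings"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1)
  if (settings$center) {
    mid <- (apply(points, 2, min) + apply(points, 2, max)) / 2
    points <- sweep(points, 2, mid, `-`)
  }
  sweep(points, 2, settings$axis_scale, `*`)
}

# ---- scene configuration files ---------------------------------------------

#' Write a scene configuration file
#'
#' Serialises a scene to a human-editable JSON config so a command-line
#' render is reproducible. Data files are referenced by path, not
#' embedded; the datasets and layers currently in the scene must have
#' been loaded from the referenced files (or be re-creatable from them).
#'
#' @param sc A [scene()] whose bindings carry `dataset_path` /
#'   `layer_path` provenance (as produced by [read_scene_config()]), or a
#'   config-shaped list.
#' @param paths A list mapping dataset names to
#'   `list(dataset = path, information = path)`; required when the scene
#'   was built in memory.
#' @param file Output path.
#' @return The config list, invisibly.
#' @seealso [read_scene_config()]
#' @export
write_scene_config <- function(sc, paths, file) {
  stopifnot(inherits(sc, "pw_scene"))
  cfg <- list(
    settings = list(
      axis_scale = sc$settings$axis_scale,
      raw_opacity = sc$settings$raw_opacity,
      layer_opacity = sc$settings$layer_opacity,
      raw_size = sc$settings$raw_size,
      layer_size = sc$settings$layer_size,
      center = sc$settings$center),
    worlds = lapply(sc$worlds, function(w) {
      list(id = w$id, bindings = lapply(w$bindings, function(b) {
        p <- paths[[b$dataset$name]]
        if (is.null(p)) stop("no file paths recorded for dataset '",
                             b$dataset$name, "'")
        out <- list(dataset = p$dataset)
        if (!is.null(b$layer)) {
          out$information <- p$information
          out$layer_index <- layer_position(p, b$layer)
          out$classes <- lapply(seq_len(nrow(b$display)), function(i) {
            list(visible = b$display$visible[i],
                 colour = round(as.numeric(b$display[i, c("r", "g", "b")]), 6))
          })
        }
        out
      }))
    }))
  writeLines(as.character(toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                                 digits = NA)), file)
  invisible(cfg)
}

layer_position <- function(p, layer) {
  if (!is.null(p$layer_index)) return(p$layer_index)
  1L
}

#' Read a scene configuration file and build the scene
#'
#' Loads the referenced dataset and information files (any dialect),
#' validates each pairing and reconstructs the scene including per-class
#' visibility/colour overrides.
#'
#' @param file Path to a JSON scene config (see [write_scene_config()]).
#' @param base_dir Directory against which relative data paths are
#'   resolved; defaults to the config file's directory.
#' @return A [scene()].
#' @export
read_scene_config <- function(file, base_dir = dirname(file)) {
  cfg <- tryCatch(fromJSON(file, simplifyVector = FALSE),
                  error = function(e) stop_issue("SYNTAX_ERROR",
                    paste("invalid scene config:", conditionMessage(e))))
  s <- cfg$settings
  settings <- scene_settings(
    axis_scale = if (is.null(s$axis_scale)) c(1, 1, 1)
                 else unlist(s$axis_scale),
    raw_opacity = s$raw_opacity %||% 0.15,
    layer_opacity = s$layer_opacity %||% 0.9,
    raw_size = s$raw_size %||% 1,
    layer_size = s$layer_size %||% 1,
    center = isTRUE(s$center))
  sc <- scene(settings)
  if (length(cfg$worlds) > 4) {
    stop_issue("WORLD_LIMIT",
               sprintf("config declares %d worlds; at most 4 are allowed",
                       length(cfg$worlds)))
  }
  for (w in cfg$worlds) {
    sc <- add_world(sc)
    wid <- world_ids(sc)[length(sc$worlds)]
    for (b in w$bindings) {
      ds_path <- resolve_path(b$dataset, base_dir)
      ds <- read_dataset(read_text(ds_path))
      sc <- attach_dataset(sc, wid, ds)
      if (!is.null(b$information)) {
        info <- read_information(read_text(resolve_path(b$information, base_dir)))
        li <- b$layer_index %||% 1
        sc <- attach_layer(sc, wid, length(world_binding(sc, wid)), info,
                           layer_index = li)
        if (!is.null(b$classes)) {
          for (ci in seq_along(b$classes)) {
            cls <- b$classes[[ci]]
            sc <- set_class_display(
              sc, wid, length(world_binding(sc, wid)), ci - 1L,
              visible = cls$visible %||% TRUE,
              colour = if (is.null(cls$colour)) NULL else unlist(cls$colour))
          }
        }
      }
    }
  }
  sc
}

world_binding <- function(sc, world_id) {
  sc$worlds[[world_index(sc, world_id)]]$bindings
}

resolve_path <- function(path, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base_dir, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_text <- function(path) {
  if (!file.exists(path)) stop_issue("IO_ERROR", paste("cannot read", path))
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
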