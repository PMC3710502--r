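#' Compile one world into renderer-agnostic primitives
#'
#' For every dataset bound to the world this produces: (a) one low-opacity
#' "shadow" particle batch of all raw points — the faint backdrop over
#' which the coloured classes are read, always present even when every
#' class is hidden; (b) one particle batch per *visible* class of the
#' active information layer, in that class' display colour (hidden
#' classes contribute no coloured batch but remain in the shadow); and
#' (c) for chained datasets, one polyline through all N points in file
#' order (N - 1 segments; none for N = 1). Coordinates pass through
#' [apply_settings()] first.
#'
#' @param world One element of `scene$worlds`.
#' @param settings A [scene_settings()].
#' @return A list of primitives; each primitive is a list with fields
#'   `kind` (`"particles"` or `"polyline"`), `positions` (N x 3 matrix),
#'   `colour` (RGB in `[0,1]`), `opacity`, `size` and `tag` (provenance:
#'   world id, dataset name, class index or `"raw"`).
#' @export
build_primitives <- function(world, settings) {
  stopifnot(inherits(settings, "pw_settings"))
  prims <- list()
  shadow_colour <- c(0.55, 0.55, 0.55)
  line_colour <- c(0.35, 0.35, 0.35)
  for (b in world$bindings) {
    ds <- b$dataset
    pts <- apply_settings(ds$points, settings)
    prims[[length(prims) + 1]] <- list(
      kind = "particles", positions = pts, colour = shadow_colour,
      opacity = settings$raw_opacity, size = settings$raw_size,
      tag = list(world = world$id, dataset = ds$name, class = "raw"))
    if (!is.null(b$layer)) {
      for (row in seq_len(nrow(b$display))) {
        if (!b$display$visible[row]) next
        cls <- b$display$class[row]
        sel <- b$layer$values == cls
        if (!any(sel)) next
        prims[[length(prims) + 1]] <- list(
          kind = "particles", positions = pts[sel, , drop = FALSE],
          colour = as.numeric(b$display[row, c("r", "g", "b")]),
          opacity = settings$layer_opacity, size = settings$layer_size,
          tag = list(world = world$id, dataset = ds$name, class = cls))
      }
    }
    if (ds$chain && nrow(pts) >= 2) {
      prims[[length(prims) + 1]] <- list(
        kind = "polyline", positions = pts, colour = line_colour,
        opacity = settings$layer_opacity, size = settings$raw_size,
        tag = list(world = world$id, dataset = ds$name, class = "raw"))
    }
  }
  prims
}

#' Compile every world of a scene
#' @param sc A [scene()].
#' @return A named list: one primitive list per world (`world_1`, ...).
#' @export
scene_primitives <- function(sc) {
  stopifnot(inherits(sc, "pw_scene"))
  out <- lapply(sc$worlds, build_primitives, settings = sc$settings)
  names(out) <- paste0("world_", world_ids(sc))
  out
}

check_nonempty_scene <- function(sc) {
  n_bound <- sum(vapply(sc$worlds, function(w) length(w$bindings), integer(1)))
  if (length(sc$worlds) == 0 || n_bound == 0) {
    stop_issue("EMPTY_SCENE", "no world has a bound dataset")
  }
  invisible(sc)
}

scene_payload <- function(sc) {
  list(
    format = "pointworlds-scene",
    version = "1",
    settings = list(raw_size = sc$settings$raw_size,
                    layer_size = sc$settings$layer_size),
    worlds = lapply(sc$worlds, function(w) {
      list(id = w$id,
           primitives = lapply(build_primitives(w, sc$settings), function(p) {
             list(kind = p$kind,
                  positions = unname(p$positions),
                  colour = p$colour,
                  opacity = p$opacity,
                  size = p$size,
                  tag = p$tag)
           }))
    }))
}

#' Render a scene to a self-contained interactive HTML document
#'
#' Produces a single HTML file viewable offline: it embeds all geometry
#' in a machine-extractable JSON data island
#' (`<script type="application/json" id="pointworlds-data">`) together
#' with a small dependency-free canvas renderer (drag to orbit, wheel to
#' zoom). One sub-view is laid out per world: full width for one world,
#' split for two, a 2 x 2 grid for three or four. The document makes no
#' network fetches.
#'
#' @param sc A [scene()] with at least one world binding a dataset.
#' @param file Optional output path; when given the document is written
#'   there.
#' @return The HTML text, invisibly when `file` is given.
#' @seealso [extract_data_island()]
#' @export
render_document <- function(sc, file = NULL) {
  check_nonempty_scene(sc)
  payload <- scene_payload(sc)
  json <- as.character(toJSON(payload, auto_unbox = TRUE, digits = NA))
  json <- gsub("</", "<\\\\/", json, fixed = TRUE)  # keep the island inert
  n_worlds <- length(sc$worlds)
  panel_class <- if (n_worlds == 1) "full" else if (n_worlds == 2) "half" else "quad"
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>pointworlds scene</title>\n",
    "<style>\n",
    "body { margin: 0; background: #111; color: #ddd; font-family: sans-serif; }\n",
    "#panels { display: flex; flex-wrap: wrap; width: 100vw; height: 100vh; }\n",
    ".world { position: relative; box-sizing: border-box; border: 1px solid #333; }\n",
    ".world.full { width: 100%; height: 100%; }\n",
    ".world.half { width: 50%; height: 100%; }\n",
    ".world.quad { width: 50%; height: 50%; }\n",
    ".world .label { position: absolute; top: 4px; left: 8px; opacity: 0.7; }\n",
    "canvas { width: 100%; height: 100%; display: block; }\n",
    "</style>\n</head>\n<body>\n",
    "<script type=\"application/json\" id=\"pointworlds-data\">\n",
    json,
    "\n</script>\n",
    "<div id=\"panels\"></div>\n",
    "<script>\n", viewer_js(panel_class), "</script>\n",
    "</body>\n</html>\n")
  if (!is.null(file)) {
    writeLines(html, file, sep = "")
    return(invisible(html))
  }
  html
}

# Minimal orbit viewer: orthographic projection onto a 2D canvas, points
# drawn as quads. Written in plain JS so the document stays dependency-free.
viewer_js <- function(panel_class) {
  paste0(
"var data = JSON.parse(document.getElementById('pointworlds-data').textContent);
var panels = document.getElementById('panels');
data.worlds.forEach(function (world) {
  var div = document.createElement('div');
  div.className = 'world ", panel_class, "';
  var label = document.createElement('div');
  label.className = 'label';
  label.textContent = 'world ' + world.id;
  var canvas = document.createElement('canvas');
  div.appendChild(canvas); div.appendChild(label); panels.appendChild(div);
  var az = 0.6, el = 0.4, zoom = 1;
  var lo = [Infinity, Infinity, Infinity], hi = [-Infinity, -Infinity, -Infinity];
  world.primitives.forEach(function (p) {
    p.positions.forEach(function (q) {
      for (var a = 0; a < 3; a++) {
        if (q[a] < lo[a]) lo[a] = q[a];
        if (q[a] > hi[a]) hi[a] = q[a];
      }
    });
  });
  var mid = [0, 1, 2].map(function (a) { return (lo[a] + hi[a]) / 2; });
  var span = Math.max(hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9);
  function draw() {
    var w = canvas.clientWidth, h = canvas.clientHeight;
    canvas.width = w; canvas.height = h;
    var ctx = canvas.getContext('2d');
    ctx.clearRect(0, 0, w, h);
    var ca = Math.cos(az), sa = Math.sin(az), ce = Math.cos(el), se = Math.sin(el);
    var s = zoom * 0.8 * Math.min(w, h) / span;
    function project(q) {
      var x = q[0] - mid[0], y = q[1] - mid[1], z = q[2] - mid[2];
      var x1 = ca * x + sa * y, y1 = -sa * x + ca * y;
      var y2 = ce * y1 + se * z, z2 = -se * y1 + ce * z;
      return [w / 2 + s * x1, h / 2 - s * z2, y2];
    }
    world.primitives.forEach(function (p) {
      ctx.globalAlpha = p.opacity;
      ctx.fillStyle = ctx.strokeStyle = 'rgb(' +
        Math.round(255 * p.colour[0]) + ',' + Math.round(255 * p.colour[1]) +
        ',' + Math.round(255 * p.colour[2]) + ')';
      if (p.kind === 'polyline') {
        ctx.lineWidth = p.size;
        ctx.beginPath();
        p.positions.forEach(function (q, i) {
          var v = project(q);
          if (i === 0) ctx.moveTo(v[0], v[1]); else ctx.lineTo(v[0], v[1]);
        });
        ctx.stroke();
      } else {
        var r = Math.max(1, 1.5 * p.size);
        p.positions.forEach(function (q) {
          var v = project(q);
          ctx.fillRect(v[0] - r / 2, v[1] - r / 2, r, r);
        });
      }
    });
    ctx.globalAlpha = 1;
  }
  var dragging = false, px = 0, py = 0;
  canvas.addEventListener('mousedown', function (e) {
    dragging = true; px = e.clientX; py = e.clientY;
  });
  window.addEventListener('mouseup', function () { dragging = false; });
  window.addEventListener('mousemove', function (e) {
    if (!dragging) return;
    az += (e.clientX - px) * 0.01; el += (e.clientY - py) * 0.01;
    px = e.clientX; py = e.clientY; draw();
  });
  canvas.addEventListener('wheel', function (e) {
    zoom *= e.deltaY < 0 ? 1.1 : 0.9; e.preventDefault(); draw();
  });
  window.addEventListener('resize', draw);
  draw();
});
")
}

#' Extract the geometry data island from a rendered document
#'
#' The embedded JSON block is the machine-readable ground truth of what a
#' document displays; this parses it back without a browser.
#'
#' @param html Text of a document produced by [render_document()].
#' @return The parsed payload: a list with `worlds`, each holding
#'   `primitives` with `kind`, `positions`, `colour`, `opacity`, `size`
#'   and `tag`.
#' @export
extract_data_island <- function(html) {
  open_tag <- "<script type=\"application/json\" id=\"pointworlds-data\">"
  start <- regexpr(open_tag, html, fixed = TRUE)
  if (start == -1) stop("no data island found in document")
  body_start <- start + attr(start, "match.length")
  close_rel <- regexpr("</script>", substr(html, body_start, nchar(html)),
                       fixed = TRUE)
  if (close_rel == -1) stop("data island is not terminated")
  json <- substr(html, body_start, body_start + close_rel - 2)
  json <- gsub("<\\/", "</", json, fixed = TRUE)
  fromJSON(trimws(json), simplifyVector = FALSE)
}

#' Render a scene to a static raster image
#'
#' Deterministic publication-style export: every world becomes one panel
#' (full / split / 2 x 2 layout as in [render_document()]), drawn with an
#' orthographic projection at the requested view angles. Rendering the
#' same scene twice yields byte-identical files.
#'
#' @param sc A [scene()] with at least one bound dataset.
#' @param file Output PNG path.
#' @param azimuth,elevation View angles in degrees (rotation about the
#'   vertical axis, then tilt).
#' @param width,height Image size in pixels.
#' @return `file`, invisibly.
#' @export
render_static <- function(sc, file, azimuth = 45, elevation = 30,
                          width = 640, height = 480) {
  check_nonempty_scene(sc)
  n_worlds <- length(sc$worlds)
  grDevices::png(file, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  mf <- if (n_worlds == 1) c(1, 1) else if (n_worlds == 2) c(1, 2) else c(2, 2)
  graphics::par(mfrow = mf, mar = c(0.5, 0.5, 1.2, 0.5), bg = "white")
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  for (w in sc$worlds) {
    prims <- build_primitives(w, sc$settings)
    projected <- lapply(prims, function(p) project_ortho(p$positions, az, el))
    all_xy <- do.call(rbind, projected)
    graphics::plot(NA, xlim = range(all_xy[, 1]), ylim = range(all_xy[, 2]),
                   asp = 1, axes = FALSE, xlab = "", ylab = "",
                   main = paste("world", w$id), cex.main = 0.8)
    for (i in seq_along(prims)) {
      p <- prims[[i]]
      xy <- projected[[i]]
      col <- grDevices::rgb(p$colour[1], p$colour[2], p$colour[3],
                            alpha = p$opacity)
      if (p$kind == "polyline") {
        graphics::lines(xy[, 1], xy[, 2], col = col, lwd = p$size)
      } else {
        graphics::points(xy[, 1], xy[, 2], col = col, pch = 15,
                         cex = 0.5 * p$size)
      }
    }
  }
  invisible(file)
}

# Orthographic projection: rotate about z by azimuth, tilt by elevation,
# drop the depth axis.
project_ortho <- function(points, az, el) {
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  x1 <- cos(az) * x + sin(az) * y
  y1 <- -sin(az) * x + cos(az) * y
  z2 <- -sin(el) * y1 + cos(el) * z
  cbind(x1, z2)
}
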