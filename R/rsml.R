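# Spline smoothing of extracted paths and RSML (Root System Markup Language)
# read/write. Coordinates are 0-based, origin top-left, x right, y down.

#' Fit a cardinal spline to a pixel path
#'
#' Control points are sampled at equal arc-length spacing along the path
#' (endpoints always included) and interpolated with a cubic cardinal
#' spline: the tangent at control point `i` is
#' `(1 - tension) * (P[i+1] - P[i-1]) / 2` (one-sided differences at the
#' endpoints), evaluated with cubic Hermite segments. The spline
#' interpolates every control point.
#'
#' @param path n x 2 polyline (pixel coordinates).
#' @param spacing control-point spacing in pixels (default 8).
#' @param tension cardinal tension parameter (default 0.5).
#' @param sample_spacing spacing of the returned sampled points (default 2).
#' @return object of class `spline_curve`: list with `control_points`,
#'   `tension`, and `samples` (m x 2 matrix of points on the curve).
#' @export
fit_spline <- function(path, spacing = 8, tension = 0.5, sample_spacing = 2) {
  path <- as.matrix(path)
  if (nrow(path) < 2 || polyline_length(path) <= 0)
    stop("cannot fit a spline to a degenerate (single-point) path")
  cp <- resample_polyline(path, spacing)
  n <- nrow(cp)
  # tangents
  tg <- matrix(0, n, 2)
  s <- 1 - tension
  if (n == 2) {
    tg[1, ] <- s * (cp[2, ] - cp[1, ])
    tg[2, ] <- s * (cp[2, ] - cp[1, ])
  } else {
    tg[1, ] <- s * (cp[2, ] - cp[1, ])
    tg[n, ] <- s * (cp[n, ] - cp[n - 1, ])
    for (i in 2:(n - 1)) tg[i, ] <- s * (cp[i + 1, ] - cp[i - 1, ]) / 2
  }
  eval_seg <- function(i, t) {
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    cbind(h00 %o% cp[i, ] + h10 %o% tg[i, ] +
          h01 %o% cp[i + 1, ] + h11 %o% tg[i + 1, ])[, , drop = TRUE]
  }
  samples <- list(cp[1, , drop = FALSE])
  for (i in seq_len(n - 1)) {
    seg_len <- sqrt(sum((cp[i + 1, ] - cp[i, ])^2))
    k <- max(2L, ceiling(seg_len / sample_spacing) + 1L)
    t <- seq(0, 1, length.out = k)[-1]
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    px <- h00 * cp[i, 1] + h10 * tg[i, 1] + h01 * cp[i + 1, 1] + h11 * tg[i + 1, 1]
    py <- h00 * cp[i, 2] + h10 * tg[i, 2] + h01 * cp[i + 1, 2] + h11 * tg[i + 1, 2]
    samples[[length(samples) + 1L]] <- cbind(px, py)
  }
  out <- list(control_points = cp, tension = tension,
              samples = do.call(rbind, samples))
  class(out) <- "spline_curve"
  out
}

#' Evaluate a fitted spline at its control points (identity check helper)
#' @param sc a `spline_curve`.
#' @return the control-point matrix.
#' @export
spline_control_points <- function(sc) sc$control_points

rsml_point_nodes <- function(parent, pts) {
  for (i in seq_len(nrow(pts)))
    xml2::xml_add_child(parent, "point",
                        x = format(pts[i, 1], digits = 12),
                        y = format(pts[i, 2], digits = 12))
  invisible(parent)
}

root_to_xml <- function(parent_node, rt, children, id, spline_spacing,
                        spline_tension) {
  rn <- xml2::xml_add_child(parent_node, "root", id = id,
                            label = paste0("root_", id),
                            po.accession = if (rt$order == 1L) "PO:0020127" else "PO:0020121")
  geom <- xml2::xml_add_child(rn, "geometry")
  poly <- xml2::xml_add_child(geom, "polyline")
  rsml_point_nodes(poly, rt$points)
  # spline as an annotation so strict readers still parse the polyline
  if (nrow(rt$points) >= 2 && polyline_length(rt$points) > 0) {
    sc <- fit_spline(rt$points, spacing = spline_spacing,
                     tension = spline_tension)
    ann <- xml2::xml_add_child(rn, "annotations")
    sp <- xml2::xml_add_child(ann, "annotation", name = "spline",
                              tension = format(spline_tension))
    rsml_point_nodes(sp, sc$control_points)
  }
  for (ch in children) {
    root_to_xml(rn, ch$root, list(), ch$id, spline_spacing, spline_tension)
  }
  invisible(rn)
}

#' Write a root system to RSML
#'
#' Standard RSML: `rsml > metadata + scene > plant* > root*` with laterals
#' nested under their parent root element. Each root carries its polyline
#' geometry; the fitted cardinal-spline control points are stored as an
#' annotation so strict readers still parse the polyline. Coordinates are
#' native-image pixels unless the caller scaled the system.
#'
#' @param rs a `root_system`.
#' @param path output file path.
#' @param image_metadata optional named list (e.g. `image file`, `resolution`).
#' @param spline_spacing,spline_tension spline parameters (defaults 20, 0.5).
#' @return the path, invisibly.
#' @export
write_rsml <- function(rs, path, image_metadata = list(),
                       spline_spacing = 8, spline_tension = 0.5) {
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  md <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(md, "version", "1")
  xml2::xml_add_child(md, "unit", "pixel")
  xml2::xml_add_child(md, "resolution", "1")
  xml2::xml_add_child(md, "software", "rootarch")
  xml2::xml_add_child(md, "image-width", as.character(rs$image_size[1]))
  xml2::xml_add_child(md, "image-height", as.character(rs$image_size[2]))
  for (nm in names(image_metadata))
    xml2::xml_add_child(md, nm, as.character(image_metadata[[nm]]))
  scene <- xml2::xml_add_child(doc, "scene")
  for (pi in seq_along(rs$plants)) {
    pl <- rs$plants[[pi]]
    pn <- xml2::xml_add_child(scene, "plant", id = as.character(pi),
                              label = paste0("plant_", pi))
    xml2::xml_set_attr(pn, "seed-x", format(pl$seed[1], digits = 12))
    xml2::xml_set_attr(pn, "seed-y", format(pl$seed[2], digits = 12))
    o1_idx <- which(vapply(pl$roots, function(r) r$order == 1L, logical(1)))
    for (k in seq_along(o1_idx)) {
      ri <- o1_idx[k]
      kids <- list()
      for (j in seq_along(pl$roots)) {
        rt <- pl$roots[[j]]
        if (rt$order == 2L && !is.na(rt$parent) && rt$parent == ri)
          kids[[length(kids) + 1L]] <-
            list(root = rt, id = paste0(pi, ".", k, ".", length(kids) + 1L))
      }
      root_to_xml(pn, pl$roots[[ri]], kids, paste0(pi, ".", k),
                  spline_spacing, spline_tension)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_polyline <- function(root_node) {
  pts <- xml2::xml_find_all(root_node, "./geometry/polyline/point")
  if (length(pts) == 0) stop("RSML parse error: root without polyline geometry at ",
                             xml2::xml_path(root_node))
  cbind(as.numeric(xml2::xml_attr(pts, "x")),
        as.numeric(xml2::xml_attr(pts, "y")))
}

#' Read a root system from RSML
#'
#' Parses scene/plant/root nesting with polyline geometry. This tool models
#' root orders 1 and 2 only; roots nested three or more levels deep raise an
#' error.
#'
#' @param path RSML file path.
#' @return a `root_system`.
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  w <- xml2::xml_text(xml2::xml_find_first(doc, "./metadata/image-width"))
  h <- xml2::xml_text(xml2::xml_find_first(doc, "./metadata/image-height"))
  plants <- list()
  for (pn in xml2::xml_find_all(doc, "./scene/plant")) {
    roots <- list()
    o1_nodes <- xml2::xml_find_all(pn, "./root")
    for (rn in o1_nodes) {
      pts1 <- parse_polyline(rn)
      roots[[length(roots) + 1L]] <-
        list(order = 1L, points = pts1, parent = NA_integer_, attachment = NULL)
      parent_idx <- length(roots)
      for (cn in xml2::xml_find_all(rn, "./root")) {
        if (length(xml2::xml_find_all(cn, "./root")) > 0)
          stop("unsupported root order: RSML roots nested more than 2 deep")
        pts2 <- parse_polyline(cn)
        roots[[length(roots) + 1L]] <-
          list(order = 2L, points = pts2, parent = parent_idx,
               attachment = pts2[1, ])
      }
    }
    sx <- xml2::xml_attr(pn, "seed-x")
    sy <- xml2::xml_attr(pn, "seed-y")
    seed <- if (!is.na(sx) && !is.na(sy)) c(as.numeric(sx), as.numeric(sy))
            else if (length(roots) > 0) roots[[1]]$points[1, ] else c(0, 0)
    plants[[length(plants) + 1L]] <- list(seed = seed, roots = roots)
  }
  size <- c(ifelse(is.na(w), NA, as.numeric(w)), ifelse(is.na(h), NA, as.numeric(h)))
  rs <- list(plants = plants, image_size = size, style = "rsml")
  class(rs) <- "root_system"
  rs
}

#' Write binary segmentation masks as PNG files
#'
#' One binary (0/1) PNG per root order.
#'
#' @param maps class-map array `(H, W, 3)`.
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
write_masks <- function(maps, prefix) {
  p1 <- paste0(prefix, "_order1.png")
  p2 <- paste0(prefix, "_order2.png")
  png::writePNG(round(clamp01(maps[, , 2])), p1)
  png::writePNG(round(clamp01(maps[, , 3])), p2)
  invisible(c(p1, p2))
}
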