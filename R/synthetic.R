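# Procedural generator of root systems and renderable images. Two assay
# styles are emulated: `fibrous` (a single plant with several first-order
# seminal roots on a blue germination-paper background, wheat-like) and
# `taproot` (up to five plants per image, each a single primary root with
# laterals, on a dark plate-like background, Arabidopsis/rapeseed-like).
# Roots are direction-biased random walks resampled to polylines.

#' Synthetic architecture parameters
#'
#' @param style `"fibrous"` (one plant, several first-order roots) or
#'   `"taproot"` (1-5 plants, one first-order root each).
#' @param n_plants number of plants (fibrous style forces 1).
#' @param n_first_order integer range `c(lo, hi)` of first-order roots per
#'   plant (taproot style forces `c(1, 1)`).
#' @param laterals_per_root integer range of second-order roots per
#'   first-order root.
#' @param image_size `c(width, height)` in pixels.
#' @param root_width stroke width in pixels used when rendering.
#' @param curvature_noise per-step angular standard deviation (radians) of
#'   the growth random walk.
#' @param growth_length pixel range `c(lo, hi)` of first-order root lengths.
#' @param noise_sd standard deviation of additive pixel noise in rendered
#'   images.
#' @param min_tip_sep minimum distance between same-class tips (enforced by
#'   rejection), so that feature deduplication cannot merge distinct tips.
#' @param rng_seed integer seed; identical parameters give identical systems
#'   and images.
#' @return an object of class `ra_arch_params`.
#' @export
architecture_params <- function(style = c("fibrous", "taproot"),
                                n_plants = if (style == "fibrous") 1L else 3L,
                                n_first_order = if (style == "fibrous") c(3L, 5L) else c(1L, 1L),
                                laterals_per_root = c(1L, 3L),
                                image_size = c(1024L, 1024L),
                                root_width = 8,
                                curvature_noise = 0.10,
                                growth_length = NULL,
                                noise_sd = 0.02,
                                min_tip_sep = 12,
                                rng_seed = 1L) {
  style <- match.arg(style)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (is.null(growth_length))
    growth_length <- round(c(0.35, 0.75) * image_size[2])
  if (length(n_first_order) == 1L) n_first_order <- rep(n_first_order, 2L)
  if (length(laterals_per_root) == 1L) laterals_per_root <- rep(laterals_per_root, 2L)
  p <- list(style = style, n_plants = as.integer(n_plants),
            n_first_order = as.integer(n_first_order),
            laterals_per_root = as.integer(laterals_per_root),
            image_size = as.integer(image_size), root_width = root_width,
            curvature_noise = curvature_noise,
            growth_length = as.numeric(growth_length), noise_sd = noise_sd,
            min_tip_sep = min_tip_sep, rng_seed = as.integer(rng_seed))
  class(p) <- "ra_arch_params"
  validate_arch_params(p)
  p
}

validate_arch_params <- function(p) {
  stopifnot(inherits(p, "ra_arch_params"))
  if (p$n_plants < 1L) stop("invalid parameters: n_plants must be >= 1")
  if (p$style == "fibrous" && p$n_plants != 1L)
    stop("invalid parameters: fibrous style implies a single plant")
  if (p$style == "taproot" && !all(p$n_first_order == 1L))
    stop("invalid parameters: taproot style implies one first-order root per plant")
  rngs <- list(p$n_first_order, p$laterals_per_root, p$growth_length)
  for (r in rngs)
    if (length(r) != 2L || r[1] > r[2]) stop("invalid parameters: empty range")
  if (any(p$image_size < 32L)) stop("invalid parameters: image too small")
  if (p$root_width <= 0 || p$min_tip_sep <= 0 || p$curvature_noise < 0)
    stop("invalid parameters: widths/separations must be positive")
  invisible(p)
}

# Grow one root as a direction-biased random walk. heading 0 = straight down
# (+y); dev is clamped so y is non-decreasing. Returns an n x 2 (x, y) matrix.
grow_root <- function(start, heading0, length_px, step, curv, bounds, margin) {
  n_steps <- max(2L, ceiling(length_px / step))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- start
  dev <- heading0
  max_dev <- 75 * pi / 180
  for (i in seq_len(n_steps)) {
    dev <- dev + stats::rnorm(1L, 0, curv) - 0.02 * dev  # restoring pull to vertical
    dev <- max(-max_dev, min(max_dev, dev))
    nxt <- pts[i, ] + step * c(sin(dev), cos(dev))
    if (nxt[1] < margin || nxt[1] > bounds[1] - 1 - margin ||
        nxt[2] > bounds[2] - 1 - margin) {
      return(pts[seq_len(i), , drop = FALSE])
    }
    pts[i + 1L, ] <- nxt
  }
  pts
}

# Uniform draw from an integer range c(lo, hi) (robust to lo == hi).
sample_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq(r[1], r[2]), 1L)
}

# Point on a polyline at arc-length fraction u, plus the local direction.
polyline_point_at <- function(pts, u) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  s <- u * cum[length(cum)]
  i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  t <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  pt <- pts[i, ] + t * (pts[i + 1L, ] - pts[i, ])
  dirv <- (pts[i + 1L, ] - pts[i, ])
  dirv <- dirv / sqrt(sum(dirv^2))
  list(point = pt, dir = dirv, s = s)
}

#' Generate a synthetic root system
#'
#' Deterministic for a fixed `rng_seed`. Each plant has a seed point and a
#' set of first-order roots growing predominantly downward; second-order
#' roots attach on their parent's polyline. Same-class tips (and seeds) are
#' kept at least `min_tip_sep` pixels apart by rejection sampling.
#'
#' @param params an [architecture_params()] object.
#' @return an object of class `root_system`: a list of plants, each
#'   `list(seed = c(x, y), roots = list(...))`; roots carry `order`,
#'   `points` (n x 2 polyline), `parent` (index or `NA`) and `attachment`.
#' @export
generate_architecture <- function(params) {
  validate_arch_params(params)
  old <- local_seed(params$rng_seed)
  on.exit(restore_seed(old))
  W <- params$image_size[1]; H <- params$image_size[2]
  step <- max(4, H / 80)
  margin <- params$root_width
  sep <- params$min_tip_sep

  ok_sep <- function(p, existing) {
    if (length(existing) == 0L) return(TRUE)
    all(vapply(existing, function(q) sqrt(sum((p - q)^2)), numeric(1)) >= sep)
  }

  # Clearance: a candidate root may not come within `clear` px of any other
  # root's polyline, so distinct roots never overlap or cross and every root
  # is resolvable by the path search. Related roots (the parent of a
  # lateral; sibling first-order roots sharing the seed) are exempt over the
  # candidate's first `exempt_kin` px of arc length, which permits the
  # shared origin; unrelated roots get only a one-step grace.
  clear <- 1.25 * params$root_width
  exempt_kin <- 5 * params$root_width
  exempt_other <- params$root_width
  ok_clearance <- function(pts, others, kin) {
    arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    for (i in seq_len(nrow(pts))) {
      if (arc[i] >= exempt_other) {
        for (other in others)
          if (point_polyline_dist(pts[i, ], other) < clear) return(FALSE)
      }
      if (arc[i] >= exempt_kin) {
        for (other in kin)
          if (point_polyline_dist(pts[i, ], other) < clear) return(FALSE)
      }
    }
    TRUE
  }

  # seed positions
  seeds <- list()
  for (i in seq_len(params$n_plants)) {
    for (att in 1:200) {
      if (params$n_plants == 1L) {
        s <- c(W / 2 + stats::runif(1, -W / 8, W / 8),
               H * stats::runif(1, 0.05, 0.10))
      } else {
        cell <- W / params$n_plants
        s <- c((i - 0.5) * cell + stats::runif(1, -cell / 6, cell / 6),
               H * stats::runif(1, 0.05, 0.12))
      }
      if (ok_sep(s, seeds)) break
    }
    seeds[[i]] <- s
  }

  tips1 <- list(); tips2 <- list()
  plants <- vector("list", params$n_plants)
  plant_polys <- replicate(params$n_plants, list(), simplify = FALSE)
  other_polys <- function(i) do.call(c, plant_polys[-i])
  for (i in seq_len(params$n_plants)) {
    seed <- seeds[[i]]
    n1 <- sample_range(params$n_first_order)
    roots <- list()
    headings <- if (n1 == 1L) 0 else seq(-0.8, 0.8, length.out = n1)
    for (r in seq_len(n1)) {
      pts <- NULL
      siblings <- plant_polys[[i]]
      strangers <- other_polys(i)
      for (att in 1:200) {
        start <- seed + stats::runif(2, -params$root_width / 3, params$root_width / 3)
        start[2] <- seed[2] + abs(start[2] - seed[2])  # never above the seed
        len <- stats::runif(1, params$growth_length[1], params$growth_length[2])
        cand <- grow_root(start, headings[r] + stats::rnorm(1, 0, 0.15), len,
                          step, params$curvature_noise, c(W, H), margin)
        if (nrow(cand) >= 3 && polyline_length(cand) >= 0.4 * len &&
            ok_sep(cand[nrow(cand), ], tips1) &&
            ok_clearance(cand, strangers, siblings)) {
          pts <- cand
          break
        }
      }
      if (is.null(pts)) stop("could not place first-order root with the required separation")
      tips1[[length(tips1) + 1L]] <- pts[nrow(pts), ]
      plant_polys[[i]][[length(plant_polys[[i]]) + 1L]] <- pts
      roots[[length(roots) + 1L]] <-
        list(order = 1L, points = pts, parent = NA_integer_, attachment = NULL)
    }
    # laterals
    for (r in seq_len(n1)) {
      parent <- roots[[r]]
      n2 <- sample_range(params$laterals_per_root)
      if (n2 == 0L) next
      for (j in seq_len(n2)) {
        pts <- NULL
        att_pt <- NULL
        shrink <- 1
        parent_poly <- parent$points
        for (att in 1:200) {
          u <- stats::runif(1, 0.2, 0.85)
          loc <- polyline_point_at(parent_poly, u)
          side <- sample(c(-1, 1), 1L)
          base_ang <- atan2(loc$dir[1], loc$dir[2])  # parent local heading
          ang <- base_ang + side * stats::runif(1, 0.6, 1.2)
          len <- shrink * stats::runif(1, 0.15, 0.35) *
            (params$growth_length[1] + params$growth_length[2]) / 2
          # laterals emerge at the parent root's surface (half a stroke
          # width off its axis), as on a real root; the attachment point
          # recorded is the axis point
          perp <- if (side > 0) c(loc$dir[2], -loc$dir[1])
                  else c(-loc$dir[2], loc$dir[1])
          edge <- loc$point + 0.5 * params$root_width * perp
          cand <- grow_root(edge, ang, len, step,
                            params$curvature_noise * 1.5, c(W, H), margin)
          non_parent <- c(Filter(function(q) !identical(q, parent_poly),
                                 plant_polys[[i]]), other_polys(i))
          if (nrow(cand) >= 3 &&
              polyline_length(cand) >= 0.5 * len &&
              ok_sep(cand[nrow(cand), ], tips2) &&
              ok_clearance(cand, non_parent, list(parent_poly))) {
            # prepend the axis attachment so the stored polyline spans the
            # same axis-to-surface stub the reconstruction traverses
            pts <- rbind(loc$point, cand)
            att_pt <- loc$point
            break
          }
          if (att %% 40 == 0) shrink <- shrink * 0.85
        }
        if (is.null(pts)) stop("could not place lateral root with the required separation")
        tips2[[length(tips2) + 1L]] <- pts[nrow(pts), ]
        plant_polys[[i]][[length(plant_polys[[i]]) + 1L]] <- pts
        roots[[length(roots) + 1L]] <-
          list(order = 2L, points = pts, parent = r, attachment = att_pt)
      }
    }
    plants[[i]] <- list(seed = seed, roots = roots)
  }
  rs <- list(plants = plants, image_size = c(W, H), style = params$style)
  class(rs) <- "root_system"
  rs
}

#' Validate a root system's structural invariants
#'
#' Checks: second-order roots have a first-order parent and an attachment
#' point on the parent polyline (within 1 px); first-order roots have no
#' parent and start within `root_width` of their plant's seed; polylines have
#' positive arc length.
#'
#' @param rs a `root_system`.
#' @param root_width tolerance for the seed-to-root-base distance.
#' @return `rs` invisibly; errors on violation.
#' @export
validate_root_system <- function(rs, root_width = 8) {
  stopifnot(inherits(rs, "root_system"))
  for (pl in rs$plants) {
    for (rt in pl$roots) {
      if (nrow(rt$points) < 2L || polyline_length(rt$points) <= 0)
        stop("root polyline must have positive arc length")
      if (rt$order == 1L) {
        if (!is.na(rt$parent)) stop("first-order roots have no parent")
        if (sqrt(sum((rt$points[1L, ] - pl$seed)^2)) > root_width + 1e-6)
          stop("first-order root must start at its plant's seed")
      } else if (rt$order == 2L) {
        if (is.na(rt$parent)) stop("second-order root lacks a parent")
        par <- pl$roots[[rt$parent]]
        if (par$order != 1L) stop("second-order parent must be first-order")
        if (point_polyline_dist(rt$attachment, par$points) > 1)
          stop("attachment point must lie on the parent polyline")
      } else stop("unsupported root order ", rt$order)
    }
  }
  invisible(rs)
}

# All root segments of a system at given order(s), as an n x 4 matrix.
root_segments <- function(rs, orders = c(1L, 2L), scale = 1) {
  segs <- list()
  for (pl in rs$plants)
    for (rt in pl$roots)
      if (rt$order %in% orders && nrow(rt$points) >= 2) {
        p <- rt$points * scale
        segs[[length(segs) + 1L]] <-
          cbind(p[-nrow(p), 1], p[-nrow(p), 2], p[-1, 1], p[-1, 2])
      }
  if (length(segs) == 0L) return(matrix(numeric(0), 0, 4))
  do.call(rbind, segs)
}

#' Render a root system to a raster image
#'
#' Draws anti-aliased root strokes of `root_width` over a procedurally
#' textured background (fibrous: blue germination-paper-like; taproot: dark
#' plate-like), with additive pixel noise. Deterministic for a fixed
#' `rng_seed`. Root points outside the image are clipped with a warning.
#'
#' @param rs a `root_system`.
#' @param params the [architecture_params()] used (controls size, width,
#'   noise and style).
#' @return numeric array `(H, W, 3)` in `[0, 1]`.
#' @export
render_image <- function(rs, params) {
  W <- params$image_size[1]; H <- params$image_size[2]
  old <- local_seed(params$rng_seed + 1000003L)
  on.exit(restore_seed(old))
  # background texture
  if (params$style == "fibrous") {
    base <- c(0.23, 0.35, 0.62)
    root_col <- c(0.93, 0.91, 0.84)
  } else {
    base <- c(0.09, 0.10, 0.11)
    root_col <- c(0.86, 0.88, 0.86)
  }
  lowfreq <- cpp_gauss_blur(matrix(stats::rnorm(H * W, 0, 1), H, W),
                            max(4, H / 50)) * 2
  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3) img[, , k] <- clamp01(base[k] + lowfreq * 0.35 * base[k])

  pts_all <- do.call(rbind, lapply(rs$plants, function(pl)
    do.call(rbind, lapply(pl$roots, function(rt) rt$points))))
  if (!is.null(pts_all) && nrow(pts_all) > 0 &&
      (min(pts_all) < 0 || max(pts_all[, 1]) > W - 1 || max(pts_all[, 2]) > H - 1))
    warning("root points outside image bounds were clipped")

  seg1 <- root_segments(rs, 1L)
  seg2 <- root_segments(rs, 2L)
  cov <- matrix(0, H, W)
  if (nrow(seg1) > 0)
    cov <- pmax(cov, cpp_stroke_segments(H, W, seg1, params$root_width / 2, TRUE))
  if (nrow(seg2) > 0)
    cov <- pmax(cov, cpp_stroke_segments(H, W, seg2, params$root_width * 0.35, TRUE))
  for (k in 1:3) img[, , k] <- img[, , k] * (1 - cov) + root_col[k] * cov
  img <- img + array(stats::rnorm(H * W * 3, 0, params$noise_sd), dim = dim(img))
  clamp01(img)
}

#' Scale a root system's coordinates
#'
#' Multiplies every coordinate (seeds, polylines, attachments) by `factor`,
#' e.g. 0.5 to express a native-resolution system in network-output
#' coordinates.
#'
#' @param rs a `root_system`.
#' @param factor scalar scale factor.
#' @return the scaled `root_system`.
#' @export
scale_root_system <- function(rs, factor) {
  rs$plants <- lapply(rs$plants, function(pl) {
    pl$seed <- pl$seed * factor
    pl$roots <- lapply(pl$roots, function(rt) {
      rt$points <- rt$points * factor
      if (!is.null(rt$attachment)) rt$attachment <- rt$attachment * factor
      rt
    })
    pl
  })
  rs$image_size <- rs$image_size * factor
  rs
}

# Convenience counters used throughout the tests and pipeline.
count_roots <- function(rs, order) {
  sum(vapply(rs$plants, function(pl)
    sum(vapply(pl$roots, function(rt) rt$order == order, logical(1))),
    numeric(1)))
}
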