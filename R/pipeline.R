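# Pipeline orchestration: configuration, synthetic dataset generation,
# single-image and batch inference (with an oracle mode that feeds
# ground-truth maps past the network to exercise the whole non-learned
# pipeline deterministically).

#' Pipeline configuration
#'
#' All constants default to the reference operating point: 1024x1024 network
#' input, NMS threshold 0.7, deduplication radius 8 px, graph weights
#' 0.01/0.1/10.0 with sqrt(2) diagonal factor, spline tension 0.5.
#'
#' @param input_size network input side length (default 1024).
#' @param crf_enabled run dense-CRF refinement (default TRUE).
#' @param crf_iters,crf_sxy_app,crf_srgb,crf_w_app,crf_w_sm,crf_sxy_sm CRF
#'   kernel parameters, see [crf_refine()].
#' @param nms_threshold,dedup_radius feature localization constants.
#' @param spline_spacing,spline_tension spline constants.
#' @param resample_step trait resampling step (px).
#' @param mm_per_px optional physical scale for traits.
#' @param rng_seed seed for any stochastic stage.
#' @return object of class `ra_pipeline_config`.
#' @export
pipeline_config <- function(input_size = 1024L, crf_enabled = TRUE,
                            crf_iters = 5L, crf_sxy_app = 30,
                            crf_srgb = 13 / 255, crf_w_app = 4, crf_w_sm = 2,
                            crf_sxy_sm = 3, nms_threshold = 0.7,
                            dedup_radius = 8, spline_spacing = 8,
                            spline_tension = 0.5, resample_step = 2,
                            mm_per_px = NULL, rng_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "ra_pipeline_config"
  cfg
}

#' Generate an in-memory synthetic training set
#'
#' Each sample pairs a rendered image with its training targets at half the
#' image resolution: binary class masks (stroke width scaled with the image)
#' and unit-peak heat maps (sigma 1 px).
#'
#' @param n number of samples.
#' @param rng_seed base seed; sample `i` uses `rng_seed + i`.
#' @param style,image_size,... forwarded to [architecture_params()].
#' @return list of samples `list(image, masks, heats, rs, params)`.
#' @export
make_training_set <- function(n, rng_seed = 1L, style = "fibrous",
                              image_size = 128L, ...) {
  lapply(seq_len(n), function(i) {
    params <- architecture_params(style = style, image_size = image_size,
                                  rng_seed = rng_seed + i, ...)
    rs <- generate_architecture(params)
    img <- render_image(rs, params)
    half <- scale_root_system(rs, 0.5)
    shape <- c(dim(img)[1] %/% 2L, dim(img)[2] %/% 2L)
    list(image = img,
         masks = render_class_masks(half, shape,
                                    stroke_width = params$root_width * 0.5),
         heats = render_heatmaps(half, shape, sigma = 1.0),
         rs = rs, params = params)
  })
}

#' Write a synthetic dataset to disk
#'
#' For each of `n` systems, writes the rendered image (PNG), the ground-truth
#' architecture (RSML) and the training-target maps (PNG per channel), plus
#' a `manifest.csv` listing the files. Re-running with the same seed is
#' bit-identical.
#'
#' @param n number of systems.
#' @param out_dir output directory (created if needed).
#' @param rng_seed base seed.
#' @param ... forwarded to [make_training_set()].
#' @return the manifest data frame, invisibly.
#' @export
synth_dataset <- function(n, out_dir, rng_seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  samples <- make_training_set(n, rng_seed = rng_seed, ...)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stem <- file.path(out_dir, sprintf("synth_%04d", i))
    png::writePNG(s$image, paste0(stem, ".png"))
    write_rsml(s$rs, paste0(stem, ".rsml"))
    write_map_pngs(s$masks, paste0(stem, "_mask"))
    write_map_pngs(s$heats, paste0(stem, "_heat"))
    rows[[i]] <- data.frame(id = i, image = paste0(stem, ".png"),
                            rsml = paste0(stem, ".rsml"),
                            split = if (i %% 5 == 0) "val" else "train")
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(id = integer(0), image = character(0),
                              rsml = character(0), split = character(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# Letterbox an (H, W, 3) image to (size, size): aspect-preserving resize
# plus centred padding with the image mean. Returns the image and the
# transform needed to map output-space coordinates back to native pixels.
letterbox_image <- function(img, size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- min(size / W, size / H)
  h2 <- round(H * s); w2 <- round(W * s)
  x4 <- img
  dim(x4) <- c(H, W, 3L, 1L)
  rs <- cpp_resize_bilinear(x4, h2, w2)
  out <- array(mean(img), dim = c(size, size, 3L))
  oy <- (size - h2) %/% 2L
  ox <- (size - w2) %/% 2L
  out[oy + seq_len(h2), ox + seq_len(w2), ] <- rs[, , , 1]
  list(image = out, scale = s, off_x = ox, off_y = oy)
}

#' Run the full pipeline on one image
#'
#' Resizes (letterboxes) the image to the network input size, runs the
#' forward pass, optionally refines the segmentation with the dense CRF,
#' localizes features, reconstructs the architecture by heuristic search,
#' scales coordinates back to native resolution, and computes splines and
#' traits. In oracle mode (`oracle_rs` supplied) the network is bypassed:
#' ground-truth class maps and heat maps rendered from the given
#' architecture (at its native resolution) are fed directly to
#' post-processing, exercising the whole non-learned pipeline.
#'
#' @param input image array `(H, W, 3)` or `(H, W)` (grayscale is channel
#'   duplicated), or a PNG file path.
#' @param model a trained `ra_model` (not needed in oracle mode).
#' @param oracle_rs optional `root_system` for oracle mode.
#' @param config a [pipeline_config()].
#' @param out_prefix optional path prefix; if given, RSML, masks and a trait
#'   CSV are written.
#' @return list with `rs` (native-resolution `root_system`), `traits`,
#'   `features`, `class_maps` and the processing scale.
#' @export
infer_image <- function(input, model = NULL, oracle_rs = NULL,
                        config = pipeline_config(), out_prefix = NULL) {
  if (is.character(input)) input <- png::readPNG(input)
  if (!is.null(dim(input)) && length(dim(input)) == 3L && dim(input)[3] > 3L)
    input <- input[, , 1:3]
  img <- gray_to_rgb(input)

  if (!is.null(oracle_rs)) {
    # oracle mode runs at the architecture's own resolution
    H <- oracle_rs$image_size[2]; W <- oracle_rs$image_size[1]
    maps <- render_class_masks(oracle_rs, c(H, W), stroke_width = 8)
    heats <- render_heatmaps(oracle_rs, c(H, W))
    to_native <- function(p) p
    scale_out <- 1
  } else {
    if (is.null(model)) stop("either a model or oracle_rs is required")
    lb <- letterbox_image(img, config$input_size)
    pred <- net_predict(model, lb$image)
    maps <- pred$seg_prob[, , , 1]
    heats <- pred$heat[, , , 1]
    if (config$crf_enabled) {
      small <- letterbox_image(img, config$input_size %/% 2L)
      maps <- crf_refine(maps, small$image, iters = config$crf_iters,
                         sxy_app = config$crf_sxy_app, srgb = config$crf_srgb,
                         w_app = config$crf_w_app, w_sm = config$crf_w_sm,
                         sxy_sm = config$crf_sxy_sm)
    }
    # output space is half the input; map back to native pixels
    to_native <- function(p) {
      p[, 1] <- (p[, 1] * 2 - lb$off_x) / lb$scale
      p[, 2] <- (p[, 2] * 2 - lb$off_y) / lb$scale
      p
    }
    scale_out <- 2 / lb$scale
  }

  features <- localize_features(heats, threshold = config$nms_threshold,
                                radius = config$dedup_radius)
  rs <- reconstruct(maps, features)
  # smooth every root with the cardinal spline and return to native scale
  rs$plants <- lapply(rs$plants, function(pl) {
    pl$seed <- as.numeric(to_native(rbind(pl$seed)))
    pl$roots <- lapply(pl$roots, function(rt) {
      if (nrow(rt$points) >= 2 && polyline_length(rt$points) > 0) {
        sc <- fit_spline(rt$points, spacing = config$spline_spacing,
                         tension = config$spline_tension)
        rt$spline <- to_native(sc$samples)
      }
      rt$points <- to_native(rt$points)
      if (!is.null(rt$attachment))
        rt$attachment <- as.numeric(to_native(rbind(rt$attachment)))
      rt
    })
    pl
  })
  rs$image_size <- c(dim(img)[2], dim(img)[1])
  traits <- compute_traits(rs, resample_step = config$resample_step,
                           mm_per_px = config$mm_per_px)
  if (!is.null(out_prefix)) {
    write_rsml(rs, paste0(out_prefix, ".rsml"),
               spline_spacing = config$spline_spacing,
               spline_tension = config$spline_tension)
    write_masks(maps, out_prefix)
    write_traits_csv(traits, paste0(out_prefix, "_traits.csv"),
                     image_id = basename(out_prefix))
  }
  list(rs = rs, traits = traits, features = features, class_maps = maps,
       scale = scale_out)
}

#' Batch inference over a directory
#'
#' Processes every PNG in `in_dir` unattended; unreadable images are skipped
#' with a logged error. Returns a summary data frame; the `status` column is
#' `"ok"` or `"error"`.
#'
#' @param in_dir input directory.
#' @param out_dir output directory.
#' @param model trained `ra_model`.
#' @param config a [pipeline_config()].
#' @return summary data frame, invisibly.
#' @export
infer_directory <- function(in_dir, out_dir, model,
                            config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(in_dir, pattern = "\\.png$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    res <- tryCatch({
      infer_image(f, model = model, config = config,
                  out_prefix = file.path(out_dir,
                                         sub("\\.png$", "", basename(f))))
      "ok"
    }, error = function(e) {
      message("error processing ", f, ": ", conditionMessage(e))
      "error"
    })
    data.frame(file = f, status = res)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(file = character(0), status = character(0))
  invisible(out)
}
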