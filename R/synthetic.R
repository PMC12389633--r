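# Deterministic synthetic plant-scene generator. Scenes emulate the
# documented statistical structure of the field dataset — varied
# resolutions, mean grayscale brightness inside [100, 120], five classes
# with distinctive appearance, cluttered backgrounds, optional occlusion —
# without any claim of photorealism: objects are parameterized color/shape
# signatures with tight bounding boxes.

PLANT_CLASSES <- c("Acanthus mollis", "Cirsium eriophorum",
                   "Gentiana lutea", "Hyacinthoides non-scripta",
                   "Urospermum dalechampii")

# per-class color/geometry signature: RGB fill and a shape tag
class_signature <- function(class_name) {
  sig <- list(
    "Acanthus mollis" = list(col = c(150, 60, 200), shape = "star"),
    "Cirsium eriophorum" = list(col = c(225, 45, 90), shape = "ring"),
    "Gentiana lutea" = list(col = c(240, 210, 40), shape = "ellipse"),
    "Hyacinthoides non-scripta" = list(col = c(55, 90, 225),
                                       shape = "diamond"),
    "Urospermum dalechampii" = list(col = c(240, 150, 30), shape = "disc")
  )[[class_name]]
  if (is.null(sig)) stop("no appearance signature for class ", class_name)
  sig
}

#' Scene specification for the synthetic generator
#'
#' @param width,height scene size in pixels
#' @param n_objects number of plant objects to draw (>= 0)
#' @param class_names classes objects are drawn from (default the five
#'   modeled species)
#' @param object_classes optional explicit class per object (recycled)
#' @param brightness_target mean-grayscale range the scene is gain-adjusted
#'   into (default `c(100, 120)`)
#' @param clutter_level background clutter density in \[0, 1\]
#' @param occlusion_prob per-object probability of a partial occluding bar
#' @param size_range object diameter range as a fraction of `min(width,
#'   height)`
#' @param seed scene RNG seed
#' @return a `scene_spec` list
#' @export
scene_spec <- function(width = 640L, height = 480L, n_objects = 3L,
                       class_names = PLANT_CLASSES,
                       object_classes = NULL,
                       brightness_target = c(100, 120),
                       clutter_level = 0.5, occlusion_prob = 0.2,
                       size_range = c(0.25, 0.45), seed = 42L) {
  stopifnot(n_objects >= 0, width >= 32, height >= 32,
            brightness_target[1] >= 0, brightness_target[2] <= 255,
            brightness_target[1] < brightness_target[2])
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_objects = as.integer(n_objects),
                 class_names = class_names,
                 object_classes = object_classes,
                 brightness_target = brightness_target,
                 clutter_level = clutter_level,
                 occlusion_prob = occlusion_prob,
                 size_range = size_range, seed = as.integer(seed)),
            class = "scene_spec")
}

# coarse random field upscaled bilinearly: cheap low-frequency texture
noise_field <- function(h, w, cells = 8L, amplitude = 1) {
  coarse <- matrix(runif(cells * cells, -1, 1), cells, cells)
  resize_bilinear(coarse, h, w) * amplitude
}

shape_mask <- function(shape, X, Y, cx, cy, rx, ry, theta0 = 0) {
  u <- (X - cx) / rx
  v <- (Y - cy) / ry
  r <- sqrt(u^2 + v^2)
  switch(shape,
         disc = r <= 1,
         ring = r <= 1 & r >= 0.45,
         ellipse = r <= 1,
         diamond = (abs(u) + abs(v)) <= 1,
         star = {
           ang <- atan2(v, u) + theta0
           r <= 0.45 + 0.55 * cos(3.5 * ang)^2
         },
         stop("unknown shape ", shape))
}

#' Generate one synthetic plant scene
#'
#' Draws a textured background, clutter ellipses, and `n_objects`
#' class-distinctive shapes; records a tight bounding box per object; then
#' gain-adjusts the whole image until its mean grayscale lies inside
#' `brightness_target`. Bit-identical under the same spec (including seed).
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (H x W x 3 array in \[0, 255\]) and
#'   `annotation` (a [voc_annotation()])
#' @export
make_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height
    w <- spec$width
    X <- matrix(rep(seq_len(w), each = h), h, w)
    Y <- matrix(rep(seq_len(h), times = w), h, w)
    base <- c(75, 95, 60) + runif(3, -10, 10)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      img[, , ch] <- base[ch] + noise_field(h, w, 8L, 25) +
        noise_field(h, w, 24L, 12)
    }
    # background clutter: muted random ellipses
    n_clutter <- round(spec$clutter_level * 15)
    for (i in seq_len(n_clutter)) {
      cx <- runif(1, 1, w)
      cy <- runif(1, 1, h)
      rx <- runif(1, 0.03, 0.10) * w
      ry <- runif(1, 0.03, 0.10) * h
      m <- shape_mask("ellipse", X, Y, cx, cy, rx, ry)
      col <- base + runif(3, -35, 35)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- 0.6 * plane[m] + 0.4 * col[ch]
        img[, , ch] <- plane
      }
    }
    # objects
    cls <- if (!is.null(spec$object_classes)) {
      rep(spec$object_classes, length.out = spec$n_objects)
    } else if (spec$n_objects > 0) {
      sample(spec$class_names, spec$n_objects, replace = TRUE)
    } else character(0)
    objects <- NULL
    for (i in seq_len(spec$n_objects)) {
      sig <- class_signature(cls[i])
      diam <- runif(1, spec$size_range[1], spec$size_range[2]) *
        min(h, w)
      rx <- diam / 2
      ry <- rx * (if (sig$shape == "ellipse") runif(1, 0.55, 0.75) else
        runif(1, 0.85, 1.15))
      cx <- runif(1, rx + 2, w - rx - 1)
      cy <- runif(1, ry + 2, h - ry - 1)
      m <- shape_mask(sig$shape, X, Y, cx, cy, rx, ry,
                      theta0 = runif(1, 0, pi))
      col <- sig$col + runif(3, -15, 15)
      shade <- 1 - 0.3 * ((Y - cy) / max(ry, 1))  # simple vertical shading
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- col[ch] * shade[m]
        img[, , ch] <- plane
      }
      if (runif(1) < spec$occlusion_prob) {
        # gray bar across the lower part of the object (box unchanged)
        y1 <- min(h, round(cy + 0.2 * ry))
        y2 <- min(h, round(cy + 0.5 * ry))
        x1 <- max(1, round(cx - rx))
        x2 <- min(w, round(cx + rx))
        img[y1:y2, x1:x2, ] <- 110
      }
      cols_hit <- which(colSums(m) > 0)
      rows_hit <- which(rowSums(m) > 0)
      objects <- rbind(objects, data.frame(
        name = cls[i],
        xmin = min(cols_hit), ymin = min(rows_hit),
        xmax = max(cols_hit), ymax = max(rows_hit)))
    }
    img <- clip255(img)
    # gain-adjust mean grayscale into the target band
    tgt <- mean(spec$brightness_target)
    for (it in 1:10) {
      mg <- mean(to_gray(img))
      if (mg >= spec$brightness_target[1] &&
          mg <= spec$brightness_target[2]) break
      img <- clip255(img * (tgt / mg))
    }
    ann <- if (is.null(objects)) {
      voc_annotation("scene.png", w, h)
    } else {
      voc_annotation("scene.png", w, h, 3L, objects)
    }
    list(image = img, annotation = ann)
  })
}

#' Generate a VOC-layout synthetic dataset
#'
#' Writes `n_images` PNG scenes plus their VOC XML annotations into
#' `out_dir` (flat layout, image and XML sharing a basename), with the
#' per-image primary class drawn from `class_mix` and the resolution from
#' `size_pool`. Returns the manifest.
#'
#' @param n_images number of scenes (>= 1)
#' @param out_dir output directory (created if needed)
#' @param class_mix class sampling weights (named or in `class_names`
#'   order); uniform by default
#' @param size_pool list of `c(width, height)` resolutions to draw from
#' @param class_names class name vector
#' @param n_objects_range inclusive range of objects per scene
#' @param seed dataset seed; scene i uses `seed + i`
#' @param ... further arguments passed to [scene_spec()]
#' @return data.frame manifest: filename, xml, class, width, height,
#'   n_objects
#' @export
make_dataset <- function(n_images, out_dir, class_mix = NULL,
                         size_pool = list(c(640L, 480L), c(512L, 512L),
                                          c(500L, 375L)),
                         class_names = PLANT_CLASSES,
                         n_objects_range = c(1L, 3L), seed = 42L, ...) {
  stopifnot(n_images >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  if (is.null(class_mix)) {
    class_mix <- rep(1 / length(class_names), length(class_names))
  }
  manifest <- NULL
  with_seed(seed, {
    primary <- sample(class_names, n_images, replace = TRUE,
                      prob = class_mix)
    sizes <- sample(seq_along(size_pool), n_images, replace = TRUE)
    n_obj <- sample(seq(n_objects_range[1], n_objects_range[2]),
                    n_images, replace = TRUE)
    for (i in seq_len(n_images)) {
      wh <- size_pool[[sizes[i]]]
      sp <- scene_spec(width = wh[1], height = wh[2],
                       n_objects = n_obj[i],
                       class_names = class_names,
                       object_classes = primary[i],
                       seed = seed + i, ...)
      sc <- make_scene(sp)
      stem <- sprintf("img_%04d", i)
      sc$annotation$filename <- paste0(stem, ".png")
      write_image(sc$image, file.path(out_dir, paste0(stem, ".png")))
      write_voc_xml(sc$annotation, file.path(out_dir,
                                             paste0(stem, ".xml")))
      manifest <- rbind(manifest, data.frame(
        filename = paste0(stem, ".png"), xml = paste0(stem, ".xml"),
        class = primary[i], width = wh[1], height = wh[2],
        n_objects = n_obj[i]))
    }
  })
  manifest
}
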