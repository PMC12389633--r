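# Pascal VOC XML annotation I/O, stratified splitting, and dataset
# statistics. Annotation objects keep the VOC convention (1-based inclusive
# pixel corners); `ann_boxes()` converts to the package-internal 0-based
# half-open form at that single boundary.

#' Construct a VOC annotation record
#'
#' @param filename image file name
#' @param width,height,depth image dimensions
#' @param objects data.frame with columns `name`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (1-based inclusive corners, the VOC convention)
#' @return a `voc_annotation` object
#' @export
voc_annotation <- function(filename, width, height, depth = 3L,
                           objects = data.frame(name = character(0),
                                                xmin = numeric(0),
                                                ymin = numeric(0),
                                                xmax = numeric(0),
                                                ymax = numeric(0))) {
  stopifnot(width >= 1, height >= 1)
  if (nrow(objects) > 0) {
    with(objects, {
      if (any(xmin > xmax) || any(ymin > ymax)) {
        stop("degenerate bounding box (min corner beyond max corner)")
      }
      if (any(xmin < 1) || any(ymin < 1) || any(xmax > width) ||
          any(ymax > height)) {
        stop("bounding box outside image bounds")
      }
    })
  }
  structure(list(filename = filename, width = as.integer(width),
                 height = as.integer(height), depth = as.integer(depth),
                 objects = objects),
            class = "voc_annotation")
}

# 0-based half-open boxes for the detector internals
ann_boxes <- function(ann) {
  if (nrow(ann$objects) == 0) return(matrix(0, 0, 4))
  with(ann$objects, cbind(xmin - 1, ymin - 1, xmax, ymax))
}

xml_num <- function(node, xpath, where) {
  el <- xml2::xml_find_first(node, xpath)
  if (inherits(el, "xml_missing")) {
    stop("VOC parse error: missing <", xpath, "> element in <", where, ">")
  }
  as.numeric(xml2::xml_text(el))
}

#' Read / write a Pascal VOC XML annotation
#'
#' Reads the folder/filename/size/object/bndbox dialect emitted by common
#' labeling tools. `write_voc_xml()` followed by `read_voc_xml()` is a
#' lossless round trip of the modeled fields.
#'
#' @param path XML file path
#' @return a [voc_annotation()] object
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing")) {
    stop("VOC parse error: missing <size> element in ", path)
  }
  width <- xml_num(size, "./width", "size")
  height <- xml_num(size, "./height", "size")
  depth_el <- xml2::xml_find_first(size, "./depth")
  depth <- if (inherits(depth_el, "xml_missing")) 3L else {
    as.integer(xml2::xml_text(depth_el))
  }
  fn_el <- xml2::xml_find_first(doc, "./filename")
  filename <- if (inherits(fn_el, "xml_missing")) "" else {
    xml2::xml_text(fn_el)
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  rows <- lapply(objs, function(o) {
    nm <- xml2::xml_find_first(o, "./name")
    if (inherits(nm, "xml_missing")) {
      stop("VOC parse error: missing <name> element in <object>")
    }
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (inherits(bb, "xml_missing")) {
      stop("VOC parse error: missing <bndbox> element in <object>")
    }
    data.frame(name = xml2::xml_text(nm),
               xmin = xml_num(bb, "./xmin", "bndbox"),
               ymin = xml_num(bb, "./ymin", "bndbox"),
               xmax = xml_num(bb, "./xmax", "bndbox"),
               ymax = xml_num(bb, "./ymax", "bndbox"))
  })
  objects <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(objects)) {
    voc_annotation(filename, width, height, depth)
  } else {
    voc_annotation(filename, width, height, depth, objects)
  }
}

#' @rdname read_voc_xml
#' @param ann a [voc_annotation()] object
#' @export
write_voc_xml <- function(ann, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", ann$filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", as.character(ann$depth))
  for (i in seq_len(nrow(ann$objects))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ann$objects$name[i])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(ann$objects$xmin[i]))
    xml2::xml_add_child(bb, "ymin", as.character(ann$objects$ymin[i]))
    xml2::xml_add_child(bb, "xmax", as.character(ann$objects$xmax[i]))
    xml2::xml_add_child(bb, "ymax", as.character(ann$objects$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Partitions record indices so that each stratum (class label) is divided
#' according to `ratios` with largest-remainder rounding: per-class subset
#' sizes deviate from the exact fractions by at most one. Deterministic
#' under `seed`. Strata with fewer records than split parts are assigned
#' entirely to the training set, with a warning.
#'
#' @param labels stratification label per record
#' @param ratios train/validation/test fractions summing to one
#' @param seed RNG seed
#' @return list of integer index vectors `train`, `val`, `test`
#' @export
stratified_split <- function(labels, ratios = c(0.8, 0.1, 0.1),
                             seed = 42L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  if (length(ratios) != 3) stop("ratios must have three parts")
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < length(ratios)) {
        warning("stratum '", cl, "' has fewer records (", length(idx),
                ") than split parts; assigning all to train")
        out$train <- c(out$train, idx)
        next
      }
      idx <- sample(idx)
      exact <- length(idx) * ratios
      base <- floor(exact)
      rem <- length(idx) - sum(base)
      if (rem > 0) {
        give <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[give] <- base[give] + 1
      }
      splits <- split(idx, rep(seq_along(base), times = base))
      out$train <- c(out$train, splits[["1"]])
      out$val <- c(out$val, splits[["2"]])
      out$test <- c(out$test, splits[["3"]])
    }
  })
  lapply(out, sort)
}

#' Per-image brightness statistics
#'
#' Brightness is estimated as the mean of the standard luminance grayscale
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param images list of H x W x 3 arrays in \[0, 255\] (or image file
#'   paths)
#' @param breaks histogram bin edges over \[0, 255\]
#' @return list with `mean` (per-image mean gray) and `histogram`
#'   (data.frame of bin edges and counts)
#' @export
brightness_stats <- function(images, breaks = seq(0, 256, by = 16)) {
  if (length(images) == 0) stop("empty image set")
  means <- vapply(images, function(im) {
    if (is.character(im)) im <- read_image(im)
    mean(to_gray(im))
  }, numeric(1))
  h <- hist(means, breaks = breaks, plot = FALSE, right = FALSE)
  list(mean = means,
       histogram = data.frame(low = head(breaks, -1),
                              high = breaks[-1],
                              count = h$counts))
}

#' Resolution frequency table
#'
#' @param annotations list of [voc_annotation()] objects
#' @return data.frame of distinct (width, height) pairs with counts
#' @export
resolution_table <- function(annotations) {
  if (length(annotations) == 0) {
    return(data.frame(width = integer(0), height = integer(0),
                      count = integer(0)))
  }
  wh <- data.frame(width = vapply(annotations, `[[`, 1L, "width"),
                   height = vapply(annotations, `[[`, 1L, "height"))
  agg <- aggregate(list(count = rep(1L, nrow(wh))), wh, sum)
  agg[order(agg$width, agg$height), , drop = FALSE]
}

# read an image + XML folder (as written by make_dataset) into detector
# records: image array, 0-based half-open boxes, class labels
load_voc_dir <- function(dir) {
  xmls <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (length(xmls) == 0) stop("no VOC XML annotations found in ", dir)
  lapply(xmls, function(p) {
    ann <- read_voc_xml(p)
    img_path <- file.path(dir, ann$filename)
    if (!file.exists(img_path)) {
      stop("annotated image not found: ", img_path)
    }
    list(image = read_image(img_path), ann = ann,
         boxes = ann_boxes(ann), labels = ann$objects$name,
         path = img_path)
  })
}
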