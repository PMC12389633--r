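# Image enhancement operators. Images are H x W x 3 (or H x W) arrays of
# intensities in [0, 255]; all enhancers preserve shape and clip back into
# the 8-bit range. Convolutions use symmetric (mirror) border reflection.

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Sharpening parameters
#'
#' Parameters of the unsharp-masking enhancer: the enhancement intensity
#' `k` applied to the high-frequency residual, and the Gaussian low-pass
#' filter given by `sigma` (pixels) and its odd square support
#' `kernel_size`. The defaults follow the experimental setting `k = 1.5`
#' with a 3-sigma support for `sigma = 2`.
#'
#' @param k enhancement intensity, > 0
#' @param sigma Gaussian standard deviation in pixels, > 0
#' @param kernel_size odd integer >= 3, kernel support in pixels
#' @return an object of class `sharpen_params`
#' @export
sharpen_params <- function(k = 1.5, sigma = 2.0, kernel_size = 13L) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be > 0")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be > 0")
  }
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3 || kernel_size %% 2 == 0) {
    stop("kernel_size must be an odd integer >= 3")
  }
  structure(list(k = k, sigma = sigma, kernel_size = kernel_size),
            class = "sharpen_params")
}

gaussian_kernel <- function(sigma, size) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# apply a 2-D correlation kernel per channel with reflected borders
filter_image <- function(img, kernel) {
  if (length(dim(img)) == 2) return(cpp_filter2d_reflect(img, kernel))
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- cpp_filter2d_reflect(img[, , ch], kernel)
  }
  out
}

#' Gaussian blur (low-frequency component)
#'
#' Convolves each channel with a normalized 2-D Gaussian kernel,
#' reflecting the image at its borders. This is the low-pass component
#' `B = G_sigma * I` that unsharp masking subtracts from the input.
#'
#' @param img H x W x 3 (or H x W) intensity array in \[0, 255\]
#' @param params a [sharpen_params()] object
#' @return blurred image, same shape as `img`
#' @export
gaussian_blur <- function(img, params = sharpen_params()) {
  stopifnot(inherits(params, "sharpen_params"))
  if (length(img) == 0) stop("empty image")
  filter_image(img, gaussian_kernel(params$sigma, params$kernel_size))
}

#' Unsharp masking
#'
#' Sharpens an image by adding back `k` times its high-frequency residual:
#' `I_sharp = I + k (I - B) = (1 + k) I - k B`, where `B` is the Gaussian
#' blur of `I`. Applied independently per RGB channel in floating point,
#' then clipped to \[0, 255\] (disable with `clip = FALSE` to inspect the
#' raw linear combination).
#'
#' @inheritParams gaussian_blur
#' @param clip clip the result to \[0, 255\] (default TRUE)
#' @return sharpened image, same shape as `img`
#' @export
unsharp_mask <- function(img, params = sharpen_params(), clip = TRUE) {
  b <- gaussian_blur(img, params)
  out <- (1 + params$k) * img - params$k * b
  if (clip) out <- clip255(out)
  out
}

laplace_sharpen <- function(img) {
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  clip255(img - filter_image(img, kern))
}

sobel_sharpen <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  gx <- filter_image(img, kx)
  gy <- filter_image(img, ky)
  clip255(img + sqrt(gx^2 + gy^2))
}

high_boost <- function(img, params = sharpen_params(), amount = 2.0) {
  clip255(amount * img - gaussian_blur(img, params))
}

hsv_value_equalize <- function(img) {
  if (length(dim(img)) != 3) stop("hsv_value enhancement requires RGB input")
  d <- dim(img)
  m <- matrix(c(img[, , 1], img[, , 2], img[, , 3]),
              nrow = 3, byrow = TRUE)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  v <- hsv[3, ]
  # histogram equalization of the value channel via its empirical CDF
  r <- rank(v, ties.method = "max")
  v_eq <- (r - min(r)) / max(1, (length(v) - min(r)))
  v_eq <- pmin(pmax(v_eq, 0), 1)
  cols <- grDevices::hsv(hsv[1, ], hsv[2, ], v_eq)
  rgb <- grDevices::col2rgb(cols)
  out <- img
  out[, , 1] <- matrix(rgb[1, ], d[1], d[2])
  out[, , 2] <- matrix(rgb[2, ], d[1], d[2])
  out[, , 3] <- matrix(rgb[3, ], d[1], d[2])
  out
}

#' Apply a named enhancement method
#'
#' Dispatches to one of the five enhancers compared in this package:
#' unsharp masking (the default training-time transform), Laplacian
#' sharpening (`I` minus the 4-neighbour Laplacian response), Sobel
#' sharpening (`I` plus the gradient magnitude), high-boost filtering
#' (`A I - B` with `A = 2`), and histogram equalization of the HSV value
#' channel.
#'
#' @inheritParams gaussian_blur
#' @param method one of `"unsharp_mask"`, `"laplace"`, `"sobel"`,
#'   `"high_boost"`, `"hsv_value"`
#' @param params a [sharpen_params()] object (used by unsharp masking and
#'   high-boost)
#' @return enhanced image, same shape as `img`, intensities in \[0, 255\]
#' @export
apply_enhancement <- function(img, method = "unsharp_mask",
                              params = sharpen_params()) {
  methods <- c("unsharp_mask", "laplace", "sobel", "high_boost", "hsv_value")
  if (!is.character(method) || length(method) != 1 || !method %in% methods) {
    stop("unknown enhancement method '", method, "'; expected one of: ",
         paste(methods, collapse = ", "))
  }
  switch(method,
         unsharp_mask = unsharp_mask(img, params),
         laplace = laplace_sharpen(img),
         sobel = sobel_sharpen(img),
         high_boost = high_boost(img, params),
         hsv_value = hsv_value_equalize(img))
}

#' Read / write an image file
#'
#' PNG and JPEG I/O on \[0, 255\] intensity arrays (chosen by file
#' extension). Grayscale files are expanded to three identical channels.
#'
#' @param path file path ending in .png, .jpg or .jpeg
#' @return H x W x 3 array in \[0, 255\]
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop("unsupported image extension: ", ext))
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' @rdname read_image
#' @param img image array in \[0, 255\]
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- clip255(img) / 255
  switch(ext,
         png = png::writePNG(scaled, path),
         jpg = ,
         jpeg = jpeg::writeJPEG(scaled, path, quality = 0.95),
         stop("unsupported image extension: ", ext))
  invisible(path)
}

# standard luminance grayscale
to_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
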