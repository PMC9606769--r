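# Internal raster helpers. Images are plain numeric arrays in [0,1]:
# H x W matrices (grayscale) or H x W x 3 arrays (RGB).

rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] < .Machine$double.eps) {
    return(array(0.5, dim = dim(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# Rec. 709 luma weights, applied to (already gamma-encoded) sRGB values.
LUMA_709 <- c(0.2126, 0.7152, 0.0722)

luminance <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  LUMA_709[1] * img[, , 1] + LUMA_709[2] * img[, , 2] + LUMA_709[3] * img[, , 3]
}

as_rgb_image <- function(img, promote_gray = TRUE) {
  d <- dim(img)
  if (is.matrix(img)) {
    if (!promote_gray) {
      abort("grayscale input where RGB required.", class = "sipstats_format_error")
    }
    img <- array(rep(img, 3L), dim = c(d[1], d[2], 3L))
  } else if (length(d) == 3L && d[3] == 4L) {
    img <- img[, , 1:3]                       # drop alpha
  } else if (length(d) != 3L || d[3] != 3L) {
    abort("expected an H x W x 3 array or an H x W matrix.",
          class = "sipstats_format_error")
  }
  if (any(!is.finite(img))) {
    abort("image contains non-finite values.", class = "sipstats_format_error")
  }
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    abort("image values must lie in [0, 1].", class = "sipstats_format_error")
  }
  img
}

# Bilinear resample to side x side (EBImage).
resize_rgb <- function(img, side) {
  if (dim(img)[1] == side && dim(img)[2] == side) return(img)
  out <- EBImage::resize(img, w = side, h = side)
  out <- pmin(pmax(as.numeric(out), 0), 1)
  array(out, dim = c(side, side, dim(img)[3]))
}

# Pixel matrix (n x 3) of CIELab values, D65, standard scales
# (L in [0,100], a/b roughly [-128, 127]).
rgb_to_lab <- function(img) {
  px <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
              as.numeric(img[, , 3]))
  convertColor(px, from = "sRGB", to = "Lab")
}

# Pixel matrix (n x 3) of HSV values; h, s, v all in [0, 1].
rgb_to_hsv_mat <- function(img) {
  px <- rbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
              as.numeric(img[, , 3]))
  t(rgb2hsv(px, maxColorValue = 1))
}

#' Read images from a directory or file paths
#'
#' Decodes PNG/TIFF rasters losslessly to `[0, 1]` arrays. Image ids are the
#' file name stems; files are taken in deterministic lexicographic order.
#' Lossy formats (JPEG) are refused.
#'
#' @param path A directory, or a character vector of file paths.
#' @return A named list of image arrays (names = ids).
#' @export
read_images <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                    full.names = TRUE))
  } else {
    path
  }
  if (length(files) == 0L) {
    abort("no readable PNG/TIFF images found.", class = "sipstats_format_error")
  }
  if (any(grepl("\\.jpe?g$", files, ignore.case = TRUE))) {
    abort("JPEG is lossy and not supported; use PNG or TIFF.",
          class = "sipstats_format_error")
  }
  ids <- sub("\\.[^.]+$", "", basename(files))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate image ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "sipstats_format_error")
  }
  imgs <- lapply(files, function(f) {
    x <- tryCatch(
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f),
      error = function(e) abort(paste0("cannot decode image: ", f),
                                class = "sipstats_format_error")
    )
    if (is.matrix(x)) x else as_rgb_image(x)
  })
  names(imgs) <- ids
  imgs
}

#' Write an image as lossless PNG
#'
#' @param img Grayscale matrix or H x W x 3 array in `[0, 1]`.
#' @param path Output path; must end in `.png` (JPEG refused).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    abort("JPEG is lossy; refusing to write. Use .png.",
          class = "sipstats_format_error")
  }
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    abort("only .png output is supported.", class = "sipstats_format_error")
  }
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}
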