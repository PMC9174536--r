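#' Structuring element for gray-scale morphology
#'
#' Builds a flat binary structuring element used by the top-hat transforms.
#' A disk of radius `r` contains every offset `(di, dj)` with
#' `di^2 + dj^2 <= r^2`; a square of radius `r` is the full
#' `(2r+1) x (2r+1)` window.
#'
#' @param shape `"disk"` or `"square"`.
#' @param radius Positive integer radius in pixels.
#' @return A logical matrix of odd dimensions, `TRUE` inside the element.
#' @examples
#' structuring_element("disk", 2)
#' @export
structuring_element <- function(shape = c("disk", "square"), radius = 9L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("structuring element radius must be >= 1")
  d <- 2L * radius + 1L
  if (shape == "square") return(matrix(TRUE, d, d))
  off <- seq(-radius, radius)
  outer(off, off, function(a, b) a^2 + b^2 <= radius^2)
}

check_se_fits <- function(img, se) {
  if (!is.matrix(img) || !is.numeric(img)) stop("img must be a numeric matrix")
  if (nrow(se) > nrow(img) || ncol(se) > ncol(img)) {
    stop("structuring element (", nrow(se), "x", ncol(se),
         ") is larger than the image (", nrow(img), "x", ncol(img), ")")
  }
}

gray_opening <- function(img, se) {
  cpp_gray_morph(cpp_gray_morph(img, se, 0L), se, 1L)
}

gray_closing <- function(img, se) {
  cpp_gray_morph(cpp_gray_morph(img, se, 1L), se, 0L)
}

#' White top-hat transform
#'
#' `img - opening(img, se)`: extracts bright structures smaller than the
#' structuring element.  All output values are non-negative.
#'
#' @param img Gray image matrix in \[0, 1\].
#' @param se Structuring element from [structuring_element()].
#' @return Matrix of the same shape, values `>= 0`.
#' @export
white_tophat <- function(img, se = structuring_element("disk", 9L)) {
  check_se_fits(img, se)
  img - gray_opening(img, se)
}

#' Black top-hat transform
#'
#' `closing(img, se) - img`: extracts dark structures smaller than the
#' structuring element -- in an angiogram, the contrast-filled vessels.
#'
#' @inheritParams white_tophat
#' @return Matrix of the same shape, values `>= 0`.
#' @export
black_tophat <- function(img, se = structuring_element("disk", 9L)) {
  check_se_fits(img, se)
  gray_closing(img, se) - img
}

#' Top-hat contrast enhancement
#'
#' Adds the white top-hat to the image and subtracts the black top-hat,
#' pixel by pixel, then clips to \[0, 1\]:
#' `clip(img + white_tophat(img) - black_tophat(img), 0, 1)`.
#' Bright detail is amplified and dark curvilinear structures (vessels) are
#' deepened, while flat regions are left untouched.
#'
#' @inheritParams white_tophat
#' @return Enhanced gray image matrix in \[0, 1\], same shape as `img`.
#' @examples
#' img <- matrix(0.5, 32, 32); img[16, 8:24] <- 0.3 # a dark "vessel"
#' enh <- tophat_enhance(img, structuring_element("disk", 3))
#' enh[16, 16] < img[16, 16]
#' @export
tophat_enhance <- function(img, se = structuring_element("disk", 9L)) {
  check_se_fits(img, se)
  clip01(img + white_tophat(img, se) - black_tophat(img, se))
}

#' Scale a structuring-element radius to the image size
#'
#' The default top-hat radius (9 px) is defined at the native 300x300
#' angiogram scale; for other sizes it is scaled proportionally to the
#' shorter image side, with a floor of 1.
#'
#' @param img Gray image matrix.
#' @param base_radius Radius at 300x300 scale.
#' @return Integer radius for this image.
#' @export
scaled_se_radius <- function(img, base_radius = 9L) {
  max(1L, as.integer(round(base_radius * min(dim(img)) / 300)))
}
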