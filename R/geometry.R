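#' Central crop
#'
#' Extracts the central `target` window of an image, e.g. 300x300 angiograms
#' to 288x288 (6-pixel margins) or 768x768 to 576x576.  Apply the same call
#' to a paired mask to keep the pair aligned.
#'
#' @param img Gray image or mask matrix.
#' @param target Integer vector `c(h, w)`.
#' @return The central `h x w` submatrix.
#' @export
center_crop <- function(img, target) {
  target <- as.integer(target)
  if (length(target) == 1L) target <- c(target, target)
  if (target[1] > nrow(img) || target[2] > ncol(img)) {
    stop("crop target (", target[1], "x", target[2],
         ") exceeds image size (", nrow(img), "x", ncol(img), ")")
  }
  r0 <- (nrow(img) - target[1]) %/% 2L
  c0 <- (ncol(img) - target[2]) %/% 2L
  img[r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE]
}

#' Resize a gray image or mask
#'
#' Bilinear interpolation for intensity images, nearest-neighbour for masks
#' (so mask outputs stay strictly binary).  Uses the half-pixel-centre
#' coordinate convention; source coordinates are clamped to the image.
#'
#' @param img Matrix to resize.
#' @param target Integer vector `c(h, w)`, both `>= 1`.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return The resized `h x w` matrix.
#' @export
resize_image <- function(img, target, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  target <- as.integer(target)
  if (length(target) == 1L) target <- c(target, target)
  ho <- target[1]; wo <- target[2]
  if (ho < 1L || wo < 1L) stop("resize target must be positive")
  H <- nrow(img); W <- ncol(img)
  if (ho == H && wo == W) return(img)
  sy <- H / ho; sx <- W / wo
  yc <- (seq_len(ho) - 0.5) * sy + 0.5   # source row coordinate per output row
  xc <- (seq_len(wo) - 0.5) * sx + 0.5
  if (mode == "nearest") {
    ri <- pmin(pmax(floor(yc - 0.5) + 1L, 1L), H)
    ci <- pmin(pmax(floor(xc - 0.5) + 1L, 1L), W)
    return(img[ri, ci, drop = FALSE])
  }
  y0 <- pmin(pmax(floor(yc - 0.5) + 0.5, 0.5), H - 0.5)
  x0 <- pmin(pmax(floor(xc - 0.5) + 0.5, 0.5), W - 0.5)
  fy <- pmin(pmax(yc - y0, 0), 1)
  fx <- pmin(pmax(xc - x0, 0), 1)
  r0 <- pmin(pmax(y0 + 0.5, 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(x0 + 0.5, 1), W); c1 <- pmin(c0 + 1, W)
  A <- img[r0, c0, drop = FALSE]; B <- img[r0, c1, drop = FALSE]
  C <- img[r1, c0, drop = FALSE]; D <- img[r1, c1, drop = FALSE]
  wy <- matrix(fy, ho, wo); wx <- matrix(fx, ho, wo, byrow = TRUE)
  (1 - wy) * (1 - wx) * A + (1 - wy) * wx * B + wy * (1 - wx) * C + wy * wx * D
}

# Rotate about the image centre by `angle` degrees (inverse mapping with
# edge-replicate sampling).  mode "nearest" keeps masks binary.
rotate_image <- function(img, angle, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (angle == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  i <- matrix(seq_len(H), H, W) - cy
  j <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation of output coordinates into the source frame
  si <- cos(th) * i - sin(th) * j + cy
  sj <- sin(th) * i + cos(th) * j + cx
  if (mode == "nearest") {
    ri <- pmin(pmax(round(si), 1), H)
    ci <- pmin(pmax(round(sj), 1), W)
    return(matrix(img[cbind(as.vector(ri), as.vector(ci))], H, W))
  }
  r0 <- pmin(pmax(floor(si), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(sj), 1), W); c1 <- pmin(c0 + 1, W)
  fy <- pmin(pmax(si - r0, 0), 1); fx <- pmin(pmax(sj - c0, 0), 1)
  g <- function(r, cc) matrix(img[cbind(as.vector(r), as.vector(cc))], H, W)
  (1 - fy) * (1 - fx) * g(r0, c0) + (1 - fy) * fx * g(r0, c1) +
    fy * (1 - fx) * g(r1, c0) + fy * fx * g(r1, c1)
}

#' Random paired augmentation
#'
#' Draws one random geometric transform -- rotation, crop window, horizontal
#' and vertical flips -- and applies it identically to an image and its mask.
#' Both members are resampled with the same nearest-neighbour map, so the
#' mask stays strictly binary and every augmented label stays attached to
#' the exact pixel it describes (vessels are only a few pixels wide, so a
#' mismatched interpolation would mislabel every edge).  The crop is
#' resized back to the original frame size, and the whole draw is fully
#' determined by `seed`.
#'
#' @param sample List with elements `image` (gray matrix) and `mask`
#'   (binary matrix of the same shape).
#' @param seed Integer seed for the transform draw.
#' @param rotate_deg Maximum absolute rotation in degrees (default 15).
#' @param crop_min Minimum crop fraction of each side (default 0.9).
#' @return A list with transformed `image` and `mask`.
#' @export
augment_pair <- function(sample, seed, rotate_deg = 15, crop_min = 0.9) {
  stopifnot(identical(dim(sample$image), dim(sample$mask)))
  rs <- local_rng(seed)
  angle <- rs$unif(-rotate_deg, rotate_deg)
  frac <- rs$unif(crop_min, 1)
  H <- nrow(sample$image); W <- ncol(sample$image)
  ch <- max(8L, round(H * frac)); cw <- max(8L, round(W * frac))
  r0 <- if (H > ch) rs$int(H - ch + 1L) - 1L else 0L
  c0 <- if (W > cw) rs$int(W - cw + 1L) - 1L else 0L
  hflip <- rs$unif(0, 1) < 0.5
  vflip <- rs$unif(0, 1) < 0.5
  apply_pair_transform(sample, angle, c(r0, c0, ch, cw), hflip, vflip)
}

# Deterministic core of augment_pair: rotation, crop rectangle
# (row0, col0, h, w; 0-based offsets), flips; resizes back to the original
# frame so batch shapes stay constant.  Both members are sampled with the
# same nearest-neighbour map: at the 1-3 px width of vessels, interpolating
# the image differently from its label would systematically mislabel every
# edge pixel, so image and mask must come from identical source pixels.
apply_pair_transform <- function(sample, angle, crop, hflip, vflip) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  tf <- function(x) {
    y <- rotate_image(x, angle, "nearest")
    y <- y[crop[1] + seq_len(crop[3]), crop[2] + seq_len(crop[4]), drop = FALSE]
    y <- resize_image(y, c(H, W), "nearest")
    if (hflip) y <- y[, rev(seq_len(W)), drop = FALSE]
    if (vflip) y <- y[rev(seq_len(H)), , drop = FALSE]
    y
  }
  list(image = clip01(tf(sample$image)), mask = (tf(sample$mask) >= 0.5) * 1)
}

# A small self-contained RNG handle: runs draws under a private seed without
# touching the caller's global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(as.numeric(seed) %% 2147483647))
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  }
  draw <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    unif = function(lo, hi) draw(function() runif(1, lo, hi)),
    int = function(n) draw(function() sample.int(n, 1L)),
    norm = function(n, sd = 1) draw(function() rnorm(n, 0, sd)),
    perm = function(n) draw(function() sample.int(n)),
    runifn = function(n, lo = 0, hi = 1) draw(function() runif(n, lo, hi))
  )
}
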