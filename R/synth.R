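# Seeded generator of synthetic angiogram/mask fixtures: a connected,
# branching, tapering vessel tree on a noisy, unevenly illuminated
# background.  Emulates the statistics that make real angiograms hard --
# thin dark curvilinear structures covering a few percent of the frame,
# nonuniform illumination, low contrast, noise -- without modelling X-ray
# physics or anatomy.

#' Parameters of the vessel phantom generator
#'
#' @param image_size `c(h, w)` frame size; default 96x96 (divisible by 16)
#'   for fast CPU experiments, 288x288 for realism.
#' @param n_branches Children spawned per parent segment (1--3 typical).
#' @param width_range `c(min, max)` trunk half-width range in pixels.
#' @param vessel_contrast Intensity dip of vessel cores below background.
#' @param illumination_amplitude Amplitude of the smooth illumination field.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param target_vessel_fraction `c(lo, hi)` admissible vessel pixel
#'   fraction; masks outside it are regenerated (bounded retries).
#' @param seed Integer seed; with the parameters it fully determines output.
#' @return A named list.
#' @export
phantom_params <- function(image_size = c(96L, 96L), n_branches = 2L,
                           width_range = c(1.2, 2.6), vessel_contrast = 0.28,
                           illumination_amplitude = 0.12, noise_sd = 0.035,
                           target_vessel_fraction = c(0.03, 0.10), seed = 1L) {
  fr <- target_vessel_fraction
  if (!(fr[1] > 0 && fr[1] < fr[2] && fr[2] < 0.2)) {
    stop("target_vessel_fraction must satisfy 0 < lo < hi < 0.2")
  }
  if (width_range[1] < 0.5) stop("minimum width must be >= 0.5 px")
  list(image_size = as.integer(image_size), n_branches = as.integer(n_branches),
       width_range = width_range, vessel_contrast = vessel_contrast,
       illumination_amplitude = illumination_amplitude, noise_sd = noise_sd,
       target_vessel_fraction = fr, seed = as.integer(seed))
}

# One random-walk branch: stamps disks of shrinking radius along a smooth
# curved centerline; returns the updated mask and the sampled path.
walk_branch <- function(mask, start, dir, width, len, rs) {
  H <- nrow(mask); W <- ncol(mask)
  pos <- start
  path <- matrix(0, len, 3L)
  for (s in seq_len(len)) {
    dir <- dir + rs$unif(-0.25, 0.25)            # curvature jitter
    pos <- pos + c(cos(dir), sin(dir))
    if (pos[1] < 2 || pos[1] > H - 1 || pos[2] < 2 || pos[2] > W - 1) {
      path <- path[seq_len(s - 1L), , drop = FALSE]
      break
    }
    # taper toward the tip; the 0.75 floor keeps consecutive disk stamps
    # overlapping on the pixel grid (radius must exceed sqrt(2)/2)
    wcur <- max(0.75, width * (1 - 0.6 * s / len))
    r <- ceiling(wcur)
    ii <- max(1, floor(pos[1] - r)):min(H, ceiling(pos[1] + r))
    jj <- max(1, floor(pos[2] - r)):min(W, ceiling(pos[2] + r))
    d2 <- outer((ii - pos[1])^2, (jj - pos[2])^2, `+`)
    mask[ii, jj][d2 <= wcur^2] <- 1
    path[s, ] <- c(pos, wcur)
  }
  list(mask = mask, path = path)
}

#' Generate a branching vessel-tree mask
#'
#' A trunk enters from a random border point and performs a smooth random
#' walk across the frame; child branches split off at random points with
#' reduced width and length (recursively, two generations).  Children start
#' on the parent centerline, so the tree is one connected component.  Masks
#' whose vessel fraction falls outside `target_vessel_fraction` are
#' regenerated, up to 25 attempts.
#'
#' @param params See [phantom_params()].
#' @return Binary `h x w` matrix with attribute `vessel_fraction`.
#' @export
generate_tree_mask <- function(params = phantom_params()) {
  H <- params$image_size[1]; W <- params$image_size[2]
  fr <- params$target_vessel_fraction
  for (attempt in seq_len(25L)) {
    rs <- local_rng(as.numeric(params$seed) * 1000 + attempt)
    mask <- matrix(0, H, W)
    side <- rs$int(4L)
    start <- switch(side,
      c(2, rs$unif(0.2, 0.8) * W),
      c(H - 1, rs$unif(0.2, 0.8) * W),
      c(rs$unif(0.2, 0.8) * H, 2),
      c(rs$unif(0.2, 0.8) * H, W - 1))
    dir <- switch(side, 0, pi, pi / 2, -pi / 2) + rs$unif(-0.4, 0.4)
    width <- rs$unif(params$width_range[1], params$width_range[2])
    len <- round(1.25 * min(H, W))
    trunk <- walk_branch(mask, start, dir, width, len, rs)
    mask <- trunk$mask
    queue <- list(list(path = trunk$path, width = width, len = len, depth = 0L))
    while (length(queue)) {
      parent <- queue[[1]]; queue <- queue[-1]
      if (parent$depth >= 2L || nrow(parent$path) < 10L) next
      for (k in seq_len(params$n_branches)) {
        at <- parent$path[rs$int(nrow(parent$path)), ]
        cw <- max(0.75, parent$width * rs$unif(0.55, 0.75))
        cl <- round(parent$len * rs$unif(0.35, 0.6))
        sgn <- if (rs$unif(0, 1) < 0.5) 1 else -1
        cd <- atan2(parent$path[min(nrow(parent$path), 5L), 1] - parent$path[1, 1],
                    parent$path[min(nrow(parent$path), 5L), 2] - parent$path[1, 2])
        cd <- cd + sgn * rs$unif(0.35, 0.9)
        child <- walk_branch(mask, at[1:2], cd, cw, cl, rs)
        mask <- child$mask
        queue[[length(queue) + 1L]] <- list(path = child$path, width = cw,
                                            len = cl, depth = parent$depth + 1L)
      }
    }
    frac <- mean(mask)
    if (frac >= fr[1] && frac <= fr[2]) {
      attr(mask, "vessel_fraction") <- frac
      return(mask)
    }
  }
  stop("could not generate a mask with vessel fraction in (",
       fr[1], ", ", fr[2], ") after 25 attempts")
}

# 3x3 box blur with edge replication (used for soft vessel edges and for
# smoothing the illumination grid).
box_blur <- function(x, passes = 1L) {
  H <- nrow(x); W <- ncol(x)
  for (p in seq_len(passes)) {
    up <- x[c(1, seq_len(H - 1)), , drop = FALSE]
    dn <- x[c(seq_len(H - 1) + 1, H), , drop = FALSE]
    x <- (up + x + dn) / 3
    lf <- x[, c(1, seq_len(W - 1)), drop = FALSE]
    rt <- x[, c(seq_len(W - 1) + 1, W), drop = FALSE]
    x <- (lf + x + rt) / 3
  }
  x
}

#' Render a synthetic angiogram from a vessel mask
#'
#' Background = mid-gray plus a smooth low-frequency illumination field
#' (a coarse random grid, bilinearly upsampled) plus Gaussian noise.  Only
#' vessel pixels are darkened, by `vessel_contrast` modulated with a
#' distance-to-edge proxy (a box-blurred mask restricted to the mask), so
#' cores are darker and edge pixels softer while the dip stays exactly
#' inside the labelled region; the result is clipped to \[0, 1\].
#'
#' @param mask Binary vessel mask from [generate_tree_mask()].
#' @param params See [phantom_params()].
#' @return Gray image matrix in \[0, 1\].
#' @export
render_angiogram <- function(mask, params = phantom_params()) {
  H <- nrow(mask); W <- ncol(mask)
  mask <- matrix(as.vector(mask), H, W)  # drop generator bookkeeping attributes
  rs <- local_rng(as.numeric(params$seed) * 1000 + 500)
  illum <- 0
  if (params$illumination_amplitude > 0) {
    grid <- matrix(rs$runifn(16L, -1, 1), 4L, 4L) * params$illumination_amplitude
    illum <- resize_image(grid, c(H, W), "bilinear")
  }
  depth <- box_blur(mask, passes = 2L) * mask      # ~ distance to edge, 0 outside
  dip <- params$vessel_contrast * mask * (0.4 + 0.6 * depth)
  img <- 0.55 + illum - dip
  if (params$noise_sd > 0) {
    img <- img + matrix(rs$norm(H * W, params$noise_sd), H, W)
  }
  clip01(img)
}

#' Generate and write a synthetic dataset
#'
#' Writes `n` image/mask PNG pairs (`img_###.png`, `mask_###.png`) plus a
#' JSON manifest recording the per-image seeds, parameters and vessel
#' fractions.  Images reload through [load_image()] losslessly within 8-bit
#' quantization; masks reload exactly.
#'
#' @param n Number of pairs.
#' @param params See [phantom_params()]; per-image seed is
#'   `params$seed + i`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(n, params = phantom_params(), out_dir) {
  if (n < 1) stop("n must be >= 1")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- params
    pi$seed <- params$seed + i
    mask <- generate_tree_mask(pi)
    img <- render_angiogram(mask, pi)
    fi <- sprintf("img_%03d.png", i)
    fm <- sprintf("mask_%03d.png", i)
    save_image_png(img, file.path(out_dir, fi))
    save_image_png(mask, file.path(out_dir, fm))
    entries[[i]] <- list(image = fi, mask = fm, seed = pi$seed,
                         vessel_fraction = attr(mask, "vessel_fraction"))
  }
  manifest <- list(n = n, params = params[setdiff(names(params), "seed")],
                   base_seed = params$seed, samples = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load an image/mask dataset directory
#'
#' Reads every `img_*.png` / `mask_*.png` pair written by
#' [generate_dataset()] (or any directory laid out the same way).
#'
#' @param dir Dataset directory.
#' @return List of `list(image, mask)` pairs.
#' @export
load_dataset <- function(dir) {
  imgs <- sort(list.files(dir, "^img_.*\\.png$", full.names = TRUE))
  if (length(imgs) == 0L) stop("no img_*.png files found in ", dir)
  lapply(imgs, function(f) {
    mf <- file.path(dirname(f), sub("^img_", "mask_", basename(f)))
    if (!file.exists(mf)) stop("missing mask for ", f)
    list(image = load_image(f), mask = load_mask(mf))
  })
}
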