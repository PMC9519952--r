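#' Speckle reduction of a B-mode frame
#'
#' Speckle-reducing anisotropic diffusion (SRAD): an edge-preserving diffusion
#' whose conduction coefficient is driven by the local instantaneous
#' coefficient of variation, so fully developed speckle is smoothed while
#' tissue/void boundaries are preserved. A plain median-filter fallback is
#' available.
#'
#' @param img Numeric matrix, typically an 8-bit B-mode frame (0–255).
#' @param iterations Number of diffusion steps (default 30).
#' @param step Diffusion time step (default 0.7; the explicit scheme is
#'   stable for steps up to 1).
#' @param method `"srad"` or `"median"`.
#' @param q0 Speckle scale separating speckle from edges; default estimated
#'   as the coefficient of variation of the bright (above-median) pixels,
#'   i.e. of the speckle inside the sample.
#' @param rho Exponential decay rate of `q0` over diffusion time (default 0:
#'   constant speckle scale).
#' @param median_radius Window radius of the median fallback.
#' @return Numeric matrix of the same size (same intensity scale as input).
#' @export
speckle_reduce <- function(img, iterations = 30, step = 0.7,
                           method = c("srad", "median"), q0 = NULL, rho = 0,
                           median_radius = 2) {
  if (!is.matrix(img)) stop_input("`img` must be a matrix.")
  method <- match.arg(method)
  if (iterations < 0) stop_input("`iterations` must be >= 0.")
  if (iterations == 0) return(img)
  if (method == "median") {
    sc <- max(img)
    if (sc <= 0) return(img)
    out <- EBImage::medianFilter(EBImage::Image(img / sc), median_radius)
    return(EBImage::imageData(out) * sc)
  }
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  sc <- max(img)
  if (sc <= 0) return(img)
  x <- img / sc
  if (is.null(q0)) {
    pos <- x[x > 0]
    bright <- pos[pos > stats::median(pos)]
    q0 <- if (length(bright) > 1) sd(bright) / mean(bright) else 0.5
    q0 <- min(max(q0, 0.02), 1)
  }
  srad_cpp(x, as.integer(iterations), step, q0, rho) * sc
}

decompress_bmode <- function(frame, dynamic_range) {
  # invert the log compression back to relative envelope amplitude so that
  # thresholds sit on the physically meaningful half-amplitude contour
  # rather than on the dark-stretched log scale
  10^(dynamic_range * (pmin(pmax(frame, 0), 255) / 255 - 1) / 20)
}

#' Segment the total sample region of a B-mode frame
#'
#' Global Otsu threshold, retention of the largest connected foreground
#' component (one construct per scan), and flood filling of interior holes so
#' that voids count as part of the total sample. The threshold is computed on
#' the relative envelope amplitude (the 8-bit frame decompressed through its
#' dynamic range): on the linear scale the boundary of a blurred object falls
#' near the half-amplitude contour, which is where the true edge lies, while
#' on the log scale it would be displaced outward into the stretched dark
#' tail.
#'
#' @param frame Numeric matrix; 8-bit log-compressed B-mode scale (0–255),
#'   normally after [speckle_reduce()].
#' @param dynamic_range Dynamic range (dB) used in the log compression.
#' @param close_radius Radius (px) of the morphological closing applied to
#'   the thresholded foreground before hole filling; bridges speckle notches
#'   in thin tissue bands so that interior voids remain enclosed holes.
#' @return Logical matrix. If no foreground is found a warning (class
#'   `tissueqc_empty_mask`) is signalled and an all-`FALSE` mask returned.
#' @export
segment_total <- function(frame, dynamic_range = 60, close_radius = 4) {
  if (!is.matrix(frame)) stop_input("`frame` must be a matrix.")
  if (max(frame) <= 0) {
    warn("Frame has no foreground; returning an empty mask.",
         class = "tissueqc_empty_mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  x <- decompress_bmode(frame, dynamic_range)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  fg <- x > th
  if (close_radius > 0 && any(fg)) {
    br <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    fg <- EBImage::imageData(EBImage::closing(EBImage::Image(fg * 1), br)) > 0
  }
  if (!any(fg)) {
    warn("Otsu threshold leaves no foreground; returning an empty mask.",
         class = "tissueqc_empty_mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labd <- EBImage::imageData(lab)
  sizes <- tabulate(labd[labd > 0])
  keep <- which.max(sizes)
  mask <- labd == keep
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  # a construct cross-section is star-convex along depth: close each axial
  # column between its first and last tissue pixel, so an interior void stays
  # enclosed even where a speckle notch breaches its thin tissue band
  for (j in which(colSums(filled) > 0)) {
    rr <- range(which(filled[, j]))
    filled[rr[1]:rr[2], j] <- TRUE
  }
  filled
}

gaussian_local_mean <- function(x, window, weights = NULL) {
  brush <- EBImage::makeBrush(window, shape = "gaussian", sigma = window / 6)
  brush <- brush / sum(brush)
  f2 <- function(m) {
    EBImage::imageData(
      EBImage::filter2(EBImage::Image(m), brush, boundary = "replicate")
    )
  }
  if (is.null(weights)) return(f2(x))
  num <- f2(x * weights)
  den <- f2(weights * 1)
  # regularize toward the global weighted mean where no weight mass is local
  g <- sum(x * weights) / max(sum(weights), 1)
  eps <- 1e-3
  (num + eps * g) / (den + eps)
}

#' Segment void regions within the total sample mask
#'
#' Two-pass local adaptive threshold on the relative envelope amplitude.
#' Pass 1 marks provisional void pixels falling below `ratio` times the local
#' Gaussian-weighted mean. Pass 2 recomputes the local mean over
#' non-void tissue only (so large anechoic regions no longer drag their own
#' reference down) and rethresholds; on the linear amplitude scale
#' `ratio = 0.5` of the local *tissue* level is the half-amplitude contour,
#' i.e. the unbiased edge position of a blurred anechoic void. Detected
#' components are hole-filled, intersected with the total mask eroded by a
#' few pixels (the sample's own boundary layer sits at half amplitude by
#' construction and must not count as void), and filtered by minimum area.
#'
#' Optional contrast-limited adaptive histogram equalization (CLAHE) can be
#' applied first (`contrast = "clahe"`); it is off by default because
#' remapping amplitudes shifts the detected boundary away from the
#' half-amplitude contour.
#'
#' @param frame Numeric matrix on the 8-bit B-mode scale; normally the
#'   speckle-reduced frame.
#' @param total Logical matrix from [segment_total()] (same dimensions).
#' @param window Side of the local-mean window in pixels (odd; default 51,
#'   i.e. 255 µm at 5 µm/px).
#' @param ratio Multiplicative threshold on the local tissue mean
#'   (default 0.5).
#' @param offset Additive threshold offset on the linear amplitude scale
#'   (default 0); a pixel is marked if
#'   `amplitude < ratio * local_mean + offset`.
#' @param min_area Minimum void area in pixels (default 100, about
#'   0.0025 mm^2 at 5 µm/px).
#' @param dynamic_range Dynamic range (dB) of the log compression.
#' @param boundary_margin Erosion radius (px) applied to `total` when
#'   intersecting void candidates, excluding the sample's own edge layer.
#' @param contrast `"none"` (default) or `"clahe"`.
#' @param clahe_limit CLAHE contrast limit (EBImage parameterization).
#' @param clahe_tiles CLAHE tile grid (n x n).
#' @param fill_holes Fill interior holes of detected components.
#' @return Logical matrix marking void pixels (subset of `total`).
#' @export
segment_voids <- function(frame, total, window = 51, ratio = 0.5, offset = 0,
                          min_area = 100, dynamic_range = 60,
                          boundary_margin = 3,
                          contrast = c("none", "clahe"),
                          clahe_limit = 2, clahe_tiles = 8,
                          fill_holes = TRUE) {
  if (!is.matrix(frame)) stop_input("`frame` must be a matrix.")
  if (!is.logical(total) || !identical(dim(frame), dim(total))) {
    stop_input("`total` must be a logical matrix with the dimensions of `frame`.")
  }
  contrast <- match.arg(contrast)
  if (!any(total)) return(total)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop_input("`window` must be an odd integer >= 3.")
  }
  x <- decompress_bmode(frame, dynamic_range)
  if (contrast == "clahe") {
    # CLAHE needs dimensions divisible by the tile grid: pad by replication
    pad_r <- (clahe_tiles - nrow(x) %% clahe_tiles) %% clahe_tiles
    pad_c <- (clahe_tiles - ncol(x) %% clahe_tiles) %% clahe_tiles
    xp <- rbind(x, x[rep(nrow(x), pad_r), , drop = FALSE])
    xp <- cbind(xp, xp[, rep(ncol(xp), pad_c), drop = FALSE])
    xp <- EBImage::clahe(EBImage::Image(xp), nx = clahe_tiles,
                         ny = clahe_tiles, limit = clahe_limit)
    x <- EBImage::imageData(xp)[seq_len(nrow(x)), seq_len(ncol(x))]
  }
  interior <- if (boundary_margin > 0) {
    EBImage::imageData(EBImage::erode(
      EBImage::Image(total * 1),
      EBImage::makeBrush(2 * boundary_margin + 1, shape = "disc")
    )) > 0
  } else {
    total
  }
  fill <- function(m) {
    if (!any(m)) return(m)
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    EBImage::imageData(EBImage::fillHull(lab)) > 0
  }
  # pass 1: provisional voids against the plain local mean; inside a wide
  # void only the rim is marked (the local mean there is the void level), so
  # fill detected components before building the tissue reference
  lm1 <- gaussian_local_mean(x, window)
  cand <- fill(x < ratio * lm1 + offset & total)
  # pass 2: reference the local mean of non-void tissue only, placing the
  # detected boundary at the half-amplitude contour of the local tissue;
  # a dilated shell around the provisional voids is excluded too, since the
  # partial-volume mix zone at a void edge is neither void nor clean tissue
  if (any(cand)) {
    shell <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(cand * 1), EBImage::makeBrush(15, shape = "disc")
    )) > 0
  } else {
    shell <- cand
  }
  tissue <- total & !shell
  if (any(tissue)) {
    lm2 <- gaussian_local_mean(x, window, weights = tissue)
    cand <- x < ratio * lm2 + offset & total
  }
  cand <- cand & interior
  if (fill_holes) cand <- fill(cand) & interior
  if (!any(cand)) return(cand)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  cand & matrix(lab %in% keep, nrow(lab), ncol(lab))
}

signed_distance <- function(mask) {
  m <- EBImage::Image(mask * 1)
  inside <- EBImage::imageData(EBImage::distmap(m))
  outside <- EBImage::imageData(EBImage::distmap(1 - m))
  inside - outside
}

#' Shape-based interpolation of binary mask frames
#'
#' Inserts `factor - 1` intermediate slices between each pair of consecutive
#' mask frames by linear interpolation of their signed Euclidean distance
#' transforms, thresholded at zero. Original frames are reproduced exactly at
#' their positions; `n` input frames become `(n - 1) * factor + 1` slices.
#'
#' @param masks Logical array `[nr, nc, n_frames]` or list of logical
#'   matrices.
#' @param factor Integer interpolation factor (>= 1; default 20).
#' @return Logical array `[nr, nc, (n_frames - 1) * factor + 1]`.
#' @export
interpolate_masks <- function(masks, factor = 20) {
  if (is.list(masks)) masks <- simplify2array(masks)
  if (is.matrix(masks)) masks <- array(masks, c(dim(masks), 1L))
  if (!is.array(masks) || length(dim(masks)) != 3L) {
    stop_input("`masks` must be a logical array [nr, nc, n_frames].")
  }
  factor <- as.integer(factor)
  if (factor < 1L) stop_input("`factor` must be a positive integer.")
  n <- dim(masks)[3]
  if (factor == 1L) return(masks > 0)
  if (n < 2L) stop_input("Need at least 2 frames to interpolate.")
  nr <- dim(masks)[1]; nc <- dim(masks)[2]
  out <- array(FALSE, c(nr, nc, (n - 1L) * factor + 1L))
  sdists <- lapply(seq_len(n), function(f) {
    m <- masks[, , f] > 0
    if (any(m)) signed_distance(m) else NULL # NULL marks an empty frame
  })
  for (f in seq_len(n - 1L)) {
    sd_a <- sdists[[f]]
    sd_b <- sdists[[f + 1]]
    # a shape next to an empty frame tapers out linearly: the empty side is
    # a constant level set at minus the shape's largest inside distance, so
    # the shape shrinks to nothing halfway through the gap (a cone-like cap)
    if (is.null(sd_a) && !is.null(sd_b)) {
      sd_a <- matrix(-max(sd_b), nr, nc)
    } else if (!is.null(sd_a) && is.null(sd_b)) {
      sd_b <- matrix(-max(sd_a), nr, nc)
    }
    out[, , (f - 1L) * factor + 1L] <- masks[, , f] > 0
    if (!is.null(sd_a)) {
      for (j in seq_len(factor - 1L)) {
        w <- j / factor
        out[, , (f - 1L) * factor + 1L + j] <- ((1 - w) * sd_a + w * sd_b) > 0
      }
    }
  }
  out[, , (n - 1L) * factor + 1L] <- masks[, , n] > 0
  out
}

#' Construct a mask volume
#'
#' @param voxels Logical 3-D array.
#' @param voxel_size Length-3 numeric, µm per voxel along each axis.
#' @param kind `"total"` or `"void"`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, voxel_size, kind = c("total", "void")) {
  kind <- match.arg(kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_input("`voxels` must be a 3-D array.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop_input("`voxel_size` must be a positive length-3 vector (um).")
  }
  structure(list(voxels = voxels > 0, voxel_size = voxel_size, kind = kind),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<mask_volume> %s: %d x %d x %d voxels @ %g x %g x %g um | %d set\n",
    x$kind, d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
    x$voxel_size[3], sum(x$voxels)
  ))
  invisible(x)
}

#' Percent void volume from total and void mask volumes
#'
#' Volumes are voxel counts times the voxel volume; the void mask is
#' intersected with the total mask so that void is always a subset of total.
#'
#' @param total,void `mask_volume` objects with matching dimensions and voxel
#'   size.
#' @return A one-row tibble: `total_mm3`, `void_mm3`, `void_percent`.
#' @export
void_volume_percent <- function(total, void) {
  stopifnot(inherits(total, "mask_volume"), inherits(void, "mask_volume"))
  if (!identical(dim(total$voxels), dim(void$voxels)) ||
      !isTRUE(all.equal(total$voxel_size, void$voxel_size))) {
    stop_input("`total` and `void` must share dimensions and voxel size.")
  }
  vox_mm3 <- prod(total$voxel_size) * 1e-9 # µm³ -> mm³
  n_total <- sum(total$voxels)
  if (n_total == 0L) {
    abort("Total mask is empty; void percentage is undefined.",
          class = "tissueqc_undefined_result")
  }
  n_void <- sum(void$voxels & total$voxels)
  tibble(
    total_mm3 = n_total * vox_mm3,
    void_mm3 = n_void * vox_mm3,
    void_percent = 100 * n_void / n_total
  )
}

#' End-to-end void volumetry of a B-mode volume
#'
#' Runs the full segmentation chain on every frame (speckle reduction, total
#' segmentation, void segmentation), interpolates both mask stacks across
#' frames (factor 20 by default), and reports voxel-counted volumes. The voxel
#' volume uses the post-interpolation spacing
#' (in-plane pitch x frame_spacing / factor).
#'
#' @param volume A `bmode_volume` from [reconstruct_volume()].
#' @param factor Mask interpolation factor.
#' @param iterations,step Speckle-reduction settings, see [speckle_reduce()].
#' @param window,ratio,min_area Void-threshold settings, see
#'   [segment_voids()].
#' @param ... Further arguments passed to [segment_voids()].
#' @return A one-row tibble as from [void_volume_percent()], with the mask
#'   volumes attached as attribute `"masks"`.
#' @export
void_volumetry <- function(volume, factor = 20, iterations = 30, step = 0.7,
                           window = 51, ratio = 0.5, min_area = 100, ...) {
  stopifnot(inherits(volume, "bmode_volume"))
  nf <- dim(volume$frames)[3]
  totals <- vector("list", nf)
  voids <- vector("list", nf)
  for (f in seq_len(nf)) {
    sm <- speckle_reduce(volume$frames[, , f], iterations = iterations,
                         step = step)
    totals[[f]] <- segment_total(sm, dynamic_range = volume$dynamic_range)
    voids[[f]] <- segment_voids(sm, totals[[f]], window = window,
                                ratio = ratio, min_area = min_area,
                                dynamic_range = volume$dynamic_range, ...)
  }
  tvol <- interpolate_masks(simplify2array(totals), factor)
  vvol <- interpolate_masks(simplify2array(voids), factor)
  vs <- c(volume$voxel_size[1:2], volume$voxel_size[3] / factor)
  total <- mask_volume(tvol, vs, "total")
  void <- mask_volume(vvol & tvol, vs, "void")
  res <- void_volume_percent(total, void)
  attr(res, "masks") <- list(total = total, void = void)
  res
}
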