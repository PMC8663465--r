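# HOG and uniform-LBP texture descriptors over eye and mouth regions of the
# normalized face. Facial rigidity flattens fine expression-related texture
# (wrinkles, folds), so gradient-orientation and micro-pattern statistics of
# these regions separate the groups even when single landmarks do not.

#' Region-of-interest specification
#'
#' A ROI is the bounding box of a landmark subset, expanded by a fractional
#' margin on every side, clipped to the canonical frame, and resampled to a
#' fixed size.
#'
#' @param region region label (`"mouth"` or `"eyes"`).
#' @param landmark_indices 0-based iBUG indices defining the box.
#' @param margin fractional expansion per side (of box width/height).
#' @param target_size `c(width, height)` of the resampled patch in pixels.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(region, landmark_indices, margin, target_size) {
  if (margin < 0) fs_error("fs_config_error", "margin must be >= 0")
  structure(
    list(region = region, landmark_indices = as.integer(landmark_indices),
         margin = margin, target_size = as.integer(target_size)),
    class = "roi_spec"
  )
}

#' @rdname roi_spec
#' @export
roi_mouth <- function() roi_spec("mouth", 48:67, 0.2, c(64, 32))

#' @rdname roi_spec
#' @export
roi_eyes <- function() roi_spec("eyes", 36:47, 0.25, c(128, 32))

#' Extract and resample a region of interest
#'
#' @param face a `normalized_face` with an image.
#' @param spec a [roi_spec()].
#' @return A `target_size[2]` x `target_size[1]` intensity matrix.
#' @export
extract_roi <- function(face, spec) {
  if (is.null(face$image)) {
    fs_error("fs_config_error", "normalized face has no image to extract from")
  }
  lms <- face$landmarks[spec$landmark_indices + 1L, , drop = FALSE]
  x0 <- min(lms[, 1]); x1 <- max(lms[, 1])
  y0 <- min(lms[, 2]); y1 <- max(lms[, 2])
  bw <- x1 - x0; bh <- y1 - y0
  if (bw <= 0 || bh <= 0) {
    fs_error("fs_degenerate_geometry", "empty ROI box")
  }
  x0 <- max(0, x0 - spec$margin * bw)
  x1 <- min(ncol(face$image) - 1, x1 + spec$margin * bw)
  y0 <- max(0, y0 - spec$margin * bh)
  y1 <- min(nrow(face$image) - 1, y1 + spec$margin * bh)
  wo <- spec$target_size[1]
  ho <- spec$target_size[2]
  # map output pixel centers onto the box (area convention)
  sx <- x0 + ((seq_len(wo) - 0.5) / wo) * (x1 - x0)
  sy <- y0 + ((seq_len(ho) - 0.5) / ho) * (y1 - y0)
  gx <- rep(sx, each = ho)
  gy <- rep(sy, times = wo)
  matrix(bilinear_sample(face$image, gx, gy), nrow = ho, ncol = wo)
}

#' HOG parameters
#'
#' @param cell cell side in pixels.
#' @param block block side in cells (blocks slide by one cell).
#' @param bins number of unsigned orientation bins over \[0, 180).
#' @param clip L2-Hys clipping value.
#' @return A list of class `hog_params`.
#' @export
hog_params <- function(cell = 8, block = 2, bins = 9, clip = 0.2) {
  if (bins < 2 || block < 1 || cell < 1) {
    fs_error("fs_config_error", "invalid HOG parameters")
  }
  structure(list(cell = as.integer(cell), block = as.integer(block),
                 bins = as.integer(bins), clip = clip),
            class = "hog_params")
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Centered finite-difference gradients (one-sided at the borders);
#' orientation folded to \[0, 180) and voted with magnitude weighting,
#' linearly interpolated between the two nearest bin centers (centers at
#' `i * 180/bins` degrees, wrapping at 180); per-cell histograms grouped
#' into `block` x `block` cell blocks sliding by one cell; each block
#' L2-Hys-normalized (L2, clip, re-L2). Blocks are emitted row-major
#' (block row outer, block column inner; within a block, cells row-major,
#' bins fastest). Invariant to global additive intensity shifts.
#'
#' @param patch an intensity matrix whose dimensions are divisible by
#'   `params$cell`.
#' @param params a [hog_params()].
#' @return Numeric descriptor of length
#'   `n_blocks_x * n_blocks_y * block^2 * bins`.
#' @export
hog_descriptor <- function(patch, params = hog_params()) {
  h <- nrow(patch)
  w <- ncol(patch)
  cs <- params$cell
  if (h %% cs != 0 || w %% cs != 0) {
    fs_error("fs_config_error", sprintf(
      "patch %dx%d not divisible by cell size %d", w, h, cs
    ))
  }
  ncx <- w %/% cs
  ncy <- h %/% cs
  bins <- params$bins

  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (patch[, 3:w] - patch[, 1:(w - 2)]) / 2
  gx[, 1] <- patch[, 2] - patch[, 1]
  gx[, w] <- patch[, w] - patch[, w - 1]
  if (h >= 3) gy[2:(h - 1), ] <- (patch[3:h, ] - patch[1:(h - 2), ]) / 2
  gy[1, ] <- patch[2, ] - patch[1, ]
  gy[h, ] <- patch[h, ] - patch[h - 1, ]

  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180

  beta <- 180 / bins
  pos <- ang / beta
  i0 <- floor(pos)
  w1 <- pos - i0
  bin0 <- as.integer(i0) %% bins
  bin1 <- (bin0 + 1L) %% bins

  row_i <- matrix(rep(seq_len(h), times = w), h, w)
  col_i <- matrix(rep(seq_len(w), each = h), h, w)
  cellx <- (col_i - 1L) %/% cs
  celly <- (row_i - 1L) %/% cs
  base <- (celly * ncx + cellx) * bins
  acc <- numeric(ncx * ncy * bins)
  idx <- c(base + bin0 + 1L, base + bin1 + 1L)
  wts <- c(mag * (1 - w1), mag * w1)
  tb <- rowsum(wts, idx)
  acc[as.integer(rownames(tb))] <- tb
  # acc layout: cells row-major (celly outer, cellx inner), bins fastest
  cell_hist <- function(cy, cx) acc[((cy * ncx + cx) * bins + 1):((cy * ncx + cx) * bins + bins)]

  bs <- params$block
  eps <- 1e-10
  out <- list()
  k <- 1L
  for (by in 0:(ncy - bs)) {
    for (bx in 0:(ncx - bs)) {
      v <- unlist(lapply(0:(bs - 1), function(dy) {
        unlist(lapply(0:(bs - 1), function(dx) cell_hist(by + dy, bx + dx)))
      }))
      v <- v / sqrt(sum(v^2) + eps^2)
      v <- pmin(v, params$clip)
      v <- v / sqrt(sum(v^2) + eps^2)
      out[[k]] <- v
      k <- k + 1L
    }
  }
  unlist(out, use.names = FALSE)
}

#' LBP parameters
#'
#' @param neighbors number of circular neighbors P.
#' @param radius circle radius R in pixels.
#' @param cell_grid `c(rows, cols)` histogram grid over the patch.
#' @return A list of class `lbp_params`.
#' @export
lbp_params <- function(neighbors = 8, radius = 1, cell_grid = c(4, 8)) {
  if (neighbors < 4 || radius < 1) {
    fs_error("fs_config_error", "need neighbors >= 4 and radius >= 1")
  }
  structure(list(neighbors = as.integer(neighbors), radius = radius,
                 cell_grid = as.integer(cell_grid)),
            class = "lbp_params")
}

# Uniform-pattern code map for P neighbors: codes with <= 2 circular 0/1
# transitions get indices 1..P(P-1)+2 in ascending code order; all others
# share the final bin P(P-1)+3.
lbp_uniform_table <- function(P) {
  codes <- 0:(2^P - 1)
  bits <- t(vapply(codes, function(cd) as.integer(intToBits(cd)[1:P]), integer(P)))
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  uniform <- trans <= 2
  map <- integer(2^P)
  map[uniform] <- seq_len(sum(uniform))
  map[!uniform] <- sum(uniform) + 1L
  map
}

#' Uniform local-binary-pattern histogram descriptor
#'
#' For every pixel with a complete circular neighborhood (a border margin of
#' `ceiling(radius)` pixels is skipped), the P neighbors at angles
#' `2*pi*k/P` counterclockwise from the positive x axis (offset
#' `(R cos, -R sin)`, bilinearly sampled) are compared to the center;
#' `neighbor >= center` sets bit k (ties set the bit). Codes are mapped to
#' the `P*(P-1) + 3` uniform bins (59 for P = 8) and histogrammed over the
#' `cell_grid`, each cell histogram L1-normalized and the cells
#' concatenated row-major. Invariant to strictly increasing intensity
#' transforms of the patch.
#'
#' @param patch an intensity matrix larger than `2*radius + 1` in both
#'   dimensions.
#' @param params an [lbp_params()].
#' @return Numeric descriptor of length
#'   `prod(cell_grid) * (P*(P-1) + 3)`.
#' @export
lbp_descriptor <- function(patch, params = lbp_params()) {
  h <- nrow(patch)
  w <- ncol(patch)
  P <- params$neighbors
  R <- params$radius
  m <- ceiling(R)
  if (h <= 2 * R + 1 || w <= 2 * R + 1) {
    fs_error("fs_config_error", "patch too small for LBP radius")
  }
  rows <- (m + 1):(h - m)
  cols <- (m + 1):(w - m)
  cy <- rep(rows, times = length(cols)) - 1 # 0-based y
  cx <- rep(cols, each = length(rows)) - 1  # 0-based x
  center <- patch[cbind(cy + 1, cx + 1)]
  code <- integer(length(center))
  for (k in 0:(P - 1)) {
    ang <- 2 * pi * k / P
    nb <- bilinear_sample(patch, cx + R * cos(ang), cy - R * sin(ang))
    code <- code + bitwShiftL(as.integer(nb >= center), k)
  }
  map <- lbp_uniform_table(P)
  mapped <- map[code + 1L]

  gr <- params$cell_grid[1]
  gc <- params$cell_grid[2]
  cell_r <- pmin(floor(cy / (h / gr)), gr - 1)
  cell_c <- pmin(floor(cx / (w / gc)), gc - 1)
  cell_id <- cell_r * gc + cell_c # row-major 0-based
  nbin <- P * (P - 1) + 3L
  out <- numeric(gr * gc * nbin)
  idx <- cell_id * nbin + mapped
  tb <- rowsum(rep(1, length(idx)), idx)
  out[as.integer(rownames(tb))] <- tb
  for (cid in 0:(gr * gc - 1)) {
    sl <- (cid * nbin + 1):(cid * nbin + nbin)
    s <- sum(out[sl])
    if (s > 0) out[sl] <- out[sl] / s
  }
  out
}

#' Combined texture feature vector of a normalized face
#'
#' Concatenates, in this fixed order: HOG of the mouth ROI, HOG of the eyes
#' ROI, LBP of the mouth ROI, LBP of the eyes ROI. The `layout` field gives
#' the slice lengths so region or descriptor subsets can be taken (e.g. for
#' an eye-vs-mouth comparison).
#'
#' @param face a `normalized_face` with an image.
#' @param hog a [hog_params()].
#' @param lbp_mouth,lbp_eyes [lbp_params()] for the two ROIs (default cell
#'   grids 4 x 8 over 64 x 32 and 4 x 16 over 128 x 32, i.e. 8 px cells).
#' @param mouth_spec,eyes_spec [roi_spec()]s for the two regions.
#' @return A list of class `texture_features`: `vector` (named numeric) and
#'   `layout` (named slice lengths).
#' @export
texture_feature_vector <- function(face,
                                   hog = hog_params(),
                                   lbp_mouth = lbp_params(cell_grid = c(4, 8)),
                                   lbp_eyes = lbp_params(cell_grid = c(4, 16)),
                                   mouth_spec = roi_mouth(),
                                   eyes_spec = roi_eyes()) {
  pm <- extract_roi(face, mouth_spec)
  pe <- extract_roi(face, eyes_spec)
  parts <- list(
    hog_mouth = hog_descriptor(pm, hog),
    hog_eyes = hog_descriptor(pe, hog),
    lbp_mouth = lbp_descriptor(pm, lbp_mouth),
    lbp_eyes = lbp_descriptor(pe, lbp_eyes)
  )
  vec <- unlist(parts, use.names = FALSE)
  layout <- vapply(parts, length, integer(1))
  names(vec) <- unlist(lapply(names(parts), function(nm) {
    paste0(nm, "_", seq_len(layout[[nm]]))
  }))
  structure(list(vector = vec, layout = layout), class = "texture_features")
}

#' Slice a texture feature vector by layout component
#'
#' @param features a `texture_features` object.
#' @param components layout component names, e.g. `c("hog_eyes", "lbp_eyes")`.
#' @return The named numeric subvector.
#' @export
texture_subset <- function(features, components) {
  bad <- setdiff(components, names(features$layout))
  if (length(bad)) {
    fs_error("fs_layout_error", sprintf("unknown components: %s",
                                        paste(bad, collapse = ", ")))
  }
  ends <- cumsum(features$layout)
  starts <- ends - features$layout + 1
  idx <- unlist(lapply(components, function(nm) starts[[nm]]:ends[[nm]]))
  features$vector[idx]
}
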