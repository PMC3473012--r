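# Per-section nuclei detection from the nuclear-stain channel.
#
# Chain: adaptive (Wiener) denoising -> moving-average background subtraction
# -> threshold -> connected components -> splitting of over-sized (fused)
# objects by morphological reconstruction markers -> intensity-weighted
# centroids. Detection is strictly 2D per section; per-section counts are
# later converted to volume densities with Abercrombie's correction, so 3D
# linking of nuclei across sections would double-correct.

#' Detection parameters
#'
#' @param wiener_window_px Odd window (>= 3) of the adaptive noise filter.
#' @param background_window_px Moving-average background window; ideally
#'   about one nucleus diameter.
#' @param maxima_threshold Intensity threshold on the background-subtracted
#'   image; `NULL` (default) selects a per-section Otsu threshold.
#' @param split_area_factor Objects larger than this multiple of the median
#'   object area are candidates for fused-nucleus splitting.
#' @param min_object_area_px Components smaller than this are discarded as
#'   noise.
#' @return A `detection_params` list.
#' @export
detection_params <- function(wiener_window_px = 3, background_window_px = 10,
                             maxima_threshold = NULL, split_area_factor = 2,
                             min_object_area_px = 4) {
  assert_that(is_number(wiener_window_px) && wiener_window_px >= 3 &&
                wiener_window_px %% 2 == 1,
              "`wiener_window_px` must be an odd integer >= 3")
  assert_that(is_number(background_window_px) && background_window_px >= 2,
              "`background_window_px` must be >= 2")
  assert_that(is_number(split_area_factor) && split_area_factor > 1,
              "`split_area_factor` must be > 1")
  structure(list(wiener_window_px = as.integer(wiener_window_px),
                 background_window_px = as.integer(background_window_px),
                 maxima_threshold = maxima_threshold,
                 split_area_factor = split_area_factor,
                 min_object_area_px = as.integer(min_object_area_px)),
            class = "detection_params")
}

# Moving-average (box) filter supporting even windows, replicate padding.
boxmean <- function(img, wx, wy = wx) {
  ax <- floor((wx - 1) / 2); bx <- wx - 1 - ax
  ay <- floor((wy - 1) / 2); by <- wy - 1 - ay
  W <- nrow(img); H <- ncol(img)
  pad <- img[c(rep(1, ax), 1:W, rep(W, bx)), c(rep(1, ay), 1:H, rep(H, by)),
             drop = FALSE]
  cs <- apply(pad, 2, cumsum); cs <- rbind(0, cs)
  colsum <- cs[(wx + 1):(wx + W), , drop = FALSE] - cs[1:W, , drop = FALSE]
  cs2 <- t(apply(colsum, 1, cumsum)); cs2 <- cbind(0, cs2)
  (cs2[, (wy + 1):(wy + H), drop = FALSE] - cs2[, 1:H, drop = FALSE]) / (wx * wy)
}

# Adaptive Wiener denoising: local mean/variance over a w x w window; the
# filter's noise variance is the average of all locally estimated variances.
wiener_filter <- function(img, window_px = 3) {
  m <- boxmean(img, window_px)
  v <- pmax(boxmean(img^2, window_px) - m^2, 0)
  noise <- mean(v)
  gain <- pmax(v - noise, 0) / pmax(v, noise)
  gain[v == 0 & noise == 0] <- 0
  m + gain * (img - m)
}

# Otsu threshold on a 256-bin histogram; works on arbitrary-range (possibly
# negative) images such as the background-subtracted output.
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p); mu <- cumsum(p * mids); mu_t <- mu[n_bins]
  sb <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Denoise and background-correct one nuclear-stain section
#'
#' Applies the adaptive noise filter (noise variance set to the mean of the
#' locally estimated variances) and subtracts a moving-average background
#' image. The subtraction makes detection independent of smooth background
#' gradients; negative values are kept.
#'
#' @param img 2D numeric matrix (one section, nuclear channel).
#' @param params A [detection_params()].
#' @return Matrix of the same size, approximately zero-mean background.
#' @export
preprocess <- function(img, params = detection_params()) {
  assert_that(is.matrix(img) && is.numeric(img), "`img` must be a numeric matrix")
  if (min(dim(img)) < max(params$wiener_window_px, params$background_window_px))
    abort("image is smaller than the filter windows")
  f <- wiener_filter(img, params$wiener_window_px)
  f - boxmean(f, params$background_window_px)
}

#' Threshold a preprocessed section into candidate nucleus objects
#'
#' @param filtered Output of [preprocess()].
#' @param params A [detection_params()]; `maxima_threshold = NULL` uses the
#'   per-section Otsu threshold.
#' @return Integer label matrix (8-connected components, small ones removed);
#'   the threshold used is stored in `attr(, "threshold")`.
#' @export
segment <- function(filtered, params = detection_params()) {
  thr <- params$maxima_threshold %||% otsu_threshold(filtered)
  bw <- filtered > thr
  lab <- bwlabel8(bw)
  if (max(lab) > 0) {
    ar <- tabulate(lab[lab > 0], max(lab))
    drop <- which(ar < params$min_object_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_consecutive(lab)
  }
  attr(lab, "threshold") <- thr
  lab
}

# 8-connected component labelling: 4-connected pass, then union-find merge of
# components touching diagonally.
bwlabel8 <- function(bw) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw))))
  n <- max(lab)
  if (n < 2) return(lab)
  W <- nrow(lab); H <- ncol(lab)
  a1 <- lab[-W, -H]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -H]; b2 <- lab[-W, -1]    # up-right diagonal
  pairs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
                 cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, 1L)
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

# Grey-value morphology on small crops via shifted min/max stacking.
shift_mat <- function(m, dx, dy, fill) {
  W <- nrow(m); H <- ncol(m)
  out <- matrix(fill, W, H)
  xs <- max(1, 1 + dx):min(W, W + dx)
  ys <- max(1, 1 + dy):min(H, H + dy)
  out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

disc_offsets <- function(radius_px) {
  o <- expand.grid(dx = -radius_px:radius_px, dy = -radius_px:radius_px)
  o[o$dx^2 + o$dy^2 <= radius_px^2 + 1e-9, ]
}

grey_erode <- function(img, offsets) {
  out <- img
  for (i in seq_len(nrow(offsets)))
    out <- pmin(out, shift_mat(img, offsets$dx[i], offsets$dy[i], Inf))
  out
}

grey_dilate <- function(img, offsets) {
  out <- img
  for (i in seq_len(nrow(offsets)))
    out <- pmax(out, shift_mat(img, offsets$dx[i], offsets$dy[i], -Inf))
  out
}

# Grey-value opening-by-reconstruction restricted to a cropped window:
# erosion with a disc, then iterative geodesic dilation under the original.
open_by_reconstruction <- function(img, radius_px) {
  marker <- grey_erode(img, disc_offsets(radius_px))
  b3 <- expand.grid(dx = -1:1, dy = -1:1)
  repeat {
    nxt <- pmin(grey_dilate(marker, b3), img)
    if (max(abs(nxt - marker)) < 1e-9) break
    marker <- nxt
  }
  marker
}

#' Split fused nucleus objects
#'
#' Objects larger than `split_area_factor` times the median object area are
#' treated as possibly multiple nuclei. Markers are taken as the regional
#' maxima of the object's intensity after grey-value opening-by-reconstruction
#' (disc radius tied to the median nucleus size, so the operator is
#' self-calibrating), and the object's pixels are partitioned among markers by
#' seeded watershed-style propagation on the intensity image. Objects at or
#' below the area cut, and oversized objects with a single interior maximum,
#' pass through unchanged. The operation is idempotent: each emitted object is
#' at most nucleus-sized for its marker, so a second pass finds nothing to
#' re-split.
#'
#' @param lab Integer label matrix from [segment()].
#' @param filtered The preprocessed intensity image the labels came from.
#' @param params A [detection_params()].
#' @return Relabelled integer matrix; `attr(, "n_split")` counts the objects
#'   that were divided.
#' @export
split_fused <- function(lab, filtered, params = detection_params()) {
  n_obj <- max(lab)
  if (n_obj == 0) { attr(lab, "n_split") <- 0L; return(lab) }
  ar <- tabulate(lab[lab > 0], n_obj)
  med <- median(ar[ar > 0])
  big <- which(ar > params$split_area_factor * med)
  if (!length(big)) { attr(lab, "n_split") <- 0L; return(lab) }
  radius <- max(1L, ceiling(sqrt(med / pi) / 2))
  out <- lab
  next_id <- n_obj
  n_split <- 0L
  for (oid in big) {
    pix <- which(lab == oid, arr.ind = TRUE)
    x0 <- max(1L, min(pix[, 1]) - 2L); x1 <- min(nrow(lab), max(pix[, 1]) + 2L)
    y0 <- max(1L, min(pix[, 2]) - 2L); y1 <- min(ncol(lab), max(pix[, 2]) + 2L)
    sub <- filtered[x0:x1, y0:y1]
    inmask <- lab[x0:x1, y0:y1] == oid
    sub_m <- sub; sub_m[!inmask] <- min(sub)
    rec <- open_by_reconstruction(sub_m, radius)
    dil <- grey_dilate(rec, expand.grid(dx = -1:1, dy = -1:1))
    maxima <- (rec >= dil - 1e-9) & inmask
    seeds <- bwlabel8(maxima)
    n_mark <- max(seeds)
    if (n_mark < 2) next  # no interior structure: leave unsplit
    prop <- EBImage::propagate(EBImage::Image(sub_m), EBImage::Image(seeds),
                               mask = EBImage::Image(inmask))
    prop <- as.matrix(EBImage::imageData(prop))
    n_split <- n_split + 1L
    first <- TRUE
    for (m in sort(unique(prop[prop > 0]))) {
      sel <- prop == m
      id <- if (first) oid else { next_id <- next_id + 1L; next_id }
      first <- FALSE
      blk <- out[x0:x1, y0:y1]; blk[sel] <- id; out[x0:x1, y0:y1] <- blk
    }
  }
  out <- relabel_consecutive(out)
  attr(out, "n_split") <- n_split
  out
}

#' Reduce labelled objects to nucleus records
#'
#' One record per object with its intensity-weighted (sub-pixel) centroid,
#' pixel area, and the material id sampled from the mask at the centroid
#' pixel. Records whose centroid falls on background material (id 0) are kept
#' but flagged `excluded`, so they can be reported without entering counts.
#'
#' @param lab Label matrix (after [split_fused()]).
#' @param filtered Preprocessed intensity image (weights).
#' @param mask Integer material mask for this section (same size), or `NULL`.
#' @param section Section index stored on the records.
#' @param pixel_size_um Pixel size used to convert centroids to um.
#' @return A tibble of nucleus records: `id`, `section`, `x_um`, `y_um`,
#'   `x_px`, `y_px`, `area_px`, `material`, `excluded`.
#' @export
reduce_to_centroids <- function(lab, filtered, mask = NULL, section = 1L,
                                pixel_size_um = 1) {
  n_obj <- max(lab)
  if (n_obj == 0)
    return(tibble(id = integer(), section = integer(), x_um = numeric(),
                  y_um = numeric(), x_px = numeric(), y_px = numeric(),
                  area_px = integer(), material = integer(), excluded = logical()))
  sel <- lab > 0
  ids <- factor(lab[sel], levels = seq_len(n_obj))
  w <- pmax(filtered[sel], 1e-9)  # intensity weights, guarded non-negative
  rows <- row(lab)[sel]; cols <- col(lab)[sel]
  sw <- tapply(w, ids, sum)
  sx <- tapply(w * rows, ids, sum) / sw
  sy <- tapply(w * cols, ids, sum) / sw
  area <- tabulate(ids, n_obj)
  cx <- pmin(pmax(round(sx), 1), nrow(lab))
  cy <- pmin(pmax(round(sy), 1), ncol(lab))
  mat <- if (is.null(mask)) rep(1L, n_obj) else mask[cbind(cx, cy)]
  tibble(id = seq_len(n_obj), section = as.integer(section),
         x_um = (as.numeric(sx) - 0.5) * pixel_size_um,
         y_um = (as.numeric(sy) - 0.5) * pixel_size_um,
         x_px = as.numeric(sx), y_px = as.numeric(sy),
         area_px = area, material = as.integer(mat),
         excluded = as.integer(mat) == 0L)
}

#' Detect nuclei in every section of a stack
#'
#' Runs [preprocess()], [segment()], [split_fused()] and
#' [reduce_to_centroids()] per section and binds the records.
#'
#' @param stack A [section_stack()].
#' @param params A [detection_params()].
#' @return A tibble of nucleus records for the whole stack, with per-section
#'   record ids unique within the stack; `attr(, "label_stacks")` holds the
#'   per-section label matrices (needed by the classifier), and
#'   `attr(, "thresholds")` the per-section thresholds used.
#' @export
detect_nuclei <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "section_stack"))
  S <- dim(stack$nuclear)[3]
  labs <- vector("list", S); filt <- vector("list", S)
  thresholds <- numeric(S)
  recs <- vector("list", S)
  for (s in seq_len(S)) {
    f <- preprocess(stack$nuclear[, , s], params)
    lab <- segment(f, params)
    thresholds[s] <- attr(lab, "threshold")
    lab <- split_fused(lab, f, params)
    labs[[s]] <- lab; filt[[s]] <- f
    recs[[s]] <- reduce_to_centroids(lab, f, stack$mask[, , s], s,
                                     stack$pixel_size_um)
  }
  out <- dplyr::bind_rows(recs)
  out$record <- seq_len(nrow(out))
  attr(out, "label_stacks") <- labs
  attr(out, "filtered_stacks") <- filt
  attr(out, "thresholds") <- thresholds
  out
}

#' Control image of detected centroids
#'
#' Renders the nuclear section scaled to `[0, 1]` with detected centre pixels
#' (rounded centroids) marked as white crosses, for visual validation.
#'
#' @param stack A [section_stack()].
#' @param records Records from [detect_nuclei()].
#' @param section Section index.
#' @return A 2D matrix in `[0, 1]` suitable for [png::writePNG()].
#' @export
detection_control_image <- function(stack, records, section) {
  img <- stack$nuclear[, , section]
  img <- (img - min(img)) / max(diff(range(img)), 1)
  r <- records[records$section == section, ]
  for (i in seq_len(nrow(r))) {
    cx <- round(r$x_px[i]); cy <- round(r$y_px[i])
    xs <- pmin(pmax(cx + (-2:2), 1), nrow(img))
    ys <- pmin(pmax(cy + (-2:2), 1), ncol(img))
    img[xs, cy] <- 1; img[cx, ys] <- 1
  }
  img
}
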