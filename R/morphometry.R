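# Mask-based morphometry of lymphatic endothelial cells and sprouts.
# Masks are numeric/integer matrices, rows = y (increasing downward),
# columns = x. A mask whose maximum exceeds 1 is taken as already labeled;
# otherwise connected components are labeled 8-connected via EBImage.

.label_mask <- function(mask) {
  m <- as.matrix(mask)
  if (max(m) > 1) return(m)
  # 8-connected components via the pixel adjacency graph (EBImage::bwlabel
  # is 4-connected, which would split diagonal sprout necks)
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m > 0)
  if (!length(fg)) return(matrix(0L, nr, nc))
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[(c2[ok] - 1L) * nr + r2[ok]]
    has <- nb > 0L
    edges[[length(edges) + 1L]] <- cbind(id[fg[ok]][has], nb[has])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[fg] <- as.integer(memb)
  out
}

# Perimeter of one labeled object: boundary pixel centres traced with
# EBImage::ocontour, then a closed moving-average smoothing (window 5)
# before summing segment lengths. Raw chain-code length overestimates
# smooth outlines (stair-stepping); the smoothed polygon recovers both the
# circle (circularity -> 1.005 at r = 100 px) and the axis-aligned square
# (-> 0.80) to within the documented tolerances.
.perimeter <- function(obj_mask, k = 2L) {
  oc <- EBImage::ocontour(t(obj_mask))[[1]]
  n <- nrow(oc)
  if (n < 3L) return(max(n, 1) * 2)  # degenerate 1-2 px objects
  win <- 2L * k + 1L
  smooth_closed <- function(v) {
    as.numeric(stats::filter(c(utils::tail(v, k), v, utils::head(v, k)),
                             rep(1 / win, win)))[(k + 1L):(k + n)]
  }
  x <- smooth_closed(oc[, 1]); y <- smooth_closed(oc[, 2])
  dx <- c(diff(x), x[1] - x[n]); dy <- c(diff(y), y[1] - y[n])
  sum(sqrt(dx^2 + dy^2))
}

#' Per-object shape metrics from a binary or labeled mask
#'
#' For each connected component (8-connected): pixel-count area, smoothed
#' boundary-contour perimeter, circularity `4*pi*A/P^2` (clamped at 1 for
#' discretization overshoot), and aspect ratio plus orientation from the
#' second-central-moment equivalent ellipse. Orientation is measured in
#' degrees from the +x axis, counter-clockwise in standard (y-up)
#' coordinates, wrapped to `[-90, 90)` — cell orientation is axial.
#'
#' @param mask binary (0/1) or labeled integer matrix; rows = y, cols = x.
#' @param pixel_size um per pixel.
#' @param min_area minimum component area in px to report (noise filter).
#' @return data.frame with columns `label, area, perimeter, circularity,
#'   aspect_ratio, orientation, centroid_x, centroid_y, touches_border`
#'   (areas in um^2, perimeter/centroids in um). Empty mask: zero-row
#'   data.frame with a warning.
#' @export
shape_metrics <- function(mask, pixel_size = 1, min_area = 20L) {
  lab <- .label_mask(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  fg <- which(lab > 0)
  by_label <- split(fg, lab[fg])
  res <- list()
  for (lname in names(by_label)) {
    l <- as.numeric(lname)
    idx1 <- by_label[[lname]]
    npx <- length(idx1)
    if (npx < min_area) next
    ypix <- ((idx1 - 1L) %% nr) + 1L
    xpix <- ((idx1 - 1L) %/% nr) + 1L
    cx <- mean(xpix); cy <- mean(ypix)
    # central second moments with y flipped so angles are CCW-from-+x
    u <- xpix - cx; w <- -(ypix - cy)
    # +1/12: variance of the unit-square pixel footprint
    mu20 <- mean(u^2) + 1 / 12
    mu02 <- mean(w^2) + 1 / 12
    mu11 <- mean(u * w)
    common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    ar <- sqrt(l1 / max(l2, .Machine$double.eps))
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (theta >= 90) theta <- theta - 180
    if (theta < -90) theta <- theta + 180
    # crop to the bounding box (1-px pad) before contour tracing
    y0 <- min(ypix); x0 <- min(xpix)
    crop <- matrix(0, max(ypix) - y0 + 3L, max(xpix) - x0 + 3L)
    crop[cbind(ypix - y0 + 2L, xpix - x0 + 2L)] <- 1
    P <- .perimeter(crop) * pixel_size
    A <- npx * pixel_size^2
    circ <- min(4 * pi * A / P^2, 1)
    border <- min(xpix) == 1 || min(ypix) == 1 ||
      max(xpix) == nc || max(ypix) == nr
    res[[length(res) + 1L]] <- data.frame(
      label = l, area = A, perimeter = P, circularity = circ,
      aspect_ratio = ar, orientation = theta,
      centroid_x = cx * pixel_size, centroid_y = cy * pixel_size,
      touches_border = border)
  }
  if (!length(res)) {
    warning("mask contains no component above the minimum area")
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), circularity = numeric(),
                      aspect_ratio = numeric(), orientation = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      touches_border = logical()))
  }
  do.call(rbind, res)
}

#' Polar orientation histogram with circular statistics
#'
#' Bins orientations for a polar plot and computes the circular mean and
#' mean resultant length. Orientation data are axial (180-degree periodic):
#' in `"half-circle"` mode angles are doubled before the circular
#' statistics, as is standard for axial data, and the mean is halved back.
#'
#' @param angles degrees.
#' @param n_bins number of bins (>= 4).
#' @param range_mode `"half-circle"` (axial, bins over \[-90, 90)) or
#'   `"full-circle"` (directional, bins over \[-180, 180)).
#' @return list with `counts`, `breaks` (deg), `circular_mean` (deg),
#'   `resultant_length`, `n`.
#' @export
orientation_histogram <- function(angles, n_bins = 12,
                                  range_mode = c("half-circle", "full-circle")) {
  range_mode <- match.arg(range_mode)
  if (n_bins < 4) stop("'n_bins' must be >= 4")
  half <- range_mode == "half-circle"
  lo <- if (half) -90 else -180
  span <- if (half) 180 else 360
  if (any(angles < lo | angles >= lo + span)) {
    warning("angles outside the declared range were wrapped")
  }
  a <- ((angles - lo) %% span) + lo
  breaks <- seq(lo, lo + span, length.out = n_bins + 1)
  counts <- as.vector(table(cut(a, breaks, right = FALSE,
                                include.lowest = TRUE)))
  mult <- if (half) 2 else 1
  rad <- a * pi / 180 * mult
  C <- mean(cos(rad)); S <- mean(sin(rad))
  Rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) / mult * 180 / pi
  list(counts = counts, breaks = breaks, circular_mean = mu,
       resultant_length = Rbar, n = length(angles))
}

#' Sprout-front quantification from a gel-region mask
#'
#' Structures in the gel region that are connected (8-connected) to the
#' gel interface are sprouts; their distance is the maximum perpendicular
#' extent from the interface line. Foreground not connected to the
#' interface is counted separately as single-cell migration and excluded
#' from the sprout distances, following the convention of excluding single
#' migrating cells from sprouting-distance measurements.
#'
#' @param gel_mask binary matrix of the gel region (rows = y, cols = x);
#'   the gel lies at columns >= `interface_col`.
#' @param interface_col column index of the gel interface (sprouts grow
#'   toward increasing x).
#' @param pixel_size um per pixel.
#' @param min_area minimum component area (px), default 20.
#' @param connect_tol_px a component whose minimum distance from the
#'   interface is within this many pixels counts as attached (default 1).
#' @return list of class `sprout_metrics`: `distances` (um, per sprout),
#'   `max_distance`, `mean_distance`, `sprout_area` (um^2),
#'   `direction_angles` (deg, base-centroid to tip), `n_sprouts`,
#'   `n_single_cells`.
#' @export
sprout_quantification <- function(gel_mask, interface_col = 1L,
                                  pixel_size = 1, min_area = 20L,
                                  connect_tol_px = 1L) {
  m <- as.matrix(gel_mask)
  if (interface_col < 1L || interface_col > ncol(m)) {
    stop("interface position outside image")
  }
  gel <- m[, interface_col:ncol(m), drop = FALSE]
  if (!any(gel > 0)) {
    return(structure(list(distances = numeric(0), max_distance = 0,
                          mean_distance = 0, sprout_area = 0,
                          direction_angles = numeric(0),
                          n_sprouts = 0L, n_single_cells = 0L),
                     class = "sprout_metrics"))
  }
  lab <- .label_mask(gel)
  labels <- setdiff(sort(unique(as.vector(lab))), 0)
  dist <- c(); ang <- c(); area_px <- 0; n_single <- 0L
  for (l in labels) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    mincol <- min(idx[, 2])
    if (mincol <= 1L + connect_tol_px) {
      d_px <- max(idx[, 2]) - 1L
      dist <- c(dist, d_px * pixel_size)
      area_px <- area_px + nrow(idx)
      base <- idx[idx[, 2] == mincol, , drop = FALSE]
      tip <- idx[idx[, 2] == max(idx[, 2]), , drop = FALSE]
      dy <- -(mean(tip[, 1]) - mean(base[, 1]))  # y-up
      dx <- mean(tip[, 2]) - mean(base[, 2])
      ang <- c(ang, atan2(dy, dx) * 180 / pi)
    } else {
      n_single <- n_single + 1L
    }
  }
  structure(list(distances = dist,
                 max_distance = if (length(dist)) max(dist) else 0,
                 mean_distance = if (length(dist)) mean(dist) else 0,
                 sprout_area = area_px * pixel_size^2,
                 direction_angles = ang,
                 n_sprouts = length(dist),
                 n_single_cells = n_single),
            class = "sprout_metrics")
}
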