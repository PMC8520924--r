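# Seeded synthetic-data generators with recorded ground truth. Every
# generator is a pure function of (parameters, seed): same inputs give
# bit-identical outputs, and each returns a `ground_truth` manifest the
# test suite consumes directly.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

.ground_truth <- function(generator, seed, params, truth) {
  structure(list(generator = generator, seed = seed, params = params,
                 truth = truth), class = "ground_truth")
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` falls back to the
#' circular uniform. Used for cell orientations and sprout direction bias.
#'
#' @param n number of draws. @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in radians, in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        theta <- sign(u[3] - 0.5) * acos(f)
        out[i] <- theta + mu
        break
      }
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

.raster_ellipse <- function(nr, nc, cy, cx, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  yy <- matrix(seq_len(nr), nr, nc) - cy
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  # y-up convention to match shape_metrics orientation
  u <- xx * cos(th) - yy * sin(th)
  w <- -xx * sin(th) - yy * cos(th)
  (u / a)^2 + (w / b)^2 <= 1
}

# rasterize only within the bounding box; returns row/col ranges + patch
.raster_ellipse_patch <- function(nr, nc, cy, cx, a, b, theta_deg) {
  ext <- ceiling(a) + 2
  ys <- max(1, floor(cy - ext)):min(nr, ceiling(cy + ext))
  xs <- max(1, floor(cx - ext)):min(nc, ceiling(cx + ext))
  th <- theta_deg * pi / 180
  yy <- matrix(ys, length(ys), length(xs)) - cy
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  u <- xx * cos(th) - yy * sin(th)
  w <- -xx * sin(th) - yy * cos(th)
  list(ys = ys, xs = xs, patch = (u / a)^2 + (w / b)^2 <= 1)
}

.flip_boundary <- function(mask, rate) {
  if (rate <= 0) return(mask)
  m <- mask
  inner <- m & rbind(FALSE, m[-nrow(m), ]) & rbind(m[-1, ], FALSE) &
    cbind(FALSE, m[, -ncol(m)]) & cbind(m[, -1], FALSE)
  boundary <- which(m & !inner)
  flip <- boundary[stats::runif(length(boundary)) < rate]
  m[flip] <- FALSE
  m
}

#' Generate labeled elliptical cell masks with known shape parameters
#'
#' Ellipses emulating lymphatic endothelial cell bodies: aspect ratios
#' drawn uniformly from `ar_range`, axial orientations from a von Mises
#' distribution (on doubled angles), equivalent radii from `size_range`.
#' Objects are laid out on a jittered tile grid so they never overlap.
#' Optional boundary-pixel flip noise mimics segmentation jitter without
#' breaking connectivity.
#'
#' @param n number of cells.
#' @param ar_range aspect-ratio range, within \[1, 20\].
#' @param mu,kappa von Mises orientation parameters (mu in degrees, axial).
#' @param size_range equivalent-radius range in px.
#' @param noise boundary-pixel flip probability.
#' @param seed RNG seed.
#' @return list with `mask` (labeled matrix) and `truth` (a `ground_truth`
#'   whose `truth` data.frame has per-object `label, ar, orientation,
#'   area_px`).
#' @export
gen_ellipse_masks <- function(n = 50, ar_range = c(1, 10), mu = 0, kappa = 0,
                              size_range = c(12, 20), noise = 0, seed = 1) {
  stopifnot(ar_range[1] >= 1, ar_range[2] <= 20, n >= 1)
  .with_seed(seed, {
    ar <- stats::runif(n, ar_range[1], ar_range[2])
    # axial orientations: von Mises on doubled angles
    th2 <- rvonmises(n, mu * 2 * pi / 180, kappa)
    theta <- th2 / 2 * 180 / pi
    r <- stats::runif(n, size_range[1], size_range[2])
    a <- r * sqrt(ar); b <- r / sqrt(ar)
    tile <- ceiling(2 * max(r * sqrt(ar_range[2])) + 6)
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    mask <- matrix(0L, nrows * tile, ncols * tile)
    truth <- data.frame(label = seq_len(n), ar = ar, orientation = theta,
                        area_px = NA_real_)
    for (i in seq_len(n)) {
      ri <- (i - 1) %/% ncols; ci <- (i - 1) %% ncols
      cy <- ri * tile + tile / 2 + stats::runif(1, -2, 2)
      cx <- ci * tile + tile / 2 + stats::runif(1, -2, 2)
      p <- .raster_ellipse_patch(nrow(mask), ncol(mask), cy, cx, a[i], b[i],
                                 theta[i])
      e <- .flip_boundary(p$patch, noise)
      truth$area_px[i] <- sum(e)
      sub <- mask[p$ys, p$xs]
      sub[e] <- i
      mask[p$ys, p$xs] <- sub
    }
    list(mask = mask,
         truth = .ground_truth("gen_ellipse_masks", seed,
                               list(n = n, ar_range = ar_range, mu = mu,
                                    kappa = kappa, size_range = size_range,
                                    noise = noise),
                               truth))
  })
}

#' Generate a sprout-front mask with known distances and directions
#'
#' Interface-connected fingers (sprouts) growing in +x from the gel
#' interface at column 1, with per-sprout horizontal extents drawn from
#' `distance_range` and direction angles from a von Mises distribution
#' biased toward +x; a fraction of additional disconnected blobs emulates
#' single-cell migration events.
#'
#' @param n_sprouts number of fingers.
#' @param distance_range horizontal extent range (px).
#' @param kappa direction concentration toward +x.
#' @param single_cell_fraction disconnected blobs per sprout.
#' @param width_range finger thickness range (px).
#' @param pixel_size um per px (recorded in the truth).
#' @param seed RNG seed.
#' @return list with `mask` (binary matrix, interface at column 1) and
#'   `truth` (`ground_truth` with per-sprout `distance_px`, `angle`, plus
#'   `n_single_cells`).
#' @export
gen_sprout_field <- function(n_sprouts = 5, distance_range = c(80, 300),
                             kappa = 4, single_cell_fraction = 0,
                             width_range = c(14, 24), pixel_size = 1,
                             seed = 1) {
  stopifnot(n_sprouts >= 0)
  .with_seed(seed, {
    max_d <- distance_range[2]
    ang_max <- 20  # clamp keeps each finger inside its own lane
    lane <- 2 * ceiling(max_d * tan(ang_max * pi / 180) +
                          max(width_range)) + 10
    n_single <- round(n_sprouts * single_cell_fraction)
    nr <- max(1, n_sprouts + n_single) * lane
    nc <- max_d + 120
    mask <- matrix(0L, nr, nc)
    d_px <- if (n_sprouts) round(stats::runif(n_sprouts, distance_range[1],
                                              distance_range[2])) else integer(0)
    angles <- if (n_sprouts) {
      a <- rvonmises(n_sprouts, 0, kappa) * 180 / pi
      pmax(pmin(a, 20), -20)
    } else numeric(0)
    widths <- if (n_sprouts) round(stats::runif(n_sprouts, width_range[1],
                                                width_range[2])) else integer(0)
    for (i in seq_len(n_sprouts)) {
      y0 <- (i - 1) * lane + lane / 2
      half <- widths[i] / 2
      slope <- tan(angles[i] * pi / 180)
      for (x in 0:d_px[i]) {
        yc <- y0 - slope * x  # y-up angle convention
        ys <- max(1, floor(yc - half)):min(nr, ceiling(yc + half))
        mask[ys, x + 1] <- 1L
      }
    }
    for (j in seq_len(n_single)) {
      y0 <- (n_sprouts + j - 1) * lane + lane / 2
      x0 <- round(stats::runif(1, max_d * 0.5, max_d)) + 40
      rr <- round(stats::runif(1, 6, 10))
      blob <- .raster_ellipse(nr, nc, y0, x0, rr, rr, 0)
      mask[blob] <- 1L
    }
    truth <- .ground_truth("gen_sprout_field", seed,
                           list(n_sprouts = n_sprouts,
                                distance_range = distance_range,
                                kappa = kappa,
                                single_cell_fraction = single_cell_fraction,
                                pixel_size = pixel_size),
                           list(distance_px = d_px, angle = angles,
                                n_single_cells = n_single))
    list(mask = mask, truth = truth)
  })
}

#' Render noisy intensity images from a transport solution
#'
#' Emulates the fluorescent dextran monitoring: for each sampled time the
#' 1D concentration profile is rendered as a 2D image (constant across the
#' transverse rows) with additive Gaussian noise. Default sampling every
#' 3 h (10800 s).
#'
#' @param field a `concentration_field` from [simulate_transport()].
#' @param sampling_interval s between frames (default 10800).
#' @param noise_sd Gaussian noise s.d. (intensity units; >= 0).
#' @param n_rows transverse image rows.
#' @param pixel_size um per px (recorded).
#' @param seed RNG seed.
#' @return list with `images` (list of matrices), `times`, and `truth`
#'   (`ground_truth` with the noiseless profiles).
#' @export
gen_intensity_series <- function(field, sampling_interval = 10800,
                                 noise_sd = 0, n_rows = 32, pixel_size = 1,
                                 seed = 1) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  want <- seq(0, max(field$times), by = sampling_interval)
  keep <- vapply(want, function(t)
    which.min(abs(field$times - t)), integer(1))
  if (max(abs(field$times[keep] - want)) > 1) {
    stop("transport solution does not cover the requested sampling times")
  }
  .with_seed(seed, {
    imgs <- lapply(keep, function(k) {
      prof <- field$conc[k, ]
      img <- matrix(rep(prof, each = n_rows), nrow = n_rows)
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow = n_rows)
      }
      img
    })
    list(images = imgs, times = field$times[keep],
         truth = .ground_truth("gen_intensity_series", seed,
                               list(sampling_interval = sampling_interval,
                                    noise_sd = noise_sd, n_rows = n_rows,
                                    pixel_size = pixel_size),
                               list(profiles = field$conc[keep, , drop = FALSE],
                                    x = field$x)))
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Target Ct = baseline - log2(fold) + noise; the housekeeping gene is flat
#' across groups. With `ct_sd = 0`, [relative_expression()] returns the
#' true folds exactly.
#'
#' @param genes target gene names.
#' @param groups group names; the first is the control (fold 1).
#' @param true_folds matrix (genes x groups) or named list per gene of
#'   per-group folds; control column forced to 1.
#' @param ct_sd Ct noise s.d. (cycles, >= 0).
#' @param n_replicates biological replicates per group.
#' @param housekeeping housekeeping gene name.
#' @param baseline_ct target-gene baseline Ct; housekeeping at
#'   `baseline_ct - 5`.
#' @param seed RNG seed.
#' @return list with `table` (Ct data.frame) and `truth`.
#' @export
gen_ct_table <- function(genes = c("DLL4", "VEGFR3"),
                         groups = c("control", "flow+GF"),
                         true_folds = NULL, ct_sd = 0, n_replicates = 3,
                         housekeeping = "GAPDH", baseline_ct = 24,
                         seed = 1) {
  if (ct_sd < 0) stop("'ct_sd' must be >= 0")
  if (is.null(true_folds)) {
    true_folds <- matrix(2, length(genes), length(groups),
                         dimnames = list(genes, groups))
  }
  true_folds <- as.matrix(true_folds)
  true_folds[, 1] <- 1
  if (any(true_folds <= 0)) stop("'true_folds' must be positive")
  .with_seed(seed, {
    rows <- list()
    for (gr in groups) for (r in seq_len(n_replicates)) {
      sid <- paste0(gr, "_", r)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = gr, gene = housekeeping, replicate = r,
        ct = baseline_ct - 5 + stats::rnorm(1, 0, ct_sd))
      for (g in genes) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = gr, gene = g, replicate = r,
          ct = baseline_ct - log2(true_folds[g, gr]) +
            stats::rnorm(1, 0, ct_sd))
      }
    }
    tab <- do.call(rbind, rows)
    list(table = tab,
         truth = .ground_truth("gen_ct_table", seed,
                               list(genes = genes, groups = groups,
                                    ct_sd = ct_sd,
                                    n_replicates = n_replicates),
                               list(folds = true_folds)))
  })
}

#' Generate an ELISA plate from known 4PL parameters
#'
#' @param params named vector `c(a, d, c, b)` of true 4PL parameters.
#' @param concentrations standard concentrations.
#' @param od_sd optical-density noise s.d. (>= 0).
#' @param n_replicates wells per concentration.
#' @param seed RNG seed.
#' @return list with `plate` (data.frame concentration, od) and `truth`.
#' @export
gen_elisa_plate <- function(params = c(a = 0.05, d = 2.4, c = 150, b = 1.2),
                            concentrations = c(7.8, 15.6, 31.2, 62.5, 125,
                                               250, 500, 1000),
                            od_sd = 0, n_replicates = 2, seed = 1) {
  if (od_sd < 0) stop("'od_sd' must be >= 0")
  .with_seed(seed, {
    conc <- rep(concentrations, each = n_replicates)
    od <- .fourpl(conc, params["a"], params["d"], params["c"], params["b"]) +
      stats::rnorm(length(conc), 0, od_sd)
    list(plate = data.frame(concentration = conc, od = od),
         truth = .ground_truth("gen_elisa_plate", seed,
                               list(od_sd = od_sd,
                                    n_replicates = n_replicates),
                               list(params = params)))
  })
}

#' Write a binary or labeled mask as PNG
#'
#' @param mask matrix; values are scaled to the 16-bit range on write.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as.matrix(mask)
  mx <- max(m, 1)
  png::writePNG(m / mx, path)
  invisible(path)
}

#' Read a mask PNG back to an integer matrix
#'
#' Inverts the scaling of [write_mask_png()] given the original maximum
#' label (defaults to treating the image as binary).
#'
#' @param path PNG path. @param max_label maximum label used on write.
#' @return integer matrix.
#' @export
read_mask_png <- function(path, max_label = 1) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * max_label)), nrow = nrow(m))
}
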