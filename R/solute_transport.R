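#' Build a 1D multi-layer transport domain
#'
#' Cell-centred finite-volume grid across the gel region, x = 0 at the
#' lymphangiogenic-factor-channel/gel interface and positive x toward the
#' stimulated channel. The endothelial monolayer is represented as an
#' interface conductance (a permeability in m/s) between its neighbouring
#' cells — not as resolved cells — which avoids the extreme cell-size
#' contrast of a 10-um layer inside a 2-mm domain.
#'
#' @param layers list of [porous_layer()] to resolve on the grid (the
#'   monolayer is passed separately). Each contributes its thickness and
#'   diffusivity; a named `diffusivity` vector is looked up by
#'   `solute$name`.
#' @param solute optional [solute()]; supplies the monolayer permeability
#'   default and selects per-solute diffusivities.
#' @param n_cells number of cells (>= 10).
#' @param boundary two-sided boundary spec, a list with `left` and `right`
#'   elements, each `list(type = "dirichlet", value = ...)` or
#'   `list(type = "closed")`.
#' @param monolayer `NULL` for no monolayer, or
#'   `list(position = <m>, permeability = <m/s>)`; `position` defaults to
#'   the right end of the resolved stack, `permeability` to the solute's.
#' @return a `transport_domain` object.
#' @export
build_domain <- function(layers = list(porous_layer("COL1", 2e-3, 1.04e-13)),
                         solute = NULL, n_cells = 200,
                         boundary = list(left = list(type = "dirichlet", value = 1),
                                         right = list(type = "dirichlet", value = 0)),
                         monolayer = list()) {
  if (n_cells < 10) stop("'n_cells' must be >= 10")
  thick <- vapply(layers, `[[`, numeric(1), "thickness")
  L <- sum(thick)
  dx <- L / n_cells
  x <- (seq_len(n_cells) - 0.5) * dx
  bnd <- cumsum(thick)
  layer_index <- findInterval(x, c(0, utils::head(bnd, -1)))
  pick_D <- function(l) {
    D <- l$diffusivity
    if (!is.null(names(D)) && !is.null(solute)) {
      if (solute$name %in% names(D)) return(unname(D[solute$name]))
    }
    if (!is.null(solute) && length(D) == 1L && is.null(names(D)) &&
        identical(l$name, "COL1")) {
      return(solute$gel_diffusivity)
    }
    unname(D[1])
  }
  D_layer <- vapply(layers, pick_D, numeric(1))
  D <- D_layer[layer_index]
  mono_face <- NA_integer_
  P_m <- NA_real_
  if (!is.null(monolayer)) {
    pos <- monolayer$position
    if (is.null(pos)) pos <- L
    P_m <- monolayer$permeability
    if (is.null(P_m)) {
      P_m <- if (!is.null(solute)) solute$monolayer_permeability else 1e-8
    }
    if (pos < 0 || pos > L) stop("monolayer position outside the domain")
    mono_face <- as.integer(round(pos / dx))  # face index in 0..n
  }
  structure(list(x = x, dx = dx, L = L, n = n_cells,
                 layer_index = layer_index, D = D,
                 interfaces = bnd,
                 monolayer_face = mono_face, monolayer_permeability = P_m,
                 boundary = boundary),
            class = "transport_domain")
}

# Patankar-family face weighting A(|P|): fraction of the diffusive
# conductance retained at cell-Peclet P.
.face_A <- function(absP, scheme) {
  switch(scheme,
    upwind = rep(1, length(absP)),
    central = 1 - absP / 2,
    exponential = ifelse(absP < 1e-12, 1 - absP / 2,
                         absP / expm1(absP)))
}

# Assemble dc/dt = (A c + b + s) / dx. Returns sparse A (n x n), b (n).
.assemble <- function(domain, velocity, scheme) {
  n <- domain$n; dx <- domain$dx; D <- domain$D
  # diffusive conductance of each face 0..n (distance-weighted series)
  g <- numeric(n + 1)
  g[1] <- 2 * D[1] / dx
  g[n + 1] <- 2 * D[n] / dx
  if (n > 1) {
    i <- seq_len(n - 1)
    g[i + 1] <- 1 / (dx / (2 * D[i]) + dx / (2 * D[i + 1]))
  }
  if (!is.na(domain$monolayer_face)) {
    f <- domain$monolayer_face + 1L
    g[f] <- 1 / (1 / g[f] + 1 / domain$monolayer_permeability)
  }
  closed_l <- identical(domain$boundary$left$type, "closed")
  closed_r <- identical(domain$boundary$right$type, "closed")
  F <- rep(velocity, n + 1)
  if (closed_l) { g[1] <- 0; F[1] <- 0 }
  if (closed_r) { g[n + 1] <- 0; F[n + 1] <- 0 }
  P <- ifelse(g > 0, abs(F) / g, 0)
  gA <- g * .face_A(P, scheme)
  aW <- gA + pmax(F, 0)    # coefficient multiplying left state at each face
  aE <- gA + pmax(-F, 0)   # coefficient multiplying right state
  # face flux J_f = aW[f] * c_left - aE[f] * c_right
  ii <- integer(0); jj <- integer(0); vv <- numeric(0); b <- numeric(n)
  add <- function(i, j, v) { ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v) }
  for (i in seq_len(n)) {
    # inflow face i (left of cell i)
    if (i == 1) {
      if (!closed_l) {
        cb <- domain$boundary$left$value
        b[i] <- b[i] + aW[1] * cb
        add(i, i, -aE[1])
      }
    } else {
      add(i, i - 1, aW[i])
      add(i, i, -aE[i])
    }
    # outflow face i+1 (right of cell i)
    if (i == n) {
      if (!closed_r) {
        cb <- domain$boundary$right$value
        add(i, i, -aW[n + 1])
        b[i] <- b[i] + aE[n + 1] * cb
      }
    } else {
      add(i, i, -aW[i + 1])
      add(i, i + 1, aE[i + 1])
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  list(A = A, b = b, g = g, aW = aW, aE = aE)
}

.face_fluxes <- function(domain, asm, c) {
  n <- domain$n
  cl <- c(if (identical(domain$boundary$left$type, "dirichlet"))
            domain$boundary$left$value else c[1], c)
  cr <- c(c, if (identical(domain$boundary$right$type, "dirichlet"))
               domain$boundary$right$value else c[n])
  asm$aW * cl - asm$aE * cr
}

#' Steady-state concentration profile
#'
#' Direct solve of the discretized steady advection-diffusion balance.
#'
#' @param domain a [build_domain()] object.
#' @param velocity Darcy velocity (m/s), positive toward +x.
#' @param scheme face scheme: `"exponential"` (default; exact for steady
#'   uniform coefficients), `"upwind"` or `"central"`.
#' @param source optional per-cell volumetric source (length n, units c/s
#'   times m; i.e. flux per face area deposited in the cell).
#' @return a data.frame `(x, c)` with attribute `flux` (per-face fluxes).
#' @export
steady_profile <- function(domain, velocity = 0,
                           scheme = c("exponential", "upwind", "central"),
                           source = NULL) {
  scheme <- match.arg(scheme)
  asm <- .assemble(domain, velocity, scheme)
  b <- asm$b
  if (!is.null(source)) b <- b + source
  cvec <- as.numeric(Matrix::solve(asm$A, -b))
  out <- data.frame(x = domain$x, c = cvec)
  attr(out, "flux") <- .face_fluxes(domain, asm, cvec)
  attr(out, "scheme") <- scheme
  out
}

#' Transient advection-diffusion simulation
#'
#' Finite-volume integration of the solute concentration across the domain,
#' implicit (backward Euler) by default; an explicit mode is retained for
#' cross-checks and refuses unstable steps. Snapshots default to every 3 h,
#' the monitoring interval used for the dextran gradients.
#'
#' @inheritParams steady_profile
#' @param t_end total time (s).
#' @param dt step (s); default 60 for implicit, checked against stability
#'   for explicit.
#' @param output_times snapshot times (s); default `seq(0, t_end, 10800)`.
#' @param initial initial concentration, scalar or length-n vector.
#' @param method `"implicit"` or `"explicit"`.
#' @return a `concentration_field`: list with `times`, `x`,
#'   `conc` (time x cell matrix), `flux` (per-face, final time), `domain`.
#' @export
simulate_transport <- function(domain, velocity = 0, t_end = 24 * 3600,
                               dt = 60,
                               output_times = seq(0, t_end, by = 10800),
                               initial = 0,
                               scheme = c("exponential", "upwind", "central"),
                               method = c("implicit", "explicit"),
                               source = NULL) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (dt <= 0 || t_end < dt) stop("need dt > 0 and t_end >= dt")
  asm <- .assemble(domain, velocity, scheme)
  n <- domain$n; dx <- domain$dx
  b <- asm$b
  if (!is.null(source)) b <- b + source
  if (method == "explicit") {
    dt_max <- dx / max(-Matrix::diag(asm$A))
    if (dt > dt_max) {
      stop(sprintf(paste0("explicit step dt = %g s exceeds the stability ",
                          "limit %.3g s; reduce dt or use method = ",
                          "'implicit'"), dt, dt_max))
    }
  }
  cvec <- rep_len(initial, n)
  output_times <- sort(unique(pmin(output_times, t_end)))
  nsteps <- ceiling(t_end / dt)
  # align steps so each requested output time is hit exactly
  times_grid <- sort(unique(c(seq(0, t_end, by = dt), output_times, t_end)))
  if (method == "implicit") {
    # constant-coefficient system: factor per distinct step size
    Mfac <- list()
    getM <- function(h) {
      key <- sprintf("%.12g", h)
      if (is.null(Mfac[[key]])) {
        M <- Matrix::Diagonal(n, dx / h) - asm$A
        Mfac[[key]] <<- Matrix::lu(M)
      }
      Mfac[[key]]
    }
  }
  snaps <- matrix(NA_real_, nrow = length(output_times), ncol = n)
  si <- 1L
  record <- function(t) {
    while (si <= length(output_times) &&
           abs(output_times[si] - t) < 1e-9 * max(1, t_end)) {
      snaps[si, ] <<- cvec
      si <<- si + 1L
    }
  }
  record(0)
  for (k in seq_len(length(times_grid) - 1L)) {
    h <- times_grid[k + 1L] - times_grid[k]
    if (h <= 0) next
    if (method == "implicit") {
      rhs <- cvec * dx / h + b
      cvec <- as.numeric(Matrix::solve(getM(h), rhs))
    } else {
      cvec <- cvec + (as.numeric(asm$A %*% cvec) + b) * h / dx
    }
    record(times_grid[k + 1L])
  }
  structure(list(times = output_times, x = domain$x, conc = snaps,
                 flux = .face_fluxes(domain, asm, cvec),
                 domain = domain, velocity = velocity, scheme = scheme),
            class = "concentration_field")
}

#' Analytic steady state of the gel + monolayer series path
#'
#' Pure-diffusion series-resistance solution for a gel slab of thickness
#' `L_gel` and diffusivity `D_gel` terminated by a monolayer of permeability
#' `P_monolayer`: linear in the gel, with the fraction of the total
#' concentration drop taken across the monolayer equal to
#' \deqn{\frac{1/P_m}{L_{gel}/D_{gel} + 1/P_m}.}
#' A large monolayer resistance reproduces the observed two-phase profile:
#' linear in the COL1 hydrogel, steep decrease over the endothelium.
#'
#' @param D_gel m^2/s. @param L_gel m. @param P_monolayer m/s.
#' @param c_source,c_sink boundary concentrations.
#' @param x positions at which to evaluate the gel profile (default 101
#'   points across the gel).
#' @return list with `profile` data.frame (x, c), `flux` (per area),
#'   `drop_fraction_monolayer`, `c_gel_end` (gel-side concentration at the
#'   monolayer).
#' @export
steady_two_layer_analytic <- function(D_gel, L_gel, P_monolayer,
                                      c_source = 1, c_sink = 0,
                                      x = seq(0, L_gel, length.out = 101)) {
  .check_positive(D_gel, "D_gel")
  .check_positive(L_gel, "L_gel")
  .check_positive(P_monolayer, "P_monolayer")
  R_gel <- L_gel / D_gel
  R_mono <- 1 / P_monolayer
  J <- (c_source - c_sink) / (R_gel + R_mono)
  cx <- c_source - J * x / D_gel
  list(profile = data.frame(x = x, c = cx),
       flux = J,
       drop_fraction_monolayer = R_mono / (R_gel + R_mono),
       c_gel_end = c_source - J * R_gel)
}

#' Exact steady advection-diffusion profile (uniform coefficients)
#'
#' Dirichlet ends `c(0) = c0`, `c(L) = cL`:
#' \deqn{c(x) = c_0 + (c_L - c_0)\frac{e^{Pe\,x/L} - 1}{e^{Pe} - 1}.}
#'
#' @param x positions (m). @param L domain length (m). @param Pe Peclet
#'   number `vL/D`. @param c0,cL boundary values.
#' @return concentrations at `x`.
#' @export
steady_advection_diffusion <- function(x, L, Pe, c0 = 1, cL = 0) {
  if (abs(Pe) < 1e-12) return(c0 + (cL - c0) * x / L)
  # expm1 keeps the profile accurate at small and large Pe
  c0 + (cL - c0) * expm1(Pe * x / L) / expm1(Pe)
}

#' Steady secretion under interstitial flow
#'
#' Steady concentration field for a thin source secreting at a fixed rate
#' inside the gel (e.g. CCL21 secreted by sprouting lymphatic endothelium)
#' with both channel boundaries acting as sinks. Reports the fraction of
#' the domain's solute mass found upstream (x < source) — against the flow:
#' 0.5 at rest by symmetry, shrinking as the Peclet number grows.
#'
#' @param domain a [build_domain()] object.
#' @param velocity m/s, positive toward +x (downstream).
#' @param source_position m; snapped to the nearest cell centre.
#' @param source_rate secretion rate (arbitrary linear units); the upstream
#'   fraction is invariant to it.
#' @param scheme face scheme (see [steady_profile()]).
#' @return list with `field` (data.frame x, c), `upstream_fraction`,
#'   `source_position` (snapped).
#' @export
secretion_under_flow <- function(domain, velocity = 0,
                                 source_position = domain$L / 2,
                                 source_rate = 1,
                                 scheme = c("exponential", "upwind", "central")) {
  scheme <- match.arg(scheme)
  if (source_position < 0 || source_position > domain$L) {
    stop("source position outside the domain")
  }
  k <- which.min(abs(domain$x - source_position))
  src <- numeric(domain$n)
  src[k] <- source_rate
  prof <- steady_profile(domain, velocity, scheme = scheme, source = src)
  m <- prof$c * domain$dx
  upstream <- sum(m[seq_len(k - 1)]) + 0.5 * m[k]
  list(field = prof, upstream_fraction = upstream / sum(m),
       source_position = domain$x[k])
}

#' Extract an intensity line profile from an image
#'
#' Mean intensity across the transverse direction of a rectangular ROI,
#' mirroring an ImageJ line-profile measurement of the dextran gradient
#' images.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param roi `list(x = c(first, last), y = c(first, last))` in pixels;
#'   `NULL` for the whole image.
#' @param axis `"x"` (profile along columns, averaging rows) or `"y"`.
#' @param pixel_size physical size per pixel (m or um per px).
#' @param normalize add a min-max normalized column.
#' @return data.frame `(position, intensity[, norm])`.
#' @export
extract_line_profile <- function(image, roi = NULL, axis = c("x", "y"),
                                 pixel_size = 1, normalize = TRUE) {
  axis <- match.arg(axis)
  if (is.null(roi)) roi <- list(x = c(1L, ncol(image)), y = c(1L, nrow(image)))
  xs <- roi$x[1]:roi$x[2]; ys <- roi$y[1]:roi$y[2]
  if (length(xs) < 1L || length(ys) < 1L ||
      min(xs) < 1L || max(xs) > ncol(image) ||
      min(ys) < 1L || max(ys) > nrow(image)) {
    stop("ROI empty or outside image")
  }
  sub <- image[ys, xs, drop = FALSE]
  if (axis == "x") {
    prof <- colMeans(sub)
    pos <- (xs - 0.5) * pixel_size
  } else {
    prof <- rowMeans(sub)
    pos <- (ys - 0.5) * pixel_size
  }
  out <- data.frame(position = pos, intensity = prof)
  if (normalize) {
    rng <- range(prof)
    out$norm <- if (diff(rng) > 0) (prof - rng[1]) / diff(rng) else prof * 0
  }
  out
}
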