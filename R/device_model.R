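#' Device geometry of the macrofluidic chip
#'
#' Parametric geometry of the three-channel macrofluidic device: a central
#' ECM channel holding the collagen (COL1) hydrogel, flanked by medium
#' channels (lymphangiogenic-factor / stimulated / control), with punched
#' medium and ECM reservoirs. Defaults are the fabricated dimensions: ECM
#' channel 2 x 1 mm and medium channels 4 x 1.2 mm (width x height),
#' 4-mm medium and 1-mm ECM reservoir punches.
#'
#' The channel length along the flow axis is not part of the fabricated
#' cross-section; it defaults to 10 mm and every downstream quantity that
#' depends on it reports it in its metadata.
#'
#' @param ecm_channel_width,ecm_channel_height ECM channel cross-section (m).
#' @param medium_channel_width,medium_channel_height medium channel
#'   cross-section (m).
#' @param channel_length channel length (m); default 10 mm.
#' @param medium_reservoir_diameter,ecm_reservoir_diameter punch diameters (m).
#' @param n_reservoirs_per_channel reservoirs feeding each medium channel.
#' @return an object of class `device_geometry`.
#' @export
device_geometry <- function(ecm_channel_width = 2e-3,
                            ecm_channel_height = 1e-3,
                            medium_channel_width = 4e-3,
                            medium_channel_height = 1.2e-3,
                            channel_length = 10e-3,
                            medium_reservoir_diameter = 4e-3,
                            ecm_reservoir_diameter = 1e-3,
                            n_reservoirs_per_channel = 2L) {
  g <- list(
    ecm_channel_width = parse_quantity(ecm_channel_width),
    ecm_channel_height = parse_quantity(ecm_channel_height),
    medium_channel_width = parse_quantity(medium_channel_width),
    medium_channel_height = parse_quantity(medium_channel_height),
    channel_length = parse_quantity(channel_length),
    medium_reservoir_diameter = parse_quantity(medium_reservoir_diameter),
    ecm_reservoir_diameter = parse_quantity(ecm_reservoir_diameter),
    n_reservoirs_per_channel = as.integer(n_reservoirs_per_channel)
  )
  for (nm in setdiff(names(g), "n_reservoirs_per_channel")) {
    .check_positive(g[[nm]], nm)
  }
  if (g$n_reservoirs_per_channel < 1L) {
    stop("'n_reservoirs_per_channel' must be >= 1")
  }
  structure(g, class = "device_geometry")
}

#' Working fluid properties
#'
#' @param density kg/m^3; default water at room temperature.
#' @param viscosity Pa s.
#' @param surface_tension N/m, precursor/medium-air interface.
#' @param g gravitational acceleration, m/s^2.
#' @return an object of class `fluid`.
#' @export
fluid <- function(density = 1000, viscosity = 1.0e-3,
                  surface_tension = 0.072, g = 9.81) {
  f <- list(density = density, viscosity = viscosity,
            surface_tension = surface_tension, g = g)
  for (nm in names(f)) .check_positive(f[[nm]], nm)
  structure(f, class = "fluid")
}

#' A porous flow/diffusion layer
#'
#' One layer of the interstitial flow path, e.g. the COL1 hydrogel
#' (Darcy permeability 1.04e-13 m^2) or the lymphatic endothelial monolayer
#' (2.46e-16 m^2). Solute diffusivity and partition coefficient may be given
#' per solute (named vector) or as a single value.
#'
#' @param name layer label.
#' @param thickness layer thickness along the flow path (m).
#' @param permeability Darcy permeability K (m^2).
#' @param diffusivity solute diffusivity within the layer (m^2/s), scalar or
#'   named per solute.
#' @param partition dimensionless partition coefficient, scalar or named.
#' @return an object of class `porous_layer`.
#' @export
porous_layer <- function(name, thickness, permeability,
                         diffusivity = 6.5e-11, partition = 1) {
  thickness <- parse_quantity(thickness)
  permeability <- parse_quantity(permeability, "area")
  .check_positive(thickness, "thickness")
  .check_positive(permeability, "permeability")
  if (any(diffusivity <= 0)) stop("'diffusivity' must be positive")
  if (any(partition <= 0)) stop("'partition' must be positive")
  structure(list(name = name, thickness = thickness,
                 permeability = permeability,
                 diffusivity = diffusivity, partition = partition),
            class = "porous_layer")
}

#' A transported solute
#'
#' @param name solute label (e.g. `"FITC-dextran-40k"`, `"VEGF-C"`, `"CCL21"`).
#' @param molecular_weight kDa.
#' @param free_diffusivity diffusivity in free medium (m^2/s).
#' @param gel_diffusivity diffusivity in the hydrogel (m^2/s).
#' @param monolayer_permeability endothelial monolayer permeability (m/s).
#' @param initial_concentration source concentration (mol/m^3 or ng/ml; the
#'   transport model is linear so units carry through).
#' @return an object of class `solute`.
#' @export
solute <- function(name, molecular_weight = 40,
                   free_diffusivity = 1e-10,
                   gel_diffusivity = 6.5e-11,
                   monolayer_permeability = 1e-8,
                   initial_concentration = 1) {
  .check_positive(molecular_weight, "molecular_weight")
  .check_positive(free_diffusivity, "free_diffusivity")
  .check_positive(gel_diffusivity, "gel_diffusivity")
  .check_positive(monolayer_permeability, "monolayer_permeability")
  structure(list(name = name, molecular_weight = molecular_weight,
                 free_diffusivity = free_diffusivity,
                 gel_diffusivity = gel_diffusivity,
                 monolayer_permeability = monolayer_permeability,
                 initial_concentration = initial_concentration),
            class = "solute")
}

#' Default device configuration
#'
#' The fabricated geometry, water-like medium, COL1 gel + endothelial
#' monolayer layer stack with the measured Darcy permeabilities, and the two
#' dextran tracers (40 and 10 kDa) used to visualise the growth-factor
#' gradient.
#'
#' @return a `device_config` list with elements `geometry`, `fluid`,
#'   `layers`, `solutes`, `schema_version`.
#' @export
default_config <- function() {
  geom <- device_geometry()
  structure(list(
    schema_version = 1L,
    geometry = geom,
    fluid = fluid(),
    layers = list(
      porous_layer("COL1", thickness = geom$ecm_channel_width,
                   permeability = 1.04e-13, diffusivity = 6.5e-11),
      porous_layer("endothelium", thickness = 10e-6,
                   permeability = 2.46e-16, diffusivity = 1e-11)
    ),
    solutes = list(
      solute("dextran-40k", molecular_weight = 40,
             gel_diffusivity = 6.5e-11),
      solute("dextran-10k", molecular_weight = 10,
             gel_diffusivity = 1.3e-10)
    )
  ), class = "device_config")
}

.schema_fields <- list(
  geometry = c("ecm_channel_width", "ecm_channel_height",
               "medium_channel_width", "medium_channel_height",
               "channel_length", "medium_reservoir_diameter",
               "ecm_reservoir_diameter", "n_reservoirs_per_channel"),
  fluid = c("density", "viscosity", "surface_tension", "g"),
  layer = c("name", "thickness", "permeability", "diffusivity", "partition"),
  solute = c("name", "molecular_weight", "free_diffusivity",
             "gel_diffusivity", "monolayer_permeability",
             "initial_concentration")
)

#' Load a device configuration from YAML or JSON
#'
#' Unspecified fields are filled with the defaults of [default_config()].
#' Lengths accept unit suffixes (`"2 mm"`, `"10 um"`); bare numbers are SI.
#' A `layers:` list must name each layer; a layer entry missing `thickness`
#' or `permeability` is a schema error naming the field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `device_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  if (!is.null(raw$geometry)) {
    bad <- setdiff(names(raw$geometry), .schema_fields$geometry)
    if (length(bad)) stop("unknown geometry field(s): ", paste(bad, collapse = ", "))
    args <- utils::modifyList(unclass(cfg$geometry), raw$geometry)
    cfg$geometry <- do.call(device_geometry, args)
  }
  if (!is.null(raw$fluid)) {
    bad <- setdiff(names(raw$fluid), .schema_fields$fluid)
    if (length(bad)) stop("unknown fluid field(s): ", paste(bad, collapse = ", "))
    cfg$fluid <- do.call(fluid, utils::modifyList(unclass(cfg$fluid), raw$fluid))
  }
  if (!is.null(raw$layers)) {
    cfg$layers <- lapply(raw$layers, function(l) {
      for (req in c("name", "thickness", "permeability")) {
        if (is.null(l[[req]])) {
          stop("layer entry missing mandatory field '", req, "'")
        }
      }
      bad <- setdiff(names(l), .schema_fields$layer)
      if (length(bad)) stop("unknown layer field(s): ", paste(bad, collapse = ", "))
      do.call(porous_layer, l)
    })
  }
  if (!is.null(raw$solutes)) {
    cfg$solutes <- lapply(raw$solutes, function(s) {
      if (is.null(s$name)) stop("solute entry missing mandatory field 'name'")
      bad <- setdiff(names(s), .schema_fields$solute)
      if (length(bad)) stop("unknown solute field(s): ", paste(bad, collapse = ", "))
      do.call(solute, s)
    })
  }
  if (!is.null(raw$schema_version)) cfg$schema_version <- as.integer(raw$schema_version)
  cfg
}

#' Save a device configuration to YAML
#'
#' Written in SI units so that [load_config()] round-trips all fields exactly.
#'
#' @param config a `device_config`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(
    schema_version = config$schema_version,
    geometry = unclass(config$geometry),
    fluid = unclass(config$fluid),
    layers = lapply(config$layers, unclass),
    solutes = lapply(config$solutes, unclass)
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Stokes-Einstein diffusivity for a globular solute or dextran
#'
#' `D = kT / (6 pi mu R_h)`. The hydrodynamic radius is either given
#' explicitly (`radius_nm`) or estimated from molecular weight with the
#' empirical dextran scaling `R_h[nm] = 0.488 * MW[kDa]^0.437`
#' (flexible-coil calibration; gives ~2.4 nm at 40 kDa).
#'
#' @param mw_kda molecular weight in kDa (ignored when `radius_nm` given).
#' @param temperature K.
#' @param viscosity Pa s.
#' @param radius_nm optional explicit hydrodynamic radius (nm).
#' @return diffusivity in m^2/s.
#' @export
stokes_einstein_diffusivity <- function(mw_kda = NULL, temperature = 310,
                                        viscosity = 0.7e-3,
                                        radius_nm = NULL) {
  kB <- 1.380649e-23
  .check_positive(temperature, "temperature")
  .check_positive(viscosity, "viscosity")
  if (is.null(radius_nm)) {
    if (is.null(mw_kda)) stop("give either 'mw_kda' or 'radius_nm'")
    .check_positive(mw_kda, "mw_kda")
    radius_nm <- 0.488 * mw_kda^0.437
  }
  .check_positive(radius_nm, "radius_nm")
  kB * temperature / (6 * pi * viscosity * radius_nm * 1e-9)
}
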