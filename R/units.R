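#' @keywords internal
"_PACKAGE"

# Unit handling for config files. Internally everything is SI (m, s, kg, Pa).
# Config values may be numbers (assumed SI) or strings with a unit suffix,
# e.g. "2 mm", "10 um", "40 kDa", "0.49 um/s".

.length_units <- c(m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9, cm = 1e-2)

#' Parse a physical quantity with an optional unit suffix
#'
#' Accepts a bare number (taken as SI) or a string like `"2 mm"`, `"10 um"`,
#' `"1.04e-13 m2"`. Returns the value in SI base units.
#'
#' @param x numeric or character scalar.
#' @param kind one of `"length"`, `"area"`, `"velocity"`, `"none"`; controls
#'   which unit suffixes are understood.
#' @return numeric scalar in SI units.
#' @export
parse_quantity <- function(x, kind = c("length", "area", "velocity", "none")) {
  kind <- match.arg(kind)
  if (is.numeric(x)) return(as.numeric(x))
  stopifnot(is.character(x), length(x) == 1L)
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([A-Za-z/0-9]*)$", s))[[1]]
  if (length(m) != 3L) stop("cannot parse quantity: ", x)
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(val)
  fac <- switch(kind,
    length = .length_units[unit],
    area = {
      base <- sub("2$", "", unit)
      unname(.length_units[base])^2
    },
    velocity = {
      parts <- strsplit(unit, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L || parts[2] != "s") NA_real_
      else unname(.length_units[parts[1]])
    },
    none = NA_real_
  )
  fac <- unname(fac)
  if (is.na(fac)) stop("unknown unit '", unit, "' for ", kind, " in: ", x)
  val * fac
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'", name, "' must be a single positive finite number (got ",
         deparse(substitute(x)), " = ", paste(x, collapse = ","), ")",
         call. = FALSE)
  }
  invisible(x)
}
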