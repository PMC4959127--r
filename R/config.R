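#' Built-in parameter presets
#'
#' Returns a complete model configuration.  The \code{"reference"}
#' preset is the incisor-scale parameter set used throughout the
#' package documentation: root height 13.0 mm, crest semi-axis
#' b = 3.9 mm, eccentricity 0.6, PDL thickness 0.229 mm, relaxed
#' modulus 680 kPa, Poisson's ratio 0.49, and the calibrated kernel
#' gamma = 0.35, tau_sigma = 550 s, nu_sigma = 1300.
#'
#' @param name preset name; currently \code{"reference"}.
#' @return a validated model configuration (see
#'   \code{\link{load_config}}).
#' @examples
#' cfg <- pdl_preset()
#' cfg$geometry$h  # mm
#' @export
pdl_preset <- function(name = "reference") {
  name <- match.arg(name, "reference")
  validate_config(list(
    geometry = list(h = 13.0, b = 3.9, e = 0.6, delta = 0.229,
                    units = "mm"),
    material = list(E_inf = 680, nu = 0.49, units = "kPa"),
    kernel = list(gamma = 0.35, tau_sigma = 550, nu_sigma = 1.3e3,
                  tol = 1e-10, n_max = 200),
    load = list(f = c(0, -2, 0), r_f = c(0, 0, 0), units = "N"),
    numerics = list(n_r = 256, n_phi = 256, t_min = 1e-2, t_max = 300,
                    n_t = 600, dF = "projected",
                    stiffness_method = "traction",
                    creep_form = "calibrated")))
}

length_scale <- c(m = 1, mm = 1e-3)
modulus_scale <- c(Pa = 1, kPa = 1e3, MPa = 1e6)

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration with blocks \code{geometry}
#' (h, b, e, delta; units "m" or "mm"), \code{material} (E_inf, nu;
#' units "Pa", "kPa" or "MPa"), \code{kernel} (gamma plus one of the
#' parameter pairs), and optional \code{load} and \code{numerics}
#' blocks.  Missing numerics entries are filled from the reference
#' preset.  Validation errors name the offending field.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a validated configuration list with attribute
#'   \code{"si"} = TRUE after unit resolution (lengths in m, moduli in
#'   Pa).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || length(cfg) == 0L)
    stop("config schema error: empty or non-mapping document")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  need <- function(block, fields) {
    if (is.null(cfg[[block]]))
      stop(sprintf("config schema error: missing block '%s'", block))
    miss <- setdiff(fields, names(cfg[[block]]))
    if (length(miss))
      stop(sprintf("config schema error: block '%s' missing field(s) %s",
                   block, paste(sQuote(miss), collapse = ", ")))
  }
  need("geometry", c("h", "b", "e", "delta"))
  need("material", c("E_inf", "nu"))
  need("kernel", "gamma")
  gu <- cfg$geometry$units %||% "m"
  if (!gu %in% names(length_scale))
    stop("config schema error: geometry.units must be 'm' or 'mm', got ",
         sQuote(gu))
  mu <- cfg$material$units %||% "Pa"
  if (!mu %in% names(modulus_scale))
    stop("config schema error: material.units must be Pa/kPa/MPa, got ",
         sQuote(mu))
  ke <- cfg$kernel
  if (is.null(ke$tau_sigma) && is.null(ke$tau_eps))
    stop("config schema error: kernel needs tau_sigma or tau_eps")
  defaults <- list(n_r = 256, n_phi = 256, t_min = 1e-2, t_max = 300,
                   n_t = 600, dF = "projected",
                   stiffness_method = "traction",
                   creep_form = "calibrated")
  cfg$numerics <- utils::modifyList(defaults, as.list(cfg$numerics))
  structure(cfg, si = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build model objects from a configuration
#'
#' Resolves units to SI and instantiates the geometry, material and
#' kernel objects of a configuration.
#'
#' @param cfg a configuration from \code{\link{load_config}} or
#'   \code{\link{pdl_preset}}.
#' @return list with \code{geom}, \code{material}, \code{kernel},
#'   \code{load} (a \code{\link{load_case}} or NULL), \code{numerics}.
#' @export
build_model <- function(cfg) {
  ls <- length_scale[[cfg$geometry$units %||% "m"]]
  ms <- modulus_scale[[cfg$material$units %||% "Pa"]]
  g <- cfg$geometry
  geom <- root_geometry(g$h * ls, g$b * ls, g$e, g$delta * ls)
  material <- pdl_material(cfg$material$E_inf * ms, cfg$material$nu)
  ke <- cfg$kernel
  kernel <- fractional_kernel(ke$gamma,
                              tau_sigma = ke$tau_sigma,
                              nu_sigma = ke$nu_sigma,
                              tau_eps = ke$tau_eps, nu_eps = ke$nu_eps,
                              tol = ke$tol %||% 1e-10,
                              n_max = ke$n_max %||% 200L)
  ld <- NULL
  if (!is.null(cfg$load))
    ld <- load_case(cfg$load$f,
                    (cfg$load$r_f %||% c(0, 0, 0)) * ls)
  list(geom = geom, material = material, kernel = kernel, load = ld,
       numerics = cfg$numerics)
}

#' Write a run result to disk
#'
#' Serialises a result list (inputs echo, outputs, provenance) to JSON
#' (full double precision, deterministic field order) or a data.frame
#' to CSV.
#'
#' @param result a named list (JSON) or data.frame (CSV).
#' @param path output path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return invisibly, the path.
#' @export
write_results <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(result))
      stop("CSV output requires a data.frame result")
    utils::write.csv(result, path, row.names = FALSE)
  }
  invisible(path)
}

## provenance block attached to every CLI result
run_provenance <- function(cfg) {
  list(package = "pdlvisco",
       version = as.character(utils::packageVersion("pdlvisco")),
       conventions = list(
         stiffness_method = cfg$numerics$stiffness_method,
         dF = cfg$numerics$dF,
         creep_form = cfg$numerics$creep_form,
         shear = "engineering in local frame; tensor = engineering/2"))
}
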