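# Geometric threshold configuration for the seven detectors. All values are
# configurable; the defaults are deliberately permissive literature-standard
# values so that slightly distorted geometries in lower-quality structures
# are still matched.

#' Default geometric thresholds
#'
#' Distances in Angstrom, angles in degrees:
#' \describe{
#'   \item{hydrophobic_dist_max}{4.0 — max C...C distance for a hydrophobic contact.}
#'   \item{hbond_dist_max}{4.1 — max donor-acceptor heavy-atom distance.}
#'   \item{hbond_don_angle_min}{100 — min D-H...A angle at the hydrogen.}
#'   \item{pistack_dist_max}{5.5 — max ring centroid-centroid distance.}
#'   \item{pistack_ang_dev}{30 — allowed deviation from 0 (parallel) or 90
#'     (T-shaped) degrees between ring planes.}
#'   \item{pistack_offset_max}{2.0 — max lateral centroid offset (also used
#'     for pi-cation).}
#'   \item{pication_dist_max}{6.0 — max ring-centroid to charge distance.}
#'   \item{saltbridge_dist_max}{5.5 — max distance between charge centroids.}
#'   \item{halogen_dist_max}{4.0 — max X...acceptor distance.}
#'   \item{halogen_don_angle}{165 — target C-X...A sigma-hole angle.}
#'   \item{halogen_acc_angle}{120 — target Y-A...X angle at the acceptor.}
#'   \item{halogen_angle_dev}{30 — allowed deviation from both targets.}
#'   \item{waterbridge_mindist / waterbridge_maxdist}{2.5 / 4.1 — allowed
#'     water-to-polar-atom leg distances.}
#'   \item{waterbridge_omega_min / waterbridge_omega_max}{75 / 140 — allowed
#'     water-centered angle between the two legs.}
#'   \item{waterbridge_theta_min}{100 — min donor angle of a donating leg.}
#' }
#'
#' @return Named list of class `threshold_config`.
#' @export
default_thresholds <- function() {
  structure(
    list(
      hydrophobic_dist_max = 4.0,
      hbond_dist_max = 4.1,
      hbond_don_angle_min = 100,
      pistack_dist_max = 5.5,
      pistack_ang_dev = 30,
      pistack_offset_max = 2.0,
      pication_dist_max = 6.0,
      saltbridge_dist_max = 5.5,
      halogen_dist_max = 4.0,
      halogen_don_angle = 165,
      halogen_acc_angle = 120,
      halogen_angle_dev = 30,
      waterbridge_mindist = 2.5,
      waterbridge_maxdist = 4.1,
      waterbridge_omega_min = 75,
      waterbridge_omega_max = 140,
      waterbridge_theta_min = 100
    ),
    class = "threshold_config"
  )
}

#' Validate a threshold configuration
#'
#' @param cfg A `threshold_config`.
#' @return The configuration, invisibly; errors on invalid values.
#' @export
validate_thresholds <- function(cfg) {
  ref <- default_thresholds()
  missing <- setdiff(names(ref), names(cfg))
  if (length(missing) > 0) {
    stop("missing threshold keys: ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0) {
    stop("unknown threshold key: ", paste(unknown, collapse = ", "))
  }
  vals <- unlist(cfg[names(ref)])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive finite numbers")
  }
  if (cfg$waterbridge_mindist >= cfg$waterbridge_maxdist) {
    stop("waterbridge_mindist must be smaller than waterbridge_maxdist")
  }
  ang <- c(
    cfg$hbond_don_angle_min, cfg$halogen_don_angle, cfg$halogen_acc_angle,
    cfg$waterbridge_omega_min, cfg$waterbridge_omega_max,
    cfg$waterbridge_theta_min
  )
  if (any(ang < 0 | ang > 180)) {
    stop("angle thresholds must lie within [0, 180] degrees")
  }
  invisible(cfg)
}

#' Read thresholds from a flat key-value file
#'
#' Lines of the form `key = value` (or `key value`); `#` starts a comment.
#' Keys must match the names in [default_thresholds()]; unspecified keys
#' keep their default.
#'
#' @param path Path to the configuration file.
#' @param base Configuration to override (default [default_thresholds()]).
#' @return A validated `threshold_config`.
#' @export
read_thresholds <- function(path, base = default_thresholds()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- base
  for (ln in lines) {
    parts <- strsplit(ln, "[=[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2) stop("malformed config line: '", ln, "'")
    key <- parts[1]
    if (!key %in% names(cfg)) stop("unknown threshold key: ", key)
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("non-numeric value for threshold key: ", key)
    cfg[[key]] <- val
  }
  validate_thresholds(cfg)
  cfg
}

#' Apply named overrides to a threshold configuration
#'
#' @param cfg A `threshold_config`.
#' @param overrides Named numeric vector or list (e.g.
#'   `c(hbond_dist_max = 3.5)`).
#' @return A validated `threshold_config`.
#' @export
override_thresholds <- function(cfg, overrides) {
  if (length(overrides) == 0) return(cfg)
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown threshold key: ", key)
    cfg[[key]] <- as.numeric(overrides[[key]])
  }
  validate_thresholds(cfg)
  cfg
}
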