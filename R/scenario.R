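#' Bolus deposition exposure scenario
#'
#' An exposure represented as instantaneous deposited masses in the three
#' respiratory entry regions at time zero, with no ongoing source.
#'
#' @param upp,tra,alv Deposited mass (ng) in the upper airway,
#'   tracheobronchial and alveolar regions.
#' @return An object of class `pbtk_scenario` with `mode = "bolus"`.
#' @examples
#' sc <- bolus_scenario(tra = 40, alv = 892)
#' @export
bolus_scenario <- function(upp = 0, tra = 0, alv = 0) {
  dep <- c(upp = upp, tra = tra, alv = alv)
  if (any(!is.finite(dep)) || any(dep < 0))
    stop("deposited masses must be finite and >= 0", call. = FALSE)
  structure(list(mode = "bolus", deposit = dep), class = "pbtk_scenario")
}

#' Continuous inhalation exposure scenario
#'
#' A constant aerosol source active on `[0, duration]`: mass enters the three
#' respiratory entry regions at rate `EC * BR * 60 * FR_region` ng/h. The
#' breathing rate is accepted in L/min (the conventional unit for rodent
#' minute volume) and converted internally to L/h.
#'
#' @param EC Aerosol mass concentration, ng/L.
#' @param BR Breathing rate, L/min.
#' @param duration Exposure duration, h.
#' @param FR Named numeric vector `c(upp=, tra=, alv=)` of regional deposition
#'   fractions; each in \[0, 1\] and summing to at most 1.
#' @return An object of class `pbtk_scenario` with `mode = "continuous"`.
#' @examples
#' sc <- continuous_scenario(EC = 20000, BR = 0.19, duration = 6,
#'                           FR = c(upp = 0.35, tra = 0.06, alv = 0.12))
#' @export
continuous_scenario <- function(EC, BR, duration,
                                FR = c(upp = 0, tra = 0, alv = 0)) {
  if (!is.finite(EC) || EC < 0) stop("EC must be >= 0", call. = FALSE)
  if (!is.finite(BR) || BR < 0) stop("BR must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration < 0)
    stop("duration must be >= 0", call. = FALSE)
  if (!all(c("upp", "tra", "alv") %in% names(FR)))
    stop("FR must be named with upp, tra, alv", call. = FALSE)
  FR <- FR[c("upp", "tra", "alv")]
  if (any(!is.finite(FR)) || any(FR < 0) || any(FR > 1) || sum(FR) > 1)
    stop("deposition fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  structure(list(mode = "continuous", EC = EC, BR = BR, duration = duration,
                 FR = FR), class = "pbtk_scenario")
}

#' @export
print.pbtk_scenario <- function(x, ...) {
  if (x$mode == "bolus") {
    cat("PBTK exposure scenario: bolus deposition (ng)\n")
    cat("  upper airway:", x$deposit[["upp"]],
        " tracheobronchial:", x$deposit[["tra"]],
        " alveolar:", x$deposit[["alv"]], "\n")
  } else {
    cat("PBTK exposure scenario: continuous inhalation\n")
    cat("  EC:", x$EC, "ng/L  BR:", x$BR, "L/min  duration:", x$duration,
        "h\n")
    cat("  deposition fractions upp/tra/alv:",
        paste(x$FR, collapse = "/"), "\n")
  }
  invisible(x)
}

#' Instantaneous aerosol source rate
#'
#' Total mass entry rate of the exposure source at time `t`, before
#' apportioning by deposition fraction. Zero for bolus scenarios and after
#' the exposure cut-off.
#'
#' @param scenario A `pbtk_scenario`.
#' @param t Time, h (vectorized).
#' @return Source rate EC x BR x 60 (ng/h) while the exposure is active,
#'   otherwise 0.
#' @export
source_rate <- function(scenario, t) {
  if (scenario$mode != "continuous") return(rep(0, length(t)))
  ifelse(t < scenario$duration, scenario$EC * scenario$BR * 60, 0)
}

#' Load an exposure scenario from file
#'
#' YAML or JSON with a `mode` field. Bolus files carry `initial_deposits`
#' (ng) with entries `upp`, `tra`, `alv`; continuous files carry
#' `EC_ng_per_L`, `BR_L_per_min`, `duration_h` and an `FR` mapping.
#'
#' @param path Path to the scenario file.
#' @return A `pbtk_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  if (is.null(doc$mode)) stop("scenario file lacks a 'mode' field",
                              call. = FALSE)
  if (doc$mode == "bolus") {
    dep <- doc$initial_deposits
    num <- function(x) if (is.null(x)) 0 else as.numeric(x)
    bolus_scenario(upp = num(dep$upp), tra = num(dep$tra), alv = num(dep$alv))
  } else if (doc$mode == "continuous") {
    continuous_scenario(EC = as.numeric(doc$EC_ng_per_L),
                        BR = as.numeric(doc$BR_L_per_min),
                        duration = as.numeric(doc$duration_h),
                        FR = c(upp = as.numeric(doc$FR$upp),
                               tra = as.numeric(doc$FR$tra),
                               alv = as.numeric(doc$FR$alv)))
  } else stop("unknown scenario mode: ", doc$mode, call. = FALSE)
}

#' Write an exposure scenario to file
#'
#' Inverse of [load_scenario()]; format chosen by extension.
#'
#' @param scenario A `pbtk_scenario`.
#' @param path Output path (`.yaml`, `.yml`, or `.json`).
#' @return `path`, invisibly.
#' @export
serialize_scenario <- function(scenario, path) {
  doc <- if (scenario$mode == "bolus") {
    list(mode = "bolus",
         initial_deposits = as.list(scenario$deposit))
  } else {
    list(mode = "continuous", EC_ng_per_L = scenario$EC,
         BR_L_per_min = scenario$BR, duration_h = scenario$duration,
         FR = as.list(scenario$FR))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}
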