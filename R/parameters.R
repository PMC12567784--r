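#' Default model parameters
#'
#' Returns the reference parameter set of the rat TiO2 nanoparticle PBTK
#' model: physiological constants (body weight, cardiac output, blood and
#' organ sub-compartment volumes, organ blood flows), chemical-specific
#' constants per systemic organ (permeability coefficient, tissue--blood
#' partition ratio, Hill uptake set, phagocytic-cell release and excretion
#' rates) and the respiratory-tract constants (regional clearance rates,
#' alveolar and interstitial Hill sets, lung permeability and partition).
#'
#' All values refer to a 0.263 kg rat and are held at that reference weight;
#' no allometric rescaling is applied. Units: volumes L, flows L/h, first-order
#' rates 1/h, half-maximum times h, permeability and partition coefficients
#' dimensionless. Hill coefficients `n0` default to 1 for every organ and lung
#' region and are exposed as ordinary configuration keys.
#'
#' @return An object of class `pbtk_parameters`: a list with components
#'   `physiological`, `chemical` (one entry per organ in liver, kidney,
#'   spleen, rob) and `respiratory`.
#' @seealso [load_parameters()], [validate_parameters()], [set_parameter()]
#' @examples
#' p <- default_parameters()
#' p$physiological$QC
#' p$chemical$liver$K_max
#' p$respiratory$P_lu
#' @export
default_parameters <- function() {
  p <- list(
    physiological = list(
      BW = 0.263,          # kg
      QC = 6.0345,         # total cardiac output, L/h
      V_ven = 0.0106,      # venous blood volume, L
      V_art = 0.0025,      # arterial blood volume, L
      liver  = list(V = 0.00983, V_cab = 0.00023, V_tis = 0.0096,  Q = 1.05),
      lung   = list(V = 0.00167, V_cab = 0.00047, V_tis = 0.0012,  Q = 6.0345),
      kidney = list(V = 0.00221, V_cab = 0.00031, V_tis = 0.0019,  Q = 0.8509),
      spleen = list(V = 0.00065, V_cab = 0.00012, V_tis = 0.00053, Q = 0.0736),
      rob    = list(V = 0.2613,  V_cab = 0.0102,  V_tis = 0.2511,  Q = 4.06)
    ),
    chemical = list(
      liver = list(X = 489.2806, P = 47.4101, K_max = 263.8254, K_50 = 0.3592,
                   n0 = 1, K_out = 19.4813, K_excrete = 0.0884),
      kidney = list(X = 0.0199, P = 209, K_max = 0.9929, K_50 = 13.6432,
                    n0 = 1, K_out = 20, K_excrete = 0.00005),
      spleen = list(X = 130.1283, P = 150, K_max = 240, K_50 = 1000,
                    n0 = 1, K_out = 0.9507, K_excrete = 0),
      rob = list(X = 0.0001, P = 10.8944, K_max = 0.000001, K_50 = 0.008,
                 n0 = 1, K_out = 0.00005, K_excrete = 0)
    ),
    respiratory = list(
      K_upp_robtis = 0.05,      # upper airway -> rest-of-body tissue, 1/h
      K_upp_feces = 0.008,      # upper airway -> feces (swallowed), 1/h
      K_trach_feces = 0.3099,   # tracheobronchial -> feces, 1/h
      K_alvpcs_trach = 8.3465,  # alveolar PCs -> tracheobronchial, 1/h
      K_alv_inter = 0.353,      # alveolar -> lung interstitium, 1/h
      K_inter_alv = 0.09,       # lung interstitium -> alveolar, 1/h
      K_alvmax = 0.000004,      # alveolar Hill maximum uptake, 1/h
      K_alv50 = 202.1309,       # alveolar Hill half-maximum time, h
      n0_alv = 1,
      K_alvout = 0.0109,        # alveolar PC release, 1/h
      K_inter_max = 0.000050504,# interstitial Hill maximum uptake, 1/h
      K_inter50 = 628.416,      # interstitial Hill half-maximum time, h
      n0_inter = 1,
      K_interout = 0.0672,      # interstitial PC release, 1/h
      P_lu = 30359,             # lung tissue--blood partition, dimensionless
      X_lu = 49.1745            # lung permeability coefficient, dimensionless
    )
  )
  class(p) <- "pbtk_parameters"
  p
}

#' @export
print.pbtk_parameters <- function(x, ...) {
  cat("PBTK parameter set (rat, BW =", x$physiological$BW, "kg)\n")
  cat("  cardiac output QC:", x$physiological$QC, "L/h\n")
  cat("  systemic organs: ", paste(names(x$chemical), collapse = ", "), "\n")
  cat("  lung partition P_lu:", x$respiratory$P_lu,
      " permeability X_lu:", x$respiratory$X_lu, "\n")
  invisible(x)
}

#' Flatten a parameter set to dotted keys
#'
#' Converts the nested parameter list into a named numeric vector whose names
#' are dotted paths such as `physiological.liver.V_cab`, `chemical.kidney.P`
#' or `respiratory.P_lu`. The flat form is the configuration-file dialect and
#' the addressing scheme used by [set_parameter()], [local_sensitivity()] and
#' [fit_parameters()].
#'
#' @param params A `pbtk_parameters` object.
#' @return Named numeric vector.
#' @export
flatten_parameters <- function(params) {
  stopifnot(inherits(params, "pbtk_parameters"))
  flat <- c()
  rec <- function(x, prefix) {
    for (nm in names(x)) {
      key <- paste(prefix, nm, sep = ".")
      if (is.list(x[[nm]])) rec(x[[nm]], key)
      else flat[[key]] <<- as.numeric(x[[nm]])
    }
  }
  for (top in names(unclass(params))) rec(params[[top]], top)
  unlist(flat)
}

#' Read a single parameter by dotted key
#'
#' @param params A `pbtk_parameters` object.
#' @param key Dotted parameter name, e.g. `"chemical.liver.K_50"`.
#' @return The numeric value.
#' @export
get_parameter <- function(params, key) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- unclass(params)
  for (part in path) {
    if (is.null(node[[part]]))
      stop("unknown parameter key: ", key, call. = FALSE)
    node <- node[[part]]
  }
  if (!is.numeric(node) || length(node) != 1L)
    stop("key does not address a scalar parameter: ", key, call. = FALSE)
  node
}

#' Override a single parameter by dotted key
#'
#' @inheritParams get_parameter
#' @param value Replacement numeric value.
#' @return The modified `pbtk_parameters` object.
#' @export
set_parameter <- function(params, key, value) {
  get_parameter(params, key)  # existence + scalar check
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("parameter value must be a single finite number: ", key, call. = FALSE)
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  params[[path]] <- unname(as.numeric(value))
  params
}

#' Load a parameter configuration
#'
#' Builds a parameter set by applying overrides to the defaults. Overrides may
#' come from a YAML or JSON file mapping dotted keys to numbers, or from a
#' named list/vector given directly. Unknown keys are rejected and the merged
#' result must pass [validate_parameters()].
#'
#' @param path Optional path to a YAML (`.yml`/`.yaml`) or JSON configuration
#'   file of dotted keys.
#' @param overrides Optional named list or numeric vector of dotted keys,
#'   applied after the file.
#' @param base Parameter set to start from; defaults to [default_parameters()].
#' @return A validated `pbtk_parameters` object.
#' @examples
#' p <- load_parameters(overrides = list("respiratory.P_lu" = 15179.5))
#' p$respiratory$P_lu
#' @export
load_parameters <- function(path = NULL, overrides = NULL,
                            base = default_parameters()) {
  params <- base
  apply_map <- function(params, map) {
    if (length(map) == 0) return(params)
    if (is.null(names(map)) || any(names(map) == ""))
      stop("parameter overrides must be a named mapping", call. = FALSE)
    for (key in names(map)) {
      val <- map[[key]]
      if (!is.numeric(val) || length(val) != 1L)
        stop("configuration value for '", key, "' is not a single number",
             call. = FALSE)
      params <- set_parameter(params, key, val)
    }
    params
  }
  if (!is.null(path)) {
    doc <- read_config_file(path)
    params <- apply_map(params, doc)
  }
  params <- apply_map(params, as.list(overrides))
  violations <- validate_parameters(params)
  if (length(violations) > 0)
    stop("invalid parameter configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  params
}

# Read a YAML or JSON mapping file; returns a flat named list (dotted keys).
read_config_file <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    doc <- yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  # allow nesting in the file: flatten to dotted keys
  flat <- list()
  rec <- function(x, prefix) {
    for (nm in names(x)) {
      key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
      if (is.list(x[[nm]])) rec(x[[nm]], key) else flat[[key]] <<- x[[nm]]
    }
  }
  rec(doc, "")
  flat
}

#' Serialize a parameter set to a configuration file
#'
#' Writes the full flat (dotted-key) representation as YAML or JSON, chosen by
#' file extension. `load_parameters()` on the written file reproduces the
#' parameter set exactly.
#'
#' @param params A `pbtk_parameters` object.
#' @param path Output path (`.yaml`, `.yml`, or `.json`).
#' @return `path`, invisibly.
#' @export
serialize_parameters <- function(params, path) {
  flat <- flatten_parameters(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # I(17) significant digits: enough for an exact double round trip
    jsonlite::write_json(as.list(flat), path, auto_unbox = TRUE,
                         digits = I(17))
  } else {
    # format numbers at full precision; yaml::write_yaml default would round
    txt <- paste0(names(flat), ": ", formatC(flat, digits = 17, format = "g"))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model constants: strict positivity
#' of physiological values, sub-compartment volumes not exceeding the organ
#' volume, systemic blood flows summing to cardiac output (relative tolerance
#' 1e-3, which the reference values satisfy), lung flow equal to cardiac
#' output, and sign constraints on the chemical and respiratory rate
#' constants.
#'
#' @param params A `pbtk_parameters` object.
#' @return Character vector of human-readable violation descriptions; empty
#'   when the set is valid. Violations are returned, never raised.
#' @export
validate_parameters <- function(params) {
  v <- character()
  ph <- params$physiological
  organs <- c("liver", "lung", "kidney", "spleen", "rob")

  scalars <- c(BW = ph$BW, QC = ph$QC, V_ven = ph$V_ven, V_art = ph$V_art)
  for (nm in names(scalars))
    if (!is.finite(scalars[[nm]]) || scalars[[nm]] <= 0)
      v <- c(v, paste0("physiological.", nm, " must be strictly positive"))
  for (o in organs) {
    for (fld in c("V", "V_cab", "V_tis", "Q")) {
      val <- ph[[o]][[fld]]
      if (!is.finite(val) || val <= 0)
        v <- c(v, paste0("physiological.", o, ".", fld,
                         " must be strictly positive"))
    }
    if (is.finite(ph[[o]]$V_cab) && is.finite(ph[[o]]$V_tis) &&
        is.finite(ph[[o]]$V)) {
      if (ph[[o]]$V_cab + ph[[o]]$V_tis > ph[[o]]$V * (1 + 1e-6))
        v <- c(v, paste0("physiological.", o,
                         ": V_cab + V_tis exceeds organ volume V"))
    }
  }
  qsum <- ph$liver$Q + ph$kidney$Q + ph$spleen$Q + ph$rob$Q
  if (is.finite(qsum) && is.finite(ph$QC) && ph$QC > 0 &&
      abs(qsum - ph$QC) / ph$QC > 1e-3)
    v <- c(v, sprintf(paste0("systemic blood flows sum to %.6g L/h, which ",
                             "differs from cardiac output QC = %.6g L/h"),
                      qsum, ph$QC))
  if (is.finite(ph$lung$Q) && is.finite(ph$QC) && ph$QC > 0 &&
      abs(ph$lung$Q - ph$QC) / ph$QC > 1e-3)
    v <- c(v, "lung blood flow must equal total cardiac output QC")

  for (o in c("liver", "kidney", "spleen", "rob")) {
    ch <- params$chemical[[o]]
    pre <- paste0("chemical.", o, ".")
    if (ch$X < 0) v <- c(v, paste0(pre, "X must be >= 0"))
    if (ch$P <= 0) v <- c(v, paste0(pre, "P must be > 0"))
    if (ch$K_max < 0) v <- c(v, paste0(pre, "K_max must be >= 0"))
    if (ch$K_50 <= 0) v <- c(v, paste0(pre, "K_50 must be > 0"))
    if (ch$n0 <= 0) v <- c(v, paste0(pre, "n0 must be > 0"))
    if (ch$K_out < 0) v <- c(v, paste0(pre, "K_out must be >= 0"))
    if (ch$K_excrete < 0) v <- c(v, paste0(pre, "K_excrete must be >= 0"))
  }

  re <- params$respiratory
  nonneg <- c("K_upp_robtis", "K_upp_feces", "K_trach_feces", "K_alvpcs_trach",
              "K_alv_inter", "K_inter_alv", "K_alvmax", "K_alvout",
              "K_inter_max", "K_interout", "X_lu")
  for (nm in nonneg)
    if (re[[nm]] < 0) v <- c(v, paste0("respiratory.", nm, " must be >= 0"))
  for (nm in c("K_alv50", "K_inter50", "P_lu", "n0_alv", "n0_inter"))
    if (re[[nm]] <= 0) v <- c(v, paste0("respiratory.", nm, " must be > 0"))

  v
}
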