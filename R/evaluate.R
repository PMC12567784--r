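#' Absolute average fold error
#'
#' `AAFE = 10 ^ ((1/n) * sum(|log10(sim_i / meas_i)|))`. Equals 1 only for a
#' pointwise perfect match, is always >= 1, is symmetric in its arguments and
#' invariant under a common positive rescaling of both series. Values of 2 or
#' below are the conventional acceptability threshold for PBTK models.
#'
#' @param simulated,measured Positive numeric vectors of equal length.
#' @return Dimensionless fold error >= 1.
#' @examples
#' aafe(c(10, 1000), c(100, 100))  # 10
#' @export
aafe <- function(simulated, measured) {
  if (length(simulated) != length(measured) || length(simulated) < 1)
    stop("simulated and measured must have equal length >= 1", call. = FALSE)
  if (any(simulated <= 0) || any(measured <= 0))
    stop("AAFE requires strictly positive values", call. = FALSE)
  10^(mean(abs(log10(simulated / measured))))
}

#' Relative error in percent
#'
#' `|simulated - measured| / measured * 100`, the pointwise agreement metric
#' used alongside AAFE.
#'
#' @param simulated,measured Numeric (vectorized); `measured` must be > 0.
#' @return Percent error.
#' @export
relative_error <- function(simulated, measured) {
  if (any(measured <= 0)) stop("measured must be > 0", call. = FALSE)
  abs(simulated - measured) / measured * 100
}

#' Squared Pearson correlation between simulated and measured series
#'
#' Computed on log10-transformed pairs by default: organ contents span
#' several orders of magnitude, and a linear-space correlation would be
#' dominated entirely by the largest compartment. Linear space is available
#' by flag.
#'
#' @param simulated,measured Numeric vectors of equal length >= 2 (strictly
#'   positive in log10 space).
#' @param space `"log10"` (default) or `"linear"`.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(simulated, measured, space = c("log10", "linear")) {
  space <- match.arg(space)
  if (length(simulated) != length(measured) || length(simulated) < 2)
    stop("need paired series of length >= 2", call. = FALSE)
  if (space == "log10") {
    if (any(simulated <= 0) || any(measured <= 0))
      stop("log10 space requires strictly positive values", call. = FALSE)
    simulated <- log10(simulated); measured <- log10(measured)
  }
  if (stats::sd(simulated) == 0 || stats::sd(measured) == 0)
    stop("zero variance in a series: R-squared undefined", call. = FALSE)
  stats::cor(simulated, measured)^2
}

#' Fraction of predictions within the 0.5- to 2-fold band
#'
#' WHO PBPK guidance considers a model acceptable when simulated values fall
#' within 0.5 to 2 times the measured data; this returns the fraction of
#' points satisfying `0.5 <= sim/meas <= 2`.
#'
#' @param simulated,measured Positive numeric vectors of equal length.
#' @return Fraction in \[0, 1\].
#' @export
fold_band_fraction <- function(simulated, measured) {
  if (length(simulated) != length(measured) || length(simulated) < 1)
    stop("simulated and measured must have equal length >= 1", call. = FALSE)
  if (any(simulated <= 0) || any(measured <= 0))
    stop("fold band requires strictly positive values", call. = FALSE)
  ratio <- simulated / measured
  mean(ratio >= 0.5 & ratio <= 2)
}

#' Elimination half-life by mono-exponential log-linear regression
#'
#' Fits `ln(mass)` against time by least squares over the given window and
#' returns `t1/2 = ln(2) / k` with `k` the negated slope. The default window
#' of 1--672 h is the elimination-phase convention used for the organ
#' half-life table; it is configurable because it can straddle the peak of
#' slowly-filling organs. A non-negative slope yields a `"no elimination"`
#' status with `t_half = NA` rather than a negative half-life.
#'
#' @param series Data frame with `time` and `mass` columns, strictly positive
#'   within the window.
#' @param window Length-2 numeric `c(from, to)`, h.
#' @return List with `t_half` (h or `NA`), `k` (1/h) and `status` (`"ok"` or
#'   `"no elimination"`).
#' @export
half_life <- function(series, window = c(1, 672)) {
  sel <- series$time >= window[1] & series$time <= window[2]
  if (sum(sel) < 2)
    stop("fewer than 2 points in the regression window", call. = FALSE)
  m <- series$mass[sel]
  if (any(m <= 0))
    stop("non-positive mass in the regression window", call. = FALSE)
  k <- -unname(stats::coef(stats::lm(log(m) ~ series$time[sel]))[2])
  # slopes at roundoff scale (e.g. from a constant series) are not decay
  if (k <= 1e-12) return(list(t_half = NA_real_, k = k,
                              status = "no elimination"))
  list(t_half = log(2) / k, k = k, status = "ok")
}

#' Normalized log-log sensitivity of an arbitrary evaluator
#'
#' Central finite difference in log space:
#' `S = (ln f(theta * e^h) - ln f(theta * e^-h)) / (2h)`, the discrete form
#' of `d ln y / d ln theta`. This is the computational core of
#' [local_sensitivity()], exposed separately so closed-form models can be
#' wired in directly (e.g. for oracle checks).
#'
#' @param f Function of a single positive scalar returning a numeric vector
#'   of outputs (all evaluated at the same perturbation).
#' @param theta Parameter value (> 0).
#' @param h Log-space step; default 0.01.
#' @return Numeric vector of sensitivities, `NA` where either perturbed
#'   output is non-positive.
#' @examples
#' log_log_sensitivity(function(th) th^2, theta = 3)  # 2
#' @export
log_log_sensitivity <- function(f, theta, h = 0.01) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  y_up <- f(theta * exp(h))
  y_dn <- f(theta * exp(-h))
  s <- rep(NA_real_, length(y_up))
  ok <- is.finite(y_up) & is.finite(y_dn) & y_up > 0 & y_dn > 0
  s[ok] <- (log(y_up[ok]) - log(y_dn[ok])) / (2 * h)
  s
}

#' Local sensitivity of model outputs to one parameter
#'
#' Normalized local sensitivity coefficient `S(t) = d ln y(t) / d ln theta`
#' of one or more observables with respect to a single parameter, by central
#' finite differences in log space (two perturbed simulations per
#' parameter). The aggregate score is the maximum of `|S(t)|` over the
#' evaluated times by default; the aggregation rule is recorded in the
#' result so alternatives remain switchable.
#'
#' @param params A `pbtk_parameters` object; the unperturbed baseline.
#' @param scenario A `pbtk_scenario`.
#' @param parameter Dotted parameter key (e.g. `"respiratory.P_lu"`); its
#'   baseline value must be > 0.
#' @param outputs Character vector of observable names.
#' @param times Evaluation times, h.
#' @param h Log-space finite-difference step; default 0.01.
#' @param map Observable composition.
#' @param aggregate Aggregation rule over times: `"max_abs"` (default),
#'   `"mean_abs"`, or `"final"`.
#' @param dt Simulation output spacing, h.
#' @param ... Further arguments passed to [run_simulation()].
#' @return Object of class `pbtk_sensitivity`: list with `parameter`,
#'   `theta`, `times`, `S` (matrix, time x output; `NA` where the output is
#'   non-positive), `aggregate` (named vector) and `rule`.
#' @export
local_sensitivity <- function(params, scenario, parameter, outputs, times,
                              h = 0.01, map = default_observable_map(),
                              aggregate = c("max_abs", "mean_abs", "final"),
                              dt = 0.5, ...) {
  rule <- match.arg(aggregate)
  theta <- get_parameter(params, parameter)
  if (theta <= 0)
    stop("sensitivity requires a positive baseline value for ", parameter,
         call. = FALSE)
  t_end <- max(times)
  eval_outputs <- function(value) {
    p <- set_parameter(params, parameter, value)
    res <- tryCatch(
      run_simulation(p, scenario, t_end = t_end, dt = dt,
                     obs_times = times, ...),
      error = function(e) stop("solver failure at ", parameter, " = ",
                               value, ": ", conditionMessage(e),
                               call. = FALSE))
    vapply(outputs, function(nm) {
      ser <- extract_observable(res, nm, map)
      ser$mass[match(times, ser$time)]
    }, numeric(length(times)))
  }
  y_up <- eval_outputs(theta * exp(h))
  y_dn <- eval_outputs(theta * exp(-h))
  S <- matrix(NA_real_, nrow = length(times), ncol = length(outputs),
              dimnames = list(NULL, outputs))
  ok <- is.finite(y_up) & is.finite(y_dn) & y_up > 0 & y_dn > 0
  S[ok] <- (log(y_up[ok]) - log(y_dn[ok])) / (2 * h)
  agg <- apply(S, 2, function(s) {
    s <- s[is.finite(s)]
    if (length(s) == 0) return(NA_real_)
    switch(rule,
           max_abs = max(abs(s)),
           mean_abs = mean(abs(s)),
           final = s[length(s)])
  })
  structure(list(parameter = parameter, theta = theta, times = times, S = S,
                 aggregate = agg, rule = rule),
            class = "pbtk_sensitivity")
}

#' @export
print.pbtk_sensitivity <- function(x, ...) {
  cat("Local sensitivity to ", x$parameter, " (baseline ", x$theta, ")\n",
      sep = "")
  cat("  aggregation rule:", x$rule, "\n")
  for (nm in names(x$aggregate))
    cat(sprintf("  %-18s %s\n", nm, format(x$aggregate[[nm]], digits = 4)))
  invisible(x)
}

#' Parameter perturbation study
#'
#' Re-simulates the model with one parameter scaled by each factor (classically
#' 0.5x and 2x) and returns the perturbed content--time curves together with
#' their pointwise fold change against the unperturbed baseline.
#'
#' @param params A `pbtk_parameters` object.
#' @param scenario A `pbtk_scenario`.
#' @param parameter Dotted parameter key.
#' @param factors Positive scale factors; default `c(0.5, 2)`.
#' @param outputs Character vector of observable names.
#' @param t_end Simulation end, h.
#' @param map Observable composition.
#' @param dt Output grid spacing, h.
#' @param ... Passed to [run_simulation()].
#' @return Object of class `pbtk_perturbation`: list with `parameter`,
#'   `factors` and `data`, a long data frame with columns `output`, `factor`
#'   (1 denotes the baseline), `time`, `mass` and `fold_change` (vs.
#'   baseline at the same time).
#' @export
perturbation_study <- function(params, scenario, parameter,
                               factors = c(0.5, 2), outputs,
                               t_end, map = default_observable_map(),
                               dt = 0.5, ...) {
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  theta <- get_parameter(params, parameter)
  run_at <- function(fac) {
    p <- set_parameter(params, parameter, theta * fac)
    run_simulation(p, scenario, t_end = t_end, dt = dt, ...)
  }
  base <- run_at(1)
  base_series <- lapply(outputs, function(nm)
    extract_observable(base, nm, map))
  names(base_series) <- outputs
  pieces <- list()
  for (fac in unique(c(1, factors))) {
    res <- if (fac == 1) base else run_at(fac)
    for (nm in outputs) {
      ser <- extract_observable(res, nm, map)
      bm <- base_series[[nm]]$mass
      pieces[[length(pieces) + 1]] <- data.frame(
        output = nm, factor = fac, time = ser$time, mass = ser$mass,
        fold_change = ifelse(bm > 0, ser$mass / bm, NA_real_))
    }
  }
  structure(list(parameter = parameter, factors = factors,
                 data = do.call(rbind, pieces)),
            class = "pbtk_perturbation")
}

#' @export
print.pbtk_perturbation <- function(x, ...) {
  cat("Perturbation study of", x$parameter, "at factors",
      paste(x$factors, collapse = ", "), "\n")
  cat("  outputs:", paste(unique(x$data$output), collapse = ", "), "\n")
  invisible(x)
}

#' Least-squares calibration of selected parameters
#'
#' Bounded minimization of `sum((ln sim - ln meas)^2)` over the dataset
#' points, the natural objective for contents spanning orders of magnitude.
#' Optimization is performed in log-parameter space: Brent's method for a
#' single free parameter, L-BFGS-B otherwise. Deterministic given a fixed
#' starting point.
#'
#' @param params Starting parameter set (also supplies fixed parameters).
#' @param scenario A `pbtk_scenario`.
#' @param dataset Observed dataset: data frame with columns `observable`,
#'   `time_h`, `mean_ng` (and optionally `sd_ng`), as produced by
#'   [generate_observed()] or [read_observed()]. Points with non-positive
#'   means are rejected.
#' @param free Character vector of dotted parameter keys to fit; empty
#'   returns the input unchanged.
#' @param lower,upper Optional named bounds on the free parameters (same
#'   order as `free`); default is a factor of 50 around the starting values.
#' @param map Observable composition.
#' @param t_end Simulation end, h; defaults to the latest dataset time.
#' @param dt Output grid spacing for the fitting simulations, h.
#' @param ... Passed to [run_simulation()].
#' @return List with `params` (fitted set), `estimates` (named vector of
#'   fitted values), `objective` and `convergence` (0 = converged).
#' @export
fit_parameters <- function(params, scenario, dataset, free,
                           lower = NULL, upper = NULL,
                           map = default_observable_map(), t_end = NULL,
                           dt = 0.5, ...) {
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  if (any(dataset$mean_ng <= 0))
    stop("dataset means must be > 0 for the log-space objective",
         call. = FALSE)
  if (is.null(t_end)) t_end <- max(dataset$time_h)
  obs_times <- sort(unique(dataset$time_h))

  objective <- function(values) {
    p <- params
    for (i in seq_along(free)) p <- set_parameter(p, free[i], values[i])
    res <- run_simulation(p, scenario, t_end = t_end, dt = dt,
                          obs_times = obs_times, ...)
    sim <- mapply(function(nm, tt) {
      ser <- extract_observable(res, nm, map)
      ser$mass[match(tt, ser$time)]
    }, dataset$observable, dataset$time_h)
    if (any(!is.finite(sim)) || any(sim <= 0)) return(1e10)
    sum((log(sim) - log(dataset$mean_ng))^2)
  }

  if (length(free) == 0) {
    return(list(params = params, estimates = numeric(0),
                objective = objective(numeric(0)), convergence = 0L))
  }
  start <- vapply(free, function(k) get_parameter(params, k), numeric(1))
  if (any(start <= 0))
    stop("free parameters must start at positive values", call. = FALSE)
  if (!is.finite(objective(start)) || objective(start) >= 1e10)
    stop("objective is not finite at the starting point", call. = FALSE)
  lo <- if (is.null(lower)) start / 50 else lower
  hi <- if (is.null(upper)) start * 50 else upper
  if (any(lo <= 0)) stop("bounds must be positive", call. = FALSE)

  if (length(free) == 1) {
    opt <- stats::optimize(function(lt) objective(exp(lt)),
                           interval = c(log(lo), log(hi)), tol = 1e-10)
    est <- exp(opt$minimum); obj <- opt$objective; conv <- 0L
  } else {
    opt <- stats::optim(log(start), function(lt) objective(exp(lt)),
                        method = "L-BFGS-B", lower = log(lo),
                        upper = log(hi),
                        control = list(factr = 1e4))
    est <- exp(opt$par); obj <- opt$value; conv <- opt$convergence
  }
  fitted <- params
  for (i in seq_along(free)) fitted <- set_parameter(fitted, free[i], est[i])
  list(params = fitted, estimates = stats::setNames(est, free),
       objective = obj, convergence = conv)
}

#' Read an observed content--time dataset
#'
#' CSV with columns `observable`, `time_h`, `mean_ng`, `sd_ng`.
#'
#' @param path CSV path.
#' @return Data frame with those four columns.
#' @export
read_observed <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("observable", "time_h", "mean_ng", "sd_ng")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0)
    stop("observed dataset lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(d$time_h < 0) || any(d$mean_ng < 0) || any(d$sd_ng < 0))
    stop("observed dataset has negative times, means, or sds", call. = FALSE)
  d[required]
}

#' Write an observed content--time dataset
#'
#' @param dataset Data frame with columns `observable`, `time_h`, `mean_ng`,
#'   `sd_ng`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observed <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
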