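# State registry. Order is fixed and shared by the RHS, the solver output and
# the CSV writer: respiratory tract, lung sub-compartments, central blood,
# systemic organ triplets, then the two excretion sinks.
.state_names <- c(
  "M_upp", "M_tra", "M_alv", "M_alv_PCs",
  "M_lu_cab", "M_lu_tis", "M_lu_PCs",
  "M_art", "M_ven",
  "M_liver_cab", "M_liver_tis", "M_liver_PCs",
  "M_kidney_cab", "M_kidney_tis", "M_kidney_PCs",
  "M_spleen_cab", "M_spleen_tis", "M_spleen_PCs",
  "M_rob_cab", "M_rob_tis", "M_rob_PCs",
  "M_feces", "M_urine"
)

.systemic_organs <- c("liver", "kidney", "spleen", "rob")

#' State vector component names
#'
#' The 23 named masses (ng) of the model state: upper airway, tracheobronchial
#' and alveolar free mass, alveolar phagocytic cells, lung capillary / tissue /
#' phagocytic cells, arterial and venous blood, the capillary--tissue--PC
#' triplet of each systemic organ (liver, kidney, spleen, rest of body), and
#' the cumulative feces and urine sinks.
#'
#' @return Character vector of length 23.
#' @export
pbtk_states <- function() .state_names

#' Initial state for an exposure scenario
#'
#' @param scenario A `pbtk_scenario`. Bolus deposits populate the upper
#'   airway, tracheobronchial and alveolar states; all other components (and
#'   every component under continuous exposure) start at zero.
#' @return Named numeric vector over [pbtk_states()].
#' @export
initial_state <- function(scenario) {
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  if (scenario$mode == "bolus") {
    y["M_upp"] <- scenario$deposit[["upp"]]
    y["M_tra"] <- scenario$deposit[["tra"]]
    y["M_alv"] <- scenario$deposit[["alv"]]
  }
  y
}

#' Hill-equation phagocytic uptake rate
#'
#' Time-dependent saturable endocytosis rate of tissue phagocytic cells,
#' `K_up(t) = K_max * t^n0 / (K_50^n0 + t^n0)`. The rate rises from 0 at the
#' start of exposure, reaches half of `K_max` at `t = K_50`, and saturates at
#' `K_max`. The clock `t` is absolute simulation time measured from exposure
#' onset and is shared by all compartments.
#'
#' @param K_max Maximum uptake rate, 1/h.
#' @param K_50 Time of half-maximum uptake, h (> 0).
#' @param n0 Hill coefficient, dimensionless (> 0).
#' @param t Time since exposure onset, h (>= 0; vectorized).
#' @return Uptake rate in 1/h, bounded by `[0, K_max]` and non-decreasing
#'   in `t`.
#' @examples
#' hill_uptake_rate(263.8254, 0.3592, 1, 0.3592)  # half of K_max
#' @export
hill_uptake_rate <- function(K_max, K_50, n0, t) {
  if (K_50 <= 0) stop("K_50 must be > 0", call. = FALSE)
  if (n0 <= 0) stop("n0 must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tn <- t^n0
  K_max * tn / (K_50^n0 + tn)
}

#' Sub-compartment mass fluxes of a systemic organ
#'
#' Net rates of change (ng/h) for the capillary, tissue and phagocytic-cell
#' masses of one systemic organ. The capillary exchanges with arterial blood
#' by perfusion and with tissue through the permeability-limited term
#' `X_o * Q_o * (C_cab - C_tis / P_o)`; tissue exchanges with the phagocytic
#' pool at the Hill uptake rate against first-order release. Kidney tissue
#' additionally excretes to urine, liver phagocytic cells to feces, and the
#' rest-of-body tissue receives the upper-airway translocation inflow.
#'
#' @param organ One of `"liver"`, `"kidney"`, `"spleen"`, `"rob"`.
#' @param state Named non-negative state vector over [pbtk_states()].
#' @param params A `pbtk_parameters` object.
#' @param t Time since exposure onset, h.
#' @return Named numeric vector `c(cab=, tis=, PCs=)` in ng/h.
#' @export
organ_fluxes <- function(organ, state, params, t) {
  if (!organ %in% .systemic_organs)
    stop("unknown organ: ", organ, call. = FALSE)
  ph <- params$physiological[[organ]]
  ch <- params$chemical[[organ]]
  cab <- state[[paste0("M_", organ, "_cab")]]
  tis <- state[[paste0("M_", organ, "_tis")]]
  pcs <- state[[paste0("M_", organ, "_PCs")]]
  C_art <- state[["M_art"]] / params$physiological$V_art
  C_cab <- cab / ph$V_cab
  perm <- ch$X * ph$Q * (C_cab - tis / (ch$P * ph$V_tis))
  K_up <- hill_uptake_rate(ch$K_max, ch$K_50, ch$n0, t)
  pc_net <- K_up * tis - ch$K_out * pcs

  d_cab <- ph$Q * (C_art - C_cab) - perm
  d_tis <- perm - pc_net
  if (organ == "kidney") d_tis <- d_tis - ch$K_excrete * tis
  if (organ == "rob")
    d_tis <- d_tis + params$respiratory$K_upp_robtis * state[["M_upp"]]
  d_pcs <- pc_net
  if (organ == "liver") d_pcs <- d_pcs - ch$K_excrete * pcs
  c(cab = d_cab, tis = d_tis, PCs = d_pcs)
}

#' Respiratory-tract mass fluxes
#'
#' Net rates of change (ng/h) for the seven respiratory states. The upper
#' airway clears to rest-of-body tissue and feces; the tracheobronchial
#' region receives the mucociliary escalator inflow from alveolar phagocytic
#' cells and clears to feces; the alveolar surface exchanges with the lung
#' interstitium and with its phagocytic pool (Hill uptake); the interstitium
#' exchanges with the lung capillary through the permeability-limited term
#' and with its own phagocytic pool; the lung capillary sits in series in the
#' central circulation, fed by venous blood. Under continuous exposure the
#' inhaled source `EC * BR * 60` ng/h is apportioned to the three entry
#' regions by their deposition fractions while the exposure is active.
#'
#' @param state Named non-negative state vector over [pbtk_states()].
#' @param params A `pbtk_parameters` object.
#' @param scenario A `pbtk_scenario` (bolus scenarios contribute no source
#'   term).
#' @param t Time since exposure onset, h.
#' @return Named numeric vector of rates for `M_upp`, `M_tra`, `M_alv`,
#'   `M_alv_PCs`, `M_lu_tis`, `M_lu_PCs`, `M_lu_cab` in ng/h.
#' @export
respiratory_fluxes <- function(state, params, scenario, t) {
  re <- params$respiratory
  lu <- params$physiological$lung
  src <- source_rate(scenario, t)
  FR <- if (scenario$mode == "continuous") scenario$FR else
    c(upp = 0, tra = 0, alv = 0)

  M_upp <- state[["M_upp"]]; M_tra <- state[["M_tra"]]
  M_alv <- state[["M_alv"]]; M_alv_PCs <- state[["M_alv_PCs"]]
  M_lu_cab <- state[["M_lu_cab"]]; M_lu_tis <- state[["M_lu_tis"]]
  M_lu_PCs <- state[["M_lu_PCs"]]

  d_upp <- src * FR[["upp"]] - re$K_upp_robtis * M_upp -
    re$K_upp_feces * M_upp
  # mucociliary escalator: alveolar PC material is carried INTO the
  # tracheobronchial region, then cleared to feces
  d_tra <- src * FR[["tra"]] + re$K_alvpcs_trach * M_alv_PCs -
    re$K_trach_feces * M_tra

  K_alv_up <- hill_uptake_rate(re$K_alvmax, re$K_alv50, re$n0_alv, t)
  pc_alv <- K_alv_up * M_alv - re$K_alvout * M_alv_PCs
  d_alv_pcs <- pc_alv - re$K_alvpcs_trach * M_alv_PCs

  inter_to_alv <- re$K_inter_alv * M_lu_tis - re$K_alv_inter * M_alv
  d_alv <- src * FR[["alv"]] + inter_to_alv - pc_alv

  perm_lu <- re$X_lu * lu$Q *
    (M_lu_cab / lu$V_cab - M_lu_tis / (re$P_lu * lu$V_tis))
  K_inter_up <- hill_uptake_rate(re$K_inter_max, re$K_inter50, re$n0_inter, t)
  pc_lu <- K_inter_up * M_lu_tis - re$K_interout * M_lu_PCs
  d_lu_tis <- -inter_to_alv + perm_lu - pc_lu
  d_lu_pcs <- pc_lu
  d_lu_cab <- params$physiological$QC *
    (state[["M_ven"]] / params$physiological$V_ven - M_lu_cab / lu$V_cab) -
    perm_lu

  c(M_upp = d_upp, M_tra = d_tra, M_alv = d_alv, M_alv_PCs = d_alv_pcs,
    M_lu_cab = d_lu_cab, M_lu_tis = d_lu_tis, M_lu_PCs = d_lu_pcs)
}

#' Right-hand side of the full PBTK ODE system
#'
#' Assembles the 23 state derivatives: respiratory-tract fluxes, the four
#' systemic organ triplets, the central circulation closure (arterial blood
#' fed by the lung capillary; venous blood collecting all organ capillary
#' outflows; organs in parallel, lung in series) and the cumulative feces and
#' urine sinks. The sum of all components equals the instantaneous external
#' source exactly, so total mass is conserved.
#'
#' @param t Time since exposure onset, h.
#' @param state Named state vector over [pbtk_states()].
#' @param params A `pbtk_parameters` object.
#' @param scenario A `pbtk_scenario`.
#' @return Named numeric vector of 23 derivatives, ng/h.
#' @export
pbtk_rhs <- function(t, state, params, scenario) {
  if (any(!is.finite(state)))
    stop("non-finite state at t = ", t, call. = FALSE)
  d <- stats::setNames(numeric(length(.state_names)), .state_names)
  resp <- respiratory_fluxes(state, params, scenario, t)
  d[names(resp)] <- resp

  ph <- params$physiological
  ven_in <- 0
  for (o in .systemic_organs) {
    fo <- organ_fluxes(o, state, params, t)
    d[[paste0("M_", o, "_cab")]] <- fo[["cab"]]
    d[[paste0("M_", o, "_tis")]] <- fo[["tis"]]
    d[[paste0("M_", o, "_PCs")]] <- fo[["PCs"]]
    ven_in <- ven_in +
      ph[[o]]$Q * state[[paste0("M_", o, "_cab")]] / ph[[o]]$V_cab
  }
  d[["M_art"]] <- ph$QC *
    (state[["M_lu_cab"]] / ph$lung$V_cab - state[["M_art"]] / ph$V_art)
  d[["M_ven"]] <- ven_in - ph$QC * state[["M_ven"]] / ph$V_ven
  d[["M_feces"]] <- params$respiratory$K_upp_feces * state[["M_upp"]] +
    params$respiratory$K_trach_feces * state[["M_tra"]] +
    params$chemical$liver$K_excrete * state[["M_liver_PCs"]]
  d[["M_urine"]] <- params$chemical$kidney$K_excrete * state[["M_kidney_tis"]]
  d
}

#' Mass-balance audit of a simulation
#'
#' Conservation check used as a solver-quality gate: at every grid time the
#' total of all 23 state components (sinks included) must equal the initial
#' total plus the integrated external source. For bolus scenarios the source
#' integral is zero; for continuous scenarios it is
#' `EC * BR * 60 * (FR_upp + FR_tra + FR_alv) * min(t, duration)`.
#'
#' @param result A `pbtk_result` from [run_simulation()].
#' @return Maximum absolute conservation residual over the grid, ng.
#' @export
mass_balance_audit <- function(result) {
  total <- rowSums(result$states)
  sc <- result$scenario
  dosed <- if (sc$mode == "continuous") {
    sc$EC * sc$BR * 60 * sum(sc$FR) * pmin(result$time, sc$duration)
  } else rep(0, length(result$time))
  max(abs(total - total[1] - dosed))
}
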