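#' Generative parameters of a simulated cell
#'
#' Ground-truth parameters of the single-compartment forward model. Free
#' calcium `c` (normalised units) relaxes toward its resting level through
#' two linear clearance pathways attributed to SERCA (ER sequestration,
#' modelled as exchange referenced to the resting level, so blocking it
#' does not change resting calcium) and PMCA (extrusion against a constant
#' inward leak fixed at cell construction, so blocking it raises resting
#' calcium). With nominal rates the two formulations coincide with
#' `dc/dt = -(k_serca + k_pmca) (c - baseline_ca)`. Each action potential
#' adds `influx_per_ap * bath_ca_factor` instantaneously. The indicator
#' binds cooperatively: `db/dt = kon c^hill_n (Btot - b) - koff b`, and
#' noiseless fluorescence is `f_rest + f_gain * b`.
#'
#' Nominal pump rates and bath factor are stored at construction so that
#' reversible manipulations (pH recovery) can restore them exactly; see
#' [apply_condition()].
#'
#' @param baseline_ca resting free calcium, normalised concentration units.
#' @param influx_per_ap calcium increment per action potential (same units).
#' @param k_serca,k_pmca clearance rate constants, 1/s. Their sum must be
#'   positive.
#' @param indicator_kon binding rate, 1/(concentration^hill_n * s).
#' @param indicator_koff unbinding rate, 1/s. Must be positive.
#' @param indicator_total concentration of indicator binding sites.
#' @param hill_n Hill coefficient of binding.
#' @param f_rest fluorescence offset, detector a.u.
#' @param f_gain fluorescence per unit bound indicator, a.u.
#' @param noise_sd per-pixel Gaussian noise standard deviation, a.u.
#' @param bath_ca_factor multiplier on `influx_per_ap` representing bath
#'   calcium (1 = normal 2 mM).
#' @return An object of class `sim_cell_params`.
#' @export
sim_cell_params <- function(baseline_ca = 0.15,
                            influx_per_ap = 0.033,
                            k_serca = 0.20,
                            k_pmca = 0.42,
                            indicator_kon = 1.0,
                            indicator_koff = 0.75,
                            indicator_total = 1,
                            hill_n = 2,
                            f_rest = 411,
                            f_gain = 950,
                            noise_sd = 25,
                            bath_ca_factor = 1) {
  vals <- c(baseline_ca = baseline_ca, influx_per_ap = influx_per_ap,
            k_serca = k_serca, k_pmca = k_pmca,
            indicator_kon = indicator_kon, indicator_koff = indicator_koff,
            indicator_total = indicator_total, hill_n = hill_n,
            f_rest = f_rest, f_gain = f_gain, noise_sd = noise_sd,
            bath_ca_factor = bath_ca_factor)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("sim_cell_params: all rates, concentrations and gains must be finite and >= 0")
  if (k_serca + k_pmca <= 0) stop("sim_cell_params: k_serca + k_pmca must be > 0")
  if (indicator_koff <= 0) stop("sim_cell_params: indicator_koff must be > 0")
  p <- as.list(vals)
  # constant inward leak balancing PMCA extrusion at rest, fixed for the
  # lifetime of the cell (nominal rates)
  p$leak <- k_pmca * baseline_ca
  p$nominal <- list(k_serca = k_serca, k_pmca = k_pmca,
                    bath_ca_factor = bath_ca_factor)
  structure(p, class = "sim_cell_params")
}

#' @export
print.sim_cell_params <- function(x, ...) {
  cat("simulated cell parameters:\n")
  flds <- setdiff(names(x), "nominal")
  cat(paste0("  ", flds, " = ", signif(unlist(x[flds]), 4), collapse = "\n"), "\n")
  invisible(x)
}

.conditions <- c("baseline", "vehicle", "TG", "pH8.8", "pH-recovery",
                 "normal-Ca", "high-Ca", "no-added-Ca")

#' Apply an experimental condition to cell parameters
#'
#' Returns a modified copy of the generative parameters representing a bath
#' manipulation: thapsigargin (`"TG"`) reduces the SERCA clearance rate to
#' `tg_block_fraction` of nominal; raising bath pH to 8.8 (`"pH8.8"`)
#' reduces the PMCA rate to `ph_block_fraction` of nominal;
#' `"pH-recovery"` restores the nominal PMCA rate (pH block is reversible);
#' the bath-calcium conditions set `bath_ca_factor`. `"baseline"` and
#' `"vehicle"` return the parameters unchanged.
#'
#' @param params a [sim_cell_params()] object.
#' @param condition one of `"baseline"`, `"vehicle"`, `"TG"`, `"pH8.8"`,
#'   `"pH-recovery"`, `"normal-Ca"`, `"high-Ca"`, `"no-added-Ca"`.
#' @param tg_block_fraction fraction of SERCA activity remaining under TG.
#' @param ph_block_fraction fraction of PMCA activity remaining at pH 8.8.
#' @param ca_factors named vector of bath-calcium multipliers for the
#'   `normal-Ca`, `high-Ca` and `no-added-Ca` conditions. No added calcium
#'   is a reduction, not zero: some calcium remains in the bath.
#' @return A `sim_cell_params` object.
#' @examples
#' p <- sim_cell_params()
#' identical(apply_condition(apply_condition(p, "pH8.8"), "pH-recovery"), p)
#' @export
apply_condition <- function(params, condition,
                            tg_block_fraction = 0.1,
                            ph_block_fraction = 0.2,
                            ca_factors = c("normal-Ca" = 1.0, "high-Ca" = 2.0,
                                           "no-added-Ca" = 0.1)) {
  stopifnot(inherits(params, "sim_cell_params"))
  if (!is.character(condition) || length(condition) != 1L ||
      !(condition %in% .conditions))
    stop("unknown condition label: ", paste(condition, collapse = ", "))
  p <- params
  switch(condition,
    "baseline" = ,
    "vehicle" = p,
    "TG" = { p$k_serca <- p$nominal$k_serca * tg_block_fraction; p },
    "pH8.8" = { p$k_pmca <- p$nominal$k_pmca * ph_block_fraction; p },
    "pH-recovery" = {
      p$k_pmca <- p$nominal$k_pmca
      p$bath_ca_factor <- p$nominal$bath_ca_factor
      p
    },
    "normal-Ca" = ,
    "high-Ca" = ,
    "no-added-Ca" = {
      p$bath_ca_factor <- unname(ca_factors[[condition]])
      p
    })
}
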