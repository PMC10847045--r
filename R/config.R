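#' Model configuration
#'
#' All physiological, allometric, thermodynamic and numerical constants of the
#' model live in one nested list created by `deb_config()`. Every entry has a
#' literature-scale default; any entry can be overridden by name, and unknown
#' names are rejected so typos cannot silently fall back to defaults.
#'
#' The main groups are:
#' \describe{
#'   \item{chemistry}{`temperature` (K), `solute_density` (g cm^-3, used to
#'     estimate molar volume from molar mass), `viscosity_cP` (water),
#'     `energy_per_electron` (kJ per mol electrons transferred to O2 during
#'     aerobic oxidation; negative).}
#'   \item{allometry}{power laws anchoring the cell model: cell volume
#'     `v_alpha * (G/1e6 bp)^v_beta` (um^3), dry mass `m_alpha * V^m_beta` (g),
#'     total protein volume `p_alpha * V^p_beta` (um^3, sublinear), the shared
#'     reserve/structure biomass formula `composition` (per C-mol), carbon
#'     fraction of dry mass `c_fraction`, and the reserve chemical potential
#'     `mu_E` (kJ per C-mol).}
#'   \item{ribosome}{translation economics: mean protein length `l_P` (bp
#'     equivalents), ribosome length `l_R` (bp), maximum ribosome processing
#'     rate `r_R` (bp h^-1), specific degradation rates `eta`, `phi` (h^-1),
#'     average protein volume `v_P` (um^3) and the ribosome volume scaling
#'     constant `v_R` (dimensionless; calibrated so the ribosome-demand bound
#'     returns a volume comparable to direct ribosome counting).}
#'   \item{translation}{`y_max`, `y_min`: translational yield at 1 and at
#'     `rrn_max` rRNA operon copies (piecewise-linear in log copies).}
#'   \item{thermo}{`dG_block` (kJ per C-mol, building-block conversion),
#'     `dG_syn` and `nu` (dissipation `dG_syn/nu`), `e_porter` (kJ per mol of
#'     transporter proteins synthesized).}
#'   \item{kinetics}{`k2` (s^-1, maximum substrate processing rate per binding
#'     site), `r_p` (m, transporter cross-section radius), `rho_max` (membrane
#'     packing limit for the total porter area fraction).}
#'   \item{maintenance}{`kappa_M` (mol C um^-3 h^-1): basal maintenance flux
#'     per unit cell volume.}
#'   \item{enzyme}{`zX_slope`: linear map from genome-size-normalized glycoside
#'     hydrolase frequency to the constitutive enzyme production coefficient.}
#'   \item{turnover}{density-dependent biomass turnover `gamma0 * B_tot/B_ref`
#'     (h^-1) applied to both reserve and structure.}
#'   \item{closure}{root-finder relative tolerance `tol`, porter-cost fixed
#'     point tolerance `fp_tol` and iteration cap `fp_max_iter`.}
#'   \item{integrator}{`rtol`, `atol` for the stiff ODE solver,
#'     `starvation_overhead` (structure-to-maintenance conversion overhead
#'     multiplier), `growth_rate_floor` (h^-1, below which time points are not
#'     counted as part of the growth curve).}
#'   \item{reporting}{`bp_mode`: `"gross"` counts cumulative reserve and
#'     structural synthesis fluxes as biomass production (turnover losses
#'     remain inside BP and flow to necromass), `"net"` counts the net
#'     biomass increment plus necromass; `r_metric`: statistic of the
#'     instantaneous total-biomass growth rate over the growth curve
#'     (`"median"`, `"mean"` or `"max"`).}
#' }
#'
#' @param ... named overrides; nested groups may be given as named lists,
#'   e.g. `deb_config(kinetics = list(k2 = 90))`.
#' @return A named nested list of class `deb_config`.
#' @examples
#' cfg <- deb_config(thermo = list(dG_block = 120))
#' cfg$thermo$dG_block
#' @export
deb_config <- function(...) {
  defaults <- list(
    chemistry = list(
      temperature = 298.15,
      solute_density = 1.0,
      viscosity_cP = 0.8904,
      energy_per_electron = -119.5
    ),
    allometry = list(
      v_alpha = 0.25, v_beta = 1.0,
      m_alpha = 435e-15, m_beta = 0.86,
      p_alpha = 0.21, p_beta = 0.80,
      composition = c(C = 1, H = 1.8, O = 0.5, N = 0.2),
      c_fraction = 0.47,
      mu_E = 560
    ),
    ribosome = list(
      l_P = 975, l_R = 4566, r_R = 226800,
      eta = 0.02, phi = 0.02,
      v_P = 6e-8, v_R = 0.0143
    ),
    translation = list(y_min = 0.3, y_max = 0.8, rrn_max = 15),
    thermo = list(dG_block = 100, dG_syn = 700, nu = 5, e_porter = 1e6),
    kinetics = list(k2 = 180, r_p = 1e-9, rho_max = 0.25),
    maintenance = list(kappa_M = 5e-17),
    enzyme = list(zX_slope = 1),
    turnover = list(gamma0 = 0.1, B_ref = 0.01),
    closure = list(tol = 1e-8, fp_tol = 1e-6, fp_max_iter = 50),
    integrator = list(
      rtol = 1e-8, atol = 1e-14,
      starvation_overhead = 1.2,
      growth_rate_floor = 1e-4
    ),
    reporting = list(bp_mode = "gross", r_metric = "median")
  )
  cfg <- .merge_config(defaults, list(...), path = "")
  structure(cfg, class = c("deb_config", "list"))
}

.merge_config <- function(base, over, path) {
  if (length(over) == 0) return(base)
  nms <- names(over)
  if (is.null(nms) || any(nms == "")) {
    abort(paste0("config overrides must be named (at '", path, "')"))
  }
  unknown <- setdiff(nms, names(base))
  if (length(unknown)) {
    abort(paste0(
      "unknown config key(s): ",
      paste0(path, unknown, collapse = ", ")
    ))
  }
  for (nm in nms) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(over[[nm]])) {
        abort(paste0("config key '", path, nm, "' must be a named list"))
      }
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]], paste0(path, nm, "$"))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a configuration from YAML
#'
#' Reads a YAML file of overrides and merges it onto [deb_config()] defaults;
#' unknown keys are rejected with the offending key named.
#'
#' @param path path to a YAML file.
#' @return A `deb_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(deb_config, raw)
}

#' Simulation protocol
#'
#' Batch and mixed-medium culture conditions. Defaults reproduce the standard
#' study protocol: substrate at 125 mg C per litre, an inoculum of 10^3 cells
#' per gram of soil (mapped one-to-one to cells per millilitre of medium),
#' split 90% reserve / 10% structural biomass, integrated for 500 h (batch) or
#' 1,500 h (mixed medium, total concentration split evenly across metabolites)
#' or until substrate exhaustion.
#'
#' @param conc_mgC total substrate concentration, mg C per litre.
#' @param inoculum_cells cells per gram soil.
#' @param soil_g_per_l grams of soil equivalent per litre of medium (the
#'   default 1000 maps 1 g soil to 1 ml of solution).
#' @param reserve_fraction fraction of inoculum carbon held as reserve.
#' @param t_batch,t_mixed horizon of batch / mixed runs, h.
#' @param dt output resolution, h.
#' @param depletion_threshold substrate concentration (mol C per litre) at
#'   which a metabolite counts as exhausted and integration stops.
#' @return A named list of class `deb_protocol`.
#' @export
deb_protocol <- function(conc_mgC = 125,
                         inoculum_cells = 1e3,
                         soil_g_per_l = 1000,
                         reserve_fraction = 0.9,
                         t_batch = 500,
                         t_mixed = 1500,
                         dt = 0.5,
                         depletion_threshold = 1e-12) {
  stopifnot(conc_mgC > 0, inoculum_cells >= 0,
            reserve_fraction >= 0, reserve_fraction <= 1,
            t_batch > 0, t_mixed > 0, dt > 0)
  structure(
    list(
      conc_mgC = conc_mgC,
      inoculum_cells = inoculum_cells,
      soil_g_per_l = soil_g_per_l,
      reserve_fraction = reserve_fraction,
      t_batch = t_batch,
      t_mixed = t_mixed,
      dt = dt,
      depletion_threshold = depletion_threshold
    ),
    class = c("deb_protocol", "list")
  )
}
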