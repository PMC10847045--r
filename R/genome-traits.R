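#' Translational yield from rRNA operon copy number
#'
#' rRNA operon copy number is used as a genomic predictor of translational
#' yield `y_VE` (C-mol structure per C-mol reserve mobilized for growth): many
#' operons buy translation speed at the cost of yield. The map is
#' piecewise-linear in `log(rrn)` between `y_max` at one copy and `y_min` at
#' `rrn_max` copies (config group `translation`); copy numbers beyond
#' `rrn_max` saturate at `y_min`.
#'
#' @param rrn_copies integer vector of rRNA operon copies (>= 1).
#' @param config a [deb_config()].
#' @return `y_VE` in `(0, 1]`, monotone decreasing in `rrn_copies`.
#' @examples
#' translational_yield(c(1, 4, 15))
#' @export
translational_yield <- function(rrn_copies, config = deb_config()) {
  if (any(rrn_copies < 1)) abort("rrn_copies must be >= 1")
  tr <- config$translation
  f <- pmin(log(rrn_copies) / log(tr$rrn_max), 1)
  tr$y_max - (tr$y_max - tr$y_min) * f
}

#' Minimum ribosomal volume supporting a growth rate
#'
#' Lower bound on the ribosomal volume required to replicate all proteins and
#' ribosomes within a division cycle at specific growth rate `r`, while also
#' replacing degraded proteins (rate `phi`) and ribosomes (rate `eta`):
#'
#' `V_R = l_P v_P N_P (phi/r + 1) / (v_R (r_R/r - l_R (eta/r + 1)))`
#'
#' The bound is strictly increasing in `r`; growth rates at which the
#' denominator vanishes are infeasible (the ribosome economy cannot replicate
#' itself fast enough) and raise an error.
#'
#' @param r specific growth rate, h^-1 (vectorized).
#' @param N_P total number of proteins in the cell.
#' @param config a [deb_config()]; constants from the `ribosome` group.
#' @return Ribosomal volume in um^3.
#' @export
min_ribosome_volume <- function(r, N_P, config = deb_config()) {
  rb <- config$ribosome
  if (any(r <= 0)) abort("growth rate must be positive")
  denom <- rb$v_R * (rb$r_R / r - rb$l_R * (rb$eta / r + 1))
  if (any(denom <= 0)) {
    abort(paste0(
      "infeasible growth rate: the ribosome economy cannot sustain r = ",
      format(max(r)), " h^-1 (ribosome replication limit ~",
      format((rb$r_R - rb$l_R * rb$eta) / rb$l_R, digits = 3), " h^-1)"
    ))
  }
  rb$l_P * rb$v_P * N_P * (rb$phi / r + 1) / denom
}

#' Reserve turnover rate from translation economics
#'
#' `k_E = r_max V_P / V_R`: the first-order reserve turnover (energy
#' conductance over length) implied by running the ribosome complement at the
#' genome-inferred maximum specific growth rate. Since `V_P >= V_R`,
#' `k_E >= r_max`, making `k_E` the asymptotic ceiling of the realized
#' specific growth rate.
#'
#' @param r_max genome-inferred maximum specific growth rate, h^-1.
#' @param V_P total protein volume, um^3.
#' @param V_R ribosomal volume, um^3 (the minimum feasible volume at `r_max`).
#' @return `k_E` in h^-1.
#' @export
reserve_turnover <- function(r_max, V_P, V_R) {
  stopifnot(all(r_max > 0), all(V_P > 0), all(V_R > 0))
  r_max * V_P / V_R
}

#' Allometric cell model and translation economics for a set of isolates
#'
#' Expands an isolate trait table into the full cell-level parameterization:
#' cell volume from genome size (power law), spherical radius, dry mass,
#' protein and ribosome volumes, protein count, cells per mol biomass C
#' (`lambda_B`, using the configured carbon fraction of dry mass), reserve
#' turnover `k_E`, translational yield `y_VE` (and its inverse `y_EV`), and
#' the volume-proportional basal maintenance coefficient `k_M`.
#'
#' @param isolates isolate trait table; requires columns `isolate_id`,
#'   `genome_size` (bp), `rrn_copies`, and either `r_max` (h^-1) or
#'   `min_gen_time_h`.
#' @param config a [deb_config()].
#' @return The input tibble with columns `r_max`, `V_c`, `L_c`, `r_c`,
#'   `M_dry`, `V_P`, `N_P`, `V_R`, `lambda_B`, `k_E`, `y_VE`, `y_EV`, `k_M`
#'   appended.
#' @examples
#' isolate_geometry(fixture_isolates(n = 3, seed = 1))
#' @export
isolate_geometry <- function(isolates, config = deb_config()) {
  isolates <- as_tibble(isolates)
  req <- c("isolate_id", "genome_size", "rrn_copies")
  missing_cols <- setdiff(req, names(isolates))
  if (length(missing_cols)) {
    abort(paste0("isolate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"r_max" %in% names(isolates)) {
    if (!"min_gen_time_h" %in% names(isolates)) {
      abort("isolate table needs either 'r_max' or 'min_gen_time_h'")
    }
    isolates$r_max <- log(2) / isolates$min_gen_time_h
  }
  if (any(isolates$genome_size <= 0)) abort("genome_size must be positive")
  if (any(isolates$r_max <= 0)) abort("r_max must be positive")
  al <- config$allometry
  out <- isolates |>
    mutate(
      V_c = al$v_alpha * (.data$genome_size / 1e6)^al$v_beta,
      L_c = .data$V_c^(1 / 3),
      r_c = (3 * .data$V_c / (4 * pi))^(1 / 3) * 1e-6,
      M_dry = al$m_alpha * .data$V_c^al$m_beta,
      V_P = al$p_alpha * .data$V_c^al$p_beta,
      N_P = .data$V_P / config$ribosome$v_P,
      V_R = min_ribosome_volume(.data$r_max, .data$N_P, config),
      lambda_B = .const$M_C / (al$c_fraction * .data$M_dry),
      k_E = reserve_turnover(.data$r_max, .data$V_P, .data$V_R),
      y_VE = translational_yield(.data$rrn_copies, config),
      y_EV = 1 / .data$y_VE,
      k_M = maintenance_rate(.data$V_c, .data$lambda_B, config)
    )
  if (any(out$V_R > out$V_P)) {
    abort("configuration error: ribosomal volume exceeds protein volume (V_R > V_P)")
  }
  if (any(out$V_P >= out$V_c)) {
    abort("configuration error: protein volume exceeds cell volume (V_P >= V_c)")
  }
  out
}

#' Cells per mol biomass carbon
#'
#' `lambda_B = M_C / (c_fraction * M_dry)`: the number of cells containing one
#' mol of biomass C, assuming a fixed carbon fraction of dry mass (default
#' 47%).
#'
#' @param M_dry cell dry mass, g.
#' @param c_fraction carbon fraction of dry mass.
#' @return cells per mol C.
#' @examples
#' cells_per_molC(2.5e-13)
#' @export
cells_per_molC <- function(M_dry, c_fraction = 0.47) {
  stopifnot(all(M_dry > 0), c_fraction > 0, c_fraction <= 1)
  .const$M_C / (c_fraction * M_dry)
}
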