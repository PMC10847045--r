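#' Catabolism-anabolism coupling number
#'
#' `lambda = (dG_an + dG_diss) / (-dG_cat)`: how many times the catabolic
#' reaction must run to fund one anabolic turn, i.e. to supply the Gibbs
#' energy of reserve synthesis (`dG_an`) plus the dissipated share
#' (`dG_diss`). All energies per C-mol. Substrates with non-negative `dG_cat`
#' are not viable electron donors and raise an error.
#'
#' @param dG_an anabolic Gibbs energy demand, kJ per C-mol (>= 0 in practice).
#' @param dG_diss dissipation, kJ per C-mol.
#' @param dG_cat catabolic Gibbs energy, kJ per C-mol substrate (< 0).
#' @return Dimensionless coupling number >= 0.
#' @examples
#' coupling_lambda(30, 20, -100) # 0.5
#' @export
coupling_lambda <- function(dG_an, dG_diss, dG_cat) {
  if (any(dG_cat >= 0)) {
    abort("thermodynamic infeasibility: dG_cat must be negative (exergonic catabolism)")
  }
  lam <- (dG_an + dG_diss) / (-dG_cat)
  if (any(lam < 0)) abort("negative coupling number: dG_an + dG_diss < 0")
  lam
}

#' Thermodynamic assimilation yield
#'
#' `y_ED = 1 / (Y_cat + lambda * Y_an)`: C-mol reserve assimilated per mol
#' substrate, given the stoichiometric coefficients of the catabolic and
#' anabolic routes (mol substrate per C-mol reserve) and the coupling number
#' `lambda`. Strictly decreasing in `lambda`.
#'
#' @param Y_cat,Y_an stoichiometric coefficients, mol substrate per C-mol.
#' @param lambda coupling number from [coupling_lambda()].
#' @return `y_ED`, C-mol reserve per mol substrate.
#' @examples
#' assimilation_yield(1, 1, 1) # 0.5
#' @export
assimilation_yield <- function(Y_cat, Y_an, lambda) {
  stopifnot(all(Y_cat > 0), all(Y_an > 0), all(lambda >= 0))
  1 / (Y_cat + lambda * Y_an)
}

#' Synthesis cost of membrane transporters
#'
#' Gibbs energy cost, per C-mol of biomass, of synthesizing the transporter
#' proteins occupying an area fraction `rho_porter` of the cell surface:
#' linear in the biomass-specific binding site count,
#' `e_porter * N(rho_porter)` with `N` from [binding_sites_per_molC()].
#' Zero at `rho_porter = 0`; densities at or above the membrane packing limit
#' are infeasible.
#'
#' @param rho_porter porter area fraction (vectorized).
#' @param r_c cell radius, m.
#' @param M_dry cell dry mass, g.
#' @param config a [deb_config()].
#' @return kJ per C-mol biomass.
#' @export
porter_synthesis_cost <- function(rho_porter, r_c, M_dry,
                                  config = deb_config()) {
  if (any(rho_porter < 0)) abort("rho_porter must be non-negative")
  if (any(rho_porter >= config$kinetics$rho_max)) {
    abort(paste0("rho_porter exceeds the membrane packing limit (",
                 config$kinetics$rho_max, ")"))
  }
  N <- binding_sites_per_molC(rho_porter, r_c, M_dry,
                              r_p = config$kinetics$r_p,
                              c_fraction = config$allometry$c_fraction)
  config$thermo$e_porter * N
}

#' Per-substrate thermodynamic coupling for one consumer
#'
#' Computes, for every substrate in a property table, the stoichiometric
#' coefficients (electron-balance route: the catabolic turn fully oxidizes
#' `1/a` mol substrate per C-mol CO2, the anabolic turn conserves `1/a` mol
#' substrate per C-mol reserve), the coupling number and the assimilation
#' yield `y_ED`, given the consumer's total porter area fraction (whose
#' synthesis cost enters `dG_an`). Per-substrate overrides of `dG_cat_Cmol`
#' or `dG_block` may be supplied as columns of `properties`.
#'
#' @param properties substrate property table from [substrate_properties()].
#' @param rho_total the consumer's total porter area fraction.
#' @param r_c,M_dry consumer cell radius (m) and dry mass (g).
#' @param config a [deb_config()].
#' @return A tibble with columns `name`, `Y_cat`, `Y_an`, `dG_an`, `dG_diss`,
#'   `lambda`, `y_ED`.
#' @export
substrate_thermo <- function(properties, rho_total, r_c, M_dry,
                             config = deb_config()) {
  th <- config$thermo
  dG_block <- if ("dG_block" %in% names(properties)) {
    ifelse(is.na(properties$dG_block), th$dG_block, properties$dG_block)
  } else rep(th$dG_block, nrow(properties))
  dG_rho <- porter_synthesis_cost(rho_total, r_c, M_dry, config)
  dG_an <- dG_block + dG_rho
  dG_diss <- th$dG_syn / th$nu
  lam <- coupling_lambda(dG_an, dG_diss, properties$dG_cat_Cmol)
  Y_cat <- 1 / properties$a
  Y_an <- 1 / properties$a
  y_ED <- assimilation_yield(Y_cat, Y_an, lam)
  if (any(y_ED > properties$a + 1e-12)) {
    abort("assimilation yield exceeds substrate carbon content")
  }
  tibble(
    name = properties$name,
    Y_cat = Y_cat, Y_an = Y_an,
    dG_an = dG_an, dG_diss = dG_diss,
    lambda = lam, y_ED = y_ED
  )
}
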