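#' Read and validate an isolate trait table
#'
#' Reads a CSV/TSV isolate table and validates the schema: required columns
#' `isolate_id`, `genome_size`, `rrn_copies`, one of `r_max` /
#' `min_gen_time_h`, at least one `z_rho_<class>` column, and optional `z_X`
#' and `response_group`. Offending rows are named in errors.
#'
#' @param path CSV or TSV file.
#' @return A validated tibble.
#' @export
read_isolates <- function(path) {
  df <- .read_table(path)
  req <- c("isolate_id", "genome_size", "rrn_copies")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("isolate file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("r_max", "min_gen_time_h") %in% names(df))) {
    abort("isolate file needs 'r_max' or 'min_gen_time_h'")
  }
  zcols <- grep("^z_rho_", names(df), value = TRUE)
  if (!length(zcols)) abort("isolate file lacks z_rho_<class> columns")
  .check_rows(df$genome_size > 0, "non-positive genome_size", df)
  .check_rows(df$rrn_copies >= 1, "rrn_copies < 1", df)
  if ("r_max" %in% names(df)) .check_rows(df$r_max > 0, "non-positive r_max", df)
  if ("min_gen_time_h" %in% names(df)) {
    .check_rows(is.na(df$min_gen_time_h) | df$min_gen_time_h > 0,
                "non-positive min_gen_time_h", df)
  }
  zs <- rowSums(as.matrix(df[zcols]))
  .check_rows(abs(zs - 1) < 1e-6 | zs == 0,
              "z_rho_<class> rows must sum to 1 (or all be 0)", df)
  if ("z_X" %in% names(df)) .check_rows(df$z_X >= 0, "negative z_X", df)
  df
}

#' Read and validate a substrate table
#'
#' Reads a CSV/TSV substrate table (columns `name`, `class`, `formula`,
#' `charge`, optional `molar_mass` and thermodynamic overrides) and parses
#' every formula; unparsable formulas and unknown classes are reported with
#' their row.
#'
#' @param path CSV or TSV file.
#' @return A validated tibble.
#' @export
read_substrates <- function(path) {
  df <- .read_table(path)
  req <- c("name", "class", "formula", "charge")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("substrate file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_chem_formula(df$formula[i]),
             error = function(e) {
               abort(paste0("row ", i, " (", df$name[i], "): ",
                            conditionMessage(e)))
             })
  }
  known <- names(.substrate_templates)
  bad <- which(!df$class %in% known)
  if (length(bad)) {
    abort(paste0("row ", bad[1], ": unknown substrate class '",
                 df$class[bad[1]], "'"))
  }
  if ("molar_mass" %in% names(df)) {
    .check_rows(is.na(df$molar_mass) | df$molar_mass > 0,
                "non-positive molar_mass", df)
  }
  df
}

.read_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

.check_rows <- function(ok, msg, df) {
  if (all(ok)) return(invisible(TRUE))
  abort(paste0(msg, " (row ", paste(which(!ok), collapse = ", "), ")"))
}

#' Write a table to CSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Export consumer parameters as JSON
#'
#' Writes one JSON object per isolate with the closed DEB parameter set
#' (`k_E`, `y_EV`, `k_M`, `zeta_X`, `rho_total`, `lambda_B`, `m_E_star`) and
#' the per-substrate porter allocation and assimilation yields.
#'
#' @param consumers a `deb_consumers` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_consumers <- function(consumers, path) {
  stopifnot(inherits(consumers, "deb_consumers"))
  cc <- consumers$consumers
  objs <- purrr::map(seq_len(nrow(cc)), function(j) {
    list(
      isolate_id = cc$isolate_id[j],
      response_group = if ("response_group" %in% names(cc))
        cc$response_group[j] else NULL,
      k_E = cc$k_E[j], y_VE = cc$y_VE[j], y_EV = cc$y_EV[j],
      k_M = cc$k_M[j], zeta_X = cc$zeta_X[j],
      rho_total = cc$rho_total[j], m_E_star = cc$m_E_star[j],
      lambda_B = cc$lambda_B[j],
      V_c = cc$V_c[j], r_c = cc$r_c[j], M_dry = cc$M_dry[j],
      rho_porter = as.list(setNames(consumers$rho[, j],
                                    rownames(consumers$rho))),
      y_ED = as.list(setNames(consumers$y_ED[, j],
                              rownames(consumers$y_ED)))
    )
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
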