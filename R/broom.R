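#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solubility result
#'
#' @param x a `solubility_result` tibble.
#' @param ... unused.
#' @return A plain tibble, one row per compound x hydration model.
#' @method tidy solubility_result
#' @export
tidy.solubility_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "solubility_result")
  tibble::as_tibble(out)
}

#' Summarize a solubility result in one row
#'
#' @param x a `solubility_result` tibble.
#' @param ... unused.
#' @return A one-row tibble with `n_models`, `n_compounds`, `mae`,
#'   `rmse` and `max_abs_error` of log S0 against the experimental
#'   references (NA when no references are present).
#' @method glance solubility_result
#' @export
glance.solubility_result <- function(x, ...) {
  err <- x$error[!is.na(x$error)]
  tibble::tibble(
    n_models = nrow(x),
    n_compounds = length(unique(x$compound)),
    mae = if (length(err)) mean(abs(err)) else NA_real_,
    rmse = if (length(err)) sqrt(mean(err^2)) else NA_real_,
    max_abs_error = if (length(err)) max(abs(err)) else NA_real_)
}

#' Tidy a sublimation result
#'
#' @param x a `sublimation_result` tibble.
#' @param ... unused.
#' @return A long tibble with columns `term`, `value`, `units`.
#' @method tidy sublimation_result
#' @export
tidy.sublimation_result <- function(x, ...) {
  tibble::tibble(
    term = c("dh_sub", "tds_sub", "dg_sub_std", "dg_sub_star",
             "dh_plus_e_latt", "temperature"),
    value = c(x$dh_sub, x$tds_sub, x$dg_sub_std, x$dg_sub_star,
              x$dh_plus_e_latt, x$temperature),
    units = c(rep("kJ/mol", 5), "K"))
}

#' Summarize a sublimation result in one row
#'
#' @param x a `sublimation_result` tibble.
#' @param ... unused.
#' @return A one-row tibble including `two_rt_deviation`, the gap between
#'   the diagnostic `dh_plus_e_latt` and -2RT (zero when the 2RT
#'   approximation is exact).
#' @method glance sublimation_result
#' @export
glance.sublimation_result <- function(x, ...) {
  tibble::tibble(
    dg_sub_std = x$dg_sub_std,
    dh_sub = x$dh_sub,
    tds_sub = x$tds_sub,
    two_rt_deviation = x$dh_plus_e_latt - (-2 * .rt_kj(x$temperature)),
    temperature = x$temperature)
}
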