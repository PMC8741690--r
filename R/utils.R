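#' Convert HbA1c between IFCC and DCCT units
#'
#' Deterministic conversion between HbA1c in mmol/mol (IFCC) and percent
#' (DCCT/NGSP): \code{percent = mmol_mol / 10.929 + 2.15}.
#'
#' @param mmol_mol HbA1c in mmol/mol.
#' @return HbA1c in percent.
#' @examples
#' hba1c_to_percent(58) # 7.5
#' @export
hba1c_to_percent <- function(mmol_mol) {
  mmol_mol / 10.929 + 2.15
}

#' Format a p value in the package's reporting style
#'
#' Percent-style reporting used in the human-readable report layer:
#' p >= 0.01 to two decimals, 0.001 <= p < 0.01 to three decimals, and
#' p < 0.001 in scientific notation with one significant digit.
#'
#' @param p numeric vector of p values.
#' @return character vector.
#' @export
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi >= 0.01) sprintf("%.2f", pi)
    else if (pi >= 0.001) sprintf("%.3f", pi)
    else sprintf("%.0e", pi)
  }, character(1))
}

# round a proportion to a percentage with 1 decimal (reporting convention)
as_percent <- function(x, digits = 1) round(100 * x, digits)

# linear-interpolation empirical quantile (the type 7 convention, stated
# explicitly because centile thresholds are classification cut-offs)
emp_quantile <- function(x, probs) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
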