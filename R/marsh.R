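#' Weight-scaled Marsh three-compartment propofol parameters
#'
#' Derives the Marsh parameter set used by plasma-targeting TCI pumps for
#' propofol.  The central volume scales with body weight, `V1 = 0.228 * weight`
#' litres; the five first-order rate constants are fixed population values
#' (per minute).  Peripheral volumes follow from the steady-state flux
#' balances `V2 = V1 * k12 / k21` and `V3 = V1 * k13 / k31`.
#'
#' @param weight Body mass in kg; must be a single positive number.
#' @return An object of class `marsh_params`: a list with `weight`, `V1`,
#'   `V2`, `V3` (litres) and rate constants `k10`, `k12`, `k21`, `k13`,
#'   `k31` (1/min).
#' @examples
#' p <- marsh_parameters(80)
#' p$V1            # 18.24 L
#' @export
marsh_parameters <- function(weight) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0) {
    stop("invalid demographics: `weight` must be a single positive number (kg)",
         call. = FALSE)
  }
  p <- list(
    weight = as.numeric(weight),
    V1  = 0.228 * weight,
    k10 = 0.1190,
    k12 = 0.1140,
    k21 = 0.0550,
    k13 = 0.0419,
    k31 = 0.0033
  )
  p$V2 <- p$V1 * p$k12 / p$k21
  p$V3 <- p$V1 * p$k13 / p$k31
  structure(p, class = "marsh_params")
}

#' @export
print.marsh_params <- function(x, ...) {
  cat(sprintf("Marsh 3-compartment parameters (weight %.1f kg)\n", x$weight))
  cat(sprintf("  V1 = %.3f L, V2 = %.3f L, V3 = %.3f L\n", x$V1, x$V2, x$V3))
  cat(sprintf("  k10 = %.4f, k12 = %.4f, k21 = %.4f, k13 = %.4f, k31 = %.4f  [1/min]\n",
              x$k10, x$k12, x$k21, x$k13, x$k31))
  invisible(x)
}
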