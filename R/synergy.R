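## Median-effect dose-response fitting and the Chou-Talalay combination
## index. The median-effect equation fa = 1 / (1 + (Dm/D)^m) linearizes as
## log(fa/(1-fa)) = m*log(D) - m*log(Dm); single agents and fixed-ratio
## combinations are fitted the same way.

#' Fit the median-effect model to dose-response data
#'
#' Least-squares line on log-odds of fraction affected versus log dose:
#' slope is `m`, intercept is `-m * log(Dm)`. Rows with `fa` of exactly 0
#' or 1 are excluded with a warning (their log-odds are infinite), or
#' clipped into `[0.01, 0.99]` when `clip = TRUE`.
#'
#' @param dose dose vector (positive, consistent units)
#' @param fa fraction affected in (0, 1)
#' @param drug_id identifier carried into the result
#' @param clip clip out-of-range `fa` instead of dropping (with a warning)
#' @return a `median_effect_fit`: list with drug_id, Dm, m, r (correlation
#'   of the linear fit), n (usable dose points)
#' @export
fit_median_effect <- function(dose, fa, drug_id = "drug", clip = FALSE) {
  stopifnot(length(dose) == length(fa))
  if (any(dose <= 0)) stop("doses must be positive")
  if (clip) {
    out_of_range <- fa < 0.01 | fa > 0.99
    if (any(out_of_range))
      warning(sum(out_of_range), " fa value(s) clipped into [0.01, 0.99]")
    fa <- pmin(pmax(fa, 0.01), 0.99)
  }
  usable <- fa > 0 & fa < 1
  if (any(!usable))
    warning(sum(!usable), " row(s) with fa of 0 or 1 excluded from the fit")
  dose <- dose[usable]; fa <- fa[usable]
  if (length(dose) < 3)
    stop("median-effect fit needs at least 3 dose points with fa in (0,1)")
  x <- log(dose)
  y <- log(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  Dm <- exp(-unname(coef(fit)[1]) / m)
  r <- if (stats::sd(y) == 0) 1 else unname(cor(x, y))
  structure(list(drug_id = drug_id, Dm = Dm, m = m, r = r,
                 n = length(dose)), class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit [%s]: Dm = %.4g, m = %.4g, r = %.4f (n = %d)\n",
              x$drug_id, x$Dm, x$m, x$r, x$n))
  invisible(x)
}

#' Dose required for a given fraction affected
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit a `median_effect_fit`
#' @param fa effect level(s) in (0, 1)
#' @return dose vector
#' @export
dose_at_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index at fixed effect levels
#'
#' For each effect level `fa`, the combination's total dose producing that
#' effect is computed from `fit_combo` and split into component doses
#' `d1`, `d2` by the fixed dose ratio; `Dx1`, `Dx2` are the single-agent
#' doses producing the same effect. The mutually exclusive form is used:
#' `CI = d1/Dx1 + d2/Dx2` (no interaction term). CI < 1 is called synergy,
#' CI > 1 antagonism (tolerance 1e-8 around 1 for the additive call). The
#' index is invariant to a consistent global change of concentration
#' units.
#'
#' @param fit1,fit2 single-agent `median_effect_fit`s
#' @param fit_combo `median_effect_fit` of the fixed-ratio combination
#'   (doses expressed as total concentration)
#' @param ratio length-2 numeric, the dose proportions of drug 1 and
#'   drug 2 in the combination (e.g. `c(1, 1)` for 50:50)
#' @param fa effect levels (default 0.5, 0.75, 0.9)
#' @return data.frame with fa, d1, d2, Dx1, Dx2, CI, call
#' @export
combination_index <- function(fit1, fit2, fit_combo, ratio = c(1, 1),
                              fa = c(0.5, 0.75, 0.9)) {
  stopifnot(length(ratio) == 2, all(ratio >= 0), sum(ratio) > 0)
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0, 1)")
  total <- dose_at_effect(fit_combo, fa)
  d1 <- total * ratio[1] / sum(ratio)
  d2 <- total * ratio[2] / sum(ratio)
  Dx1 <- dose_at_effect(fit1, fa)
  Dx2 <- dose_at_effect(fit2, fa)
  CI <- d1 / Dx1 + d2 / Dx2
  call <- ifelse(abs(CI - 1) < 1e-8, "additive",
                 ifelse(CI < 1, "synergy", "antagonism"))
  data.frame(fa = fa, d1 = d1, d2 = d2, Dx1 = Dx1, Dx2 = Dx2, CI = CI,
             call = call, stringsAsFactors = FALSE)
}
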