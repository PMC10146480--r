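#' Ascertainment-corrected conversion of heritability to the liability scale
#'
#' Converts heritability of a 0/1 disease label estimated in an ascertained
#' case-control sample to the heritability of the underlying liability in
#' the population (Lee et al. 2011, equation 23):
#' \deqn{h^2_l = h^2_o \; \frac{K(1-K)}{z^2} \; \frac{K(1-K)}{P(1-P)},}
#' where `K` is the population prevalence, `P` the sample case proportion,
#' and `z` the standard normal density at the liability threshold
#' `qnorm(1 - K)`. When `P = K` the ascertainment factor is 1 and the
#' formula reduces to the classic unascertained transform. For a late-onset
#' disease with unscreened young controls, `P` should first be uplifted with
#' [uplift_case_proportion()] to count controls who carry liability but have
#' not yet reached onset.
#'
#' @param h2_obs Observed-scale heritability (non-negative).
#' @param K Population prevalence appropriate for the cases' age, in (0, 1).
#' @param P Sample case proportion (possibly uplifted), in (0, 1).
#' @return Liability-scale heritability.
#' @references Lee SH, Wray NR, Goddard ME, Visscher PM (2011) Estimating
#'   missing heritability for disease from genome-wide association studies.
#'   Am J Hum Genet 88:294-305.
#' @examples
#' observed_to_liability(0.30, K = 0.15, P = uplift_case_proportion(0.56, 0.15))
#' @export
observed_to_liability <- function(h2_obs, K, P) {
  .assert(all(K > 0 & K < 1), "'K' must lie strictly in (0, 1)")
  .assert(all(P > 0 & P < 1), "'P' must lie strictly in (0, 1)")
  .assert(all(h2_obs >= 0), "'h2_obs' must be non-negative")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  h2_obs * (K * (1 - K))^2 / (z^2 * P * (1 - P))
}

#' @rdname observed_to_liability
#' @param h2_liab Liability-scale heritability to convert back to the
#'   observed scale (the algebraic inverse of `observed_to_liability`).
#' @export
liability_to_observed <- function(h2_liab, K, P) {
  .assert(all(K > 0 & K < 1), "'K' must lie strictly in (0, 1)")
  .assert(all(P > 0 & P < 1), "'P' must lie strictly in (0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  h2_liab * (z^2 * P * (1 - P)) / (K * (1 - K))^2
}

#' Uplift the sample case proportion for unscreened controls
#'
#' For late-onset disease, controls far younger than the cases have not yet
#' lived through their risk period: a fraction `f` of them is expected to
#' develop the disease eventually and thus carries case-like genetic
#' liability. The effective case proportion used in the liability transform
#' is therefore \deqn{P_{actual} = P + f (1 - P).}
#'
#' @param P Observed sample case proportion, in (0, 1).
#' @param f Fraction of controls expected to convert, in `[0, 1)`.
#' @return The uplifted case proportion.
#' @examples
#' uplift_case_proportion(0.56, 0.15)  # 0.626
#' @export
uplift_case_proportion <- function(P, f) {
  .assert(all(P > 0 & P < 1), "'P' must lie strictly in (0, 1)")
  .assert(all(f >= 0 & f < 1), "'f' must lie in [0, 1)")
  P + f * (1 - P)
}

#' Liability-threshold specification
#'
#' Bundles the quantities entering the liability-scale conversion: the
#' population prevalence `K`, its threshold `t = qnorm(1 - K)` and density
#' `z = dnorm(t)`, the sample case proportion `P`, an optional
#' control-conversion fraction `f`, and the resulting uplifted proportion.
#'
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1).
#' @param control_conversion Fraction of controls expected to develop the
#'   disease, in `[0, 1)` (default 0).
#' @return An object of class `"liability_spec"`.
#' @export
liability_spec <- function(K, P, control_conversion = 0) {
  .assert(K > 0 && K < 1, "'K' must lie strictly in (0, 1)")
  .assert(P > 0 && P < 1, "'P' must lie strictly in (0, 1)")
  .assert(control_conversion >= 0 && control_conversion < 1,
          "'control_conversion' must lie in [0, 1)")
  t <- stats::qnorm(1 - K)
  structure(list(K = K, P = P, control_conversion = control_conversion,
                 P_actual = uplift_case_proportion(P, control_conversion),
                 t = t, z = stats::dnorm(t)),
            class = "liability_spec")
}

#' @export
print.liability_spec <- function(x, ...) {
  cat(sprintf("liability spec: K = %.4f (t = %.4f, z = %.4f), P = %.4f",
              x$K, x$t, x$z, x$P))
  if (x$control_conversion > 0)
    cat(sprintf(", uplifted P = %.4f (f = %.2f)", x$P_actual,
                x$control_conversion))
  cat("\n")
  invisible(x)
}
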