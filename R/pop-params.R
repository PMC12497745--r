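#' Population parameter set for the clozapine PPK model
#'
#' Bundles the fixed effects, inter-individual variability (IIV) and residual
#' error of the one-compartment oral model with allometric weight scaling and
#' an optional zopiclone effect on apparent clearance. Defaults are the final
#' published model for a 70 kg reference adult: CL/F 29.6 L/h, V/F 308 L,
#' Ka fixed at 1.3 /h, a -25.4% zopiclone effect on clearance, log-scale IIV
#' SD 0.348 on clearance and proportional residual SD 0.257.
#'
#' @param cl_std Typical apparent oral clearance (L/h) at the 70 kg reference.
#' @param v_std Typical apparent volume of distribution (L) at the reference.
#' @param ka First-order absorption rate constant (1/h).
#' @param ka_fixed Logical; treat `ka` as fixed (not estimated). The published
#'   analysis fixes Ka at 1.3 /h because trough-dominated sampling carries
#'   almost no absorption-phase information.
#' @param theta_zop Fractional zopiclone effect on clearance; clearance is
#'   multiplied by `1 + theta_zop * zop`. Must keep that factor positive.
#' @param allo_exp_cl,allo_exp_v Allometric exponents on clearance and volume
#'   (0.75 and 1 by convention).
#' @param omega_cl SD of the log-normal inter-individual variability on
#'   clearance.
#' @param sigma_prop SD of the proportional residual error.
#' @param ref_weight Reference body weight (kg) for the allometric scaling.
#'
#' @return An object of class `clz_pop`, a named list of the above.
#' @examples
#' pop <- pop_params()
#' typical_params(pop, weight = 70, zop = 0)
#' @export
pop_params <- function(cl_std = 29.6,
                       v_std = 308,
                       ka = 1.3,
                       ka_fixed = TRUE,
                       theta_zop = -0.254,
                       allo_exp_cl = 0.75,
                       allo_exp_v = 1,
                       omega_cl = 0.348,
                       sigma_prop = 0.257,
                       ref_weight = 70) {
  stopifnot(
    is.numeric(cl_std), length(cl_std) == 1L,
    is.numeric(v_std), length(v_std) == 1L,
    is.numeric(ka), length(ka) == 1L
  )
  if (cl_std <= 0) stop("`cl_std` must be positive", call. = FALSE)
  if (v_std <= 0) stop("`v_std` must be positive", call. = FALSE)
  if (ka <= 0) stop("`ka` must be positive", call. = FALSE)
  if (omega_cl < 0) stop("`omega_cl` must be non-negative", call. = FALSE)
  if (sigma_prop <= 0) stop("`sigma_prop` must be positive", call. = FALSE)
  if (ref_weight <= 0) stop("`ref_weight` must be positive", call. = FALSE)
  if (1 + theta_zop <= 0) {
    stop("`theta_zop` leaves a non-positive clearance factor for zop = 1",
         call. = FALSE)
  }
  structure(
    list(
      cl_std = cl_std, v_std = v_std, ka = ka, ka_fixed = ka_fixed,
      theta_zop = theta_zop,
      allo_exp_cl = allo_exp_cl, allo_exp_v = allo_exp_v,
      omega_cl = omega_cl, sigma_prop = sigma_prop, ref_weight = ref_weight
    ),
    class = "clz_pop"
  )
}

#' @export
print.clz_pop <- function(x, ...) {
  cat("<clz_pop> clozapine population PK parameters\n")
  cat(sprintf("  CL/F %.4g L/h, V/F %.4g L, Ka %.4g /h%s (ref %g kg)\n",
              x$cl_std, x$v_std, x$ka, if (isTRUE(x$ka_fixed)) " (fixed)" else "",
              x$ref_weight))
  cat(sprintf("  allometric exponents: CL %.3g, V %.3g\n",
              x$allo_exp_cl, x$allo_exp_v))
  cat(sprintf("  theta_zop %.4g (clearance x %.4g under zopiclone)\n",
              x$theta_zop, 1 + x$theta_zop))
  cat(sprintf("  omega_CL %.4g (log-SD), sigma_prop %.4g\n",
              x$omega_cl, x$sigma_prop))
  invisible(x)
}

#' Describe an additional covariate effect on a PK parameter
#'
#' Effects compose multiplicatively after the allometric weight factor.
#' Continuous covariates use a power form `(value / s_m) ^ q` referenced at
#' the population median `s_m`; categorical/binary covariates use the
#' linear-fractional form `1 + q * value`.
#'
#' @param target `"cl"` or `"v"`: which typical parameter the effect scales.
#' @param name Covariate column name (matched in the dataset / covariate set).
#' @param kind `"power"` (continuous) or `"linear"` (categorical fraction).
#' @param q Fitted coefficient.
#' @param s_m Population median of a continuous covariate (required for
#'   `kind = "power"`).
#'
#' @return A `clz_effect` list.
#' @examples
#' covariate_effect("cl", "zop", kind = "linear", q = -0.254)
#' @export
covariate_effect <- function(target = c("cl", "v"), name,
                             kind = c("linear", "power"), q = 0, s_m = NULL) {
  target <- match.arg(target)
  kind <- match.arg(kind)
  if (kind == "power" && (is.null(s_m) || s_m <= 0)) {
    stop("power-form effects need a positive reference median `s_m`",
         call. = FALSE)
  }
  structure(
    list(target = target, name = name, kind = kind, q = q, s_m = s_m),
    class = "clz_effect"
  )
}

# Multiplicative factor contributed by one effect for a covariate value.
effect_factor <- function(effect, value) {
  fac <- switch(effect$kind,
    power = (value / effect$s_m)^effect$q,
    linear = 1 + effect$q * value
  )
  if (any(!is.finite(fac)) || any(fac <= 0)) {
    stop(sprintf(
      "covariate effect '%s' on %s yields a non-positive factor",
      effect$name, effect$target
    ), call. = FALSE)
  }
  fac
}
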