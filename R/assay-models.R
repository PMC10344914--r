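#' Round half away from zero
#'
#' Reported fold-changes use conventional half-up rounding at the
#' requested number of decimals (base R `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fit first-order thermal inactivation
#'
#' Fits the single-exponential inactivation model
#' `E_t = E_0 exp(-k t)` to a residual-activity time course. The default
#' log-linear method regresses `ln(activity)` on time; the nonlinear
#' option fits the exponential directly (useful with noisy tails).
#' Activities are normalized internally to the fitted (or observed) t = 0
#' value, so fractions and percentages are both accepted.
#'
#' @param times incubation times, hours, strictly increasing from 0.
#' @param activities relative activities (> 0 for the log-linear method).
#' @param method `"log_linear"` or `"nonlinear"`.
#' @return object of class `DecayFit`: list with `k` (1/h), `t_half` (h),
#'   `r_squared`, `E0`, `method`, `ok`.
#' @export
fit_inactivation <- function(times, activities,
                             method = c("log_linear", "nonlinear")) {
  method <- match.arg(method)
  if (length(times) < 3L) stop("need at least 3 time points")
  if (length(times) != length(activities)) stop("times/activities mismatch")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (method == "log_linear") {
    if (any(activities <= 0)) {
      stop("non-positive activity; use method = 'nonlinear'")
    }
    fit <- stats::lm(log(activities) ~ times)
    k <- -unname(stats::coef(fit)[2])
    # summary.lm warns on zero-residual (noise-free) data; the SE of 0 and
    # r^2 of 1 it reports are exactly right for that case
    sm <- suppressWarnings(summary(fit))
    se_k <- unname(sm$coefficients[2, "Std. Error"])
    E0 <- exp(unname(stats::coef(fit)[1]))
    r2 <- sm$r.squared
  } else {
    start <- list(E0 = max(activities),
                  k = max(1e-6, (log(max(activities)) -
                                   log(max(min(activities), 1e-12))) /
                            diff(range(times))))
    # scaleOffset makes the convergence test valid on zero-residual data
    fit <- stats::nls(activities ~ E0 * exp(-k * times), start = start,
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    co <- stats::coef(fit)
    k <- unname(co["k"]); E0 <- unname(co["E0"])
    se_k <- unname(suppressWarnings(
      summary(fit))$coefficients["k", "Std. Error"])
    ss_res <- sum(stats::resid(fit)^2)
    ss_tot <- sum((activities - mean(activities))^2)
    r2 <- 1 - ss_res / ss_tot
  }
  ok <- is.finite(k) && k > 0
  if (!ok) warning("fitted rate constant is not positive; fit flagged")
  structure(list(k = k, se_k = se_k,
                 t_half = if (ok) log(2) / k else NA_real_,
                 r_squared = r2, E0 = E0, method = method, ok = ok),
            class = "DecayFit")
}

#' Half-life from a first-order rate constant
#'
#' `t_1/2 = ln 2 / k`.
#'
#' @param k first-order inactivation rate constant, 1/h (> 0).
#' @return half-life in hours.
#' @export
half_life <- function(k) {
  if (!is.finite(k) || k <= 0) stop("k must be a positive finite rate")
  log(2) / k
}

#' Percent crystallinity from DSC enthalpies
#'
#' `crystallinity = (dH_m - dH_c) / dH_ref x 100`, where `dH_m` is the
#' melting enthalpy, `dH_c` the cold-crystallization enthalpy, and
#' `dH_ref` the melting enthalpy of a 100% crystalline PET sample
#' (140.1 J/g). A negative result (cold crystallization exceeding melting)
#' is physically suspect and returned with a warning.
#'
#' @param dH_m melting enthalpy, J/g.
#' @param dH_c cold-crystallization enthalpy, J/g.
#' @param dH_ref reference enthalpy of 100% crystalline PET, J/g.
#' @return percent crystallinity.
#' @export
crystallinity <- function(dH_m, dH_c = 0, dH_ref = 140.1) {
  if (dH_ref <= 0) stop("dH_ref must be positive")
  out <- (dH_m - dH_c) / dH_ref * 100
  if (out < 0) warning("cold-crystallization enthalpy exceeds melting ",
                       "enthalpy; negative crystallinity is physically suspect")
  out
}

#' BHET purity from HPLC peak areas
#'
#' @param bhet_peak_area BHET peak area.
#' @param total_peak_area total peak area (> 0, >= BHET area).
#' @return purity in percent.
#' @export
bhet_purity <- function(bhet_peak_area, total_peak_area) {
  if (total_peak_area <= 0) stop("total peak area must be positive")
  if (bhet_peak_area > total_peak_area) {
    stop("BHET peak area exceeds total peak area")
  }
  bhet_peak_area / total_peak_area * 100
}

# molar masses (g/mol): PET repeat unit (TPA-EG) and BHET
.M_REPEAT <- 192.2
.M_BHET <- 254.24

#' BHET yield of a PET glycolysis reaction
#'
#' Actual recovered BHET mass over the theoretical maximum, where the
#' theoretical BHET mass converts each PET repeat unit (TPA-EG,
#' 192.2 g/mol) into one BHET (254.24 g/mol).
#'
#' @param actual_bhet_mass recovered BHET, g.
#' @param initial_pet_mass PET input, g (> 0).
#' @param M_repeat,M_BHET molar masses, g/mol.
#' @return yield in percent.
#' @export
bhet_yield <- function(actual_bhet_mass, initial_pet_mass,
                       M_repeat = .M_REPEAT, M_BHET = .M_BHET) {
  if (initial_pet_mass <= 0) stop("initial PET mass must be positive")
  theoretical <- initial_pet_mass / M_repeat * M_BHET
  actual_bhet_mass / theoretical * 100
}

#' Theoretical maximum hydrolysis yield
#'
#' Actual molar TPA concentration over the theoretical maximum obtainable
#' from the PET loading: `tpa_mM / (pet_g_per_L / 192.2 x 1000) x 100`.
#'
#' @param tpa_mM measured TPA concentration, mM.
#' @param pet_g_per_L PET loading, g/L (> 0).
#' @param M_repeat repeat-unit molar mass, g/mol.
#' @return yield in percent.
#' @export
theoretical_max_hydrolysis_yield <- function(tpa_mM, pet_g_per_L,
                                             M_repeat = .M_REPEAT) {
  if (pet_g_per_L <= 0) stop("PET concentration must be positive")
  tpa_mM / (pet_g_per_L / M_repeat * 1000) * 100
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of `v = Vmax S / (K_M + S)` with
#' Lineweaver-Burk starting values. When the enzyme concentration is
#' supplied, `k_cat = Vmax / enzyme_conc` and the catalytic efficiency
#' `k_cat / K_M` are reported with delta-method standard errors.
#'
#' @param substrate substrate concentrations, mM (>= 4 distinct levels).
#' @param rates initial rates (units consistent with `Vmax`).
#' @param enzyme_conc optional enzyme concentration for the
#'   `Vmax -> k_cat` conversion.
#' @return object of class `KineticsFit`: list with `K_M`, `Vmax`,
#'   `k_cat`, `efficiency`, `se` (named vector), `converged`, `fit`.
#' @export
fit_michaelis_menten <- function(substrate, rates, enzyme_conc = NULL) {
  if (length(substrate) != length(rates)) stop("substrate/rates mismatch")
  if (length(unique(substrate)) < 4L) {
    stop("need at least 4 distinct substrate levels")
  }
  if (any(substrate <= 0)) stop("substrate concentrations must be positive")
  # Lineweaver-Burk start values, guarded against noisy intercepts
  lb <- stats::lm(I(1 / rates) ~ I(1 / substrate))
  v0 <- 1 / stats::coef(lb)[1]
  k0 <- stats::coef(lb)[2] * v0
  if (!is.finite(v0) || v0 <= 0) v0 <- max(rates)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(substrate)
  fit <- tryCatch(
    stats::nls(rates ~ Vmax * substrate / (K_M + substrate),
               start = list(Vmax = unname(v0), K_M = unname(k0)),
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(K_M = NA_real_, Vmax = NA_real_, k_cat = NA_real_,
                          efficiency = NA_real_, se = c(Vmax = NA, K_M = NA),
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "KineticsFit"))
  }
  co <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  k_cat <- if (!is.null(enzyme_conc)) unname(co["Vmax"]) / enzyme_conc else NA_real_
  vk <- unname(co["Vmax"]) / unname(co["K_M"])
  structure(list(K_M = unname(co["K_M"]), Vmax = unname(co["Vmax"]),
                 k_cat = k_cat,
                 efficiency = if (is.na(k_cat)) vk else k_cat / unname(co["K_M"]),
                 se = c(Vmax = unname(se["Vmax"]), K_M = unname(se["K_M"])),
                 converged = TRUE, fit = fit),
            class = "KineticsFit")
}

#' Fold change of a treatment over a control
#'
#' @param treatment treatment value (e.g. product concentration).
#' @param control control value (> 0).
#' @param digits decimals for half-up rounding (`NULL` = no rounding).
#' @return fold change.
#' @export
fold_change <- function(treatment, control, digits = 1) {
  if (!is.finite(control) || control <= 0) stop("control must be positive")
  fc <- treatment / control
  if (is.null(digits)) fc else round_half_up(fc, digits)
}
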