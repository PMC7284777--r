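#' First-order release model parameters
#'
#' The cumulative drug concentration released from a porous reservoir into
#' a well-stirred bath follows \eqn{c(t) = c_0 + c_s (1 - e^{-t/\tau})}:
#' `c0` is the baseline, `cs` the steady-state concentration increment and
#' `tau` the exponential time constant of the delivery system (the time to
#' reach \eqn{1 - e^{-1} \approx 63.2\%} of the final increment).
#'
#' @param c0 baseline concentration, uM.
#' @param cs steady-state increment, uM (>= 0).
#' @param tau time constant, hours (> 0).
#' @return a list of class `release_model_params`.
#' @export
release_model_params <- function(c0 = 0, cs, tau) {
  stopifnot_scalar_number(c0, "c0")
  stopifnot_scalar_number(cs, "cs", lower = 0)
  stopifnot_scalar_number(tau, "tau", lower = 0, strict_lower = TRUE)
  structure(list(c0 = c0, cs = cs, tau = tau), class = "release_model_params")
}

#' Time-concentration release curve
#'
#' @param times hours, non-negative and strictly increasing.
#' @param concentrations uM, non-negative.
#' @param c_load loading concentration, uM (used by [release_efficiency()]).
#' @param substrate substrate label.
#' @return a list of class `release_curve` with a `data` data.frame
#'   (`time_h`, `conc_uM`).
#' @export
release_curve <- function(times, concentrations, c_load = NA_real_,
                          substrate = NA_character_) {
  if (length(times) != length(concentrations))
    stop("`times` and `concentrations` must have equal length")
  if (any(times < 0)) stop("`times` must be non-negative")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(concentrations < 0)) stop("`concentrations` must be non-negative")
  structure(
    list(data = data.frame(time_h = times, conc_uM = concentrations),
         c_load = c_load, substrate = substrate),
    class = "release_curve"
  )
}

#' Evaluate the first-order release model
#'
#' @param t times, hours (>= 0); vectorised.
#' @param p a [release_model_params()] object.
#' @return concentrations \eqn{c_0 + c_s(1 - e^{-t/\tau})}, uM.
#' @export
first_order_model <- function(t, p) {
  stopifnot(inherits(p, "release_model_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  p$c0 + p$cs * (1 - exp(-t / p$tau))
}

#' Fit the first-order release model to a curve
#'
#' Nonlinear least squares (Levenberg–Marquardt) with bounds `cs >= 0`,
#' `tau > 0`. Initial values: `cs0 = max(c) - min(c)`; `tau0` is the first
#' time the concentration exceeds `c0 + 0.63 * cs0` (falling back to the
#' median observation time). By default `c0` is fixed at 0 — release into
#' pure water starts from a drug-free bath — and can instead be estimated
#' with `fix_c0 = FALSE`.
#'
#' @param curve a [release_curve()] object.
#' @param fix_c0 keep `c0` fixed at `c0_value` instead of fitting it.
#' @param c0_value the fixed baseline, uM.
#' @return list of class `release_fit`: `params`
#'   ([release_model_params()]), `rss`, `converged`, `flag` (`NA` or a
#'   character diagnostic, e.g. for a near-constant curve whose `tau` is
#'   unidentifiable), `n_points`, and `fitted` values.
#' @export
fit_release <- function(curve, fix_c0 = TRUE, c0_value = 0) {
  stopifnot(inherits(curve, "release_curve"))
  tt <- curve$data$time_h
  cc <- curve$data$conc_uM
  n_min <- if (fix_c0) 2 else 3
  if (length(tt) < n_min)
    stop(sprintf("need at least %d time points", n_min))

  cs0 <- max(cc) - min(cc)
  c0_0 <- if (fix_c0) c0_value else min(cc)
  idx <- which(cc > c0_0 + 0.63 * cs0)
  tau0 <- if (length(idx) > 0 && tt[idx[1]] > 0) tt[idx[1]] else median(tt)
  if (tau0 <= 0) tau0 <- max(tt) / 2

  flag <- NA_character_
  if (cs0 <= .Machine$double.eps * max(1, abs(max(cc)))) {
    # constant curve: cs is 0 and tau carries no information
    return(structure(
      list(params = release_model_params(c0 = if (fix_c0) c0_value else cc[1],
                                         cs = 0, tau = tau0),
           rss = sum((cc - mean(cc))^2), converged = TRUE,
           flag = "constant curve: cs = 0, tau unidentifiable",
           n_points = length(tt), fitted = rep(mean(cc), length(tt))),
      class = "release_fit"
    ))
  }

  df <- data.frame(t = tt, c = cc)
  fit <- tryCatch({
    if (fix_c0) {
      minpack.lm::nlsLM(
        c ~ c0_value + cs * (1 - exp(-t / tau)), data = df,
        start = list(cs = max(cs0, 1e-8), tau = tau0),
        lower = c(cs = 0, tau = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        c ~ c0 + cs * (1 - exp(-t / tau)), data = df,
        start = list(c0 = c0_0, cs = max(cs0, 1e-8), tau = tau0),
        lower = c(c0 = -Inf, cs = 0, tau = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(
      list(params = NULL, rss = NA_real_, converged = FALSE,
           flag = paste("fit failed:", conditionMessage(fit)),
           n_points = length(tt), fitted = NULL),
      class = "release_fit"
    ))
  }
  est <- coef(fit)
  params <- release_model_params(
    c0 = if (fix_c0) c0_value else unname(est["c0"]),
    cs = unname(est["cs"]), tau = unname(est["tau"])
  )
  structure(
    list(params = params, rss = sum(resid(fit)^2), converged = TRUE,
         flag = flag, n_points = length(tt),
         fitted = first_order_model(tt, params)),
    class = "release_fit"
  )
}

#' @export
print.release_fit <- function(x, ...) {
  cat("<release_fit>\n")
  if (!is.null(x$params)) {
    cat(sprintf("  c0 = %.4g uM, cs = %.4g uM, tau = %.4g h (v = %.4g uM/h)\n",
                x$params$c0, x$params$cs, x$params$tau, initial_velocity(x$params)))
    cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n_points))
  }
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Initial release velocity
#'
#' Taylor expansion of the release model about \eqn{t = 0} gives, to first
#' order, \eqn{c(t) \approx (c_s/\tau)\, t}: the early-stage release
#' velocity is \eqn{v = c_s / \tau}, identical to the analytic slope
#' \eqn{c'(0)}.
#'
#' @param p a [release_model_params()] object.
#' @return v, uM/h.
#' @export
initial_velocity <- function(p) {
  stopifnot(inherits(p, "release_model_params"))
  p$cs / p$tau
}

#' Release efficiency profile
#'
#' Released concentration normalised to the loading concentration:
#' \eqn{c(t) / c_{load}}, plus the asymptotic efficiency
#' \eqn{c_s / c_{load}} reached as \eqn{t \to \infty}.
#'
#' @param p a [release_model_params()] object.
#' @param c_load loading concentration, uM (> 0).
#' @param times evaluation times, hours.
#' @return list with `profile` (data.frame `time_h`, `efficiency`) and
#'   `asymptotic` (cs / c_load).
#' @export
release_efficiency <- function(p, c_load, times = seq(0, 240, by = 12)) {
  stopifnot(inherits(p, "release_model_params"))
  stopifnot_scalar_number(c_load, "c_load", lower = 0, strict_lower = TRUE)
  list(
    profile = data.frame(time_h = times,
                         efficiency = first_order_model(times, p) / c_load),
    asymptotic = p$cs / c_load
  )
}

#' Drug efficacy from adhering-cell counts
#'
#' Efficacy of drug delivery measured by cell-culture outcome: the fraction
#' of cells suppressed relative to the drug-free control,
#' \eqn{E = 1 - N_{drug} / N_{ctrl}}. Vectorised over paired counts.
#'
#' @param N_drug mean adhering-cell count on the drug-loaded substrate.
#' @param N_ctrl mean count on the same substrate without drug (> 0).
#' @param substrate,time_h optional labels carried into the record.
#' @return data.frame of class `efficacy_record` with columns `substrate`,
#'   `time_h`, `N_drug`, `N_ctrl`, `E`.
#' @export
drug_efficacy <- function(N_drug, N_ctrl, substrate = NA_character_,
                          time_h = NA_real_) {
  if (any(N_ctrl <= 0)) stop("`N_ctrl` must be positive")
  if (any(N_drug < 0)) stop("`N_drug` must be non-negative")
  out <- data.frame(
    substrate = substrate, time_h = time_h,
    N_drug = N_drug, N_ctrl = N_ctrl,
    E = 1 - N_drug / N_ctrl
  )
  class(out) <- c("efficacy_record", class(out))
  out
}

#' Half-life extension afforded by sustained release
#'
#' Compares the active-release duration of the delivery system with a
#' drug's intrinsic elimination half-life: `fold = duration / half_life`
#' and the corresponding percent increase `(fold - 1) * 100`.
#'
#' @param release_duration hours of active release (> 0).
#' @param drug_half_life intrinsic half-life, hours (> 0).
#' @return list `fold`, `percent_increase`.
#' @export
half_life_extension <- function(release_duration, drug_half_life) {
  stopifnot_scalar_number(release_duration, "release_duration", lower = 0,
                          strict_lower = TRUE)
  stopifnot_scalar_number(drug_half_life, "drug_half_life", lower = 0,
                          strict_lower = TRUE)
  fold <- release_duration / drug_half_life
  list(fold = fold, percent_increase = (fold - 1) * 100)
}

#' Round half away from zero
#'
#' Report-table rounding at a fixed number of decimals, with exact halves
#' rounded up in magnitude (0.005 -> 0.01), matching the conventional
#' presentation of "approximately equal" values in publications.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
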