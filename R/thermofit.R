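# Two-state denaturation thermodynamics.
#
# Thermal unfolding (F <-> U) monitored by a spectroscopic signal y(T) with
# sloping linear baselines yF(T) and yU(T):
#   fU = (yF - y) / (yF - yU)         fraction unfolded
#   K  = fU / (1 - fU)                equilibrium constant
#   dG = -R T ln K                    free energy of unfolding (kcal/mol)
#   dG(Tm) = 0 = dHm - Tm dSm         van't Hoff relation at the midpoint
# and the Gibbs-Helmholtz extrapolation
#   dG(T) = dHm (1 - T/Tm) - dCp [(Tm - T) + T ln(T/Tm)].
# Temperatures are Kelvin internally, Celsius at the interface; baselines
# are linear in Celsius. R = 1.987e-3 kcal/(mol K).

#' Construct a melting curve
#'
#' @param temp_C temperature grid, degrees Celsius (strictly increasing for
#'   heating scans).
#' @param signal spectroscopic signal (e.g. molar ellipticity at 222 nm),
#'   arbitrary units.
#' @param direction \code{"heating"} or \code{"cooling"}.
#' @param ph optional pH annotation, carried into fits for variant
#'   comparisons.
#' @return a data frame of class \code{melting_curve}.
#' @export
melting_curve <- function(temp_C, signal, direction = c("heating", "cooling"),
                          ph = NA_real_) {
  direction <- match.arg(direction)
  stopifnot(length(temp_C) == length(signal), length(temp_C) >= 10L,
            all(is.finite(temp_C)), all(is.finite(signal)))
  if (direction == "heating" && any(diff(temp_C) <= 0)) {
    stop("temperature grid must be strictly increasing for a heating scan")
  }
  out <- data.frame(temp_C = temp_C, signal = signal)
  attr(out, "direction") <- direction
  attr(out, "ph") <- ph
  class(out) <- c("melting_curve", "data.frame")
  out
}

# accept melting_curve or any data frame with recognizable columns
as_melting_curve <- function(curve) {
  if (inherits(curve, "melting_curve")) return(curve)
  nm <- names(curve)
  tcol <- intersect(c("temp_C", "temperature_C", "temperature"), nm)[1L]
  ycol <- intersect(c("signal", "y"), nm)[1L]
  if (is.na(tcol) || is.na(ycol)) {
    stop("curve must have temperature and signal columns")
  }
  melting_curve(curve[[tcol]], curve[[ycol]])
}

baseline_eval <- function(bl, temp_C) {
  list(yF = bl$aF + bl$bF * temp_C, yU = bl$aU + bl$bU * temp_C)
}

# two-state van't Hoff signal model (baselines linear in Celsius)
two_state_signal <- function(temp_C, Tm_C, dHm, aF, bF, aU, bU) {
  TK <- celsius_to_kelvin(temp_C)
  TmK <- celsius_to_kelvin(Tm_C)
  K <- exp((dHm / R_KCAL) * (1 / TmK - 1 / TK))
  ((aF + bF * temp_C) + (aU + bU * temp_C) * K) / (1 + K)
}

default_windows <- function(temp_C, frac = 0.15) {
  span <- diff(range(temp_C))
  list(pre = c(min(temp_C), min(temp_C) + frac * span),
       post = c(max(temp_C) - frac * span, max(temp_C)))
}

#' Linearized two-state analysis of a thermal unfolding curve
#'
#' Fits linear folded/unfolded baselines on the pre- and post-transition
#' windows, converts the masked transition points to fraction unfolded,
#' equilibrium constant and free energy, and extracts the midpoint from the
#' linear temperature dependence of dG: Tm is the zero crossing, the slope
#' gives -dSm, and dHm = Tm dSm (van't Hoff).
#'
#' @param curve a \code{melting_curve} (or data frame with
#'   \code{temp_C}/\code{signal} columns).
#' @param pre_window,post_window numeric \code{c(lo, hi)} temperature ranges
#'   (Celsius) for the folded/unfolded baselines; default: the first/last
#'   15 percent of the temperature range.
#' @param fu_mask range of fraction-unfolded values used for the dG fit
#'   (default \code{c(0.15, 0.85)}; extreme fractions amplify baseline
#'   error).
#' @return an object of class \code{stability_analysis}: list with
#'   \code{profile} (per-temperature \code{fU}, \code{fF}, \code{K},
#'   \code{dG_kcal_mol}, \code{in_mask}) and \code{fit} (a
#'   \code{two_state_fit} with \code{Tm_C}, \code{dHm_kcal_mol},
#'   \code{dSm_kcal_mol_K}, baselines, rss).
#' @export
linearized_stability <- function(curve, pre_window = NULL, post_window = NULL,
                                 fu_mask = c(0.15, 0.85)) {
  curve <- as_melting_curve(curve)
  tC <- curve$temp_C; y <- curve$signal
  win <- default_windows(tC)
  if (is.null(pre_window)) pre_window <- win$pre
  if (is.null(post_window)) post_window <- win$post

  pre <- tC >= pre_window[1L] & tC <= pre_window[2L]
  post <- tC >= post_window[1L] & tC <= post_window[2L]
  if (sum(pre) < 3L || sum(post) < 3L) {
    stop("baseline windows must each contain at least 3 points")
  }
  cf <- coef(lm(y[pre] ~ tC[pre]))
  cu <- coef(lm(y[post] ~ tC[post]))
  bl <- list(aF = unname(cf[1L]), bF = unname(cf[2L]),
             aU = unname(cu[1L]), bU = unname(cu[2L]))

  be <- baseline_eval(bl, tC)
  sep <- be$yF - be$yU
  if (any(abs(sep) < 1e-9 * max(abs(y), 1))) {
    stop("degenerate baselines: yF(T) equals yU(T) inside the data range")
  }
  fU <- (be$yF - y) / sep
  in_mask <- fU >= fu_mask[1L] & fU <= fu_mask[2L]
  if (sum(in_mask) < 3L) {
    stop("insufficient transition: fewer than 3 points with fU in [",
         fu_mask[1L], ", ", fu_mask[2L], "]")
  }
  TK <- celsius_to_kelvin(tC)
  K <- fU / (1 - fU)
  dG <- rep(NA_real_, length(tC))
  dG[in_mask] <- -R_KCAL * TK[in_mask] * log(K[in_mask])

  gfit <- lm(dG[in_mask] ~ TK[in_mask])
  slope <- unname(coef(gfit)[2L]); icpt <- unname(coef(gfit)[1L])
  if (!is.finite(slope) || slope >= 0) {
    stop("dG(T) does not decrease with temperature: not a cooperative ",
         "unfolding transition")
  }
  TmK <- -icpt / slope
  dSm <- -slope
  dHm <- TmK * dSm

  profile <- data.frame(temp_C = tC, temp_K = TK, signal = y,
                        yF = be$yF, yU = be$yU, fU = fU, fF = 1 - fU,
                        K = K, dG_kcal_mol = dG, in_mask = in_mask)
  fit <- new_two_state_fit(Tm_C = kelvin_to_celsius(TmK),
                           dHm = dHm, baselines = bl,
                           rss = sum(resid(gfit)^2), method = "linearized",
                           ph = attr(curve, "ph"),
                           n_used = sum(in_mask))
  structure(list(profile = profile, fit = fit), class = "stability_analysis")
}

new_two_state_fit <- function(Tm_C, dHm, baselines, rss, method,
                              ph = NA_real_, n_used = NA_integer_) {
  TmK <- celsius_to_kelvin(Tm_C)
  structure(list(Tm_C = Tm_C, Tm_K = TmK, dHm_kcal_mol = dHm,
                 dSm_kcal_mol_K = dHm / TmK, baselines = baselines,
                 rss = rss, method = method, ph = ph, n_used = n_used),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<two_state_fit> Tm = %.2f C, dHm = %.1f kcal/mol, dSm = %.4f kcal/(mol K) [%s]\n",
    x$Tm_C, x$dHm_kcal_mol, x$dSm_kcal_mol_K, x$method))
  invisible(x)
}

#' Gibbs-Helmholtz free-energy extrapolation
#'
#' Evaluates dG(T) = dHm (1 - T/Tm) - dCp [(Tm - T) + T ln(T/Tm)]. With
#' dCp = 0 (the default throughout the package) this reduces to the van't
#' Hoff line dHm (1 - T/Tm).
#'
#' @param fit a \code{two_state_fit}, or a list with \code{Tm_K} (or
#'   \code{Tm_C}) and \code{dHm_kcal_mol}.
#' @param temp_K temperature(s) at which to evaluate, Kelvin.
#' @param dCp heat-capacity change of unfolding, kcal/(mol K) (default 0).
#' @return dG in kcal/mol.
#' @export
gibbs_helmholtz <- function(fit, temp_K, dCp = 0) {
  stopifnot(all(temp_K > 0))
  TmK <- if (!is.null(fit$Tm_K)) fit$Tm_K else celsius_to_kelvin(fit$Tm_C)
  dHm <- fit$dHm_kcal_mol
  dHm * (1 - temp_K / TmK) -
    dCp * ((TmK - temp_K) + temp_K * log(temp_K / TmK))
}

#' Direct nonlinear two-state fit of a melting curve
#'
#' Six-parameter least squares of
#' y(T) = [yF(T) + yU(T) K(T)] / [1 + K(T)] with
#' K(T) = exp[(dHm/R)(1/Tm - 1/T)] and linear baselines, initialized from
#' the linearized analysis unless starting values are supplied.
#'
#' @param curve a \code{melting_curve}.
#' @param init optional named list of starting values
#'   (\code{Tm_C}, \code{dHm}, \code{aF}, \code{bF}, \code{aU}, \code{bU}).
#' @return a \code{two_state_fit} (method \code{"nls"}). On non-convergence
#'   an error is signalled whose condition carries the linearized fallback
#'   fit in \code{$fallback} when one exists.
#' @export
fit_two_state <- function(curve, init = NULL) {
  curve <- as_melting_curve(curve)
  fallback <- NULL
  if (is.null(init)) {
    lin <- tryCatch(linearized_stability(curve), error = function(e) e)
    if (inherits(lin, "error")) {
      stop("cannot initialize two-state fit (", conditionMessage(lin), ")")
    }
    fallback <- lin$fit
    init <- list(Tm_C = lin$fit$Tm_C, dHm = lin$fit$dHm_kcal_mol,
                 aF = lin$fit$baselines$aF, bF = lin$fit$baselines$bF,
                 aU = lin$fit$baselines$aU, bU = lin$fit$baselines$bU)
  }
  df <- data.frame(tC = curve$temp_C, y = curve$signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_state_signal(tC, Tm_C, dHm, aF, bF, aU, bU),
      data = df, start = init,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error") || !is.finite(sum(coef(fit)))) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else "non-finite fit"
    cond <- structure(
      class = c("two_state_fit_error", "error", "condition"),
      list(message = paste0("two-state fit did not converge: ", msg),
           call = sys.call(-1), fallback = fallback))
    stop(cond)
  }
  cf <- as.list(coef(fit))
  new_two_state_fit(Tm_C = cf$Tm_C, dHm = cf$dHm,
                    baselines = cf[c("aF", "bF", "aU", "bU")],
                    rss = sum(resid(fit)^2), method = "nls",
                    ph = attr(curve, "ph"), n_used = nrow(df))
}

# linear-extrapolation-model signal: linear baselines mixed by the two-state
# fraction unfolded at denaturant concentration cc
lem_signal <- function(cc, Cm, m, aF, bF, aU, bU, RT) {
  fU <- 1 / (1 + exp(m * (Cm - cc) / RT))
  (aF + bF * cc) * (1 - fU) + (aU + bU * cc) * fU
}

#' Chemical denaturation midpoint (linear extrapolation model)
#'
#' Fits y(c) with linear baselines and
#' fU(c) = 1 / (1 + exp[m (Cm - c) / (R T)]), the two-state linear
#' extrapolation model dG(c) = m (Cm - c) at fixed temperature.
#'
#' @param curve data frame with denaturant concentration (\code{conc_M})
#'   and \code{signal} columns.
#' @param temp_K temperature of the experiment, Kelvin (default 298.15).
#' @param init optional starting values (\code{Cm}, \code{m}, \code{aF},
#'   \code{bF}, \code{aU}, \code{bU}).
#' @return an object of class \code{chem_fit}: list with \code{Cm_M},
#'   \code{m_kcal_mol_M}, \code{baselines}, \code{rss}, \code{temp_K}.
#' @export
chem_midpoint <- function(curve, temp_K = 298.15, init = NULL) {
  nm <- names(curve)
  ccol <- intersect(c("conc_M", "conc", "c"), nm)[1L]
  ycol <- intersect(c("signal", "y"), nm)[1L]
  if (is.na(ccol) || is.na(ycol)) {
    stop("curve must have concentration and signal columns")
  }
  cc <- curve[[ccol]]; y <- curve[[ycol]]
  span <- diff(range(y))
  lin <- lm(y ~ cc)
  if (span == 0 || sd(resid(lin)) < 1e-6 * max(abs(y), 1)) {
    stop("no sigmoidal transition in the data (flat or purely linear signal)")
  }
  if (is.null(init)) {
    mid <- (max(y) + min(y)) / 2
    init <- list(Cm = cc[which.min(abs(y - mid))], m = 2,
                 aF = y[1L], bF = 0, aU = y[length(y)], bU = 0)
  }
  RT <- R_KCAL * temp_K
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lem_signal(cc, Cm, m, aF, bF, aU, bU, RT),
      data = data.frame(cc = cc, y = y), start = init,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("chemical denaturation fit did not converge: ",
         conditionMessage(fit))
  }
  cf <- as.list(coef(fit))
  if (cf$Cm < min(cc) || cf$Cm > max(cc)) {
    stop(sprintf("fitted midpoint %.2f M lies outside the data range", cf$Cm))
  }
  structure(list(Cm_M = cf$Cm, m_kcal_mol_M = cf$m,
                 baselines = cf[c("aF", "bF", "aU", "bU")],
                 rss = sum(resid(fit)^2), temp_K = temp_K),
            class = "chem_fit")
}

#' @export
print.chem_fit <- function(x, ...) {
  cat(sprintf("<chem_fit> Cm = %.3f M, m = %.2f kcal/(mol M)\n",
              x$Cm_M, x$m_kcal_mol_M))
  invisible(x)
}

#' Compare the stability of two variants
#'
#' Reports the melting-temperature shift dTm = Tm(mut) - Tm(ref) in Celsius
#' and the stability change ddG = dG(mut, T) - dG(ref, T) in kcal/mol at a
#' common temperature (Gibbs-Helmholtz extrapolation when fits are given).
#' Plain numeric inputs are taken as already-extrapolated dG values at the
#' common temperature.
#'
#' @param ref,mut \code{two_state_fit} objects, or numeric dG values
#'   (kcal/mol).
#' @param temp_C common comparison temperature, Celsius (default 25).
#' @param dCp heat-capacity change passed to [gibbs_helmholtz()].
#' @return list with \code{dTm_C}, \code{ddG_kcal_mol} and \code{temp_C}.
#' @export
compare_variants <- function(ref, mut, temp_C = 25, dCp = 0) {
  TK <- celsius_to_kelvin(temp_C)
  if (is.numeric(ref) && is.numeric(mut)) {
    return(list(dTm_C = NA_real_, ddG_kcal_mol = mut - ref, temp_C = temp_C))
  }
  stopifnot(inherits(ref, "two_state_fit"), inherits(mut, "two_state_fit"))
  if (!identical(is.na(ref$ph), is.na(mut$ph)) ||
      (!is.na(ref$ph) && !is.na(mut$ph) && ref$ph != mut$ph)) {
    warning("variants measured at different pH; dTm/ddG may not be comparable")
  }
  list(dTm_C = mut$Tm_C - ref$Tm_C,
       ddG_kcal_mol = gibbs_helmholtz(mut, TK, dCp) -
         gibbs_helmholtz(ref, TK, dCp),
       temp_C = temp_C)
}
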