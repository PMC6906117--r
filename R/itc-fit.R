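# Nonlinear least-squares fit of the single-site isotherm and cross-ligand
# thermodynamic comparison.

#' Construct a binding fit
#'
#' Container for fitted (or externally reported) single-site thermodynamic
#' parameters. `Kd`, `dG` and `dS` are derived from `Ka`, `dH` and the
#' temperature via [derive_thermodynamics()] unless an explicit `dS_JmolK`
#' is supplied (e.g. a published value); in that case the object records
#' whether the supplied triple is consistent with `dG = dH - T dS/1000`.
#'
#' @param n stoichiometry.
#' @param Ka association constant, l/mol.
#' @param dH_kJmol enthalpy, kJ/mol.
#' @param temperature_K temperature, K.
#' @param ligand ligand name.
#' @param dS_JmolK optional externally reported entropy, J/mol/K.
#' @param se named list of standard errors for free parameters.
#' @param fixed character vector naming fixed parameters.
#' @param rss residual sum of squares (microjoule^2), if fitted.
#' @param converged logical convergence status, if fitted.
#' @param options echoed fit options.
#' @return object of class `binding_fit`.
#' @export
binding_fit <- function(n, Ka, dH_kJmol, temperature_K = 298,
                        ligand = "ligand", dS_JmolK = NULL,
                        se = list(), fixed = character(0), rss = NA_real_,
                        converged = NA, options = list()) {
  der <- derive_thermodynamics(n, Ka, dH_kJmol, temperature_K)
  dS_cons <- TRUE
  if (!is.null(dS_JmolK)) {
    dG_from_triple <- dH_kJmol - temperature_K * dS_JmolK / 1000
    dS_cons <- isTRUE(abs(dG_from_triple - der$dG_kJmol) < 0.1)
  } else {
    dS_JmolK <- der$dS_JmolK
  }
  if (length(fixed) && any(fixed %in% names(se)))
    stop_cavitherm("fixed parameters carry no standard error",
                   "cavitherm_validation_error")
  structure(list(ligand = ligand, n = n, Ka = Ka, dH_kJmol = dH_kJmol,
                 Kd_M = der$Kd_M, dG_kJmol = der$dG_kJmol,
                 dS_JmolK = dS_JmolK, dS_consistent = dS_cons,
                 temperature_K = temperature_K, se = se, fixed = fixed,
                 rss = rss, converged = converged, options = options),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s: Kd = %.3g M, n = %.3g%s, dH = %.4g kJ/mol, dS = %.3g J/mol/K (T = %g K)\n",
              x$ligand, x$Kd_M, x$n,
              if ("n" %in% x$fixed) " (fixed)" else "",
              x$dH_kJmol, x$dS_JmolK, x$temperature_K))
  if (!x$dS_consistent)
    cat("  note: supplied dS is not consistent with dG = dH - T*dS/1000\n")
  invisible(x)
}

# molar ratio X_i/M_i at each injection of a protocol
.molar_ratio <- function(tg) {
  v <- cumsum(tg$injection_volumes_ul) * 1e-6
  cc <- .effective_conc(tg, v)
  cc$X / cc$M
}

#' Fit the single-site binding model to a thermogram
#'
#' Preprocessing subtracts the control heats when present, then drops the
#' first injection (the conventional discard of the diffusion-contaminated
#' first peak) unless `drop_first_injection = FALSE`. The free parameters
#' among (n, Ka, dH) are then estimated by Levenberg-Marquardt least
#' squares, with Ka parameterized on the log scale to preserve positivity.
#' Standard errors come from the Jacobian at the optimum; fixed parameters
#' carry none.
#'
#' Initialization: dH from the mean molar heat of the first two retained
#' injections, n from the molar ratio at the steepest change of the
#' isotherm, Ka from `10 / (M0 * transition width)` in molar-ratio units.
#'
#' @param tg a [thermogram()] with heats.
#' @param fix_n optional value at which the stoichiometry is held fixed.
#' @param drop_first_injection drop injection 1 before fitting (default TRUE).
#' @param weights_sigma_uJ optional per-point standard deviations for
#'   weighted least squares (after preprocessing, same length as retained
#'   injections).
#' @param ligand ligand name recorded in the fit.
#' @return a [binding_fit()].
#' @export
fit_single_site <- function(tg, fix_n = NULL, drop_first_injection = TRUE,
                            weights_sigma_uJ = NULL, ligand = "ligand") {
  stopifnot(inherits(tg, "thermogram"))
  if (is.null(tg$heats_uJ))
    stop_cavitherm("thermogram has no heats", "cavitherm_validation_error")
  heats <- tg$heats_uJ
  if (!is.null(tg$control_heats_uJ))
    heats <- subtract_dilution(heats, tg$control_heats_uJ)
  keep <- seq_along(heats)
  if (drop_first_injection) keep <- keep[-1L]
  if (length(keep) < 3L)
    stop_cavitherm("need at least 3 usable injections",
                   "cavitherm_validation_error")
  h_uJ <- heats[keep]
  if (all(abs(h_uJ) < 1e-12))
    stop_cavitherm("all heats are zero: nothing to fit",
                   "cavitherm_degenerate_data_error")
  dV <- tg$injection_volumes_ul * 1e-6
  molar <- heats * 1e-6 / (tg$syringe_conc_M * dV)   # J/mol injectant
  mh <- molar[keep]
  r <- .molar_ratio(tg)[keep]
  if ((max(mh) - min(mh)) < 1e-3 * max(abs(mh)))
    stop_cavitherm("no detectable transition in the isotherm",
                   "cavitherm_degenerate_data_error")

  # initial values
  dH0 <- mean(mh[1:2]) / 1000                        # kJ/mol
  if (abs(dH0) < 1e-6) dH0 <- sign(mean(mh)) * max(abs(mh)) / 1000
  istar <- which.max(abs(diff(mh)))
  n0 <- min(max((r[istar] + r[istar + 1L]) / 2, 0.2), 5)
  drop_tot <- mh[1L] - mh[length(mh)]
  frac <- if (abs(drop_tot) > 0) (mh[1L] - mh) / drop_tot else rep(0, length(mh))
  mid <- which(frac > 0.2 & frac < 0.8)
  width <- if (length(mid) >= 2L) max(r[mid]) - min(r[mid]) else
    2 * mean(diff(r))
  width <- max(width, 1e-3)
  Ka0 <- min(max(10 / (tg$cell_conc_M * width), 1e2), 1e12)

  fixed <- character(0)
  par0 <- c(logKa = log(Ka0), dH = dH0)
  if (!is.null(fix_n)) fixed <- "n" else par0 <- c(par0, n = n0)

  wts <- if (is.null(weights_sigma_uJ)) rep(1, length(h_uJ)) else {
    if (length(weights_sigma_uJ) != length(h_uJ))
      stop_cavitherm("weights length mismatch", "cavitherm_validation_error")
    1 / weights_sigma_uJ
  }
  protocol <- tg
  resid_fn <- function(p) {
    nn <- if (is.null(fix_n)) p[["n"]] else fix_n
    if (nn <= 0) return(rep(1e6, length(h_uJ)))
    pred <- single_site_model(binding_params(nn, exp(p[["logKa"]]),
                                             p[["dH"]]), protocol)[keep]
    (pred - h_uJ) * wts
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0L, 5L))
    stop_cavitherm(paste("single-site fit did not converge:", fit$message),
                   "cavitherm_fit_failure_error",
                   residuals = fit$fvec)
  p <- coef(fit)
  Ka <- exp(p[["logKa"]])
  n_hat <- if (is.null(fix_n)) p[["n"]] else fix_n
  se <- list()
  cov <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    ses <- sqrt(diag(cov))
    se$Ka <- Ka * ses[["logKa"]]          # delta method from log scale
    se$dH_kJmol <- ses[["dH"]]
    if (is.null(fix_n)) se$n <- ses[["n"]]
  }
  binding_fit(n = n_hat, Ka = Ka, dH_kJmol = p[["dH"]],
              temperature_K = tg$temperature_K, ligand = ligand, se = se,
              fixed = fixed, rss = sum(fit$fvec^2),
              converged = !(fit$info %in% c(0L, 5L)),
              options = list(fix_n = fix_n,
                             drop_first_injection = drop_first_injection))
}

#' Compare ligand thermodynamics against a reference ligand
#'
#' Computes per-ligand enthalpy and entropy differences
#' `ddH = dH_ligand - dH_ref` (kJ/mol) and `ddS = dS_ligand - dS_ref`
#' (J/mol/K), plus the mean ddS over the non-reference ligands.
#'
#' @param reference a [binding_fit()] for the reference ligand.
#' @param others list of [binding_fit()] objects to compare.
#' @return object of class `ligand_comparison` with a `table` data frame
#'   (input order) and `mean_ddS_JmolK`.
#' @export
compare_ligands <- function(reference, others) {
  stopifnot(inherits(reference, "binding_fit"))
  if (inherits(others, "binding_fit")) others <- list(others)
  temps <- vapply(others, function(f) f$temperature_K, 0)
  if (any(abs(temps - reference$temperature_K) > 1e-6))
    stop_cavitherm("all fits must share the same temperature",
                   "cavitherm_validation_error")
  tab <- data.frame(
    ligand = vapply(others, function(f) f$ligand, ""),
    dH_kJmol = vapply(others, function(f) f$dH_kJmol, 0),
    dS_JmolK = vapply(others, function(f) f$dS_JmolK, 0))
  tab$ddH_kJmol <- tab$dH_kJmol - reference$dH_kJmol
  tab$ddS_JmolK <- tab$dS_JmolK - reference$dS_JmolK
  nonref <- tab$ligand != reference$ligand
  structure(list(reference = reference$ligand, table = tab,
                 mean_ddS_JmolK = if (any(nonref))
                   mean(tab$ddS_JmolK[nonref]) else NA_real_,
                 temperature_K = reference$temperature_K),
            class = "ligand_comparison")
}

#' @export
print.ligand_comparison <- function(x, ...) {
  cat(sprintf("<ligand_comparison> reference: %s\n", x$reference))
  print(x$table, row.names = FALSE)
  cat(sprintf("mean ddS over %d ligands: %.3g J/mol/K\n",
              nrow(x$table), x$mean_ddS_JmolK))
  invisible(x)
}
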