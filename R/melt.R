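#' @title Two-state analysis of UV melting profiles
#' @description
#' The melting module treats a strand as either fully folded or fully
#' unfolded with a single temperature-dependent equilibrium constant
#' K(T) = exp(-(dH - T dS/1000) / (R T / 1000)), dH in kcal/mol, dS in
#' cal/(mol K), R = 1.987 cal/(mol K). The folded fraction theta is linked
#' to K through the mass-action law of the stated molecularity:
#' unimolecular K = theta / (1 - theta); self-complementary bimolecular
#' K = theta / (2 cT (1 - theta)^2); non-self-complementary bimolecular
#' (equal strand mixing, both strands at cT/2) K = 2 theta / (cT (1 - theta)^2).
#' Temperatures are carried in Kelvin internally and reported in Celsius.
#' @name melt_thermo
NULL

#' Construct a melting curve
#'
#' @param temperature_C Strictly increasing temperatures, degrees Celsius.
#' @param absorbance Absorbance (AU), same length; increases on melting
#'   (hyperchromicity).
#' @param c_T Total strand concentration, mol/L. Required (> 0) for
#'   bimolecular molecularities.
#' @param molecularity One of [molecularity_levels()] (shorthands accepted).
#' @param wavelength_nm Detection wavelength, typically 250 or 260.
#' @param path_length_mm Cuvette path length.
#' @param replicate_id Free-text replicate label.
#' @return A `melting_curve` object.
#' @export
melting_curve <- function(temperature_C, absorbance, c_T = NA_real_,
                          molecularity = "unimolecular_hairpin",
                          wavelength_nm = 260, path_length_mm = 10,
                          replicate_id = "r1") {
  molecularity <- as_molecularity(molecularity)
  temperature_C <- as.numeric(temperature_C)
  absorbance <- as.numeric(absorbance)
  if (length(temperature_C) != length(absorbance))
    stop("temperature and absorbance must have equal length", call. = FALSE)
  if (length(temperature_C) < 20L)
    stop("a melting curve needs at least 20 points", call. = FALSE)
  if (any(diff(temperature_C) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (molecularity != "unimolecular_hairpin" &&
      (!is.finite(c_T) || c_T <= 0))
    stop("bimolecular models require a strand concentration c_T > 0",
         call. = FALSE)
  structure(
    list(temperature_C = temperature_C, absorbance = absorbance,
         c_T = c_T, molecularity = molecularity,
         wavelength_nm = wavelength_nm, path_length_mm = path_length_mm,
         replicate_id = replicate_id),
    class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %d pts, %.1f-%.1f degC, c_T = %s M, %s\n",
              length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C),
              ifelse(is.na(x$c_T), "NA", format(x$c_T)), x$molecularity))
  invisible(x)
}

# ---- forward model -------------------------------------------------------

#' Two-state folded fraction at temperature T
#'
#' Closed-form solution of the mass-action equilibrium for each
#' molecularity. Bimolecular cases are the numerically stable root of the
#' quadratic in theta: self-complementary theta = 2a / (2a + 1 + sqrt(4a + 1))
#' with a = 2 cT K, non-self theta = b / (b + 1 + sqrt(2b + 1)) with b = cT K.
#'
#' @param T_K Temperature(s), Kelvin.
#' @param dH van't Hoff enthalpy, kcal/mol (negative for folding).
#' @param dS entropy, cal/(mol K).
#' @param molecularity One of [molecularity_levels()].
#' @param c_T Total strand concentration, mol/L (bimolecular only).
#' @return Folded fraction in \[0, 1\], same length as `T_K`.
#' @export
two_state_theta <- function(T_K, dH, dS, molecularity, c_T = NA_real_) {
  molecularity <- as_molecularity(molecularity)
  lnK <- -(dH * 1000 - T_K * dS) / (.R_GAS * T_K)
  if (molecularity == "unimolecular_hairpin")
    return(stats::plogis(lnK))
  if (!is.finite(c_T) || c_T <= 0)
    stop("bimolecular theta requires c_T > 0", call. = FALSE)
  K <- exp(pmin(lnK, 700))
  if (molecularity == "bimolecular_self_complementary") {
    a <- 2 * c_T * K
    2 * a / (2 * a + 1 + sqrt(4 * a + 1))
  } else {
    b <- c_T * K
    b / (b + 1 + sqrt(2 * b + 1))
  }
}

#' Melting temperature implied by (dH, dS) and the molecularity
#'
#' Solves theta = 1/2: unimolecular Tm = 1000 dH / dS; bimolecular from
#' 1/Tm = (R / (1000 dH)) ln(x) + dS / (1000 dH) with x = cT for a
#' self-complementary duplex and x = cT / 4 for a non-self duplex.
#'
#' @inheritParams two_state_theta
#' @return Tm in Kelvin.
#' @export
two_state_tm <- function(dH, dS, molecularity, c_T = NA_real_) {
  molecularity <- as_molecularity(molecularity)
  if (molecularity == "unimolecular_hairpin") return(1000 * dH / dS)
  if (!is.finite(c_T) || c_T <= 0)
    stop("bimolecular Tm requires c_T > 0", call. = FALSE)
  x <- if (molecularity == "bimolecular_self_complementary") c_T else c_T / 4
  1 / ((.R_GAS / (1000 * dH)) * log(x) + dS / (1000 * dH))
}

# ---- derivative Tm -------------------------------------------------------

#' Melting temperature from the first derivative of the profile
#'
#' Smooths dA/dT with a Savitzky-Golay filter (local polynomial; defaults
#' window 11 points, order 3) and returns the temperature of the derivative
#' maximum, refined by quadratic interpolation through the three points
#' around the discrete peak. With `on = "theta"` the derivative is taken on
#' the baseline-corrected folded fraction (maximum of -d theta/dT) instead
#' of raw absorbance.
#'
#' @param curve A [melting_curve()].
#' @param window Savitzky-Golay window length (odd, points).
#' @param order Polynomial order.
#' @param on `"absorbance"` (default) or `"theta"`.
#' @return Tm in degrees Celsius, with attributes `window`/`order`.
#' @export
tm_first_derivative <- function(curve, window = 11L, order = 3L,
                                on = c("absorbance", "theta")) {
  on <- match.arg(on)
  stopifnot(inherits(curve, "melting_curve"))
  tc <- curve$temperature_C
  y <- if (on == "absorbance") curve$absorbance
       else -fit_baselines(curve)$theta
  dt <- diff(tc)
  ts <- mean(dt)
  if (max(abs(dt - ts)) > 0.05 * ts)
    warning("temperature grid is not uniform; derivative uses mean spacing")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  dAdT <- signal::sgolayfilt(y, p = order, n = window, m = 1L, ts = ts)
  edge <- max(2L, (window - 1L) %/% 2L)
  interior <- seq(edge + 1L, length(tc) - edge)
  i <- interior[which.max(dAdT[interior])]
  margin <- max(window, 5L)
  # judge peak prominence against the flank (baseline) derivative level
  nf <- max(5L, round(0.15 * length(interior)))
  flank <- dAdT[c(utils::head(interior, nf), utils::tail(interior, nf))]
  prominence <- dAdT[i] - stats::median(flank)
  scale <- max(stats::mad(flank), 1e-12)
  if (dAdT[i] <= 0 || i <= margin || i > length(tc) - margin ||
      prominence < 5 * scale) {
    # peak absent, indistinct, or pinned near the range edge:
    # monotone/featureless profile, or a transition not contained in the
    # observed window
    stop("no melting transition found inside the temperature range",
         call. = FALSE)
  }
  # quadratic refinement around the discrete maximum
  y3 <- dAdT[(i - 1L):(i + 1L)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  shift <- if (abs(denom) > 0) 0.5 * (y3[1] - y3[3]) / denom else 0
  shift <- max(-1, min(1, shift))
  tm <- tc[i] + shift * ts
  structure(tm, window = window, order = order, on = on)
}

# ---- baselines and folded fraction --------------------------------------

#' Fit linear folded/unfolded baselines and compute the folded fraction
#'
#' Straight lines are fitted to a low-temperature (folded) and a
#' high-temperature (unfolded) window; by default the coolest and hottest
#' 15% of points. The folded fraction is
#' theta(T) = (A_u(T) - A(T)) / (A_u(T) - A_f(T)), clipped to \[0, 1\];
#' because pairing is hypochromic the unfolded baseline lies above the
#' folded one and theta decreases with temperature.
#'
#' @param curve A [melting_curve()].
#' @param frac Fraction of points in each baseline window.
#' @param folded_window,unfolded_window Optional explicit temperature
#'   ranges `c(lo, hi)` in degrees Celsius overriding `frac`.
#' @return List with `baselines` (folded/unfolded slope+intercept),
#'   `theta` (folded fraction per point) and the window index vectors.
#' @export
fit_baselines <- function(curve, frac = 0.15,
                          folded_window = NULL, unfolded_window = NULL) {
  stopifnot(inherits(curve, "melting_curve"))
  tc <- curve$temperature_C
  A <- curve$absorbance
  n <- length(tc)
  idx_f <- if (is.null(folded_window)) seq_len(max(3L, floor(frac * n)))
           else which(tc >= folded_window[1] & tc <= folded_window[2])
  idx_u <- if (is.null(unfolded_window)) seq(n - max(3L, floor(frac * n)) + 1L, n)
           else which(tc >= unfolded_window[1] & tc <= unfolded_window[2])
  if (length(idx_f) < 2L || length(idx_u) < 2L)
    stop("baseline windows must contain at least 2 points each", call. = FALSE)
  cf <- stats::coef(stats::lm(A[idx_f] ~ tc[idx_f]))
  cu <- stats::coef(stats::lm(A[idx_u] ~ tc[idx_u]))
  A_f <- cf[1] + cf[2] * tc
  A_u <- cu[1] + cu[2] * tc
  gap <- A_u - A_f
  mid <- gap[seq(floor(n * 0.25), ceiling(n * 0.75))]
  if (max(abs(gap)) < 1e-6 * max(abs(A), 1) || stats::median(mid) <= 0)
    stop("degenerate baselines: unfolded baseline does not lie above the folded baseline",
         call. = FALSE)
  if (any(gap <= 0))
    warning("baselines cross inside the temperature range; theta clipped")
  theta <- pmin(1, pmax(0, (A_u - A) / gap))
  list(
    baselines = list(
      folded = c(intercept = unname(cf[1]), slope = unname(cf[2])),
      unfolded = c(intercept = unname(cu[1]), slope = unname(cu[2]))),
    theta = theta, idx_folded = idx_f, idx_unfolded = idx_u)
}

# ---- thermo_params container --------------------------------------------

new_thermo_params <- function(dH, dS, molecularity, c_T = NA_real_,
                              se = c(dH = NA_real_, dS = NA_real_,
                                     dG298 = NA_real_, Tm_C = NA_real_),
                              method = "unknown", flags = character(0)) {
  dG298 <- dH - .T_REF * dS / 1000
  Tm_K <- tryCatch(two_state_tm(dH, dS, molecularity, c_T),
                   error = function(e) NA_real_)
  structure(
    list(dH = dH, dS = dS, dG298 = dG298,
         Tm_C = kelvin_to_celsius(Tm_K),
         se = se, molecularity = molecularity, c_T = c_T,
         method = method, flags = flags),
    class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  fmt <- function(v, s) if (is.finite(s)) sprintf("%.1f +/- %.1f", v, s)
                        else sprintf("%.1f", v)
  cat(sprintf(
    "<thermo_params> [%s, %s]\n  dH    = %s kcal/mol\n  dS    = %s cal/(mol K)\n  dG298 = %s kcal/mol\n  Tm    = %s degC\n",
    x$method, x$molecularity,
    fmt(x$dH, x$se[["dH"]]), fmt(x$dS, x$se[["dS"]]),
    fmt(x$dG298, x$se[["dG298"]]), fmt(x$Tm_C, x$se[["Tm_C"]])))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# ---- van't Hoff fit ------------------------------------------------------

#' van't Hoff fit of a single melting curve
#'
#' Two-stage least squares. Stage one estimates linear baselines from the
#' coolest/hottest windows ([fit_baselines()]) and start values for
#' (dH, dS) from a linearized van't Hoff regression of ln K(theta) against
#' 1/T over the transition region. Stage two refines all six parameters --
#' both baselines and (dH, dS) -- against the raw absorbance profile
#' A(T) = A_f(T) theta + A_u(T) (1 - theta), which removes the bias that
#' fixed baseline windows pick up from transition tails and makes the fit
#' an exact inverse of the forward model on noise-free data.
#'
#' @param curve A [melting_curve()].
#' @param frac,folded_window,unfolded_window Passed to [fit_baselines()]
#'   for the stage-one baseline estimate.
#' @param refine_baselines Set `FALSE` to keep the stage-one baselines
#'   fixed and fit (dH, dS) against theta only.
#' @return A `thermo_params` object (dH, dS, dG298, Tm with standard errors).
#' @export
van_t_hoff_fit <- function(curve, frac = 0.15,
                           folded_window = NULL, unfolded_window = NULL,
                           refine_baselines = TRUE) {
  stopifnot(inherits(curve, "melting_curve"))
  bl <- fit_baselines(curve, frac = frac, folded_window = folded_window,
                      unfolded_window = unfolded_window)
  theta <- bl$theta
  tc <- curve$temperature_C
  T_K <- celsius_to_kelvin(tc)
  A <- curve$absorbance
  mol <- curve$molecularity
  c_T <- curve$c_T

  # start values: linearized van't Hoff on the transition region
  use <- which(theta > 0.05 & theta < 0.95)
  if (length(use) < 5L)
    stop("melting transition not resolved: fewer than 5 points with 0.05 < theta < 0.95",
         call. = FALSE)
  th <- theta[use]
  lnK_obs <- switch(mol,
    unimolecular_hairpin = log(th / (1 - th)),
    bimolecular_self_complementary = log(th / (2 * c_T * (1 - th)^2)),
    bimolecular_nonself = log(2 * th / (c_T * (1 - th)^2)))
  lin <- stats::lm(lnK_obs ~ I(1 / T_K[use]))
  dH0 <- -stats::coef(lin)[[2]] * .R_GAS / 1000
  dS0 <- stats::coef(lin)[[1]] * .R_GAS
  if (!is.finite(dH0) || dH0 >= 0) { dH0 <- -60; dS0 <- -170 }

  fit <- tryCatch({
    if (refine_baselines) {
      bf <- bl$baselines$folded; bu <- bl$baselines$unfolded
      df <- data.frame(T_K = T_K, tc = tc, A = A)
      minpack.lm::nlsLM(
        A ~ melt_profile_model(T_K, tc, dH, dS, af, mf, au, mu, mol, c_T),
        data = df,
        start = list(dH = dH0, dS = dS0,
                     af = bf[["intercept"]], mf = bf[["slope"]],
                     au = bu[["intercept"]], mu = bu[["slope"]]),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      df <- data.frame(T_K = T_K, theta = theta)
      minpack.lm::nlsLM(
        theta ~ two_state_theta(T_K, dH, dS, mol, c_T),
        data = df, start = list(dH = dH0, dS = dS0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }},
    error = function(e)
      stop(sprintf(
        "van't Hoff fit failed to converge (start dH=%.1f, dS=%.1f): %s",
        dH0, dS0, conditionMessage(e)), call. = FALSE))
  est <- stats::coef(fit)[c("dH", "dS")]
  V <- tryCatch(suppressWarnings(stats::vcov(fit)[1:2, 1:2]),
                error = function(e) matrix(NA_real_, 2, 2))
  se_dH <- sqrt(V[1, 1]); se_dS <- sqrt(V[2, 2])
  # dG298 = dH - T dS/1000, Tm via delta method on the closed form
  g <- c(1, -.T_REF / 1000)
  se_dG <- sqrt(drop(t(g) %*% V %*% g))
  tm_fun <- function(p) two_state_tm(p[1], p[2], mol, c_T)
  gr <- tryCatch(numeric_grad(tm_fun, est), error = function(e) c(NA, NA))
  se_tm <- sqrt(drop(t(gr) %*% V %*% gr))
  new_thermo_params(est[["dH"]], est[["dS"]], mol, c_T,
                    se = c(dH = se_dH, dS = se_dS, dG298 = se_dG,
                           Tm_C = se_tm),
                    method = "vant_hoff_curve")
}

# full absorbance profile: baselines mixed by the two-state folded fraction
melt_profile_model <- function(T_K, tc, dH, dS, af, mf, au, mu, mol, c_T) {
  th <- two_state_theta(T_K, dH, dS, mol, c_T)
  (af + mf * tc) * th + (au + mu * tc) * (1 - th)
}

numeric_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# ---- Tm vs concentration regression -------------------------------------

#' Thermodynamics from the concentration dependence of Tm
#'
#' For bimolecular duplexes, regresses 1/Tm on ln(cT)
#' (self-complementary) or ln(cT/4) (non-self-complementary):
#' slope = R / (1000 dH), intercept = dS / (1000 dH). Standard errors are
#' propagated from the regression coefficients by the delta method.
#'
#' @param Tm_K Melting temperatures, Kelvin (>= 3 distinct concentrations).
#' @param c_T Total strand concentrations, mol/L.
#' @param molecularity A bimolecular tag; unimolecular input is an error
#'   (hairpin Tm does not depend on concentration).
#' @param weights Optional regression weights.
#' @return A `thermo_params` object (`Tm_C` is reported at the median
#'   concentration).
#' @export
tm_concentration_fit <- function(Tm_K, c_T, molecularity, weights = NULL) {
  molecularity <- as_molecularity(molecularity)
  if (molecularity == "unimolecular_hairpin")
    stop("Tm is concentration-independent for a unimolecular hairpin; ",
         "the concentration fit applies to bimolecular duplexes only",
         call. = FALSE)
  if (length(Tm_K) != length(c_T)) stop("Tm_K and c_T lengths differ")
  if (length(Tm_K) < 3L)
    stop("at least 3 (Tm, c_T) points are required", call. = FALSE)
  x <- if (molecularity == "bimolecular_self_complementary") log(c_T)
       else log(c_T / 4)
  if (length(unique(signif(x, 12))) < 2L)
    stop("rank-deficient regression: concentrations are not distinct",
         call. = FALSE)
  fit <- if (is.null(weights)) stats::lm(I(1 / Tm_K) ~ x)
         else stats::lm(I(1 / Tm_K) ~ x, weights = weights)
  vcov_lm <- function(f) suppressWarnings(stats::vcov(f))
  cf <- stats::coef(fit)
  slope <- cf[[2]]; intercept <- cf[[1]]
  flags <- character(0)
  if (slope >= 0) {
    warning("non-negative 1/Tm vs ln(c) slope implies dH >= 0; flagged non-two-state")
    flags <- "non_two_state"
  }
  dH <- .R_GAS / (1000 * slope)
  dS <- 1000 * dH * intercept        # = R * intercept / slope
  V <- vcov_lm(fit)                  # (intercept, slope)
  # delta method: dH = R/(1000 s); dS = R i / s
  J <- rbind(dH = c(0, -.R_GAS / (1000 * slope^2)),
             dS = c(.R_GAS / slope, -.R_GAS * intercept / slope^2))
  Vp <- J %*% V %*% t(J)
  g <- c(1, -.T_REF / 1000)
  se_dG <- sqrt(drop(t(g) %*% Vp %*% g))
  cmid <- stats::median(c_T)
  tm_fun <- function(p) two_state_tm(p[1], p[2], molecularity, cmid)
  gr <- numeric_grad(tm_fun, c(dH, dS))
  se_tm <- sqrt(drop(t(gr) %*% Vp %*% gr))
  new_thermo_params(dH, dS, molecularity, cmid,
                    se = c(dH = sqrt(Vp[1, 1]), dS = sqrt(Vp[2, 2]),
                           dG298 = se_dG, Tm_C = se_tm),
                    method = "tm_vs_concentration", flags = flags)
}

# ---- derived quantities --------------------------------------------------

#' Gibbs energy from enthalpy and entropy
#'
#' dG(T) = dH - T dS / 1000 (dH kcal/mol, dS cal/(mol K), T Kelvin).
#'
#' @param params A `thermo_params` object, or a numeric dH (with `dS`).
#' @param dS Entropy if `params` is numeric.
#' @param T_K Evaluation temperature, default 298.15 K.
#' @return Gibbs energy, kcal/mol.
#' @export
#' @examples
#' delta_g(-79.7, -212)   # -16.5 kcal/mol at 298.15 K
delta_g <- function(params, dS = NULL, T_K = 298.15) {
  if (inherits(params, "thermo_params")) {
    dH <- params$dH; dS <- params$dS
  } else {
    dH <- params
    if (is.null(dS)) stop("supply dS when giving dH as a number")
  }
  dH - T_K * dS / 1000
}

#' Stability change of a modified strand relative to its reference
#'
#' @param mod,ref `thermo_params` objects (modified and reference strand).
#' @return Named numeric: `dTm_C` = Tm(mod) - Tm(ref) and
#'   `ddG298` = dG298(mod) - dG298(ref).
#' @export
compare_to_reference <- function(mod, ref) {
  stopifnot(inherits(mod, "thermo_params"), inherits(ref, "thermo_params"))
  c(dTm_C = mod$Tm_C - ref$Tm_C, ddG298 = mod$dG298 - ref$dG298)
}

#' Aggregate replicate thermodynamic fits
#'
#' Per-parameter mean with a 95% confidence half-width computed as
#' t(0.975, n-1) * sd / sqrt(n) over the replicates (the plain replicate
#' standard deviation is available with `interval = "sd"`). Single fits
#' carry no interval and raise a warning.
#'
#' @param fits List of `thermo_params` replicate fits.
#' @param interval `"ci95"` (default) or `"sd"`.
#' @return List with `mean` (a `thermo_params`), `half_width` named vector,
#'   `n`, and `interval`.
#' @export
aggregate_replicates <- function(fits, interval = c("ci95", "sd")) {
  interval <- match.arg(interval)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "thermo_params")))
  n <- length(fits)
  grab <- function(fld) vapply(fits, function(f) f[[fld]], numeric(1))
  vals <- list(dH = grab("dH"), dS = grab("dS"),
               dG298 = grab("dG298"), Tm_C = grab("Tm_C"))
  mu <- vapply(vals, mean, numeric(1))
  if (n == 1L) {
    warning("single replicate: no confidence interval")
    hw <- c(dH = NA_real_, dS = NA_real_, dG298 = NA_real_, Tm_C = NA_real_)
  } else {
    sdv <- vapply(vals, stats::sd, numeric(1))
    hw <- if (interval == "ci95")
      stats::qt(0.975, df = n - 1) * sdv / sqrt(n) else sdv
  }
  mp <- new_thermo_params(mu[["dH"]], mu[["dS"]],
                          fits[[1]]$molecularity, fits[[1]]$c_T,
                          se = c(dH = hw[["dH"]], dS = hw[["dS"]],
                                 dG298 = hw[["dG298"]], Tm_C = hw[["Tm_C"]]),
                          method = sprintf("replicate_mean(n=%d,%s)", n,
                                           interval))
  list(mean = mp, half_width = hw, n = n, interval = interval)
}
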