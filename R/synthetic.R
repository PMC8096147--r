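#' @title Synthetic raw-data generators
#' @description
#' Each generator is the exact forward model of the corresponding fitting
#' routine, plus optional Gaussian noise: sigmoidal two-state melting
#' profiles on sloping linear baselines with hypochromicity, CLEANEX-PM
#' build-ups on the standard twelve-point mixing-time schedule,
#' single-site titration shift curves, and idealized planar base pairs
#' with waters at exact requested distances. With the noise set to zero,
#' fit-then-generate is the identity to solver tolerance, which is the
#' package's central self-consistency check. All generators are
#' deterministic for a fixed seed.
#' @name synthetic_data
NULL

#' Default synthetic melting baselines
#'
#' Folded baseline slope +0.0003 AU/degC from 0.95 AU, unfolded slope
#' +0.0005 AU/degC from 1.14 AU at 0 degC (20% hyperchromicity), typical
#' of RNA UV melts at 260 nm.
#'
#' @return List with folded/unfolded `c(intercept, slope)`.
#' @export
default_baselines <- function() {
  list(folded = c(intercept = 0.95, slope = 3e-4),
       unfolded = c(intercept = 1.14, slope = 5e-4))
}

#' The five standard strand concentrations
#'
#' Log-spaced 1 to 100 micromolar, mol/L.
#' @return Numeric vector of 5 concentrations.
#' @export
default_concentrations <- function() c(1, 3, 10, 30, 100) * 1e-6

#' Generate two-state melting curves
#'
#' A(T) = A_f(T) theta(T) + A_u(T) (1 - theta(T)) + N(0, sigma^2) with
#' theta from the molecularity-specific mass-action solution
#' ([two_state_theta()]). `sigma_frac` scales the noise to the baseline
#' gap (transition amplitude) at the melting temperature.
#'
#' @param dH,dS Generator truth, kcal/mol and cal/(mol K).
#' @param molecularity One of [molecularity_levels()].
#' @param c_T Concentrations, mol/L; one curve per value (ignored for a
#'   hairpin unless supplied, where it only labels the curve).
#' @param t_range Temperature range, degC.
#' @param t_step Grid step, degC.
#' @param baselines As [default_baselines()].
#' @param sigma_frac Gaussian noise sd as a fraction of the transition
#'   amplitude (0 = noise-free).
#' @param seed Integer seed (noise reproducibility).
#' @param replicate_id Replicate label stamped on each curve.
#' @return List of [melting_curve()] objects, one per concentration.
#' @export
gen_melting_curve <- function(dH, dS, molecularity,
                              c_T = default_concentrations(),
                              t_range = c(20, 90), t_step = 0.5,
                              baselines = default_baselines(),
                              sigma_frac = 0, seed = NULL,
                              replicate_id = "sim") {
  molecularity <- as_molecularity(molecularity)
  if (molecularity == "unimolecular_hairpin" && length(c_T) == 0)
    c_T <- NA_real_
  tc <- seq(t_range[1], t_range[2], by = t_step)
  T_K <- celsius_to_kelvin(tc)
  bf <- baselines$folded; bu <- baselines$unfolded
  A_f <- bf[["intercept"]] + bf[["slope"]] * tc
  A_u <- bu[["intercept"]] + bu[["slope"]] * tc
  make <- function(cc) {
    th <- two_state_theta(T_K, dH, dS, molecularity, cc)
    tm_K <- two_state_tm(dH, dS, molecularity, cc)
    if (tm_K < min(T_K) + 2 || tm_K > max(T_K) - 2)
      stop(sprintf("transition center (%.1f degC) outside temperature grid",
                   kelvin_to_celsius(tm_K)), call. = FALSE)
    amp <- (bu[["intercept"]] + bu[["slope"]] * kelvin_to_celsius(tm_K)) -
           (bf[["intercept"]] + bf[["slope"]] * kelvin_to_celsius(tm_K))
    A <- A_f * th + A_u * (1 - th)
    if (sigma_frac > 0)
      A <- A + stats::rnorm(length(A), 0, sigma_frac * amp)
    melting_curve(tc, A, c_T = cc, molecularity = molecularity,
                  replicate_id = replicate_id)
  }
  gen <- function() lapply(c_T, make)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a CLEANEX-PM build-up series
#'
#' Pointwise [buildup_model()] values on the mixing-time schedule plus
#' Gaussian noise; duplicated mixing times are produced as listed and act
#' as genuine repeats.
#'
#' @param k,R1A Generator truth, 1/s.
#' @param R1_water Water relaxation rate, 1/s (default 1/3.03).
#' @param schedule Mixing times, s (default [cleanex_schedule()]).
#' @param sigma Gaussian noise sd on I/I0 (0 = noise-free).
#' @param seed Integer seed.
#' @param residue_label Label for the series.
#' @return A [cleanex_series()].
#' @export
gen_cleanex_series <- function(k, R1A = 20, R1_water = 1 / 3.03,
                               schedule = cleanex_schedule(),
                               sigma = 0, seed = NULL,
                               residue_label = "sim imino") {
  mu <- buildup_model(schedule, k, R1A, R1_water)
  gen <- function() {
    y <- if (sigma > 0) mu + stats::rnorm(length(mu), 0, sigma) else mu
    cleanex_series(schedule, y, residue_label = residue_label,
                   R1_water = R1_water)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a saturation-recovery series
#'
#' M(t) = M0 (1 - exp(-t/T1)) plus Gaussian noise.
#'
#' @param T1 Longitudinal relaxation time, s.
#' @param M0 Plateau intensity.
#' @param delay Recovery delays, s.
#' @param sigma Noise sd; `seed` as elsewhere.
#' @param seed Integer seed.
#' @return List with `delay` and `intensity`.
#' @export
gen_saturation_recovery <- function(T1, M0 = 1,
                                    delay = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12),
                                    sigma = 0, seed = NULL) {
  mu <- M0 * (1 - exp(-delay / T1))
  gen <- function() {
    y <- if (sigma > 0) mu + stats::rnorm(length(mu), 0, sigma) else mu
    list(delay = delay, intensity = y)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a pH titration series
#'
#' [titration_model()] on a pH grid plus Gaussian shift noise.
#'
#' @param pKa,delta_prot,delta_deprot Generator truth.
#' @param pH pH grid (default 10 points spanning pKa +/- 2, clipped to
#'   the measurable range 0..14).
#' @param sigma Shift noise sd, ppm.
#' @param seed Integer seed.
#' @param nucleus Label.
#' @return A [titration_series()].
#' @export
gen_titration <- function(pKa, delta_prot, delta_deprot,
                          pH = seq(max(0, pKa - 2), min(14, pKa + 2),
                                   length.out = 10),
                          sigma = 0, seed = NULL, nucleus = "C2") {
  if (diff(range(pH)) < 2)
    stop("pH grid must span at least 2 units", call. = FALSE)
  mu <- titration_model(pH, pKa, delta_prot, delta_deprot)
  gen <- function() {
    y <- if (sigma > 0) mu + stats::rnorm(length(mu), 0, sigma) else mu
    titration_series(pH, y, nucleus = nucleus)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# idealized planar base-pair coordinates (Angstrom, z = 0 plane);
# minor-groove face points toward negative y
.toy_pair_atoms <- function(preset, deaza3) {
  pur_res <- switch(preset, AU = "A", GC = "G")
  pyr_res <- switch(preset, AU = "U", GC = "C")
  if (deaza3) pur_res <- paste0("C3", pur_res)  # residue name e.g. C3A
  pur <- rbind(
    N1  = c(0.00,  0.00), C2 = c(-0.40, -1.30),
    N3  = c(0.30, -2.45), C4 = c(1.65, -2.35),
    C5  = c(2.35, -1.15), C6 = c(1.40,  0.05),
    N9  = c(2.65, -3.45), `C1'` = c(3.15, -4.75),
    `O2'` = c(4.50, -5.15))
  pyr <- rbind(
    N3  = c(2.85,  0.95), C2 = c(3.45, -0.25),
    O2  = c(2.95, -1.35), N1 = c(4.80, -0.35),
    C4  = c(3.55,  2.15), C6 = c(5.50,  0.80),
    `C1'` = c(5.55, -1.55), `O2'` = c(6.90, -1.25))
  # the pyrimidine ring sits across the pair axis; shift it outward
  pyr[, 1] <- pyr[, 1] + 0.9
  mk <- function(m, resname, resno) {
    nm <- rownames(m)
    if (deaza3 && resname == pur_res) nm[nm == "N3"] <- "C3"
    data.frame(
      element = substr(nm, 1, 1), atom_name = nm,
      residue_name = resname, residue_number = resno, chain = "A",
      x = m[, 1], y = m[, 2], z = 0, occupancy = 1, altloc = "",
      is_water = FALSE, stringsAsFactors = FALSE)
  }
  rbind(mk(pur, pur_res, 2670L), mk(pyr, pyr_res, 2650L))
}

#' Generate an idealized base pair with placed waters
#'
#' Builds a planar toy Watson-Crick pair (purine residue 2670, pyrimidine
#' residue 2650, minor-groove face toward negative y) and adds water
#' oxygens at exact requested distances from named anchor atoms. With
#' `deaza3 = TRUE` the purine N3 becomes the C3 carbon of a
#' 3-deazapurine. Waters closer than 1.5 Angstrom to any solute atom are
#' rejected as clashes. The model round-trips through
#' [write_structure_pdb()] / [read_structure()].
#'
#' @param preset `"AU"` or `"GC"`.
#' @param waters List of placements, each
#'   `list(anchor = "N3", distance = 2.8, direction = c(0, -1, 0))`;
#'   `direction` defaults to straight down the minor groove (0, -1, 0).
#' @param deaza3 Replace the purine N3 nitrogen by a C3 carbon.
#' @param path Optional output path; if given the model is also written
#'   as PDB.
#' @return A `structure_model`.
#' @export
gen_toy_base_pair <- function(preset = c("AU", "GC"), waters = list(),
                              deaza3 = FALSE, path = NULL) {
  preset <- match.arg(preset)
  atoms <- .toy_pair_atoms(preset, deaza3)
  wnum <- 3000L
  for (w in waters) {
    anchor <- atoms[atoms$atom_name == w$anchor & !atoms$is_water, ]
    if (nrow(anchor) == 0L)
      stop("water anchor atom not found: ", w$anchor, call. = FALSE)
    anchor <- anchor[1L, ]
    dirv <- if (!is.null(w$direction)) w$direction else c(0, -1, 0)
    dirv <- dirv / sqrt(sum(dirv^2))
    pos <- c(anchor$x, anchor$y, anchor$z) + w$distance * dirv
    dmin <- min(sqrt((atoms$x - pos[1])^2 + (atoms$y - pos[2])^2 +
                     (atoms$z - pos[3])^2))
    if (dmin < 1.5)
      stop(sprintf("water placement clashes (%.2f A to nearest atom)", dmin),
           call. = FALSE)
    wnum <- wnum + 1L
    atoms <- rbind(atoms, data.frame(
      element = "O", atom_name = "O", residue_name = "HOH",
      residue_number = wnum, chain = "W",
      x = pos[1], y = pos[2], z = pos[3],
      occupancy = 1, altloc = "", is_water = TRUE,
      stringsAsFactors = FALSE))
  }
  rownames(atoms) <- NULL
  model <- new_structure_model(atoms,
                               source_id = paste0("toy_", preset,
                                                  if (deaza3) "_c3" else ""))
  if (!is.null(path)) write_structure_pdb(model, path)
  model
}
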