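#' @title Nucleobase pKa from NMR pH titrations and base-pair pKa gaps
#' @description
#' A single-site protonation equilibrium shifts an observed carbon
#' resonance between its protonated and deprotonated end points following
#' delta_obs = (delta_deprot * 10^(pH - pKa) + delta_prot) / (1 + 10^(pH - pKa)).
#' Fitting pH-dependent chemical shifts to this curve yields the site pKa.
#' The module also carries the reference pKa table for the purine N1 /
#' pyrimidine N3 sites of A, G, U, C and their 3- and 7-deaza analogues,
#' and computes the donor-acceptor pKa gap of each Watson-Crick pair -- the
#' quantity whose near-optimal value of about 5.4-5.5 for natural A-U and
#' G-C pairs is eroded (c3A-U) or overshot (c3G-C) by 3-deazapurines.
#' @name pka
NULL

#' Construct a titration series
#'
#' @param pH pH values (within 0..14).
#' @param shift Chemical shifts, ppm.
#' @param nucleus Label of the reporter nucleus, e.g. "C2" or "C6".
#' @return A `titration_series` object.
#' @export
titration_series <- function(pH, shift, nucleus = "C2") {
  pH <- as.numeric(pH); shift <- as.numeric(shift)
  if (length(pH) != length(shift)) stop("pH and shift lengths differ")
  if (length(pH) < 5L)
    stop("a titration series needs at least 5 points", call. = FALSE)
  if (any(pH < 0 | pH > 14)) stop("pH outside [0, 14]", call. = FALSE)
  structure(list(pH = pH, shift = shift, nucleus = nucleus),
            class = "titration_series")
}

#' Single-site titration curve
#'
#' @param pH pH value(s).
#' @param pKa Site pKa.
#' @param delta_prot Chemical shift of the protonated species, ppm.
#' @param delta_deprot Chemical shift of the deprotonated species, ppm.
#' @return Observed shift, ppm.
#' @export
#' @examples
#' titration_model(11.3, 12.3, 110, 105)  # 109.545 ppm
titration_model <- function(pH, pKa, delta_prot, delta_deprot) {
  r <- 10^(pH - pKa)
  (delta_deprot * r + delta_prot) / (1 + r)
}

#' Fit a pKa from a pH titration
#'
#' Least-squares estimation of (pKa, delta_prot, delta_deprot) with
#' covariance-derived standard errors. A fitted pKa outside the sampled pH
#' window by more than one unit is reported but flagged "extrapolated".
#' A flat series (indistinguishable end points) is unidentifiable and
#' raises an error, as do biphasic-looking data via fit failure; multi-site
#' titrations are out of scope and should be split by the caller.
#'
#' @param series A [titration_series()].
#' @return A `pka_fit`: pKa, delta_prot, delta_deprot, se (named vector),
#'   flags, nucleus.
#' @export
fit_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  pH <- series$pH; y <- series$shift
  if (diff(range(y)) < 1e-9)
    stop("flat titration series: end-point shifts coincide, pKa unidentifiable",
         call. = FALSE)
  o <- order(pH)
  d_lo <- mean(y[o][seq_len(min(2L, length(y)))])          # acid side
  d_hi <- mean(y[o][seq(length(y) - 1L, length(y))])       # basic side
  mid <- (d_lo + d_hi) / 2
  pKa0 <- pH[which.min(abs(y - mid))]
  df <- data.frame(pH = pH, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ titration_model(pH, pKa, dp, dd), data = df,
                      start = list(pKa = pKa0, dp = d_lo, dd = d_hi),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("titration fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  flags <- character(0)
  if (est[["pKa"]] < min(pH) - 1 || est[["pKa"]] > max(pH) + 1)
    flags <- "extrapolated"
  structure(
    list(pKa = est[["pKa"]], delta_prot = est[["dp"]],
         delta_deprot = est[["dd"]],
         se = c(pKa = unname(se[1]), delta_prot = unname(se[2]),
                delta_deprot = unname(se[3])),
         flags = flags, nucleus = series$nucleus),
    class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("<pka_fit> %s: pKa = %.2f", x$nucleus, x$pKa))
  if (is.finite(x$se[["pKa"]])) cat(sprintf(" +/- %.2f", x$se[["pKa"]]))
  cat(sprintf("  (delta_prot %.2f, delta_deprot %.2f ppm)\n",
              x$delta_prot, x$delta_deprot))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Reference pKa values of nucleobases and deaza analogues
#'
#' Protonation/deprotonation sites in the Watson-Crick context: the pKa of
#' the protonated cation at purine N1 / cytosine N3 (the H-bond acceptor
#' side) and of the neutral imino site U N3-H / G(-analogue) N1-H (the
#' donor side).
#'
#' @return data.frame with columns `base`, `site`, `role`
#'   (donor/acceptor) and `pKa`.
#' @export
pka_reference_table <- function() {
  data.frame(
    base = c("A", "c3A", "c7A", "U", "G", "c3G", "c7G", "C"),
    site = c("N1(H+)", "N1(H+)", "N1(H+)", "N3-H",
             "N1-H", "N1-H", "N1-H", "N3(H+)"),
    role = c("acceptor", "acceptor", "acceptor", "donor",
             "donor", "donor", "donor", "acceptor"),
    pKa  = c(3.7, 6.8, 5.3, 9.2, 9.5, 12.3, 10.3, 4.1),
    stringsAsFactors = FALSE)
}

#' Donor-acceptor pKa gap
#'
#' @param donor_pKa pKa of the H-bond donor site (e.g. U N3-H).
#' @param acceptor_pKa pKa of the protonated acceptor site (e.g. A N1-H+).
#' @return donor_pKa - acceptor_pKa.
#' @export
#' @examples
#' delta_pka_gap(9.2, 3.7)  # 5.5 for the A-U pair
delta_pka_gap <- function(donor_pKa, acceptor_pKa) donor_pKa - acceptor_pKa

#' pKa gaps for all Watson-Crick purine-pyrimidine pairs in the table
#'
#' Pairs every purine (and deaza analogue) with its pyrimidine partner
#' (A-type with U, G-type with C) and reports the donor-acceptor gap. For
#' A-type pairs the donor is U N3-H and the acceptor the (deaza)adenine
#' N1; for G-type pairs the donor is the (deaza)guanine N1-H and the
#' acceptor cytosine N3.
#'
#' @param table Override of [pka_reference_table()] (same columns).
#' @return data.frame: pair, donor, acceptor, pKa_donor, pKa_acceptor, gap.
#' @export
base_pair_gaps <- function(table = pka_reference_table()) {
  get_pka <- function(b) {
    i <- match(b, table$base)
    if (is.na(i)) stop("base not in pKa table: ", b, call. = FALSE)
    table$pKa[i]
  }
  a_type <- c("A", "c3A", "c7A")
  g_type <- c("G", "c3G", "c7G")
  rows <- rbind(
    data.frame(pair = paste0(a_type, "-U"),
               donor = "U", acceptor = a_type,
               pKa_donor = get_pka("U"),
               pKa_acceptor = vapply(a_type, get_pka, numeric(1)),
               stringsAsFactors = FALSE),
    data.frame(pair = paste0(g_type, "-C"),
               donor = g_type, acceptor = "C",
               pKa_donor = vapply(g_type, get_pka, numeric(1)),
               pKa_acceptor = get_pka("C"),
               stringsAsFactors = FALSE))
  rows$gap <- delta_pka_gap(rows$pKa_donor, rows$pKa_acceptor)
  rownames(rows) <- NULL
  rows
}

#' Fraction of a site protonated at a given pH
#'
#' Henderson-Hasselbalch: 1 / (1 + 10^(pH - pKa)).
#'
#' @param pKa Site pKa.
#' @param pH pH value(s).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' protonated_fraction(6.8, 7.0)  # ~0.387: c3A partially protonated at pH 7
protonated_fraction <- function(pKa, pH) 1 / (1 + 10^(pH - pKa))
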