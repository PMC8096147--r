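#' @title Workflow runners and report assembly
#' @description
#' Thin front ends that tie the analysis stages into complete runs driven
#' by a configuration list (or YAML file): melting thermodynamics with a
#' reference comparison, per-residue CLEANEX exchange tables, pKa fits with
#' the base-pair gap report, structure superposition plus hydration, and a
#' simulator that writes every raw-data type. Each runner writes a
#' machine-readable JSON report (and the resolved configuration beside it)
#' when an output directory is configured, and returns the report
#' invisibly, so the same functions serve interactive use and scripted
#' pipelines.
#' @name cli_io
NULL

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  config
}

write_report <- function(report, config, out_dir, stem) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  jsonlite::write_json(config, file.path(out_dir,
                                         paste0(stem, "_config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

read_melt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "absorbance")
  if (!all(need %in% names(df)))
    stop("melting CSV needs columns temperature_C, absorbance: ", path,
         call. = FALSE)
  if (!"replicate" %in% names(df)) df$replicate <- "r1"
  if (!"concentration_M" %in% names(df)) df$concentration_M <- NA_real_
  df
}

#' Run the melting-thermodynamics workflow
#'
#' Configuration keys: `sequences` -- a named list where each entry has
#' `files` (long-format CSVs with temperature_C, absorbance and optional
#' replicate / concentration_M columns) and `molecularity`; optional
#' `reference` (name of the reference sequence for dTm/ddG columns),
#' `out_dir`. Each (file, replicate, concentration) trace is fitted by
#' [van_t_hoff_fit()] (with [tm_first_derivative()] Tm alongside);
#' replicates are aggregated with a 95% t-interval. When a sequence has
#' three or more concentrations, a [tm_concentration_fit()] over the
#' per-curve derivative Tm values is reported as an independent path; the
#' report states which method produced each number.
#'
#' @param config List or YAML path.
#' @return Report list (per-sequence table and method notes), invisibly.
#' @export
run_melt <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$sequences) || !length(config$sequences))
    stop("run_melt config needs a non-empty `sequences` list", call. = FALSE)
  fits <- list()
  for (nm in names(config$sequences)) {
    sq <- config$sequences[[nm]]
    mol <- as_molecularity(sq$molecularity)
    traces <- list()
    for (f in sq$files) {
      df <- read_melt_csv(f)
      for (key in unique(paste(df$replicate, df$concentration_M))) {
        sub <- df[paste(df$replicate, df$concentration_M) == key, ]
        traces[[length(traces) + 1L]] <- melting_curve(
          sub$temperature_C, sub$absorbance,
          c_T = sub$concentration_M[1], molecularity = mol,
          replicate_id = as.character(sub$replicate[1]))
      }
    }
    if (!length(traces)) stop("no melting traces for ", nm, call. = FALSE)
    per_curve <- lapply(traces, van_t_hoff_fit)
    tm_deriv <- vapply(traces, function(tr)
      as.numeric(tm_first_derivative(tr)), numeric(1))
    agg <- aggregate_replicates(per_curve)
    conc <- vapply(traces, function(tr) tr$c_T, numeric(1))
    conc_fit <- NULL
    if (mol != "unimolecular_hairpin" &&
        length(unique(conc[is.finite(conc)])) >= 3L) {
      keep <- is.finite(conc)
      conc_fit <- tm_concentration_fit(celsius_to_kelvin(tm_deriv[keep]),
                                       conc[keep], mol)
    }
    fits[[nm]] <- list(aggregate = agg, conc_fit = conc_fit,
                       tm_deriv_C = tm_deriv)
  }
  ref_name <- config$reference
  rows <- lapply(names(fits), function(nm) {
    mp <- fits[[nm]]$aggregate$mean
    row <- data.frame(
      sequence = nm, n_curves = fits[[nm]]$aggregate$n,
      Tm_C = round(mean(fits[[nm]]$tm_deriv_C), 1),
      dTm_C = NA_real_,
      dG298 = round(mp$dG298, 1), dG298_ci = round(mp$se[["dG298"]], 1),
      dH = round(mp$dH, 1), dH_ci = round(mp$se[["dH"]], 1),
      dS = round(mp$dS, 0), dS_ci = round(mp$se[["dS"]], 0),
      method = if (is.null(fits[[nm]]$conc_fit)) "vant_hoff_curve"
               else "vant_hoff_curve+tm_vs_concentration",
      stringsAsFactors = FALSE)
    row
  })
  table <- do.call(rbind, rows)
  if (!is.null(ref_name)) {
    if (!ref_name %in% table$sequence) {
      warning("reference sequence '", ref_name,
              "' not found; dTm column left empty")
    } else {
      ref_tm <- table$Tm_C[table$sequence == ref_name]
      table$dTm_C <- round(table$Tm_C - ref_tm, 1)
    }
  }
  report <- list(table = table,
                 concentration_fits = lapply(fits, function(f)
                   if (is.null(f$conc_fit)) NULL else
                     list(dH = f$conc_fit$dH, dS = f$conc_fit$dS,
                          dG298 = f$conc_fit$dG298,
                          flags = f$conc_fit$flags)))
  write_report(report, config, config$out_dir, "melt_report")
  invisible(report)
}

#' Run the CLEANEX exchange-rate workflow
#'
#' Configuration keys: `file` (CSV with columns tau_mix_s and either
#' rel_intensity or intensity_cleanex + intensity_reference, plus an
#' optional residue column), `R1_water` (1/s), `n_mc` (default 1000),
#' `seed`, `out_dir`.
#'
#' @param config List or YAML path.
#' @return Report list with the per-residue table, invisibly.
#' @export
run_cleanex <- function(config) {
  config <- read_run_config(config)
  df <- utils::read.csv(config$file, stringsAsFactors = FALSE)
  if (!"tau_mix_s" %in% names(df))
    stop("CLEANEX CSV needs a tau_mix_s column", call. = FALSE)
  if (!"rel_intensity" %in% names(df)) {
    if (!all(c("intensity_cleanex", "intensity_reference") %in% names(df)))
      stop("CLEANEX CSV needs rel_intensity or intensity_cleanex + intensity_reference",
           call. = FALSE)
    df$rel_intensity <- df$intensity_cleanex / df$intensity_reference
  }
  if (!"residue" %in% names(df)) df$residue <- "imino"
  R1w <- config$R1_water %||% (1 / 3.03)
  n_mc <- config$n_mc %||% 1000L
  rows <- lapply(split(df, df$residue), function(sub) {
    fit <- fit_exchange(cleanex_series(sub$tau_mix_s, sub$rel_intensity,
                                       residue_label = sub$residue[1],
                                       R1_water = R1w))
    fit <- monte_carlo_errors(fit, n = n_mc, seed = config$seed)
    data.frame(residue = sub$residue[1],
               k = fit$k, k_err = fit$k_err,
               R1A = fit$R1A, R1A_err = fit$R1A_err,
               n_mc = fit$n_mc,
               flags = paste(fit$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 R1_water = R1w)
  write_report(report, config, config$out_dir, "cleanex_report")
  invisible(report)
}

#' Run the pKa titration workflow
#'
#' Configuration keys: `file` (CSV with pH, shift_ppm and optional nucleus
#' column; fitted separately per nucleus), optional `joint = TRUE` for an
#' additional shared-pKa fit across nuclei, `out_dir`. The report always
#' includes the built-in Watson-Crick pKa-gap table
#' ([base_pair_gaps()]), overridable via a `pka_table` config entry
#' (list of base/site/role/pKa records).
#'
#' @param config List or YAML path.
#' @return Report list with fit and gap tables, invisibly.
#' @export
run_pka <- function(config) {
  config <- read_run_config(config)
  fit_rows <- NULL
  if (!is.null(config$file)) {
    df <- utils::read.csv(config$file, stringsAsFactors = FALSE)
    if (!all(c("pH", "shift_ppm") %in% names(df)))
      stop("pKa CSV needs columns pH, shift_ppm", call. = FALSE)
    if (!"nucleus" %in% names(df)) df$nucleus <- "C2"
    fit_rows <- do.call(rbind, lapply(split(df, df$nucleus), function(sub) {
      fit <- fit_titration(titration_series(sub$pH, sub$shift_ppm,
                                            nucleus = sub$nucleus[1]))
      data.frame(nucleus = fit$nucleus, pKa = fit$pKa,
                 pKa_err = fit$se[["pKa"]],
                 delta_prot = fit$delta_prot,
                 delta_deprot = fit$delta_deprot,
                 flags = paste(fit$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    rownames(fit_rows) <- NULL
  }
  tab <- if (!is.null(config$pka_table))
    do.call(rbind, lapply(config$pka_table, as.data.frame))
  else pka_reference_table()
  report <- list(fits = fit_rows, gaps = base_pair_gaps(tab))
  write_report(report, config, config$out_dir, "pka_report")
  invisible(report)
}

#' Run the structure superposition + hydration workflow
#'
#' Configuration keys: `mobile`, `target` (structure file paths; `target`
#' optional), `base_pair` (two residue numbers), `cutoff` (default 3.6),
#' `min_occupancy` (default 0.5), `out_dir`.
#'
#' @param config List or YAML path.
#' @return Report list with rmsd and hydration tables, invisibly.
#' @export
run_structure <- function(config) {
  config <- read_run_config(config)
  mobile <- read_structure(config$mobile)
  report <- list(mobile = mobile$source_id)
  if (!is.null(config$target)) {
    target <- read_structure(config$target)
    sp <- superpose(mobile, target)
    report$target <- target$source_id
    report$rmsd <- sp$rmsd
    report$n_atoms <- sp$n_atoms
  }
  if (!is.null(config$base_pair)) {
    hyd <- minor_groove_waters(mobile, as.integer(config$base_pair),
                               cutoff = config$cutoff %||% 3.6,
                               min_occupancy = config$min_occupancy %||% 0.5)
    report$hydration <- as.data.frame(hyd)
    report$cutoff <- attr(hyd, "cutoff")
  }
  write_report(report, config, config$out_dir, "structure_report")
  invisible(report)
}

#' Run the synthetic-data simulator
#'
#' Writes the raw-data files the analysis runners read. Configuration:
#' `out_dir` (required), `seed`, and any of `melt` (dH, dS, molecularity,
#' optional concentrations_M / sigma_frac), `cleanex` (list of residues:
#' k, R1A, optional R1_water / sigma), `titration` (pKa, delta_prot,
#' delta_deprot, optional sigma), `toy_pair` (preset, deaza3, waters). A
#' manifest recording files and seeds is written beside the data.
#'
#' @param config List or YAML path.
#' @return Manifest list, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("run_simulate needs out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  manifest <- list(seed = seed, files = character(0))
  if (!is.null(config$melt)) {
    m <- config$melt
    curves <- gen_melting_curve(
      m$dH, m$dS, m$molecularity,
      c_T = unlist(m$concentrations_M) %||% default_concentrations(),
      sigma_frac = m$sigma_frac %||% 0.003, seed = seed)
    df <- do.call(rbind, lapply(curves, function(cv)
      data.frame(temperature_C = cv$temperature_C,
                 absorbance = cv$absorbance, replicate = cv$replicate_id,
                 concentration_M = cv$c_T)))
    f <- file.path(out_dir, "melt_sim.csv")
    utils::write.csv(df, f, row.names = FALSE)
    manifest$files <- c(manifest$files, f)
  }
  if (!is.null(config$cleanex)) {
    rows <- list()
    for (i in seq_along(config$cleanex)) {
      r <- config$cleanex[[i]]
      ser <- gen_cleanex_series(r$k, r$R1A %||% 20,
                                R1_water = r$R1_water %||% (1 / 3.03),
                                sigma = r$sigma %||% 0.005,
                                seed = seed + i,
                                residue_label = r$residue %||%
                                  paste0("res", i))
      rows[[i]] <- data.frame(residue = ser$residue_label,
                              tau_mix_s = ser$tau_mix,
                              rel_intensity = ser$rel_intensity)
    }
    f <- file.path(out_dir, "cleanex_sim.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    manifest$files <- c(manifest$files, f)
  }
  if (!is.null(config$titration)) {
    t <- config$titration
    ser <- gen_titration(t$pKa, t$delta_prot, t$delta_deprot,
                         sigma = t$sigma %||% 0.05, seed = seed)
    f <- file.path(out_dir, "titration_sim.csv")
    utils::write.csv(data.frame(pH = ser$pH, shift_ppm = ser$shift,
                                nucleus = ser$nucleus),
                     f, row.names = FALSE)
    manifest$files <- c(manifest$files, f)
  }
  if (!is.null(config$toy_pair)) {
    tp <- config$toy_pair
    f <- file.path(out_dir, "toy_pair_sim.pdb")
    gen_toy_base_pair(tp$preset %||% "AU", waters = tp$waters %||% list(),
                      deaza3 = isTRUE(tp$deaza3), path = f)
    manifest$files <- c(manifest$files, f)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
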