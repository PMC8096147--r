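#' @title Structure superposition and minor-groove hydration
#' @description
#' Atomic models (PDB or mmCIF) are held as a flat atom table; rigid-body
#' superposition uses the Kabsch least-squares algorithm with a proper
#' rotation (det = +1), and hydration analysis lists the ordered waters
#' within a cutoff of the minor-groove face of a chosen base pair. The
#' minor-groove face atoms are the purine N3 (or the C3 carbon that
#' replaces it in a 3-deazapurine), the pyrimidine O2, and both riboses'
#' 2'-OH oxygens. Residue numbers are preserved from the source (sarcin-
#' ricin loop constructs keep E. coli 23S rRNA numbering, e.g. 2650/2670).
#' @name structure_module
NULL

.WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP", "TIP3")

new_structure_model <- function(atoms, source_id = NA_character_) {
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "chain", "x", "y", "z", "occupancy", "altloc", "is_water")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure model", call. = FALSE)
  structure(list(atoms = atoms, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %s: %d atoms (%d waters), %d residues\n",
              x$source_id, nrow(a), sum(a$is_water),
              length(unique(paste(a$chain, a$residue_number)))))
  invisible(x)
}

#' Read a structure from a PDB or mmCIF file
#'
#' Parsing is delegated to bio3d; alternate locations and occupancies are
#' retained, waters are flagged by residue name (HOH and common variants).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param source_id Identifier stored with the model (default: file name).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif"
              else "pdb"
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop(sprintf("cannot parse %s file '%s': %s",
                                     format, path, conditionMessage(e)),
                             call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no atoms found in ", path, call. = FALSE)
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem)] <- ""
  atoms <- data.frame(
    element = trimws(elem), atom_name = trimws(at$elety),
    residue_name = trimws(at$resid), residue_number = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = occ, altloc = alt,
    is_water = trimws(at$resid) %in% .WATER_RESNAMES,
    stringsAsFactors = FALSE)
  new_structure_model(atoms,
                      source_id = source_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a structure model as a PDB file
#'
#' Minimal fixed-column ATOM/HETATM writer used for synthetic fixtures;
#' waters are written as HETATM records.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    rec <- if (a$is_water[i]) "HETATM" else "ATOM  "
    sprintf("%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, i,
            formatC(a$atom_name[i], width = 4, flag = "-"),
            substr(paste0(a$altloc[i], " "), 1, 1),
            a$residue_name[i], a$chain[i], a$residue_number[i],
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0,
            a$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# resolve atoms by predicate; returns row indices
select_atoms <- function(model, chain = NULL, residue_number = NULL,
                         atom_name = NULL, element = NULL,
                         include_water = FALSE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!include_water) keep <- keep & !a$is_water
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residue_number)) keep <- keep & a$residue_number %in% residue_number
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  if (!is.null(element)) keep <- keep & a$element %in% element
  which(keep)
}

# one row per (chain, resno, atom_name): the highest-occupancy altloc,
# ties broken by alphabetical altloc ("A" first)
dedupe_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$residue_number, atoms$atom_name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(atoms$chain, atoms$residue_number,
                          atoms$atom_name, sep = "|")), , drop = FALSE]
}

#' Rigid-body superposition (Kabsch) of two structures
#'
#' By default the paired atom set is every shared non-hydrogen, non-water
#' atom matched by (residue_number, atom_name) across the two models
#' (chains matched by name when both have the same chain set); with
#' `isosteric_c3 = TRUE` a purine C3 is matched to an N3 at the same
#' residue number, so a 3-deazapurine superposes onto its parent purine.
#' Explicit index selections override the automatic pairing. The rotation
#' returned is proper (det = +1).
#'
#' @param mobile,target `structure_model`s.
#' @param mobile_idx,target_idx Optional equal-length atom row indices.
#' @param isosteric_c3 Match C3 to N3 at the same residue (default TRUE).
#' @return List: `rmsd` (Angstrom, after superposition), `rotation`
#'   (3x3), `translation` (length-3), `n_atoms`, and `transform(xyz)`.
#' @export
superpose <- function(mobile, target, mobile_idx = NULL, target_idx = NULL,
                      isosteric_c3 = TRUE) {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(target, "structure_model"))
  if (is.null(mobile_idx) != is.null(target_idx))
    stop("supply both or neither of mobile_idx/target_idx", call. = FALSE)
  if (is.null(mobile_idx)) {
    am <- dedupe_altloc(mobile$atoms[!mobile$atoms$is_water &
                                     mobile$atoms$element != "H", ])
    at <- dedupe_altloc(target$atoms[!target$atoms$is_water &
                                     target$atoms$element != "H", ])
    norm_name <- function(d) {
      nm <- d$atom_name
      if (isosteric_c3) nm[nm == "C3"] <- "N3"
      paste(d$chain, d$residue_number, nm, sep = "|")
    }
    km <- norm_name(am); kt <- norm_name(at)
    shared <- intersect(km, kt)
    if (length(shared) < 3L) {
      miss_m <- setdiff(km, kt); miss_t <- setdiff(kt, km)
      stop("cannot pair atoms for superposition; unmatched examples: ",
           paste(utils::head(c(miss_m, miss_t), 5), collapse = ", "),
           call. = FALSE)
    }
    P <- as.matrix(am[match(shared, km), c("x", "y", "z")])
    Q <- as.matrix(at[match(shared, kt), c("x", "y", "z")])
  } else {
    if (length(mobile_idx) != length(target_idx))
      stop("mobile_idx and target_idx must have equal length", call. = FALSE)
    if (length(mobile_idx) < 3L)
      stop("superposition needs at least 3 atom pairs", call. = FALSE)
    P <- as.matrix(mobile$atoms[mobile_idx, c("x", "y", "z")])
    Q <- as.matrix(target$atoms[target_idx, c("x", "y", "z")])
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-10)
    stop("superposition selection is (near-)collinear", call. = FALSE)
  dd <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, dd)) %*% t(sv$v)
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  translation <- cq - drop(cp %*% R)
  list(rmsd = rmsd, rotation = R, translation = translation,
       n_atoms = nrow(P),
       transform = function(xyz) sweep(as.matrix(xyz) %*% R, 2,
                                       translation, `+`))
}

#' Euclidean distance between two uniquely selected atoms
#'
#' Each selection is a list of predicates understood by the internal atom
#' selector (`chain`, `residue_number`, `atom_name`, `element`,
#' `include_water`). A selection matching several atoms after
#' highest-occupancy altloc resolution is an error.
#'
#' @param model A `structure_model`.
#' @param sel1,sel2 Selection lists.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' # atom_distance(m, list(residue_number = 2670, atom_name = "N3"),
#' #                  list(residue_number = 3001, atom_name = "O",
#' #                       include_water = TRUE))
atom_distance <- function(model, sel1, sel2) {
  res <- function(sel) {
    idx <- do.call(select_atoms, c(list(model), sel))
    rows <- dedupe_altloc(model$atoms[idx, , drop = FALSE])
    if (nrow(rows) == 0L) stop("selection matches no atom", call. = FALSE)
    if (nrow(rows) > 1L)
      stop("ambiguous selection: matches ",
           paste(utils::head(paste0(rows$residue_name, rows$residue_number,
                                    "/", rows$atom_name), 5),
                 collapse = ", "), call. = FALSE)
    c(rows$x, rows$y, rows$z)
  }
  sqrt(sum((res(sel1) - res(sel2))^2))
}

#' Ordered waters on the minor-groove face of a base pair
#'
#' Reports every water whose oxygen lies within `cutoff` of any
#' minor-groove face atom of the two residues (purine N3 or its 3-deaza C3
#' carbon, pyrimidine O2, and the 2'-OH oxygens O2'), together with its
#' nearest face contact. Waters below `min_occupancy` are skipped and
#' altlocs resolved to the highest-occupancy conformer (ties to "A").
#' Entries are sorted by ascending contact distance, so the report at a
#' smaller cutoff is a prefix of the report at a larger one.
#'
#' @param model A `structure_model`.
#' @param base_pair Two residue numbers, e.g. `c(2650, 2670)`.
#' @param cutoff Contact cutoff, Angstrom (default 3.6).
#' @param min_occupancy Minimum water occupancy (default 0.5).
#' @param chain Optional chain restriction for the base-pair residues.
#' @return A data.frame (class `hydration_report`): water chain/number,
#'   nearest face atom (residue and name) and distance; attribute `cutoff`.
#' @export
minor_groove_waters <- function(model, base_pair, cutoff = 3.6,
                                min_occupancy = 0.5, chain = NULL) {
  stopifnot(inherits(model, "structure_model"), length(base_pair) == 2L)
  face_names <- c("N3", "C3", "O2", "O2'", "O2*")
  idx <- select_atoms(model, chain = chain, residue_number = base_pair,
                      atom_name = face_names)
  if (!any(model$atoms$residue_number %in% base_pair & !model$atoms$is_water))
    stop("base-pair residues not found: ",
         paste(base_pair, collapse = ", "), call. = FALSE)
  face <- dedupe_altloc(model$atoms[idx, , drop = FALSE])
  if (nrow(face) == 0L)
    stop("no minor-groove face atoms (N3/C3/O2/O2') found for residues ",
         paste(base_pair, collapse = ", "), call. = FALSE)
  wat <- model$atoms[model$atoms$is_water &
                     model$atoms$element %in% c("O", "") &
                     model$atoms$occupancy >= min_occupancy, , drop = FALSE]
  wat <- dedupe_altloc(wat)
  out <- data.frame(water_chain = character(0), water_number = integer(0),
                    nearest_atom = character(0), nearest_residue = integer(0),
                    distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(wat)) {
    fxyz <- as.matrix(face[, c("x", "y", "z")])
    for (i in seq_len(nrow(wat))) {
      d <- sqrt(colSums((t(fxyz) - c(wat$x[i], wat$y[i], wat$z[i]))^2))
      j <- which.min(d)
      if (d[j] <= cutoff)
        out <- rbind(out, data.frame(
          water_chain = wat$chain[i], water_number = wat$residue_number[i],
          nearest_atom = face$atom_name[j],
          nearest_residue = face$residue_number[j],
          distance = d[j], stringsAsFactors = FALSE))
    }
    out <- out[order(out$distance), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, cutoff = cutoff, base_pair = base_pair,
            class = c("hydration_report", "data.frame"))
}

#' @export
print.hydration_report <- function(x, ...) {
  cat(sprintf("<hydration_report> base pair %s, cutoff %.1f A: %d water(s)\n",
              paste(attr(x, "base_pair"), collapse = "/"),
              attr(x, "cutoff"), nrow(x)))
  if (nrow(x)) {
    y <- as.data.frame(x)
    y$distance <- round(y$distance, 1)  # report to 0.1 A
    print(y, row.names = FALSE)
  }
  invisible(x)
}
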