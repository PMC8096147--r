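#' @title Modified RNA sequences with deazapurine residues
#' @description
#' RNA sequences are represented as ordered vectors of residue tokens over
#' the closed alphabet `A, C, G, U, c3A, c3G, c7A, c7G`. The deazapurines
#' are distinct residues (the ring nitrogen N3 or N7 is replaced by CH) but
#' pair through the same Watson-Crick face as their parent purine: c3G and
#' c7G pair with C, c3A and c7A pair with U.
#' @name seqmod
NULL

# closed residue alphabet; multi-character tokens first for greedy parsing
.RNA_TOKENS <- c("c3A", "c3G", "c7A", "c7G", "A", "C", "G", "U")

# deaza residue -> unmodified pairing parent
.PAIRING_PARENT <- c(
  A = "A", C = "C", G = "G", U = "U",
  c3A = "A", c3G = "G", c7A = "A", c7G = "G"
)

.WC_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Parse an RNA sequence string containing deazapurine tokens
#'
#' Tokens are consumed greedily left to right; the multi-character tokens
#' `c3A`, `c3G`, `c7A`, `c7G` take precedence over single letters. Matching
#' is case-insensitive (`c3g` and `C3G` both parse as c3G; plain bases are
#' upper-cased). `T` is not accepted: this is an RNA alphabet.
#'
#' @param text Character scalar, e.g. `"GGUCc3GACC"`.
#' @param name Optional free-text label attached to the sequence.
#' @return A `modified_rna` object (character vector of residue tokens).
#' @export
#' @examples
#' parse_rna("GGUCc3GACC")
parse_rna <- function(text, name = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("`text` must be a single non-empty string", call. = FALSE)
  txt <- text
  n <- nchar(txt)
  residues <- character(0)
  i <- 1L
  while (i <= n) {
    chunk3 <- substr(txt, i, i + 2L)
    hit <- match(toupper(chunk3), toupper(.RNA_TOKENS[1:4]))
    if (!is.na(hit)) {
      residues <- c(residues, .RNA_TOKENS[hit])
      i <- i + 3L
      next
    }
    ch <- toupper(substr(txt, i, i))
    if (ch %in% c("A", "C", "G", "U")) {
      residues <- c(residues, ch)
      i <- i + 1L
    } else {
      stop(sprintf("unknown residue token at position %d of \"%s\": '%s'",
                   i, text, substr(txt, i, i)), call. = FALSE)
    }
  }
  new_modified_rna(residues, name = name)
}

new_modified_rna <- function(residues, name = NULL) {
  stopifnot(length(residues) >= 1L, all(residues %in% .RNA_TOKENS))
  structure(residues, name = name, class = "modified_rna")
}

#' @export
format.modified_rna <- function(x, ...) paste(unclass(x), collapse = "")

#' @export
print.modified_rna <- function(x, ...) {
  nm <- attr(x, "name")
  cat("<modified_rna", if (!is.null(nm)) paste0("'", nm, "'") else "", "> ",
      format(x), "  (", length(x), " nt)\n", sep = "")
  invisible(x)
}

#' Pairing-parent sequence of a modified RNA
#'
#' Maps every deazapurine residue to the unmodified purine whose
#' Watson-Crick face it shares (c3A/c7A -> A, c3G/c7G -> G).
#'
#' @param seq A `modified_rna` object or string.
#' @return A `modified_rna` containing only unmodified residues.
#' @export
pairing_parent <- function(seq) {
  seq <- as_modified_rna(seq)
  new_modified_rna(unname(.PAIRING_PARENT[unclass(seq)]), name = attr(seq, "name"))
}

as_modified_rna <- function(x) {
  if (inherits(x, "modified_rna")) x else parse_rna(x)
}

#' Reverse complement under Watson-Crick rules
#'
#' Deaza residues are complemented through their pairing parent, so the
#' result contains only unmodified residues (the complement of a strand is
#' the natural strand it hybridizes to).
#'
#' @param seq A `modified_rna` object or string.
#' @return A `modified_rna` with unmodified residues, reverse order.
#' @export
#' @examples
#' format(complement_rna("GGCAGAGGC"))  # "GCCUCUGCC"
complement_rna <- function(seq) {
  seq <- as_modified_rna(seq)
  parents <- .PAIRING_PARENT[unclass(seq)]
  comp <- rev(unname(.WC_COMPLEMENT[parents]))
  new_modified_rna(comp, name = attr(seq, "name"))
}

#' Is a sequence self-complementary (palindromic) at the pairing-parent level?
#'
#' @param seq A `modified_rna` object or string.
#' @return Logical scalar.
#' @export
is_self_complementary <- function(seq) {
  seq <- as_modified_rna(seq)
  identical(unclass(pairing_parent(seq)), unclass(complement_rna(seq)))
}

#' Molecularity tags
#'
#' Closed enumeration of the three folding transitions handled by the
#' melting module: a unimolecular hairpin, a bimolecular duplex of one
#' self-complementary (palindromic) strand, and a bimolecular duplex of two
#' different strands.
#'
#' @return Character vector of the three valid tags.
#' @export
molecularity_levels <- function() {
  c("unimolecular_hairpin", "bimolecular_self_complementary",
    "bimolecular_nonself")
}

#' Normalise a molecularity specification
#'
#' Accepts the full tag or the shorthands "hairpin", "self", "nonself".
#'
#' @param x Character scalar.
#' @return One of [molecularity_levels()].
#' @export
as_molecularity <- function(x) {
  if (length(x) != 1L || !is.character(x))
    stop("molecularity must be a single string", call. = FALSE)
  lv <- molecularity_levels()
  alias <- c(hairpin = lv[1], unimolecular = lv[1],
             self = lv[2], self_complementary = lv[2], palindrome = lv[2],
             nonself = lv[3], duplex = lv[3])
  if (x %in% lv) return(x)
  if (x %in% names(alias)) return(unname(alias[x]))
  hit <- pmatch(x, lv)
  if (!is.na(hit)) return(lv[hit])
  stop(sprintf("unknown molecularity '%s'; valid: %s", x,
               paste(lv, collapse = ", ")), call. = FALSE)
}

#' Classify the molecularity of a strand (convenience heuristic)
#'
#' With an explicit `partner` the system is a bimolecular duplex of two
#' different strands. A single strand is classified as a self-complementary
#' bimolecular duplex when its pairing-parent sequence equals its own
#' reverse complement, and as a unimolecular hairpin otherwise. Hairpin
#' versus self-dimer cannot in general be decided from sequence alone, so
#' the melting analysis always takes molecularity as an explicit argument;
#' this helper encodes the usual design logic. A 3'-dangling residue (used
#' to reduce end fraying in hairpin constructs) can be stripped before the
#' palindrome check via `strip_dangling_3p`.
#'
#' @param seq A `modified_rna` or string.
#' @param partner Optional second strand.
#' @param strip_dangling_3p Drop the final residue before the
#'   self-complementarity check (default `FALSE`).
#' @return One of [molecularity_levels()].
#' @export
#' @examples
#' classify_molecularity("GGUCGACC")            # palindromic dimer
#' classify_molecularity("GAAGGGCAACCUUCG")     # hairpin
classify_molecularity <- function(seq, partner = NULL,
                                  strip_dangling_3p = FALSE) {
  seq <- as_modified_rna(seq)
  if (!is.null(partner)) return("bimolecular_nonself")
  if (strip_dangling_3p && length(seq) > 1L)
    seq <- new_modified_rna(unclass(seq)[-length(seq)])
  if (is_self_complementary(seq)) "bimolecular_self_complementary"
  else "unimolecular_hairpin"
}

#' Read unmodified RNA sequences from a FASTA file
#'
#' Deazapurine tokens are not legal FASTA; this reader accepts plain
#' A/C/G/U records only (T is rejected).
#'
#' @param path FASTA file path.
#' @return Named list of `modified_rna` objects.
#' @export
read_rna_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], ">"))
    stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(startsWith(lines, ">"))
  out <- lapply(split(lines, idx), function(block) {
    nm <- sub("^>\\s*", "", block[[1]])
    seqtxt <- paste(block[-1], collapse = "")
    parse_rna(seqtxt, name = nm)
  })
  names(out) <- vapply(out, function(s) attr(s, "name"), character(1))
  out
}
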