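# Genetic code, substitution typing and codon utilities.

BASES <- c("A", "C", "G", "T")

# complement on integer-coded bases (A=1, C=2, G=3, T=4)
COMP_INT <- c(4L, 3L, 2L, 1L)

AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

.code_cache <- new.env(parent = emptyenv())

#' Vertebrate mitochondrial genetic code
#'
#' Returns the vertebrate mitochondrial genetic code (NCBI translation
#' table 2) as a named character vector mapping each of the 64 DNA codons to
#' a three-letter amino-acid symbol, with `"Ter"` for stop codons. Relative
#' to the standard code, AGA and AGG are stops, ATA is Met and TGA is Trp.
#' This is the only genetic code valid for human mtDNA mRNAs; no override is
#' offered.
#'
#' @return Named character vector of length 64 (names are codons, values are
#'   three-letter amino-acid symbols including `"Ter"`).
#' @export
#' @examples
#' mito_genetic_code()[c("TGA", "AGA", "ATA")]
mito_genetic_code <- function() {
  if (is.null(.code_cache$code)) {
    code1 <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
    .code_cache$code <- setNames(unname(AA3[code1]), names(code1))
  }
  .code_cache$code
}

#' Translate codons under the vertebrate mitochondrial code
#'
#' @param codons Character vector of 3-mers over \{A,C,G,T\}.
#' @return Character vector of three-letter amino-acid symbols (`"Ter"` for
#'   stops).
#' @export
#' @examples
#' translate_codons(c("TGA", "AGA", "ACC"))
translate_codons <- function(codons) {
  code <- mito_genetic_code()
  aa <- code[codons]
  if (anyNA(aa)) {
    bad <- unique(codons[is.na(aa)])
    abort(paste0(
      "Invalid codon(s): ", paste(head(bad, 5), collapse = ", "),
      ". Codons must be 3-mers over {A,C,G,T}."
    ), class = "mitoselect_invalid_codon")
  }
  unname(aa)
}

#' Classify single-base substitutions into the 12 directional types
#'
#' Labels each (ref, alt) pair as one of the 12 directional substitution
#' types on the reference strand (e.g. `"C>T"`) and flags transitions
#' (A<->G, C<->T). The reference strand of the rCRS corresponds to the
#' light strand; [hl_label()] converts reference-strand labels to the
#' heavy/light presentation used in figures.
#'
#' @param ref,alt Character vectors of single bases; `ref != alt` pairwise.
#' @return A tibble with columns `subst_type` and `is_transition`.
#' @export
#' @examples
#' classify_substitutions(c("C", "C"), c("T", "A"))
classify_substitutions <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  bad <- !(ref %in% BASES) | !(alt %in% BASES)
  if (any(bad)) {
    abort(paste0("Non-ACGT base at entries: ",
                 paste(head(which(bad), 5), collapse = ", ")),
          class = "mitoselect_invalid_substitution")
  }
  same <- ref == alt
  if (any(same)) {
    abort(paste0("ref == alt at entries: ",
                 paste(head(which(same), 5), collapse = ", ")),
          class = "mitoselect_invalid_substitution")
  }
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  tibble(
    subst_type = paste0(ref, ">", alt),
    is_transition = unname(purine[ref] == purine[alt])
  )
}

#' All 12 directional substitution labels
#'
#' @return Character vector of the 12 `"X>Y"` labels in a fixed order
#'   (transitions first).
#' @export
substitution_types <- function() {
  all <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  all <- all[all$ref != all$alt, ]
  lab <- paste0(all$ref, ">", all$alt)
  ts <- c("A>G", "G>A", "C>T", "T>C")
  c(ts, sort(setdiff(lab, ts)))
}

#' Heavy/light-strand display label for a substitution type
#'
#' The rCRS reference strand is the light (L) strand. Figures conventionally
#' label each substitution by its pyrimidine-strand representation, e.g.
#' reference-strand `G>A` is shown as `C_H>T_H` and reference-strand `T>C`
#' as `T_L>C_L`. This mapping is presentational only; all computation uses
#' reference-strand labels.
#'
#' @param subst_type Character vector of `"X>Y"` reference-strand labels.
#' @return Character vector of display labels.
#' @export
#' @examples
#' hl_label(c("G>A", "T>C"))
hl_label <- function(subst_type) {
  ref <- substr(subst_type, 1, 1)
  alt <- substr(subst_type, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_pyr <- ref %in% c("C", "T")
  if_else(is_pyr,
          paste0(ref, "_L>", alt, "_L"),
          paste0(comp[ref], "_H>", comp[alt], "_H"))
}

#' Codon/anticodon complementarity classes
#'
#' Classifies the 60 sense codons of the vertebrate mitochondrial code as
#' completely complementary (CC) to their decoding tRNA anticodon or not
#' (NCC), under an idealized wobble model of the 22-tRNA mitochondrial
#' decoding system: a four-fold degenerate family box is read by a single
#' tRNA with a U at the wobble position (CC codon ends in A); a two-codon
#' NNY set is read by a G-wobble tRNA (CC codon ends in C); a two-codon NNR
#' set is read by a U-wobble tRNA (CC codon ends in A), except the Met tRNA
#' whose anticodon CAU makes ATG the CC codon. Stop codons have no tRNA and
#' are excluded.
#'
#' @return A tibble with columns `codon`, `aa` and `cc` (logical; TRUE for
#'   completely complementary).
#' @export
codon_cc_table <- function() {
  code <- mito_genetic_code()
  codons <- names(code)
  sense <- codons[code != "Ter"]
  fam <- substr(sense, 1, 2)
  third <- substr(sense, 3, 3)
  cc <- logical(length(sense))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    aas <- code[sense[idx]]
    if (length(idx) == 4 && length(unique(aas)) == 1) {
      cc[idx] <- third[idx] == "A"  # family box, U34 wobble
    } else {
      # split into NNY and NNR sets
      y <- idx[third[idx] %in% c("C", "T")]
      r <- idx[third[idx] %in% c("A", "G")]
      cc[y] <- third[y] == "C"  # G34 wobble
      if (length(r)) {
        if (any(code[sense[r]] == "Met")) {
          cc[r] <- third[r] == "G"  # anticodon CAU
        } else {
          cc[r] <- third[r] == "A"  # U34 wobble
        }
      }
    }
  }
  tibble(codon = sense, aa = unname(code[sense]), cc = cc)
}
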