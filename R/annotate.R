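# Per-mutation annotation against a mito_genome.

#' Annotate single-base substitutions
#'
#' Annotates each mutation against every feature containing its position:
#' one output row per (mutation, feature) pair. For mRNA features the
#' reference and mutant codons are computed from the gene's reading frame
#' (strand-aware; the mutant base is substituted in place) and translated
#' under the vertebrate mitochondrial code; terminal codons truncated by
#' the gene boundary (completed by polyadenylation in vivo) get an empty
#' mutation class and are excluded from codon/amino-acid tables. The
#' triplet context (`triplet_mut`) is the mutant base flanked by the
#' reference 5' and 3' neighbours on the reference strand, with circular
#' wraparound at the origin.
#'
#' @param x A data frame with columns `position`, `ref`, `alt` (additional
#'   columns are preserved).
#' @param genome A [load_reference()] genome.
#' @return A tibble with one row per (mutation, feature): the input columns
#'   plus `.mut_id`, `region`, `ftype`, `complex`, `strand`, `mclass`,
#'   `codon_index`, `ref_codon`, `mut_codon`, `ref_aa`, `mut_aa`,
#'   `subst_type`, `is_transition`, `triplet_mut`, `trna_unit`.
#' @export
#' @examples
#' g <- load_reference()
#' muts <- tibble::tibble(position = 3460, ref = "G", alt = "A")
#' annotate_mutations(muts, g)
annotate_mutations <- function(x, genome) {
  stopifnot(inherits(genome, "mito_genome"))
  x <- as_tibble(x)
  need <- c("position", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
          class = "mitoselect_bad_input")
  }
  pos <- as.integer(x$position)
  if (any(is.na(pos) | pos < 1 | pos > genome$length)) {
    abort("position out of range [1, genome length].",
          class = "mitoselect_bad_input")
  }
  genome_ref <- genome$seq[pos]
  mism <- which(x$ref != genome_ref)
  if (length(mism)) {
    i <- mism[1]
    abort(paste0(
      "Reference mismatch at position ", pos[i], ": table says ", x$ref[i],
      ", genome has ", genome_ref[i],
      if (length(mism) > 1) paste0(" (and ", length(mism) - 1, " more)") else ""
    ), class = "mitoselect_ref_mismatch")
  }
  cls <- classify_substitutions(x$ref, x$alt)  # errors if ref == alt

  idx <- genome$index
  prev_b <- BASES[idx$prev_int[pos]]
  next_b <- BASES[idx$next_int[pos]]

  out <- x %>%
    mutate(.mut_id = row_number(),
           position = pos,
           subst_type = cls$subst_type,
           is_transition = cls$is_transition,
           triplet_mut = paste0(prev_b, .data$alt, next_b))

  ann <- out %>%
    inner_join(genome$pos_map, by = "position", relationship = "many-to-many")

  # codon fields for mRNA rows with complete codons
  is_m <- ann$ftype == "mRNA" & !is.na(ann$codon_complete) & ann$codon_complete
  ref_codon <- rep(NA_character_, nrow(ann))
  mut_codon <- rep(NA_character_, nrow(ann))
  if (any(is_m)) {
    s <- genome$seq
    rc <- paste0(s[ann$cpos1[is_m]], s[ann$cpos2[is_m]], s[ann$cpos3[is_m]])
    onL <- ann$strand[is_m] == "L"
    rc[onL] <- comp_base(rc[onL])
    alt_cs <- ann$alt[is_m]
    alt_cs[onL] <- comp_base(alt_cs[onL])
    mc <- rc
    substr(mc, ann$codon_offset[is_m] + 1L, ann$codon_offset[is_m] + 1L) <- alt_cs
    ref_codon[is_m] <- rc
    mut_codon[is_m] <- mc
  }
  ann$ref_codon <- ref_codon
  ann$mut_codon <- mut_codon
  ann$ref_aa <- NA_character_
  ann$mut_aa <- NA_character_
  if (any(is_m)) {
    ann$ref_aa[is_m] <- translate_codons(ann$ref_codon[is_m])
    ann$mut_aa[is_m] <- translate_codons(ann$mut_codon[is_m])
  }

  mclass <- rep(NA_character_, nrow(ann))
  mclass[ann$ftype == "tRNA"] <- "tRNA"
  mclass[ann$ftype == "rRNA"] <- "rRNA"
  mclass[ann$ftype == "noncoding"] <- "noncoding"
  mclass[is_m] <- dplyr::case_when(
    ann$ref_aa[is_m] != "Ter" & ann$mut_aa[is_m] == "Ter" ~ "stopgain",
    ann$ref_aa[is_m] == "Ter" & ann$mut_aa[is_m] != "Ter" ~ "stoploss",
    ann$ref_aa[is_m] == ann$mut_aa[is_m] ~ "synonymous",
    TRUE ~ "nonsynonymous"
  )
  ann$mclass <- mclass

  ann %>%
    rename(region = "gene") %>%
    select(all_of(c(names(x), ".mut_id", "region", "ftype", "complex",
                    "strand", "slot", "mclass", "codon_index", "ref_codon",
                    "mut_codon", "ref_aa", "mut_aa", "subst_type",
                    "is_transition", "triplet_mut", "trna_unit",
                    "trna_sub_unit")))
}

CLASS_SEVERITY <- c(stopgain = 1, stoploss = 2, nonsynonymous = 3,
                    synonymous = 4, tRNA = 5, rRNA = 6, noncoding = 7)

#' Collapse feature-level annotations to one class per mutation
#'
#' A mutation falling in overlapping genes is annotated once per gene;
#' genome-wide class tallies count each mutation once, using the most
#' severe class across frames (stopgain/stoploss > nonsynonymous >
#' synonymous > tRNA > rRNA > noncoding).
#'
#' @param ann Output of [annotate_mutations()].
#' @return A tibble with one row per mutation (`.mut_id`) carrying the most
#'   severe `mclass` and the corresponding feature columns.
#' @export
mutation_classes <- function(ann) {
  ann %>%
    mutate(.sev = unname(CLASS_SEVERITY[.data$mclass])) %>%
    mutate(.sev = if_else(is.na(.data$.sev), 99, .data$.sev)) %>%
    group_by(.data$.mut_id) %>%
    arrange(.data$.sev, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-".sev") %>%
    arrange(.data$.mut_id)
}
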