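# Neutral reference model: substitution-spectrum calibration and simulation.

#' Calibrate a 12-type substitution spectrum from observed mutations
#'
#' Counts the occurrences of each of the 12 directional base substitutions
#' in a mutation table and converts them to relative frequencies, the
#' neutral mutation-rate estimate used by [simulate_neutral()]. The
#' estimate assumes selection plays a negligible role in shaping the
#' overall substitution pattern of the calibration cohort.
#'
#' @param x A data frame with `ref` and `alt` columns (e.g. a cohort).
#' @return An `mt_spectrum`: a tibble with columns `subst_type`, `count`,
#'   `freq` (all 12 types present, frequencies summing to 1).
#' @export
#' @examples
#' calibrate_spectrum(tibble::tibble(ref = c("C", "C", "C", "A"),
#'                                   alt = c("T", "T", "T", "G")))
calibrate_spectrum <- function(x) {
  if (is.null(x) || nrow(x) == 0) {
    abort("Cannot calibrate a spectrum from an empty cohort.",
          class = "mitoselect_calibration_error")
  }
  cls <- classify_substitutions(x$ref, x$alt)
  counts <- table(factor(cls$subst_type, levels = substitution_types()))
  out <- tibble(subst_type = names(counts),
                count = as.integer(counts)) %>%
    mutate(freq = .data$count / sum(.data$count))
  class(out) <- c("mt_spectrum", class(out))
  out
}

#' Default transition-dominated substitution spectrum
#'
#' A reference-strand spectrum with the strong transition bias typical of
#' tumor somatic mtDNA mutations: heavy-strand C>T (reference `G>A`)
#' dominant, followed by light-strand T>C (reference `T>C`), transitions
#' totalling 92% of mutations, and the eight transversions sharing the
#' remainder uniformly.
#'
#' @return An `mt_spectrum` tibble.
#' @export
default_spectrum <- function() {
  freq <- c("G>A" = 0.45, "T>C" = 0.33, "C>T" = 0.08, "A>G" = 0.06)
  tv <- setdiff(substitution_types(), names(freq))
  freq <- c(freq, setNames(rep(0.01, length(tv)), tv))
  out <- tibble(subst_type = substitution_types(),
                count = as.integer(round(freq[substitution_types()] * 10000)),
                freq = unname(freq[substitution_types()]))
  class(out) <- c("mt_spectrum", class(out))
  out
}

#' Write / read a spectrum as TSV
#'
#' Plain-text interchange format: `subst_type<TAB>count<TAB>freq`.
#'
#' @param spectrum An `mt_spectrum`.
#' @param path File path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns an `mt_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(as_tibble(spectrum), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_spectrum(out)
  class(out) <- c("mt_spectrum", class(out))
  out
}

validate_spectrum <- function(spectrum) {
  need <- c("subst_type", "freq")
  if (!all(need %in% names(spectrum))) {
    abort("Spectrum needs columns subst_type and freq.",
          class = "mitoselect_config_error")
  }
  if (!setequal(spectrum$subst_type, substitution_types())) {
    abort("Spectrum must list all 12 substitution types exactly once.",
          class = "mitoselect_config_error")
  }
  if (any(spectrum$freq < 0) || abs(sum(spectrum$freq) - 1) > 1e-9) {
    abort("Spectrum frequencies must be non-negative and sum to 1.",
          class = "mitoselect_config_error")
  }
  invisible(spectrum)
}

# deterministic per-replicate child seeds from one root seed
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate mutation sets under neutrality
#'
#' Draws `n_mutations` independent mutations per replicate: the
#' substitution type is sampled from the spectrum and the position
#' uniformly over all genome positions carrying the type's source base
#' (sampling with replacement, so the same site may recur, mirroring
#' recurrent observed mutations). Placement is deliberately context-free:
#' weighting by local context would build in the very signal the
#' triplet-context residual analysis is designed to detect.
#'
#' @param genome A [load_reference()] genome.
#' @param spectrum An `mt_spectrum` (e.g. [calibrate_spectrum()]).
#' @param n_mutations Mutations per replicate.
#' @param n_replicates Number of replicates (default 10).
#' @param seed Integer root seed; replicate `r` uses a child seed derived
#'   deterministically from it, so results are reproducible independently
#'   of scheduling.
#' @return A tibble with columns `replicate`, `position`, `ref`, `alt`.
#' @export
simulate_neutral <- function(genome, spectrum, n_mutations,
                             n_replicates = 10, seed = 1L) {
  stopifnot(inherits(genome, "mito_genome"),
            n_mutations >= 1, n_replicates >= 1)
  validate_spectrum(spectrum)
  sp <- spectrum[match(substitution_types(), spectrum$subst_type), ]
  src <- match(substr(sp$subst_type, 1, 1), BASES)
  alt <- substr(sp$subst_type, 3, 3)
  n_src <- lengths(genome$index$pos_by_base)[src]
  if (any(sp$freq > 0 & n_src == 0)) {
    abort("Spectrum puts positive mass on a source base absent from the genome.",
          class = "mitoselect_config_error")
  }
  seeds <- child_seeds(seed, n_replicates)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    set.seed(seeds[r])
    ty <- sample.int(12L, n_mutations, replace = TRUE, prob = sp$freq)
    pos <- integer(n_mutations)
    for (t in unique(ty)) {
      sel <- ty == t
      pool <- genome$index$pos_by_base[[src[t]]]
      pos[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
    tibble(replicate = r, position = pos,
           ref = BASES[src[ty]], alt = alt[ty])
  })
}

#' Count mutant codons, amino acids or triplet contexts
#'
#' Tallies the categories produced by single-base substitutions: the mutant
#' codon (64 possible), the mutant amino acid (20 + Ter), or the mutant
#' triplet (mutant base with its reference-strand 5' and 3' neighbours,
#' circular at the origin). Codon and amino-acid modes are restricted to
#' mutations hitting complete codons of mRNA regions on the primary frame
#' (the earlier-started gene in overlaps); the triplet mode uses all
#' mutations. If the input has a `replicate` column the per-replicate
#' counts are averaged arithmetically (a category absent from a replicate
#' counts as 0).
#'
#' @param x A data frame with `position` and `alt` columns (and optionally
#'   `replicate`), e.g. a cohort or [simulate_neutral()] output.
#' @param genome A [load_reference()] genome.
#' @param mode `"codon"`, `"amino_acid"` or `"triplet"`.
#' @param drop_zero Drop categories with zero (mean) count? Default TRUE.
#' @return A tibble with columns `category` and `count` (the
#'   replicate-averaged count when replicates are present; attribute
#'   `"n_replicates"` records how many).
#' @export
count_mutant_categories <- function(x, genome,
                                    mode = c("codon", "amino_acid", "triplet"),
                                    drop_zero = TRUE) {
  mode <- match.arg(mode)
  idx <- genome$index
  pos <- as.integer(x$position)
  alt_int <- match(x$alt, BASES)
  R <- if ("replicate" %in% names(x)) length(unique(x$replicate)) else 1L

  if (mode == "triplet") {
    cat_idx <- 16L * (idx$prev_int[pos] - 1L) + 4L * (alt_int - 1L) +
      (idx$next_int[pos] - 1L)
    counts <- tabulate(cat_idx + 1L, nbins = 64L)
    labels <- idx$codon_names
  } else {
    ok <- idx$mr_ok[pos]
    p <- pos[ok]
    a <- alt_int[ok]
    onL <- idx$mr_L[p]
    ref_c <- idx$base_int[p]
    a[onL] <- COMP_INT[a[onL]]
    ref_c[onL] <- COMP_INT[ref_c[onL]]
    mut_idx <- idx$mr_refidx[p] + (a - ref_c) * idx$mr_place[p]
    if (mode == "codon") {
      counts <- tabulate(mut_idx + 1L, nbins = 64L)
      labels <- idx$codon_names
    } else {
      aa_lev <- sort(unique(idx$aa_of_codon))
      aa_idx <- match(idx$aa_of_codon[mut_idx + 1L], aa_lev)
      counts <- tabulate(aa_idx, nbins = length(aa_lev))
      labels <- aa_lev
    }
  }
  out <- tibble(category = labels, count = counts / R)
  if (drop_zero) out <- out[out$count > 0, ]
  attr(out, "n_replicates") <- R
  attr(out, "mode") <- mode
  out
}
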