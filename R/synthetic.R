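# Synthetic tumor cohorts with plantable region- and codon-level selection.

default_tumor_types <- function() {
  tibble(
    tumor_type = c("liver", "colorectal", "breast", "lung", "stomach",
                   "kidney", "bile duct", "CNS", "osteosarcoma",
                   "leiomyosarcoma"),
    weight = c(0.20, 0.16, 0.14, 0.13, 0.10, 0.08, 0.05, 0.06, 0.04, 0.04),
    histology_group = c(rep("carcinoma", 7), "other", "sarcoma", "sarcoma")
  )
}

# per-patient mutation-count law: supported on 1..8, mode at 1, mean ~1.8,
# matching the shape of observed per-patient burden histograms
default_count_law <- function() {
  c(`1` = 0.543, `2` = 0.270, `3` = 0.100, `4` = 0.045,
    `5` = 0.020, `6` = 0.012, `7` = 0.006, `8` = 0.004)
}

#' Generative model for synthetic tumor mtDNA cohorts
#'
#' Describes a cohort generator with the statistical structure the
#' analysis assumes: per-patient mutation counts on 1..8 (mode at 1, mean
#' about 1.8), a transition-dominated 12-type substitution spectrum,
#' heteroplasmy drawn from a two-component mixture (a low-frequency
#' component on \[0.02, 0.2\] and a near-homoplasmic component on
#' \[0.9, 1.0\], equal weights, Beta-shaped within each interval) with
#' half the records lacking a measured level, and plantable selection:
#' `region_multipliers` scale the placement rate of positions by feature
#' label (gene name, ftype, complex, or tRNA unit), `codon_effects` scale
#' it by the mutant codon the substitution would produce (primary frame).
#' All defaults are neutral (multipliers of 1).
#'
#' @param n_patients Number of patients.
#' @param tumor_types Tibble with `tumor_type`, `weight`,
#'   `histology_group`.
#' @param count_law Named numeric vector of per-patient count
#'   probabilities (names are counts).
#' @param spectrum An `mt_spectrum` ([default_spectrum()] by default).
#' @param region_multipliers Named numeric vector, e.g. `c(ATP8 = 0.2)`.
#' @param codon_effects Named numeric vector, e.g. `c(CCC = 10)`.
#' @param heteroplasmy List: `weight_low`, `low` / `high` interval bounds,
#'   Beta shapes, and `prop_missing`.
#' @return An `mt_cohort_model` list.
#' @export
cohort_model <- function(n_patients = 3277,
                         tumor_types = default_tumor_types(),
                         count_law = default_count_law(),
                         spectrum = default_spectrum(),
                         region_multipliers = c(),
                         codon_effects = c(),
                         heteroplasmy = list(weight_low = 0.5,
                                             low = c(0.02, 0.2),
                                             high = c(0.9, 1.0),
                                             shape = c(1.5, 3),
                                             prop_missing = 0.5)) {
  stopifnot(n_patients >= 1,
            all(count_law >= 0), sum(count_law) > 0,
            !anyNA(as.integer(names(count_law))),
            all(as.integer(names(count_law)) >= 1))
  validate_spectrum(spectrum)
  if (length(region_multipliers) &&
      (is.null(names(region_multipliers)) || any(region_multipliers < 0))) {
    abort("region_multipliers must be a named non-negative vector.",
          class = "mitoselect_config_error")
  }
  if (length(codon_effects) &&
      (is.null(names(codon_effects)) || any(codon_effects < 0))) {
    abort("codon_effects must be a named non-negative vector.",
          class = "mitoselect_config_error")
  }
  structure(list(n_patients = n_patients, tumor_types = tumor_types,
                 count_law = count_law / sum(count_law), spectrum = spectrum,
                 region_multipliers = region_multipliers,
                 codon_effects = codon_effects,
                 heteroplasmy = heteroplasmy),
            class = "mt_cohort_model")
}

# per-position placement multiplier: product over the position's feature
# labels (gene, ftype, complex as "I".."V", tRNA unit) of any matching
# region multiplier
position_multipliers <- function(model, genome) {
  w <- rep(1, genome$length)
  rm <- model$region_multipliers
  if (!length(rm)) return(w)
  pm <- genome$pos_map
  for (key in names(rm)) {
    hit <- pm$position[pm$gene == key | pm$ftype == key |
                         (pm$ftype == "mRNA" & pm$complex == key) |
                         (!is.na(pm$trna_unit) & pm$trna_unit == key)]
    w[unique(hit)] <- w[unique(hit)] * rm[[key]]
  }
  w
}

#' Generate a synthetic tumor cohort
#'
#' Draws patients (tumor type, mutation count), then mutations: the
#' substitution type follows the model spectrum; conditional on type, the
#' position is drawn over all genome positions carrying the source base
#' with probability proportional to the product of the position's region
#' multiplier and, for mRNA positions (primary frame), the effect of the
#' mutant codon the substitution would create; heteroplasmy follows the
#' model's mixture law. Fully reproducible from `seed`.
#'
#' @param model An [cohort_model()].
#' @param genome A [load_reference()] genome.
#' @param seed Integer seed.
#' @return A cohort tibble in the canonical layout (one row per
#'   patient-mutation record).
#' @export
generate_cohort <- function(model, genome, seed = 1L) {
  stopifnot(inherits(model, "mt_cohort_model"),
            inherits(genome, "mito_genome"))
  set.seed(seed)
  idx <- genome$index
  sp <- model$spectrum[match(substitution_types(),
                             model$spectrum$subst_type), ]
  src <- match(substr(sp$subst_type, 1, 1), BASES)
  alt_chr <- substr(sp$subst_type, 3, 3)
  alt_int <- match(alt_chr, BASES)

  pos_mult <- position_multipliers(model, genome)

  # per-type placement weights over matching positions
  type_pools <- vector("list", 12L)
  type_weights <- vector("list", 12L)
  eff <- model$codon_effects
  for (t in 1:12) {
    pool <- idx$pos_by_base[[src[t]]]
    w <- pos_mult[pool]
    if (length(eff)) {
      ok <- idx$mr_ok[pool]
      p <- pool[ok]
      a <- rep(alt_int[t], length(p))
      onL <- idx$mr_L[p]
      ref_c <- idx$base_int[p]
      a[onL] <- COMP_INT[a[onL]]
      ref_c[onL] <- COMP_INT[ref_c[onL]]
      mut_codon <- idx$codon_names[idx$mr_refidx[p] +
                                     (a - ref_c) * idx$mr_place[p] + 1L]
      fx <- eff[mut_codon]
      fx[is.na(fx)] <- 1
      w[ok] <- w[ok] * unname(fx)
    }
    type_pools[[t]] <- pool
    type_weights[[t]] <- w
  }
  live <- vapply(type_weights, function(w) sum(w) > 0, logical(1))
  if (!any(live[sp$freq > 0])) {
    abort("All placement weights are zero; no position can be mutated.",
          class = "mitoselect_empty_support")
  }

  counts <- sample(as.integer(names(model$count_law)), model$n_patients,
                   replace = TRUE, prob = model$count_law)
  n <- sum(counts)
  tt <- model$tumor_types
  ttype <- sample(tt$tumor_type, model$n_patients, replace = TRUE,
                  prob = tt$weight)
  hist_grp <- tt$histology_group[match(ttype, tt$tumor_type)]

  tfreq <- sp$freq * as.numeric(live)
  ty <- sample.int(12L, n, replace = TRUE, prob = tfreq)
  pos <- integer(n)
  for (t in unique(ty)) {
    sel <- ty == t
    pool <- type_pools[[t]]
    w <- type_weights[[t]]
    pos[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE,
                                prob = w)]
  }

  hp <- model$heteroplasmy
  is_low <- stats::runif(n) < hp$weight_low
  b <- stats::rbeta(n, hp$shape[1], hp$shape[2])
  het <- if_else(is_low,
                 hp$low[1] + b * (hp$low[2] - hp$low[1]),
                 hp$high[2] - b * (hp$high[2] - hp$high[1]))
  het[stats::runif(n) < hp$prop_missing] <- NA_real_

  pid <- sprintf("P%05d", seq_len(model$n_patients))
  tibble(
    patient_id = rep(pid, counts),
    tumor_type = rep(ttype, counts),
    histology_group = rep(hist_grp, counts),
    position = pos,
    ref = genome$seq[pos],
    alt = alt_chr[ty],
    heteroplasmy = het,
    source = "synthetic",
    method = "WGS"
  )
}

#' Ground-truth report of planted selection effects
#'
#' Machine-readable list of the non-neutral effects a cohort model plants,
#' for recovery scoring. Round-trips through JSON unchanged.
#'
#' @param model An [cohort_model()].
#' @return A tibble with columns `unit_type` (`region`/`codon`), `label`,
#'   `multiplier`, `direction` (`enriched`/`depleted`); zero rows for a
#'   neutral model.
#' @export
plant_truth_report <- function(model) {
  stopifnot(inherits(model, "mt_cohort_model"))
  rows <- list()
  rm <- model$region_multipliers
  rm <- rm[rm != 1]
  if (length(rm)) {
    rows <- c(rows, list(tibble(unit_type = "region", label = names(rm),
                                multiplier = unname(rm))))
  }
  ce <- model$codon_effects
  ce <- ce[ce != 1]
  if (length(ce)) {
    rows <- c(rows, list(tibble(unit_type = "codon", label = names(ce),
                                multiplier = unname(ce))))
  }
  if (!length(rows)) {
    return(tibble(unit_type = character(), label = character(),
                  multiplier = numeric(), direction = character()))
  }
  bind_rows(rows) %>%
    mutate(direction = if_else(.data$multiplier > 1, "enriched", "depleted"))
}
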