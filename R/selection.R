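# Selection statistics: densities, recurrence, residuals, heteroplasmy
# comparisons, stratified class proportions.

#' Mutation densities across genomic groupings
#'
#' Computes, for each group of a genomic partition, the mutation count,
#' region length (bp) and density (count / length), with a chi-square test
#' of the counts against length-proportional expectations. Groupings:
#' `"coding_vs_noncoding"`; `"complex"` (OXPHOS complexes I/III/IV/V plus
#' tRNA and rRNA); `"gene"` (per gene; a mutation in overlapping genes
#' counts toward each gene, preserving per-gene density comparability);
#' `"trna_unit"` (tRNA stems versus loops/variable regions under the
#' idealized cloverleaf model). `stratify_base` restricts both counts and
#' region lengths to positions carrying that reference base.
#'
#' @param cohort A data frame with a `position` column.
#' @param genome A [load_reference()] genome.
#' @param grouping One of the groupings above.
#' @param stratify_base Optional single base `"A"/"C"/"G"/"T"`.
#' @param genes Optional character vector restricting the `"gene"` grouping
#'   (e.g. `c("ATP6", "ATP8")`).
#' @return An `mt_density` tibble (`group`, `count`, `length_bp`,
#'   `density`) with the chi-square test in attribute `"test"`; see
#'   [glance.mt_density()].
#' @export
mutation_density <- function(cohort, genome,
                             grouping = c("coding_vs_noncoding", "complex",
                                          "gene", "trna_unit"),
                             stratify_base = NULL, genes = NULL) {
  grouping <- match.arg(grouping)
  rp <- region_positions(genome, grouping)
  if (!is.null(genes)) {
    rp <- rp %>% filter(.data$group %in% genes)
  }
  if (!is.null(stratify_base)) {
    stopifnot(stratify_base %in% BASES)
    rp <- rp %>% filter(genome$seq[.data$position] == stratify_base)
  }
  lens <- rp %>% count(.data$group, name = "length_bp")
  zero <- lens$group[lens$length_bp == 0]
  if (length(zero)) {
    warn(paste0("Zero-length group(s) excluded: ",
                paste(zero, collapse = ", ")))
    lens <- lens[lens$length_bp > 0, ]
  }
  counts <- tibble(position = as.integer(cohort$position)) %>%
    inner_join(rp, by = "position", relationship = "many-to-many") %>%
    count(.data$group, name = "count")
  out <- lens %>%
    left_join(counts, by = "group") %>%
    mutate(count = if_else(is.na(.data$count), 0L, .data$count),
           density = .data$count / .data$length_bp) %>%
    select("group", "count", "length_bp", "density")
  test <- NULL
  if (nrow(out) >= 2 && sum(out$count) > 0) {
    test <- suppressWarnings(
      chisq.test(out$count, p = out$length_bp / sum(out$length_bp))
    )
  }
  structure(out, test = test, grouping = grouping,
            stratify_base = stratify_base,
            class = c("mt_density", class(out)))
}

#' Recurrence analysis of mutation positions
#'
#' For every mutated position, the recurrence `R` is the number of patient
#' records carrying a mutation there (distinct alleles at one position are
#' collapsed by summing). A position is recurrent iff `R > 1`. The
#' per-region recurrence rate is `F = sum(R) / L`, the total recurrence in
#' the region divided by its length in bp.
#'
#' @param cohort A data frame with a `position` column (one row per
#'   patient-mutation record).
#' @param genome A [load_reference()] genome.
#' @param grouping Region grouping for `F` (as in [mutation_density()]).
#' @param top_k How many top recurrent positions to report.
#' @return An `mt_recurrence` list: `positions` (position, R, recurrent),
#'   `regions` (group, sum_R, length_bp, F), `top` (the `top_k` most
#'   recurrent positions).
#' @export
recurrence <- function(cohort, genome, grouping = "coding_vs_noncoding",
                       top_k = 10) {
  if (nrow(cohort) == 0) {
    abort("Cohort is empty.", class = "mitoselect_bad_input")
  }
  positions <- cohort %>%
    count(.data$position, name = "R") %>%
    mutate(recurrent = .data$R > 1)
  rp <- region_positions(genome, grouping)
  regions <- positions %>%
    inner_join(rp, by = "position", relationship = "many-to-many") %>%
    group_by(.data$group) %>%
    summarise(sum_R = sum(.data$R), .groups = "drop") %>%
    left_join(rp %>% count(.data$group, name = "length_bp"), by = "group") %>%
    mutate(F = .data$sum_R / .data$length_bp)
  top <- positions %>%
    slice_max(.data$R, n = top_k, with_ties = FALSE) %>%
    arrange(dplyr::desc(.data$R))
  structure(list(positions = positions, regions = regions, top = top),
            class = "mt_recurrence")
}

#' @export
print.mt_recurrence <- function(x, ...) {
  n_rec <- sum(x$positions$recurrent)
  cat("<mt_recurrence> ", nrow(x$positions), " distinct positions; ",
      n_rec, " recurrent (R > 1)\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Observed-versus-simulated residual analysis
#'
#' Compares observed category counts (mutant codons, amino acids or
#' triplets) against a neutral reference (replicate-averaged simulated
#' counts). The residual of category c is `delta_c = observed_c -
#' simulated_c`, so positive values mean an observed excess; the
#' standardized residual is `(delta_c - mean(delta)) / sd(delta)` using the
#' sample (n-1) standard deviation. Categories with `|standardized| >
#' threshold` (default 2) are flagged: positive flags are candidates for
#' positive selection, negative flags for negative selection. Pearson's
#' correlation between the observed and simulated count vectors is
#' attached. An optional regression mode standardizes the residuals of the
#' least-squares line of observed on simulated instead of the raw count
#' differences.
#'
#' @param observed,simulated Tibbles with `category` and `count` columns
#'   (e.g. [count_mutant_categories()]); the category universe is the union
#'   of both, missing entries filled with 0.
#' @param threshold Outlier threshold on `|standardized residual|`.
#' @param method `"difference"` (raw count differences; default) or
#'   `"regression"` (residuals about the least-squares trend line).
#' @return An `mt_residuals` tibble: `category`, `observed`, `simulated`,
#'   `residual`, `std_residual`, `outlier`, `direction`; attributes carry
#'   the Pearson test and settings. See [tidy.mt_residuals()] /
#'   [glance.mt_residuals()] / [autoplot.mt_residuals()].
#' @export
residual_analysis <- function(observed, simulated, threshold = 2,
                              method = c("difference", "regression")) {
  method <- match.arg(method)
  universe <- union(observed$category, simulated$category)
  if (length(universe) < 3) {
    abort("Residual analysis needs at least 3 categories.",
          class = "mitoselect_insufficient_data")
  }
  o <- setNames(rep(0, length(universe)), universe)
  s <- o
  o[observed$category] <- observed$count
  s[simulated$category] <- simulated$count

  if (method == "difference") {
    delta <- o - s
  } else {
    fit <- lm(o ~ s)
    delta <- unname(resid(fit))
  }
  sdd <- sd(delta)
  if (!is.finite(sdd) || sdd == 0) {
    abort("Residuals have zero variance; standardized residuals undefined.",
          class = "mitoselect_degenerate_variance")
  }
  std <- (delta - mean(delta)) / sdd
  ct <- suppressWarnings(cor.test(o, s, method = "pearson"))
  out <- tibble(
    category = universe,
    observed = unname(o),
    simulated = unname(s),
    residual = unname(delta),
    std_residual = unname(std),
    outlier = abs(std) > threshold,
    direction = dplyr::case_when(
      abs(std) > threshold & std > 0 ~ "positive",
      abs(std) > threshold & std < 0 ~ "negative",
      TRUE ~ "none"
    )
  ) %>%
    arrange(dplyr::desc(abs(.data$std_residual)))
  structure(out, pearson = ct, threshold = threshold, method = method,
            class = c("mt_residuals", class(out)))
}

#' Compare heteroplasmy levels between groups
#'
#' Group means with SEM; a two-tailed Student's t-test for two groups, a
#' one-way ANOVA for more. Records without a heteroplasmy value are
#' excluded (and counted); groups with fewer than two values are dropped
#' with a warning.
#'
#' @param x A data frame with a `heteroplasmy` column.
#' @param group Name of the grouping column in `x`.
#' @return An `mt_het_compare` tibble (`group`, `n`, `mean`, `sem`) with
#'   the test in attribute `"test"`; see [glance.mt_het_compare()].
#' @export
heteroplasmy_compare <- function(x, group) {
  stopifnot(group %in% names(x), "heteroplasmy" %in% names(x))
  d <- x %>%
    filter(!is.na(.data$heteroplasmy), !is.na(.data[[group]]))
  n_missing <- nrow(x) - nrow(d)
  sizes <- d %>% count(.data[[group]])
  small <- sizes[[group]][sizes$n < 2]
  if (length(small)) {
    warn(paste0("Group(s) with < 2 heteroplasmy values dropped: ",
                paste(small, collapse = ", ")))
    d <- d %>% filter(!(.data[[group]] %in% small))
  }
  groups <- unique(d[[group]])
  if (length(groups) < 2) {
    abort("Need at least two groups with >= 2 heteroplasmy values.",
          class = "mitoselect_insufficient_data")
  }
  stats_tbl <- d %>%
    group_by(.data[[group]]) %>%
    summarise(n = n(), mean = mean(.data$heteroplasmy),
              sem = sd(.data$heteroplasmy) / sqrt(n()), .groups = "drop")
  names(stats_tbl)[1] <- "group"
  if (length(groups) == 2) {
    test <- safe_t_test(d$heteroplasmy[d[[group]] == groups[1]],
                        d$heteroplasmy[d[[group]] == groups[2]])
  } else {
    test <- aov(d$heteroplasmy ~ factor(d[[group]]))
  }
  structure(stats_tbl, test = test, n_missing = n_missing,
            class = c("mt_het_compare", class(stats_tbl)))
}

#' Assign heteroplasmy strata
#'
#' The three strata used for heteroplasmy-stratified analyses, with
#' boundary ties resolved outward: `low` for values <= 0.05, `high` for
#' values >= 0.9, `mid` in between; `NA` stays `NA`.
#'
#' @param h Numeric vector of heteroplasmy fractions.
#' @return Character vector in `{"low","mid","high"}`.
#' @export
heteroplasmy_stratum <- function(h) {
  dplyr::case_when(
    is.na(h) ~ NA_character_,
    h <= 0.05 ~ "low",
    h >= 0.9 ~ "high",
    TRUE ~ "mid"
  )
}

#' Class proportions stratified by heteroplasmy
#'
#' Computes, for each heteroplasmy stratum (<= 0.05, 0.05-0.9, >= 0.9), the
#' proportions of a two-or-more-level mutation classification, with a
#' chi-square test of homogeneity across strata. Panels: synonymous versus
#' nonsynonymous (mRNA mutations), benign versus deleterious tRNA impact,
#' mRNA impact grades (both requiring an impact table), and mutant codons
#' completely complementary to their anticodon (CC) versus not (NCC).
#' Optionally, unstratified three-way comparisons against a supplied
#' population count table and/or a simulated mutation set are added.
#'
#' @param cohort A cohort with a `heteroplasmy` column.
#' @param genome A [load_reference()] genome.
#' @param panel One of `"syn_vs_nonsyn"`, `"trna_benign_vs_deleterious"`,
#'   `"impact_grades"`, `"codon_CC_vs_NCC"`.
#' @param impacts An impact table ([load_impact_table()]); required for the
#'   impact panels.
#' @param population Optional tibble `category`/`count`: unstratified
#'   reference proportions from a population dataset.
#' @param simulated Optional simulated mutation set (as from
#'   [simulate_neutral()]) used as the neutral reference in the
#'   unstratified comparison.
#' @return An `mt_strata` list: `strata` (stratum, category, n, prop),
#'   `test` (chi-square across strata), optionally `unstratified` and
#'   `unstratified_test`, plus bookkeeping counts.
#' @export
stratified_class_proportions <- function(cohort, genome,
                                         panel = c("syn_vs_nonsyn",
                                                   "trna_benign_vs_deleterious",
                                                   "impact_grades",
                                                   "codon_CC_vs_NCC"),
                                         impacts = NULL, population = NULL,
                                         simulated = NULL) {
  panel <- match.arg(panel)
  lab <- panel_labels(cohort, genome, panel, impacts)
  d <- lab %>% filter(!is.na(.data$category))
  d$stratum <- heteroplasmy_stratum(d$heteroplasmy)
  ds <- d %>% filter(!is.na(.data$stratum))

  strata <- ds %>%
    count(.data$stratum, .data$category, name = "n") %>%
    group_by(.data$stratum) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
  tab <- ds %>%
    count(.data$stratum, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0)
  m <- as.matrix(tab[, -1])
  keep <- rowSums(m) > 0
  test <- NULL
  if (sum(keep) >= 2 && ncol(m) >= 2) {
    test <- suppressWarnings(chisq.test(m[keep, , drop = FALSE],
                                        correct = FALSE))
  }

  unstrat <- NULL
  unstrat_test <- NULL
  refs <- list(tumor = d %>% count(.data$category, name = "count"))
  if (!is.null(simulated)) {
    sim_lab <- panel_labels(simulated, genome, panel, impacts)
    refs$simulation <- sim_lab %>%
      filter(!is.na(.data$category)) %>%
      count(.data$category, name = "count")
  }
  if (!is.null(population)) refs$population <- as_tibble(population)
  if (length(refs) > 1) {
    unstrat <- purrr::imap_dfr(refs, function(tb, nm) {
      tb %>% mutate(dataset = nm, prop = .data$count / sum(.data$count))
    })
    wt <- unstrat %>%
      tidyr::pivot_wider(id_cols = "dataset", names_from = "category",
                         values_from = "count", values_fill = 0)
    unstrat_test <- suppressWarnings(
      chisq.test(as.matrix(wt[, -1]), correct = FALSE)
    )
  }

  structure(list(panel = panel, strata = strata, test = test,
                 unstratified = unstrat, unstratified_test = unstrat_test,
                 n_without_heteroplasmy = sum(is.na(d$stratum)),
                 n_unclassified = sum(is.na(lab$category))),
            class = "mt_strata")
}

# per-record panel classification (NA = not classifiable for this panel)
panel_labels <- function(x, genome, panel, impacts) {
  ann <- annotate_mutations(x, genome)
  cls <- mutation_classes(ann)
  category <- switch(panel,
    syn_vs_nonsyn = if_else(
      cls$mclass %in% c("synonymous", "nonsynonymous"),
      cls$mclass, NA_character_),
    codon_CC_vs_NCC = {
      cc <- codon_cc_table()
      if_else(!is.na(cls$mut_codon) & cls$mut_codon %in% cc$codon,
              if_else(cls$mut_codon %in% cc$codon[cc$cc], "CC", "NCC"),
              NA_character_)
    },
    trna_benign_vs_deleterious = {
      if (is.null(impacts)) {
        abort("Panel needs an impact table.", class = "mitoselect_config_error")
      }
      imp <- impacts %>% filter(.data$domain == "tRNA")
      j <- cls %>%
        left_join(imp, by = c("position", "ref", "alt"))
      if_else(cls$mclass == "tRNA", j$category, NA_character_)
    },
    impact_grades = {
      if (is.null(impacts)) {
        abort("Panel needs an impact table.", class = "mitoselect_config_error")
      }
      imp <- impacts %>% filter(.data$domain == "mRNA")
      j <- cls %>%
        left_join(imp, by = c("position", "ref", "alt"))
      if_else(cls$ftype == "mRNA", j$category, NA_character_)
    }
  )
  out <- tibble(category = category)
  out$heteroplasmy <- if ("heteroplasmy" %in% names(x)) x$heteroplasmy else NA_real_
  out
}
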