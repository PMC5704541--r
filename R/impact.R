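# Externally supplied functional-impact categories.

IMPACT_VOCAB <- list(
  mRNA = c("high", "medium", "low", "neutral"),
  tRNA = c("benign", "deleterious")
)

#' Load a functional-impact table
#'
#' Reads a tab-delimited table of per-substitution functional-impact
#' predictions: columns `position`, `ref`, `alt`, `domain` (`mRNA` or
#' `tRNA`) and `category` (`high`/`medium`/`low`/`neutral` for mRNA,
#' `benign`/`deleterious` for tRNA). Impact prediction itself is out of
#' scope; these tables are consumed as input. Exact duplicates collapse
#' with a warning; a key appearing with conflicting categories is an error.
#'
#' @param file Path to the TSV.
#' @return An `mt_impact` tibble with unique `(position, ref, alt, domain)`
#'   keys.
#' @export
load_impact_table <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           position = readr::col_integer(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           domain = readr::col_character(),
                           category = readr::col_character()
                         ))
  need <- c("position", "ref", "alt", "domain", "category")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    abort(paste0("Impact table missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mitoselect_config_error")
  }
  bad_dom <- !(out$domain %in% names(IMPACT_VOCAB))
  if (any(bad_dom)) {
    abort(paste0("Unknown impact domain(s): ",
                 paste(unique(out$domain[bad_dom]), collapse = ", ")),
          class = "mitoselect_vocabulary_error")
  }
  ok <- mapply(function(d, c) c %in% IMPACT_VOCAB[[d]],
               out$domain, out$category)
  if (!all(ok)) {
    abort(paste0("Invalid impact categor(ies): ",
                 paste(unique(out$category[!ok]), collapse = ", ")),
          class = "mitoselect_vocabulary_error")
  }
  dup <- duplicated(out)
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicate impact row(s) collapsed."))
    out <- out[!dup, ]
  }
  key_dup <- out %>%
    count(.data$position, .data$ref, .data$alt, .data$domain) %>%
    filter(.data$n > 1)
  if (nrow(key_dup)) {
    abort(paste0("Conflicting impact categories for key(s): ",
                 paste(head(paste0(key_dup$position, key_dup$ref, ">",
                                   key_dup$alt), 5), collapse = ", ")),
          class = "mitoselect_conflict_error")
  }
  class(out) <- c("mt_impact", class(out))
  out
}

#' Impact-category proportions across groups
#'
#' Joins functional-impact categories to annotated mutations and compares
#' category proportions across groups with a chi-square test. Records
#' without an impact annotation are counted per group but excluded from
#' proportions and from the test. `collapse` merges categories before
#' testing (e.g. `c(high = "damaging", medium = "damaging", low = "other",
#' neutral = "other")`), since figure-level binarizations vary.
#'
#' @param cohort A cohort tibble.
#' @param genome A [load_reference()] genome.
#' @param impacts An `mt_impact` table.
#' @param grouping `"complex"`, `"gene"`, `"trna_unit"`, or the name of a
#'   column already present in `cohort` (e.g. a residual-outlier class
#'   label).
#' @param domain `"mRNA"` or `"tRNA"`: which impact domain to use.
#' @param genes Optional restriction of the `"gene"` grouping.
#' @param collapse Optional named character vector mapping categories to
#'   merged labels.
#' @return An `mt_impact_prop` list: `proportions` (group, category, n,
#'   prop), `unannotated` (per-group counts), `test`.
#' @export
impact_proportions <- function(cohort, genome, impacts,
                               grouping = "complex", domain = "mRNA",
                               genes = NULL, collapse = NULL) {
  stopifnot(domain %in% names(IMPACT_VOCAB))
  imp <- impacts %>% filter(.data$domain == !!domain)

  if (grouping %in% names(cohort)) {
    d <- cohort %>%
      mutate(group = .data[[grouping]]) %>%
      select("position", "ref", "alt", "group")
  } else {
    rp <- region_positions(genome, grouping)
    if (!is.null(genes)) rp <- rp %>% filter(.data$group %in% genes)
    d <- cohort %>%
      select("position", "ref", "alt") %>%
      inner_join(rp, by = "position", relationship = "many-to-many")
  }
  d <- d %>%
    left_join(imp %>% select("position", "ref", "alt", "category"),
              by = c("position", "ref", "alt"))
  if (!is.null(collapse)) {
    d <- d %>%
      mutate(category = if_else(.data$category %in% names(collapse),
                                unname(collapse[.data$category]),
                                .data$category))
  }
  unann <- d %>%
    group_by(.data$group) %>%
    summarise(n_unannotated = sum(is.na(.data$category)), .groups = "drop")
  da <- d %>% filter(!is.na(.data$category))
  empty <- setdiff(unique(d$group), unique(da$group))
  if (length(empty)) {
    warn(paste0("Group(s) without annotated records excluded: ",
                paste(empty, collapse = ", ")))
  }
  props <- da %>%
    count(.data$group, .data$category, name = "n") %>%
    group_by(.data$group) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
  tab <- da %>%
    count(.data$group, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0)
  test <- NULL
  if (nrow(tab) >= 2 && ncol(tab) >= 3) {
    test <- suppressWarnings(chisq.test(as.matrix(tab[, -1]), correct = FALSE))
  }
  structure(list(proportions = props, unannotated = unann, test = test,
                 grouping = grouping, domain = domain),
            class = "mt_impact_prop")
}
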