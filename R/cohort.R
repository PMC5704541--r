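# Cohort assembly: reading, merging, filtering and summarizing somatic
# mutation tables from multiple sources.

COHORT_COLS <- c("patient_id", "tumor_type", "histology_group", "position",
                 "ref", "alt", "heteroplasmy", "source", "method")

#' Read a somatic mutation table
#'
#' Reads a delimited text file of somatic single-base mutation calls into
#' the canonical cohort layout. A dialect maps the file's column names onto
#' the canonical ones and declares the heteroplasmy unit. Rows failing
#' validation (position outside \[1, 16569\], non-ACGT or equal ref/alt
#' bases, unparseable heteroplasmy) are collected into a rejection report
#' attached as the `"rejections"` attribute, never silently dropped.
#'
#' @param file Path to a TSV/CSV file.
#' @param dialect A list (or path to a YAML file) with elements `columns`
#'   (named list canonical -> file column; `patient_id`, `position`, `ref`,
#'   `alt` are mandatory), `heteroplasmy_unit` (`"fraction"` or
#'   `"percent"`), and optional fixed `method` and `source` labels.
#' @param delim Field delimiter; guessed from the file extension by default.
#' @return A tibble of mutation records with attribute `"rejections"` (a
#'   tibble with columns `row` and `reason`).
#' @export
read_mutation_table <- function(file, dialect, delim = NULL) {
  if (is.character(dialect) && length(dialect) == 1) {
    rlang::check_installed("yaml")
    dialect <- yaml::read_yaml(dialect)
  }
  cols <- dialect$columns
  mandatory <- c("patient_id", "position", "ref", "alt")
  miss <- setdiff(mandatory, names(cols))
  if (length(miss)) {
    abort(paste0("Dialect lacks mapping for mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mitoselect_config_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  absent <- setdiff(unlist(cols), names(raw))
  if (length(absent)) {
    abort(paste0("File lacks mapped column(s): ",
                 paste(absent, collapse = ", ")),
          class = "mitoselect_config_error")
  }
  get <- function(canon) {
    if (canon %in% names(cols)) raw[[cols[[canon]]]] else NA_character_
  }
  n <- nrow(raw)
  out <- tibble(
    patient_id = get("patient_id"),
    tumor_type = get("tumor_type"),
    histology_group = get("histology_group"),
    position = suppressWarnings(as.integer(get("position"))),
    ref = toupper(get("ref")),
    alt = toupper(get("alt")),
    heteroplasmy = {
      h <- get("heteroplasmy")
      h <- sub("%$", "", h)
      suppressWarnings(as.numeric(h))
    },
    source = if (!is.null(dialect$source)) dialect$source else get("source"),
    method = if (!is.null(dialect$method)) dialect$method else get("method")
  )
  if (identical(dialect$heteroplasmy_unit, "percent")) {
    out$heteroplasmy <- out$heteroplasmy / 100
  }
  reason <- rep(NA_character_, n)
  had_het <- !is.na(get("heteroplasmy")) & nzchar(get("heteroplasmy"))
  bad_pos <- is.na(out$position) | out$position < 1 | out$position > MT_LENGTH
  bad_base <- !(out$ref %in% BASES) | !(out$alt %in% BASES) | out$ref == out$alt
  bad_het <- had_het & is.na(out$heteroplasmy)
  reason[bad_het] <- "unparseable heteroplasmy"
  reason[bad_base] <- "invalid ref/alt base"
  reason[bad_pos] <- "position out of range"
  keep <- is.na(reason)
  rej <- tibble(row = which(!keep), reason = reason[!keep])
  if (nrow(rej)) {
    warn(paste0(nrow(rej), " row(s) rejected while reading ", file,
                "; see attr(x, \"rejections\")."))
  }
  res <- out[keep, ]
  attr(res, "rejections") <- rej
  res
}

#' Read mutation records from a VCF file
#'
#' A minimal convenience reader for uncompressed single-sample VCFs:
#' POS/REF/ALT are taken from the fixed fields, multiallelic rows are
#' expanded, and only single-base substitutions are kept. No genotype
#' semantics are interpreted.
#'
#' @param file Path to a VCF.
#' @param patient_id,source,method Labels applied to every record.
#' @return A tibble of mutation records.
#' @export
read_mutation_vcf <- function(file, patient_id, source = "vcf",
                              method = "WGS") {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble(position = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT) %>%
    tidyr::separate_longer_delim("alt", delim = ",") %>%
    filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1,
           .data$ref %in% BASES, .data$alt %in% BASES)
  out %>%
    mutate(patient_id = patient_id, tumor_type = NA_character_,
           histology_group = NA_character_, heteroplasmy = NA_real_,
           source = source, method = method) %>%
    select(all_of(COHORT_COLS))
}

new_provenance <- function() {
  tibble(step = character(), detail = character(),
         n_before = integer(), n_after = integer())
}

log_step <- function(prov, step, detail, n_before, n_after) {
  bind_rows(prov, tibble(step = step, detail = detail,
                         n_before = as.integer(n_before),
                         n_after = as.integer(n_after)))
}

#' Provenance log of a cohort
#'
#' @param x A cohort produced by [merge_cohorts()] or [apply_filters()].
#' @return A tibble of merge/filter actions with before/after record counts.
#' @export
provenance <- function(x) {
  attr(x, "provenance") %||% new_provenance()
}

mutation_key <- function(x) {
  paste(x$position, x$ref, x$alt, sep = ":")
}

#' Merge mutation sources into one cohort
#'
#' Applies the dataset-assembly rules used for multi-source tumor mtDNA
#' collections: within each patient, sources sequenced by the same method
#' are intersected (a mutation is kept only if every same-method source
#' listing that patient reports it); when a patient was sequenced by
#' several methods, only the highest-priority method is retained
#' (WGS > WES > capture). Exact duplicate records within one source are
#' collapsed with a warning. Conflicting reference bases at the same
#' position across sources raise an error.
#'
#' @param sources A list of mutation-record tibbles (each with `source` and
#'   `method` columns filled, e.g. by [read_mutation_table()]).
#' @return A cohort tibble with a `"provenance"` attribute (see
#'   [provenance()]).
#' @export
merge_cohorts <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1)
  prov <- new_provenance()
  sources <- purrr::imap(sources, function(s, i) {
    s <- as_tibble(s)
    if (!"source" %in% names(s) || all(is.na(s$source))) {
      s$source <- paste0("source", i)
    }
    if (!"method" %in% names(s)) {
      abort("Every source needs a 'method' column (WGS/WES/capture).",
            class = "mitoselect_config_error")
    }
    dup <- duplicated(s[, c("patient_id", "position", "ref", "alt")])
    if (any(dup)) {
      warn(paste0(sum(dup), " duplicate record(s) collapsed within source '",
                  s$source[1], "'."))
      s <- s[!dup, ]
    }
    s
  })
  all <- bind_rows(sources)
  n0 <- nrow(all)

  conf <- all %>%
    distinct(.data$position, .data$ref) %>%
    count(.data$position) %>%
    filter(.data$n > 1)
  if (nrow(conf)) {
    abort(paste0("Conflicting reference base across sources at position(s): ",
                 paste(head(conf$position, 5), collapse = ", ")),
          class = "mitoselect_conflict_error")
  }

  pri <- c(WGS = 1, WES = 2, capture = 3)
  method_rank <- function(m) {
    r <- pri[m]
    if (anyNA(r)) r[is.na(r)] <- 4 + match(m[is.na(r)], unique(m[is.na(r)]))
    r
  }
  all$.rank <- method_rank(all$method)

  merged <- all %>%
    group_by(.data$patient_id) %>%
    group_modify(function(d, key) {
      best <- min(d$.rank)
      d <- d[d$.rank == best, ]
      srcs <- unique(d$source)
      if (length(srcs) > 1) {
        keys <- lapply(srcs, function(s) mutation_key(d[d$source == s, ]))
        keep <- Reduce(intersect, keys)
        d <- d[d$source == srcs[1] & mutation_key(d) %in% keep, ]
      }
      d
    }) %>%
    ungroup() %>%
    select(-".rank")

  prov <- log_step(prov, "merge",
                   paste0(length(sources),
                          " source(s); same-method intersection, ",
                          "method priority WGS > WES > capture"),
                   n0, nrow(merged))
  structure(as_tibble(merged), provenance = prov)
}

#' Filter a cohort on heteroplasmy and per-patient mutation burden
#'
#' Applies, in order: (1) the variant-allele-fraction filter, dropping
#' records with `heteroplasmy < min_vaf` (records without a heteroplasmy
#' value are kept); (2) the hypermutator exclusion, dropping every record
#' of a patient whose remaining mutation count exceeds
#' `max_mutations_per_patient` (default 12, i.e. patients with >= 13
#' mutations are excluded).
#'
#' @param cohort A cohort tibble.
#' @param max_mutations_per_patient Highest per-patient count retained.
#' @param min_vaf Minimum heteroplasmy (variant allele fraction) retained.
#' @return The filtered cohort with updated provenance.
#' @export
apply_filters <- function(cohort, max_mutations_per_patient = 12,
                          min_vaf = 0.02) {
  stopifnot(max_mutations_per_patient > 0, min_vaf > 0)
  prov <- provenance(cohort)
  n0 <- nrow(cohort)
  out <- cohort %>%
    filter(is.na(.data$heteroplasmy) | .data$heteroplasmy >= min_vaf)
  prov <- log_step(prov, "vaf_filter",
                   paste0("heteroplasmy >= ", min_vaf,
                          " (records without a value kept)"),
                   n0, nrow(out))
  n1 <- nrow(out)
  out <- out %>%
    group_by(.data$patient_id) %>%
    filter(n() <= max_mutations_per_patient) %>%
    ungroup()
  prov <- log_step(prov, "burden_filter",
                   paste0("patients with > ", max_mutations_per_patient,
                          " mutations excluded"),
                   n1, nrow(out))
  structure(as_tibble(out), provenance = prov)
}

#' Summarize a cohort
#'
#' Computes the descriptive characterization of a mutation cohort:
#' mutation-class counts (one class per mutation, most severe across
#' overlapping frames), transition/transversion split, 12-type substitution
#' counts with heavy/light display labels, the per-patient mutation-count
#' histogram, mean mutations per patient by tumor type, a carcinoma-versus-
#' sarcoma comparison of per-patient counts (Student's t-test, two-tailed),
#' and coding versus non-coding mutation densities with a chi-square test
#' against length-proportional expectations.
#'
#' @param cohort A cohort tibble.
#' @param genome A [load_reference()] genome.
#' @return An object of class `mt_cohort_summary` (a named list of tibbles
#'   and test results).
#' @export
summarize_cohort <- function(cohort, genome) {
  if (nrow(cohort) == 0) {
    abort("Cohort is empty.", class = "mitoselect_bad_input")
  }
  ann <- annotate_mutations(cohort, genome)
  cls <- mutation_classes(ann)

  class_counts <- cls %>%
    count(.data$mclass, name = "n") %>%
    mutate(prop = .data$n / sum(.data$n))

  titv <- cls %>%
    count(.data$is_transition, name = "n") %>%
    mutate(kind = if_else(.data$is_transition, "transition", "transversion"),
           prop = .data$n / sum(.data$n)) %>%
    select("kind", "n", "prop")

  subst_counts <- cls %>%
    count(.data$subst_type, name = "n") %>%
    mutate(display = hl_label(.data$subst_type)) %>%
    arrange(dplyr::desc(.data$n))

  per_patient <- cohort %>%
    count(.data$patient_id, name = "n_mutations")
  patient_hist <- per_patient %>%
    count(.data$n_mutations, name = "n_patients")

  per_type <- NULL
  histology_test <- NULL
  if ("tumor_type" %in% names(cohort) && !all(is.na(cohort$tumor_type))) {
    per_type <- cohort %>%
      group_by(.data$tumor_type) %>%
      summarise(n_patients = n_distinct(.data$patient_id),
                n_mutations = n(), .groups = "drop") %>%
      mutate(mean_per_patient = .data$n_mutations / .data$n_patients) %>%
      arrange(dplyr::desc(.data$mean_per_patient))
  } else {
    warn("tumor_type missing; per-type stratification skipped.")
  }
  if ("histology_group" %in% names(cohort) &&
      all(c("carcinoma", "sarcoma") %in% cohort$histology_group)) {
    pp <- cohort %>%
      group_by(.data$patient_id) %>%
      summarise(n = n(), histology = first(.data$histology_group),
                .groups = "drop") %>%
      filter(.data$histology %in% c("carcinoma", "sarcoma"))
    histology_test <- safe_t_test(pp$n[pp$histology == "carcinoma"],
                                  pp$n[pp$histology == "sarcoma"])
  }

  dens <- mutation_density(cohort, genome, grouping = "coding_vs_noncoding")

  structure(list(
    n_mutations = nrow(cohort),
    n_patients = n_distinct(cohort$patient_id),
    mean_mutations_per_patient = nrow(cohort) / n_distinct(cohort$patient_id),
    class_counts = class_counts,
    titv = titv,
    subst_counts = subst_counts,
    patient_hist = patient_hist,
    per_type = per_type,
    histology_test = histology_test,
    density_coding = dens
  ), class = "mt_cohort_summary")
}

#' @export
print.mt_cohort_summary <- function(x, ...) {
  cat("<mt_cohort_summary>\n")
  cat("  mutations:", x$n_mutations, " patients:", x$n_patients,
      " mean/patient:", round(x$mean_mutations_per_patient, 3), "\n")
  ts <- x$titv$prop[x$titv$kind == "transition"]
  cat("  transitions:", sprintf("%.2f%%", 100 * ts), "\n")
  cat("  classes:\n")
  print(x$class_counts)
  invisible(x)
}

# Student's t-test robust to zero pooled variance (returns p = 0 with an
# infinite statistic instead of erroring on constant data)
safe_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NULL)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p.value = 1, method = "Student's t-test"))
    }
    return(list(statistic = Inf, p.value = 0, method = "Student's t-test"))
  }
  t.test(a, b, var.equal = TRUE)
}
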