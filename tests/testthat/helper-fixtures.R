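# Shared fixtures, built in code and cached for the test run.

.fx <- new.env(parent = emptyenv())

ref_genome <- function() {
  if (is.null(.fx$ref)) .fx$ref <- load_reference()
  .fx$ref
}

# 9-bp single-gene genome: ATG AAA TAA
mini_genome <- function() {
  if (is.null(.fx$mini)) {
    d <- tempfile("mini"); dir.create(d)
    ann <- file.path(d, "ann.tsv")
    fa <- file.path(d, "seq.fa")
    readr::write_tsv(tibble::tibble(
      gene = "G1", ftype = "mRNA", complex = "none", strand = "H",
      start = 1L, end = 9L, frame_anchor = 1L), ann)
    writeLines(c(">mini", "ATGAAATAA"), fa)
    .fx$mini <- load_reference(ann, fa)
  }
  .fx$mini
}

# 400-bp two-gene genome (lengths 100 and 300), random but fixed sequence
toy400_genome <- function() {
  if (is.null(.fx$toy400)) {
    d <- tempfile("toy400"); dir.create(d)
    ann <- file.path(d, "ann.tsv")
    fa <- file.path(d, "seq.fa")
    readr::write_tsv(tibble::tibble(
      gene = c("GA", "GB"), ftype = "mRNA", complex = "none", strand = "H",
      start = c(1L, 101L), end = c(100L, 400L),
      frame_anchor = c(1L, 101L)), ann)
    set.seed(42)
    writeLines(c(">toy400",
                 paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                       collapse = "")), fa)
    .fx$toy400 <- load_reference(ann, fa)
  }
  .fx$toy400
}

# a cohort row
rec <- function(patient, position, ref, alt, het = NA_real_,
                source = "s1", method = "WGS", tumor = "liver",
                histology = "carcinoma") {
  tibble::tibble(patient_id = patient, tumor_type = tumor,
                 histology_group = histology, position = as.integer(position),
                 ref = ref, alt = alt, heteroplasmy = het,
                 source = source, method = method)
}

# cohort rows at given positions against a genome, alt = any non-ref base
recs_at <- function(genome, positions, patients = NULL, het = NA_real_) {
  ref <- genome$seq[positions]
  alt <- ifelse(ref == "A", "G", "A")
  if (is.null(patients)) patients <- paste0("P", seq_along(positions))
  rec(patients, positions, ref, alt, het = het)
}

# find an example mutation of a given class in the reference genome
find_mutation <- function(genome, class, n = 1) {
  pm <- genome$pos_map
  cand <- pm[pm$slot == 1 & !is.na(pm$codon_complete) & pm$codon_complete &
               pm$strand == "H", ]
  cand <- cand[sample.int(nrow(cand)), ]
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    p <- cand$position[i]
    ref <- genome$seq[p]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- annotate_mutations(tibble::tibble(position = p, ref = ref,
                                             alt = alt), genome)
      a <- mutation_classes(a)
      if (a$mclass == class) {
        hits[[length(hits) + 1]] <- tibble::tibble(position = p, ref = ref,
                                                   alt = alt)
        break
      }
    }
    if (length(hits) >= n) break
  }
  dplyr::bind_rows(hits)
}
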