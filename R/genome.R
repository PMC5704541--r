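# Mitochondrial reference genome: annotation, fixture builder, loader, index.

MT_LENGTH <- 16569L

# Gene coordinates on the rCRS (1-based, inclusive, reference strand).
# These are the standard human mtDNA gene boundaries; frame_anchor is the
# genomic position of codon 1 base 1 (gene end for the L-strand ND6).
rcrs_gene_coords <- function() {
  m <- function(gene, cx, strand, start, end, anchor) {
    tibble(gene = gene, ftype = "mRNA", complex = cx, strand = strand,
           start = as.integer(start), end = as.integer(end),
           frame_anchor = as.integer(anchor))
  }
  t_ <- function(gene, strand, start, end) {
    tibble(gene = gene, ftype = "tRNA", complex = "none", strand = strand,
           start = as.integer(start), end = as.integer(end),
           frame_anchor = NA_integer_)
  }
  r_ <- function(gene, start, end) {
    tibble(gene = gene, ftype = "rRNA", complex = "none", strand = "H",
           start = as.integer(start), end = as.integer(end),
           frame_anchor = NA_integer_)
  }
  bind_rows(
    m("ND1",  "I",   "H",  3307,  4262,  3307),
    m("ND2",  "I",   "H",  4470,  5511,  4470),
    m("COX1", "IV",  "H",  5904,  7445,  5904),
    m("COX2", "IV",  "H",  7586,  8269,  7586),
    m("ATP8", "V",   "H",  8366,  8572,  8366),
    m("ATP6", "V",   "H",  8527,  9207,  8527),
    m("COX3", "IV",  "H",  9207,  9990,  9207),
    m("ND3",  "I",   "H", 10059, 10404, 10059),
    m("ND4L", "I",   "H", 10470, 10766, 10470),
    m("ND4",  "I",   "H", 10760, 12137, 10760),
    m("ND5",  "I",   "H", 12337, 14148, 12337),
    m("ND6",  "I",   "L", 14149, 14673, 14673),
    m("CYTB", "III", "H", 14747, 15887, 14747),
    t_("TRNF",  "H",   577,   647),
    t_("TRNV",  "H",  1602,  1670),
    t_("TRNL1", "H",  3230,  3304),
    t_("TRNI",  "H",  4263,  4331),
    t_("TRNQ",  "L",  4329,  4400),
    t_("TRNM",  "H",  4402,  4469),
    t_("TRNW",  "H",  5512,  5579),
    t_("TRNA",  "L",  5587,  5655),
    t_("TRNN",  "L",  5657,  5729),
    t_("TRNC",  "L",  5761,  5826),
    t_("TRNY",  "L",  5826,  5891),
    t_("TRNS1", "L",  7446,  7514),
    t_("TRND",  "H",  7518,  7585),
    t_("TRNK",  "H",  8295,  8364),
    t_("TRNG",  "H",  9991, 10058),
    t_("TRNR",  "H", 10405, 10469),
    t_("TRNH",  "H", 12138, 12206),
    t_("TRNS2", "H", 12207, 12265),
    t_("TRNL2", "H", 12266, 12336),
    t_("TRNE",  "L", 14674, 14742),
    t_("TRNT",  "H", 15888, 15953),
    t_("TRNP",  "L", 15956, 16023),
    r_("RNR1",   648,  1601),
    r_("RNR2",  1671,  3229)
  )
}

# Control region (two segments around the origin) plus computed intergenic
# spacers, so that the feature set covers all 16,569 positions.
rcrs_noncoding_rows <- function(genes) {
  cr <- tibble(gene = "CR", ftype = "noncoding", complex = "none",
               strand = "H", start = c(16024L, 1L), end = c(16569L, 576L),
               frame_anchor = NA_integer_)
  covered <- rep(FALSE, MT_LENGTH)
  for (i in seq_len(nrow(genes))) {
    covered[genes$start[i]:genes$end[i]] <- TRUE
  }
  covered[c(16024:16569, 1:576)] <- TRUE
  gaps <- which(!covered)
  if (length(gaps) == 0) return(cr)
  brk <- c(0, which(diff(gaps) > 1), length(gaps))
  seg <- purrr::map_dfr(seq_len(length(brk) - 1), function(k) {
    s <- gaps[brk[k] + 1]
    e <- gaps[brk[k + 1]]
    tibble(start = as.integer(s), end = as.integer(e))
  })
  bind_rows(
    cr,
    tibble(gene = sprintf("NC%02d", seq_len(nrow(seg))), ftype = "noncoding",
           complex = "none", strand = "H", start = seg$start, end = seg$end,
           frame_anchor = NA_integer_)
  )
}

#' Full feature table for the bundled mitochondrial annotation
#'
#' One row per feature segment: the 37 genes (13 mRNA, 22 tRNA, 2 rRNA) at
#' their standard rCRS coordinates, the control region as two segments
#' wrapping the origin, and the explicit intergenic noncoding spacers so
#' that every one of the 16,569 positions is covered.
#'
#' @return A tibble with columns `gene`, `ftype`, `complex`, `strand`,
#'   `start`, `end`, `frame_anchor`.
#' @export
mito_feature_table <- function() {
  genes <- rcrs_gene_coords()
  bind_rows(genes, rcrs_noncoding_rows(genes))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# Deterministic synthetic mtDNA-like sequence consistent with the bundled
# annotation: realistic base composition, open reading frames (start codon,
# no internal stops on the primary frame, full or polyadenylation-completed
# terminal stops), and a handful of pinned well-known reference alleles
# (m.3460G, m.8993T, m.11778G, m.14484T). The sequence is synthetic -- it is
# NOT the rCRS sequence -- but it satisfies every structural property the
# annotation machinery relies on.
synth_mito_sequence <- function(features, seed = 20170917L) {
  set.seed(seed)
  seqv <- sample(BASES, MT_LENGTH, replace = TRUE,
                 prob = c(0.309, 0.313, 0.131, 0.247))
  code <- mito_genetic_code()
  sense <- names(code)[code != "Ter"]
  bp <- c(A = 0.309, C = 0.313, G = 0.131, T = 0.247)
  cw <- vapply(strsplit(sense, ""), function(b) prod(bp[b]), numeric(1))

  genes <- features[features$ftype == "mRNA", ]
  # Write genes in descending start order so that, in overlaps, the
  # earlier-started gene (the primary reading frame) is written last and
  # keeps a clean ORF.
  genes <- genes[order(-genes$start), ]
  for (i in seq_len(nrow(genes))) {
    gl <- genes$end[i] - genes$start[i] + 1L
    nfull <- gl %/% 3L
    rem <- gl %% 3L
    if (rem == 0L) {
      codons <- c(sample(c("ATG", "ATA"), 1),
                  sample(sense, nfull - 2L, replace = TRUE, prob = cw),
                  "TAA")
      tail_b <- character(0)
    } else {
      codons <- c(sample(c("ATG", "ATA"), 1),
                  sample(sense, nfull - 1L, replace = TRUE, prob = cw))
      tail_b <- strsplit(substr("TAA", 1, rem), "")[[1]]
    }
    bases <- c(unlist(strsplit(codons, "")), tail_b)
    stopifnot(length(bases) == gl)
    if (genes$strand[i] == "H") {
      seqv[genes$start[i]:genes$end[i]] <- bases
    } else {
      seqv[seq(genes$end[i], genes$start[i])] <- comp_base(bases)
    }
  }
  # Overlap junctions: the primary-frame codon that straddles the end of an
  # overwritten overlap (ATP6 codon 16, ND4 codon 3) can pick up a stop
  # (AGA/AGG) from the neighbouring gene's terminal TAA; repair the third
  # base (a position private to the affected gene) if so.
  code_map <- mito_genetic_code()
  for (c1 in list(8572:8574, 10766:10768)) {
    if (code_map[paste(seqv[c1], collapse = "")] == "Ter") {
      seqv[c1[3]] <- "C"
    }
  }
  # pinned reference alleles inside safe whole codons
  seqv[3460:3462] <- c("G", "C", "C")    # ND1 codon start, Ala
  seqv[11777:11779] <- c("C", "G", "C")  # ND4 codon start, Arg
  seqv[8992:8994] <- c("C", "T", "A")    # ATP6 codon start, Leu
  seqv[14482:14484] <- c("G", "A", "T")  # ND6 L-strand codon ATC, Ile
  seqv
}

#' Rebuild the bundled synthetic reference fixture
#'
#' Writes `synthetic_rcrs.fasta` (a deterministic synthetic 16,569-bp
#' sequence; see Details) and `mito_features.tsv` (the annotation from
#' [mito_feature_table()]) into `dir`. The shipped copies under
#' `inst/extdata/` were produced by this function with the default seed.
#'
#' @details The sequence is synthetic, not the real rCRS: it has
#'   mtDNA-like base composition, valid open reading frames on every
#'   primary frame, and pins the well-known reference alleles m.3460G,
#'   m.8993T, m.11778G and m.14484T. Gene coordinates are the authentic
#'   rCRS coordinates.
#' @param dir Output directory.
#' @param seed Integer seed for the sequence generator.
#' @return Invisibly, the two file paths.
#' @export
build_synthetic_reference <- function(dir, seed = 20170917L) {
  feats <- mito_feature_table()
  seqv <- synth_mito_sequence(feats, seed = seed)
  fa <- file.path(dir, "synthetic_rcrs.fasta")
  tsv <- file.path(dir, "mito_features.tsv")
  dna <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(dna) <- "synthetic_rCRS synthetic human mtDNA stand-in (not NC_012920)"
  Biostrings::writeXStringSet(dna, fa, width = 70)
  readr::write_tsv(feats, tsv)
  invisible(c(fasta = fa, features = tsv))
}

# canonical cloverleaf template over 73 positions -> structural sub-units
trna_template <- function() {
  sub <- rep("", 73)
  sub[1:7] <- "acceptor_stem"; sub[8:9] <- "linker"
  sub[10:13] <- "d_stem"; sub[14:21] <- "d_loop"; sub[22:25] <- "d_stem"
  sub[26] <- "linker"
  sub[27:31] <- "anticodon_stem"; sub[32:38] <- "anticodon_loop"
  sub[39:43] <- "anticodon_stem"
  sub[44:48] <- "variable_region"
  sub[49:53] <- "t_stem"; sub[54:60] <- "t_loop"; sub[61:65] <- "t_stem"
  sub[66:72] <- "acceptor_stem"; sub[73] <- "discriminator"
  unit <- if_else(grepl("stem", sub), "stem", "loop_or_variable")
  tibble(idx = 1:73, sub_unit = sub, unit = unit)
}

# per-position structural class for one tRNA gene (idealized cloverleaf
# scaled to gene length; L-strand genes read from the gene's 3' end)
trna_classes_for_gene <- function(start, end, strand) {
  gl <- end - start + 1L
  i <- seq_len(gl)
  t_idx <- round((i - 1) * 72 / (gl - 1)) + 1
  tmpl <- trna_template()
  pos <- if (strand == "H") start:end else end:start
  tibble(position = pos, unit = tmpl$unit[t_idx], sub_unit = tmpl$sub_unit[t_idx])
}

#' Load a mitochondrial reference genome
#'
#' Reads a feature annotation (tab-delimited: `gene`, `ftype`, `complex`,
#' `strand`, `start`, `end`, `frame_anchor`; one row per segment) and a
#' single-record FASTA sequence, validates them, and precomputes the
#' position-level index used by annotation, simulation and density
#' functions. With no arguments the bundled fixture is loaded: authentic
#' rCRS gene coordinates over a synthetic 16,569-bp sequence (see
#' [build_synthetic_reference()]).
#'
#' @param annotation Path to the annotation TSV, or `NULL` for the bundled
#'   fixture.
#' @param sequence Path to the FASTA sequence, or `NULL` for the bundled
#'   fixture.
#' @return A `mito_genome` object: a list with elements `length`, `seq`
#'   (character vector of bases), `features` (segment table), `genes` (one
#'   row per feature), `pos_map` (long position-by-feature table with codon
#'   indexing) and a precomputed `index`.
#' @export
#' @examples
#' g <- load_reference()
#' g$length
load_reference <- function(annotation = NULL, sequence = NULL) {
  builtin <- is.null(annotation) && is.null(sequence)
  if (builtin) {
    annotation <- system.file("extdata", "mito_features.tsv",
                              package = "mitoselect", mustWork = TRUE)
    sequence <- system.file("extdata", "synthetic_rcrs.fasta",
                            package = "mitoselect", mustWork = TRUE)
  }
  feats <- parse_feature_table(annotation)
  seqv <- parse_reference_fasta(sequence)
  new_mito_genome(feats, seqv, source = if (builtin) "builtin" else "custom")
}

parse_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path),
          class = "mitoselect_parse_error")
  }
  feats <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      gene = readr::col_character(),
                      ftype = readr::col_character(),
                      complex = readr::col_character(),
                      strand = readr::col_character(),
                      start = readr::col_integer(),
                      end = readr::col_integer(),
                      frame_anchor = readr::col_integer()
                    )),
    error = function(e) abort(paste0("Malformed annotation: ",
                                     conditionMessage(e)),
                              class = "mitoselect_parse_error")
  )
  need <- c("gene", "ftype", "complex", "strand", "start", "end", "frame_anchor")
  miss <- setdiff(need, names(feats))
  if (length(miss)) {
    abort(paste0("Annotation missing column(s): ", paste(miss, collapse = ", ")),
          class = "mitoselect_parse_error")
  }
  bad <- which(!(feats$ftype %in% c("mRNA", "tRNA", "rRNA", "noncoding")) |
                 !(feats$strand %in% c("H", "L")) |
                 is.na(feats$start) | is.na(feats$end) |
                 feats$start > feats$end)
  if (length(bad)) {
    abort(paste0("Malformed annotation line(s) (1-based, excluding header): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "mitoselect_parse_error")
  }
  feats
}

parse_reference_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Sequence file not found: ", path),
          class = "mitoselect_parse_error")
  }
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) != 1) {
    abort("Reference FASTA must contain exactly one sequence.",
          class = "mitoselect_parse_error")
  }
  s <- strsplit(toupper(as.character(dna[[1]])), "")[[1]]
  if (!all(s %in% BASES)) {
    abort("Reference sequence contains non-ACGT characters.",
          class = "mitoselect_parse_error")
  }
  s
}

KNOWN_COMPLEX <- c(
  ND1 = "I", ND2 = "I", ND3 = "I", ND4 = "I", ND4L = "I", ND5 = "I",
  ND6 = "I", CYTB = "III", COX1 = "IV", COX2 = "IV", COX3 = "IV",
  ATP6 = "V", ATP8 = "V"
)

new_mito_genome <- function(feats, seqv, source = "custom") {
  L <- length(seqv)
  if (any(feats$end > L)) {
    abort(paste0("Feature segment(s) extend beyond sequence length ", L, "."),
          class = "mitoselect_validation_error")
  }
  # known OXPHOS complex membership must be honoured when those genes exist
  kn <- feats$gene %in% names(KNOWN_COMPLEX)
  if (any(kn)) {
    wrong <- feats$gene[kn][feats$complex[kn] != KNOWN_COMPLEX[feats$gene[kn]]]
    if (length(wrong)) {
      abort(paste0("Wrong complex assignment for: ",
                   paste(unique(wrong), collapse = ", ")),
            class = "mitoselect_validation_error")
    }
  }
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(feats))) covered[feats$start[i]:feats$end[i]] <- TRUE
  if (!all(covered)) {
    gaps <- which(!covered)
    abort(paste0("Annotation does not cover position(s): ",
                 paste(head(gaps, 10), collapse = ", "),
                 if (length(gaps) > 10) " ..." else ""),
          class = "mitoselect_validation_error")
  }

  genes <- feats %>%
    group_by(.data$gene) %>%
    summarise(ftype = first(.data$ftype), complex = first(.data$complex),
              strand = first(.data$strand),
              frame_anchor = first(.data$frame_anchor),
              start = min(.data$start), end = max(.data$end),
              n_bp = sum(.data$end - .data$start + 1), .groups = "drop") %>%
    arrange(.data$start)
  # recompute per-segment n_bp (multi-segment features)
  seg_bp <- feats %>%
    group_by(.data$gene) %>%
    summarise(n_bp = sum(.data$end - .data$start + 1), .groups = "drop")
  genes$n_bp <- seg_bp$n_bp[match(genes$gene, seg_bp$gene)]

  mr <- genes[genes$ftype == "mRNA", ]
  if (any(is.na(mr$frame_anchor))) {
    abort("Every mRNA feature needs a frame_anchor.",
          class = "mitoselect_validation_error")
  }
  if (any(mr$n_bp < 3)) {
    abort("mRNA feature shorter than one codon.",
          class = "mitoselect_validation_error")
  }

  # long position-by-feature map (one row per position x overlapping feature)
  pm <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    tibble(position = feats$start[i]:feats$end[i],
           gene = feats$gene[i], ftype = feats$ftype[i],
           complex = feats$complex[i], strand = feats$strand[i],
           feat_start = feats$start[i], frame_anchor = feats$frame_anchor[i])
  })
  gene_lim <- genes %>% select("gene", g_start = "start", g_end = "end")
  pm <- pm %>%
    left_join(gene_lim, by = "gene") %>%
    arrange(.data$position, .data$g_start, .data$gene) %>%
    group_by(.data$position) %>%
    mutate(slot = row_number()) %>%
    ungroup()

  is_m <- pm$ftype == "mRNA"
  k <- integer(nrow(pm)); k[] <- NA_integer_
  hh <- is_m & pm$strand == "H"
  ll <- is_m & pm$strand == "L"
  k[hh] <- pm$position[hh] - pm$frame_anchor[hh]
  k[ll] <- pm$frame_anchor[ll] - pm$position[ll]
  codon_index <- k %/% 3L + 1L
  codon_offset <- k %% 3L
  cpos1 <- ifelse(hh, pm$position - codon_offset,
                  ifelse(ll, pm$frame_anchor - 3L * (codon_index - 1L), NA))
  cpos2 <- ifelse(hh, cpos1 + 1L, ifelse(ll, cpos1 - 1L, NA))
  cpos3 <- ifelse(hh, cpos1 + 2L, ifelse(ll, cpos1 - 2L, NA))
  complete <- ifelse(hh, cpos3 <= pm$g_end, ifelse(ll, cpos3 >= pm$g_start, NA))
  pm$codon_index <- ifelse(is_m, codon_index, NA_integer_)
  pm$codon_offset <- ifelse(is_m, codon_offset, NA_integer_)
  pm$cpos1 <- as.integer(ifelse(is_m, cpos1, NA))
  pm$cpos2 <- as.integer(ifelse(is_m, cpos2, NA))
  pm$cpos3 <- as.integer(ifelse(is_m, cpos3, NA))
  pm$codon_complete <- as.logical(ifelse(is_m, complete, NA))

  # tRNA structural classes (idealized cloverleaf)
  tr <- feats[feats$ftype == "tRNA", ]
  if (nrow(tr)) {
    tcl <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
      trna_classes_for_gene(tr$start[i], tr$end[i], tr$strand[i]) %>%
        mutate(gene = tr$gene[i])
    })
    pm <- pm %>%
      left_join(tcl, by = c("position", "gene")) %>%
      rename(trna_unit = "unit", trna_sub_unit = "sub_unit")
  } else {
    pm$trna_unit <- NA_character_
    pm$trna_sub_unit <- NA_character_
  }
  pm <- pm %>% select(-"g_start", -"g_end", -"feat_start", -"frame_anchor")

  g <- list(length = L, seq = seqv, features = feats, genes = genes,
            pos_map = pm, source = source)
  g$index <- build_genome_index(g)
  class(g) <- "mito_genome"
  g
}

# flat arrays for the hot paths (simulation, codon counting, density)
build_genome_index <- function(g) {
  L <- g$length
  base_int <- match(g$seq, BASES)
  pm1 <- g$pos_map[g$pos_map$slot == 1L, ]
  pm1 <- pm1[order(pm1$position), ]
  stopifnot(nrow(pm1) == L)

  prev_int <- base_int[c(L, seq_len(L - 1))]
  next_int <- base_int[c(seq(2, L), 1)]

  # primary-frame mRNA codon arithmetic
  mr_ok <- !is.na(pm1$ftype) & pm1$ftype == "mRNA" &
    !is.na(pm1$codon_complete) & pm1$codon_complete
  mr_L <- mr_ok & pm1$strand == "L"
  b1 <- b2 <- b3 <- integer(L)
  b1[mr_ok] <- base_int[pm1$cpos1[mr_ok]]
  b2[mr_ok] <- base_int[pm1$cpos2[mr_ok]]
  b3[mr_ok] <- base_int[pm1$cpos3[mr_ok]]
  b1[mr_L] <- COMP_INT[b1[mr_L]]
  b2[mr_L] <- COMP_INT[b2[mr_L]]
  b3[mr_L] <- COMP_INT[b3[mr_L]]
  refidx <- integer(L)
  refidx[mr_ok] <- 16L * (b1[mr_ok] - 1L) + 4L * (b2[mr_ok] - 1L) + (b3[mr_ok] - 1L)
  place <- integer(L)
  place[mr_ok] <- c(16L, 4L, 1L)[pm1$codon_offset[mr_ok] + 1L]

  codon_names <- codon_universe()
  aa_of_codon <- translate_codons(codon_names)

  region2 <- rep(NA_character_, L)
  pm2 <- g$pos_map[g$pos_map$slot == 2L, ]
  region2[pm2$position] <- pm2$gene

  list(
    base_int = base_int,
    pos_by_base = lapply(1:4, function(b) which(base_int == b)),
    prev_int = prev_int, next_int = next_int,
    region1 = pm1$gene, ftype1 = pm1$ftype, region2 = region2,
    coding = pm1$ftype != "noncoding",
    mr_ok = mr_ok, mr_L = mr_L, mr_refidx = refidx, mr_place = place,
    mr_gene = ifelse(mr_ok, pm1$gene, NA_character_),
    trna_unit1 = pm1$trna_unit,
    codon_names = codon_names, aa_of_codon = aa_of_codon
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$length, " bp, circular (", x$source, ")\n", sep = "")
  tab <- table(x$genes$ftype)
  cat("  features:", paste(paste0(names(tab), "=", tab), collapse = ", "), "\n")
  invisible(x)
}

codon_universe <- function() {
  eg <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                    stringsAsFactors = FALSE)
  paste0(eg$b1, eg$b2, eg$b3)
}

# codon index (0..63) -> codon string; codon_universe() is ordered so that
# idx = 16*(b1-1) + 4*(b2-1) + (b3-1) indexes it directly (+1).
codon_from_idx <- function(idx) codon_universe()[idx + 1L]

# region lengths (bp) for a grouping over positions, honouring overlaps
# (positions in two features count toward both groups)
region_positions <- function(genome, grouping) {
  pm <- genome$pos_map
  switch(grouping,
    coding_vs_noncoding = pm %>%
      distinct(.data$position, .keep_all = TRUE) %>%
      mutate(group = if_else(.data$ftype == "noncoding",
                             "noncoding", "coding")) %>%
      select("position", "group"),
    gene = pm %>%
      filter(.data$ftype != "noncoding") %>%
      select("position", group = "gene"),
    complex = pm %>%
      filter(.data$ftype != "noncoding") %>%
      mutate(group = if_else(.data$ftype == "mRNA",
                             paste0("Complex ", .data$complex), .data$ftype)) %>%
      distinct(.data$position, .data$group) %>%
      select("position", "group"),
    trna_unit = pm %>%
      filter(.data$ftype == "tRNA", !is.na(.data$trna_unit)) %>%
      distinct(.data$position, .data$trna_unit) %>%
      select("position", group = "trna_unit"),
    abort(paste0("Unsupported grouping: ", grouping),
          class = "mitoselect_bad_grouping")
  )
}
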