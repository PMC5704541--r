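# Reference genome model: structure, genetic code, annotation.

test_that("bundled reference satisfies the genome invariants", {
  g <- ref_genome()
  expect_equal(g$length, 16569L)
  tab <- table(g$genes$ftype)
  expect_equal(unname(tab[["mRNA"]]), 13)
  expect_equal(unname(tab[["tRNA"]]), 22)
  expect_equal(unname(tab[["rRNA"]]), 2)
  # complex membership
  gm <- g$genes
  expect_setequal(gm$gene[gm$complex == "V"], c("ATP6", "ATP8"))
  expect_setequal(gm$gene[gm$complex == "III"], "CYTB")
  expect_setequal(gm$gene[gm$complex == "IV"], c("COX1", "COX2", "COX3"))
  expect_setequal(gm$gene[gm$complex == "I"],
                  c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6"))
  # every position covered exactly once after overlap deduplication
  rp <- region_lengths_check <- table(g$pos_map$slot)
  expect_equal(sum(g$pos_map$slot == 1), 16569)
})

test_that("coding + noncoding positions partition the genome", {
  g <- ref_genome()
  d <- mutation_density(recs_at(g, c(100, 5000)), g,
                        grouping = "coding_vs_noncoding")
  expect_equal(sum(d$length_bp), 16569)
  # control region length: two segments wrapping the origin
  cr <- g$features[g$features$gene == "CR", ]
  expect_equal(nrow(cr), 2)
  expect_equal(sum(cr$end - cr$start + 1), 1122)
})

test_that("loading a malformed or gappy annotation fails loudly", {
  d <- tempfile("bad"); dir.create(d)
  ann <- file.path(d, "ann.tsv"); fa <- file.path(d, "seq.fa")
  writeLines(c(">x", "ATGAAATAAGG"), fa)  # 11 bp
  readr::write_tsv(tibble::tibble(
    gene = "G1", ftype = "mRNA", complex = "none", strand = "H",
    start = 1L, end = 9L, frame_anchor = 1L), ann)
  expect_error(load_reference(ann, fa), class = "mitoselect_validation_error")
  readr::write_tsv(tibble::tibble(
    gene = "G1", ftype = "banana", complex = "none", strand = "H",
    start = 1L, end = 11L, frame_anchor = 1L), ann)
  expect_error(load_reference(ann, fa), class = "mitoselect_parse_error")
})

test_that("toy annotations load and validate", {
  g <- mini_genome()
  expect_equal(g$length, 9L)
  expect_equal(nrow(g$genes), 1)
  g2 <- toy400_genome()
  expect_equal(nrow(g2$genes), 2)
})

test_that("translation follows the vertebrate mitochondrial code", {
  expect_equal(translate_codons("TGA"), "Trp")
  expect_equal(translate_codons(c("AGA", "AGG")), c("Ter", "Ter"))
  expect_equal(translate_codons("ATA"), "Met")
  expect_equal(translate_codons("ACC"), "Thr")
  expect_equal(sort(unique(mito_genetic_code())) |> length(), 21)
  expect_error(translate_codons("AXC"), class = "mitoselect_invalid_codon")
})

test_that("substitution classifier is a bijection onto 12 labels", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitutions(pairs$ref, pairs$alt)
  expect_equal(length(unique(cls$subst_type)), 12)
  expect_equal(sum(cls$is_transition), 4)
  expect_equal(sum(!cls$is_transition), 8)
  one <- classify_substitutions(c("C", "C"), c("T", "A"))
  expect_equal(one$subst_type, c("C>T", "C>A"))
  expect_equal(one$is_transition, c(TRUE, FALSE))
  expect_error(classify_substitutions("A", "A"),
               class = "mitoselect_invalid_substitution")
})

test_that("well-known pathogenic positions annotate to their genes", {
  g <- ref_genome()
  m <- tibble::tibble(position = c(3460L, 11778L, 8993L),
                      ref = c("G", "G", "T"), alt = c("A", "A", "G"))
  a <- mutation_classes(annotate_mutations(m, g))
  expect_equal(a$region, c("ND1", "ND4", "ATP6"))
  expect_equal(a$ftype, rep("mRNA", 3))
  expect_equal(a$complex[3], "V")
})

test_that("codon fields are computed by in-place substitution", {
  g <- mini_genome()
  a <- annotate_mutations(
    tibble::tibble(position = 4L, ref = "A", alt = "C"), g)
  expect_equal(a$ref_codon, "AAA")
  expect_equal(a$mut_codon, "CAA")
  expect_equal(a$ref_aa, "Lys")
  expect_equal(a$mut_aa, "Gln")
  expect_equal(a$mclass, "nonsynonymous")
})

test_that("annotation rejects reference mismatches and identities", {
  g <- mini_genome()
  expect_error(
    annotate_mutations(tibble::tibble(position = 4L, ref = "C", alt = "G"), g),
    class = "mitoselect_ref_mismatch")
  expect_error(
    annotate_mutations(tibble::tibble(position = 4L, ref = "A", alt = "A"), g),
    class = "mitoselect_invalid_substitution")
})

test_that("overlap positions annotate once per gene, tallies count once", {
  g <- ref_genome()
  p <- 8550L  # inside the ATP8/ATP6 overlap
  ref <- g$seq[p]
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  a <- annotate_mutations(tibble::tibble(position = p, ref = ref, alt = alt), g)
  expect_setequal(a$region, c("ATP8", "ATP6"))
  cls <- mutation_classes(a)
  expect_equal(nrow(cls), 1)
})

test_that("triplet context wraps around the circular origin", {
  g <- ref_genome()
  m <- tibble::tibble(position = c(1L, 16569L),
                      ref = g$seq[c(1, 16569)], alt = NA_character_)
  m$alt <- ifelse(m$ref == "A", "C", "A")
  a <- annotate_mutations(m, g) |> mutation_classes()
  expect_equal(a$triplet_mut[1], paste0(g$seq[16569], m$alt[1], g$seq[2]))
  expect_equal(a$triplet_mut[2], paste0(g$seq[16568], m$alt[2], g$seq[1]))
})

test_that("four-fold degenerate third positions always annotate synonymous", {
  g <- ref_genome()
  pm <- g$pos_map
  third <- pm[pm$slot == 1 & !is.na(pm$codon_complete) & pm$codon_complete &
                pm$codon_offset == 2, ]
  code <- mito_genetic_code()
  fourfold <- names(which(tapply(code, substr(names(code), 1, 2),
                                 function(x) length(unique(x)) == 1)))
  set.seed(11)
  third <- third[sample.int(nrow(third), 300), ]
  for (i in seq_len(nrow(third))) {
    p <- third$position[i]
    s <- genome_strand <- third$strand[i]
    rc <- if (s == "H") {
      paste0(g$seq[third$cpos1[i]], g$seq[third$cpos2[i]], g$seq[third$cpos3[i]])
    } else {
      chartr("ACGT", "TGCA",
             paste0(g$seq[third$cpos1[i]], g$seq[third$cpos2[i]],
                    g$seq[third$cpos3[i]]))
    }
    if (!substr(rc, 1, 2) %in% fourfold) next
    ref <- g$seq[p]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- annotate_mutations(
        tibble::tibble(position = p, ref = ref, alt = alt), g)
      a <- a[a$region == third$gene[i], ]
      expect_equal(a$mclass, "synonymous")
    }
  }
})

test_that("mutating then reverting restores the reference codon", {
  g <- ref_genome()
  set.seed(7)
  pm <- g$pos_map
  mr <- pm[pm$slot == 1 & !is.na(pm$codon_complete) & pm$codon_complete, ]
  mr <- mr[sample.int(nrow(mr), 100), ]
  ref <- g$seq[mr$position]
  alt <- ifelse(ref == "G", "T", "G")
  a <- annotate_mutations(
    tibble::tibble(position = mr$position, ref = ref, alt = alt), g)
  a <- a[a$ftype == "mRNA" & !is.na(a$ref_codon), ]
  # revert: substitute the reference coding-strand base back into mut_codon
  back <- a$mut_codon
  ref_cs <- ifelse(a$strand == "L", chartr("ACGT", "TGCA", a$ref), a$ref)
  off <- a$codon_index  # recompute offset from codon strings instead
  for (i in seq_len(nrow(a))) {
    o <- which(strsplit(a$ref_codon[i], "")[[1]] !=
                 strsplit(a$mut_codon[i], "")[[1]])
    substr(back[i], o, o) <- ref_cs[i]
  }
  expect_equal(back, a$ref_codon)
})

test_that("incomplete terminal codons carry no class", {
  g <- ref_genome()
  # ND1 ends with a 2-bp partial codon (completed by polyadenylation)
  p <- 4262L
  ref <- g$seq[p]
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  a <- annotate_mutations(tibble::tibble(position = p, ref = ref, alt = alt), g)
  nd1 <- a[a$region == "ND1", ]
  expect_true(is.na(nd1$mclass))
  expect_true(is.na(nd1$mut_codon))
})

test_that("tRNA positions carry exactly one structural class", {
  g <- ref_genome()
  tr <- g$pos_map[g$pos_map$ftype == "tRNA", ]
  expect_true(all(tr$trna_unit %in% c("stem", "loop_or_variable")))
  expect_equal(anyDuplicated(tr[, c("position", "gene")]), 0)
})

test_that("heavy/light display labels map the reference strand convention", {
  expect_equal(hl_label(c("G>A", "T>C")), c("C_H>T_H", "T_L>C_L"))
})
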