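# Selection statistics: densities, recurrence, residuals, heteroplasmy,
# stratified proportions.

test_that("equal densities give a null chi-square", {
  g <- toy400_genome()
  # lengths 100/300 scaled to the 200/800 example: use proportional counts
  pos <- as.integer(c(seq(10, 90, length.out = 2),
                      seq(110, 390, length.out = 6)))
  d <- mutation_density(recs_at(g, pos), g, grouping = "gene")
  expect_equal(d$density[1], d$density[2])
  gl <- glance(d)
  expect_equal(unname(gl$statistic), 0, tolerance = 1e-12)
  expect_equal(gl$p.value, 1)
})

test_that("a one-sided pile-up gives the hand-computed chi-square", {
  # two equal-length regions, counts 0 and 20 -> chi2 = 20
  d <- tempfile("eq"); dir.create(d)
  ann <- file.path(d, "ann.tsv"); fa <- file.path(d, "seq.fa")
  set.seed(9)
  writeLines(c(">t", paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                           collapse = "")), fa)
  readr::write_tsv(tibble::tibble(
    gene = c("GA", "GB"), ftype = "rRNA", complex = "none", strand = "H",
    start = c(1L, 101L), end = c(100L, 200L),
    frame_anchor = NA_integer_), ann)
  g <- load_reference(ann, fa)
  pos <- as.integer(seq(101, 196, length.out = 20))
  dd <- mutation_density(recs_at(g, pos), g, grouping = "gene")
  gl <- glance(dd)
  expect_equal(unname(gl$statistic), 20, tolerance = 1e-12)
  expect_lt(gl$p.value, 1e-4)
})

test_that("base-stratified densities restrict counts and lengths", {
  g <- ref_genome()
  pos <- which(g$seq == "G")[1:20]
  d <- mutation_density(recs_at(g, pos), g, grouping = "coding_vs_noncoding",
                        stratify_base = "G")
  expect_equal(sum(d$length_bp), sum(g$seq == "G"))
  expect_equal(sum(d$count), 20)
})

test_that("ATP6 and ATP8 densities honour the overlap policy", {
  g <- ref_genome()
  # one mutation in the ATP8/ATP6 overlap counts toward both genes
  d <- mutation_density(recs_at(g, 8550L), g, grouping = "gene",
                        genes = c("ATP6", "ATP8"))
  expect_equal(d$count[d$group == "ATP6"], 1L)
  expect_equal(d$count[d$group == "ATP8"], 1L)
  expect_equal(d$length_bp[d$group == "ATP8"], 207L)
  expect_equal(d$length_bp[d$group == "ATP6"], 681L)
})

test_that("recurrence reproduces F = sum(R)/L by hand", {
  g <- toy400_genome()
  # gene GA has length 100; pos 5 mutated in 3 patients, pos 7 in 1
  x <- recs_at(g, c(5L, 5L, 5L, 7L), patients = c("P1", "P2", "P3", "P4"))
  r <- recurrence(x, g, grouping = "gene")
  ga <- r$regions[r$regions$group == "GA", ]
  expect_equal(ga$F, 4 / 100)
  expect_equal(r$positions$R[r$positions$position == 5], 3)
  expect_true(r$positions$recurrent[r$positions$position == 5])
  expect_false(r$positions$recurrent[r$positions$position == 7])
  expect_equal(sum(r$positions$R), nrow(x))
})

test_that("all-singleton cohorts have F = n/L and no recurrent set", {
  g <- toy400_genome()
  x <- recs_at(g, as.integer(seq(5, 95, length.out = 10)))
  r <- recurrence(x, g, grouping = "gene")
  expect_false(any(r$positions$recurrent))
  expect_equal(r$regions$F[r$regions$group == "GA"], 10 / 100)
})

test_that("two double-hit positions in a 4-bp region give F = 1", {
  # brute-force tally: R = {2, 2}, L = 4
  d <- tempfile("f4"); dir.create(d)
  ann <- file.path(d, "ann.tsv"); fa <- file.path(d, "seq.fa")
  writeLines(c(">t", "ACGTACGT"), fa)
  readr::write_tsv(tibble::tibble(
    gene = c("GA", "GB"), ftype = "rRNA", complex = "none", strand = "H",
    start = c(1L, 5L), end = c(4L, 8L), frame_anchor = NA_integer_), ann)
  g <- load_reference(ann, fa)
  x <- recs_at(g, c(1L, 1L, 3L, 3L), patients = paste0("P", 1:4))
  r <- recurrence(x, g, grouping = "gene")
  expect_equal(r$regions$F[r$regions$group == "GA"], 1)
})

test_that("observed count tables tally mutant codons, aa and triplets", {
  g <- mini_genome()  # ATG AAA TAA
  # AAA -> CAA at position 4 (nonsynonymous, mutant codon CAA -> Gln)
  x <- tibble::tibble(position = 4L, ref = "A", alt = "C")
  cod <- count_mutant_categories(x, g, "codon")
  expect_equal(cod$count[cod$category == "CAA"], 1)
  aa <- count_mutant_categories(x, g, "amino_acid")
  expect_equal(aa$count[aa$category == "Gln"], 1)
  # stop-gain increments Ter: AAA -> TAA at position 4
  sg <- count_mutant_categories(
    tibble::tibble(position = 4L, ref = "A", alt = "T"), g, "amino_acid")
  expect_equal(sg$count[sg$category == "Ter"], 1)
})

test_that("triplet counting uses reference flanks around the mutant base", {
  g <- ref_genome()
  pos <- which(g$seq == "G" & dplyr::lag(g$seq) == "C" &
                 dplyr::lead(g$seq) == "C")[1:3]
  x <- tibble::tibble(position = pos, ref = "G", alt = "A")
  tri <- count_mutant_categories(x, g, "triplet")
  expect_equal(tri$count[tri$category == "CAC"], 3)
})

test_that("standardized residuals match the printed formula by hand", {
  obs <- tibble::tibble(category = c("a", "b", "c", "d"),
                        count = c(1, 2, 3, 6))
  sim <- tibble::tibble(category = c("a", "b", "c", "d"), count = 0)
  r <- residual_analysis(obs, sim)
  r <- r[order(r$category), ]
  expect_equal(r$residual, c(1, 2, 3, 6))
  sdd <- sd(c(1, 2, 3, 6))
  expect_equal(r$std_residual, (c(1, 2, 3, 6) - 3) / sdd, tolerance = 1e-12)
  expect_equal(round(r$std_residual, 3), c(-0.926, -0.463, 0, 1.389))
  expect_false(any(r$outlier))
  # standardization: mean 0, sd 1
  expect_equal(mean(r$std_residual), 0, tolerance = 1e-9)
  expect_equal(sd(r$std_residual), 1, tolerance = 1e-9)
})

test_that("identical tables give degenerate variance, not silent zeros", {
  t1 <- tibble::tibble(category = c("a", "b", "c"), count = c(1, 2, 3))
  expect_error(residual_analysis(t1, t1),
               class = "mitoselect_degenerate_variance")
  expect_error(
    residual_analysis(t1[1:2, ], t1[1:2, ]),
    class = "mitoselect_insufficient_data")
})

test_that("an inflated category is flagged as a positive outlier", {
  set.seed(31)
  n <- 30
  s <- tibble::tibble(category = sprintf("c%02d", 1:n),
                      count = 100 + rnorm(n, 0, 3))
  o <- s
  o$count[5] <- o$count[5] + 10 * 3 * 10  # ~10 sd of the noise, scaled
  r <- residual_analysis(o, s)
  expect_true(r$outlier[r$category == "c05"])
  expect_equal(r$direction[r$category == "c05"], "positive")
  expect_equal(sum(r$outlier), 1)
})

test_that("residuals are invariant to category order and uniform scaling", {
  set.seed(33)
  o <- tibble::tibble(category = letters[1:10], count = rpois(10, 50))
  s <- tibble::tibble(category = letters[1:10], count = rpois(10, 50))
  r1 <- residual_analysis(o, s)
  perm <- sample(10)
  r2 <- residual_analysis(o[perm, ], s[perm, ])
  expect_equal(dplyr::arrange(as.data.frame(r1), category),
               dplyr::arrange(as.data.frame(r2), category))
  # small uniform relative inflation flags nothing
  o2 <- o
  o2$count <- o2$count * 1.01
  r3 <- residual_analysis(o2, o)
  expect_false(any(r3$outlier))
})

test_that("regression-mode residuals standardize the trend-line residuals", {
  set.seed(35)
  s <- tibble::tibble(category = letters[1:12], count = rpois(12, 80))
  o <- s
  o$count <- 2 * s$count + rnorm(12, 0, 1)  # strong linear trend, slope 2
  r <- residual_analysis(o, s, method = "regression")
  fit <- lm(o$count ~ s$count)
  expect_equal(sort(r$residual), sort(unname(resid(fit))), tolerance = 1e-9)
  expect_equal(mean(r$std_residual), 0, tolerance = 1e-9)
  # raw differences, by contrast, carry the slope: all positive
  rd <- residual_analysis(o, s, method = "difference")
  expect_true(all(rd$residual > 0))
})

test_that("heteroplasmy comparisons run t-tests and ANOVA", {
  x <- tibble::tibble(heteroplasmy = c(0.1, 0.3, 0.1, 0.3),
                      grp = c("a", "a", "b", "b"))
  hc <- heteroplasmy_compare(x, "grp")
  expect_equal(hc$mean, c(0.2, 0.2))
  expect_equal(glance(hc)$p.value, 1)

  y <- tibble::tibble(heteroplasmy = c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1),
                      grp = rep(c("hi", "lo"), each = 3))
  expect_lt(glance(heteroplasmy_compare(y, "grp"))$p.value, 0.01)

  z <- tibble::tibble(heteroplasmy = rep(c(0.2, 0.4), 3),
                      grp = rep(c("a", "b", "c"), each = 2))
  gz <- glance(heteroplasmy_compare(z, "grp"))
  expect_equal(gz$statistic, 0)
  expect_equal(gz$test, "ANOVA")
})

test_that("groups with fewer than two heteroplasmy values are dropped", {
  x <- tibble::tibble(heteroplasmy = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      grp = c("a", "a", "b", "b", "c"))
  expect_warning(hc <- heteroplasmy_compare(x, "grp"), "dropped")
  expect_setequal(hc$group, c("a", "b"))
})

test_that("heteroplasmy strata resolve boundary ties outward", {
  expect_equal(heteroplasmy_stratum(c(0.02, 0.05, 0.051, 0.89, 0.9, 1)),
               c("low", "low", "mid", "mid", "high", "high"))
  expect_true(is.na(heteroplasmy_stratum(NA)))
})

test_that("stratified class proportions reproduce a hand chi-square", {
  g <- ref_genome()
  set.seed(41)
  syn <- find_mutation(g, "synonymous")
  non <- find_mutation(g, "nonsynonymous")
  mk <- function(m, n, het) {
    dplyr::bind_rows(replicate(n, m, simplify = FALSE)) %>%
      dplyr::mutate(heteroplasmy = het,
                    patient_id = sprintf("P%03d", seq_len(n)))
  }
  # low stratum: 30 syn / 70 nonsyn; high stratum: 70 syn / 30 nonsyn
  x <- dplyr::bind_rows(mk(syn, 30, 0.03), mk(non, 70, 0.03),
                        mk(syn, 70, 0.95), mk(non, 30, 0.95))
  sc <- stratified_class_proportions(x, g, panel = "syn_vs_nonsyn")
  expect_equal(unname(sc$test$statistic), 32, tolerance = 1e-12)
  expect_lt(sc$test$p.value, 1e-7)
  props <- sc$strata %>%
    dplyr::group_by(stratum) %>%
    dplyr::summarise(s = sum(prop))
  expect_equal(props$s, rep(1, nrow(props)))
})

test_that("identical stratum compositions give a zero chi-square", {
  g <- ref_genome()
  set.seed(43)
  syn <- find_mutation(g, "synonymous")
  non <- find_mutation(g, "nonsynonymous")
  x <- dplyr::bind_rows(
    syn %>% dplyr::mutate(heteroplasmy = 0.03),
    non %>% dplyr::mutate(heteroplasmy = 0.03),
    syn %>% dplyr::mutate(heteroplasmy = 0.95),
    non %>% dplyr::mutate(heteroplasmy = 0.95))
  sc <- stratified_class_proportions(x, g, panel = "syn_vs_nonsyn")
  expect_equal(unname(sc$test$statistic), 0, tolerance = 1e-12)
})

test_that("the CC/NCC panel classifies mutant codons by wobble pairing", {
  cc <- codon_cc_table()
  expect_equal(nrow(cc), 60)  # sense codons only
  expect_true(cc$cc[cc$codon == "ATG"])   # Met anticodon CAU
  expect_true(cc$cc[cc$codon == "TGA"])   # Trp anticodon UCA
  expect_true(cc$cc[cc$codon == "CTA"])   # Leu(CUN) family, U34
  expect_false(cc$cc[cc$codon == "CTG"])
  expect_true(cc$cc[cc$codon == "AAC"])   # Asn NNY set, G34
  expect_false(cc$cc[cc$codon == "AAT"])
  # exactly one CC codon per tRNA species: 22 in total
  expect_equal(sum(cc$cc), 22)
})
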