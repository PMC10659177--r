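two_group_sites <- function(ref, alt, groups = c(p = "g1", q = "g2")) {
  vt <- scan_alignment(toy_aln(c(p = ref, q = alt)), "p")
  diagnostic_sites(vt, groups)
}

test_that("probes embed each group allele in reference flanks", {
  ref <- "AAGCTACGGTCAGTACGGATCATG"
  alt <- "AAGCTACGGTTAGTACGGATCATG"    # C->T at position 11
  sites <- two_group_sites(ref, alt)
  probes <- build_probes(sites, dna_records("p", ref), k = 4, min_k = 4)
  expect_equal(nrow(probes), 1L)
  expect_equal(probes$probe_a, "CGGTCAGTA")
  expect_equal(probes$probe_b, "CGGTTAGTA")
  expect_equal(probes$label_a, "g1")
})

test_that("sites too close to the sequence end are dropped", {
  ref <- "ACGGTCAGTACGGATCAAGG"
  alt <- "ACGGTCAGTACGGATCAAGC"  # SNP 3 bp from the end
  sites <- two_group_sites(ref, alt)
  expect_message(probes <- build_probes(sites, dna_records("p", ref), k = 6),
                 "too close")
  expect_equal(nrow(probes), 0L)
})

test_that("all planted diagnostic sites yield unique probe pairs", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  d <- diagnostic_sites(vt, c(AU = "AUgrp", AM = "AMgrp", AO = "AMgrp"))
  au <- refs$nrdna[refs$nrdna$id == "AU", ]
  au$residues <- degap(au$residues)
  probes <- build_probes(d, au)
  expect_equal(nrow(probes), 21L)
  expect_false(anyDuplicated(probes$probe_a) > 0)
  # the two probes of a site differ only at the allele
  snp <- probes[probes$kind == "SNP", ]
  expect_true(all(nchar(snp$probe_a) == nchar(snp$probe_b)))
})

test_that("error-free pure reads give fraction 1 at every site", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  d <- diagnostic_sites(vt, c(AU = "AUgrp", AM = "AMgrp", AO = "AMgrp"))
  au <- refs$nrdna[refs$nrdna$id == "AU", ]
  au$residues <- degap(au$residues)
  probes <- build_probes(d, au)
  s <- simulate_sample(refs, "AU", coverage = 60, seed = 611)
  depths <- count_allele_depths(s$reads, probes)
  expect_true(all(depths$total > 0))
  expect_true(all(depths$frac_a == 1))
  st <- call_state(depths)
  expect_equal(st$state, "HOM")
  expect_equal(st$label, "AUgrp")
  expect_equal(st$minor_fraction_mean, 0)
})

test_that("mixture fractions are recovered within binomial sampling error", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  d <- diagnostic_sites(vt, c(AU = "AUgrp", AM = "AMgrp", AO = "AMgrp"))
  au <- refs$nrdna[refs$nrdna$id == "AU", ]
  au$residues <- degap(au$residues)
  probes <- build_probes(d, au)
  f <- 0.65
  s <- simulate_sample(refs, "HYBRID", maternal = "AU", paternal = "AM",
                       f = f, coverage = 500, seed = 612)
  depths <- count_allele_depths(s$reads, probes)
  bound <- 3 * sqrt(f * (1 - f) / depths$total)
  within <- abs(depths$frac_a - f) <= bound
  expect_gte(mean(within), 0.95)
  st <- call_state(depths)
  expect_equal(st$state, "HET")
  expect_equal(st$minor_fraction_mean, mean(pmin(depths$frac_a,
                                                 depths$frac_b)))
})

test_that("state calling handles balanced, skewed and fixed depth tables", {
  mk <- function(ca, cb) {
    as_site_depths(data.frame(ref_pos = seq_along(ca),
                              allele_a = "X", count_a = ca,
                              allele_b = "Y", count_b = cb))
  }
  st <- call_state(mk(rep(100L, 8), rep(0L, 8)))
  expect_equal(st$state, "HOM")
  expect_equal(st$label, "X")
  expect_equal(st$minor_fraction_mean, 0)

  set.seed(62)
  ca <- round(500 * stats::runif(10, 0.61, 0.71))
  st2 <- call_state(mk(ca, 500L - ca))
  expect_equal(st2$state, "HET")
  expect_equal(st2$minor_fraction_mean, mean(1 - ca / 500), tolerance = 1e-9)

  st3 <- call_state(mk(rep(250L, 6), rep(250L, 6)))
  expect_equal(st3$state, "HET")
  expect_equal(st3$minor_fraction_mean, 0.5)   # minor <= 0.5 by definition

  st4 <- call_state(mk(rep(5L, 4), rep(5L, 4)))
  expect_equal(st4$state, "NO_CALL")
  expect_match(st4$reason, "depth")
})

test_that("fractions are invariant under read duplication", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  d <- diagnostic_sites(vt, c(AU = "AUgrp", AM = "AMgrp", AO = "AMgrp"))
  au <- refs$nrdna[refs$nrdna$id == "AU", ]
  au$residues <- degap(au$residues)
  probes <- build_probes(d, au)[1:5, ]
  s <- simulate_sample(refs, "HYBRID", maternal = "AU", paternal = "AM",
                       f = 0.6, coverage = 50, seed = 613)
  d1 <- count_allele_depths(s$reads, probes)
  doubled <- read_set(c(s$reads$id, paste0(s$reads$id, "_dup")),
                      rep(s$reads$residues, 2), rep(s$reads$quality, 2))
  d2 <- count_allele_depths(doubled, probes)
  expect_equal(d2$count_a, 2L * d1$count_a)
  expect_equal(d2$frac_a, d1$frac_a)
})

test_that("raising the minor-fraction threshold never turns HOM into HET", {
  set.seed(63)
  for (rep in 1:20) {
    n <- 8
    ca <- rbinom(n, 400, stats::runif(1, 0.5, 1))
    depths <- as_site_depths(data.frame(ref_pos = 1:n, allele_a = "X",
                                        count_a = ca, allele_b = "Y",
                                        count_b = 400L - ca))
    lo <- call_state(depths, min_minor_frac = 0.1)
    hi <- call_state(depths, min_minor_frac = 0.3)
    if (lo$state == "HOM") expect_equal(hi$state, "HOM")
  }
})
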