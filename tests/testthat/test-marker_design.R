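test_that("InDel target selection enforces the strict >10 bp rule", {
  # plant gap runs of 5, 10 and 15 bp in one record
  set.seed(41)
  base <- strsplit(random_seq(400), "")[[1]]
  alt <- base
  alt[51:55] <- "-"
  alt[151:160] <- "-"
  alt[251:265] <- "-"
  vt <- scan_alignment(toy_aln(c(p = paste0(base, collapse = ""),
                                 q = paste0(alt, collapse = ""))), "p")
  expect_equal(sort(vt$length[vt$kind == "INDEL"]), c(5L, 10L, 15L))
  sel <- select_indel_targets(vt, min_len = 11L)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$length, 15L)
  # never returns an event of length <= 10
  expect_true(all(select_indel_targets(vt)$length > 10L))
})

test_that("planted marker-length InDels are all recovered as targets", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$plastome, "AU")
  sel <- select_indel_targets(vt, groups = species_groups(refs$plastome))
  planted <- refs$truth[refs$truth$compartment == "PLASTOME" &
                          refs$truth$kind == "INDEL" &
                          refs$truth$length > 10L, ]
  expect_equal(sort(sel$aln_start), sort(planted$aln_start))
  expect_equal(sel$length, sort(planted$length, decreasing = TRUE))
})

test_that("designed codominant pairs separate allele classes by the event length", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$plastome, "AU")
  sel <- select_indel_targets(vt, groups = species_groups(refs$plastome))
  for (i in 1:2) {
    m <- design_codominant_indel(refs$plastome, sel[i, ],
                                 name = paste0("t", i))
    sizes <- as.integer(m$class_sizes)
    expect_equal(abs(diff(sizes)), sel$length[i])
    # design/verify closure: in-silico PCR on every reference reproduces
    # the marker's own expected sizes
    for (s in refs$plastome$id) {
      tmpl <- degap(refs$plastome$residues[refs$plastome$id == s])
      cl <- names(m$class_samples)[vapply(m$class_samples, function(x)
        s %in% x, logical(1))]
      expect_equal(predict_products(tmpl, m$primers),
                   as.integer(m$class_sizes[[cl]]))
    }
    # primer geometry constraints hold
    expect_true(all(nchar(c(m$primers$fwd, m$primers$rev)) %in% 18:27))
    expect_true(m$primers$tm_fwd >= 57 && m$primers$tm_fwd <= 63)
    expect_true(m$primers$gc_fwd >= 0.35 && m$primers$gc_fwd <= 0.65)
  }
})

test_that("primer design refuses targets without sufficient flanks", {
  set.seed(43)
  base <- strsplit(random_seq(250), "")[[1]]
  alt <- base
  alt[120:134] <- "-"
  aln <- toy_aln(c(p = paste0(base, collapse = ""),
                   q = paste0(alt, collapse = "")))
  vt <- scan_alignment(aln, "p")
  target <- vt[vt$kind == "INDEL", ][1, ]
  expect_error(design_primer_pair(aln, target), "no primer site")
})

test_that("dominant markers anchor the allele on the forward 3' end", {
  set.seed(44)
  base <- strsplit(random_seq(1000), "")[[1]]
  base[500] <- "A"
  alt <- base
  alt[500] <- "G"
  aln <- toy_aln(c(p = paste0(base, collapse = ""),
                   q = paste0(alt, collapse = "")))
  vt <- scan_alignment(aln, "p")
  target <- vt[vt$aln_start == 500, ]
  m <- design_dominant_snp(aln, target, allele = "A", name = "dom1")
  expect_equal(substr(m$primers$fwd, nchar(m$primers$fwd),
                      nchar(m$primers$fwd)), "A")
  expect_equal(m$class_sizes[["B"]], "-")
  # the A template amplifies, the G template does not
  expect_length(predict_products(paste0(base, collapse = ""), m$primers,
                                 anchor_3prime = TRUE), 1L)
  expect_length(predict_products(paste0(alt, collapse = ""), m$primers,
                                 anchor_3prime = TRUE), 0L)
})

test_that("dominant markers genotype pure samples without miscalls", {
  set.seed(45)
  base <- strsplit(random_seq(800), "")[[1]]
  base[400] <- "C"
  alt <- base
  alt[400] <- "T"
  aln <- toy_aln(c(p = paste0(base, collapse = ""),
                   q = paste0(alt, collapse = "")))
  vt <- scan_alignment(aln, "p")
  m <- design_dominant_snp(aln, vt[vt$aln_start == 400, ], allele = "C",
                           name = "dom2")
  for (rep in 1:50) {
    cls <- sample(c("p", "q"), 1)
    tmpl <- if (cls == "p") paste0(base, collapse = "")
            else paste0(alt, collapse = "")
    call <- genotype_sample(dna_records("s", tmpl), list(m))$call
    expect_equal(call, if (cls == "p") "A" else "B")
  }
})

test_that("HRM targets cover clustered SNPs with equal-size amplicons", {
  set.seed(46)
  base <- strsplit(random_seq(600), "")[[1]]
  alt <- base
  for (pos in c(280, 300, 320)) {
    alt[pos] <- sample(setdiff(c("A", "C", "G", "T"), base[pos]), 1)
  }
  aln <- toy_aln(c(p = paste0(base, collapse = ""),
                   q = paste0(alt, collapse = "")), compartment = "NRDNA")
  vt <- scan_alignment(aln, "p")
  d <- diagnostic_sites(vt, c(p = "g1", q = "g2"))
  hrm <- select_hrm_targets(aln, d, window = 120)
  expect_equal(length(hrm), 1L)
  m <- hrm[[1]]
  expect_equal(m$marker_type, "HRM_SNP")
  expect_length(m$hrm_offsets, 3L)
  expect_equal(length(unique(m$class_sizes)), 1L)
  expect_equal(unname(nchar(m$class_alleles)), c(3L, 3L))
  # amplicon alleles recover each template's bases
  amp <- extract_amplicons(paste0(base, collapse = ""), m$primers)
  expect_length(amp, 1L)
  expect_equal(paste0(substring(amp, m$hrm_offsets, m$hrm_offsets),
                      collapse = ""),
               unname(m$class_alleles[["A"]]))
})

test_that("every planted nrDNA SNP is covered by an HRM design or reported", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  d <- diagnostic_sites(vt, species_groups(refs$nrdna))
  hrm <- select_hrm_targets(refs$nrdna, d)
  covered <- unlist(lapply(hrm, function(m) {
    # amplicon interval in reference (AU) coordinates
    sites <- d$aln_start[d$kind == "SNP" &
                           d$ref_pos >= m$primers$fwd_start &
                           d$ref_pos <= m$primers$rev_start]
    sites
  }))
  uncovered <- attr(hrm, "uncovered")
  planted <- d$aln_start[d$kind == "SNP"]
  expect_setequal(c(covered, uncovered), planted)
})

test_that("marker panels round-trip through the TSV dialect", {
  refs <- mini_refs()
  design <- design_marker_panel(refs$plastome, refs$nrdna)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_markers(design$panel, path)
  back <- read_markers(path)
  expect_equal(length(back), length(design$panel))
  for (i in seq_along(back)) {
    orig <- design$panel[[i]]
    expect_equal(back[[i]]$name, orig$name)
    expect_equal(back[[i]]$marker_type, orig$marker_type)
    expect_equal(back[[i]]$primers$fwd, orig$primers$fwd)
    expect_equal(back[[i]]$primers$rev, orig$primers$rev)
    expect_equal(back[[i]]$class_sizes, orig$class_sizes)
  }
})
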