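# Independent brute-force oracle: walks columns one at a time, tracking
# the current gap pattern to delimit InDel events, and calls a SNP at any
# column where >= 2 non-gap bases differ.
oracle_scan <- function(seqs) {
  M <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(M) <- names(seqs)
  snp_cols <- integer(0)
  indels <- list()
  cur_pat <- ""
  cur_start <- NA_integer_
  flush <- function(end_col) {
    if (nzchar(cur_pat)) {
      indels[[length(indels) + 1L]] <<- c(cur_start, end_col)
    }
    cur_pat <<- ""
  }
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    pat <- paste0(ifelse(col == "-", "1", "0"), collapse = "")
    if (all(col == "-")) { flush(j - 1L); next }  # all-gap: dropped
    if (grepl("1", pat)) {
      if (pat != cur_pat) {
        flush(j - 1L)
        cur_pat <- pat
        cur_start <- j
      }
    } else {
      flush(j - 1L)
    }
    bases <- col[col != "-"]
    if (all(bases %in% c("A", "C", "G", "T")) &&
        length(unique(bases)) >= 2L) {
      snp_cols <- c(snp_cols, j)
    }
  }
  flush(ncol(M))
  list(n_snps = length(snp_cols), snp_cols = snp_cols,
       indels = indels)
}

random_gapped_aln <- function(n_samples = 5, n_cols = 50) {
  anc <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  seqs <- vapply(seq_len(n_samples), function(i) {
    x <- anc
    # random substitutions
    k <- sample(0:4, 1)
    if (k > 0) {
      pos <- sample.int(n_cols, k)
      x[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    # random gap runs
    for (g in seq_len(sample(0:2, 1))) {
      len <- sample(1:6, 1)
      st <- sample.int(n_cols - len, 1)
      x[st:(st + len - 1)] <- "-"
    }
    paste0(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n_samples))
  # ensure the first (reference) record keeps at least one base
  if (!grepl("[ACGT]", seqs[1])) seqs[1] <- paste0(anc, collapse = "")
  seqs
}

test_that("scan_alignment calls the textbook SNP and InDel examples", {
  vt <- scan_alignment(toy_aln(c(r = "ACGT", s = "ACGA")), "r")
  expect_equal(nrow(vt), 1L)
  expect_equal(vt$kind, "SNP")
  expect_equal(vt$ref_pos, 4L)
  expect_equal(vt$r, "T")
  expect_equal(vt$s, "A")

  vt2 <- scan_alignment(toy_aln(c(r = "ACCCGT", s = "AC---T")), "r")
  expect_equal(sum(vt2$kind == "SNP"), 0L)
  ind <- vt2[vt2$kind == "INDEL", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length, 3L)
  expect_equal(ind$ref_pos, 2L)
  expect_equal(ind$r, "CCG")
  expect_equal(ind$s, "---")
})

test_that("scan_alignment matches a brute-force column-walk oracle", {
  set.seed(31)
  for (rep in 1:25) {
    seqs <- random_gapped_aln()
    vt <- scan_alignment(toy_aln(seqs), "s1")
    orc <- oracle_scan(seqs)
    expect_equal(sum(vt$kind == "SNP"), orc$n_snps)
    expect_equal(vt$aln_start[vt$kind == "SNP"], orc$snp_cols)
    ind <- vt[vt$kind == "INDEL", ]
    expect_equal(nrow(ind), length(orc$indels))
    if (length(orc$indels)) {
      expect_equal(ind$aln_start,
                   vapply(orc$indels, `[`, numeric(1), 1))
      expect_equal(ind$length,
                   vapply(orc$indels, function(x) x[2] - x[1] + 1,
                          numeric(1)))
    }
  }
})

test_that("scan_alignment is invariant to record order", {
  set.seed(32)
  seqs <- random_gapped_aln()
  vt1 <- scan_alignment(toy_aln(seqs), "s1")
  vt2 <- scan_alignment(toy_aln(rev(seqs)), "s1")
  expect_equal(as.data.frame(vt1)[, c("kind", "ref_pos", "length",
                                      "aln_start", names(seqs))],
               as.data.frame(vt2)[, c("kind", "ref_pos", "length",
                                      "aln_start", names(seqs))])
})

test_that("gap-free alignments reduce to Hamming-difference columns", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 40
    a <- random_seq(n)
    bc <- strsplit(a, "")[[1]]
    pos <- sample.int(n, 5)
    bc[pos] <- vapply(bc[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    b <- paste0(bc, collapse = "")
    vt <- scan_alignment(toy_aln(c(x = a, y = b)), "x")
    expect_equal(sum(vt$kind == "INDEL"), 0L)
    hamming <- sum(strsplit(a, "")[[1]] != bc)
    expect_equal(sum(vt$kind == "SNP"), hamming)
    pc <- pairwise_counts(vt, "x", "y")
    expect_equal(pc$n_snps, hamming)
  }
})

test_that("pairwise counts are symmetric, zero on self, exact on planted truth", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$plastome, "AU")
  expect_equal(unclass(pairwise_counts(vt, "AU", "AU"))[c("n_snps", "n_indels")],
               list(n_snps = 0L, n_indels = 0L))
  ab <- pairwise_counts(vt, "AU", "AM")
  ba <- pairwise_counts(vt, "AM", "AU")
  expect_equal(ab$n_snps, ba$n_snps)
  expect_equal(ab$n_indels, ba$n_indels)

  # planted per-branch events give exact pairwise totals
  tr <- refs$truth[refs$truth$compartment == "PLASTOME", ]
  expected <- function(a, b, kind) {
    sum(tr$kind == kind & tr$branch %in% c(a, b))
  }
  expect_equal(ab$n_snps, expected("AU", "AM", "SNP"))
  expect_equal(ab$n_indels, expected("AU", "AM", "INDEL"))
  mo <- pairwise_counts(vt, "AM", "AO")
  expect_equal(mo$n_snps, expected("AM", "AO", "SNP"))
  expect_equal(mo$n_indels, expected("AM", "AO", "INDEL"))
  expect_error(pairwise_counts(vt, "AU", "nope"), "unknown sample")
})

test_that("nrDNA contrast carries 20 SNPs and one 1-bp InDel by construction", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  pc <- pairwise_counts(vt, "AU", "AM")
  expect_equal(pc$n_snps, 20L)
  expect_equal(pc$n_indels, 1L)
  # AM and AO nrDNA identical by construction
  pc2 <- pairwise_counts(vt, "AM", "AO")
  expect_equal(pc2$n_snps + pc2$n_indels, 0L)
})

test_that("diagnostic_sites returns fixed, differing sites with group alleles", {
  aln <- toy_aln(c(a1 = "AATT", a2 = "AATT", b1 = "GATT"))
  vt <- scan_alignment(aln, "a1")
  d <- diagnostic_sites(vt, c(a1 = "g1", a2 = "g1", b1 = "g2"))
  expect_equal(nrow(d), 1L)
  expect_equal(d$group_allele.g1, "A")
  expect_equal(d$group_allele.g2, "G")

  # a site polymorphic inside one group is excluded against that group
  aln2 <- toy_aln(c(a1 = "AATT", a2 = "CATT", b1 = "GATT", b2 = "GATT"))
  vt2 <- scan_alignment(aln2, "a1")
  d2 <- diagnostic_sites(vt2, c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"))
  expect_equal(nrow(d2), 0L)
  expect_equal(attr(d2, "n_excluded_polymorphic"), 1L)

  # synthetic nrDNA: all planted AU-branch events are diagnostic
  refs <- mini_refs()
  nvt <- scan_alignment(refs$nrdna, "AU")
  nd <- diagnostic_sites(nvt, c(AU = "AUgrp", AM = "AMgrp", AO = "AMgrp"))
  expect_equal(nrow(nd), 21L)
})

test_that("variant tables round-trip through TSV and export minimal VCF", {
  refs <- mini_refs()
  vt <- scan_alignment(refs$nrdna, "AU")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(vt, path)
  back <- read_variants(path, reference_id = "AU")
  expect_equal(back$ref_pos, vt$ref_pos)
  expect_equal(back$AM, vt$AM)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, refs$nrdna[refs$nrdna$id == "AU", ], vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(vt))
  ref_col <- vapply(strsplit(body, "\t"), `[`, character(1), 4)
  expect_true(all(grepl("^[ACGT]+$", ref_col)))
})
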