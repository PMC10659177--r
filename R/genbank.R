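#' Accessions of the deposited Allium reference set
#'
#' The six plastomes and six 45S nrDNA sequences of the reference
#' samples (AU, AM, AO and the farm collections TB, JB, SA), in sample
#' order.
#'
#' @return Named list with `plastome` and `nrdna` accession vectors.
#' @export
allium_accessions <- function() {
  samples <- c("AU", "AM", "AO", "Farm-TB", "Farm-JB", "Farm-SA")
  list(
    plastome = stats::setNames(paste0("OQ1835", 91:96), samples),
    nrdna = stats::setNames(paste0("OQ1839", 20:25), samples))
}

#' Download the deposited reference sequences from GenBank
#'
#' Fetches the twelve accessions via NCBI efetch into `dir` (one FASTA
#' per accession, named `<sample>_<compartment>.fasta`). Requires
#' network access.
#'
#' @param dir Target directory.
#' @param timeout Per-download timeout in seconds.
#' @return `dir`, invisibly; errors if any download fails.
#' @export
fetch_genbank_references <- function(dir, timeout = 300) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- allium_accessions()
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                 "efetch.fcgi?db=nuccore&rettype=fasta&retmode=text&id=")
  for (comp in names(acc)) {
    for (s in names(acc[[comp]])) {
      dest <- file.path(dir, paste0(s, "_", comp, ".fasta"))
      if (file.exists(dest) && file.size(dest) > 0) next
      status <- tryCatch(
        utils::download.file(paste0(base, acc[[comp]][[s]]), dest,
                             quiet = TRUE, mode = "wb"),
        error = function(e) -1L, warning = function(w) -1L)
      if (!identical(status, 0L) || !file.exists(dest) ||
          file.size(dest) == 0) {
        unlink(dest)
        stop("could not download ", acc[[comp]][[s]], " (", s, " ", comp,
             ") from GenBank")
      }
    }
  }
  invisible(dir)
}

load_reference_set <- function(dir) {
  acc <- allium_accessions()
  load_comp <- function(comp, tag) {
    recs <- do.call(rbind, lapply(names(acc[[comp]]), function(s) {
      p <- file.path(dir, paste0(s, "_", comp, ".fasta"))
      if (!file.exists(p)) stop("reference file missing: ", p)
      r <- read_fasta(p, compartment = tag)
      r$id <- s
      r
    }))
    class(recs) <- c("dna_records", "data.frame")
    recs
  }
  list(plastome = load_comp("plastome", "PLASTOME"),
       nrdna = load_comp("nrdna", "NRDNA"))
}

#' Align records with MAFFT
#'
#' Convenience wrapper around an external `mafft` executable; the
#' pipeline otherwise accepts pre-aligned FASTA, so MAFFT is only needed
#' when starting from unaligned sequences.
#'
#' @param records A [dna_records] data frame (unaligned).
#' @param mafft Path to the mafft executable.
#' @return An [aligned_set].
#' @export
align_with_mafft <- function(records, mafft = Sys.which("mafft")) {
  if (!nzchar(mafft)) stop("mafft executable not found")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(records, fin)
  status <- system2(mafft, c("--auto", "--quiet", fin),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  out <- read_fasta(fout, compartment = records$compartment[1L])
  out$id <- records$id[match(out$id, records$id)]
  aligned_set(out)
}

#' Recompute the headline reference-set numbers from deposited sequences
#'
#' Given a directory holding the twelve deposited FASTA files (see
#' [fetch_genbank_references()]), aligns each compartment, scans for
#' variants and recomputes: SNP/InDel counts between the two nrDNA
#' lineages, the position of the 1-bp nrDNA InDel, the AU vs Farm-TB
#' plastome SNP count, the number of diagnostic nrDNA sites between the
#' lineages, and the in-silico product sizes of the published AL_1 and
#' AL_4 assays.
#'
#' @param dir Directory of reference FASTAs.
#' @return Named list of computed quantities.
#' @export
reproduce_reference_numbers <- function(dir) {
  refs <- load_reference_set(dir)
  nr_aln <- align_with_mafft(refs$nrdna)
  pl_aln <- align_with_mafft(refs$plastome)

  nr_vt <- scan_alignment(nr_aln, "AU")
  pl_vt <- scan_alignment(pl_aln, "AU")

  nr_groups <- c("AU" = "AUgrp", "Farm-TB" = "AUgrp", "Farm-JB" = "AUgrp",
                 "Farm-SA" = "AUgrp", "AM" = "AMgrp", "AO" = "AMgrp")
  nr_pair <- pairwise_counts(nr_vt, "AU", "AM")
  nr_diag <- diagnostic_sites(nr_vt, nr_groups)
  # the 1-bp event is reported in the coordinate of the longer (AM)
  # sequence, on whose 1936th nucleotide the extra base sits
  nr_vt_am <- scan_alignment(nr_aln, "AM")
  indel_rows <- nr_vt_am[nr_vt_am$kind == "INDEL" & nr_vt_am$length == 1L, ]
  pl_pair_au_tb <- pairwise_counts(pl_vt, "AU", "Farm-TB")

  panel <- reference_marker_panel()
  al1 <- panel[[which(vapply(panel, `[[`, character(1), "name") == "AL_1")]]
  al4 <- panel[[which(vapply(panel, `[[`, character(1), "name") == "AL_4")]]
  au_pl <- refs$plastome$residues[refs$plastome$id == "AU"]
  am_pl <- refs$plastome$residues[refs$plastome$id == "AM"]
  ao_pl <- refs$plastome$residues[refs$plastome$id == "AO"]

  list(
    nrdna_snps_between_groups = nr_pair$n_snps,
    nrdna_indels_between_groups = nr_pair$n_indels,
    nrdna_1bp_indel_position = if (nrow(indel_rows))
      indel_rows$ref_pos[1L] + 1L else NA_integer_,
    plastome_snps_au_vs_tb = pl_pair_au_tb$n_snps,
    plastome_indels_au_vs_tb = pl_pair_au_tb$n_indels,
    nrdna_diagnostic_sites = nrow(nr_diag),
    al1_product_au = predict_products(au_pl, al1$primers),
    al1_product_am = predict_products(am_pl, al1$primers),
    al4_product_ao = predict_products(ao_pl, al4$primers))
}
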