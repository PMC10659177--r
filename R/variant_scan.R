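#' Scan a multiple sequence alignment for SNPs and InDel events
#'
#' SNP calling operates per column on the records that carry a base there:
#' a column where at least two of them differ yields one SNP (gapped
#' records get the allele `-`). InDel events are maximal runs of adjacent
#' columns sharing an identical non-empty gap pattern across records; each
#' run is a single event whose length is the run length, regardless of how
#' many bases it spans — a 15-bp gap is one event, not fifteen. Columns
#' that are gap in every record are dropped, and a column may contribute
#' both to an InDel event and (among its non-gap records) to a SNP, so the
#' two counts stay independent. Columns containing ambiguity codes among
#' the non-gap records are excluded from SNP calling and tallied in the
#' `n_ambiguous_excluded` attribute.
#'
#' Reported positions (`ref_pos`) are 1-based in the ungapped coordinate
#' of `reference_id`; an InDel's `ref_pos` is the last reference base
#' before the event (0 at the sequence start).
#'
#' @param aln An [aligned_set].
#' @param reference_id Record id whose ungapped coordinate anchors
#'   `ref_pos`.
#' @param mask Optional two-column matrix/data frame of 1-based alignment
#'   column intervals (start, end) to exclude from scanning, e.g. one
#'   inverted-repeat copy.
#' @return A `variant_table`: data frame with columns `kind` (`"SNP"` or
#'   `"INDEL"`), `ref_pos`, `length`, `aln_start`, then one allele column
#'   per record id. Attributes: `reference_id`, `sample_ids`,
#'   `n_ambiguous_excluded`.
#' @export
scan_alignment <- function(aln, reference_id, mask = NULL) {
  if (!reference_id %in% aln$id) {
    stop("reference_id '", reference_id, "' not in alignment")
  }
  M <- aln_matrix(aln)
  ns <- nrow(M)
  nc <- ncol(M)
  gap <- M == "-"
  all_gap <- colSums(gap) == ns

  masked <- rep(FALSE, nc)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    for (r in seq_len(nrow(mask))) {
      masked[max(1L, mask[r, 1L]):min(nc, mask[r, 2L])] <- TRUE
    }
  }
  usable <- !all_gap & !masked

  # ungapped reference coordinate of every column (position of the
  # reference base at/before the column)
  ref_row <- M[reference_id, ]
  ref_cum <- cumsum(ref_row != "-")

  keep <- which(usable)
  snps <- list()
  indels <- list()
  n_ambig <- 0L

  if (length(keep)) {
    # ---- InDel events: constant non-empty gap pattern over columns that
    # are adjacent within the kept set
    key <- as.integer(crossprod(gap[, keep, drop = FALSE], 2^(seq_len(ns) - 1L)))
    # break runs where kept columns are not contiguous in the alignment
    brk <- c(TRUE, diff(keep) != 1L | key[-1L] != key[-length(key)])
    run_id <- cumsum(brk)
    for (rid in unique(run_id[key > 0L])) {
      cols <- keep[run_id == rid]
      if (key[run_id == rid][1L] == 0L) next
      len <- length(cols)
      is_gap_sample <- gap[, cols[1L]]
      alleles <- apply(M[, cols, drop = FALSE], 1L, paste0, collapse = "")
      start_col <- cols[1L]
      rp <- if (start_col == 1L) 0L else ref_cum[start_col - 1L]
      indels[[length(indels) + 1L]] <- c(
        list(kind = "INDEL", ref_pos = as.integer(rp), length = len,
             aln_start = start_col), as.list(alleles))
    }

    # ---- SNPs: per kept column, among non-gap records
    sub <- M[, keep, drop = FALSE]
    gsub_ <- gap[, keep, drop = FALSE]
    acgt <- sub == "A" | sub == "C" | sub == "G" | sub == "T"
    bad_col <- colSums(!acgt & !gsub_) > 0L          # ambiguity among bases
    n_ambig <- sum(bad_col)
    for (j in which(!bad_col)) {
      bases <- sub[!gsub_[, j], j]
      if (length(unique(bases)) >= 2L) {
        col <- keep[j]
        alleles <- sub[, j]
        snps[[length(snps) + 1L]] <- c(
          list(kind = "SNP", ref_pos = as.integer(ref_cum[col]), length = 1L,
               aln_start = col), as.list(alleles))
      }
    }
  }

  rows <- c(snps, indels)
  if (length(rows)) {
    vt <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
    }))
    vt <- vt[order(vt$aln_start, vt$kind), , drop = FALSE]
    rownames(vt) <- NULL
  } else {
    vt <- data.frame(kind = character(0), ref_pos = integer(0),
                     length = integer(0), aln_start = integer(0),
                     check.names = FALSE)
    for (s in aln$id) vt[[s]] <- character(0)
  }
  attr(vt, "reference_id") <- reference_id
  attr(vt, "sample_ids") <- aln$id
  attr(vt, "n_ambiguous_excluded") <- n_ambig
  class(vt) <- c("variant_table", "data.frame")
  vt
}

sample_ids <- function(vt) attr(vt, "sample_ids")

is_gap_allele <- function(allele) {
  allele == strrep("-", nchar(allele))
}

#' Pairwise SNP and InDel counts between two samples
#'
#' A SNP counts when both samples carry a (non-gap) base and the bases
#' differ; an InDel event counts when the two samples' gap status at the
#' event differs.
#'
#' @param vt A `variant_table` from [scan_alignment()].
#' @param a,b Sample ids.
#' @return List of class `pairwise_variation`: `sample_a`, `sample_b`,
#'   `n_snps`, `n_indels`.
#' @export
pairwise_counts <- function(vt, a, b) {
  ids <- sample_ids(vt)
  if (!a %in% ids) stop("unknown sample: ", a)
  if (!b %in% ids) stop("unknown sample: ", b)
  aa <- vt[[a]]
  bb <- vt[[b]]
  snp <- vt$kind == "SNP"
  n_snps <- sum(snp & aa != bb & aa != "-" & bb != "-")
  ind <- vt$kind == "INDEL"
  n_indels <- sum(ind & is_gap_allele(aa) != is_gap_allele(bb))
  structure(list(sample_a = a, sample_b = b,
                 n_snps = as.integer(n_snps), n_indels = as.integer(n_indels)),
            class = "pairwise_variation")
}

#' All pairwise variation counts (the comparison-matrix view)
#'
#' @param vt A `variant_table`.
#' @return Data frame with one row per unordered sample pair and columns
#'   `sample_a`, `sample_b`, `n_snps`, `n_indels`.
#' @export
pairwise_matrix <- function(vt) {
  ids <- sample_ids(vt)
  cmb <- utils::combn(ids, 2L)
  do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    pc <- pairwise_counts(vt, cmb[1L, k], cmb[2L, k])
    data.frame(sample_a = pc$sample_a, sample_b = pc$sample_b,
               n_snps = pc$n_snps, n_indels = pc$n_indels,
               stringsAsFactors = FALSE)
  }))
}

#' Group-diagnostic variant sites
#'
#' A variant is diagnostic when, for at least one pair of groups, every
#' member of each group shares one allele and the two group alleles
#' differ. Sites polymorphic inside every group are excluded (their count
#' is reported in the `n_excluded_polymorphic` attribute).
#'
#' @param vt A `variant_table`.
#' @param groups Named character vector: `sample id -> group label`. At
#'   least two non-empty groups.
#' @return The diagnostic subset of `vt`, with one extra column
#'   `group_allele.<label>` per group (the fixed allele, or `NA` when the
#'   group is polymorphic at the site), and a `groups` attribute.
#' @export
diagnostic_sites <- function(vt, groups) {
  labs <- unique(unname(groups))
  if (length(labs) < 2L) stop("need at least two groups")
  missing <- setdiff(names(groups), sample_ids(vt))
  if (length(missing)) stop("unknown sample in groups: ", missing[1L])

  fixed <- sapply(labs, function(g) {
    members <- names(groups)[groups == g]
    apply(as.data.frame(vt)[, members, drop = FALSE], 1L, function(al) {
      if (length(unique(al)) == 1L) al[[1L]] else NA_character_
    })
  })
  fixed <- matrix(fixed, nrow = nrow(vt), dimnames = list(NULL, labs))

  diag_row <- apply(fixed, 1L, function(fa) {
    fa <- fa[!is.na(fa)]
    length(unique(fa)) >= 2L
  })
  if (!nrow(vt)) diag_row <- logical(0)

  out <- vt[diag_row, , drop = FALSE]
  for (g in labs) out[[paste0("group_allele.", g)]] <- fixed[diag_row, g]
  attr(out, "reference_id") <- attr(vt, "reference_id")
  attr(out, "sample_ids") <- sample_ids(vt)
  attr(out, "groups") <- groups
  attr(out, "n_excluded_polymorphic") <- sum(!diag_row)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write a variant table as TSV
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vt, path) {
  utils::write.table(as.data.frame(vt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant table written by [write_variants()]
#' @param path TSV path.
#' @param reference_id Reference id to re-attach (first sample column if
#'   omitted).
#' @return A `variant_table`.
#' @export
read_variants <- function(path, reference_id = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  df$ref_pos <- as.integer(df$ref_pos)
  df$length <- as.integer(df$length)
  df$aln_start <- as.integer(df$aln_start)
  fixed_cols <- c("kind", "ref_pos", "length", "aln_start")
  ids <- setdiff(names(df), c(fixed_cols, grep("^group_allele\\.",
                                               names(df), value = TRUE)))
  attr(df, "sample_ids") <- ids
  attr(df, "reference_id") <- if (is.null(reference_id)) ids[1L] else reference_id
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Minimal VCF 4.2 export of a variant table
#'
#' SNPs are written as single-base REF/ALT; InDel events are left-anchored
#' on the base preceding the event, following the VCF convention. The
#' reference allele is the allele of the table's reference sample; sample
#' genotypes are emitted as haploid GT indices into REF/ALT.
#'
#' @param vt A `variant_table`.
#' @param reference A [dna_records] row (or 1-row data frame) holding the
#'   ungapped reference sequence used for anchor bases.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, reference, path) {
  ref_id <- attr(vt, "reference_id")
  ids <- sample_ids(vt)
  refseq <- degap(reference$residues[1L])
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", ref_id, ",length=", nchar(refseq), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  for (i in seq_len(nrow(vt))) {
    alleles <- unlist(as.data.frame(vt)[i, ids], use.names = TRUE)
    ref_allele <- alleles[[ref_id]]
    if (vt$kind[i] == "SNP") {
      pos <- vt$ref_pos[i]
      # a reference gap at a SNP column cannot be represented; anchor it
      if (ref_allele == "-") next
      lift <- function(a) a
      ref_field <- ref_allele
    } else {
      pos <- max(vt$ref_pos[i], 1L)
      anchor <- substr(refseq, pos, pos)
      lift <- function(a) paste0(anchor, gsub("-", "", a, fixed = TRUE))
      ref_field <- lift(ref_allele)
    }
    alts <- setdiff(unique(vapply(alleles, lift, character(1))), ref_field)
    if (!length(alts)) next
    gt <- vapply(alleles, function(a) {
      v <- lift(a)
      if (v == ref_field) "0" else as.character(match(v, alts))
    }, character(1))
    lines <- c(lines, paste(c(ref_id, pos, ".", ref_field,
                              paste(alts, collapse = ","), ".", "PASS", ".",
                              "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
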