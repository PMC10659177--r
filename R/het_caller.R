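#' Build allele probes for diagnostic sites
#'
#' For every diagnostic site, two probes are built: the site's two group
#' alleles embedded in `k` bp of reference flank on each side. A read
#' then supports an allele when the probe (or its reverse complement)
#' occurs in it exactly — a transparent stand-in for read mapping that
#' suits a short, well-separated reference such as a 45S nrDNA cistron.
#' InDel sites use the same machinery: the deletion allele's probe is
#' simply the two flanks joined.
#'
#' The flank is shrunk per-site (with a message) when another variant
#' falls within `k` bp, and a site is dropped (with a message) when it is
#' too close to the sequence end, when the remaining flank is shorter
#' than `min_k`, or when either probe is not unique in the reference.
#'
#' @param sites Diagnostic `variant_table` (from [diagnostic_sites()])
#'   carrying `group_allele.<label>` columns for exactly two group
#'   labels, or any `variant_table` plus an explicit `labels` pair.
#' @param reference A [dna_records] row holding the ungapped reference
#'   the probes are cut from. Must be one of the samples of `sites`.
#' @param k Flank length per side (default 10).
#' @param min_k Smallest admissible flank after shrinking (default 6).
#' @param labels Optional character(2): the two group labels to probe
#'   (defaults to the first two groups of the table).
#' @return Data frame of class `allele_probes`: `ref_pos`, `kind`,
#'   `label_a`, `probe_a`, `label_b`, `probe_b`, `k`.
#' @export
build_probes <- function(sites, reference, k = 10L, min_k = 6L,
                         labels = NULL) {
  grp_cols <- grep("^group_allele\\.", names(sites), value = TRUE)
  if (is.null(labels)) {
    if (length(grp_cols) < 2L) {
      stop("sites carry no group annotation; run diagnostic_sites() first")
    }
    labels <- sub("^group_allele\\.", "", grp_cols[1:2])
  }
  refseq <- degap(reference$residues[1L])
  ref_id <- reference$id[1L]
  L <- nchar(refseq)

  # other variant positions, to keep probe flanks variant-free
  all_pos <- sites$ref_pos

  out <- list()
  for (i in seq_len(nrow(sites))) {
    al_a <- sites[[paste0("group_allele.", labels[1L])]][i]
    al_b <- sites[[paste0("group_allele.", labels[2L])]][i]
    if (is.na(al_a) || is.na(al_b) || al_a == al_b) next
    pos <- sites$ref_pos[i]
    is_indel <- sites$kind[i] == "INDEL"

    # shrink k if a neighbouring variant intrudes into the flank
    near <- all_pos[all_pos != pos]
    ki <- k
    if (length(near)) {
      d <- min(abs(near - pos))
      if (d <= k) {
        ki <- d - 1L
        message("site ", pos, ": flank shrunk to ", ki,
                " bp (neighbouring variant)")
      }
    }
    if (ki < min_k) {
      message("site ", pos, ": dropped (flank < ", min_k, " bp)")
      next
    }

    if (is_indel) {
      left_end <- pos
      right_start <- pos + 1L +
        (if (is_gap_allele(sites[[ref_id]][i])) 0L else sites$length[i])
    } else {
      left_end <- pos - 1L
      right_start <- pos + 1L
    }
    if (left_end - ki + 1L < 1L || right_start + ki - 1L > L) {
      message("site ", pos, ": dropped (too close to sequence end)")
      next
    }
    left <- substr(refseq, left_end - ki + 1L, left_end)
    right <- substr(refseq, right_start, right_start + ki - 1L)
    emb <- function(allele) {
      paste0(left, gsub("-", "", allele, fixed = TRUE), right)
    }
    pa <- emb(al_a)
    pb <- emb(al_b)
    n_occ <- function(p) {
      Biostrings::countPattern(p, Biostrings::BString(refseq)) +
        Biostrings::countPattern(revcomp(p), Biostrings::BString(refseq))
    }
    if (n_occ(pa) > 1L || n_occ(pb) > 1L) {
      message("site ", pos, ": dropped (probe not unique in reference)")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      ref_pos = pos, kind = sites$kind[i],
      label_a = labels[1L], probe_a = pa,
      label_b = labels[2L], probe_b = pb,
      k = ki, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ref_pos = integer(0), kind = character(0),
               label_a = character(0), probe_a = character(0),
               label_b = character(0), probe_b = character(0),
               k = integer(0))
  rownames(res) <- NULL
  class(res) <- c("allele_probes", "data.frame")
  res
}

#' Count per-site allele depths in a read pool
#'
#' A read supports an allele iff that allele's probe, or its reverse
#' complement, is an exact substring of the read; reads matching neither
#' probe at a site (e.g. reads carrying a sequencing error inside the
#' probe window) contribute nothing there.
#'
#' @param reads A [read_set].
#' @param probes [build_probes()] output.
#' @return Data frame of class `site_depths`: `ref_pos`, `allele_a`,
#'   `count_a`, `frac_a`, `allele_b`, `count_b`, `frac_b`, `total`.
#' @export
count_allele_depths <- function(reads, probes) {
  pool <- Biostrings::DNAStringSet(reads$residues)
  hit_count <- function(p) {
    sum(Biostrings::vcountPattern(p, pool) > 0L |
          Biostrings::vcountPattern(revcomp(p), pool) > 0L)
  }
  rows <- lapply(seq_len(nrow(probes)), function(i) {
    ca <- hit_count(probes$probe_a[i])
    cb <- hit_count(probes$probe_b[i])
    tot <- ca + cb
    data.frame(ref_pos = probes$ref_pos[i],
               allele_a = probes$label_a[i], count_a = ca,
               frac_a = if (tot > 0L) ca / tot else NA_real_,
               allele_b = probes$label_b[i], count_b = cb,
               frac_b = if (tot > 0L) cb / tot else NA_real_,
               total = tot, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_pos = integer(0), allele_a = character(0),
               count_a = integer(0), frac_a = numeric(0),
               allele_b = character(0), count_b = integer(0),
               frac_b = numeric(0), total = integer(0))
  class(out) <- c("site_depths", "data.frame")
  out
}

#' Wrap externally computed per-site allele counts
#'
#' Hook for real-data workflows where counts come from a read mapper
#' rather than [count_allele_depths()].
#'
#' @param df Data frame with columns `ref_pos`, `allele_a`, `count_a`,
#'   `allele_b`, `count_b`.
#' @return A `site_depths` data frame with fractions and totals filled in.
#' @export
as_site_depths <- function(df) {
  df$total <- df$count_a + df$count_b
  df$frac_a <- ifelse(df$total > 0L, df$count_a / df$total, NA_real_)
  df$frac_b <- ifelse(df$total > 0L, df$count_b / df$total, NA_real_)
  class(df) <- c("site_depths", "data.frame")
  df
}

#' Call the homozygous/heterozygous state of a compartment
#'
#' A site is heterozygous when its minor-allele fraction reaches
#' `min_minor_frac` at depth `min_depth` or more. The compartment is
#' `HET` when at least `min_het_site_frac` of qualifying sites are
#' heterozygous, `HOM` (with the majority label) when at least that
#' fraction are fixed for the same label, and `NO_CALL` otherwise. The
#' default `min_minor_frac = 0.2` sits well below the 0.28-0.48 minor
#' fractions seen in real hybrid nrDNA read pools while staying clear of
#' sequencing noise.
#'
#' @param depths A `site_depths` data frame.
#' @param min_depth Minimum total depth for a site to qualify.
#' @param min_minor_frac Minor-allele fraction threshold for
#'   heterozygosity.
#' @param min_het_site_frac Fraction of qualifying sites that must agree.
#' @return List of class `compartment_state`: `state` (`"HOM"`, `"HET"`,
#'   `"NO_CALL"`), `label` (majority label for HOM), `minor_fraction_mean`
#'   (mean minor fraction over qualifying sites), `n_sites_supporting`,
#'   `reason`.
#' @export
call_state <- function(depths, min_depth = 20L, min_minor_frac = 0.2,
                       min_het_site_frac = 0.8) {
  qual <- depths[!is.na(depths$frac_a) & depths$total >= min_depth, ,
                 drop = FALSE]
  if (!nrow(qual)) {
    return(structure(list(state = "NO_CALL", label = NA_character_,
                          minor_fraction_mean = NA_real_,
                          n_sites_supporting = 0L,
                          reason = "no site at sufficient depth"),
                     class = "compartment_state"))
  }
  minor <- pmin(qual$frac_a, qual$frac_b)
  het <- minor >= min_minor_frac
  major_label <- ifelse(qual$frac_a >= qual$frac_b, qual$allele_a,
                        qual$allele_b)
  mfm <- mean(minor)

  if (mean(het) >= min_het_site_frac) {
    return(structure(list(state = "HET", label = NA_character_,
                          minor_fraction_mean = mfm,
                          n_sites_supporting = sum(het),
                          reason = sprintf("%d/%d sites heterozygous",
                                           sum(het), nrow(qual))),
                     class = "compartment_state"))
  }
  fixed <- !het
  for (lab in unique(major_label)) {
    supp <- fixed & major_label == lab
    if (mean(supp) >= min_het_site_frac) {
      return(structure(list(state = "HOM", label = lab,
                            minor_fraction_mean = mfm,
                            n_sites_supporting = sum(supp),
                            reason = sprintf("%d/%d sites fixed for %s",
                                             sum(supp), nrow(qual), lab)),
                       class = "compartment_state"))
    }
  }
  structure(list(state = "NO_CALL", label = NA_character_,
                 minor_fraction_mean = mfm,
                 n_sites_supporting = 0L,
                 reason = "no consistent majority across sites"),
            class = "compartment_state")
}

#' Write site depths as TSV (the machine-readable depth-ratio table)
#' @param depths A `site_depths` data frame.
#' @param path Output path.
#' @param min_depth,min_minor_frac Thresholds used to annotate each
#'   site's state column.
#' @return `path`, invisibly.
#' @export
write_site_depths <- function(depths, path, min_depth = 20L,
                              min_minor_frac = 0.2) {
  df <- as.data.frame(depths)
  minor <- pmin(df$frac_a, df$frac_b)
  df$state <- ifelse(is.na(minor) | df$total < min_depth, "no_call",
                     ifelse(minor >= min_minor_frac, "het", "hom"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
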