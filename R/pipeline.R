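#' Design a complete marker panel from reference alignments
#'
#' Reproduces the published design recipe on any reference set: select
#' group-diagnostic plastome InDel events longer than 10 bp and design
#' codominant markers on them (longest first), design one dominant
#' allele-specific marker on a SNP private to a single species, and
#' cover the diagnostic nrDNA SNPs with short equal-size HRM amplicons.
#' HRM markers get allele probes attached so samples can be genotyped
#' from read pools.
#'
#' @param plastome_aln,nrdna_aln Reference [aligned_set]s.
#' @param groups Named vector `sample -> group`; defaults to each sample
#'   being its own group (species references).
#' @param n_codominant Maximum codominant markers to design.
#' @param n_hrm Maximum HRM markers to keep.
#' @param constraints [primer_constraints()] for the plastome designs.
#' @param probe_k Flank length for HRM allele probes.
#' @return List with `panel` (list of `marker_spec`), `plastome_variants`,
#'   `nrdna_variants`, `nrdna_diagnostic` (variant tables).
#' @export
design_marker_panel <- function(plastome_aln, nrdna_aln, groups = NULL,
                                n_codominant = 6L, n_hrm = 3L,
                                constraints = primer_constraints(),
                                probe_k = 10L) {
  ids <- plastome_aln$id
  if (is.null(groups)) groups <- stats::setNames(ids, ids)
  ref_id <- ids[1L]

  pl_vt <- scan_alignment(plastome_aln, ref_id)
  nr_vt <- scan_alignment(nrdna_aln, ref_id)

  panel <- list()
  k <- 0L

  # codominant InDel markers, longest events first
  targets <- select_indel_targets(pl_vt, min_len = 11L, groups = groups)
  for (i in seq_len(nrow(targets))) {
    if (sum(vapply(panel, function(m)
      m$marker_type == "CODOMINANT_INDEL", logical(1))) >= n_codominant) break
    k <- k + 1L
    m <- tryCatch(design_codominant_indel(
      plastome_aln, targets[i, ], name = sprintf("SB_%d", k),
      constraints = constraints), error = function(e) NULL)
    if (is.null(m)) { k <- k - 1L; next }
    panel[[length(panel) + 1L]] <- m
  }

  # one dominant marker on a SNP private to a single species
  pl_diag <- diagnostic_sites(pl_vt, groups)
  snps <- pl_diag[pl_diag$kind == "SNP", , drop = FALSE]
  for (i in seq_len(nrow(snps))) {
    al <- unlist(as.data.frame(snps)[i, ids])
    tab <- table(al)
    if (!any(tab == 1L)) next
    minority <- names(tab)[tab == 1L][1L]
    m <- tryCatch(design_dominant_snp(
      plastome_aln, snps[i, ], allele = minority,
      name = sprintf("SB_%d", k + 1L), constraints = constraints),
      error = function(e) NULL)
    if (!is.null(m)) {
      k <- k + 1L
      panel[[length(panel) + 1L]] <- m
      break
    }
  }

  # HRM markers over the diagnostic nrDNA SNPs, with allele probes
  nr_diag <- diagnostic_sites(nr_vt, groups)
  hrm <- select_hrm_targets(nrdna_aln, nr_diag, name_prefix = "SB_HRM")
  hrm <- utils::head(hrm, n_hrm)
  if (length(hrm)) {
    # probe the two distinct nrDNA lineages
    nr_labels <- distinct_group_labels(nr_diag, groups)
    nr_ref <- nrdna_aln[nrdna_aln$id == ref_id, , drop = FALSE]
    nr_ref$residues <- degap(nr_ref$residues)
    probes <- suppressMessages(
      build_probes(nr_diag, nr_ref, k = probe_k, labels = nr_labels))
    # express probe positions in the reference's ungapped coordinate and
    # attach to each HRM marker the probes inside its amplicon
    for (i in seq_along(hrm)) {
      pp <- hrm[[i]]$primers
      inside <- probes$ref_pos >= pp$fwd_start & probes$ref_pos <= pp$rev_start
      hrm[[i]]$probes <- probes[inside, , drop = FALSE]
    }
  }
  panel <- c(panel, hrm)
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  list(panel = panel, plastome_variants = pl_vt, nrdna_variants = nr_vt,
       nrdna_diagnostic = nr_diag, nrdna_probes = if (length(hrm))
         probes else NULL)
}

# first two group labels that actually differ at some diagnostic site
distinct_group_labels <- function(vt_diag, groups) {
  labs <- unique(unname(groups))
  cols <- paste0("group_allele.", labs)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i >= j) next
      a <- vt_diag[[cols[i]]]
      b <- vt_diag[[cols[j]]]
      if (any(!is.na(a) & !is.na(b) & a != b)) return(c(labs[i], labs[j]))
    }
  }
  labs[1:2]
}

#' Infer the plastome type of a sample from panel calls
#'
#' Generic version of the published seven-marker lookup: each reference
#' species has an expected allele class at every plastome marker (the
#' class whose reference samples include it); a sample is assigned the
#' unique species consistent with all its non-`NULL` plastome calls.
#'
#' @param calls Data frame from [genotype_sample()].
#' @param panel The marker panel the calls came from.
#' @param species Candidate species labels (default: all reference
#'   samples appearing in the panel's class maps).
#' @param min_calls Minimum non-`NULL` plastome calls required.
#' @return List: `type` (species or `"ambiguous"`), `reason`.
#' @export
assign_type_from_panel <- function(calls, panel, species = NULL,
                                   min_calls = 3L) {
  plast <- panel[vapply(panel, function(m)
    m$compartment == "PLASTOME", logical(1))]
  if (is.null(species)) {
    species <- unique(unlist(lapply(plast, function(m)
      unlist(m$class_samples))))
  }
  obs <- stats::setNames(calls$call, calls$marker)
  n_ok <- sum(obs[names(plast)] != "NULL", na.rm = TRUE)
  if (n_ok < min_calls) {
    return(list(type = "ambiguous", reason = "insufficient calls"))
  }
  consistent <- vapply(species, function(sp) {
    all(vapply(plast, function(m) {
      o <- obs[[m$name]]
      if (is.null(o) || is.na(o) || o == "NULL") return(TRUE)
      expected <- names(m$class_samples)[vapply(m$class_samples, function(s)
        sp %in% s, logical(1))]
      length(expected) == 1L && o == expected
    }, logical(1)))
  }, logical(1))
  if (sum(consistent) == 1L) {
    return(list(type = species[consistent], reason = "pattern match"))
  }
  list(type = "ambiguous",
       reason = if (sum(consistent) == 0L) "matches no species pattern"
       else paste("consistent with:",
                  paste(species[consistent], collapse = ",")))
}

#' Run the whole authentication pipeline on simulated or supplied samples
#'
#' Chains every stage: variant scan, marker design, in-silico
#' genotyping, read-based nrDNA heterozygosity calling and cytonuclear
#' classification.
#'
#' @param refs A `sim_references` object (or list with `plastome`,
#'   `nrdna` aligned sets).
#' @param samples List of `sim_sample` objects (or lists with
#'   `sample_id`, `plastome` records, `reads`).
#' @param out_dir Optional output directory for the stage TSVs and run
#'   manifest.
#' @param min_depth,min_minor_frac Heterozygosity-calling thresholds.
#' @return List: `design` (panel + variant tables), `calls` (long data
#'   frame), `classes`, `counts`, `states` (per-sample nrDNA states).
#' @export
run_pipeline <- function(refs, samples, out_dir = NULL,
                         min_depth = 20L, min_minor_frac = 0.2) {
  design <- design_marker_panel(refs$plastome, refs$nrdna)
  panel <- design$panel

  all_calls <- list()
  rows <- list()
  states <- list()
  for (s in samples) {
    calls <- genotype_sample(s$plastome, panel, reads = s$reads,
                             min_depth = min_depth,
                             min_minor_frac = min_minor_frac)
    calls$sample_id <- s$sample_id
    all_calls[[s$sample_id]] <- calls
    pt <- assign_type_from_panel(calls, panel)

    nr_state <- if (!is.null(s$reads) && !is.null(design$nrdna_probes)) {
      call_state(count_allele_depths(s$reads, design$nrdna_probes),
                 min_depth = min_depth, min_minor_frac = min_minor_frac)
    } else {
      hrm_names <- names(panel)[vapply(panel, function(m)
        m$marker_type == "HRM_SNP", logical(1))]
      nrdna_state_from_hrm(calls$call[match(hrm_names, calls$marker)])
    }
    states[[s$sample_id]] <- nr_state
    sc <- classify_sample(pt, nr_state)
    cls <- if (sc$label == "HYBRID")
      paste0("HYBRID(maternal=", sc$maternal, ")") else sc$label
    rows[[s$sample_id]] <- data.frame(
      sample = s$sample_id, class = cls, maternal = sc$maternal,
      paternal = sc$paternal,
      minor_fraction_mean = if (!is.null(nr_state$minor_fraction_mean))
        nr_state$minor_fraction_mean else NA_real_,
      rationale = sc$rationale, stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, rows)
  rownames(classes) <- NULL
  tab <- table(classes$class)
  counts <- data.frame(class = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  calls_df <- do.call(rbind, all_calls)
  rownames(calls_df) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variants(design$plastome_variants,
                   file.path(out_dir, "plastome_variants.tsv"))
    write_variants(design$nrdna_variants,
                   file.path(out_dir, "nrdna_variants.tsv"))
    write_markers(panel, file.path(out_dir, "markers.tsv"))
    utils::write.table(calls_df, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classes, file.path(out_dir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(counts, file.path(out_dir, "class_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, list(min_depth = min_depth,
                                 min_minor_frac = min_minor_frac,
                                 n_samples = length(samples)))
  }
  list(design = design, calls = calls_df, classes = classes,
       counts = counts, states = states)
}

#' Write a run manifest (version, parameters, parameter hash)
#' @param out_dir Output directory.
#' @param params Named list of run parameters (thresholds, seeds).
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, params) {
  params <- params[!duplicated(names(params))]
  tmp <- tempfile()
  # the hash covers the analysis parameters, not the output location
  yaml::write_yaml(params[setdiff(names(params), "out")], tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "superbarcode",
    version = as.character(utils::packageVersion("superbarcode")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    params_md5 = hash)
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
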