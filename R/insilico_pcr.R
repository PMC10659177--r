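#' Find primer binding sites on both strands
#'
#' Exact or near-exact (Hamming) matching of a primer against a template,
#' on both strands. Ambiguity codes in the template are treated as
#' literal characters, i.e. mismatches, since the designed primers are
#' unambiguous. Plus-strand sites are reported at the 5' end of the
#' primer in forward coordinates; minus-strand sites are reported at the
#' forward coordinate of the primer's 5' end on that strand (the right
#' edge of the footprint).
#'
#' @param seq Template DNA string, or a [dna_records] row (first row
#'   used); gaps are removed before matching.
#' @param primer Primer sequence, 5'->3'.
#' @param max_mismatch Maximum mismatches allowed (default 0).
#' @param anchor_3prime When `TRUE`, the primer's 3'-terminal base must
#'   match exactly even when mismatches are allowed elsewhere (the
#'   dominant-marker contract).
#' @return Data frame with columns `position`, `strand` (`"+"`/`"-"`),
#'   `mismatches`, `start`, `end` (footprint in forward coordinates).
#' @export
find_binding_sites <- function(seq, primer, max_mismatch = 0L,
                               anchor_3prime = FALSE) {
  if (is.data.frame(seq)) seq <- seq$residues[1L]
  seq <- degap(toupper(seq))
  primer <- toupper(primer)
  if (nchar(primer) < 10L) stop("primer shorter than 10 bases")
  subject <- Biostrings::BString(seq)
  lp <- nchar(primer)

  hits_for <- function(pattern) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatch, fixed = TRUE)
    st <- Biostrings::start(m)
    if (!length(st)) {
      return(data.frame(start = integer(0), end = integer(0),
                        mismatches = integer(0)))
    }
    mm <- vapply(st, function(s) {
      sum(strsplit(substr(seq, s, s + nchar(pattern) - 1L), "")[[1L]] !=
            strsplit(pattern, "")[[1L]])
    }, integer(1))
    data.frame(start = st, end = st + nchar(pattern) - 1L, mismatches = mm)
  }

  plus <- hits_for(primer)
  if (nrow(plus)) {
    plus$strand <- "+"
    plus$position <- plus$start
    if (anchor_3prime) {
      ok <- substr(seq, plus$end, plus$end) == substr(primer, lp, lp)
      plus <- plus[ok, , drop = FALSE]
    }
  }

  minus <- hits_for(revcomp(primer))
  if (nrow(minus)) {
    minus$strand <- "-"
    minus$position <- minus$end
    if (anchor_3prime) {
      # primer 3' base pairs with the template base at the footprint start
      ok <- substr(seq, minus$start, minus$start) ==
        revcomp(substr(primer, lp, lp))
      minus <- minus[ok, , drop = FALSE]
    }
  }

  cols <- c("position", "strand", "mismatches", "start", "end")
  empty <- data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0), start = integer(0),
                      end = integer(0))
  out <- rbind(if (nrow(plus)) plus[, cols] else empty,
               if (nrow(minus)) minus[, cols] else empty)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Predict PCR product sizes for a primer pair on a template
#'
#' Every convergent combination of a forward-primer site and a
#' reverse-primer site (in either orientation of the template) yields one
#' product; sizes include both primer footprints (outer-edge to
#' outer-edge), the convention under which gel-observed sizes are quoted.
#'
#' @param seq Template DNA string or [dna_records] row.
#' @param pair A `primer_pair` (see [primer_pair()]), or any list with
#'   elements `fwd` and `rev` (both 5'->3', `rev` on the reverse strand).
#' @param max_len Maximum product size considered (default 2000).
#' @param max_mismatch Mismatches allowed per primer (default 0).
#' @param anchor_3prime Require exact 3'-terminal match (dominant assay).
#' @return Sorted integer vector of product sizes (possibly empty;
#'   duplicates kept — a duplicated locus yields its product twice).
#' @export
predict_products <- function(seq, pair, max_len = 2000L, max_mismatch = 0L,
                             anchor_3prime = FALSE) {
  if (is.data.frame(seq)) seq <- seq$residues[1L]
  seq <- degap(toupper(seq))
  sf <- find_binding_sites(seq, pair$fwd, max_mismatch, anchor_3prime)
  sr <- find_binding_sites(seq, pair$rev, max_mismatch, anchor_3prime)

  span_products <- function(left, right) {
    # left binds the plus strand, right the minus strand, right of left
    sizes <- integer(0)
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        if (right$start[j] >= left$end[i] + 1L) {
          size <- right$end[j] - left$start[i] + 1L
          if (size <= max_len) sizes <- c(sizes, size)
        }
      }
    }
    sizes
  }

  sizes <- c(
    span_products(sf[sf$strand == "+", , drop = FALSE],
                  sr[sr$strand == "-", , drop = FALSE]),
    span_products(sr[sr$strand == "+", , drop = FALSE],
                  sf[sf$strand == "-", , drop = FALSE]))
  sort(as.integer(sizes))
}

match_size_class <- function(size, class_sizes) {
  # class_sizes: named character vector, values like "150", "233-236", "-"
  hit <- character(0)
  for (cl in names(class_sizes)) {
    v <- class_sizes[[cl]]
    if (v == "-" || is.na(v)) next
    if (grepl("-", v, fixed = TRUE)) {
      rng <- as.integer(strsplit(v, "-", fixed = TRUE)[[1L]])
      if (size >= rng[1L] && size <= rng[2L]) hit <- c(hit, cl)
    } else if (size == as.integer(v)) {
      hit <- c(hit, cl)
    }
  }
  hit
}

#' Genotype one sample against a marker panel
#'
#' Codominant markers are called from the multiset of predicted product
#' sizes: one expected size observed gives that allele class, both classes
#' observed gives `H`. Dominant markers call the product-bearing class on
#' a size match and the null class when no product forms. HRM markers are
#' modeled at the sequence level: the call derives from which allele
#' strings are present across the sample's sequences (or, when `reads`
#' are supplied, in the read pool at the marker's diagnostic sites via
#' the allele-depth machinery). Anything unexplained is `NULL` with the
#' evidence retained.
#'
#' @param sample A [dna_records] data frame of the sample's sequences
#'   (one or more; e.g. a plastome and an nrDNA record).
#' @param panel List of `marker_spec` objects (see [marker_design]) or a
#'   panel read by [read_markers()].
#' @param reads Optional [read_set] used for HRM heterozygosity calls.
#' @param min_depth,min_minor_frac Thresholds passed to the allele-depth
#'   caller for read-based HRM calls.
#' @param max_mismatch Mismatches tolerated in primer binding (default 0).
#' @return Data frame with columns `marker`, `call` (`A`/`B`/.../`H`/
#'   `NULL`), `evidence`.
#' @export
genotype_sample <- function(sample, panel, reads = NULL,
                            min_depth = 20L, min_minor_frac = 0.2,
                            max_mismatch = 0L) {
  if (!length(panel)) stop("marker panel is empty")
  rows <- lapply(panel, function(spec) {
    res <- genotype_marker(sample, spec, reads, min_depth, min_minor_frac,
                           max_mismatch)
    data.frame(marker = spec$name, call = res$call, evidence = res$evidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

genotype_marker <- function(sample, spec, reads = NULL,
                            min_depth = 20L, min_minor_frac = 0.2,
                            max_mismatch = 0L) {
  anchored <- identical(spec$marker_type, "DOMINANT_SNP")
  sizes <- sort(unlist(lapply(sample$residues, function(s) {
    predict_products(s, spec$primers, max_mismatch = max_mismatch,
                     anchor_3prime = anchored)
  })))
  ev <- if (length(sizes)) paste0("products=", paste(sizes, collapse = ","))
        else "products=none"

  if (identical(spec$marker_type, "HRM_SNP")) {
    return(genotype_hrm(sample, spec, sizes, reads, min_depth,
                        min_minor_frac, ev))
  }

  cs <- spec$class_sizes
  if (identical(spec$marker_type, "DOMINANT_SNP")) {
    null_class <- names(cs)[cs == "-" | is.na(cs)]
    if (!length(sizes)) {
      return(list(call = if (length(null_class)) null_class[1L] else "NULL",
                  evidence = ev))
    }
    hit <- unique(unlist(lapply(sizes, match_size_class, class_sizes = cs)))
    if (length(hit) == 1L) return(list(call = hit, evidence = ev))
    warning("marker ", spec$name, ": product size(s) match no class")
    return(list(call = "NULL", evidence = ev))
  }

  # codominant
  if (!length(sizes)) return(list(call = "NULL", evidence = ev))
  hit <- unique(unlist(lapply(sizes, match_size_class, class_sizes = cs)))
  unmatched <- sizes[vapply(sizes, function(s)
    length(match_size_class(s, cs)) == 0L, logical(1))]
  if (length(unmatched)) {
    warning("marker ", spec$name, ": unexplained product size(s) ",
            paste(unmatched, collapse = ","))
    if (!length(hit)) return(list(call = "NULL", evidence = ev))
  }
  if (length(hit) == 1L) return(list(call = hit, evidence = ev))
  if (length(hit) >= 2L) return(list(call = "H", evidence = ev))
  list(call = "NULL", evidence = ev)
}

genotype_hrm <- function(sample, spec, sizes, reads, min_depth,
                         min_minor_frac, ev) {
  # read-based route: both parental allele sets supported in the read pool
  if (!is.null(reads) && !is.null(spec$probes)) {
    depths <- count_allele_depths(reads, spec$probes)
    st <- call_state(depths, min_depth = min_depth,
                     min_minor_frac = min_minor_frac,
                     min_het_site_frac = 0.5)
    ev2 <- paste0(ev, ";reads_state=", st$state)
    if (st$state == "HET") return(list(call = "H", evidence = ev2))
    if (st$state == "HOM") {
      # probe labels are sample/group labels; map to the allele class
      # whose reference samples carry that label
      cl <- names(spec$class_samples)[vapply(spec$class_samples, function(s)
        st$label %in% s, logical(1))]
      if (!length(cl)) cl <- intersect(st$label, names(spec$class_alleles))
      if (length(cl)) return(list(call = cl[1L], evidence = ev2))
      return(list(call = st$label, evidence = ev2))
    }
    return(list(call = "NULL", evidence = ev2))
  }
  # sequence-based route: which class allele strings occur among the
  # sample's amplicons
  if (!length(sizes)) return(list(call = "NULL", evidence = ev))
  if (is.null(spec$hrm_offsets) || is.null(spec$class_alleles)) {
    warning("marker ", spec$name,
            ": HRM genotyping needs reads or in-spec site offsets")
    return(list(call = "NULL", evidence = ev))
  }
  observed <- unique(unlist(lapply(sample$residues, function(s) {
    amp <- extract_amplicons(s, spec$primers)
    vapply(amp, function(a) {
      if (any(spec$hrm_offsets > nchar(a))) return(NA_character_)
      paste0(substring(a, spec$hrm_offsets, spec$hrm_offsets), collapse = "")
    }, character(1))
  })))
  observed <- observed[!is.na(observed)]
  hit <- names(spec$class_alleles)[spec$class_alleles %in% observed]
  ev2 <- paste0(ev, ";alleles=", paste(observed, collapse = "/"))
  if (length(hit) == 1L && length(observed) == 1L) {
    return(list(call = hit, evidence = ev2))
  }
  if (length(hit) >= 2L) return(list(call = "H", evidence = ev2))
  list(call = "NULL", evidence = ev2)
}

#' Extract amplicon sequences (plus-strand orientation) for a primer pair
#' @param seq Template string or [dna_records] row.
#' @param pair Primer pair.
#' @param max_len Maximum product size.
#' @return Character vector of amplicon sequences.
#' @export
extract_amplicons <- function(seq, pair, max_len = 2000L) {
  if (is.data.frame(seq)) seq <- seq$residues[1L]
  seq <- degap(toupper(seq))
  sf <- find_binding_sites(seq, pair$fwd)
  sr <- find_binding_sites(seq, pair$rev)
  out <- character(0)
  fw <- sf[sf$strand == "+", , drop = FALSE]
  rv <- sr[sr$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    if (rv$start[j] >= fw$end[i] + 1L &&
        rv$end[j] - fw$start[i] + 1L <= max_len) {
      out <- c(out, substr(seq, fw$start[i], rv$end[j]))
    }
  }
  # opposite orientation: rev on plus strand, fwd on minus
  fw2 <- sr[sr$strand == "+", , drop = FALSE]
  rv2 <- sf[sf$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fw2))) for (j in seq_len(nrow(rv2))) {
    if (rv2$start[j] >= fw2$end[i] + 1L &&
        rv2$end[j] - fw2$start[i] + 1L <= max_len) {
      out <- c(out, revcomp(substr(seq, fw2$start[i], rv2$end[j])))
    }
  }
  out
}
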