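#' Primer design constraints
#'
#' Defaults follow common PCR assay practice: primers 18-27 nt, melting
#' temperature 57-63 degC by the GC-count approximation
#' `Tm = 64.9 + 41 * (GC_count - 16.4) / N`, GC content 35-65%, product
#' 100-300 bp, and at least 150 bp of flanking sequence on each side of
#' the target.
#'
#' @param primer_len Length range (min, max).
#' @param tm Melting-temperature range, degC.
#' @param gc GC-fraction range.
#' @param product Product-size range, bp.
#' @param flank Minimum flanking sequence per side, bp.
#' @param max_candidates Per-side cap on candidate windows carried into
#'   pairing (ranked by |Tm - 60|).
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len = c(18L, 27L), tm = c(57, 63),
                               gc = c(0.35, 0.65), product = c(100L, 300L),
                               flank = 150L, max_candidates = 250L) {
  structure(list(primer_len = primer_len, tm = tm, gc = gc,
                 product = product, flank = flank,
                 max_candidates = max_candidates),
            class = "primer_constraints")
}

#' Melting temperature (GC-count approximation)
#'
#' `Tm = 64.9 + 41 * (GC_count - 16.4) / N`; intended for N >= 14.
#'
#' @param x Primer sequence(s).
#' @return Tm in degC.
#' @export
primer_tm <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  64.9 + 41 * (gc - 16.4) / n
}

#' GC fraction of a sequence
#' @param x DNA string(s).
#' @return Fraction of G+C.
#' @export
gc_fraction <- function(x) {
  nchar(gsub("[^GCgc]", "", x)) / nchar(x)
}

#' A primer pair
#'
#' @param fwd,rev Primer sequences, 5'->3'; `rev` is given on the reverse
#'   strand.
#' @param fwd_start,rev_start 1-based positions of each primer's 5' end in
#'   the ungapped coordinate of the design template.
#' @return List of class `primer_pair` with Tm and GC annotations.
#' @export
primer_pair <- function(fwd, rev, fwd_start = NA_integer_,
                        rev_start = NA_integer_) {
  structure(list(fwd = toupper(fwd), rev = toupper(rev),
                 fwd_start = fwd_start, rev_start = rev_start,
                 tm_fwd = primer_tm(fwd), tm_rev = primer_tm(rev),
                 gc_fwd = gc_fraction(fwd), gc_rev = gc_fraction(rev)),
            class = "primer_pair")
}

#' A marker specification
#'
#' @param name Marker name.
#' @param compartment `"PLASTOME"` or `"NRDNA"`.
#' @param marker_type `"CODOMINANT_INDEL"`, `"DOMINANT_SNP"` or
#'   `"HRM_SNP"`.
#' @param primers A [primer_pair()].
#' @param class_sizes Named character vector: allele class -> expected
#'   product size in bp (`"-"` for no product; a `"lo-hi"` range is
#'   accepted).
#' @param class_samples Named list: allele class -> reference sample ids.
#' @param class_alleles For HRM markers, named character vector: class ->
#'   concatenated bases at the marker's diagnostic sites.
#' @param hrm_offsets For HRM markers, 1-based offsets of the diagnostic
#'   sites within the (plus-strand) amplicon.
#' @param target_region Free-text label of the targeted gene/region.
#' @param probes Optional [build_probes()] output for read-based calls.
#' @return List of class `marker_spec`.
#' @export
marker_spec <- function(name, compartment, marker_type, primers,
                        class_sizes, class_samples = list(),
                        class_alleles = NULL, hrm_offsets = NULL,
                        target_region = "", probes = NULL) {
  marker_type <- match.arg(marker_type,
                           c("CODOMINANT_INDEL", "DOMINANT_SNP", "HRM_SNP"))
  sized <- class_sizes[class_sizes != "-" & !is.na(class_sizes)]
  if (marker_type == "CODOMINANT_INDEL" &&
      length(unique(sized)) < 2L) {
    stop("codominant marker needs >= 2 distinct expected sizes")
  }
  if (marker_type == "DOMINANT_SNP" &&
      !(length(sized) == 1L && length(class_sizes) >= 2L)) {
    stop("dominant marker needs exactly one product-bearing class and one null class")
  }
  structure(list(name = name, compartment = compartment,
                 marker_type = marker_type, primers = primers,
                 class_sizes = class_sizes, class_samples = class_samples,
                 class_alleles = class_alleles, hrm_offsets = hrm_offsets,
                 target_region = target_region, probes = probes),
            class = "marker_spec")
}

#' Select InDel events suitable for codominant marker design
#'
#' Only events strictly longer than 10 bp (i.e. `length >= min_len` with
#' the default `min_len = 11`) are retained; short events do not resolve
#' on an agarose gel. When `groups` is given, only group-diagnostic
#' events are kept. Results are sorted by length, longest first.
#'
#' @param vt A `variant_table`.
#' @param min_len Minimum event length (default 11).
#' @param groups Optional named vector `sample -> group`; filters to
#'   diagnostic events.
#' @return Subset of `vt` (INDEL rows), sorted by decreasing length.
#' @export
select_indel_targets <- function(vt, min_len = 11L, groups = NULL) {
  if (!is.null(groups)) vt <- diagnostic_sites(vt, groups)
  out <- vt[vt$kind == "INDEL" & vt$length >= min_len, , drop = FALSE]
  out <- out[order(-out$length), , drop = FALSE]
  for (a in c("reference_id", "sample_ids", "groups")) {
    attr(out, a) <- attr(vt, a)
  }
  class(out) <- c("variant_table", "data.frame")
  out
}

# conserved alignment columns: identical unambiguous base in every record
conserved_columns <- function(M) {
  first <- M[1L, ]
  same <- colSums(M != matrix(first, nrow(M), ncol(M), byrow = TRUE)) == 0L
  same & first %in% c("A", "C", "G", "T")
}

# all sub-windows [start, start+len-1] fully conserved, as a data frame
conserved_windows <- function(cons, region, len_range) {
  cum <- cumsum(cons)
  out <- list()
  for (len in len_range[1L]:len_range[2L]) {
    starts <- region[region + len - 1L <= max(region)]
    if (!length(starts)) next
    ok <- (cum[starts + len - 1L] -
             ifelse(starts > 1L, cum[starts - 1L], 0L)) == len
    st <- starts[ok]
    if (length(st)) {
      out[[length(out) + 1L]] <- data.frame(start = st, end = st + len - 1L)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

window_seq <- function(chars, w) {
  vapply(seq_len(nrow(w)), function(i) {
    paste0(chars[w$start[i]:w$end[i]], collapse = "")
  }, character(1))
}

filter_primer_windows <- function(w, chars, cc) {
  if (!nrow(w)) return(cbind(w, seq = character(0), tm = numeric(0),
                             gc = numeric(0)))
  w$seq <- window_seq(chars, w)
  w$tm <- primer_tm(w$seq)
  w$gc <- gc_fraction(w$seq)
  w[w$tm >= cc$tm[1L] & w$tm <= cc$tm[2L] &
      w$gc >= cc$gc[1L] & w$gc <= cc$gc[2L], , drop = FALSE]
}

# distance from a column to the nearest non-conserved column (variant)
dist_to_variant <- function(col, noncons_cols) {
  if (!length(noncons_cols)) return(Inf)
  min(abs(noncons_cols - col))
}

#' Design a conserved primer pair around a target variant
#'
#' Both primers are placed in alignment windows conserved across every
#' record (so the pair amplifies all reference samples), spanning the
#' target. Candidate pairs must satisfy the length/Tm/GC/product
#' constraints for every sample; pairs whose 3'-terminal bases are G or C
#' are preferred when any exist. Ties are broken deterministically:
#' maximize the distance of the 3' ends from any inter-reference variant
#' column, then minimize |Tm - 60| summed over the pair, then take the
#' leftmost forward window. The chosen pair is verified by in-silico PCR
#' on every (ungapped) record: each must yield exactly one product;
#' otherwise the next-ranked pair is tried.
#'
#' @param aln An [aligned_set] of the reference sequences.
#' @param target A 1-row subset of a `variant_table` (the event to span).
#' @param template_id Record whose sequence lends the primer letters and
#'   coordinates (defaults to the first record).
#' @param constraints A [primer_constraints()] list.
#' @param equal_sizes Require the product size to be identical in every
#'   sample (used for HRM amplicons).
#' @param max_verify How many ranked pairs to verify before giving up.
#' @return A [primer_pair()] with an attribute `sample_sizes` (named
#'   integer vector of per-sample product sizes).
#' @export
design_primer_pair <- function(aln, target, template_id = aln$id[1L],
                               constraints = primer_constraints(),
                               equal_sizes = FALSE, max_verify = 50L) {
  cc <- constraints
  M <- aln_matrix(aln)
  nc <- ncol(M)
  cons <- conserved_columns(M)
  noncons <- which(!cons)
  chars <- M[template_id, ]
  ts <- target$aln_start[1L]
  te <- ts + target$length[1L] - 1L

  # per-sample cumulative ungapped coordinate
  cums <- apply(M != "-", 1L, cumsum)           # nc x ns
  tcum <- cums[, template_id]
  if (min(tcum[ts], na.rm = TRUE) - 1L < cc$flank ||
      tcum[nc] - tcum[te] < cc$flank) {
    stop("no primer site: target has less than ", cc$flank,
         " bp of flanking sequence")
  }

  reach <- cc$product[2L]
  left_region <- max(1L, ts - reach):(ts - 1L)
  right_region <- (te + 1L):min(nc, te + reach)

  fw <- filter_primer_windows(
    conserved_windows(cons, left_region, cc$primer_len), chars, cc)
  rw <- filter_primer_windows(
    conserved_windows(cons, right_region, cc$primer_len), chars, cc)
  if (!nrow(fw) || !nrow(rw)) {
    stop("no primer site: no conserved window satisfies the constraints")
  }
  fw <- fw[order(abs(fw$tm - 60)), , drop = FALSE]
  rw <- rw[order(abs(rw$tm - 60)), , drop = FALSE]
  fw <- utils::head(fw, cc$max_candidates)
  rw <- utils::head(rw, cc$max_candidates)

  pairs <- merge(cbind(fw, k = 1L), cbind(rw, k = 1L), by = "k",
                 suffixes = c(".f", ".r"))
  # product size per sample: ungapped bases from fwd start to rev end
  size_for <- function(s) {
    cums[pairs$end.r, s] - cums[pairs$start.f, s] + 1L
  }
  sizes <- vapply(aln$id, size_for, integer(nrow(pairs)))
  sizes <- matrix(sizes, nrow = nrow(pairs),
                  dimnames = list(NULL, aln$id))
  ok <- rowSums(sizes < cc$product[1L] | sizes > cc$product[2L]) == 0L
  if (equal_sizes) {
    ok <- ok & apply(sizes, 1L, function(x) length(unique(x)) == 1L)
  }
  pairs <- pairs[ok, , drop = FALSE]
  sizes <- sizes[ok, , drop = FALSE]
  if (!nrow(pairs)) {
    stop("no primer site: no candidate pair yields in-range products ",
         "for every sample")
  }

  gc3 <- chars[pairs$end.f] %in% c("G", "C") &
    chars[pairs$start.r] %in% c("G", "C")     # rev 3' sits at window start
  if (any(gc3)) {
    pairs <- pairs[gc3, , drop = FALSE]
    sizes <- sizes[gc3, , drop = FALSE]
  }

  d3 <- pmin(vapply(pairs$end.f, dist_to_variant, numeric(1),
                    noncons_cols = noncons),
             vapply(pairs$start.r, dist_to_variant, numeric(1),
                    noncons_cols = noncons))
  tmdev <- abs(pairs$tm.f - 60) + abs(pairs$tm.r - 60)
  ord <- order(-d3, tmdev, pairs$start.f)
  pairs <- pairs[ord, , drop = FALSE]
  sizes <- sizes[ord, , drop = FALSE]

  degapped <- degap(aln$residues)
  names(degapped) <- aln$id
  for (i in seq_len(min(nrow(pairs), max_verify))) {
    pp <- primer_pair(pairs$seq.f[i], revcomp(pairs$seq.r[i]),
                      fwd_start = tcum[pairs$start.f[i]],
                      rev_start = tcum[pairs$end.r[i]])
    pred <- lapply(degapped, predict_products, pair = pp)
    if (all(lengths(pred) == 1L) &&
        all(unlist(pred) == sizes[i, names(degapped)])) {
      attr(pp, "sample_sizes") <- sizes[i, , drop = TRUE]
      attr(pp, "aln_window") <- c(pairs$start.f[i], pairs$end.r[i])
      return(pp)
    }
  }
  stop("no primer site: no verified unique-product pair within ",
       max_verify, " candidates")
}

size_classes <- function(sample_sizes) {
  # assign allele-class letters in order of first appearance
  uniq <- unique(sample_sizes)
  cls <- LETTERS[match(sample_sizes, uniq)]
  names(cls) <- names(sample_sizes)
  cls
}

#' Design a codominant InDel marker
#'
#' @param aln Reference [aligned_set].
#' @param target A 1-row INDEL subset of a `variant_table`.
#' @param name Marker name.
#' @param template_id Design template record.
#' @param constraints A [primer_constraints()].
#' @param target_region Free-text region label.
#' @return A [marker_spec()] of type `CODOMINANT_INDEL` whose expected
#'   product sizes differ between allele classes by the event length.
#' @export
design_codominant_indel <- function(aln, target, name,
                                    template_id = aln$id[1L],
                                    constraints = primer_constraints(),
                                    target_region = "") {
  pp <- design_primer_pair(aln, target, template_id, constraints)
  sz <- attr(pp, "sample_sizes")
  cls <- size_classes(sz)
  class_sizes <- vapply(unique(cls), function(cl) {
    as.character(sz[cls == cl][1L])
  }, character(1))
  class_samples <- split(names(cls), cls)
  m <- marker_spec(name, unique(aln$compartment)[1L], "CODOMINANT_INDEL", pp,
                   class_sizes, class_samples, target_region = target_region)
  m$target_length <- target$length[1L]
  m$target_aln_start <- target$aln_start[1L]
  m
}

#' Design a dominant allele-specific SNP marker
#'
#' The forward primer's 3'-terminal base sits exactly on the SNP and
#' carries the allele of the amplifying class, so templates of the other
#' class give no product under 3'-anchored matching.
#'
#' @param aln Reference [aligned_set].
#' @param target A 1-row SNP subset of a `variant_table`.
#' @param allele Base of the amplifying class (e.g. `"A"`), or a sample
#'   id whose base defines it.
#' @param name Marker name.
#' @param constraints A [primer_constraints()].
#' @param target_region Free-text region label.
#' @return A [marker_spec()] of type `DOMINANT_SNP`: the amplifying class
#'   maps to its product size, the other class to `"-"` (no product).
#' @export
design_dominant_snp <- function(aln, target, allele, name,
                                constraints = primer_constraints(),
                                target_region = "") {
  cc <- constraints
  M <- aln_matrix(aln)
  nc <- ncol(M)
  ts <- target$aln_start[1L]
  if (target$kind[1L] != "SNP") stop("dominant markers target SNPs")
  col_bases <- M[, ts]
  if (allele %in% aln$id) allele <- col_bases[[allele]]
  if (!allele %in% col_bases) stop("no sample carries allele ", allele)
  in_class <- names(col_bases)[col_bases == allele]
  template_id <- in_class[1L]
  chars <- M[template_id, ]
  cons <- conserved_columns(M)
  noncons <- which(!cons)
  cums <- apply(M != "-", 1L, cumsum)
  tcum <- cums[, template_id]
  if (tcum[ts] - 1L < cc$flank || tcum[nc] - tcum[ts] < cc$flank) {
    stop("no primer site: target has less than ", cc$flank,
         " bp of flanking sequence")
  }

  # forward windows end exactly on the SNP column; all other columns of
  # the window must be conserved
  cum <- cumsum(cons)
  fw <- do.call(rbind, lapply(cc$primer_len[1L]:cc$primer_len[2L],
                              function(len) {
    st <- ts - len + 1L
    if (st < 1L) return(NULL)
    body_ok <- (cum[ts - 1L] - ifelse(st > 1L, cum[st - 1L], 0L)) == len - 1L
    if (!body_ok) return(NULL)
    data.frame(start = st, end = ts)
  }))
  if (is.null(fw) || !nrow(fw)) {
    stop("no primer site: flank left of the SNP is not conserved")
  }
  fw <- filter_primer_windows(fw, chars, cc)
  if (!nrow(fw)) stop("no primer site: no in-constraint allele-specific window")

  reach <- cc$product[2L]
  right_region <- (ts + 1L):min(nc, ts + reach)
  rw <- filter_primer_windows(
    conserved_windows(cons, right_region, cc$primer_len), chars, cc)
  if (!nrow(rw)) stop("no conserved reverse-primer site")

  pairs <- merge(cbind(fw, k = 1L), cbind(rw, k = 1L), by = "k",
                 suffixes = c(".f", ".r"))
  sizes <- vapply(aln$id, function(s) {
    cums[pairs$end.r, s] - cums[pairs$start.f, s] + 1L
  }, integer(nrow(pairs)))
  sizes <- matrix(sizes, nrow = nrow(pairs), dimnames = list(NULL, aln$id))
  ok <- rowSums(sizes < cc$product[1L] | sizes > cc$product[2L]) == 0L
  pairs <- pairs[ok, , drop = FALSE]
  sizes <- sizes[ok, , drop = FALSE]
  if (!nrow(pairs)) stop("no primer site: no in-range product")

  d3 <- vapply(pairs$start.r, dist_to_variant, numeric(1),
               noncons_cols = setdiff(noncons, ts))
  tmdev <- abs(pairs$tm.f - 60) + abs(pairs$tm.r - 60)
  ord <- order(-d3, tmdev, pairs$start.f)
  pairs <- pairs[ord, , drop = FALSE]
  sizes <- sizes[ord, , drop = FALSE]

  degapped <- degap(aln$residues)
  names(degapped) <- aln$id
  for (i in seq_len(nrow(pairs))) {
    pp <- primer_pair(pairs$seq.f[i], revcomp(pairs$seq.r[i]),
                      fwd_start = tcum[pairs$start.f[i]],
                      rev_start = tcum[pairs$end.r[i]])
    pred <- lapply(degapped, predict_products, pair = pp,
                   anchor_3prime = TRUE)
    hit <- lengths(pred)
    if (all(hit[in_class] == 1L) &&
        all(hit[setdiff(aln$id, in_class)] == 0L)) {
      size <- as.character(pred[[in_class[1L]]])
      class_sizes <- c(A = size, B = "-")
      class_samples <- list(A = in_class, B = setdiff(aln$id, in_class))
      return(marker_spec(name, unique(aln$compartment)[1L], "DOMINANT_SNP",
                         pp, class_sizes, class_samples,
                         target_region = target_region))
    }
  }
  stop("no primer site: no verified allele-specific pair")
}

#' Select HRM amplicon targets covering diagnostic SNPs
#'
#' Greedily clusters diagnostic SNPs into short amplicons (at most
#' `window` bp, 1-3 SNPs each) whose primer sites are conserved across
#' all samples and whose size is identical across allele classes, then
#' designs each amplicon's primer pair. SNPs for which no compliant
#' amplicon can be designed are reported in the `uncovered` attribute.
#'
#' @param aln Reference [aligned_set] (nrDNA).
#' @param vt_diag Diagnostic-SNP subset of a `variant_table` (e.g. from
#'   [diagnostic_sites()]).
#' @param window Maximum amplicon size in bp (default 120).
#' @param max_snps Maximum SNPs per amplicon (default 3).
#' @param constraints Base [primer_constraints()]; the product range is
#'   overridden per cluster.
#' @param name_prefix Marker-name prefix.
#' @return List of `HRM_SNP` [marker_spec()] objects with an `uncovered`
#'   attribute (aln_start of SNPs not covered by any design).
#' @export
select_hrm_targets <- function(aln, vt_diag, window = 120L, max_snps = 3L,
                               constraints = primer_constraints(),
                               name_prefix = "HRM") {
  snps <- vt_diag[vt_diag$kind == "SNP", , drop = FALSE]
  snps <- snps[order(snps$aln_start), , drop = FALSE]
  if (!nrow(snps)) return(structure(list(), uncovered = integer(0)))
  min_len <- constraints$primer_len[1L]
  span_max <- window - 2L * min_len - 4L

  clusters <- list()
  cur <- 1L
  for (i in seq_len(nrow(snps))[-1L]) {
    first <- clusters_start <- snps$aln_start[cur[1L]]
    if (snps$aln_start[i] - first <= span_max && length(cur) < max_snps) {
      cur <- c(cur, i)
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- i
    }
  }
  clusters[[length(clusters) + 1L]] <- cur

  M <- aln_matrix(aln)
  specs <- list()
  uncovered <- integer(0)
  for (ci in seq_along(clusters)) {
    idx <- clusters[[ci]]
    cols <- snps$aln_start[idx]
    pseudo <- data.frame(aln_start = min(cols),
                         length = max(cols) - min(cols) + 1L)
    cc <- constraints
    cc$product <- c(max(2L * min_len + pseudo$length + 2L, 40L), window)
    spec <- tryCatch({
      pp <- design_primer_pair(aln, pseudo, template_id = aln$id[1L],
                               constraints = cc, equal_sizes = TRUE)
      win <- attr(pp, "aln_window")
      tcum <- cumsum(M[aln$id[1L], ] != "-")
      offsets <- tcum[cols] - tcum[win[1L]] + 1L
      allele_str <- apply(M[, cols, drop = FALSE], 1L, paste0, collapse = "")
      uniq <- unique(allele_str)
      cls <- LETTERS[match(allele_str, uniq)]
      names(cls) <- aln$id
      class_alleles <- stats::setNames(uniq, LETTERS[seq_along(uniq)])
      class_samples <- split(names(cls), cls)
      size <- as.character(attr(pp, "sample_sizes")[1L])
      class_sizes <- stats::setNames(rep(size, length(uniq)),
                                     names(class_alleles))
      marker_spec(paste0(name_prefix, "_", length(specs) + 1L),
                  unique(aln$compartment)[1L], "HRM_SNP", pp,
                  class_sizes, class_samples, class_alleles,
                  hrm_offsets = as.integer(offsets))
    }, error = function(e) NULL)
    if (is.null(spec)) {
      uncovered <- c(uncovered, cols)
    } else {
      specs[[length(specs) + 1L]] <- spec
    }
  }
  structure(specs, uncovered = uncovered)
}

serialize_map <- function(x, collapse_vec = "|") {
  paste(vapply(names(x), function(n) {
    v <- x[[n]]
    paste0(n, "=", paste(v, collapse = collapse_vec))
  }, character(1)), collapse = ";")
}

parse_map <- function(s, split_vec = NULL) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- if (length(p) > 1L) p[[2L]] else ""
    if (!is.null(split_vec)) strsplit(v, split_vec, fixed = TRUE)[[1L]] else v
  })
  stats::setNames(out, vapply(kv, `[[`, character(1), 1L))
}

#' Write a marker panel as TSV
#'
#' Columns mirror a published marker table: name, compartment, target
#' region, marker type, allele-class product sizes, class membership,
#' class allele strings (HRM), and the two primer sequences.
#'
#' @param panel List of [marker_spec()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(panel, path) {
  df <- do.call(rbind, lapply(panel, function(m) {
    data.frame(
      name = m$name, compartment = m$compartment,
      target_region = m$target_region, marker_type = m$marker_type,
      class_sizes = serialize_map(as.list(m$class_sizes)),
      class_samples = serialize_map(m$class_samples),
      class_alleles = if (is.null(m$class_alleles)) "" else
        serialize_map(as.list(m$class_alleles)),
      hrm_offsets = if (is.null(m$hrm_offsets)) "" else
        paste(m$hrm_offsets, collapse = "|"),
      fwd = m$primers$fwd, rev = m$primers$rev,
      stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker panel TSV written by [write_markers()]
#'
#' Primer sequences from external panels are accepted as-is (no length
#' re-validation), so published assays whose primers fall outside the
#' designer's own constraints still load.
#'
#' @param path TSV path.
#' @return List of `marker_spec` objects.
#' @export
read_markers <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    cs <- unlist(parse_map(r$class_sizes))
    ca <- unlist(parse_map(r$class_alleles))
    if (!length(ca)) ca <- NULL
    offs <- if (nzchar(r$hrm_offsets)) {
      as.integer(strsplit(r$hrm_offsets, "|", fixed = TRUE)[[1L]])
    } else NULL
    marker_spec(r$name, r$compartment, r$marker_type,
                primer_pair(r$fwd, r$rev),
                class_sizes = cs,
                class_samples = parse_map(r$class_samples, "|"),
                class_alleles = ca, hrm_offsets = offs,
                target_region = r$target_region)
  })
}
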