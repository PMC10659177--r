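#' Species patterns over the seven plastome markers
#'
#' The three pure-species genotype patterns over markers AL_1..AL_7, as
#' established on the reference panel: AU is all-A; AM is B at every
#' codominant InDel marker except AL_4 and A at the dominant marker; AO
#' shares the AM backbone but flips AL_4, AL_6 and AL_7.
#'
#' @return Named list of character(7) patterns.
#' @export
plastome_patterns <- function() {
  list(
    AU = c("A", "A", "A", "A", "A", "A", "A"),
    AM = c("B", "B", "B", "A", "B", "B", "A"),
    AO = c("B", "B", "B", "B", "B", "A", "B"))
}

#' Assign the plastome (maternal-lineage) type from marker calls
#'
#' The seven plastome calls are compared with each pure-species pattern;
#' `NULL` calls are treated as missing. The type is assigned only when
#' the non-missing calls are consistent with exactly one pattern;
#' anything else is `ambiguous`, with the conflicting markers named.
#'
#' @param calls Character vector of 7 calls for AL_1..AL_7 (values `A`,
#'   `B`, `H`, `NULL`/`NA`), optionally named.
#' @return List: `type` (`"AU"`, `"AM"`, `"AO"` or `"ambiguous"`),
#'   `reason`.
#' @export
assign_plastome_type <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) != 7L) stop("expected 7 plastome marker calls")
  calls[calls == "NULL"] <- NA_character_
  n_null <- sum(is.na(calls))
  if (n_null > 2L) {
    return(list(type = "ambiguous", reason = "insufficient calls"))
  }
  pat <- plastome_patterns()
  ok <- vapply(pat, function(p) {
    all(is.na(calls) | calls == p)
  }, logical(1))
  if (sum(ok) == 1L) {
    return(list(type = names(pat)[ok], reason = "pattern match"))
  }
  if (sum(ok) > 1L) {
    return(list(type = "ambiguous",
                reason = paste("consistent with multiple types:",
                               paste(names(pat)[ok], collapse = ","))))
  }
  # name the markers conflicting with the closest pattern
  mism <- vapply(pat, function(p) sum(calls != p, na.rm = TRUE), integer(1))
  best <- names(pat)[which.min(mism)]
  bad <- which(!is.na(calls) & calls != pat[[best]])
  list(type = "ambiguous",
       reason = paste0("conflicts with ", best, " at AL_",
                       paste(bad, collapse = ",AL_")))
}

#' Derive the nrDNA state from HRM-style marker calls
#'
#' @param calls Character vector of calls for the nrDNA (HRM) markers
#'   AL_8..AL_10 (`A`, `B`, `H`, `NULL`/`NA`).
#' @return List: `state` (`"HOM"`, `"HET"`, `"NO_CALL"`), `label`
#'   (`"AU"` for the all-A pattern, `"AM/AO"` for all-B).
#' @export
nrdna_state_from_hrm <- function(calls) {
  calls <- as.character(calls)
  calls[calls == "NULL"] <- NA_character_
  obs <- calls[!is.na(calls)]
  if (!length(obs)) return(list(state = "NO_CALL", label = NA_character_))
  if (any(obs == "H")) return(list(state = "HET", label = NA_character_))
  if (all(obs == "A")) return(list(state = "HOM", label = "AU"))
  if (all(obs == "B")) return(list(state = "HOM", label = "AM/AO"))
  list(state = "NO_CALL", label = NA_character_)
}

hybrid_cross_strings <- function(maternal, paternal) {
  sprintf("maternal x paternal: %s x %s; paternal x maternal: %s x %s",
          maternal, paternal, paternal, maternal)
}

#' Classify one sample from plastome type and nrDNA state
#'
#' The plastome is maternally inherited, the 45S nrDNA biparentally, so:
#' a homozygous nrDNA matching the plastome lineage gives a pure species;
#' a heterozygous nrDNA gives a hybrid whose maternal parent is the
#' plastome type; a homozygous nrDNA conflicting with the plastome
#' lineage is cytonuclear-discordant; unresolved inputs are left
#' unclassified with the reason retained. Because the AM and AO nrDNA
#' sequences are identical, nrDNA cannot separate those two species —
#' that split is plastome-only, and the nrDNA contributor opposite AU is
#' reported as `"AM"` with an AM/AO caveat in the rationale.
#'
#' @param plastome_type Output of [assign_plastome_type()], or one of
#'   `"AU"`, `"AM"`, `"AO"`, `"ambiguous"`.
#' @param nrdna_state A `compartment_state` from [call_state()], a list
#'   from [nrdna_state_from_hrm()], or both in a list of two (when two
#'   routes disagree the sample is unclassified).
#' @return List of class `species_class`: `label` (`"AU"`, `"AM"`,
#'   `"AO"`, `"HYBRID"`, `"DISCORDANT"`, `"UNCLASSIFIED"`), `maternal`,
#'   `paternal`, `rationale`.
#' @export
classify_sample <- function(plastome_type, nrdna_state) {
  if (is.list(plastome_type)) plastome_type <- plastome_type$type

  states <- if (!is.null(nrdna_state$state)) list(nrdna_state) else nrdna_state
  st <- unique(vapply(states, function(s) s$state, character(1)))
  if (length(st) > 1L && all(c("HOM", "HET") %in% st)) {
    return(species_class("UNCLASSIFIED",
                         rationale = "read-based and HRM nrDNA states disagree"))
  }
  st <- setdiff(st, "NO_CALL")
  if (!length(st)) {
    return(species_class("UNCLASSIFIED", rationale = "no nrDNA call"))
  }
  state <- st[[1L]]
  label <- NA_character_
  for (s in states) if (identical(s$state, state)) label <- s$label

  if (identical(plastome_type, "ambiguous")) {
    return(species_class("UNCLASSIFIED",
                         rationale = "plastome type unresolved"))
  }

  if (state == "HET") {
    paternal <- if (plastome_type == "AU") "AM" else "AU"
    caveat <- if (paternal == "AM")
      " (AM/AO share identical nrDNA; AO not excluded as paternal)" else ""
    return(species_class(
      "HYBRID", maternal = plastome_type, paternal = paternal,
      rationale = paste0("plastome ", plastome_type,
                         " with heterozygous nrDNA; ",
                         hybrid_cross_strings(plastome_type, paternal),
                         caveat)))
  }

  # HOM: does the nrDNA label agree with the plastome lineage?
  concordant <- (plastome_type == "AU" && label == "AU") ||
    (plastome_type %in% c("AM", "AO") && label %in% c("AM/AO", "AM", "AO"))
  if (concordant) {
    return(species_class(plastome_type, maternal = plastome_type,
                         rationale = paste0("plastome and nrDNA concordant (",
                                            plastome_type, ")")))
  }
  species_class("DISCORDANT",
                rationale = paste0("plastome ", plastome_type,
                                   " but nrDNA fixed for ", label))
}

species_class <- function(label, maternal = NA_character_,
                          paternal = NA_character_, rationale = "") {
  structure(list(label = label, maternal = maternal, paternal = paternal,
                 rationale = rationale),
            class = "species_class")
}

#' Classify a genotyped panel of samples
#'
#' @param vectors Data frame with columns `sample_id`, `AL_1`..`AL_10`
#'   (marker calls) and optionally `stem_color` (carried through as
#'   annotation, never used for classification).
#' @return List with `classes` (one row per sample: `sample`, `class`,
#'   `maternal`, `paternal`, `rationale`) and `counts` (one row per
#'   distinct class).
#' @export
classify_panel <- function(vectors) {
  if (anyDuplicated(vectors$sample_id)) {
    stop("duplicate sample id: ",
         vectors$sample_id[duplicated(vectors$sample_id)][1L])
  }
  plast_cols <- paste0("AL_", 1:7)
  hrm_cols <- paste0("AL_", 8:10)
  rows <- lapply(seq_len(nrow(vectors)), function(i) {
    pt <- assign_plastome_type(unlist(vectors[i, plast_cols]))
    ns <- nrdna_state_from_hrm(unlist(vectors[i, hrm_cols]))
    sc <- classify_sample(pt, ns)
    cls <- if (sc$label == "HYBRID") {
      paste0("HYBRID(maternal=", sc$maternal, ")")
    } else sc$label
    data.frame(sample = vectors$sample_id[i], class = cls,
               maternal = sc$maternal, paternal = sc$paternal,
               stem_color = if ("stem_color" %in% names(vectors))
                 vectors$stem_color[i] else NA_character_,
               rationale = sc$rationale, stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, rows)
  rownames(classes) <- NULL
  tab <- table(classes$class)
  counts <- data.frame(class = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(classes = classes, counts = counts)
}

#' Expand a representative-genotype table into per-sample vectors
#'
#' Published genotype tables often print one row per representative
#' genotype plus the number of collections sharing it; this expands such
#' a table into one row per (synthetic, numbered) sample for
#' [classify_panel()].
#'
#' @param df Data frame with columns `accession`, `stem_color`,
#'   `AL_1`..`AL_10`, `n_collections`.
#' @return Data frame with `sample_id`, `stem_color`, `AL_1`..`AL_10`.
#' @export
expand_genotype_rows <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    n <- df$n_collections[i]
    out <- df[rep(i, n), c("stem_color", paste0("AL_", 1:10)), drop = FALSE]
    out$sample_id <- if (n > 1L) {
      paste0(df$accession[i], "_", seq_len(n))
    } else df$accession[i]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("sample_id", "stem_color", paste0("AL_", 1:10))]
}

#' Load the bundled reference genotype panel
#'
#' The representative genotypes of the published 49-collection panel
#' (one row per distinct genotype, with collection counts and stem
#' colour), shipped as a plain-text fixture.
#'
#' @return Data frame with columns `accession`, `stem_color`,
#'   `AL_1`..`AL_10`, `n_collections`.
#' @export
reference_genotype_panel <- function() {
  path <- system.file("extdata", "allium_genotypes.tsv",
                      package = "superbarcode")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character") |>
    transform(n_collections = as.integer(n_collections))
}

#' Load the bundled published marker panel
#'
#' The ten published assays (six codominant InDel markers, one dominant
#' SNP marker, three HRM markers) with their primer sequences and
#' expected allele-class product sizes, shipped as a plain-text fixture.
#'
#' @return List of `marker_spec` objects.
#' @export
reference_marker_panel <- function() {
  read_markers(system.file("extdata", "allium_markers.tsv",
                           package = "superbarcode"))
}

#' Write classification results as TSV
#' @param result Output of [classify_panel()].
#' @param classes_path,counts_path Output paths.
#' @return `classes_path`, invisibly.
#' @export
write_classes <- function(result, classes_path, counts_path = NULL) {
  utils::write.table(result$classes, classes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(counts_path)) {
    utils::write.table(result$counts, counts_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(classes_path)
}
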