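#' Construct a set of DNA sequence records
#'
#' The basic container used throughout the package: a data frame with one
#' row per sequence, carrying an identifier, a free-text description, the
#' residues (IUPAC DNA, uppercased; `-` allowed for aligned input) and the
#' genomic compartment the sequence belongs to.
#'
#' @param id Character vector of unique record identifiers.
#' @param residues Character vector of DNA strings (same length as `id`).
#' @param description Character vector of descriptions (recycled).
#' @param compartment One of `"PLASTOME"`, `"NRDNA"`, `"UNKNOWN"` (recycled).
#' @return A `dna_records` data frame.
#' @export
dna_records <- function(id, residues, description = "", compartment = "UNKNOWN") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length")
  }
  if (any(!nzchar(residues))) {
    stop("residues must be non-empty")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1L])
  }
  compartment <- match.arg(compartment, c("UNKNOWN", "PLASTOME", "NRDNA"),
                           several.ok = FALSE)
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    residues = residues,
    compartment = rep_len(compartment, length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dna_records", "data.frame")
  out
}

#' Read a FASTA file
#'
#' Plain and aligned FASTA are both accepted; gap characters (`-`) are
#' preserved so that MAFFT output can be read back directly. Residues are
#' uppercased on ingest.
#'
#' @param path Path to a FASTA file.
#' @param compartment Compartment tag to attach to every record.
#' @return A [dna_records] data frame.
#' @export
read_fasta <- function(path, compartment = "UNKNOWN") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate record id in ", path, ": ", id[duplicated(id)][1L])
  }
  dna_records(id, as.character(set), description, compartment)
}

#' Write records to FASTA
#'
#' @param records A [dna_records] data frame (gaps allowed).
#' @param path Output path.
#' @param width Line-wrap width (fixed default 70 for reproducible output).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a read set
#'
#' @param id,residues,quality Per-read fields; `quality` may be `NA` when
#'   reads carry no quality string.
#' @param source_sample Sample name the reads came from.
#' @return A `read_set` data frame.
#' @export
read_set <- function(id, residues, quality = NA_character_,
                     source_sample = "unknown") {
  residues <- toupper(as.character(residues))
  quality <- rep_len(as.character(quality), length(residues))
  bad <- !is.na(quality) & nchar(quality) != nchar(residues)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read: ", id[bad][1L])
  }
  out <- data.frame(id = as.character(id), residues = residues,
                    quality = quality, stringsAsFactors = FALSE)
  attr(out, "source_sample") <- source_sample
  class(out) <- c("read_set", "data.frame")
  out
}

#' Read a FASTQ file (4-line records, Sanger qualities)
#'
#' Malformed trailing records are dropped with a warning giving their
#' count; a read whose quality string length disagrees with its sequence
#' is an error naming the read.
#'
#' @param path Path to a FASTQ file.
#' @param source_sample Sample label; defaults to the file name.
#' @return A [read_set] data frame (possibly empty, with a warning).
#' @export
read_fastq <- function(path, source_sample = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_sample)) {
    source_sample <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path)
  n_full <- length(lines) %/% 4L
  n_left <- length(lines) %% 4L
  if (n_left > 0L) {
    warning(n_left, " trailing line(s) in ", path,
            " do not form a complete FASTQ record; dropped")
  }
  if (n_full == 0L) {
    warning("no complete FASTQ records in ", path)
    return(read_set(character(0), character(0), character(0), source_sample))
  }
  i <- seq_len(n_full)
  hd <- lines[4L * i - 3L]
  sq <- lines[4L * i - 2L]
  pl <- lines[4L * i - 1L]
  ql <- lines[4L * i]
  if (any(substr(hd, 1L, 1L) != "@") || any(substr(pl, 1L, 1L) != "+")) {
    bad <- which(substr(hd, 1L, 1L) != "@" | substr(pl, 1L, 1L) != "+")[1L]
    stop("malformed FASTQ record #", bad, " in ", path)
  }
  id <- sub("\\s.*$", "", substring(hd, 2L))
  mism <- nchar(sq) != nchar(ql)
  if (any(mism)) {
    stop("sequence/quality length mismatch for read: ", id[mism][1L])
  }
  read_set(id, sq, ql, source_sample)
}

#' Write a read set to FASTQ
#'
#' Reads without a quality string get a constant high-quality placeholder
#' (`I`, Q40).
#'
#' @param reads A [read_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  qual[is.na(qual)] <- vapply(nchar(reads$residues[is.na(qual)]),
                              function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$residues, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle records into a validated alignment
#'
#' @param records A [dna_records] data frame whose residues all have the
#'   same length (gaps as `-`).
#' @return An `aligned_set`: the records with an `n_columns` attribute.
#' @export
aligned_set <- function(records) {
  if (nrow(records) < 2L) stop("an alignment needs at least 2 records")
  w <- unique(nchar(records$residues))
  if (length(w) != 1L) {
    stop("aligned residue strings differ in length: ",
         paste(w, collapse = ", "))
  }
  attr(records, "n_columns") <- w
  class(records) <- unique(c("aligned_set", class(records)))
  records
}

#' @export
n_columns <- function(aln) attr(aln, "n_columns")

#' Alignment as a character matrix (rows = records, columns = positions)
#' @param aln An [aligned_set].
#' @return Character matrix with record ids as row names.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Map an alignment column to an ungapped sequence position
#'
#' Positions are 1-based in the ungapped coordinate of the record; an
#' alignment column at which the record carries a gap maps to `NA`.
#'
#' @param residues Aligned residue string (with `-` gaps).
#' @param column 1-based alignment column.
#' @return 1-based ungapped position, or `NA` if the record is gapped there.
#' @export
ungapped_position <- function(residues, column) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  if (any(column < 1L) || any(column > length(chars))) {
    stop("column out of range [1, ", length(chars), "]")
  }
  cum <- cumsum(chars != "-")
  out <- cum[column]
  out[chars[column] == "-"] <- NA_integer_
  as.integer(out)
}

#' Map an ungapped position back to its alignment column
#'
#' @param residues Aligned residue string.
#' @param position 1-based ungapped position.
#' @return 1-based alignment column holding that residue.
#' @export
ungapped_to_column <- function(residues, position) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  idx <- which(chars != "-")
  if (any(position < 1L) || any(position > length(idx))) {
    stop("position out of range [1, ", length(idx), "]")
  }
  idx[position]
}

#' Remove gaps from residue strings
#' @param residues Character vector of (possibly gapped) DNA strings.
#' @return The same strings with all `-` removed.
#' @export
degap <- function(residues) gsub("-", "", residues, fixed = TRUE)

#' Reverse-complement DNA strings
#' @param x Character vector of DNA strings.
#' @return Reverse complements as character strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
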