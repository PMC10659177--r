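#' Simulation configuration
#'
#' Defines the seeded study conditions the simulator emulates: three
#' species related as AU | (AM, AO), with per-branch plastome SNP counts
#' chosen so the pairwise totals mirror the real magnitudes (AU-AM about
#' 170 SNPs, AM-AO about 60, AU-AO about 180), an nrDNA contrast of 20
#' SNPs plus one 1-bp InDel between AU and the identical AM/AO pair, and
#' InDel sets including events longer than 10 bp on each branch so that
#' codominant markers are designable. The default "mini" plastome is
#' 20 kb, which keeps a full pipeline run fast; `full_scale = TRUE`
#' plants the same structure on a 154-kb plastome with 80/40/40
#' branch-InDel totals.
#'
#' @param seed Root seed; all per-stage streams derive from it.
#' @param full_scale Use the 154-kb plastome configuration.
#' @param plastome_len,nrdna_len Sequence lengths (bp).
#' @param snp_branch Named integer vector: plastome SNPs on the `AU`,
#'   `AM`, `AO` branches.
#' @param indel_lengths Named list of per-branch plastome InDel lengths.
#' @param nr_snps,nr_indel_len nrDNA SNP count and InDel length on the
#'   AU branch.
#' @param read_len,coverage,error_rate Read-simulation parameters.
#' @param mixture_fraction Maternal nrDNA proportion for hybrid samples.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, full_scale = FALSE,
                       plastome_len = if (full_scale) 154000L else 20000L,
                       nrdna_len = 5878L,
                       snp_branch = c(AU = 145L, AM = 25L, AO = 35L),
                       indel_lengths = NULL,
                       nr_snps = 20L, nr_indel_len = 1L,
                       read_len = 150L, coverage = 500,
                       error_rate = 0, mixture_fraction = 0.65) {
  if (is.null(indel_lengths)) {
    indel_lengths <- if (full_scale) {
      list(AU = c(15L, 15L, 17L, 12L, 11L, rep(c(1L, 2L, 3L, 5L, 8L), 11L)),
           AM = c(12L, rep(c(1L, 2L, 4L, 6L), 4L), 3L, 5L, 7L),
           AO = c(23L, rep(c(1L, 2L, 3L, 6L), 4L), 4L, 5L, 8L))
    } else {
      list(AU = c(15L, 15L, 17L, 12L, 11L, 4L, 2L, 7L, 1L, 3L, 6L, 2L),
           AM = c(12L, 2L, 5L, 1L),
           AO = c(23L, 3L, 1L, 8L, 2L))
    }
  }
  if (mixture_fraction <= 0 || mixture_fraction >= 1) {
    stop("mixture_fraction must be in (0, 1)")
  }
  cfg <- list(seed = as.integer(seed), full_scale = full_scale,
              plastome_len = plastome_len, nrdna_len = nrdna_len,
              snp_branch = snp_branch, indel_lengths = indel_lengths,
              nr_snps = nr_snps, nr_indel_len = nr_indel_len,
              read_len = read_len, coverage = coverage,
              error_rate = error_rate,
              mixture_fraction = mixture_fraction)
  # feasibility: events at their spacing must fit on the sequence
  need <- event_space_needed(cfg)
  if (need$plastome > plastome_len - 400L) {
    stop("infeasible config: planted plastome events need ", need$plastome,
         " bp but only ", plastome_len, " available")
  }
  if (need$nrdna > nrdna_len - 400L) {
    stop("infeasible config: planted nrDNA events need ", need$nrdna, " bp")
  }
  class(cfg) <- "sim_config"
  cfg
}

# spacing requirements: events longer than 10 bp get wide variant-free
# flanks so conserved primer sites always exist; small events get modest
# spacing so allele probes keep clean flanks
event_clearance <- function(kind, len) {
  ifelse(kind == "INDEL" & len > 10L, 450L, 40L)
}

event_space_needed <- function(cfg) {
  pl <- sum(event_clearance("SNP", 1L) * sum(cfg$snp_branch)) +
    sum(vapply(cfg$indel_lengths, function(x)
      sum(event_clearance("INDEL", x) + x), numeric(1)))
  nr <- (cfg$nr_snps + 1L) * 40L
  list(plastome = pl, nrdna = nr)
}

derive_seed <- function(root, stream) {
  as.integer((as.numeric(root) * 7919 + stream * 104729) %% 2147483629) + 1L
}

# uniform DNA with homopolymer runs capped at 4
random_dna <- function(n) {
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, n, replace = TRUE)
  repeat {
    r <- rle(x)
    if (all(r$lengths <= 4L)) break
    ends <- cumsum(r$lengths)
    bad <- unlist(lapply(which(r$lengths > 4L), function(i) {
      (ends[i] - r$lengths[i] + 5L):ends[i]
    }))
    x[bad] <- vapply(bad, function(j) sample(setdiff(bases, x[j - 1L]), 1L),
                     character(1))
  }
  x
}

# place events along [margin, L - margin] honouring per-event clearance
place_events <- function(events, L, margin = 200L) {
  n <- nrow(events)
  events <- events[sample.int(n), , drop = FALSE]
  clr <- event_clearance(events$kind, events$length)
  need <- pmax(clr, c(0L, clr[-n])) + events$length
  slack <- (L - 2L * margin) - sum(need)
  if (slack < 0L) stop("infeasible config: events do not fit")
  extra <- diff(c(0, sort(stats::runif(n, 0, slack))))
  ends <- margin + cumsum(need + extra)
  events$aln_start <- as.integer(round(ends - events$length + 1L))
  events
}

mutated_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
         character(1))
}

build_compartment <- function(L, events, species, compartment) {
  anc <- random_dna(L)
  rows <- lapply(species, function(s) anc)
  names(rows) <- species
  events$deletion <- FALSE
  for (i in seq_len(nrow(events))) {
    br <- events$branch[i]
    others <- setdiff(species, br)
    p <- events$aln_start[i]
    if (events$kind[i] == "SNP") {
      alt <- mutated_base(anc[p])
      rows[[br]][p] <- alt
    } else {
      span <- p:(p + events$length[i] - 1L)
      del_in_branch <- stats::runif(1) < 0.5
      events$deletion[i] <- del_in_branch
      if (del_in_branch) {
        rows[[br]][span] <- "-"
      } else {
        for (o in others) rows[[o]][span] <- "-"
      }
    }
  }
  recs <- dna_records(species,
                      vapply(rows, paste0, character(1), collapse = ""),
                      compartment = compartment)
  aligned_set(recs)
}

#' Simulate the reference species set with planted variants
#'
#' Draws an ancestor sequence per compartment (uniform ACGT,
#' homopolymers capped at 4), then derives the AU, AM and AO sequences
#' by planting exactly the configured per-branch SNP and InDel events;
#' AM and AO nrDNA are identical by construction. Events are spaced so
#' that marker-length InDels keep wide variant-free flanks.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_references`: `plastome` and `nrdna`
#'   [aligned_set]s (AU, AM, AO), and `truth` — a data frame of the
#'   planted events (`compartment`, `kind`, `aln_start`, `length`,
#'   `branch`).
#' @export
simulate_references <- function(cfg) {
  species <- c("AU", "AM", "AO")

  set.seed(derive_seed(cfg$seed, 1L))
  pl_events <- rbind(
    do.call(rbind, lapply(species, function(b) {
      n <- cfg$snp_branch[[b]]
      if (n == 0L) return(NULL)
      data.frame(kind = "SNP", length = 1L, branch = b,
                 stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
    })),
    do.call(rbind, lapply(species, function(b) {
      lens <- cfg$indel_lengths[[b]]
      if (!length(lens)) return(NULL)
      data.frame(kind = "INDEL", length = as.integer(lens), branch = b,
                 stringsAsFactors = FALSE)
    })))
  plastome <- NULL
  if (!is.null(pl_events) && nrow(pl_events)) {
    pl_events <- place_events(pl_events, cfg$plastome_len)
    plastome <- build_compartment(cfg$plastome_len, pl_events, species,
                                  "PLASTOME")
    pl_events$compartment <- "PLASTOME"
  } else {
    anc <- paste0(random_dna(cfg$plastome_len), collapse = "")
    plastome <- aligned_set(dna_records(species, rep(anc, 3L),
                                        compartment = "PLASTOME"))
    pl_events <- data.frame()
  }

  set.seed(derive_seed(cfg$seed, 2L))
  nr_kinds <- c(rep("SNP", cfg$nr_snps),
                if (cfg$nr_indel_len > 0L) "INDEL")
  nr_events <- data.frame(
    kind = nr_kinds,
    length = c(rep(1L, cfg$nr_snps),
               if (cfg$nr_indel_len > 0L) cfg$nr_indel_len),
    branch = rep("AU", length(nr_kinds)), stringsAsFactors = FALSE)
  nrdna <- NULL
  if (nrow(nr_events)) {
    nr_events <- place_events(nr_events, cfg$nrdna_len)
    nrdna <- build_compartment(cfg$nrdna_len, nr_events, species, "NRDNA")
    nr_events$compartment <- "NRDNA"
  } else {
    anc <- paste0(random_dna(cfg$nrdna_len), collapse = "")
    nrdna <- aligned_set(dna_records(species, rep(anc, 3L),
                                     compartment = "NRDNA"))
    nr_events <- data.frame()
  }

  truth <- rbind(
    if (nrow(pl_events)) pl_events[, c("compartment", "kind", "aln_start",
                                       "length", "branch")],
    if (nrow(nr_events)) nr_events[, c("compartment", "kind", "aln_start",
                                       "length", "branch")])
  if (!is.null(truth)) truth <- truth[order(truth$compartment,
                                            truth$aln_start), ]
  structure(list(plastome = plastome, nrdna = nrdna, truth = truth,
                 config = cfg),
            class = "sim_references")
}

#' Simulate one sample (plastome sequence + nrDNA read set)
#'
#' The plastome is copied from the maternal parent (maternal
#' inheritance); nrDNA reads are drawn from the maternal haplotype with
#' probability `f` and the paternal haplotype otherwise (biparental
#' inheritance), with uniform start positions, both strands
#' equiprobable, and per-base substitution errors at `error_rate`.
#'
#' @param refs A `sim_references` object.
#' @param class `"AU"`, `"AM"`, `"AO"` or `"HYBRID"`.
#' @param maternal,paternal Parent species; for pure samples both default
#'   to `class`.
#' @param f Maternal nrDNA fraction (hybrids; must be in (0,1)).
#' @param coverage,read_len,error_rate Override the config values.
#' @param sample_id Sample name.
#' @param seed Stream seed (derived from the config seed by default).
#' @return List of class `sim_sample`: `sample_id`, `class`, `maternal`,
#'   `paternal`, `f`, `plastome` ([dna_records]), `reads` ([read_set]).
#' @export
simulate_sample <- function(refs, class, maternal = class,
                            paternal = class,
                            f = refs$config$mixture_fraction,
                            coverage = refs$config$coverage,
                            read_len = refs$config$read_len,
                            error_rate = refs$config$error_rate,
                            sample_id = class, seed = NULL) {
  cfg <- refs$config
  if (class == "HYBRID") {
    if (f <= 0 || f >= 1) stop("mixture fraction must be in (0, 1)")
    if (maternal == paternal) stop("a hybrid needs two distinct parents")
  } else {
    maternal <- paternal <- class
    f <- 1
  }
  if (!is.null(seed)) set.seed(seed)

  plast_seq <- degap(refs$plastome$residues[refs$plastome$id == maternal])
  plastome <- dna_records(paste0(sample_id, "_plastome"), plast_seq,
                          description = paste("maternal", maternal),
                          compartment = "PLASTOME")

  hap_m <- degap(refs$nrdna$residues[refs$nrdna$id == maternal])
  hap_p <- degap(refs$nrdna$residues[refs$nrdna$id == paternal])
  n_reads <- max(1L, round(coverage * nchar(hap_m) / read_len))
  origin_m <- stats::runif(n_reads) < f
  starts <- ifelse(origin_m,
                   sample.int(nchar(hap_m) - read_len + 1L, n_reads,
                              replace = TRUE),
                   sample.int(nchar(hap_p) - read_len + 1L, n_reads,
                              replace = TRUE))
  reads <- substring(ifelse(origin_m, hap_m, hap_p), starts,
                     starts + read_len - 1L)
  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_len, error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(read_len, n_err[i])
      ch <- strsplit(reads[i], "")[[1L]]
      ch[pos] <- mutated_base(ch[pos])
      reads[i] <- paste0(ch, collapse = "")
    }
  }
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) reads[flip] <- revcomp(reads[flip])
  rs <- read_set(sprintf("%s_read%06d", sample_id, seq_len(n_reads)),
                 reads, strrep("I", read_len), source_sample = sample_id)
  structure(list(sample_id = sample_id, class = class, maternal = maternal,
                 paternal = if (class == "HYBRID") paternal else NA_character_,
                 f = if (class == "HYBRID") f else NA_real_,
                 plastome = plastome, reads = rs),
            class = "sim_sample")
}

#' Simulate a genotyping panel of samples with its truth table
#'
#' @param refs A `sim_references` object.
#' @param class_counts Named integer vector of sample counts per class;
#'   names from `AU`, `AM`, `AO`, `HYBRID_mAU` (maternal AU, paternal
#'   AM), `HYBRID_mAM` (maternal AM, paternal AU).
#' @param out_dir Optional directory; when given, per-sample FASTA/FASTQ,
#'   the reference FASTA/alignments, `truth_variants.tsv` and
#'   `truth_classes.csv` are written there.
#' @param f,coverage,read_len,error_rate Overrides of the config values.
#' @return List of `sim_sample` objects with a `truth` attribute (data
#'   frame: `sample_id`, `class`, `maternal`, `paternal`, `f`).
#' @export
simulate_panel <- function(refs, class_counts, out_dir = NULL,
                           f = refs$config$mixture_fraction,
                           coverage = refs$config$coverage,
                           read_len = refs$config$read_len,
                           error_rate = refs$config$error_rate) {
  spec <- list(
    AU = c("AU", "AU", "AU"), AM = c("AM", "AM", "AM"),
    AO = c("AO", "AO", "AO"),
    HYBRID_mAU = c("HYBRID", "AU", "AM"),
    HYBRID_mAM = c("HYBRID", "AM", "AU"))
  unknown <- setdiff(names(class_counts), names(spec))
  if (length(unknown)) stop("unknown class: ", unknown[1L])

  samples <- list()
  k <- 0L
  for (cl in names(class_counts)) {
    for (j in seq_len(class_counts[[cl]])) {
      k <- k + 1L
      sid <- sprintf("S%03d_%s", k, cl)
      samples[[sid]] <- simulate_sample(
        refs, class = spec[[cl]][1L], maternal = spec[[cl]][2L],
        paternal = spec[[cl]][3L], f = f, coverage = coverage,
        read_len = read_len, error_rate = error_rate, sample_id = sid,
        seed = derive_seed(refs$config$seed, 100L + k))
    }
  }
  truth <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, class = s$class,
               maternal = s$maternal, paternal = s$paternal, f = s$f,
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(sample_id = character(0), class = character(0),
                        maternal = character(0), paternal = character(0),
                        f = numeric(0))
  }
  rownames(truth) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(refs$plastome, file.path(out_dir, "refs_plastome_aln.fasta"))
    write_fasta(refs$nrdna, file.path(out_dir, "refs_nrdna_aln.fasta"))
    if (!is.null(refs$truth)) {
      utils::write.table(refs$truth, file.path(out_dir, "truth_variants.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (s in samples) {
      write_fasta(s$plastome,
                  file.path(out_dir, paste0(s$sample_id, "_plastome.fasta")))
      write_fastq(s$reads,
                  file.path(out_dir, paste0(s$sample_id, "_nrdna.fastq")))
    }
    utils::write.csv(truth, file.path(out_dir, "truth_classes.csv"),
                     row.names = FALSE)
  }
  attr(samples, "truth") <- truth
  samples
}
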