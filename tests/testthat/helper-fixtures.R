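# Shared fixtures built in code.

# aligned set from a named character vector
toy_aln <- function(seqs, compartment = "UNKNOWN") {
  aligned_set(dna_records(names(seqs), unname(seqs),
                          compartment = compartment))
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small reference simulation shared by several files (built once per run)
mini_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42)
      set.seed(4242)
      cache <<- simulate_references(cfg)
    }
    cache
  }
})

species_groups <- function(aln) stats::setNames(aln$id, aln$id)
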