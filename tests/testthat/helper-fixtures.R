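# Small in-code fixtures shared across the suite.

# brute-force oracle: classify one (f5, ref, alt, f3) combination by explicit
# reverse-complement case analysis, independent of the package's vectorized path
oracle_classify <- function(f5, ref, alt, f3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("C", "T")) {
    paste0(f5, "[", ref, ">", alt, "]", f3)
  } else {
    paste0(comp[[f3]], "[", comp[[ref]], ">", comp[[alt]], "]", comp[[f5]])
  }
}

# a tiny deterministic genome built by hand (no simulator involved)
tiny_genome <- function(seq = "ACATTGACGTAGCTAGCATGCCGTA") {
  stats::setNames(toupper(seq), "chr1")
}

# a small fast cohort configuration for tests
small_cohort_configs <- function(n_species = 4, genome_length = 2e4,
                                 callable_bases = 5e7, seed = 1,
                                 n_control = 3, n_treated = 3, ...) {
  cfgs <- default_cohort_configs(
    n_control = n_control, n_treated = n_treated,
    genome_length = genome_length, callable_bases = callable_bases,
    seed = seed, ...
  )
  cfgs[seq_len(n_species), ]
}

# random valid spectrum (counts over the 96 categories)
random_spectrum <- function(rate = 5) {
  tibble::tibble(
    category = factor(sbs_categories(), levels = sbs_categories()),
    count = stats::rpois(96, rate)
  )
}

# random strictly positive trinucleotide frequency table
random_trinuc_freq <- function() {
  f <- stats::runif(32, 0.2, 1)
  tibble::tibble(trinucleotide = pyrimidine_trinucleotides(), freq = f / sum(f))
}
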