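# Canonical 96-channel single-base-substitution conventions.
#
# Category order is fixed across the whole package: the six pyrimidine-strand
# substitutions C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the 16
# (5' flank, 3' flank) pairs with both flanks in alphabetical order (5' flank
# varying slowest). Trinucleotides are strand-collapsed to the
# pyrimidine-centered representative, ordered center C before T, flanks
# alphabetical.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' The 96 single-base-substitution categories
#'
#' Returns the canonical category labels, e.g. `"A[C>T]G"`, in the fixed
#' order used throughout the package: substitution type major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank, flanks
#' alphabetical.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_categories())
sbs_categories <- function() {
  subs <- unlist(lapply(PYRIMIDINES, function(ref) {
    paste0(ref, ">", setdiff(BASES, ref))
  }))
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(BASES, BASES, function(f5, f3) paste0(f5, "[", s, "]", f3))))
  }))
}

#' The 32 pyrimidine-centered trinucleotides
#'
#' Strand-collapsed trinucleotide labels in the fixed package order:
#' center C before center T, flanks alphabetical (5' slowest).
#'
#' @return Character vector of length 32.
#' @export
pyrimidine_trinucleotides <- function() {
  unlist(lapply(PYRIMIDINES, function(ctr) {
    as.vector(t(outer(BASES, BASES, function(f5, f3) paste0(f5, ctr, f3))))
  }))
}

#' Map each category to its pyrimidine-strand trinucleotide
#'
#' @param categories Character vector of category labels (default all 96).
#' @return Character vector of trinucleotides, one per category.
#' @export
category_trinucleotide <- function(categories = sbs_categories()) {
  paste0(
    substr(categories, 1, 1),
    substr(categories, 3, 3),
    substr(categories, 7, 7)
  )
}

# alt base encoded in a category label
category_alt <- function(categories) substr(categories, 5, 5)

#' Reverse complement of DNA strings
#'
#' Vectorized over strings of any (possibly differing) lengths. Only
#' A/C/G/T/N are handled; other letters error.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("TGA", "ACGT"))
revcomp <- function(x) {
  vapply(strsplit(toupper(x), "", fixed = TRUE), function(b) {
    cc <- .COMP[b]
    if (anyNA(cc)) stop("revcomp(): non-ACGTN letter in input", call. = FALSE)
    paste(rev(unname(cc)), collapse = "")
  }, character(1))
}

# fast reverse complement restricted to 3-mers over ACGT (internal hot path)
.revcomp3 <- function(s) {
  paste0(
    unname(.COMP[substr(s, 3, 3)]),
    unname(.COMP[substr(s, 2, 2)]),
    unname(.COMP[substr(s, 1, 1)])
  )
}

# complement of single bases, vectorized
.comp1 <- function(b) unname(.COMP[b])

# normalize any supported genome representation into a named character vector
# of chromosome sequences (uppercase)
as_genome_sequences <- function(genome) {
  if (is.list(genome) && !is.null(genome$sequence)) genome <- genome$sequence
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (methods::is(genome, "DNAString")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("unsupported genome representation; supply character or DNAStringSet",
         call. = FALSE)
  }
  out <- toupper(out)
  if (is.null(names(out))) {
    names(out) <- if (length(out) == 1L) "chr1" else paste0("chr", seq_along(out))
  }
  out
}
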