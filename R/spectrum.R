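# 96-context classification, genome trinucleotide frequencies, and the
# cross-species "humanization" rescaling of mutation counts.

#' Classify SNVs into the 96 trinucleotide-context categories
#'
#' Each single-nucleotide variant is assigned its pyrimidine-strand category:
#' when the reference base is a purine the substitution and its flanking
#' trinucleotide are reverse-complemented before lookup, so e.g. a G>A call in
#' a 5'-TGA-3' context becomes `"T[C>T]A"`.
#'
#' Records whose flanking window runs off the contig end or contains an
#' ambiguity code are skipped: their category is `NA` and they are counted in
#' the `skipped` attribute, with a warning. A reference base disagreeing with
#' the genome is a data-integrity error and aborts.
#'
#' @param snvs A data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases).
#' @param genome Genome sequence(s): a named character vector of chromosome
#'   sequences, a `Biostrings::DNAStringSet`, or the list returned by
#'   [simulate_genome()].
#' @return The input as a tibble with an added `category` column (factor with
#'   the 96 canonical levels; `NA` for skipped records) and attribute
#'   `skipped` (rows skipped for flank/ambiguity reasons).
#' @seealso [build_spectrum()], [sbs_categories()]
#' @export
classify_context <- function(snvs, genome) {
  seqs <- as_genome_sequences(genome)
  snvs <- tibble::as_tibble(snvs)
  n <- nrow(snvs)
  cats <- sbs_categories()
  if (n == 0L) {
    out <- dplyr::mutate(snvs, category = factor(character(0), levels = cats))
    attr(out, "skipped") <- 0L
    return(out)
  }
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snvs)))
  if (any(!snvs$chrom %in% names(seqs))) {
    stop("classify_context(): chromosome(s) absent from genome: ",
         paste(unique(setdiff(snvs$chrom, names(seqs))), collapse = ", "),
         call. = FALSE)
  }
  seqlen <- nchar(seqs)[snvs$chrom]
  in_range <- snvs$pos >= 2L & snvs$pos <= seqlen - 1L
  ctx <- rep(NA_character_, n)
  ctx[in_range] <- substr_vec(seqs, snvs$chrom[in_range], snvs$pos[in_range])

  # reference integrity check where a context could be extracted
  ok <- !is.na(ctx)
  center <- substr(ctx[ok], 2, 2)
  mism <- center != toupper(snvs$ref[ok])
  # positions whose *center* is ambiguous cannot be integrity-checked; they are
  # skipped below with the other ambiguity cases
  mism[!center %in% BASES] <- FALSE
  if (any(mism)) {
    bad <- which(ok)[mism][1]
    stop(sprintf(
      "classify_context(): REF mismatch with genome at %s:%d (genome %s, call %s)",
      snvs$chrom[bad], snvs$pos[bad],
      substr(ctx[ok][mism][1], 2, 2), snvs$ref[bad]), call. = FALSE)
  }

  valid <- ok & !is.na(ctx) & grepl("^[ACGT]{3}$", ctx)
  category <- rep(NA_character_, n)
  if (any(valid)) {
    ref <- toupper(snvs$ref[valid])
    alt <- toupper(snvs$alt[valid])
    if (any(ref == alt)) stop("classify_context(): ref == alt record", call. = FALSE)
    tri <- ctx[valid]
    pur <- ref %in% c("A", "G")
    tri[pur] <- .revcomp3(tri[pur])
    ref[pur] <- .comp1(ref[pur])
    alt[pur] <- .comp1(alt[pur])
    category[valid] <- paste0(
      substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3)
    )
  }
  n_skip <- sum(!valid)
  if (n_skip > 0) {
    warning(sprintf("classify_context(): %d record(s) skipped (flank off contig end or ambiguity code)",
                    n_skip), call. = FALSE)
  }
  out <- dplyr::mutate(snvs, category = factor(category, levels = cats))
  attr(out, "skipped") <- n_skip
  out
}

# extract the 3-base window around pos for each (chrom, pos)
substr_vec <- function(seqs, chrom, pos) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(seqs[[ch]], pos[i] - 1L, pos[i] + 1L)
  }
  out
}

#' Build a 96-context mutation spectrum
#'
#' Tallies classifiable SNVs into the 96 canonical categories. An empty input
#' yields the all-zero spectrum.
#'
#' @inheritParams classify_context
#' @param label Label for the spectrum (sample or group name).
#' @return A tibble with columns `category` (factor, 96 levels) and `count`,
#'   one row per category in canonical order; attributes `label`, `total`
#'   (classified records) and `skipped`.
#' @export
build_spectrum <- function(snvs, genome, label = "spectrum") {
  cl <- classify_context(snvs, genome)
  tab <- table(cl$category)
  out <- tibble::tibble(
    category = factor(sbs_categories(), levels = sbs_categories()),
    count = as.numeric(tab[sbs_categories()])
  )
  out$count[is.na(out$count)] <- 0
  attr(out, "label") <- label
  attr(out, "total") <- sum(out$count)
  attr(out, "skipped") <- attr(cl, "skipped")
  class(out) <- c("context_spectrum", class(out))
  out
}

#' Genome trinucleotide frequencies (strand-collapsed)
#'
#' Slides a width-3 window (step 1) over every chromosome, skips windows
#' containing ambiguity codes, reverse-complements purine-centered windows,
#' and returns relative frequencies of the 32 pyrimidine-centered
#' trinucleotides. Counting is delegated to
#' [Biostrings::trinucleotideFrequency()].
#'
#' @inheritParams classify_context
#' @param bed Optional mask: a data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open intervals); only windows fully inside the mask
#'   are counted.
#' @return A tibble with columns `trinucleotide` (32 canonical labels) and
#'   `freq`, summing to 1; attribute `n_windows` gives the number counted.
#' @export
trinucleotide_frequencies <- function(genome, bed = NULL) {
  seqs <- as_genome_sequences(genome)
  if (!is.null(bed)) {
    seqs <- mask_sequences(seqs, bed)
  }
  if (all(nchar(seqs) < 3)) {
    stop("trinucleotide_frequencies(): no sequence of length >= 3", call. = FALSE)
  }
  counts64 <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(seqs), step = 1
  ))
  if (sum(counts64) == 0) {
    stop("trinucleotide_frequencies(): no valid (ambiguity-free) window", call. = FALSE)
  }
  tri <- pyrimidine_trinucleotides()
  nm <- names(counts64)
  pyr_name <- ifelse(substr(nm, 2, 2) %in% PYRIMIDINES, nm, .revcomp3(nm))
  counts32 <- tapply(counts64, pyr_name, sum)[tri]
  counts32[is.na(counts32)] <- 0
  out <- tibble::tibble(trinucleotide = tri, freq = as.numeric(counts32) / sum(counts32))
  attr(out, "n_windows") <- sum(counts64)
  out
}

# cut masked sequences into the kept fragments so no window spans a mask edge
mask_sequences <- function(seqs, bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  frags <- character(0)
  for (i in seq_len(nrow(bed))) {
    ch <- bed$chrom[i]
    if (!ch %in% names(seqs)) next
    frags <- c(frags, substring(seqs[[ch]], bed$start[i] + 1L, bed$end[i]))
  }
  if (length(frags) == 0) stop("BED mask covers no sequence", call. = FALSE)
  names(frags) <- paste0("frag", seq_along(frags))
  frags
}

#' Rescale a spectrum to a target genome's trinucleotide composition
#'
#' The cross-species normalization: each category count is multiplied by the
#' ratio of the target to the source genome frequency of its pyrimidine-strand
#' trinucleotide, `count' = count * f_target(t) / f_species(t)`. With a human
#' target this "humanizes" the spectrum so spectra of species with different
#' genome composition become comparable. The three categories sharing a
#' trinucleotide share one ratio; counts may become non-integer. Totals are
#' not preserved unless `preserve_total = TRUE`, which rescales the result to
#' the original sum as a sensitivity option.
#'
#' @param spectrum A spectrum as returned by [build_spectrum()] (or any data
#'   frame with `category` and `count`).
#' @param f_species,f_target Trinucleotide frequency tables as returned by
#'   [trinucleotide_frequencies()] for the source and target genomes.
#' @param preserve_total If `TRUE`, rescale the output to the input total.
#' @return A tibble like `spectrum` with rescaled `count`.
#' @export
humanize_counts <- function(spectrum, f_species, f_target, preserve_total = FALSE) {
  spectrum <- tibble::as_tibble(spectrum)
  stopifnot(all(c("category", "count") %in% names(spectrum)))
  fs <- stats::setNames(f_species$freq, f_species$trinucleotide)
  ft <- stats::setNames(f_target$freq, f_target$trinucleotide)
  tri <- category_trinucleotide(as.character(spectrum$category))
  bad <- spectrum$count > 0 & (is.na(fs[tri]) | fs[tri] <= 0)
  if (any(bad)) {
    stop("humanize_counts(): zero source-genome frequency for trinucleotide(s) ",
         paste(unique(tri[bad]), collapse = ", "),
         " with non-zero counts", call. = FALSE)
  }
  ratio <- unname(ft[tri] / fs[tri])
  new_count <- spectrum$count * ratio
  new_count[spectrum$count == 0] <- 0  # 0 * possible NA ratio
  out <- dplyr::mutate(spectrum, count = new_count)
  if (preserve_total) {
    tot_in <- sum(spectrum$count)
    tot_out <- sum(out$count)
    if (tot_out > 0) out$count <- out$count * tot_in / tot_out
  }
  for (a in c("label", "total", "skipped")) attr(out, a) <- attr(spectrum, a)
  attr(out, "total") <- sum(out$count)
  out
}
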