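# File formats: FASTA (via Biostrings), a minimal deterministic VCF v4.2
# writer with a vcfR/TSV reader, and the TSV tables the pipeline exchanges.

#' Write a simulated cohort to disk
#'
#' Produces, under `dir`: `genomes/<species>.fa`, `calls/<sample>.vcf`
#' (somatic + germline calls, condition in the INFO field),
#' `germline/<species>_germline.tsv` (the generator's truth set),
#' `metadata.tsv`, and `callable.tsv`. Output is byte-identical for
#' identical cohorts.
#'
#' @param cohort A `mut_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mut_cohort"))
  for (d in file.path(dir, c("genomes", "calls", "germline"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (sp in names(cohort$genomes)) {
    seqs <- as_genome_sequences(cohort$genomes[[sp]])
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(seqs),
      file.path(dir, "genomes", paste0(sp, ".fa"))
    )
    g <- dplyr::filter(cohort$germline, .data$species == sp)
    readr::write_tsv(g, file.path(dir, "germline", paste0(sp, "_germline.tsv")))
  }
  for (sm in unique(cohort$calls$sample)) {
    cc <- dplyr::filter(cohort$calls, .data$sample == sm)
    write_calls_vcf(cc, file.path(dir, "calls", paste0(sm, ".vcf")))
  }
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(cohort$callable, file.path(dir, "callable.tsv"))
  invisible(dir)
}

#' Write calls as a minimal VCF v4.2
#'
#' Fixed columns plus INFO keys `SPECIES`, `SAMPLE`, `SAMPLE_CONDITION` and
#' (when known) `ORIGIN`, so a call file is self-describing.
#'
#' @param calls Call tibble (one sample or many).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  calls <- tibble::as_tibble(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutexcess",
    '##INFO=<ID=SPECIES,Number=1,Type=String,Description="Species label">',
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample label">',
    '##INFO=<ID=SAMPLE_CONDITION,Number=1,Type=String,Description="control or treated">',
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="somatic or germline (generator truth)">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- paste0(
    "SPECIES=", calls$species,
    ";SAMPLE=", calls$sample,
    ";SAMPLE_CONDITION=", calls$condition,
    if (!is.null(calls$origin)) paste0(";ORIGIN=", calls$origin) else ""
  )
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
                info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a call set from VCF or TSV
#'
#' VCF files (extension `.vcf`) are parsed with vcfR when available (falling
#' back to a plain-text read of the fixed columns); the 6+ column TSV dialect
#' (`species`, `sample`, `chrom`, `pos`, `ref`, `alt`, optional `condition`,
#' `origin`) is accepted everywhere VCF is.
#'
#' @param path Path to one `.vcf` or `.tsv` file, or a directory whose
#'   `calls/*.vcf` (or top-level `*.vcf`/`*.tsv`) files are all read.
#' @return Call tibble with columns `species`, `sample`, `condition`,
#'   `chrom`, `pos`, `ref`, `alt` and `origin` when recorded.
#' @export
read_calls <- function(path) {
  if (dir.exists(path)) {
    sub <- if (dir.exists(file.path(path, "calls"))) file.path(path, "calls") else path
    files <- list.files(sub, pattern = "\\.(vcf|tsv)$", full.names = TRUE)
    if (length(files) == 0) stop("no .vcf or .tsv call files under ", path, call. = FALSE)
    return(dplyr::bind_rows(lapply(sort(files), read_calls)))
  }
  if (grepl("\\.vcf$", path)) read_vcf_calls(path) else read_tsv_calls(path)
}

read_vcf_calls <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                                           stringsAsFactors = FALSE))
    if (nrow(fix) == 0) {
      fix <- tibble::tibble(CHROM = character(0), POS = character(0),
                            REF = character(0), ALT = character(0),
                            INFO = character(0))
    }
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0) {
      fix <- tibble::tibble(CHROM = character(0), POS = character(0),
                            REF = character(0), ALT = character(0),
                            INFO = character(0))
    } else {
      m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
      fix <- tibble::tibble(CHROM = m[, 1], POS = m[, 2], REF = m[, 4],
                            ALT = m[, 5], INFO = m[, 8])
    }
  }
  info_get <- function(key) {
    val <- stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    val
  }
  tibble::tibble(
    species = info_get("SPECIES"),
    sample = info_get("SAMPLE"),
    condition = info_get("SAMPLE_CONDITION"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    origin = info_get("ORIGIN")
  )
}

read_tsv_calls <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "sample", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x))) {
    stop("TSV call file ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read genomes from FASTA files
#'
#' @param paths Named character vector of FASTA paths (names = species), or a
#'   directory containing `genomes/<species>.fa` (or top-level `*.fa`).
#' @return Named list of genome sequence vectors (one per species).
#' @export
read_genomes <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    sub <- if (dir.exists(file.path(paths, "genomes"))) file.path(paths, "genomes") else paths
    files <- list.files(sub, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    paths <- stats::setNames(files, sub("\\.(fa|fasta)$", "", basename(files)))
  }
  lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  })
}

#' Read the species metadata table
#' @param path TSV with columns `species`, `mls_years`, `body_mass_g`, `lq`.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("species", "mls_years") %in% names(x)))
  x
}

#' Read a reference signature catalog
#'
#' COSMIC-style TSV: a `category` column (96 canonical labels, any order)
#' plus one numeric column per reference signature, each summing to 1.
#'
#' @param path TSV path.
#' @return 96 x R matrix (categories in canonical order, columns named).
#' @export
read_signature_catalog <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  M <- as_spectra_matrix(x)
  s <- colSums(M)
  if (any(abs(s - 1) > 1e-6)) {
    warning("catalog column(s) not summing to 1 were renormalized: ",
            paste(colnames(M)[abs(s - 1) > 1e-6], collapse = ", "), call. = FALSE)
    M <- sweep(M, 2, s, "/")
  }
  M
}

#' The bundled synthetic reference catalog
#'
#' The three [generator_signatures()] shipped as a catalog (entries
#' `ENU_synthetic`, `clock_flat_synthetic`, `cpg_clock_synthetic`), so
#' matching can be exercised without the external COSMIC/ENU files.
#'
#' @return 96 x 3 matrix.
#' @export
synthetic_reference_catalog <- function() {
  m <- generator_signatures()
  colnames(m) <- c("ENU_synthetic", "clock_flat_synthetic", "cpg_clock_synthetic")
  m
}

#' Write a spectra matrix as TSV
#' @param M Matrix or spectra layout accepted by [as_spectra_matrix()].
#' @param path Output TSV (96 rows, `category` column first).
#' @return `path`, invisibly.
#' @export
write_spectra_tsv <- function(M, path) {
  M <- as_spectra_matrix(M)
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(category = rownames(M)),
                                    tibble::as_tibble(M)), path)
  invisible(path)
}
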