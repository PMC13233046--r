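# Built-in generator signatures used by the synthetic-cohort simulator and as
# a bundled synthetic reference catalog for tests and examples.

#' Generator mutational signatures
#'
#' Three synthetic 96-channel signatures with the qualitative structure the
#' simulator needs:
#'
#' * `ENU_like` — an alkylating-mutagen signature: 0.75 of its mass spread
#'   uniformly over the 16 T>A categories (the A>T transversions seen on the
#'   purine strand), the remaining 0.25 uniform over the other 80 categories.
#' * `clock_flat` — a flat background, 1/96 everywhere, standing in for
#'   diffuse clock-like mutagenesis.
#' * `cpg_like` — a CpG-deamination signature: 0.6 spread over the four
#'   `N[C>T]G` categories, 0.4 uniform elsewhere, standing in for the
#'   CpG>T-rich clock-like process.
#'
#' These are synthetic constructs, not copies of any published catalog entry.
#'
#' @return A 96 x 3 numeric matrix; rows named by [sbs_categories()], columns
#'   `ENU_like`, `clock_flat`, `cpg_like`. Columns sum to 1.
#' @export
#' @examples
#' colSums(generator_signatures())
generator_signatures <- function() {
  cats <- sbs_categories()
  ta <- grepl("\\[T>A\\]", cats)
  enu <- ifelse(ta, 0.75 / 16, 0.25 / 80)
  clock <- rep(1 / 96, 96)
  cpg_cat <- grepl("\\[C>T\\]G$", cats)
  cpg <- ifelse(cpg_cat, 0.6 / 4, 0.4 / 92)
  m <- cbind(ENU_like = enu, clock_flat = clock, cpg_like = cpg)
  rownames(m) <- cats
  m
}
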