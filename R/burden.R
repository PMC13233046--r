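# Germline filtering, per-sample SNV frequencies, and per-species excess
# mutation (delta-SNV) estimation with bootstrap uncertainty.

#' Filter germline variants from a call set
#'
#' Two rules, both tallied:
#'
#' * rule `germline_set`: remove any call matching a provided germline
#'   variant table on (species, chrom, pos, ref, alt);
#' * rule `recurrence`: remove any call whose (chrom, pos, alt) recurs in at
#'   least `recurrence_threshold` distinct samples of the same species — the
#'   cross-sample panel-of-normals-style rule that catches germline leakage
#'   even without a matched germline set. True somatic calls essentially never
#'   recur at the identical position across independent cultures at the
#'   mutation rates involved.
#'
#' @param calls Call tibble with columns `species`, `sample`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param germline Optional germline variant table (`species`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param recurrence_threshold Minimum number of distinct samples sharing a
#'   call for the recurrence rule (default 2); `Inf` disables the rule.
#' @return The surviving calls as a tibble, with attribute `removal_tally`
#'   (tibble of rule / n_removed); retrieve it with [removal_tally()]. If no
#'   germline table is given and the call set holds a single sample, the
#'   recurrence rule cannot act and a warning is issued.
#' @export
germline_filter <- function(calls, germline = NULL, recurrence_threshold = 2) {
  calls <- tibble::as_tibble(calls)
  n0 <- nrow(calls)
  removed_a <- 0L
  if (!is.null(germline) && nrow(germline) > 0) {
    key_cols <- intersect(c("species", "chrom", "pos", "ref", "alt"), names(germline))
    hit <- vctrs::vec_in(calls[key_cols], tibble::as_tibble(germline)[key_cols])
    removed_a <- sum(hit)
    calls <- calls[!hit, ]
  } else if (is.null(germline) && dplyr::n_distinct(calls$sample) < 2) {
    warning("germline_filter(): no germline set and a single sample; ",
            "recurrence rule has no cohort context and is disabled", call. = FALSE)
    recurrence_threshold <- Inf
  }
  removed_b <- 0L
  if (is.finite(recurrence_threshold) && nrow(calls) > 0) {
    rec <- dplyr::summarise(
      dplyr::group_by(calls, .data$species, .data$chrom, .data$pos, .data$alt),
      n_samples = dplyr::n_distinct(.data$sample), .groups = "drop"
    )
    rec <- dplyr::filter(rec, .data$n_samples >= recurrence_threshold)
    hit <- vctrs::vec_in(calls[c("species", "chrom", "pos", "alt")],
                         rec[c("species", "chrom", "pos", "alt")])
    removed_b <- sum(hit)
    calls <- calls[!hit, ]
  }
  attr(calls, "removal_tally") <- tibble::tibble(
    rule = c("germline_set", "recurrence"),
    n_removed = c(removed_a, removed_b)
  )
  attr(calls, "n_input") <- n0
  calls
}

#' Removal tally of a filtered call set
#' @param x Result of [germline_filter()].
#' @return Tibble with columns `rule` and `n_removed`.
#' @export
removal_tally <- function(x) attr(x, "removal_tally")

#' SNV frequency per megabase
#'
#' @param n_snv Non-negative SNV count(s).
#' @param callable_bases Positive callable-base count(s).
#' @param scale Scale factor (default 1e6: per Mb).
#' @return `n_snv / callable_bases * scale`.
#' @export
#' @examples
#' snv_frequency(100, 5e7)  # 2 per Mb
snv_frequency <- function(n_snv, callable_bases, scale = 1e6) {
  if (any(callable_bases <= 0)) stop("callable_bases must be positive", call. = FALSE)
  if (any(n_snv < 0)) stop("n_snv must be non-negative", call. = FALSE)
  n_snv / callable_bases * scale
}

#' Per-sample mutation burdens
#'
#' Counts post-filter somatic calls per sample and converts to frequency per
#' Mb of callable sequence. Samples present in `callable` but absent from
#' `calls` get a zero burden.
#'
#' @param calls Filtered somatic call tibble (`species`, `sample`,
#'   `condition`, ...).
#' @param callable Tibble with `species`, `sample`, `condition`,
#'   `callable_bases` — one row per sample (the sample spine).
#' @param scale Passed to [snv_frequency()].
#' @return Tibble with one row per sample: `species`, `sample`, `condition`,
#'   `n_snv`, `callable_bases`, `freq_per_mb`.
#' @export
sample_burdens <- function(calls, callable, scale = 1e6) {
  counts <- dplyr::count(tibble::as_tibble(calls), .data$sample, name = "n_snv")
  out <- dplyr::left_join(tibble::as_tibble(callable), counts, by = "sample")
  out$n_snv[is.na(out$n_snv)] <- 0L
  dplyr::mutate(out, freq_per_mb = snv_frequency(.data$n_snv, .data$callable_bases, scale))
}

#' Excess mutation frequency per species (delta-SNV)
#'
#' For each species, the excess mutation frequency is the mean treated-sample
#' SNV frequency minus the mean control frequency, with a seeded percentile
#' bootstrap confidence interval (samples resampled within condition). A
#' paired mode averages per-pair differences instead (pairs matched by sample
#' index within species).
#'
#' @param burdens Per-sample burden tibble from [sample_burdens()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @param paired If `TRUE`, compute the mean of per-pair treated-minus-control
#'   differences (requires equal sample counts per condition).
#' @return A tibble of class `delta_result`, one row per species: `species`,
#'   `mean_control`, `mean_treated`, `delta_snv`, `ci_low`, `ci_high`,
#'   `n_control`, `n_treated`.
#' @export
delta_snv <- function(burdens, n_boot = 2000, conf_level = 0.95, seed = 1L,
                      paired = FALSE) {
  burdens <- tibble::as_tibble(burdens)
  alpha <- (1 - conf_level) / 2
  res <- withr::with_seed(seed, purrr::map_dfr(
    split(burdens, burdens$species), function(b) {
      fc <- b$freq_per_mb[b$condition == "control"]
      ft <- b$freq_per_mb[b$condition == "treated"]
      if (length(fc) == 0 || length(ft) == 0)
        stop("delta_snv(): species ", b$species[1],
             " lacks a ", if (length(fc) == 0) "control" else "treated",
             " sample", call. = FALSE)
      if (paired && length(fc) != length(ft))
        stop("delta_snv(paired = TRUE): unequal sample counts for species ",
             b$species[1], call. = FALSE)
      delta <- if (paired) mean(ft - fc) else mean(ft) - mean(fc)
      bt <- rowMeans(matrix(sample(ft, n_boot * length(ft), replace = TRUE), n_boot)) -
            rowMeans(matrix(sample(fc, n_boot * length(fc), replace = TRUE), n_boot))
      ci <- unname(stats::quantile(bt, c(alpha, 1 - alpha)))
      tibble::tibble(
        species = b$species[1],
        mean_control = mean(fc), mean_treated = mean(ft),
        delta_snv = delta,
        ci_low = min(ci[1], delta), ci_high = max(ci[2], delta),
        n_control = length(fc), n_treated = length(ft)
      )
    }))
  class(res) <- c("delta_result", class(res))
  res
}
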