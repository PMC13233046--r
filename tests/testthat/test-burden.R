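# Germline filtering, SNV frequencies, and excess-mutation estimation.

make_calls <- function(species, sample, chrom = "chr1", pos, ref = "A", alt = "T",
                       condition = "control") {
  tibble::tibble(species = species, sample = sample, condition = condition,
                 chrom = chrom, pos = pos, ref = ref, alt = alt)
}

test_that("germline_filter applies both rules and tallies removals", {
  calls <- dplyr::bind_rows(
    make_calls("sp", "s1", pos = c(10, 20, 30)),
    make_calls("sp", "s2", pos = c(10, 40))
  )
  germ <- tibble::tibble(species = "sp", chrom = "chr1", pos = 20, ref = "A", alt = "T")
  out <- germline_filter(calls, germline = germ)
  tally <- removal_tally(out)
  # pos 20 removed by the set rule; pos 10 (2 samples) by recurrence
  expect_equal(tally$n_removed[tally$rule == "germline_set"], 1L)
  expect_equal(tally$n_removed[tally$rule == "recurrence"], 2L)
  expect_setequal(out$pos, c(30, 40))
})

test_that("a unique somatic call is retained; single-sample input disables recurrence", {
  calls <- make_calls("sp", "s1", pos = 5, condition = "treated")
  expect_warning(out <- germline_filter(calls), "single sample")
  expect_equal(nrow(out), 1L)
})

test_that("planted germline shared by all samples is removed by recurrence alone", {
  withr::with_seed(17, {
    germ_pos <- sample.int(1e6, 50)
    somatic <- lapply(1:6, function(j) {
      make_calls("sp", paste0("s", j), pos = sample.int(1e6, 30) + 2e6,
                 condition = ifelse(j <= 3, "control", "treated"))
    })
    shared <- lapply(1:6, function(j) {
      make_calls("sp", paste0("s", j), pos = germ_pos,
                 condition = ifelse(j <= 3, "control", "treated"))
    })
    calls <- dplyr::bind_rows(c(somatic, shared))
    out <- germline_filter(calls)  # no side file at all
    tally <- removal_tally(out)
    expect_equal(tally$n_removed[tally$rule == "recurrence"], 50L * 6L)
    expect_equal(nrow(out), 6L * 30L)  # no somatic call removed
  })
})

test_that("the recurrence rule removes only truly recurrent calls from a simulated cohort", {
  cfgs <- small_cohort_configs(n_species = 3, genome_length = 1e6, seed = 42)
  co <- simulate_cohort(cfgs, seed = 42)
  filt <- germline_filter(co$calls, germline = NULL, recurrence_threshold = 2)
  removed <- dplyr::anti_join(co$calls, filt,
                              by = c("species", "sample", "chrom", "pos", "ref", "alt"))
  # every germline row is caught by recurrence even without the side file
  expect_equal(sum(filt$origin == "germline"), 0L)
  # ground truth: somatic calls genuinely recurring across samples
  som <- dplyr::filter(co$calls, origin == "somatic")
  rec <- dplyr::summarise(dplyr::group_by(som, species, chrom, pos, alt),
                          ns = dplyr::n_distinct(sample), .groups = "drop")
  truly_recurrent <- sum(rec$ns[rec$ns >= 2])
  # coincidental recurrence is essentially absent at these rates and genome size
  expect_lte(truly_recurrent, 2L)
  # the filter removes exactly the recurrent somatic calls, no others
  expect_equal(sum(removed$origin == "somatic"), truly_recurrent)
})

test_that("snv_frequency arithmetic and guards", {
  expect_equal(snv_frequency(100, 5e7), 2.0)
  expect_equal(snv_frequency(0, 123), 0.0)
  expect_equal(snv_frequency(37, 12345678), 37 / 12345678 * 1e6)
  expect_error(snv_frequency(5, 0), "positive")
  expect_error(snv_frequency(-1, 10), "non-negative")
})

test_that("sample_burdens gives zero rows for empty samples and recomputable freqs", {
  calls <- make_calls("sp", "s1", pos = c(1, 2), condition = "control")
  callable <- tibble::tibble(species = "sp", sample = c("s1", "s2"),
                             condition = c("control", "treated"),
                             callable_bases = c(1e6, 2e6))
  b <- sample_burdens(calls, callable)
  expect_equal(b$n_snv, c(2L, 0L))
  expect_equal(b$freq_per_mb, b$n_snv / b$callable_bases * 1e6)
})

test_that("delta_snv matches hand arithmetic and the null case", {
  b <- tibble::tibble(
    species = "sp",
    sample = paste0("s", 1:4),
    condition = c("control", "control", "treated", "treated"),
    n_snv = 0L, callable_bases = 1e6,
    freq_per_mb = c(1.0, 1.2, 1.8, 2.0)
  )
  d <- delta_snv(b, n_boot = 200, seed = 1)
  expect_equal(d$delta_snv, 0.8)
  expect_equal(d$mean_control, 1.1)
  expect_equal(d$mean_treated, 1.9)
  expect_true(d$ci_low <= d$delta_snv && d$delta_snv <= d$ci_high)

  bnull <- b
  bnull$freq_per_mb <- c(1.0, 1.2, 1.0, 1.2)
  dn <- delta_snv(bnull, n_boot = 500, seed = 2)
  expect_equal(dn$delta_snv, 0)
  expect_true(dn$ci_low <= 0 && dn$ci_high >= 0)
})

test_that("paired mode averages per-pair differences", {
  b <- tibble::tibble(
    species = "sp", sample = paste0("s", 1:4),
    condition = c("control", "control", "treated", "treated"),
    n_snv = 0L, callable_bases = 1e6,
    freq_per_mb = c(1.0, 2.0, 1.5, 3.0)
  )
  d <- delta_snv(b, n_boot = 50, seed = 1, paired = TRUE)
  expect_equal(d$delta_snv, mean(c(1.5 - 1.0, 3.0 - 2.0)))
})

test_that("a species missing a condition errors by name", {
  b <- tibble::tibble(species = "lonely", sample = "s1", condition = "control",
                      n_snv = 0L, callable_bases = 1e6, freq_per_mb = 1)
  expect_error(delta_snv(b, n_boot = 10), "lonely")
})

test_that("adding treated SNVs never decreases delta", {
  b <- tibble::tibble(
    species = "sp", sample = paste0("s", 1:4),
    condition = c("control", "control", "treated", "treated"),
    n_snv = c(10L, 12L, 18L, 20L), callable_bases = 1e6,
    freq_per_mb = c(10, 12, 18, 20)
  )
  d0 <- delta_snv(b, n_boot = 10, seed = 1)$delta_snv
  for (extra in c(1, 5, 20)) {
    b2 <- b
    b2$n_snv[3] <- b2$n_snv[3] + extra
    b2$freq_per_mb[3] <- b2$freq_per_mb[3] + extra
    expect_gte(delta_snv(b2, n_boot = 10, seed = 1)$delta_snv, d0)
  }
})

test_that("delta_snv recovers the configured rate difference on small cohorts", {
  cfgs <- small_cohort_configs(n_species = 2, genome_length = 2e4, seed = 3)
  true_delta <- cfgs$treated_rate_per_mb - cfgs$control_rate_per_mb
  est <- replicate(25, NULL, simplify = FALSE)
  for (r in 1:25) {
    cfgs$seed <- 5000L + 97L * r + seq_len(nrow(cfgs))
    co <- simulate_cohort(cfgs, seed = r)
    filt <- germline_filter(co$calls, germline = co$germline,
                            recurrence_threshold = Inf)
    est[[r]] <- delta_snv(sample_burdens(filt, co$callable), n_boot = 10,
                          seed = r)$delta_snv
  }
  est <- do.call(rbind, est)
  for (k in 1:2) {
    bias <- mean(est[, k]) - true_delta[k]
    se <- stats::sd(est[, k]) / sqrt(nrow(est))
    expect_lt(abs(bias), 3 * se)
  }
})
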