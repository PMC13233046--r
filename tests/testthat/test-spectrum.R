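# Context classification, spectra, trinucleotide frequencies, humanization.

test_that("classify_context handles pyrimidine and purine references", {
  g <- tiny_genome("AACAA")  # context around pos 3 is ACA
  snv <- tibble::tibble(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  expect_equal(as.character(classify_context(snv, g)$category), "A[C>T]A")

  g2 <- tiny_genome("ATGAA")  # context around pos 3 is TGA; revcomp TCA
  snv2 <- tibble::tibble(chrom = "chr1", pos = 3, ref = "G", alt = "A")
  expect_equal(as.character(classify_context(snv2, g2)$category), "T[C>T]A")
})

test_that("all 192 flank/ref/alt combinations map onto the 96 categories as the oracle dictates", {
  combos <- expand.grid(f5 = c("A", "C", "G", "T"), ref = c("A", "C", "G", "T"),
                        alt = c("A", "C", "G", "T"), f3 = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  expect_equal(nrow(combos), 192L)
  got <- vapply(seq_len(nrow(combos)), function(i) {
    g <- tiny_genome(paste0("A", combos$f5[i], combos$ref[i], combos$f3[i], "A"))
    snv <- tibble::tibble(chrom = "chr1", pos = 3,
                          ref = combos$ref[i], alt = combos$alt[i])
    as.character(classify_context(snv, g)$category)
  }, character(1))
  want <- vapply(seq_len(nrow(combos)), function(i) {
    oracle_classify(combos$f5[i], combos$ref[i], combos$alt[i], combos$f3[i])
  }, character(1))
  expect_identical(got, want)
  # each of the 96 categories is hit by exactly 2 combinations
  expect_true(all(table(got) == 2))
  expect_setequal(unique(got), sbs_categories())
})

test_that("classification is invariant under opposite-strand representation", {
  withr::with_seed(11, {
    for (i in 1:25) {
      f5 <- sample(c("A", "C", "G", "T"), 1)
      f3 <- sample(c("A", "C", "G", "T"), 1)
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      fwd <- classify_context(
        tibble::tibble(chrom = "chr1", pos = 3, ref = ref, alt = alt),
        tiny_genome(paste0("A", f5, ref, f3, "A")))
      rev <- classify_context(
        tibble::tibble(chrom = "chr1", pos = 3,
                       ref = revcomp(ref), alt = revcomp(alt)),
        tiny_genome(paste0("A", revcomp(f3), revcomp(ref), revcomp(f5), "A")))
      expect_identical(as.character(fwd$category), as.character(rev$category))
    }
  })
})

test_that("classify_context errors on REF mismatch and skips flank problems", {
  g <- tiny_genome("AACAA")
  expect_error(
    classify_context(tibble::tibble(chrom = "chr1", pos = 3, ref = "G", alt = "A"), g),
    "REF mismatch")
  # off-end and ambiguous-flank records are skipped with a warning, not dropped
  gn <- tiny_genome("ANCAA")
  snvs <- tibble::tibble(chrom = "chr1", pos = c(1, 3, 4),
                         ref = c("A", "C", "A"), alt = c("T", "T", "G"))
  expect_warning(out <- classify_context(snvs, gn), "skipped")
  expect_equal(attr(out, "skipped"), 2L)
  expect_equal(is.na(out$category), c(TRUE, TRUE, FALSE))
})

test_that("build_spectrum tallies correctly, including the empty case", {
  g <- tiny_genome("AACAA")
  empty <- build_spectrum(tibble::tibble(chrom = character(0), pos = integer(0),
                                         ref = character(0), alt = character(0)), g)
  expect_equal(sum(empty$count), 0)
  expect_equal(nrow(empty), 96)

  one <- build_spectrum(tibble::tibble(chrom = "chr1", pos = 3, ref = "C", alt = "T"), g)
  expect_equal(attr(one, "total"), 1)
  expect_equal(one$count[one$category == "A[C>T]A"], 1)
  expect_equal(sum(one$count), 1)
})

test_that("spectrum of a simulated sample equals the generator's category tally", {
  g <- simulate_genome(5000, 0.45, seed = 3)
  cfg <- species_config("sp", genome_length = 5000, treated_rate_per_mb = 2,
                        germline_density_per_mb = 0, seed = 9)
  s <- simulate_sample(g, cfg, "treated", 1)
  som <- s[s$origin == "somatic", ]
  spec <- build_spectrum(som, g)
  truth <- table(factor(som$true_category, levels = sbs_categories()))
  expect_equal(spec$count, as.numeric(truth))
})

test_that("trinucleotide_frequencies matches hand enumeration and strand symmetry", {
  f <- trinucleotide_frequencies(stats::setNames("ACAACA", "chr1"))
  got <- stats::setNames(f$freq, f$trinucleotide)
  expect_equal(unname(got["ACA"]), 0.5)
  expect_equal(unname(got["GTT"]), 0.25)  # AAC window
  expect_equal(unname(got["TTG"]), 0.25)  # CAA window
  expect_equal(sum(f$freq), 1, tolerance = 1e-12)

  withr::with_seed(4, {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    f1 <- trinucleotide_frequencies(stats::setNames(s, "chr1"))
    f2 <- trinucleotide_frequencies(stats::setNames(revcomp(s), "chr1"))
    expect_equal(f1$freq, f2$freq, tolerance = 1e-12)
  })
  expect_error(trinucleotide_frequencies(stats::setNames("AC", "chr1")), "length")
  expect_error(trinucleotide_frequencies(stats::setNames("ANNNA", "chr1")), "window")
})

test_that("trinucleotide_frequencies honors a BED mask", {
  # mask keeps only the first 6 bases: ACAACA
  s <- stats::setNames("ACAACAGGGGGGGG", "chr1")
  f <- trinucleotide_frequencies(s, bed = tibble::tibble(chrom = "chr1", start = 0, end = 6))
  got <- stats::setNames(f$freq, f$trinucleotide)
  expect_equal(unname(got["ACA"]), 0.5)
  expect_equal(unname(got["CCC"]), 0)
})

test_that("humanize_counts performs the ratio arithmetic and flags zero frequencies", {
  spec <- tibble::tibble(category = sbs_categories(), count = 0)
  spec$count[spec$category == "A[C>T]A"] <- 10
  f_s <- random_trinuc_freq(); f_t <- f_s
  f_s$freq[f_s$trinucleotide == "ACA"] <- 0.02
  f_t$freq[f_t$trinucleotide == "ACA"] <- 0.04
  out <- humanize_counts(spec, f_s, f_t)
  expect_equal(out$count[out$category == "A[C>T]A"], 20)

  f_bad <- f_s
  f_bad$freq[f_bad$trinucleotide == "ACA"] <- 0
  expect_error(humanize_counts(spec, f_bad, f_t), "ACA")
})

test_that("humanization is identity, involution and linear (randomized)", {
  withr::with_seed(21, {
    for (i in 1:50) {
      a <- random_spectrum(); b <- random_spectrum()
      fs <- random_trinuc_freq(); ft <- random_trinuc_freq()
      expect_equal(humanize_counts(a, fs, fs)$count, a$count, tolerance = 1e-12)
      back <- humanize_counts(humanize_counts(a, fs, ft), ft, fs)
      expect_equal(back$count, a$count, tolerance = 1e-9)
      ab <- a; ab$count <- a$count + b$count
      expect_equal(humanize_counts(ab, fs, ft)$count,
                   humanize_counts(a, fs, ft)$count + humanize_counts(b, fs, ft)$count,
                   tolerance = 1e-9)
      # independent element-wise oracle
      ratio <- stats::setNames(ft$freq / fs$freq, ft$trinucleotide)
      want <- a$count * unname(ratio[category_trinucleotide(as.character(a$category))])
      expect_equal(humanize_counts(a, fs, ft)$count, want, tolerance = 1e-12)
    }
  })
})

test_that("preserve_total rescales to the input sum", {
  withr::with_seed(5, {
    a <- random_spectrum()
    out <- humanize_counts(a, random_trinuc_freq(), random_trinuc_freq(),
                           preserve_total = TRUE)
    expect_equal(sum(out$count), sum(a$count), tolerance = 1e-9)
  })
})
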