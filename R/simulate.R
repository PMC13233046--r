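# Synthetic-cohort generator: species genomes, germline variants, and paired
# control / mutagen-treated somatic SNV call sets with the statistical
# structure the downstream analysis assumes. Everything is seeded and
# reproducible bit-for-bit.

#' Species configuration for the synthetic-cohort generator
#'
#' Builds a one-row configuration tibble describing one simulated species:
#' its toy genome, covariates used by the comparative stage, sample sizes,
#' per-condition mutation rates and signature mixtures, and the species-level
#' seed from which all of its randomness is derived.
#'
#' @param species_name Species label (must be unique within a cohort).
#' @param genome_length Length of the simulated chromosome in bp (>= 1000).
#' @param gc_bias Fraction in `[0, 1]`: expected G+C content of the genome.
#' @param mls_years Maximum lifespan in years.
#' @param body_mass_g Adult body mass in grams.
#' @param lq Longevity quotient; if `NA`, computed with [longevity_quotient()].
#' @param n_control,n_treated Numbers of control / treated samples.
#' @param callable_bases Interrogated bases per sample (denominator of the
#'   SNV frequency).
#' @param control_rate_per_mb,treated_rate_per_mb Somatic SNV rates per Mb of
#'   callable sequence in each condition.
#' @param signature_weights_control,signature_weights_treated Named
#'   non-negative weights over the columns of [generator_signatures()],
#'   each summing to 1.
#' @param germline_density_per_mb Density of simulated germline variants per
#'   Mb of genome (shared by all samples of the species).
#' @param seed Species-level integer seed.
#' @return A one-row tibble (class `sim_species_config` rows are plain rows;
#'   weight vectors are stored as list-columns).
#' @export
species_config <- function(species_name,
                           genome_length = 2e5,
                           gc_bias = 0.41,
                           mls_years = 10,
                           body_mass_g = 1000,
                           lq = NA_real_,
                           n_control = 3,
                           n_treated = 3,
                           callable_bases = 5e7,
                           control_rate_per_mb = 0.3,
                           treated_rate_per_mb = 0.65,
                           signature_weights_control = c(ENU_like = 0, clock_flat = 0.7, cpg_like = 0.3),
                           signature_weights_treated = c(ENU_like = 0.75, clock_flat = 0.175, cpg_like = 0.075),
                           germline_density_per_mb = 100,
                           seed = 1L) {
  if (is.na(lq)) lq <- longevity_quotient(mls_years, body_mass_g)
  cfg <- tibble::tibble(
    species_name = species_name,
    genome_length = as.integer(genome_length),
    gc_bias = gc_bias,
    mls_years = mls_years,
    body_mass_g = body_mass_g,
    lq = lq,
    n_control = as.integer(n_control),
    n_treated = as.integer(n_treated),
    callable_bases = callable_bases,
    control_rate_per_mb = control_rate_per_mb,
    treated_rate_per_mb = treated_rate_per_mb,
    signature_weights_control = list(signature_weights_control),
    signature_weights_treated = list(signature_weights_treated),
    germline_density_per_mb = germline_density_per_mb,
    seed = as.integer(seed)
  )
  validate_species_config(cfg)
  cfg
}

validate_species_config <- function(cfg) {
  for (i in seq_len(nrow(cfg))) {
    r <- cfg[i, ]
    if (r$genome_length < 1000) stop("genome_length must be >= 1000", call. = FALSE)
    if (r$gc_bias < 0 || r$gc_bias > 1) stop("gc_bias must lie in [0, 1]", call. = FALSE)
    if (r$mls_years <= 0 || r$body_mass_g <= 0 || r$lq <= 0)
      stop("mls_years, body_mass_g and lq must be positive", call. = FALSE)
    if (r$callable_bases <= 0) stop("callable_bases must be positive", call. = FALSE)
    if (r$control_rate_per_mb < 0 || r$treated_rate_per_mb < 0)
      stop("rates must be non-negative", call. = FALSE)
    for (w in list(r$signature_weights_control[[1]], r$signature_weights_treated[[1]])) {
      if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
        stop("signature weights must be non-negative and sum to 1", call. = FALSE)
      if (!all(names(w) %in% colnames(generator_signatures())))
        stop("unknown generator signature in weights: ",
             paste(setdiff(names(w), colnames(generator_signatures())), collapse = ", "),
             call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Default treated-rate effect model
#'
#' The simulated mutagen effect declines log-linearly with maximum lifespan:
#' the treated excess over the control baseline is 0.8 SNV/Mb at MLS = 3
#' years, falling to 0.35 SNV/Mb at MLS = 211 years, mirroring the
#' short-lived-species-hypermutability pattern the analysis is designed to
#' detect.
#'
#' @param mls_years Maximum lifespan(s) in years.
#' @param control_rate_per_mb Control baseline rate (default 0.3/Mb).
#' @param excess_range Excess at the endpoints of `mls_range`.
#' @param mls_range Lifespan endpoints anchoring the log-linear decline.
#' @return Treated rate(s) per Mb.
#' @export
default_effect_model <- function(mls_years,
                                 control_rate_per_mb = 0.3,
                                 excess_range = c(0.8, 0.35),
                                 mls_range = c(3, 211)) {
  s <- (log(mls_years) - log(mls_range[1])) / (log(mls_range[2]) - log(mls_range[1]))
  control_rate_per_mb + excess_range[1] + (excess_range[2] - excess_range[1]) * s
}

#' Default 10-species cohort configuration
#'
#' One row per species for a mammalian fibroblast panel spanning maximum
#' lifespans from 3 years (mouse, hamster, rat) through human (120 y) to the
#' bowhead whale (211 y), with literature-typical body masses. Treated rates
#' follow [default_effect_model()]; GC content varies across species so the
#' trinucleotide-composition rescaling has real work to do.
#'
#' @param n_control,n_treated Samples per condition per species.
#' @param genome_length Toy chromosome length per species (bp).
#' @param callable_bases Callable bases per sample.
#' @param effect_model Function mapping MLS (years) to the treated rate per
#'   Mb; `NULL` keeps [default_effect_model()].
#' @param control_rate_per_mb Control baseline rate per Mb.
#' @param seed Cohort seed; per-species seeds are derived as
#'   `seed + 101 * species_index`.
#' @return A configuration tibble with one row per species.
#' @export
default_cohort_configs <- function(n_control = 3, n_treated = 3,
                                   genome_length = 2e5,
                                   callable_bases = 5e7,
                                   effect_model = NULL,
                                   control_rate_per_mb = 0.3,
                                   seed = 1L) {
  if (is.null(effect_model)) {
    effect_model <- function(mls) default_effect_model(mls, control_rate_per_mb)
  }
  sp <- tibble::tribble(
    ~species_name, ~mls_years, ~body_mass_g, ~gc_bias,
    "mouse",         3,    2.0e1, 0.42,
    "hamster",       3,    1.0e2, 0.41,
    "rat",           3,    3.0e2, 0.42,
    "guinea_pig",   12,    1.0e3, 0.40,
    "chinchilla",   17,    5.0e2, 0.40,
    "cow",          20,    7.5e5, 0.42,
    "beaver",       23,    2.0e4, 0.41,
    "naked_mole_rat", 37,  3.5e1, 0.40,
    "human",       120,    7.0e4, 0.41,
    "bowhead_whale", 211,  1.0e8, 0.41
  )
  purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    species_config(
      species_name = sp$species_name[i],
      genome_length = genome_length,
      gc_bias = sp$gc_bias[i],
      mls_years = sp$mls_years[i],
      body_mass_g = sp$body_mass_g[i],
      n_control = n_control,
      n_treated = n_treated,
      callable_bases = callable_bases,
      control_rate_per_mb = control_rate_per_mb,
      treated_rate_per_mb = effect_model(sp$mls_years[i]),
      seed = seed + 101L * i
    )
  })
}

#' Simulate a species genome
#'
#' Draws an i.i.d. base sequence of the requested length with expected G+C
#' fraction `gc_bias` and computes its strand-collapsed trinucleotide
#' frequencies.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_bias Expected G+C fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @return A list with elements `sequence` (named character, one chromosome
#'   `chr1`) and `trinuc_freq` (see [trinucleotide_frequencies()]).
#' @export
simulate_genome <- function(length, gc_bias = 0.41, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1L || length < 1000)
    stop("simulate_genome(): length must be a single number >= 1000", call. = FALSE)
  if (gc_bias < 0 || gc_bias > 1) stop("gc_bias must lie in [0, 1]", call. = FALSE)
  prob <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  seqchr <- withr::with_seed(seed, paste(
    sample(BASES, length, replace = TRUE, prob = prob), collapse = ""
  ))
  sequence <- stats::setNames(seqchr, "chr1")
  list(sequence = sequence, trinuc_freq = trinucleotide_frequencies(sequence))
}

# Index of genome positions by pyrimidine-strand trinucleotide context.
# Returns a list mapping each of the 32 trinucleotides to the (1-based)
# positions on chr1 whose window matches it on either strand.
context_index <- function(sequence) {
  seqs <- as_genome_sequences(sequence)
  s <- seqs[[1]]
  L <- nchar(s)
  pos <- 2:(L - 1L)
  ctx <- substring(s, pos - 1L, pos + 1L)
  keep <- grepl("^[ACGT]{3}$", ctx)
  ctx <- ctx[keep]; pos <- pos[keep]
  pur <- substr(ctx, 2, 2) %in% c("A", "G")
  ctx[pur] <- .revcomp3(ctx[pur])
  split(pos, ctx)
}

#' Simulate one sample's SNV call set
#'
#' Emulates the call-level output of single-molecule mutation sequencing for
#' one culture: the somatic SNV count is Poisson with mean
#' `rate_per_mb * callable_bases / 1e6` (rate chosen by `condition`), each
#' somatic SNV's 96-category is drawn from the condition's signature mixture
#' and placed uniformly among genome positions whose trinucleotide context
#' matches the drawn category (collisions redrawn, so context-category
#' fidelity is exact). The species' germline variants — simulated once per
#' species from the species seed at `germline_density_per_mb` — are included
#' in every sample's call set, flagged in the `origin` column.
#'
#' Randomness derives deterministically from the species seed:
#' `seed + 1000 * sample_index + 500 * (condition == "treated")` for the
#' somatic draws and `seed + 77` for the shared germline set.
#'
#' @param genome A genome from [simulate_genome()] (or a named character
#'   sequence vector).
#' @param config One-row configuration from [species_config()].
#' @param condition `"control"` or `"treated"`.
#' @param sample_index Positive integer index of the sample within its
#'   condition.
#' @param .index Precomputed context index (internal, for cohort speed).
#' @return A tibble of calls with columns `species`, `sample`, `condition`,
#'   `chrom`, `pos`, `ref`, `alt`, `origin` (`"somatic"`/`"germline"`) and
#'   `true_category` (the generated category; `NA` for germline rows);
#'   attribute `callable_bases`.
#' @export
simulate_sample <- function(genome, config, condition = c("control", "treated"),
                            sample_index = 1L, .index = NULL) {
  condition <- match.arg(condition)
  validate_species_config(config)
  seqs <- as_genome_sequences(genome)
  s <- seqs[[1]]
  if (nchar(s) != config$genome_length)
    stop("genome length disagrees with config", call. = FALSE)
  if (is.null(.index)) .index <- context_index(seqs)

  rate <- if (condition == "treated") config$treated_rate_per_mb else config$control_rate_per_mb
  w <- if (condition == "treated") config$signature_weights_treated[[1]] else config$signature_weights_control[[1]]
  p96 <- as.vector(generator_signatures()[, names(w), drop = FALSE] %*% w)

  sample_seed <- config$seed + 1000L * as.integer(sample_index) +
    if (condition == "treated") 500L else 0L
  cats <- sbs_categories()

  somatic <- withr::with_seed(sample_seed, {
    n <- stats::rpois(1, rate * config$callable_bases / 1e6)
    drawn <- if (n > 0) sample(cats, n, replace = TRUE, prob = p96) else character(0)
    place_somatic(s, drawn, .index)
  })
  germline <- simulate_germline(s, config)

  sample_name <- paste(config$species_name, condition, sample_index, sep = "_")
  calls <- dplyr::bind_rows(
    dplyr::mutate(somatic, origin = "somatic"),
    dplyr::mutate(germline, origin = "germline", true_category = NA_character_)
  )
  calls <- dplyr::arrange(
    dplyr::mutate(calls,
                  species = config$species_name,
                  sample = sample_name,
                  condition = condition,
                  .before = 1),
    .data$pos)
  attr(calls, "callable_bases") <- config$callable_bases
  calls
}

# place drawn categories on the genome; exact context fidelity by sampling
# among matching positions without replacement per trinucleotide
place_somatic <- function(s, drawn, index) {
  if (length(drawn) == 0) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          true_category = character(0)))
  }
  tri <- category_trinucleotide(drawn)
  pos <- integer(length(drawn))
  for (t in unique(tri)) {
    i <- which(tri == t)
    pool <- index[[t]]
    if (is.null(pool) || length(pool) == 0) {
      stop(sprintf("no genome position matches context of category %s", drawn[i[1]]),
           call. = FALSE)
    }
    if (length(i) > length(pool)) {
      stop(sprintf("genome too small: %d draws for %d positions with context %s (category %s)",
                   length(i), length(pool), t, drawn[i[1]]), call. = FALSE)
    }
    pos[i] <- pool[sample.int(length(pool), length(i))]
  }
  ref <- substring(s, pos, pos)
  alt <- category_alt(drawn)
  pur <- ref %in% c("A", "G")
  alt[pur] <- .comp1(alt[pur])
  tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                 true_category = drawn)
}

# species-level germline set, shared by all samples (seed + 77)
simulate_germline <- function(s, config) {
  L <- nchar(s)
  withr::with_seed(config$seed + 77L, {
    n <- stats::rpois(1, config$germline_density_per_mb * L / 1e6)
    n <- min(n, L - 2L)
    if (n == 0) {
      return(tibble::tibble(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0)))
    }
    pos <- sort(sample.int(L - 2L, n) + 1L)
    ref <- substring(s, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
    tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = unname(alt))
  })
}

#' Simulate a full multi-species cohort
#'
#' Generates, for each configured species, a toy genome, a shared germline
#' variant set, and paired control/treated call sets, plus the species
#' metadata table used by the comparative stage. Fully reproducible from
#' `seed` (per-species seeds `seed + 101 * i` unless the configs carry their
#' own).
#'
#' @param configs Configuration tibble (rows from [species_config()]); default
#'   [default_cohort_configs()].
#' @param effect_model Optional function MLS -> treated rate per Mb,
#'   overriding `treated_rate_per_mb` in `configs`.
#' @param seed Cohort seed.
#' @param out_dir Optional directory: if given, the cohort is also written to
#'   disk via [write_cohort()].
#' @return An object of class `mut_cohort`: a list with `calls` (all samples,
#'   germline included and flagged), `germline` (per-species truth set),
#'   `callable` (sample table), `metadata`, `genomes` (named list of
#'   [simulate_genome()] results), `configs` and `seed`.
#' @export
simulate_cohort <- function(configs = NULL, effect_model = NULL, seed = 1L,
                            out_dir = NULL) {
  if (is.null(configs)) configs <- default_cohort_configs(seed = seed)
  if (anyDuplicated(configs$species_name))
    stop("duplicate species names in cohort configs", call. = FALSE)
  if (nrow(configs) < 2) stop("a cohort needs at least 2 species", call. = FALSE)
  if (!is.null(effect_model)) {
    configs$treated_rate_per_mb <- vapply(configs$mls_years, effect_model, numeric(1))
  }
  if (is.null(configs$seed) || anyNA(configs$seed)) {
    configs$seed <- seed + 101L * seq_len(nrow(configs))
  }
  validate_species_config(configs)

  genomes <- list()
  calls <- vector("list", nrow(configs))
  callable <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    g <- simulate_genome(cfg$genome_length, cfg$gc_bias, seed = cfg$seed)
    genomes[[cfg$species_name]] <- g
    idx <- context_index(g$sequence)
    per_sample <- list()
    for (cond in c("control", "treated")) {
      nn <- if (cond == "control") cfg$n_control else cfg$n_treated
      for (j in seq_len(nn)) {
        per_sample[[paste(cond, j)]] <-
          simulate_sample(g, cfg, cond, j, .index = idx)
      }
    }
    calls[[i]] <- dplyr::bind_rows(per_sample)
    callable[[i]] <- dplyr::distinct(
      dplyr::select(calls[[i]], "species", "sample", "condition")
    )
    # samples with zero calls still need a callable row
    all_samples <- c(paste(cfg$species_name, "control", seq_len(cfg$n_control), sep = "_"),
                     paste(cfg$species_name, "treated", seq_len(cfg$n_treated), sep = "_"))
    missing <- setdiff(all_samples, callable[[i]]$sample)
    if (length(missing) > 0) {
      callable[[i]] <- dplyr::bind_rows(callable[[i]], tibble::tibble(
        species = cfg$species_name, sample = missing,
        condition = ifelse(grepl("_treated_", missing), "treated", "control")
      ))
    }
    callable[[i]]$callable_bases <- cfg$callable_bases
  }
  calls <- dplyr::bind_rows(calls)
  germline <- dplyr::distinct(
    dplyr::select(dplyr::filter(calls, .data$origin == "germline"),
                  "species", "chrom", "pos", "ref", "alt")
  )
  cohort <- structure(list(
    calls = calls,
    germline = germline,
    callable = dplyr::bind_rows(callable),
    metadata = dplyr::select(configs, species = "species_name",
                             "mls_years", "body_mass_g", "lq"),
    genomes = genomes,
    configs = configs,
    seed = seed
  ), class = "mut_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.mut_cohort <- function(x, ...) {
  cat(sprintf("<mut_cohort> %d species, %d samples, %d calls (%d somatic, %d germline rows)\n",
              nrow(x$metadata), nrow(x$callable), nrow(x$calls),
              sum(x$calls$origin == "somatic"), sum(x$calls$origin == "germline")))
  invisible(x)
}
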