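# End-to-end orchestration: configuration, validation, the staged pipeline,
# and its on-disk report bundle.

PIPELINE_STAGES <- c("simulate", "filter", "burden", "regression",
                     "spectra", "signatures", "report")

#' Deterministic stage seed derivation
#'
#' Stage-specific seeds are derived from the single global seed as
#' `seed + 7919 * stage_index` (7919: a prime comfortably clearing the
#' within-stage seed offsets), so any stage can be re-run in isolation and
#' reproduce the full run exactly.
#'
#' @param seed Global integer seed.
#' @param stage One of `"simulate"`, `"filter"`, `"burden"`, `"regression"`,
#'   `"spectra"`, `"signatures"`, `"report"`.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  i <- match(match.arg(stage, PIPELINE_STAGES), PIPELINE_STAGES)
  as.integer(seed + 7919L * i)
}

#' Assemble a pipeline configuration
#'
#' With `input_dir = NULL` (default) the pipeline simulates its own cohort
#' ([simulate_cohort()] defaults); otherwise `input_dir` must hold the cohort
#' layout written by [write_cohort()] (FASTA genomes, VCF/TSV call sets,
#' `metadata.tsv`, `callable.tsv`, optional `germline/`).
#'
#' @param input_dir Optional cohort directory.
#' @param out_dir Output directory for the report bundle (`NULL`: nothing
#'   written).
#' @param seed Global seed fanned out per stage via [stage_seed()].
#' @param recurrence_threshold Cross-sample recurrence threshold of
#'   [germline_filter()].
#' @param use_germline_set Use the germline side file (rule a) when present.
#' @param n_boot Bootstrap replicates for [delta_snv()].
#' @param k,n_restarts NMF rank and restarts for [nmf_extract()].
#' @param scale Frequency scale factor (1e6: per Mb).
#' @param target_species Species whose genome composition spectra are
#'   rescaled to before signature extraction (default `"human"`).
#' @param humanize_burdens Also rescale counts entering the burden stage
#'   (default `FALSE`: burdens use raw counts, the rescaling is applied for
#'   cross-species signature analysis only).
#' @param loo_species Species excluded one at a time in the sensitivity
#'   analysis.
#' @param association_signature,association_condition,association_exclude
#'   Arguments of [signature_lifespan_association()].
#' @param catalog Reference catalog matrix or TSV path (default the bundled
#'   [synthetic_reference_catalog()]).
#' @param make_figures Emit PDF figures into `out_dir/figures`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL, seed = 1L,
                            recurrence_threshold = 2,
                            use_germline_set = TRUE,
                            n_boot = 2000, k = 3, n_restarts = 30,
                            scale = 1e6,
                            target_species = "human",
                            humanize_burdens = FALSE,
                            loo_species = c("human", "bowhead_whale", "rat"),
                            association_signature = "S3",
                            association_condition = "control",
                            association_exclude = "human",
                            catalog = NULL,
                            make_figures = TRUE) {
  structure(list(
    input_dir = input_dir, out_dir = out_dir, seed = as.integer(seed),
    recurrence_threshold = recurrence_threshold,
    use_germline_set = use_germline_set,
    n_boot = n_boot, k = k, n_restarts = n_restarts, scale = scale,
    target_species = target_species, humanize_burdens = humanize_burdens,
    loo_species = loo_species,
    association_signature = association_signature,
    association_condition = association_condition,
    association_exclude = association_exclude,
    catalog = catalog, make_figures = make_figures
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Validate pipeline inputs
#'
#' Checks, without running the pipeline: file existence and parseability,
#' species cross-referencing between call sets and metadata, callable-bases
#' positivity, and agreement of each call's REF with the genome FASTA.
#' Warnings and errors are distinguished; the function never throws on
#' findings.
#'
#' @param config A `pipeline_config`.
#' @return Tibble with columns `level` (`"error"`/`"warning"`), `stage`,
#'   `message` (zero rows when everything checks out).
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(level, stage, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      level = level, stage = stage, message = message)
  }
  if (is.null(config$input_dir)) {
    return(tibble::tibble(level = character(0), stage = character(0),
                          message = character(0)))
  }
  d <- config$input_dir
  if (!dir.exists(d)) {
    note("error", "input", paste0("input_dir does not exist: ", d))
    return(dplyr::bind_rows(issues))
  }
  calls <- tryCatch(read_calls(d), error = function(e) {
    note("error", "calls", conditionMessage(e)); NULL
  })
  genomes <- tryCatch(read_genomes(d), error = function(e) {
    note("error", "genomes", conditionMessage(e)); NULL
  })
  meta <- tryCatch(read_metadata(file.path(d, "metadata.tsv")), error = function(e) {
    note("error", "metadata", conditionMessage(e)); NULL
  })
  callable <- tryCatch(
    readr::read_tsv(file.path(d, "callable.tsv"), show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) { note("error", "callable", conditionMessage(e)); NULL })
  if (!is.null(calls) && !is.null(meta)) {
    orphans <- setdiff(unique(calls$species), meta$species)
    for (sp in orphans) {
      note("error", "metadata", paste0("species in calls but absent from metadata: ", sp))
    }
  }
  if (!is.null(callable)) {
    if (!"callable_bases" %in% names(callable)) {
      note("error", "callable", "callable.tsv lacks a callable_bases column")
    } else if (any(callable$callable_bases <= 0)) {
      note("error", "callable", "non-positive callable_bases")
    }
  }
  if (!is.null(calls) && !is.null(genomes)) {
    for (sp in intersect(unique(calls$species), names(genomes))) {
      cc <- calls[calls$species == sp, ]
      seqs <- as_genome_sequences(genomes[[sp]])
      known_chrom <- cc$chrom %in% names(seqs)
      for (ch in unique(cc$chrom[!known_chrom])) {
        note("error", "genomes", paste0(sp, ": chromosome ", ch, " absent from FASTA"))
      }
      cc <- cc[known_chrom, ]
      if (nrow(cc) > 0) {
        gref <- substr_vec(seqs, cc$chrom, cc$pos)
        bad <- substr(gref, 2, 2) != cc$ref & cc$pos >= 2
        for (i in which(bad)) {
          note("error", "integrity",
               sprintf("%s %s:%d REF %s disagrees with genome %s",
                       sp, cc$chrom[i], cc$pos[i], cc$ref[i], substr(gref[i], 2, 2)))
        }
      }
    }
    for (sp in setdiff(unique(calls$species), names(genomes))) {
      note("error", "genomes", paste0("no FASTA for species ", sp))
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(level = character(0), stage = character(0), message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input),
#' germline filtering, per-sample burdens and per-species excess mutation
#' frequencies, regressions against lifespan / body mass / longevity
#' quotient with leave-one-out sensitivity, per-group 96-context spectra,
#' composition rescaling to the target species, NMF signature extraction,
#' catalog matching, contribution fractions (with a paired comparison of the
#' top signature between conditions), and the signature-lifespan
#' association. When `config$out_dir` is set, tables, figures, a
#' machine-readable manifest and a human-readable summary are written there;
#' a failing stage leaves a `FAILED` marker naming the stage.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return Invisibly, a `pipeline_result` list with elements `cohort`,
#'   `filtered`, `tally`, `burdens`, `delta`, `regressions`, `spectra`
#'   (humanized 96 x G matrix), `spectra_raw`, `trinuc_freqs`, `signatures`,
#'   `matches`, `fractions`, `s1_paired_test`, `association`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  current_stage <- "simulate"
  fail <- function(e) {
    if (!is.null(out)) {
      writeLines(paste0("stage: ", current_stage, "\n", conditionMessage(e)),
                 file.path(out, "FAILED"))
    }
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  res <- withCallingHandlers(tryCatch({
    # -- acquire cohort -----------------------------------------------------
    if (is.null(config$input_dir)) {
      cohort <- simulate_cohort(seed = stage_seed(config$seed, "simulate"))
      checksums <- tibble::tibble(file = character(0), md5 = character(0))
    } else {
      issues <- validate_inputs(config)
      if (any(issues$level == "error")) {
        stop("input validation failed:\n",
             paste(" -", issues$message[issues$level == "error"], collapse = "\n"))
      }
      calls <- read_calls(config$input_dir)
      gdir <- file.path(config$input_dir, "germline")
      germ <- if (dir.exists(gdir)) {
        dplyr::bind_rows(lapply(list.files(gdir, full.names = TRUE), function(p) {
          g <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
          if (!"species" %in% names(g)) {
            g$species <- sub("_germline\\.tsv$", "", basename(p))
          }
          g
        }))
      } else NULL
      cohort <- structure(list(
        calls = calls,
        germline = germ,
        callable = readr::read_tsv(file.path(config$input_dir, "callable.tsv"),
                                   show_col_types = FALSE, progress = FALSE),
        metadata = read_metadata(file.path(config$input_dir, "metadata.tsv")),
        genomes = read_genomes(config$input_dir),
        configs = NULL, seed = config$seed
      ), class = "mut_cohort")
      files <- list.files(config$input_dir, recursive = TRUE, full.names = TRUE)
      checksums <- tibble::tibble(
        file = list.files(config$input_dir, recursive = TRUE),
        md5 = unname(tools::md5sum(files))
      )
    }

    # -- germline filter ----------------------------------------------------
    current_stage <- "filter"
    germ_set <- if (isTRUE(config$use_germline_set)) cohort$germline else NULL
    filtered <- germline_filter(cohort$calls, germline = germ_set,
                                recurrence_threshold = config$recurrence_threshold)
    tally <- removal_tally(filtered)

    # -- burdens and excess mutations ---------------------------------------
    current_stage <- "burden"
    burdens <- sample_burdens(filtered, cohort$callable, scale = config$scale)
    delta <- delta_snv(burdens, n_boot = config$n_boot,
                       seed = stage_seed(config$seed, "burden"))

    # -- regressions --------------------------------------------------------
    current_stage <- "regression"
    points <- excess_points(burdens, cohort$metadata)
    regressions <- dplyr::bind_rows(
      leave_one_out(points, mls_years, excess_per_mb,
                    exclusions = as.list(intersect(config$loo_species,
                                                   points$species)),
                    covariate = "mls"),
      fit_regression(points, body_mass_g, excess_per_mb, covariate = "body_mass"),
      fit_regression(points, lq, excess_per_mb, covariate = "lq")
    )

    # -- spectra + composition rescaling ------------------------------------
    current_stage <- "spectra"
    somatic <- filtered
    trinuc_freqs <- lapply(cohort$genomes, trinucleotide_frequencies)
    if (!config$target_species %in% names(trinuc_freqs)) {
      stop("target_species '", config$target_species, "' has no genome")
    }
    f_target <- trinuc_freqs[[config$target_species]]
    groups <- dplyr::distinct(somatic[, c("species", "condition")])
    groups <- groups[order(groups$species, groups$condition), ]
    spec_list <- purrr::map2(groups$species, groups$condition, function(sp, cond) {
      g <- somatic[somatic$species == sp & somatic$condition == cond, ]
      build_spectrum(g, cohort$genomes[[sp]], label = paste(sp, cond, sep = "."))
    })
    names(spec_list) <- paste(groups$species, groups$condition, sep = ".")
    raw_M <- do.call(cbind, lapply(spec_list, function(s) s$count))
    rownames(raw_M) <- sbs_categories()
    hum_list <- purrr::imap(spec_list, function(s, nm) {
      sp <- sub("\\.(control|treated)$", "", nm)
      humanize_counts(s, trinuc_freqs[[sp]], f_target)
    })
    M <- do.call(cbind, lapply(hum_list, function(s) s$count))
    rownames(M) <- sbs_categories()
    if (isTRUE(config$humanize_burdens)) {
      # sensitivity mode: recompute burdens/delta from rescaled totals
      hum_tot <- vapply(names(spec_list), function(nm) sum(hum_list[[nm]]$count),
                        numeric(1))
      # note: per-sample rescaled burdens require per-sample spectra; the
      # group-level rescale factor is applied uniformly within the group
      fac <- hum_tot / pmax(colSums(raw_M), 1)
      key <- paste(burdens$species, burdens$condition, sep = ".")
      burdens$freq_per_mb <- burdens$freq_per_mb * fac[key]
      delta <- delta_snv(burdens, n_boot = config$n_boot,
                         seed = stage_seed(config$seed, "burden"))
    }

    # -- signatures ---------------------------------------------------------
    current_stage <- "signatures"
    sigs <- nmf_extract(M, k = config$k, n_restarts = config$n_restarts,
                        seed = stage_seed(config$seed, "signatures"))
    catalog <- config$catalog
    if (is.null(catalog)) catalog <- synthetic_reference_catalog()
    if (is.character(catalog)) catalog <- read_signature_catalog(catalog)
    matches <- match_signatures(sigs, catalog, top_n = 5)
    fractions <- contribution_fractions(sigs)
    s1 <- dplyr::filter(fractions, .data$signature == "S1")
    s1w <- tidyr::pivot_wider(s1[, c("species", "condition", "fraction")],
                              names_from = "condition", values_from = "fraction")
    s1_test <- paired_t_test(s1w$treated, s1w$control)
    association <- signature_lifespan_association(
      fractions, cohort$metadata,
      signature = config$association_signature,
      condition = config$association_condition,
      exclude = config$association_exclude
    )

    # -- report -------------------------------------------------------------
    current_stage <- "report"
    manifest <- list(
      package = "mutexcess",
      version = as.character(utils::packageVersion("mutexcess")),
      seed = config$seed,
      stage_seeds = stats::setNames(
        lapply(PIPELINE_STAGES, function(s) stage_seed(config$seed, s)),
        PIPELINE_STAGES),
      # out_dir is run-local and excluded so identical analyses yield
      # identical manifests wherever they are written
      config = config[setdiff(names(config), c("catalog", "out_dir"))],
      input_checksums = checksums,
      n_species = nrow(cohort$metadata),
      n_samples = nrow(cohort$callable),
      n_calls_input = nrow(cohort$calls),
      n_calls_filtered = nrow(filtered),
      removal_tally = tally,
      n_groups = ncol(M)
    )
    result <- structure(list(
      cohort = cohort, filtered = filtered, tally = tally,
      burdens = burdens, delta = delta, regressions = regressions,
      points = points,
      spectra = M, spectra_raw = raw_M, trinuc_freqs = trinuc_freqs,
      signatures = sigs, matches = matches, fractions = fractions,
      s1_paired_test = s1_test, association = association,
      manifest = manifest, config = config
    ), class = "pipeline_result")
    if (!is.null(out)) write_report(result, out)
    result
  }, error = fail))
  invisible(res)
}

#' Per-sample excess-mutation points for regression
#'
#' One point per treated sample: its SNV frequency minus the mean control
#' frequency of its species, joined to the species covariates. These are the
#' default regression points of the comparative stage (treated samples as
#' the unit of analysis).
#'
#' @param burdens Per-sample burden tibble from [sample_burdens()].
#' @param metadata Species covariate table (`species`, `mls_years`, ...).
#' @return Tibble of treated samples with `excess_per_mb` and the covariates.
#' @export
excess_points <- function(burdens, metadata) {
  ctrl <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(burdens, .data$condition == "control"),
                    .data$species),
    mean_control = mean(.data$freq_per_mb), .groups = "drop")
  pts <- dplyr::mutate(
    dplyr::inner_join(dplyr::filter(burdens, .data$condition == "treated"),
                      ctrl, by = "species"),
    excess_per_mb = .data$freq_per_mb - .data$mean_control)
  dplyr::inner_join(pts, tibble::as_tibble(metadata), by = "species")
}

write_report <- function(result, out) {
  readr::write_tsv(result$burdens, file.path(out, "burdens.tsv"))
  readr::write_tsv(tibble::as_tibble(result$delta), file.path(out, "delta_snv.tsv"))
  readr::write_tsv(result$regressions, file.path(out, "regressions.tsv"))
  readr::write_tsv(result$tally, file.path(out, "removal_tally.tsv"))
  write_spectra_tsv(result$spectra, file.path(out, "spectra_humanized.tsv"))
  write_spectra_tsv(result$spectra_raw, file.path(out, "spectra_raw.tsv"))
  tf <- purrr::imap_dfr(result$trinuc_freqs, function(f, sp) {
    dplyr::mutate(f, species = sp, .before = 1)
  })
  readr::write_tsv(tf, file.path(out, "trinucleotide_frequencies.tsv"))
  write_spectra_tsv(result$signatures$W, file.path(out, "signatures_W.tsv"))
  H <- result$signatures$H
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(signature = rownames(H)),
                                    tibble::as_tibble(H)),
                   file.path(out, "signatures_H.tsv"))
  readr::write_tsv(result$matches, file.path(out, "signature_matches.tsv"))
  readr::write_tsv(result$fractions, file.path(out, "contribution_fractions.tsv"))
  readr::write_tsv(result$association, file.path(out, "association.tsv"))
  jsonlite::write_json(result$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  cfg <- result$config
  cfg$catalog <- NULL
  cfg$out_dir <- NULL  # run-local; keeps the echoed config location-independent
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(out, "config.yaml"))
  writeLines(pipeline_summary_lines(result), file.path(out, "summary.txt"))
  if (isTRUE(result$config$make_figures)) {
    tryCatch(write_figures(result, file.path(out, "figures")),
             error = function(e) warning("figure generation failed: ",
                                         conditionMessage(e), call. = FALSE))
  }
  invisible(out)
}

pipeline_summary_lines <- function(result) {
  d <- result$delta
  r <- result$regressions
  full <- r[r$covariate == "mls" & r$excluded == "", ]
  top <- result$matches[result$matches$rank == 1, ]
  c(
    sprintf("mutexcess pipeline run (seed %d)", result$config$seed),
    sprintf("species: %d, samples: %d, calls in: %d, somatic after filter: %d",
            result$manifest$n_species, result$manifest$n_samples,
            result$manifest$n_calls_input, result$manifest$n_calls_filtered),
    sprintf("germline removals: set-match %d, recurrence %d",
            result$tally$n_removed[1], result$tally$n_removed[2]),
    "",
    "excess mutation frequency (per Mb):",
    sprintf("  %-16s delta = %.3f  [%.3f, %.3f]", d$species, d$delta_snv,
            d$ci_low, d$ci_high),
    "",
    sprintf("excess vs MLS:  slope %.4g per year, R^2 = %.4f, p = %.3g (n = %d points)",
            full$slope, full$r_squared, full$p_value, full$n),
    sprintf("top-signature matches: %s",
            paste(sprintf("%s->%s (cos %.3f)", top$signature, top$reference,
                          top$cosine), collapse = ", ")),
    sprintf("S1 fraction treated vs control: t = %.3f, p = %.3g",
            result$s1_paired_test$statistic, result$s1_paired_test$p_value),
    sprintf("%s fraction vs MLS (%s groups%s): rho = %.3f, p = %.3g",
            result$association$signature[1], result$association$condition[1],
            ifelse(result$association$excluded[1] == "", "",
                   paste0(", excl. ", result$association$excluded[1])),
            result$association$rho[1], result$association$p_value[1])
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(pipeline_summary_lines(x))
  invisible(x)
}
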