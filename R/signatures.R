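# De novo mutational-signature extraction by non-negative matrix
# factorization (multiplicative updates on the generalized Kullback-Leibler
# divergence), cosine matching against a reference catalog, and contribution
# analysis across conditions and lifespan.

#' Convert grouped spectra to a 96 x G matrix
#'
#' @param spectra Either a matrix (rows = 96 categories), or a long tibble
#'   with columns `group`, `category`, `count`, or a wide tibble with a
#'   `category` column plus one numeric column per group.
#' @return Numeric 96 x G matrix with category rownames and group colnames.
#' @export
as_spectra_matrix <- function(spectra) {
  cats <- sbs_categories()
  if (is.matrix(spectra)) {
    M <- spectra
  } else {
    spectra <- tibble::as_tibble(spectra)
    if (all(c("group", "category", "count") %in% names(spectra))) {
      wide <- tidyr::pivot_wider(spectra, id_cols = "category",
                                 names_from = "group", values_from = "count",
                                 values_fill = 0)
      M <- as.matrix(wide[, -1, drop = FALSE])
      rownames(M) <- as.character(wide$category)
    } else if ("category" %in% names(spectra)) {
      M <- as.matrix(spectra[, setdiff(names(spectra), "category"), drop = FALSE])
      rownames(M) <- as.character(spectra$category)
    } else {
      stop("unrecognized spectra layout", call. = FALSE)
    }
  }
  if (!is.null(rownames(M))) {
    missing <- setdiff(cats, rownames(M))
    if (length(missing) > 0) {
      M <- rbind(M, matrix(0, length(missing), ncol(M),
                           dimnames = list(missing, colnames(M))))
    }
    M <- M[cats, , drop = FALSE]
  } else if (nrow(M) == 96) {
    rownames(M) <- cats
  } else {
    stop("spectra matrix must have 96 rows or category names", call. = FALSE)
  }
  storage.mode(M) <- "double"
  M
}

#' Extract de novo signatures by non-negative matrix factorization
#'
#' Factorizes a 96 x G spectra matrix `M ~ W H` with `W` (96 x k) the
#' signature probability vectors and `H` (k x G) the per-group contributions,
#' by multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence `D(M || WH)` (the Brunet variant standard in mutational
#' signature work). A squared-error (`"frobenius"`) variant is available.
#' The best of `n_restarts` seeded random initializations (per-restart seed
#' `seed + restart`) is kept. Afterwards columns of `W` are normalized to sum
#' to 1 with compensating row scaling of `H`, and signatures are renamed
#' S1..Sk in decreasing order of total contribution.
#'
#' @param M Spectra in any layout accepted by [as_spectra_matrix()].
#' @param k Number of signatures, `1 <= k <= min(96, G)`.
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @param n_restarts Number of random restarts (default 30).
#' @param seed Integer seed.
#' @param method `"kl"` (default) or `"frobenius"`.
#' @return Object of class `signature_set`: list with `W`, `H`,
#'   `objective_trace` (per-iteration divergence of the winning restart,
#'   non-increasing), `final_objective`, `converged`, `seed_used`,
#'   `n_restarts`, `method`, `group_labels`.
#' @export
nmf_extract <- function(M, k, max_iter = 2000, tol = 1e-6, n_restarts = 30,
                        seed = 1L, method = c("kl", "frobenius")) {
  method <- match.arg(method)
  V <- as_spectra_matrix(M)
  G <- ncol(V)
  if (any(V < 0)) stop("nmf_extract(): negative entries in spectra", call. = FALSE)
  if (any(colSums(V) == 0)) stop("nmf_extract(): all-zero spectrum column", call. = FALSE)
  if (k < 1 || k > min(96, G))
    stop("nmf_extract(): k must satisfy 1 <= k <= min(96, G)", call. = FALSE)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(seed + r, {
      W0 <- matrix(stats::runif(96 * k, 0.1, 1), 96, k)
      H0 <- matrix(stats::runif(k * G, 0.1, 1) * mean(V) , k, G)
      nmf_run(V, W0, H0, max_iter, tol, method)
    })
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }

  # normalize signature columns, compensate in H, order by total contribution
  csum <- colSums(best$W)
  csum[csum == 0] <- 1
  W <- sweep(best$W, 2, csum, "/")
  H <- best$H * csum
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- paste0("S", seq_len(k))
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  if (!best$converged) {
    warning("nmf_extract(): maximum iterations reached before convergence",
            call. = FALSE)
  }
  structure(list(
    W = W, H = H,
    total_count = sum(V),
    objective_trace = best$trace,
    final_objective = best$objective,
    converged = best$converged,
    seed_used = seed, n_restarts = n_restarts, method = method,
    group_labels = colnames(V)
  ), class = "signature_set")
}

# one multiplicative-update run
nmf_run <- function(V, W, H, max_iter, tol, method) {
  eps <- 1e-12
  obj <- function() {
    WH <- W %*% H
    if (method == "kl") kl_divergence(V, WH) else 0.5 * sum((V - WH)^2)
  }
  trace <- numeric(max_iter + 1)
  trace[1] <- obj()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    if (method == "kl") {
      WH <- W %*% H + eps
      H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps, each = nrow(W))
    } else {
      H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    }
    trace[it + 1] <- obj()
    if (abs(trace[it] - trace[it + 1]) <= tol * max(abs(trace[it]), eps)) {
      converged <- TRUE
      break
    }
  }
  list(W = W, H = H, objective = trace[it + 1], trace = trace[seq_len(it + 1)],
       converged = converged)
}

#' Generalized Kullback-Leibler divergence D(V || WH)
#'
#' `sum(V * log(V / A) - V + A)` with the `0 log 0 = 0` convention.
#'
#' @param V,A Non-negative matrices of equal dimension.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(V, A) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / pmax(A[pos], 1e-300))) - sum(V) + sum(A)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d signatures x %d groups (%s NMF, %d restarts, seed %d)\n",
              ncol(x$W), ncol(x$H), x$method, x$n_restarts, x$seed_used))
  cat(sprintf("  final divergence %.6g (%s)\n", x$final_objective,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Cosine similarity of two non-negative vectors
#'
#' @param a,b Non-negative, non-zero numeric vectors of equal length.
#' @return `sum(a*b) / (||a|| * ||b||)`, in `[0, 1]` for non-negative input.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity(): zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Match extracted signatures against a reference catalog
#'
#' Ranks catalog entries by cosine similarity for each extracted signature,
#' ties broken by catalog name (lexicographic).
#'
#' @param sigs A `signature_set` from [nmf_extract()], or a 96 x k matrix.
#' @param catalog Reference catalog: 96 x R matrix with named columns, or a
#'   tibble with a `category` column plus one column per reference entry (see
#'   [read_signature_catalog()]).
#' @param top_n Matches retained per signature (default all).
#' @return Tibble with `signature`, `rank`, `reference`, `cosine`.
#' @export
match_signatures <- function(sigs, catalog, top_n = Inf) {
  W <- if (inherits(sigs, "signature_set")) sigs$W else as_spectra_matrix(sigs)
  C <- as_spectra_matrix(catalog)
  if (ncol(C) == 0) stop("match_signatures(): empty catalog", call. = FALSE)
  purrr::map_dfr(colnames(W), function(s) {
    cs <- vapply(colnames(C), function(r) cosine_similarity(W[, s], C[, r]),
                 numeric(1))
    ord <- order(-cs, names(cs))
    keep <- utils::head(ord, top_n)
    tibble::tibble(signature = s, rank = seq_along(keep),
                   reference = names(cs)[keep], cosine = unname(cs[keep]))
  })
}

#' Per-group signature contribution fractions
#'
#' Normalizes each column of the contribution matrix `H` to sum to 1.
#'
#' @param sigs A `signature_set` (or a k x G non-negative matrix).
#' @return Tibble with `group`, `signature`, `fraction`; fractions sum to 1
#'   within each group. If group labels follow the pipeline convention
#'   `"<species>.<condition>"`, columns `species` and `condition` are added.
#' @export
contribution_fractions <- function(sigs) {
  H <- if (inherits(sigs, "signature_set")) sigs$H else as.matrix(sigs)
  tot <- colSums(H)
  if (any(tot == 0)) stop("contribution_fractions(): all-zero contribution column",
                          call. = FALSE)
  F <- sweep(H, 2, tot, "/")
  out <- tibble::as_tibble(as.table(F), .name_repair = "minimal")
  names(out) <- c("signature", "group", "fraction")
  out <- dplyr::select(out, "group", "signature", "fraction")
  if (all(grepl("^[^.]+\\.(control|treated)$", out$group))) {
    out <- dplyr::mutate(out,
      species = sub("\\.(control|treated)$", "", .data$group),
      condition = sub("^.*\\.", "", .data$group))
  }
  tibble::as_tibble(out)
}

#' Association of a signature's fraction with species lifespan
#'
#' Spearman rank correlation between a chosen signature's per-species
#' contribution fraction (in one condition) and maximum lifespan, optionally
#' after excluding named species (e.g. a known outlier).
#'
#' @param fractions Output of [contribution_fractions()] carrying `species`
#'   and `condition` columns.
#' @param meta Species metadata with `species` and `mls_years`.
#' @param signature Signature label (e.g. `"S3"`).
#' @param condition Condition whose fractions are used (default `"control"`).
#' @param exclude Character vector of species to exclude.
#' @return Tibble from [spearman_correlation()] plus columns `signature`,
#'   `condition`, `excluded`.
#' @export
signature_lifespan_association <- function(fractions, meta, signature = "S3",
                                           condition = "control",
                                           exclude = NULL) {
  stopifnot(all(c("species", "condition", "signature", "fraction") %in% names(fractions)))
  f <- dplyr::filter(fractions, .data$signature == !!signature,
                     .data$condition == !!condition,
                     !.data$species %in% exclude)
  f <- dplyr::inner_join(f, tibble::as_tibble(meta), by = "species")
  if (nrow(f) < 4) stop("signature_lifespan_association(): fewer than 4 species",
                        call. = FALSE)
  res <- spearman_correlation(f$mls_years, f$fraction)
  dplyr::mutate(res, signature = !!signature, condition = !!condition,
                excluded = paste(exclude, collapse = ","))
}
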