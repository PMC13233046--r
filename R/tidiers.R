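# broom-style accessors for the NMF fit.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NMF signature set
#'
#' @param x A `signature_set`.
#' @param matrix `"W"` (signature probabilities, default) or `"H"`
#'   (contributions).
#' @param ... Unused.
#' @return For `"W"`: tibble with `signature`, `category`, `probability`;
#'   for `"H"`: tibble with `signature`, `group`, `contribution`.
#' @export
tidy.signature_set <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    out <- tibble::as_tibble(as.table(x$W), .name_repair = "minimal")
    names(out) <- c("category", "signature", "probability")
    out$category <- factor(out$category, levels = sbs_categories())
    dplyr::arrange(out[, c("signature", "category", "probability")],
                   .data$signature, .data$category)
  } else {
    out <- tibble::as_tibble(as.table(x$H), .name_repair = "minimal")
    names(out) <- c("signature", "group", "contribution")
    out
  }
}

#' One-row summary of an NMF signature set
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_groups`, `final_objective`,
#'   `relative_divergence` (objective over total count), `iterations`,
#'   `converged`, `n_restarts`, `method`, `seed_used`.
#' @export
glance.signature_set <- function(x, ...) {
  tibble::tibble(
    k = ncol(x$W),
    n_groups = ncol(x$H),
    final_objective = x$final_objective,
    relative_divergence = x$final_objective / (x$total_count %||% sum(x$H)),
    iterations = length(x$objective_trace) - 1L,
    converged = x$converged,
    n_restarts = x$n_restarts,
    method = x$method,
    seed_used = x$seed_used
  )
}
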