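# Comparative stage: OLS regressions of excess mutation burden against
# species covariates, leave-one-out sensitivity analysis, and the rank/paired
# tests used across the pipeline.

#' Longevity quotient from an allometric expectation
#'
#' LQ = observed MLS divided by the MLS expected from adult body mass under
#' an allometric scaling law `a * mass^b`. Defaults are the classic
#' Austad–Fischer constants for non-volant placental mammals (mass in grams,
#' MLS in years).
#'
#' @param mls_years Maximum lifespan (years).
#' @param body_mass_g Adult body mass (grams).
#' @param a,b Allometric constants.
#' @return Longevity quotient(s).
#' @export
longevity_quotient <- function(mls_years, body_mass_g, a = 10.67, b = 0.189) {
  mls_years / (a * body_mass_g^b)
}

#' Simple linear regression of burden against a covariate
#'
#' Ordinary least squares of `y` on `x` with the two-sided slope p-value from
#' the t distribution on n - 2 degrees of freedom. `r_squared` equals the
#' squared Pearson correlation of (x, y). The fit itself is delegated to
#' [stats::lm()].
#'
#' @param data Data frame of points.
#' @param x,y Column names (tidy-eval) of predictor and response.
#' @param covariate Label recorded in the result (default the `x` column
#'   name).
#' @param excluded Character vector of excluded species recorded in the
#'   result.
#' @param log10_x If `TRUE`, regress on `log10(x)` (for body-mass fits).
#' @return One-row tibble of class `mut_regression`: `covariate`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `excluded` (comma-separated,
#'   `""` if none).
#' @export
#' @examples
#' fit_regression(data.frame(x = 1:3, y = c(2, 4, 6)), x, y)
fit_regression <- function(data, x, y, covariate = NULL, excluded = character(),
                           log10_x = FALSE) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  if (is.null(covariate)) covariate <- rlang::as_name(rlang::enquo(x))
  if (log10_x) xv <- log10(xv)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("fit_regression(): need at least 3 points", call. = FALSE)
  if (stats::sd(xv) == 0) stop("fit_regression(): predictor is constant", call. = FALSE)
  if (stats::sd(yv) == 0) {
    out <- tibble::tibble(covariate = covariate, slope = 0,
                          intercept = mean(yv), r_squared = 0, p_value = 1,
                          n = n, excluded = paste(excluded, collapse = ","))
  } else {
    fit <- stats::lm(yv ~ xv)
    sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
    out <- tibble::tibble(
      covariate = covariate,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = unname(sm$r.squared),
      p_value = unname(sm$coefficients[2, 4]),
      n = n,
      excluded = paste(excluded, collapse = ",")
    )
  }
  class(out) <- c("mut_regression", class(out))
  out
}

#' Leave-one-out regression sensitivity analysis
#'
#' Re-fits the regression after excluding each requested species (or set of
#' species) in turn; each result is exactly the direct fit on the retained
#' subset. The empty exclusion (the full fit) is always included first.
#'
#' @param data Data frame with a `species` column plus the regression
#'   columns.
#' @param x,y Column names (tidy-eval).
#' @param exclusions List of character vectors of species to drop, e.g.
#'   `list("human", "bowhead_whale", "rat")`.
#' @param covariate Label recorded in the results.
#' @param log10_x Passed to [fit_regression()].
#' @return Tibble of `mut_regression` rows, one per exclusion set (full fit
#'   first).
#' @export
leave_one_out <- function(data, x, y, exclusions = list(),
                          covariate = NULL, log10_x = FALSE) {
  stopifnot("species" %in% names(data))
  xq <- rlang::enquo(x); yq <- rlang::enquo(y)
  if (is.null(covariate)) covariate <- rlang::as_name(xq)
  unknown <- setdiff(unique(unlist(exclusions)), unique(data$species))
  if (length(unknown) > 0) {
    stop("leave_one_out(): unknown species in exclusions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sets <- c(list(character(0)), lapply(exclusions, as.character))
  purrr::map_dfr(sets, function(ex) {
    sub <- data[!data$species %in% ex, ]
    fit_regression(sub, !!xq, !!yq, covariate = covariate, excluded = ex,
                   log10_x = log10_x)
  })
}

#' Spearman rank correlation
#'
#' Midranks are used for ties. The two-sided p-value comes from exact
#' permutation enumeration of the rank vector for n <= 9 (valid with ties),
#' and from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2
#' degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return Tibble with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_correlation(): need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_correlation(): constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    P <- all_permutations(n)
    cross <- as.vector(matrix(ry[P], nrow(P)) %*% rx)
    rho_perm <- (cross / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 2 / factorial(n)  # permutation floor; t statistic is unbounded
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    m <- sub + (sub >= k)
    cbind(rep.int(k, nrow(m)), m, deparse.level = 0)
  }))
}

#' Paired Student's t test
#'
#' Thin, validated wrapper around [stats::t.test()] on paired data. All-zero
#' differences (an undefined statistic) error; constant non-zero differences
#' yield an unbounded statistic (`Inf`) with p-value 0 and a warning.
#'
#' @param a,b Numeric vectors of equal length (n >= 2); differences `a - b`.
#' @return Tibble with `statistic`, `p_value`, `df`, `n`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  n <- length(d)
  if (n < 2) stop("paired_t_test(): need n >= 2", call. = FALSE)
  if (all(d == 0)) stop("paired_t_test(): all differences are zero; statistic undefined",
                        call. = FALSE)
  if (stats::sd(d) == 0) {
    warning("paired_t_test(): constant non-zero differences; t is unbounded",
            call. = FALSE)
    return(tibble::tibble(statistic = sign(d[1]) * Inf, p_value = 0,
                          df = n - 1, n = n))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), n = n)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped (with a tally in the result). The null is
#' exact (signed-rank distribution via [stats::wilcox.test()]) for n <= 25
#' non-zero pairs without tied absolute differences; with ties it is an exact
#' sign-flip enumeration for n <= 16, and the midrank normal approximation
#' (with continuity correction) otherwise.
#'
#' @param a,b Numeric vectors of equal length (n >= 5 recommended).
#' @return Tibble with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n` (non-zero pairs), `n_zero`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("wilcoxon_signed_rank(): all differences are zero; statistic undefined",
                   call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (!ties && n <= 25) {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    p <- wt$p.value
    method <- "exact signed-rank"
  } else if (ties && n <= 16) {
    # enumerate all 2^n sign assignments on the midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    EV <- n * (n + 1) / 4
    p <- mean(abs(Vs - EV) >= abs(V - EV) - 1e-12)
    method <- "exact sign-flip enumeration (midranks)"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "normal approximation"
  }
  tibble::tibble(statistic = V, p_value = p, n = n, n_zero = n_zero,
                 method = method)
}
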