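# NMF extraction, cosine matching, contributions, lifespan association.

test_that("cosine similarity endpoints and closed form", {
  v <- numeric(96)
  a <- v; a[1] <- 1; a[2] <- 1
  b <- v; b[1] <- 1
  expect_equal(cosine_similarity(a, a), 1.0)
  expect_equal(cosine_similarity(a, b), 1 / sqrt(2), tolerance = 1e-12)
  d <- v; d[3] <- 2
  expect_equal(cosine_similarity(b, d), 0.0)
  expect_error(cosine_similarity(v, b), "zero vector")
})

test_that("rank-1 matrices are factorized essentially exactly", {
  withr::with_seed(3, {
    w <- stats::runif(96); h <- stats::runif(8, 1, 10) * 100
    M <- outer(w, h)
    fit <- nmf_extract(M, k = 1, n_restarts = 3, seed = 1)
    expect_gte(cosine_similarity(fit$W[, 1], w / sum(w)), 0.999)
    # closed-form KL optimum for k = 1: outer(rowSums, colSums) / total
    A <- outer(rowSums(M), colSums(M)) / sum(M)
    expect_lte(fit$final_objective, kl_divergence(M, A) + 1e-6 * sum(M))
  })
})

test_that("objective trace is non-increasing across seeds", {
  withr::with_seed(6, {
    M <- matrix(stats::rpois(96 * 10, 40), 96, 10)
    for (s in 1:5) {
      fit <- suppressWarnings(
        nmf_extract(M, k = 3, n_restarts = 1, max_iter = 300, seed = s))
      dtr <- diff(fit$objective_trace)
      expect_lte(max(dtr), 1e-8 * max(abs(fit$objective_trace)))
    }
  })
})

test_that("planted signatures are recovered from noisy mixtures", {
  S <- generator_signatures()
  withr::with_seed(14, {
    H <- rbind(
      ENU_like = c(rep(0.05, 10), stats::runif(10, 0.5, 0.8)),
      clock_flat = stats::runif(20, 0.2, 0.5),
      cpg_like = stats::runif(20, 0.2, 0.5)
    )
    H <- sweep(H, 2, colSums(H), "/") * 2e4
    M <- matrix(stats::rpois(96 * 20, S %*% H), 96, 20)
    colnames(M) <- paste0("g", 1:20)
    fit <- nmf_extract(M, k = 3, n_restarts = 10, seed = 4)
    match <- match_signatures(fit, S, top_n = 1)
    expect_setequal(match$reference, colnames(S))
    expect_true(all(match$cosine >= 0.9))
  })
})

test_that("nmf_extract validates its inputs", {
  M <- matrix(1, 96, 4)
  expect_error(nmf_extract(M, k = 0), "k must")
  expect_error(nmf_extract(M, k = 5), "k must")
  Mneg <- M; Mneg[1, 1] <- -1
  expect_error(nmf_extract(Mneg, k = 2), "negative")
  Mzero <- M; Mzero[, 2] <- 0
  expect_error(nmf_extract(Mzero, k = 2), "all-zero")
})

test_that("signatures are ordered by total contribution and W columns sum to 1", {
  withr::with_seed(2, {
    M <- matrix(stats::rpois(96 * 12, 30), 96, 12)
    fit <- nmf_extract(M, k = 3, n_restarts = 5, seed = 3)
    expect_equal(colSums(fit$W), rep(1, 3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(diff(rowSums(fit$H)) <= 1e-9))
    # reconstruction is preserved by the normalization/reordering
    expect_equal(colnames(fit$W), c("S1", "S2", "S3"))
  })
})

test_that("column permutation of the input permutes H and leaves W invariant", {
  withr::with_seed(31, {
    M <- matrix(stats::rpois(96 * 10, 50) + 1, 96, 10)
    perm <- sample(10)
    W0 <- matrix(stats::runif(96 * 3, 0.1, 1), 96, 3)
    H0 <- matrix(stats::runif(3 * 10, 0.1, 1), 3, 10)
    # exact equivariance of the multiplicative updates: permuting the data
    # columns together with the initialization permutes H and leaves W fixed
    f1 <- mutexcess:::nmf_run(M, W0, H0, max_iter = 200, tol = 0, method = "kl")
    f2 <- mutexcess:::nmf_run(M[, perm], W0, H0[, perm], max_iter = 200,
                              tol = 0, method = "kl")
    expect_equal(f2$W, f1$W, tolerance = 1e-8)
    expect_equal(f2$H, f1$H[, perm], tolerance = 1e-8)
    expect_equal(f2$objective, f1$objective, tolerance = 1e-10)
  })
})

test_that("restarted fits on permuted groups agree up to signature matching", {
  withr::with_seed(32, {
    S <- matrix(0, 96, 3)
    S[1:32, 1] <- 1 / 32; S[33:64, 2] <- 1 / 32; S[65:96, 3] <- 1 / 32
    rownames(S) <- sbs_categories()
    H <- matrix(stats::runif(3 * 10, 0.2, 1), 3, 10) * 2e5
    M <- matrix(stats::rpois(96 * 10, S %*% H), 96, 10)
    colnames(M) <- paste0("g", 1:10)
    perm <- sample(10)
    f1 <- nmf_extract(M, k = 3, n_restarts = 8, seed = 9,
                      max_iter = 20000, tol = 1e-9)
    f2 <- nmf_extract(M[, perm], k = 3, n_restarts = 8, seed = 9,
                      max_iter = 20000, tol = 1e-9)
    # near the (finite-count) optimum the two factorizations agree closely;
    # identifiability at this depth supports ~0.98, not exact equality
    for (j in 1:3) {
      cs <- apply(f2$W, 2, cosine_similarity, f1$W[, j])
      expect_gte(max(cs), 0.98)
    }
    expect_equal(f1$final_objective, f2$final_objective,
                 tolerance = 1e-4 * f1$final_objective)
  })
})

test_that("match_signatures equals the brute-force all-pairs sort", {
  withr::with_seed(7, {
    W <- matrix(stats::runif(96 * 2), 96, 2,
                dimnames = list(sbs_categories(), c("S1", "S2")))
    W <- sweep(W, 2, colSums(W), "/")
    C <- synthetic_reference_catalog()
    got <- match_signatures(W, C)
    for (s in c("S1", "S2")) {
      cs <- sort(vapply(colnames(C), function(r) cosine_similarity(W[, s], C[, r]),
                        numeric(1)), decreasing = TRUE)
      expect_equal(got$cosine[got$signature == s], unname(cs), tolerance = 1e-12)
    }
    # the signature itself ranks first at cosine 1
    self <- match_signatures(C[, 1, drop = FALSE], C)
    expect_equal(self$reference[1], colnames(C)[1])
    expect_equal(self$cosine[1], 1.0, tolerance = 1e-12)
  })
})

test_that("contribution fractions normalize each group and handle k = 1", {
  H <- matrix(c(2, 1, 1), 3, 1, dimnames = list(paste0("S", 1:3), "g1"))
  f <- contribution_fractions(H)
  expect_equal(f$fraction, c(0.5, 0.25, 0.25))
  H1 <- matrix(c(4, 2), 1, 2, dimnames = list("S1", c("a", "b")))
  expect_equal(contribution_fractions(H1)$fraction, c(1, 1))
  Hz <- matrix(0, 2, 1, dimnames = list(c("S1", "S2"), "g"))
  expect_error(contribution_fractions(Hz), "all-zero")
  withr::with_seed(5, {
    H <- matrix(stats::runif(12), 3, 4,
                dimnames = list(paste0("S", 1:3), paste0("g", 1:4)))
    f <- contribution_fractions(H)
    sums <- as.vector(tapply(f$fraction, f$group, sum))
    expect_equal(sums, rep(1, 4), tolerance = 1e-9)
  })
})

test_that("lifespan association is monotone-consistent and respects exclusions", {
  meta <- tibble::tibble(species = letters[1:6], mls_years = c(3, 10, 20, 40, 80, 160))
  fr <- tidyr::expand_grid(species = letters[1:6],
                           condition = c("control", "treated"),
                           signature = c("S1", "S3"))
  fr$fraction <- ifelse(fr$signature == "S3", match(fr$species, letters) / 10, 0.5)
  got <- signature_lifespan_association(fr, meta, signature = "S3",
                                        condition = "control")
  expect_equal(got$rho, 1)

  sub <- signature_lifespan_association(fr, meta, signature = "S3",
                                        condition = "control", exclude = "a")
  direct <- spearman_correlation(meta$mls_years[-1],
                                 (2:6 + 0) / 10)
  expect_equal(sub$n, 5)
  expect_equal(sub$rho, direct$rho)
  expect_equal(sub$p_value, direct$p_value)
})
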