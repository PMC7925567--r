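test_that("pseudo-likelihood of the zero model is L log q per unit weight", {
  q <- 3; L <- 4; n <- 6
  alpha <- aa_alphabet(FALSE)[1:q]
  X <- withr::with_seed(1, matrix(sample(1:q, n * L, TRUE), n))
  w <- rep(1, n)
  m0 <- potts_model(matrix(0, q, L), numeric(L * (L - 1) / 2 * q * q),
                    alpha, lambda_h = 0, lambda_J = 0)
  res <- plm_objective(m0, X, w)
  expect_equal(res$value, n * L * log(q), tolerance = 1e-12)

  # doubling weights doubles the data term; penalty unchanged
  m1 <- potts_model(matrix(0.3, q, L), numeric(L * (L - 1) / 2 * q * q),
                    alpha, lambda_h = 0.05, lambda_J = 0)
  v1 <- plm_objective(m1, X, w)$value
  v2 <- plm_objective(m1, X, 2 * w)$value
  pen <- 0.05 * sum(0.3^2) * q * L
  expect_equal(v2 - pen, 2 * (v1 - pen), tolerance = 1e-10)
})

test_that("analytic PLM gradient matches central finite differences", {
  max_err <- 0
  for (k in 1:20) {
    withr::with_seed(1000 + k, {
      L <- sample(3:5, 1); q <- sample(2:4, 1); n <- sample(4:8, 1)
      alpha <- aa_alphabet(FALSE)[1:q]
      X <- matrix(sample(1:q, n * L, TRUE), n)
      w <- runif(n, 0.5, 2)
      npar_h <- q * L; npar_J <- L * (L - 1) / 2 * q * q
      h <- matrix(rnorm(npar_h, sd = 0.4), q)
      J <- rnorm(npar_J, sd = 0.4)
    })
    model <- potts_model(h, J, alpha, lambda_h = 0.01, lambda_J = 0.02)
    res <- plm_objective(model, X, w)
    g <- c(as.numeric(res$gradient$h), res$gradient$J)
    par <- c(as.numeric(h), J)
    val_at <- function(p) {
      m <- potts_model(matrix(p[1:npar_h], q), p[-(1:npar_h)], alpha,
                       0.01, 0.02)
      plm_objective(m, X, w)$value
    }
    eps <- 1e-5
    idx <- withr::with_seed(k, sample(length(par), min(60, length(par))))
    gnum <- vapply(idx, function(i) {
      p1 <- par; p1[i] <- p1[i] + eps
      p2 <- par; p2[i] <- p2[i] - eps
      (val_at(p1) - val_at(p2)) / (2 * eps)
    }, numeric(1))
    rel <- abs(g[idx] - gnum) / pmax(abs(gnum), 1e-6)
    max_err <- max(max_err, max(rel))
  }
  expect_lt(max_err, 1e-5)
})

test_that("duplicated columns produce the strongest coupling", {
  # a column pair carrying identical states couples most strongly
  withr::with_seed(42, {
    q <- 4; L <- 8; n <- 400
    alpha <- aa_alphabet(FALSE)[1:q]
    X <- matrix(sample(1:q, n * L, TRUE), n)
    X[, 8] <- X[, 1]
    seqs <- apply(X, 1, function(r) paste0(alpha[r], collapse = ""))
  })
  m <- compute_weights(msa(sprintf("s%04d", 1:400), seqs,
                           alphabet = alpha))
  fit <- fit_plm(m, alphabet = alpha)
  fn <- frobenius_scores(fit)
  pairs <- which(upper.tri(fn), arr.ind = TRUE)
  top <- pairs[which.max(fn[upper.tri(fn)]), ]
  expect_equal(unname(top), c(1L, 8L))
})

test_that("independent columns score below a permuted-column null ceiling", {
  withr::with_seed(7, {
    q <- 4; L <- 10; n <- 300
    alpha <- aa_alphabet(FALSE)[1:q]
    X <- matrix(sample(1:q, n * L, TRUE), n)
    seqs <- apply(X, 1, function(r) paste0(alpha[r], collapse = ""))
    # permuting each column independently preserves the null structure
    Xp <- apply(X, 2, sample)
    seqs_p <- apply(Xp, 1, function(r) paste0(alpha[r], collapse = ""))
  })
  fit <- fit_plm(compute_weights(msa(sprintf("a%d", 1:n), seqs,
                                     alphabet = alpha)), alphabet = alpha)
  fit_p <- fit_plm(compute_weights(msa(sprintf("b%d", 1:n), seqs_p,
                                       alphabet = alpha)), alphabet = alpha)
  s <- frobenius_scores(fit)[upper.tri(diag(L))]
  s_p <- frobenius_scores(fit_p)[upper.tri(diag(L))]
  # both spectra are noise of the same magnitude
  expect_lt(max(s), 2 * max(s_p))
  expect_gt(max(s), 0.5 * max(s_p))
})

test_that("Frobenius scores are gauge-fixed over amino-acid states", {
  q <- 4; L <- 3
  alpha <- aa_alphabet(FALSE)[1:q]
  npair <- L * (L - 1) / 2
  J <- numeric(npair * q * q)
  # single nonzero entry c in pair (1,2): after the zero-sum gauge the
  # Frobenius norm is |c| (q-1)/q
  cval <- 2.4
  J[1] <- cval # element (a=1, b=1) of pair (1,2)
  m <- potts_model(matrix(0, q, L), J, alpha)
  fn <- frobenius_scores(m)
  expect_equal(fn[1, 2], abs(cval) * (q - 1) / q, tolerance = 1e-12)
  expect_equal(fn[1, 3], 0)
  expect_true(isSymmetric(fn))

  # adding a constant to a row of J is absorbed by the gauge
  J2 <- J
  J2[1:q] <- J2[1:q] + 5 # add 5 to row a=1 of pair (1,2)
  m2 <- potts_model(matrix(0, q, L), J2, alpha)
  expect_equal(frobenius_scores(m2), fn, tolerance = 1e-10)

  # all-zero couplings give all-zero scores
  m0 <- potts_model(matrix(0, q, L), numeric(npair * q * q), alpha)
  expect_equal(frobenius_scores(m0), matrix(0, L, L))
})

test_that("average product correction removes rank-one background", {
  # constant matrix -> exactly zero
  S <- matrix(5, 6, 6); diag(S) <- 0
  expect_equal(apc(S), matrix(0, 6, 6))

  # hand-computed 3x3 example
  S3 <- sym_from_upper(3, c(2, 4, 6))
  rm_ <- c((2 + 4) / 2, (2 + 6) / 2, (4 + 6) / 2)
  grand <- mean(c(2, 4, 6))
  expected <- sym_from_upper(3, c(2 - rm_[1] * rm_[2] / grand,
                                  4 - rm_[1] * rm_[3] / grand,
                                  6 - rm_[2] * rm_[3] / grand))
  expect_equal(apc(S3), expected, tolerance = 1e-12)

  # symmetric output with near-zero grand off-diagonal mean
  S4 <- withr::with_seed(3, {
    A <- matrix(rexp(100), 10); S <- A + t(A); diag(S) <- 0; S
  })
  out <- apc(S4)
  expect_true(isSymmetric(out))
  expect_lt(abs(mean(out[upper.tri(out)])) / mean(S4[upper.tri(S4)]), 0.05)

  expect_equal(apc(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(apc(matrix(1:6, 2)), class = "coevppi_parameter_error")
})

test_that("EC tables exclude the intra diagonal band and rank by score", {
  L1 <- 10; L2 <- 10; L <- L1 + L2
  cn <- withr::with_seed(5, { A <- matrix(rnorm(L * L), L)
                              S <- A + t(A); diag(S) <- 0; S })
  tab <- build_ec_table(cn, L1, L2, n_eff = 50)
  # no intra pair within 5 positions; inter pairs never excluded
  intra <- tab[!tab$is_inter, ]
  expect_true(all(abs(intra$j - intra$i) > 5))
  expect_false(paste(1, 6) %in% paste(tab$i, tab$j))         # (i, i+5) absent
  expect_true(paste(L1, L1 + 1) %in% paste(tab$i, tab$j))    # boundary pair
  expect_true(tab$is_inter[tab$i == L1 & tab$j == L1 + 1])

  # enumerated row count: 2 * choose(10,2)-excluded + 100 inter
  n_intra_seg <- sum(outer(1:L1, 1:L1, function(i, j) j - i > 5))
  expect_equal(nrow(tab), 2 * n_intra_seg + L1 * L2)

  # ranks are a permutation and ordered by cn descending
  expect_setequal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$cn[order(tab$rank)]) <= 0))

  # monomer table: single segment, everything intra
  tabm <- build_ec_table(cn[1:10, 1:10], 10)
  expect_true(all(!tabm$is_inter))
})

test_that("inter-coupling Z-scores standardize over inter rows only", {
  cn <- sym_from_upper(4, rep(0, 6))
  cn[1, 3] <- cn[3, 1] <- 1; cn[1, 4] <- cn[4, 1] <- 2
  cn[2, 3] <- cn[3, 2] <- 3; cn[2, 4] <- cn[4, 2] <- 0
  tab <- build_ec_table(cn, 2, 2, n_eff = 10)
  tab <- inter_zscores(tab)
  vals <- c(1, 2, 3, 0)
  z <- (vals - mean(vals)) / sd(vals)
  got <- tab$z[match(paste(c(1, 1, 2, 2), c(3, 4, 3, 4)),
                     paste(tab$i, tab$j))]
  expect_equal(got, z, tolerance = 1e-12)
  expect_true(all(is.na(tab$z[!tab$is_inter])))

  # zero variance -> flagged missing
  cn2 <- matrix(1, 4, 4); diag(cn2) <- 0
  tab2 <- inter_zscores(build_ec_table(cn2, 2, 2))
  expect_true(all(is.na(tab2$z)))
  expect_true(attr(tab2, "z_degenerate"))
})

test_that("non-convergence raises a convergence error with gradient norm", {
  m <- compute_weights(random_msa(30, 8, seed = 8))
  expect_error(fit_plm(m, maxit = 2),
               class = "coevppi_convergence_error")
})
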