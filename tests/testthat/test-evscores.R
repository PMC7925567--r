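test_that("EVcomplex transform normalizes by the most negative inter score", {
  cn <- sym_from_upper(4, rep(0, 6))
  # inter pairs of a 2+2 table: (1,3), (1,4), (2,3), (2,4)
  cn[1, 3] <- cn[3, 1] <- 3; cn[1, 4] <- cn[4, 1] <- -2
  cn[2, 3] <- cn[3, 2] <- 1; cn[2, 4] <- cn[4, 2] <- 0.5
  tab <- build_ec_table(cn, 2, 2, n_eff = 400) # n_eff/L = 100 -> g = 1
  out <- evcomplex_transform(tab)
  raw <- out$evcomplex_raw[match(paste(c(1, 1, 2, 2), c(3, 4, 3, 4)),
                                 paste(out$i, out$j))]
  expect_equal(raw, c(3, -2, 1, 0.5) / 2)   # hand: divide by |-2|
  expect_equal(min(out$evcomplex_raw, na.rm = TRUE), -1)

  # scale invariance of the raw score
  out2 <- evcomplex_transform(build_ec_table(2.7 * cn, 2, 2, n_eff = 400))
  expect_equal(out2$evcomplex_raw, out$evcomplex_raw, tolerance = 1e-12)

  # diversity shrink: n_eff/L = 0.25 -> g = 0.5
  out3 <- evcomplex_transform(build_ec_table(cn, 2, 2, n_eff = 1))
  expect_equal(out3$evcomplex_score, out3$evcomplex_raw * 0.5)

  # nonnegative minimum -> degenerate, flagged not crashed
  cnp <- abs(cn)
  out4 <- evcomplex_transform(build_ec_table(cnp, 2, 2))
  expect_true(attr(out4, "evcomplex_degenerate"))
  expect_true(all(is.na(out4$evcomplex_raw)))
})

test_that("intra enrichment normalizes per segment and matches brute force", {
  # uniform scores on a ring: every residue touched equally -> enrichment 1
  L1 <- 12
  cn <- matrix(0, L1, L1)
  for (i in 1:L1) { j <- ((i + 5) %% L1) + 1
    cn[i, j] <- cn[j, i] <- 1 }
  tab <- build_ec_table(cn, L1)
  enr <- intra_enrichment(tab)
  touched <- enr[enr > 0]
  expect_true(all(abs(touched - 1) < 1e-12))

  # brute-force recomputation on a random two-segment table
  L1 <- 15; L2 <- 12; L <- L1 + L2
  cn <- withr::with_seed(11, { A <- matrix(abs(rnorm(L * L)), L)
                               S <- A + t(A); diag(S) <- 0; S })
  tab <- build_ec_table(cn, L1, L2)
  enr <- intra_enrichment(tab)
  for (seg in list(c(1, L1, "A"), c(L1 + 1, L, "B"))) {
    lo <- as.integer(seg[1]); hi <- as.integer(seg[2])
    seg_len <- hi - lo + 1
    rows <- tab[!tab$is_inter & tab$segment_i == seg[3], ]
    rows <- rows[order(-rows$cn), ][seq_len(min(seg_len, nrow(rows))), ]
    s <- numeric(seg_len)
    for (r in seq_len(nrow(rows))) {
      s[rows$i[r] - lo + 1] <- s[rows$i[r] - lo + 1] + rows$cn[r]
      s[rows$j[r] - lo + 1] <- s[rows$j[r] - lo + 1] + rows$cn[r]
    }
    expect_equal(enr[lo:hi], s / mean(s), tolerance = 1e-12)
  }
})

test_that("relative rank counts strictly greater rows plus one", {
  cn <- withr::with_seed(13, { A <- matrix(rnorm(400), 20)
                               S <- A + t(A); diag(S) <- 0; S })
  tab <- build_ec_table(cn, 10, 10)
  rr <- relative_rank(tab)
  n <- nrow(tab)
  expect_equal(rr[which.max(tab$cn)], 1 / n)      # global top
  expect_equal(rr[which.min(tab$cn)], 1)          # global bottom
  # counting oracle on every row
  oracle <- vapply(seq_len(n),
                   function(r) (sum(tab$cn > tab$cn[r]) + 1) / n, 0)
  expect_equal(rr, oracle)
  expect_true(all(rr > 0 & rr <= 1))
})

test_that("residue feature rows take the top-10 inter pairs with features", {
  L1 <- 8; L2 <- 8; L <- L1 + L2
  cn <- withr::with_seed(17, { A <- matrix(rnorm(L * L), L)
                               S <- A + t(A); diag(S) <- 0; S })
  tab <- build_ec_table(cn, L1, L2, n_eff = 4 * L)
  cons <- withr::with_seed(18, runif(L))
  feats <- build_residue_features(tab, conservation = cons)
  expect_equal(nrow(feats), 10)
  expect_true(all(diff(feats$cn) <= 0))            # ordered by cn
  expect_equal(feats$conservation_max,
               pmax(cons[feats$i], cons[feats$j]))
  expect_true(all(feats$label == "unknown"))       # no structures given

  # distance labels: contact strictly below 8, unknown when unresolved
  pdb <- write_pdb_tmp(data.frame(
    resno = c(1, 2), resname = "ALA", atom = "CA",
    x = c(0, 7.99), y = 0, z = 0, element = "C"))
  mapping <- data.frame(alignment_pos = c(3, L1 + 4), chain = "A",
                        resnum = c(1, 2))
  dmap <- min_distance_map(list(pdb), mapping)
  feats2 <- build_residue_features(tab, cons, dmap = dmap)
  known <- feats2[feats2$i == 3 & feats2$j == L1 + 4, ]
  if (nrow(known) == 1)
    expect_equal(known$label, "contact")
  expect_true(all(feats2$label[is.na(feats2$distance)] == "unknown"))

  # fewer than 10 inter rows: padded with zeros and flagged
  tab_small <- build_ec_table(cn[c(1:8, 9:10), c(1:8, 9:10)], 8, 2,
                              n_eff = 40)
  f3 <- build_residue_features(tab_small, cons[1:10])
  expect_equal(nrow(f3), 10)
  expect_lte(sum(!f3$padded), nrow(tab_small[tab_small$is_inter, ]))
  expect_true(any(f3$padded) || sum(tab_small$is_inter) >= 10)
})

test_that("residue model training recovers planted logistic weights", {
  w_true <- setNames(c(1.1, -0.7, 0.45, 0), residue_feature_names())
  dat <- make_logistic_fixture(5000, w_true, bias = 0.2, seed = 31)
  fit <- train_residue_model(dat, feature_names = names(w_true),
                             reg_weight = 0.05, seed = 1)
  expect_lt(max(abs(fit$weights - w_true)), 0.15)
  expect_true(is.finite(fit$cv$precision) && is.finite(fit$cv$recall))

  # bit-reproducible under fixed seed and row order
  fit2 <- train_residue_model(dat, feature_names = names(w_true),
                              reg_weight = 0.05, seed = 1)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$cv, fit2$cv)

  # linearly separable features reach near-perfect training accuracy
  sep <- data.frame(label = rep(c(1, 0), each = 200),
                    f = c(rnorm(200, 5), rnorm(200, -5)))
  fsep <- train_residue_model(sep, feature_names = "f", seed = 2)
  acc <- mean((predict(fsep, sep) >= 0.5) == (sep$label == 1))
  expect_gte(acc, 0.99)

  # permuted labels cannot be learned
  perm <- dat
  perm$label <- withr::with_seed(4, sample(perm$label))
  fperm <- train_residue_model(perm, feature_names = names(w_true), seed = 3)
  expect_lt(abs(fperm$cv$accuracy - 0.5), 0.05)

  # single-class input is a training error
  one <- dat[dat$label == 1, ]
  expect_error(train_residue_model(one, feature_names = names(w_true)),
               class = "coevppi_training_error")
})

test_that("interaction model selects informative features and scores pairs", {
  # one informative + ten noise features: L1 stage keeps the signal and
  # removes the noise at this sample size
  w <- setNames(c(2, rep(0, 10)), c(paste0("prob_", 1:10), "top_rank"))
  names(w)[1] <- "prob_1"
  dat <- make_logistic_fixture(400, w, seed = 41)
  names(dat)[-1] <- names(w)
  im <- train_interaction_model(dat, seed = 5)
  expect_true("prob_1" %in% im$selected)
  expect_lt(length(im$selected), 6)
  expect_equal(unname(im$weights[setdiff(names(w), im$selected)]),
               rep(0, 11 - length(im$selected)))

  # duplicate feature columns do not crash the two-stage fit
  dup <- dat
  dup$prob_2 <- dup$prob_1
  expect_s3_class(train_interaction_model(dup, seed = 6), "logistic_model")

  # held-out AUC approaches the generator's closed-form Bayes AUC
  tr <- make_feature_fixture(800, 800, class_separation = 2, seed = 42)
  te <- make_feature_fixture(1500, 1500, class_separation = 2, seed = 43)
  im2 <- train_interaction_model(tr, seed = 7)
  expect_lt(abs(auc_of(predict(im2, te), te$label) -
                  attr(tr, "bayes_auc")), 0.05)
})

test_that("interaction scoring is monotone in residue probabilities", {
  tr <- make_feature_fixture(500, 500, class_separation = 2, seed = 51)
  im <- train_interaction_model(tr, seed = 8)
  lo <- score_protein_interaction(rep(0, 10), top_rank = 1, model = im)
  hi <- score_protein_interaction(rep(1, 10), top_rank = 1 / 500,
                                  model = im)
  expect_lt(lo$probability, hi$probability)
  expect_true(lo$probability > 0 && hi$probability < 1)

  # padding: short probability vectors are zero-filled to 10
  short <- score_protein_interaction(c(0.9, 0.8), top_rank = 0.01,
                                     model = im)
  expect_true(is.finite(short$probability))
  # calls against a residue threshold
  sc <- score_protein_interaction(c(0.9, 0.85, 0.2), 0.01, im,
                                  residue_threshold = 0.8)
  expect_equal(sc$n_calls, 2L)
  expect_error(score_protein_interaction(rep(0.5, 10), 0.5, NULL),
               class = "coevppi_configuration_error")
})

test_that("threshold calibration equals exhaustive cut-point enumeration", {
  withr::with_seed(61, {
    scores <- c(rnorm(300, 1.2), rnorm(700, 0))
    labels <- rep(c(1, 0), c(300, 700))
  })
  for (mode in c("precision", "fpr")) {
    for (target in c(0.8, 0.9, 0.5, 0.1, 0.001)) {
      got <- calibrate_threshold(scores, labels, mode, target)
      # independent enumeration over every cut point
      cuts <- sort(unique(scores))
      ok <- vapply(cuts, function(th) {
        pos <- scores >= th
        if (mode == "precision") any(pos) && mean(labels[pos] == 1) >= target
        else sum(pos & labels == 0) / sum(labels == 0) <= target
      }, logical(1))
      if (any(ok)) {
        expect_true(got$attainable)
        th <- cuts[which(ok)[1]]
        expect_gte(got$threshold, max(c(-Inf, cuts[cuts < th])))
        expect_lte(got$threshold, th)
        pos <- scores >= got$threshold
        ach <- if (mode == "precision") mean(labels[pos] == 1)
               else sum(pos & labels == 0) / sum(labels == 0)
        expect_equal(got$achieved, ach)
      } else {
        expect_false(got$attainable)
      }
    }
  }

  # perfectly separated scores: midpoint of the gap
  got <- calibrate_threshold(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3),
                             "precision", 1)
  expect_equal(got$threshold, 6.5)
  # fpr target 0 with overlapping classes unattainable when the top score
  # is a negative
  got2 <- calibrate_threshold(c(0, 1, 2, 3), c(1, 0, 1, 0), "fpr", 0)
  expect_false(got2$attainable)
})

test_that("the coevolution-diagonal artifact check flags diagonal stacks", {
  L1 <- 100; L2 <- 100
  mk <- function(pos_pairs) {
    cn <- matrix(0, L1 + L2, L1 + L2)
    v <- seq(2, 1, length.out = nrow(pos_pairs))
    for (r in seq_len(nrow(pos_pairs))) {
      i <- pos_pairs[r, 1]; j <- L1 + pos_pairs[r, 2]
      cn[i, j] <- cn[j, i] <- v[r]
    }
    build_ec_table(cn, L1, L2)
  }
  # top-10 all on the exact diagonal -> flagged
  expect_true(diagonal_artifact_check(mk(cbind(1:10, 1:10))))
  # exactly half on the diagonal -> flagged (boundary)
  expect_true(diagonal_artifact_check(mk(cbind(1:10, c(1:5, 51:55)))))
  # 4 of 10 -> not flagged
  expect_false(diagonal_artifact_check(mk(cbind(1:10, c(1:4, 51:56)))))
  # random scattered top pairs: false-flag rate under 1%
  flags <- vapply(1:200, function(k) {
    pp <- withr::with_seed(7000 + k,
                           cbind(sample(L1, 10), sample(L2, 10)))
    diagonal_artifact_check(mk(pp))
  }, logical(1))
  expect_lt(mean(flags), 0.01)
})

test_that("restraint export follows the CB/CA 5 +/- 2 Angstrom convention", {
  L1 <- 6; L2 <- 6; L <- L1 + L2
  cn <- withr::with_seed(71, { A <- matrix(rnorm(L * L), L)
                               S <- A + t(A); diag(S) <- 0; S })
  tab <- build_ec_table(cn, L1, L2)
  map <- data.frame(alignment_pos = 1:L,
                    chain = rep(c("A", "B"), each = 6),
                    resnum = c(1:6, 1:6),
                    aa = c("A", "G", "L", "K", "V", "F",
                           "M", "G", "T", "S", "W", "Y"))
  lines <- export_restraints(tab, map)
  expect_length(lines, 5)   # identical top-5 under both (default) modes
  expect_true(all(grepl("^assign \\(segid .+\\) 5\\.0 2\\.0 2\\.0$", lines)))
  # glycine residues get CA, everything else CB
  gly <- grepl("resi 2 and name CA", lines)
  nongly_ca <- grepl("resi [13456] and name CA", lines)
  expect_false(any(nongly_ca))

  # disjoint top-5 sets under two scorings -> 10 lines
  inter_n <- sum(tab$is_inter)
  s1 <- seq_len(inter_n)            # prefers last rows
  s2 <- rev(s1)
  lines2 <- export_restraints(tab, map, scores_free = s1,
                              scores_aware = s2)
  expect_length(lines2, 10)

  # unmappable residues are skipped with a warning and counted
  map_miss <- map[map$alignment_pos <= 8, ]
  expect_warning(lines3 <- export_restraints(tab, map_miss),
                 "skipped")
  expect_gte(attr(lines3, "n_skipped"), 1)
})

test_that("logistic models round-trip through JSON", {
  dat <- make_logistic_fixture(300, setNames(c(1, -1), c("f1", "f2")),
                               seed = 81)
  fit <- train_residue_model(dat, feature_names = c("f1", "f2"), seed = 1)
  tf <- tempfile(fileext = ".json")
  write_logistic_model(fit, tf)
  back <- read_logistic_model(tf)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$bias, fit$bias)
  expect_equal(predict(back, dat), predict(fit, dat))
})
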