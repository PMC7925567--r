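#' Plant a paired Potts model with known couplings
#'
#' Builds a ground-truth Potts model over two concatenated segments:
#' Gaussian single-site fields, plus `n_intra` within-segment and `n_inter`
#' cross-segment coupled position pairs. Intra pairs avoid the
#' diagonal-excluded band (`|i - j| > exclude_band`); all other couplings
#' are zero. Each planted block is a rank-one +/- `coupling_strength`
#' pattern, so its pre-gauge Frobenius norm is exactly
#' `coupling_strength * q`.
#'
#' @param L1,L2 segment lengths.
#' @param n_intra,n_inter numbers of planted intra- and inter-segment pairs.
#' @param coupling_strength magnitude of planted coupling entries
#'   (default 1).
#' @param q alphabet size (default 8); states are the first `q` canonical
#'   amino-acid letters, with no gap state.
#' @param seed RNG seed; the construction is bit-reproducible.
#' @param field_sd standard deviation of the Gaussian fields (default 0.1).
#' @param exclude_band intra diagonal exclusion half-width (default 5).
#' @return object of class `planted_truth`: list with `model`
#'   ([potts_model()]), `intra_pairs` and `inter_pairs` data frames
#'   (concatenated coordinates), `seed`, `L1`, `L2` and default `sampler`
#'   settings (burn-in 500 sweeps, thinning 10).
#' @export
make_planted_potts <- function(L1, L2, n_intra, n_inter,
                               coupling_strength = 1, q = 8, seed = 1,
                               field_sd = 0.1, exclude_band = 5) {
  L <- L1 + L2
  intra_cand <- do.call(rbind, lapply(list(c(0L, L1), c(L1, L2)),
                                      function(seg) {
    off <- seg[1]; len <- seg[2]
    if (len < 2) return(NULL)
    idx <- which(upper.tri(matrix(0, len, len)), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] > exclude_band, , drop = FALSE]
    if (nrow(idx) == 0L) return(NULL)
    cbind(idx[, 1] + off, idx[, 2] + off)
  }))
  inter_cand <- as.matrix(expand.grid(i = seq_len(L1), j = L1 + seq_len(L2)))
  n_intra_avail <- if (is.null(intra_cand)) 0L else nrow(intra_cand)
  if (n_intra_avail < n_intra || nrow(inter_cand) < n_inter)
    stop_coevppi("requested more planted pairs than the geometry allows",
                 "coevppi_parameter_error")

  withr::with_seed(seed, {
    h <- matrix(rnorm(q * L, sd = field_sd), nrow = q)
    intra <- if (n_intra == 0L) matrix(integer(), 0, 2)
             else intra_cand[sample(n_intra_avail, n_intra), , drop = FALSE]
    inter <- if (n_inter == 0L) matrix(integer(), 0, 2)
             else inter_cand[sample(nrow(inter_cand), n_inter), ,
                             drop = FALSE]
    J <- numeric((L * (L - 1) / 2) * q * q)
    plant <- function(i, j) {
      sa <- sample(c(-1, 1), q, replace = TRUE)
      sb <- sample(c(-1, 1), q, replace = TRUE)
      block <- coupling_strength * outer(sa, sb)
      p <- pair_index(i, j, L)
      J[(p * q * q + 1):(p * q * q + q * q)] <<- as.numeric(t(block))
    }
    for (r in seq_len(n_intra)) plant(intra[r, 1], intra[r, 2])
    for (r in seq_len(n_inter)) plant(inter[r, 1], inter[r, 2])
  })
  alphabet <- aa_alphabet(gap = FALSE)[seq_len(q)]
  model <- potts_model(h, J, alphabet)
  structure(list(model = model,
                 intra_pairs = data.frame(i = intra[, 1], j = intra[, 2]),
                 inter_pairs = data.frame(i = inter[, 1], j = inter[, 2]),
                 seed = seed, L1 = L1, L2 = L2,
                 sampler = list(burnin = 500L, thin = 10L)),
            class = "planted_truth")
}

#' Sample an alignment from a Potts model by Gibbs sampling
#'
#' Runs a single-site Gibbs chain (full sweeps over all positions), records
#' a sequence every `thin` sweeps after `burnin` sweeps, and returns the
#' samples as an alignment over the model's alphabet.
#'
#' @param truth a `planted_truth` (or a bare [potts_model()]).
#' @param n_sequences number of sequences to record.
#' @param seed RNG seed.
#' @param burnin,thin sweep counts; default to the truth's sampler settings
#'   (500 and 10).
#' @return an [msa()] whose `alphabet` matches the model; row 1 serves as
#'   the nominal query.
#' @export
gibbs_sample <- function(truth, n_sequences, seed = 1, burnin = NULL,
                         thin = NULL) {
  stopifnot(n_sequences >= 1)
  model <- if (inherits(truth, "planted_truth")) truth$model else truth
  settings <- if (inherits(truth, "planted_truth")) truth$sampler
              else list(burnin = 500L, thin = 10L)
  burnin <- burnin %||% settings$burnin
  thin <- thin %||% settings$thin
  X <- withr::with_seed(seed,
    cpp_gibbs_sample(model$h, model$J, as.integer(n_sequences),
                     as.integer(burnin), as.integer(thin)))
  letters_q <- model$alphabet
  seqs <- apply(X, 1L, function(row) paste0(letters_q[row], collapse = ""))
  msa(ids = sprintf("sample%05d", seq_len(n_sequences)), seqs = seqs,
      query_index = 1L, alphabet = model$alphabet)
}

# mutate exactly round(rate * L) distinct positions to a different letter
mutate_seq <- function(chars, rate, alphabet) {
  L <- length(chars)
  k <- round(rate * L)
  if (k == 0) return(chars)
  pos <- sample(L, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  }
  chars
}

#' Species-labeled ortholog/paralog pairing fixture
#'
#' Generates two monomer alignments with planted ortholog pairs: per
#' species, one true ortholog of each query (a bounded mutation of the
#' query) and `paralog_rate` decoy paralogs mutated further by at least
#' `decoy_divergence`, so the true ortholog is always the species member
#' closest to the query. Optionally adds close paralogs in the query's own
#' genome to exercise the paralog-exclusion rule. Headers follow UniProt
#' mnemonic conventions so species parse from ids.
#'
#' @param n_species number of non-query species.
#' @param paralog_rate decoy paralogs per species per alignment
#'   (default 2).
#' @param decoy_divergence extra mutation rate of decoys relative to the
#'   ortholog (default 0.3); must stay below the ortholog identity.
#' @param seed RNG seed.
#' @param L1,L2 sequence lengths (defaults 40).
#' @param ortholog_divergence range of per-species ortholog mutation rates
#'   (default 0.05 to 0.25).
#' @param n_query_paralogs close paralogs planted in the query genome of
#'   alignment A (default 0); their identity to the query is ~0.95.
#' @return list with `msa_a`, `msa_b` ([msa()] objects) and `truth` (data
#'   frame species, id_a, id_b of the planted pairs).
#' @export
make_species_fixture <- function(n_species, paralog_rate = 2,
                                 decoy_divergence = 0.3, seed = 1,
                                 L1 = 40, L2 = 40,
                                 ortholog_divergence = c(0.05, 0.25),
                                 n_query_paralogs = 0) {
  aa <- aa_alphabet(gap = FALSE)
  withr::with_seed(seed, {
    qa <- sample(aa, L1, replace = TRUE)
    qb <- sample(aa, L2, replace = TRUE)
    ids_a <- "QUERYA_QRYSP"; seqs_a <- paste0(qa, collapse = "")
    ids_b <- "QUERYB_QRYSP"; seqs_b <- paste0(qb, collapse = "")
    truth <- NULL
    counter <- 0L
    for (s in seq_len(n_species)) {
      sp <- sprintf("SP%03d", s)
      d_a <- runif(1, ortholog_divergence[1], ortholog_divergence[2])
      d_b <- runif(1, ortholog_divergence[1], ortholog_divergence[2])
      orth_a <- mutate_seq(qa, d_a, aa)
      orth_b <- mutate_seq(qb, d_b, aa)
      id_a <- sprintf("O%04d_%s", counter <- counter + 1L, sp)
      id_b <- sprintf("O%04d_%s", counter <- counter + 1L, sp)
      ids_a <- c(ids_a, id_a); seqs_a <- c(seqs_a, paste0(orth_a, collapse = ""))
      ids_b <- c(ids_b, id_b); seqs_b <- c(seqs_b, paste0(orth_b, collapse = ""))
      truth <- rbind(truth, data.frame(species = sp, id_a = id_a,
                                       id_b = id_b,
                                       stringsAsFactors = FALSE))
      for (k in seq_len(paralog_rate)) {
        ids_a <- c(ids_a, sprintf("D%04d_%s", counter <- counter + 1L, sp))
        seqs_a <- c(seqs_a,
                    paste0(mutate_seq(orth_a, decoy_divergence, aa),
                           collapse = ""))
        ids_b <- c(ids_b, sprintf("D%04d_%s", counter <- counter + 1L, sp))
        seqs_b <- c(seqs_b,
                    paste0(mutate_seq(orth_b, decoy_divergence, aa),
                           collapse = ""))
      }
    }
    for (k in seq_len(n_query_paralogs)) {
      ids_a <- c(ids_a, sprintf("P%04d_QRYSP", counter <- counter + 1L))
      seqs_a <- c(seqs_a, paste0(mutate_seq(qa, 0.05, aa), collapse = ""))
    }
  })
  list(msa_a = msa(ids_a, seqs_a,
                   species = vapply(ids_a, parse_species, ""),
                   query_index = 1L),
       msa_b = msa(ids_b, seqs_b,
                   species = vapply(ids_b, parse_species, ""),
                   query_index = 1L),
       truth = truth)
}

#' Labeled Gaussian feature fixture with a known Bayes AUC
#'
#' Two multivariate Gaussian classes with unit covariance separated by
#' `class_separation` along the first feature; the Bayes-optimal AUC is
#' `pnorm(class_separation / sqrt(2))` in closed form.
#'
#' @param n_pos,n_neg class sizes.
#' @param class_separation mean shift of the positive class on feature 1.
#' @param seed RNG seed.
#' @param n_features number of feature columns (default 11).
#' @param feature_names column names; default `prob_1..prob_10`, `top_rank`
#'   to match the interaction model.
#' @return data frame with `label` (1 then 0) and feature columns;
#'   attributes `bayes_auc` and `seed`.
#' @export
make_feature_fixture <- function(n_pos, n_neg, class_separation, seed = 1,
                                 n_features = 11,
                                 feature_names = c(paste0("prob_", 1:10),
                                                   "top_rank")[1:n_features]) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  X <- withr::with_seed(seed, {
    Xp <- matrix(rnorm(n_pos * n_features), n_pos)
    Xp[, 1] <- Xp[, 1] + class_separation
    Xn <- matrix(rnorm(n_neg * n_features), n_neg)
    rbind(Xp, Xn)
  })
  colnames(X) <- feature_names
  out <- data.frame(label = c(rep(1L, n_pos), rep(0L, n_neg)), X)
  attr(out, "bayes_auc") <- pnorm(class_separation / sqrt(2))
  attr(out, "seed") <- seed
  out
}

#' Logistic-response fixture with planted weights
#'
#' Standard-normal features with Bernoulli labels from a logistic model
#' with known weights and bias, for classifier-recovery checks.
#'
#' @param n observations.
#' @param weights true coefficient vector (names become feature names;
#'   unnamed vectors get `f1..fk`).
#' @param bias true intercept (default 0).
#' @param seed RNG seed.
#' @return data frame with `label` and feature columns; attributes
#'   `weights`, `bias`.
#' @export
make_logistic_fixture <- function(n, weights, bias = 0, seed = 1) {
  k <- length(weights)
  nm <- names(weights) %||% paste0("f", seq_len(k))
  dat <- withr::with_seed(seed, {
    X <- matrix(rnorm(n * k), n)
    y <- rbinom(n, 1L, plogis(bias + X %*% weights))
    data.frame(label = y, setNames(as.data.frame(X), nm))
  })
  attr(dat, "weights") <- setNames(weights, nm)
  attr(dat, "bias") <- bias
  dat
}

#' Write a planted-truth sidecar as JSON
#' @param truth a `planted_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth$seed, L1 = truth$L1, L2 = truth$L2,
         q = truth$model$q, sampler = truth$sampler,
         intra_pairs = truth$intra_pairs, inter_pairs = truth$inter_pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
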