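#' EVcomplex score transform
#'
#' Normalizes inter-segment couplings: the raw score divides each
#' inter-protein coupling by the absolute value of the most negative
#' inter-protein coupling (so that the minimum maps to -1), and the final
#' score additionally shrinks by alignment diversity through
#' `g(n_eff/L) = min(1, sqrt(n_eff/L))`, penalizing shallow alignments.
#'
#' @param table an `ec_table` with at least one inter-segment row.
#' @param n_eff effective sequence count; defaults to the table's metadata.
#' @return the table with `evcomplex_raw` and `evcomplex_score` columns on
#'   inter rows (`NA` on intra rows). When the minimum inter coupling is not
#'   negative the transform is degenerate: scores are `NA` and attribute
#'   `evcomplex_degenerate` is set.
#' @export
evcomplex_transform <- function(table, n_eff = attr(table, "n_eff")) {
  inter <- table$is_inter
  if (!any(inter))
    stop_coevppi("no inter-segment rows", "coevppi_degenerate_input")
  m <- min(table$cn[inter])
  table$evcomplex_raw <- NA_real_
  table$evcomplex_score <- NA_real_
  if (m >= 0) {
    attr(table, "evcomplex_degenerate") <- TRUE
    return(table)
  }
  L <- attr(table, "L1") + attr(table, "L2")
  g <- if (is.null(n_eff) || is.na(n_eff)) 1 else min(1, sqrt(n_eff / L))
  table$evcomplex_raw[inter] <- table$cn[inter] / abs(m)
  table$evcomplex_score[inter] <- table$evcomplex_raw[inter] * g
  attr(table, "evcomplex_degenerate") <- FALSE
  attr(table, "evcomplex_g") <- g
  table
}

#' Per-residue intra-protein coupling enrichment
#'
#' For each residue, the sum of corrected scores over the top-ranked
#' intra-segment pairs of its own protein that involve it, normalized by the
#' mean of that sum over all residues of the segment. Residues absent from
#' the top pairs get 0.
#'
#' @param table an `ec_table`.
#' @param top_n number of top intra rows per segment to use; defaults to the
#'   segment length.
#' @return numeric vector of length `L1 + L2` (concatenated coordinates).
#' @export
intra_enrichment <- function(table, top_n = NULL) {
  L1 <- attr(table, "L1"); L2 <- attr(table, "L2")
  L <- L1 + L2
  enrich <- numeric(L)
  for (seg in c("A", "B")) {
    seg_len <- if (seg == "A") L1 else L2
    if (seg_len == 0) next
    offset <- if (seg == "A") 0L else L1
    rows <- table[!table$is_inter & table$segment_i == seg, , drop = FALSE]
    if (nrow(rows) == 0L) next
    n <- min(top_n %||% seg_len, nrow(rows))
    rows <- rows[order(-rows$cn), , drop = FALSE][seq_len(n), , drop = FALSE]
    s <- numeric(seg_len)
    for (r in seq_len(nrow(rows))) {
      s[rows$pos_i[r]] <- s[rows$pos_i[r]] + rows$cn[r]
      s[rows$pos_j[r]] <- s[rows$pos_j[r]] + rows$cn[r]
    }
    mu <- mean(s)
    enrich[offset + seq_len(seg_len)] <- if (mu == 0) 0 else s / mu
  }
  enrich
}

#' Relative rank of coupling rows
#'
#' The rank of a row among all rows (intra and inter) by corrected score,
#' expressed as a fraction of the table size:
#' `(number of rows with strictly greater score + 1) / n_rows`, in (0, 1].
#'
#' @param table an `ec_table`.
#' @param rows row indices (into the table); default all rows.
#' @return numeric vector of relative ranks.
#' @export
relative_rank <- function(table, rows = seq_len(nrow(table))) {
  n <- nrow(table)
  vapply(rows, function(r) {
    (sum(table$cn > table$cn[r]) + 1) / n
  }, numeric(1))
}

#' Residue-level feature rows for the contact classifier
#'
#' Extracts the top `n_top` inter-protein couplings (by corrected score) and
#' attaches the classifier features: the EVcomplex scores, the conservation
#' of the more conserved of the two positions, the row's relative rank, and
#' the larger of the two residues' intra-protein enrichment. With structure
#' information, also the smaller of the two relative accessibilities and the
#' precision of the intra couplings ranked above the row. Labels come from a
#' distance map (`contact` when the minimum-atom distance is below
#' `contact_cutoff`); pairs unresolved in all structures stay `unknown`.
#' When fewer than `n_top` inter rows exist, rows are padded with zeros and
#' flagged.
#'
#' @param table an `ec_table` (the EVcomplex transform is applied when its
#'   columns are absent).
#' @param conservation per-column conservation over the concatenated
#'   alignment (length `L1 + L2`), e.g. from [column_stats()].
#' @param enrichment per-residue enrichment; computed via
#'   [intra_enrichment()] when NULL.
#' @param rsa optional per-column relative solvent accessibility (length
#'   `L1 + L2`, `NA` where unknown).
#' @param dmap optional [min_distance_map()] result for labels and the
#'   precision-above feature.
#' @param contact_cutoff distance label cutoff in Angstrom (default 8).
#' @param n_top number of inter rows to keep (default 10).
#' @return data frame of class `residue_features`.
#' @export
build_residue_features <- function(table, conservation, enrichment = NULL,
                                   rsa = NULL, dmap = NULL,
                                   contact_cutoff = 8, n_top = 10) {
  if (!any(table$is_inter))
    stop_coevppi("no inter-segment rows", "coevppi_degenerate_input")
  if (is.null(table$evcomplex_score)) table <- evcomplex_transform(table)
  if (is.null(enrichment)) enrichment <- intra_enrichment(table)
  inter_idx <- which(table$is_inter)
  inter_idx <- inter_idx[order(-table$cn[inter_idx])]
  take <- head(inter_idx, n_top)

  getd <- function(i, j) if (is.null(dmap)) NA_real_ else dmap_distance(dmap, i, j)
  max2 <- function(a, b) {
    v <- c(a, b); v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else max(v)
  }
  min2 <- function(a, b) {
    v <- c(a, b); v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else min(v)
  }

  # precision of intra rows ranked above a given global rank, over intra
  # rows with known distances
  intra_precision_above <- function(global_rank) {
    if (is.null(dmap)) return(NA_real_)
    above <- table[table$rank < global_rank & !table$is_inter, , drop = FALSE]
    if (nrow(above) == 0L) return(NA_real_)
    d <- mapply(getd, above$i, above$j)
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NA_real_)
    mean(d < contact_cutoff)
  }

  rows <- lapply(take, function(r) {
    i <- table$i[r]; j <- table$j[r]
    d <- getd(i, j)
    data.frame(
      i = i, j = j, cn = table$cn[r],
      evcomplex_raw = table$evcomplex_raw[r],
      evcomplex_score = table$evcomplex_score[r],
      conservation_max = max2(conservation[i], conservation[j]),
      inter_relative_rank = relative_rank(table, r),
      enrichment_max = max2(enrichment[i], enrichment[j]),
      rsa_min = if (is.null(rsa)) NA_real_ else min2(rsa[i], rsa[j]),
      precision_above = intra_precision_above(table$rank[r]),
      distance = d,
      label = if (is.na(d)) "unknown"
              else if (d < contact_cutoff) "contact" else "noncontact",
      padded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) < n_top) { # pad rule: zero features, flagged
    pad <- out[rep(1L, n_top - nrow(out)), , drop = FALSE]
    pad[] <- lapply(pad, function(col) {
      if (is.numeric(col)) 0 else if (is.logical(col)) TRUE else "unknown"
    })
    pad$i <- NA_integer_; pad$j <- NA_integer_
    pad$padded <- TRUE
    pad$label <- "unknown"
    pad$distance <- NA_real_
    out <- rbind(out, pad)
  }
  rownames(out) <- NULL
  class(out) <- c("residue_features", "data.frame")
  out
}

#' Feature sets of the two contact classifiers
#'
#' @param mode `"structure-free"` (EVcomplex score, conservation, relative
#'   rank, enrichment) or `"structure-aware"` (adds minimum accessibility
#'   and precision-above).
#' @return character vector of feature column names.
#' @export
residue_feature_names <- function(mode = c("structure-free",
                                           "structure-aware")) {
  mode <- match.arg(mode)
  base <- c("evcomplex_score", "conservation_max", "inter_relative_rank",
            "enrichment_max")
  if (mode == "structure-aware") c(base, "rsa_min", "precision_above")
  else base
}

# glmnet-backed penalized logistic fit at a LIBLINEAR-style C.
# lambda = 1 / (n * C): the penalty weight applied when the log-likelihood
# is summed (not averaged) over observations.
fit_penalized_logistic <- function(X, y, C, alpha) {
  n <- nrow(X)
  single <- ncol(X) == 1L
  if (single) # glmnet needs >= 2 columns; pad with an inert zero column
    X <- cbind(X, `.pad` = 0)
  lambda <- 1 / (n * C)
  path <- sort(unique(lambda * 2^(6:0)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  co <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  w <- setNames(co[-1], colnames(X))
  if (single) w <- w[-length(w)]
  list(bias = co[1], weights = w, lambda = lambda)
}

new_logistic_model <- function(features, weights, bias, penalty, cv = NULL,
                               seed = NA_integer_, selected = NULL) {
  stopifnot(all(is.finite(weights)), is.finite(bias))
  structure(list(features = features, weights = weights, bias = bias,
                 penalty = penalty, cv = cv, seed = seed,
                 selected = selected %||% features),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("logistic_model (%s, C = %g): bias %.4f\n", x$penalty$type,
              x$penalty$C, x$bias))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predicted probabilities from a logistic model
#' @param object a `logistic_model`.
#' @param newdata data frame or matrix containing the model's features.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  as.numeric(plogis(object$bias + X %*% object$weights))
}

#' Train the residue-contact logistic model
#'
#' L1-penalized logistic regression of contact labels on residue-level
#' features, with the regularization weight interpreted as the LIBLINEAR
#' `C` parameter (default 0.05). Ten-fold cross-validated precision and
#' recall (at probability 0.5) are reported; folds are assigned under the
#' given seed, making training reproducible.
#'
#' @param features a data frame with a `label` column (`contact` /
#'   `noncontact`; `unknown` rows are dropped) or 0/1 labels in `label`.
#' @param feature_names feature columns; default structure-free set (use
#'   [residue_feature_names()]).
#' @param reg_weight regularization weight C (default 0.05).
#' @param folds cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return a `logistic_model` with a `cv` field (precision, recall,
#'   accuracy).
#' @export
train_residue_model <- function(features,
                                feature_names = residue_feature_names(),
                                reg_weight = 0.05, folds = 10, seed = 1) {
  lab <- features$label
  if (is.character(lab) || is.factor(lab)) {
    keep <- lab %in% c("contact", "noncontact")
    features <- features[keep, , drop = FALSE]
    y <- as.integer(features$label == "contact")
  } else {
    y <- as.integer(lab)
  }
  if (length(unique(y)) < 2L)
    stop_coevppi("both contact classes required for training",
                 "coevppi_training_error")
  X <- as.matrix(features[, feature_names, drop = FALSE])
  if (anyNA(X))
    stop_coevppi("missing feature values; drop or impute first",
                 "coevppi_training_error")
  fit <- fit_penalized_logistic(X, y, C = reg_weight, alpha = 1)

  n <- nrow(X)
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2L) { pred[!tr] <- mean(y[tr]); next }
    ft <- fit_penalized_logistic(X[tr, , drop = FALSE], y[tr],
                                 C = reg_weight, alpha = 1)
    pred[!tr] <- plogis(ft$bias +
                          X[!tr, , drop = FALSE] %*% ft$weights)
  }
  yhat <- as.integer(pred >= 0.5)
  tp <- sum(yhat == 1 & y == 1)
  cv <- list(precision = if (sum(yhat) > 0) tp / sum(yhat) else NA_real_,
             recall = if (sum(y) > 0) tp / sum(y) else NA_real_,
             accuracy = mean(yhat == y), folds = folds)
  new_logistic_model(feature_names, fit$weights, fit$bias,
                     penalty = list(type = "l1", C = reg_weight,
                                    lambda = fit$lambda),
                     cv = cv, seed = seed)
}

#' Train the protein-interaction logistic model
#'
#' Two-stage fit on pair-level features (the ten residue-contact
#' probabilities plus the relative rank of the best inter coupling): an L1
#' stage (`C = 0.1`) selects features with nonzero weight, then an L2 refit
#' on the survivors gives the final model. Classes are balanced to equal
#' counts by downsampling the larger class without replacement under the
#' seed.
#'
#' @param features data frame with 0/1 `label` column and feature columns.
#' @param feature_names the 11 feature columns (default `prob_1..prob_10`,
#'   `top_rank`).
#' @param select_weight L1 stage C (default 0.1).
#' @param final_weight L2 stage C (default 1).
#' @param seed RNG seed for class balancing.
#' @return a `logistic_model`; `selected` records the surviving features.
#' @export
train_interaction_model <- function(features,
                                    feature_names = c(paste0("prob_", 1:10),
                                                      "top_rank"),
                                    select_weight = 0.1, final_weight = 1,
                                    seed = 1) {
  y <- as.integer(features$label)
  if (length(unique(y)) < 2L)
    stop_coevppi("both classes required", "coevppi_training_error")
  pos <- which(y == 1); neg <- which(y == 0)
  n <- min(length(pos), length(neg))
  keep <- withr::with_seed(seed, c(sample(pos, n), sample(neg, n)))
  keep <- sort(keep)
  X <- as.matrix(features[keep, feature_names, drop = FALSE])
  y <- y[keep]

  sel <- fit_penalized_logistic(X, y, C = select_weight, alpha = 1)
  surv <- names(sel$weights)[sel$weights != 0]
  if (length(surv) == 0L)
    stop_coevppi("L1 selection removed all features",
                 "coevppi_training_error")
  fin <- fit_penalized_logistic(X[, surv, drop = FALSE], y,
                                C = final_weight, alpha = 0)
  w <- setNames(numeric(length(feature_names)), feature_names)
  w[surv] <- fin$weights
  new_logistic_model(feature_names, w, fin$bias,
                     penalty = list(type = "l1+l2", C = select_weight,
                                    C_final = final_weight,
                                    lambda = fin$lambda),
                     seed = seed, selected = surv)
}

#' Score a protein pair for physical interaction
#'
#' Applies the interaction model to the residue-contact probabilities of the
#' pair's top-10 inter couplings (sorted by coupling score, padded with
#' zeros when fewer) and the relative rank of the best inter coupling.
#'
#' @param residue_probs numeric vector of up to 10 contact probabilities,
#'   sorted by the underlying coupling score descending.
#' @param top_rank relative rank of the highest-scoring inter coupling.
#' @param model an interaction `logistic_model`.
#' @param residue_threshold optional residue-probability call threshold; the
#'   number of probabilities at or above it is reported as `n_calls`.
#' @return object of class `interaction_score`: list with `probability`,
#'   `residue_probs`, `top_rank`, `n_calls`.
#' @export
score_protein_interaction <- function(residue_probs, top_rank, model,
                                      residue_threshold = NULL) {
  if (is.null(model))
    stop_coevppi("interaction model missing", "coevppi_configuration_error")
  probs <- c(residue_probs, numeric(10))[1:10]
  feats <- as.data.frame(as.list(setNames(c(probs, top_rank),
                                          c(paste0("prob_", 1:10),
                                            "top_rank"))))
  p <- predict(model, feats)
  structure(list(probability = p, residue_probs = residue_probs,
                 top_rank = top_rank,
                 n_calls = if (is.null(residue_threshold)) NA_integer_
                           else sum(residue_probs >= residue_threshold)),
            class = "interaction_score")
}

#' Calibrate a decision threshold on scores
#'
#' Enumerates all cut points (the unique score values; a prediction is
#' positive when `score >= threshold`). In `precision` mode, the smallest
#' threshold whose empirical precision reaches `target`; in `fpr` mode, the
#' smallest threshold whose false-positive rate is at most `target`. The
#' returned threshold is the midpoint between the selected cut point and the
#' next lower score when one exists. Unattainable targets are flagged and
#' the best achievable operating point returned.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) true labels.
#' @param mode `"precision"` or `"fpr"`.
#' @param target target precision (>=) or FPR (<=).
#' @return list with `threshold`, `achieved`, `attainable`, `mode`,
#'   `target`.
#' @export
calibrate_threshold <- function(scores, labels, mode = c("precision", "fpr"),
                                target) {
  mode <- match.arg(mode)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop_coevppi("both classes required", "coevppi_parameter_error")
  cuts <- sort(unique(scores))
  stat <- vapply(cuts, function(th) {
    pos <- scores >= th
    if (mode == "precision") {
      if (!any(pos)) NA_real_ else mean(y[pos] == 1)
    } else {
      sum(pos & y == 0) / sum(y == 0)
    }
  }, numeric(1))
  ok <- if (mode == "precision") !is.na(stat) & stat >= target
        else stat <= target
  mid <- function(th) {
    lower <- cuts[cuts < th]
    if (length(lower) == 0L) th else (th + max(lower)) / 2
  }
  if (any(ok)) {
    k <- which(ok)[1] # smallest qualifying cut point
    list(threshold = mid(cuts[k]), achieved = stat[k], attainable = TRUE,
         mode = mode, target = target)
  } else {
    k <- if (mode == "precision") which.max(stat) else which.min(stat)
    list(threshold = mid(cuts[k]), achieved = stat[k], attainable = FALSE,
         mode = mode, target = target)
  }
}

#' Coevolution-diagonal artifact check
#'
#' Flags concatenated alignments whose strongest inter-protein couplings lie
#' along the A-to-B diagonal (position i in protein A coupled to position i
#' in protein B), a signature of homologous or duplicated segments rather
#' than a real interface.
#'
#' @param table an `ec_table`.
#' @param band diagonal half-width in segment-local coordinates (default 2).
#' @param n_top number of top inter rows examined (default 10).
#' @param frac fraction of examined rows on the diagonal that triggers the
#'   flag (default 0.5).
#' @return logical.
#' @export
diagonal_artifact_check <- function(table, band = 2, n_top = 10,
                                    frac = 0.5) {
  inter <- table[table$is_inter, , drop = FALSE]
  if (nrow(inter) == 0L) return(FALSE)
  inter <- inter[order(-inter$cn), , drop = FALSE]
  top <- head(inter, n_top)
  mean(abs(top$pos_i - top$pos_j) <= band) >= frac
}

#' Export docking distance restraints
#'
#' Selects the top-`n_top` inter-protein pairs under the structure-free and
#' structure-aware scores (their union), and writes one unambiguous distance
#' restraint per pair on the C-beta atoms (C-alpha for glycine), with an
#' effective distance of 5 Angstrom and bounds of +/- 2 Angstrom, in the
#' HADDOCK/CNS `assign` table dialect.
#'
#' @param table an `ec_table`.
#' @param residue_map data frame mapping concatenated alignment positions to
#'   structure residues: columns `alignment_pos`, `chain`, `resnum`, and
#'   optionally `aa` (one-letter code, used to pick CA for glycine).
#' @param scores_free,scores_aware optional numeric vectors of model
#'   probabilities for the inter rows of `table` (in table order of the
#'   inter rows); the corrected score is used when NULL.
#' @param n_top pairs per scoring mode (default 5).
#' @param distance,lower,upper restraint geometry in Angstrom
#'   (defaults 5, 2, 2).
#' @return character vector of restraint lines; attribute `n_skipped` counts
#'   pairs dropped because a residue was unmappable (with a warning).
#' @export
export_restraints <- function(table, residue_map, scores_free = NULL,
                              scores_aware = NULL, n_top = 5,
                              distance = 5.0, lower = 2.0, upper = 2.0) {
  inter <- which(table$is_inter)
  if (length(inter) == 0L)
    stop_coevppi("no inter-segment rows", "coevppi_degenerate_input")
  pick <- function(sc) {
    sc <- sc %||% table$cn[inter]
    inter[order(-sc)][seq_len(min(n_top, length(inter)))]
  }
  chosen <- sort(unique(c(pick(scores_free), pick(scores_aware))))
  lookup <- function(pos) {
    k <- which(residue_map$alignment_pos == pos)
    if (length(k) == 0L) return(NULL)
    k <- k[1]
    aa <- if ("aa" %in% names(residue_map)) toupper(residue_map$aa[k])
          else NA_character_
    list(chain = residue_map$chain[k], resnum = residue_map$resnum[k],
         atom = if (!is.na(aa) && aa %in% c("G", "GLY")) "CA" else "CB")
  }
  lines <- character(); skipped <- 0L
  for (r in chosen) {
    a <- lookup(table$i[r]); b <- lookup(table$j[r])
    if (is.null(a) || is.null(b)) { skipped <- skipped + 1L; next }
    lines <- c(lines, sprintf(
      "assign (segid %s and resi %d and name %s) (segid %s and resi %d and name %s) %.1f %.1f %.1f",
      a$chain, a$resnum, a$atom, b$chain, b$resnum, b$atom,
      distance, lower, upper))
  }
  if (skipped > 0L)
    warning(sprintf("%d restraint pair(s) skipped: unmappable residues",
                    skipped))
  structure(lines, n_skipped = skipped)
}

#' Serialize a logistic model to JSON
#' @param model a `logistic_model`.
#' @param path output path.
#' @export
write_logistic_model <- function(model, path) {
  jsonlite::write_json(
    list(features = model$features, weights = as.list(model$weights),
         bias = model$bias, penalty = model$penalty, seed = model$seed,
         selected = model$selected),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a logistic model from JSON
#' @param path JSON path written by [write_logistic_model()].
#' @return a `logistic_model`.
#' @export
read_logistic_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_logistic_model(d$features, unlist(d$weights), d$bias, d$penalty,
                     seed = d$seed, selected = d$selected)
}
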