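#' Construct a Potts model
#'
#' Pairwise Markov random field over L aligned positions and a q-letter
#' alphabet: per-site fields `h` and per-pair coupling blocks `J`. Couplings
#' are stored once per unordered pair (i < j) and are symmetric under
#' `(i,a,j,b) <-> (j,b,i,a)`.
#'
#' @param h q x L numeric matrix of fields.
#' @param J numeric vector of coupling blocks in upper-triangle pair order,
#'   q*q entries per pair, element (a, b) of pair (i, j) at
#'   `(pair-1)*q^2 + (a-1)*q + b` with `a` the state at `i`.
#' @param alphabet state alphabet (length q); the gap character, when
#'   present, is excluded from gauge fixing and Frobenius norms.
#' @param lambda_h,lambda_J L2 regularization weights used at fit time.
#' @return object of class `potts_model`.
#' @export
potts_model <- function(h, J, alphabet, lambda_h = NA_real_,
                        lambda_J = NA_real_) {
  q <- nrow(h); L <- ncol(h)
  stopifnot(length(alphabet) == q,
            length(J) == (L * (L - 1) / 2) * q * q)
  structure(list(h = h, J = J, q = q, L = L, alphabet = alphabet,
                 gap_state = gap_state_of(alphabet),
                 lambda_h = lambda_h, lambda_J = lambda_J),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("potts_model: L = %d sites, q = %d states (%s)\n", x$L, x$q,
              if (x$gap_state > 0) "incl. gap" else "no gap"))
  invisible(x)
}

# 0-based upper-triangle pair index (i < j, both 1-based here).
pair_index <- function(i, j, L) {
  (i - 1) * L - (i - 1) * i / 2 + (j - i - 1)
}

#' Coupling block of a Potts model
#' @param model a [potts_model()].
#' @param i,j site indices (any order, i != j); the returned q x q matrix has
#'   rows indexed by the state at `i` and columns by the state at `j`.
#' @return q x q numeric matrix.
#' @export
potts_J <- function(model, i, j) {
  q <- model$q
  swap <- i > j
  if (swap) { tmp <- i; i <- j; j <- tmp }
  p <- pair_index(i, j, model$L)
  B <- matrix(model$J[(p * q * q + 1):(p * q * q + q * q)], nrow = q,
              byrow = TRUE) # stored row-major in state-at-i
  if (swap) t(B) else B
}

# parameter vector <-> model (layout shared with the C++ objective)
model_to_par <- function(model) c(as.numeric(model$h), model$J)
par_to_model <- function(par, L, q, alphabet, lambda_h, lambda_J) {
  hlen <- L * q
  potts_model(matrix(par[seq_len(hlen)], nrow = q), par[-seq_len(hlen)],
              alphabet, lambda_h, lambda_J)
}

#' Regularized negative log pseudo-likelihood and its gradient
#'
#' The pseudo-likelihood replaces the intractable Potts likelihood with the
#' product of per-site conditionals: the site-wise softmax of
#' `h_i(a) + sum_{j != i} J_ij(a, x_j)`. Rows enter weighted; the penalty is
#' `lambda_h * ||h||^2 + lambda_J * ||J||^2` with each coupling block counted
#' once.
#'
#' @param model a [potts_model()].
#' @param encoded integer matrix of 1-based states (rows = sequences), e.g.
#'   from [msa_encode()].
#' @param weights positive per-row weights.
#' @return list with `value` (scalar objective) and `gradient` (named list
#'   with `h` (q x L) and `J` (vector in block layout)).
#' @export
plm_objective <- function(model, encoded, weights) {
  q <- model$q; L <- model$L
  if (ncol(encoded) != L)
    stop_coevppi("encoded alignment width != model L",
                 "coevppi_parameter_error")
  if (length(weights) != nrow(encoded) || any(weights <= 0))
    stop_coevppi("weights must be positive, one per row",
                 "coevppi_parameter_error")
  if (any(encoded < 1L) || any(encoded > q))
    stop_coevppi("encoded states outside [1, q]", "coevppi_parameter_error")
  res <- cpp_plm_obj_grad(model_to_par(model), encoded - 1L, weights, q,
                          model$lambda_h, model$lambda_J)
  g <- res$gradient
  hlen <- L * q
  list(value = res$value,
       gradient = list(h = matrix(g[seq_len(hlen)], nrow = q),
                       J = g[-seq_len(hlen)]))
}

#' Fit a Potts model by pseudo-likelihood maximization
#'
#' Minimizes the weighted negative log pseudo-likelihood with L2 penalties
#' by L-BFGS from a zero initialization, which makes the fit deterministic
#' given the data. The coupling penalty is scaled as
#' `lambda_J = lambda_base * (q - 1) * (L - 1)`.
#'
#' @param x an [msa()] or `paired_msa`. Rows above 50% gaps should already
#'   have been removed ([filter_gappy_rows()]); weights are computed at
#'   `theta = 0.8` when absent.
#' @param lambda_h field regularization weight (default 0.01).
#' @param lambda_base base coupling regularization weight before the
#'   `(q-1)(L-1)` scaling (default 0.01).
#' @param maxit iteration cap (default 500).
#' @param pgtol projected-gradient tolerance passed to L-BFGS (default 1e-4).
#' @param alphabet state alphabet; defaults to the alignment's own (the 20
#'   amino acids plus gap for real alignments).
#' @return a fitted [potts_model()] carrying `n_eff` and the encoding.
#' @export
fit_plm <- function(x, lambda_h = 0.01, lambda_base = 0.01, maxit = 500,
                    pgtol = 1e-4, alphabet = NULL) {
  m <- if (inherits(x, "paired_msa")) x$msa else x
  if (!inherits(m, "msa"))
    stop_coevppi("x must be an msa or paired_msa", "coevppi_parameter_error")
  if (is.null(m$weights)) m <- compute_weights(m)
  X <- msa_encode(m, alphabet)
  alphabet <- attr(X, "alphabet")
  q <- length(alphabet); L <- m$L
  lambda_J <- lambda_base * (q - 1) * (L - 1)
  npar <- L * q + (L * (L - 1) / 2) * q * q

  X0 <- X - 1L
  w <- m$weights
  cache <- new.env(parent = emptyenv())
  fg <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- cpp_plm_obj_grad(par, X0, w, q, lambda_h, lambda_J)
    cache$par <- par; cache$res <- res
    res
  }
  opt <- optim(numeric(npar), fn = function(p) fg(p)$value,
               gr = function(p) fg(p)$gradient, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = pgtol, factr = 1e7))
  if (opt$convergence == 52L)
    warning("L-BFGS line search terminated early: ", opt$message)
  if (opt$convergence != 0L && opt$convergence != 52L) {
    gnorm <- max(abs(fg(opt$par)$gradient))
    if (opt$convergence == 1L)
      stop_coevppi(sprintf(
        "PLM did not converge within %d iterations (max |grad| = %.3g)",
        maxit, gnorm), "coevppi_convergence_error", gradient_norm = gnorm)
    stop_coevppi(sprintf("optimizer failure (%d): %s", opt$convergence,
                         opt$message), "coevppi_convergence_error",
                 gradient_norm = gnorm)
  }
  model <- par_to_model(opt$par, L, q, alphabet, lambda_h, lambda_J)
  model$n_eff <- m$n_eff
  model$objective <- opt$value
  model$iterations <- opt$counts[["function"]]
  model
}

#' Frobenius-norm coupling scores in the zero-sum gauge
#'
#' Each coupling block is shifted to the zero-sum gauge over amino-acid
#' states (the gap state, when present, is excluded), then scored by its
#' Frobenius norm. The result is symmetric and nonnegative with a zero
#' diagonal.
#'
#' @param model a fitted [potts_model()].
#' @return L x L numeric matrix of scores.
#' @export
frobenius_scores <- function(model) {
  L <- model$L; q <- model$q
  keep <- if (model$gap_state > 0) setdiff(seq_len(q), model$gap_state)
          else seq_len(q)
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      B <- potts_J(model, i, j)[keep, keep, drop = FALSE]
      B <- B - outer(rowMeans(B), rep(1, ncol(B))) -
        outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
      S[i, j] <- S[j, i] <- sqrt(sum(B^2))
    }
  }
  S
}

#' Average product correction
#'
#' Removes the rank-one background of a symmetric score matrix:
#' `cn_ij = s_ij - mean_i(s) * mean_j(s) / mean(s)`, with all means taken
#' over off-diagonal entries. A zero matrix maps to zeros.
#'
#' @param scores square symmetric numeric matrix.
#' @return corrected matrix of the same shape (diagonal zero).
#' @export
apc <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores))
    stop_coevppi("scores must be a square matrix", "coevppi_parameter_error")
  if (max(abs(scores - t(scores))) > 1e-8)
    stop_coevppi("scores must be symmetric", "coevppi_parameter_error")
  L <- nrow(scores)
  if (L < 2L) return(scores * 0)
  off <- scores; diag(off) <- NA
  rm_ <- rowMeans(off, na.rm = TRUE)
  grand <- mean(off, na.rm = TRUE)
  if (grand == 0) return(scores * 0)
  out <- scores - outer(rm_, rm_) / grand
  diag(out) <- 0
  out
}

#' Build a ranked evolutionary-coupling table
#'
#' Flattens a corrected score matrix over a (possibly concatenated)
#' alignment into ranked residue-pair records. Intra-segment pairs within
#' `diag_band` positions of the diagonal are excluded (they reflect chain
#' adjacency, not contacts); cross-segment pairs are never excluded. Ranking
#' is by score descending, ties broken by (i, j) ascending.
#'
#' @param cn L x L corrected (APC) score matrix, L = L1 + L2.
#' @param L1 first-segment length; use `L2 = 0` for a monomer table.
#' @param L2 second-segment length.
#' @param n_eff effective sequence count of the alignment (carried as
#'   metadata for downstream normalization).
#' @param fn optional matrix of uncorrected Frobenius scores.
#' @param diag_band intra-segment exclusion half-width (default 5:
#'   `|i - j| <= 5` dropped).
#' @return data frame of class `ec_table` with columns `i`, `j`
#'   (concatenated 1-based), `segment_i`, `segment_j`, `pos_i`, `pos_j`
#'   (segment-local), `fn`, `cn`, `is_inter`, `rank`; attributes `L1`, `L2`,
#'   `n_eff`.
#' @export
build_ec_table <- function(cn, L1, L2 = 0, n_eff = NA_real_, fn = NULL,
                           diag_band = 5) {
  L <- nrow(cn)
  if (L != L1 + L2 && L2 > 0)
    stop_coevppi("matrix dimension != L1 + L2", "coevppi_parameter_error")
  if (L2 == 0) L1 <- L
  idx <- which(upper.tri(cn), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  seg_i <- ifelse(i <= L1, "A", "B")
  seg_j <- ifelse(j <= L1, "A", "B")
  intra <- seg_i == seg_j
  keep <- !(intra & (j - i) <= diag_band)
  i <- i[keep]; j <- j[keep]
  seg_i <- seg_i[keep]; seg_j <- seg_j[keep]
  tab <- data.frame(
    i = i, j = j, segment_i = seg_i, segment_j = seg_j,
    pos_i = ifelse(seg_i == "A", i, i - L1),
    pos_j = ifelse(seg_j == "A", j, j - L1),
    fn = if (is.null(fn)) NA_real_ else fn[cbind(i, j)],
    cn = cn[cbind(i, j)],
    is_inter = seg_i != seg_j,
    stringsAsFactors = FALSE)
  ord <- order(-tab$cn, tab$i, tab$j)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "L1") <- L1; attr(tab, "L2") <- L2; attr(tab, "n_eff") <- n_eff
  class(tab) <- c("ec_table", "data.frame")
  tab
}

#' Z-scores of inter-protein couplings
#'
#' Standardizes the corrected scores of inter-segment rows against the
#' distribution of all inter-segment rows; intra rows get `NA`.
#'
#' @param table an `ec_table`.
#' @return the table with a `z` column; when the inter scores have zero
#'   variance (or fewer than 2 rows) `z` is `NA` and attribute
#'   `z_degenerate` is set.
#' @export
inter_zscores <- function(table) {
  inter <- table$is_inter
  table$z <- NA_real_
  if (sum(inter) < 2L || sd(table$cn[inter]) == 0) {
    attr(table, "z_degenerate") <- TRUE
    return(table)
  }
  mu <- mean(table$cn[inter]); s <- sd(table$cn[inter])
  table$z[inter] <- (table$cn[inter] - mu) / s
  attr(table, "z_degenerate") <- FALSE
  table
}

#' Write an EC table as CSV
#' @param table an `ec_table`.
#' @param path output path.
#' @export
write_ec_table <- function(table, path) {
  meta <- sprintf("# L1=%d L2=%d n_eff=%s", attr(table, "L1"),
                  attr(table, "L2"),
                  format(attr(table, "n_eff"), digits = 10))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}
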