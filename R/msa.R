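#' Construct a multiple sequence alignment object
#'
#' Lightweight container for an aligned sequence set: identifiers, optional
#' per-sequence species labels, the aligned strings, the query row, and (once
#' computed) per-sequence weights and the effective sequence count `n_eff`.
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of aligned sequences (equal lengths, `-` gap).
#' @param species optional per-sequence species labels (`NA` where unknown).
#' @param query_index row index of the query sequence (default 1).
#' @param alphabet state alphabet used for model encoding; defaults to the
#'   20 canonical amino acids plus gap.
#' @return object of class `msa` with fields `ids`, `species`, `seqs`,
#'   `query_index`, `L`, `weights` (NULL until [compute_weights()]), `n_eff`.
#' @export
msa <- function(ids, seqs, species = NULL, query_index = 1L,
                alphabet = aa_alphabet()) {
  if (length(ids) != length(seqs))
    stop_coevppi("ids and seqs lengths differ", "coevppi_format_error")
  if (length(seqs) == 0L)
    stop_coevppi("empty alignment", "coevppi_empty_input")
  nc <- nchar(seqs)
  if (length(unique(nc)) != 1L)
    stop_coevppi("ragged alignment: sequences differ in length",
                 "coevppi_format_error")
  if (is.null(species)) species <- rep(NA_character_, length(ids))
  query_index <- as.integer(query_index)
  stopifnot(query_index >= 1L, query_index <= length(seqs))
  structure(list(ids = unname(as.character(ids)),
                 species = unname(as.character(species)),
                 seqs = unname(toupper(seqs)), query_index = query_index,
                 L = unname(nc[1]), weights = NULL, n_eff = NULL,
                 alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (query row %d)\n",
              length(x$ids), x$L, x$query_index))
  if (!is.null(x$n_eff))
    cat(sprintf("  n_eff = %.2f (n_eff/L = %.3f)\n", x$n_eff, x$n_eff / x$L))
  invisible(x)
}

# Alignment as a character matrix (rows = sequences).
msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$seqs, "", fixed = TRUE))
}

#' Encode an alignment as integer states
#'
#' Maps each character to its index in the alphabet. Characters outside the
#' alphabet (nonstandard amino acids such as B, Z, U, O, X and the `.`
#' character) are mapped to the gap state, or to the last state if the
#' alphabet has no gap.
#'
#' @param m an [msa()] object.
#' @param alphabet state alphabet; defaults to the alignment's own.
#' @return integer matrix (n x L) of 1-based states, with attributes
#'   `alphabet` and `gap_state`.
#' @export
msa_encode <- function(m, alphabet = NULL) {
  alphabet <- alphabet %||% m$alphabet %||% aa_alphabet()
  cm <- msa_matrix(m)
  gs <- gap_state_of(alphabet)
  enc <- match(cm, alphabet)
  enc[is.na(enc)] <- if (gs > 0L) gs else length(alphabet)
  X <- matrix(enc, nrow = nrow(cm))
  attr(X, "alphabet") <- alphabet
  attr(X, "gap_state") <- gs
  X
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA, A2M or Stockholm alignments. Residues are uppercased and `-`
#' is the gap character. In A2M input, lowercase letters and `.` are insert
#' states and are removed from every row before the alignment is checked for
#' equal lengths. Stockholm `#=GC`/`#=GS` annotation lines are ignored.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"a2m"`, `"stockholm"`, or `"auto"`
#'   (by file extension; `.sto`/`.stk` mean Stockholm, `.a2m` A2M).
#' @param query_index row of the query sequence (default 1).
#' @return an [msa()] object with species labels parsed from the headers.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a2m",
                                            "stockholm"),
                           query_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_coevppi(paste0("no such file: ", path), "coevppi_io_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sto = , stk = , stockholm = "stockholm",
                     a2m = "a2m", "fasta")
  }
  if (format == "stockholm") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(aln)
    ids <- names(seqs)
  } else {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L)
      stop_coevppi("empty alignment file", "coevppi_empty_input")
    seqs <- as.character(ss)
    ids <- names(ss)
    if (format == "a2m") # drop insert states (lowercase and '.')
      seqs <- gsub("[a-z.]", "", seqs)
  }
  seqs <- gsub(".", "-", toupper(seqs), fixed = TRUE)
  nc <- nchar(seqs)
  if (length(seqs) == 0L || all(nc == 0L))
    stop_coevppi("empty alignment file", "coevppi_empty_input")
  if (length(unique(nc)) != 1L)
    stop_coevppi("ragged alignment: sequences differ in length",
                 "coevppi_format_error")
  m <- msa(ids, seqs, species = vapply(ids, parse_species, ""),
           query_index = query_index)
  m
}

#' Write an alignment as FASTA
#'
#' @param m an [msa()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(m, path) {
  out <- character(2L * length(m$ids))
  out[c(TRUE, FALSE)] <- paste0(">", m$ids)
  out[c(FALSE, TRUE)] <- m$seqs
  writeLines(out, path)
  invisible(path)
}

#' Sequence weights and effective sequence count
#'
#' Downweights redundant sequences: each row's weight is the reciprocal of
#' the number of alignment rows (itself included) with pairwise identity at
#' or above `theta`. `n_eff` is the sum of weights. Pairwise identity is the
#' number of matching positions divided by the number of columns where both
#' rows are non-gap.
#'
#' @param m an [msa()] object.
#' @param theta identity threshold in (0, 1]; default 0.8, i.e. sequences
#'   with more than 80% identical homologs are downweighted.
#' @return the alignment with `weights` and `n_eff` filled in.
#' @export
compute_weights <- function(m, theta = 0.8) {
  if (!is.numeric(theta) || theta <= 0 || theta > 1)
    stop_coevppi("theta must be in (0, 1]", "coevppi_parameter_error")
  X <- msa_encode(m)
  w <- cpp_seq_weights(X, theta, attr(X, "gap_state"))
  m$weights <- as.numeric(w)
  m$n_eff <- sum(w)
  m$theta <- theta
  m
}

#' Pairwise identity of alignment rows to a reference row
#'
#' Identity = matches / (columns where both rows are non-gap); 0 when no
#' column qualifies. Nonstandard letters count as gaps.
#'
#' @param m an [msa()] object.
#' @param ref reference row index; defaults to the query row.
#' @return numeric vector of identities, one per row (the reference gets 1).
#' @export
identity_to_ref <- function(m, ref = m$query_index) {
  X <- msa_encode(m)
  gs <- attr(X, "gap_state")
  r <- X[ref, ]
  ok_ref <- r != gs
  apply(X, 1L, function(row) {
    both <- ok_ref & row != gs
    if (!any(both)) return(0)
    sum(row[both] == r[both]) / sum(both)
  })
}

#' Per-column conservation from amino-acid frequencies
#'
#' One minus the column's normalized Shannon entropy over the 20 canonical
#' amino acids: `C = 1 - H / log2(20)` with `H = -sum f_k log2 f_k`. Gap
#' mass is excluded and the frequencies renormalized over amino acids.
#'
#' @param f numeric vector of amino-acid frequencies (length 20, or any
#'   nonnegative vector summing to at most 1 before renormalization).
#' @return conservation in \[0, 1\]; `NA` for an all-gap column (zero mass).
#' @export
conservation <- function(f) {
  if (any(f < 0)) stop_coevppi("negative frequency", "coevppi_parameter_error")
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  f <- f[f > 0] / tot
  H <- -sum(f * log2(f))
  1 - H / log2(20)
}

#' Column-level gap and conservation statistics
#'
#' Gap fractions use unweighted counts, with nonstandard letters counted as
#' gaps; conservation is computed per [conservation()]. The coverage flag is
#' true when at least 80% of columns have gap fraction below 50% (the
#' alignment coverage rule).
#'
#' @param m an [msa()] object.
#' @param max_gap per-column gap-fraction cutoff for "covered" (default 0.5).
#' @param min_coverage required fraction of covered columns (default 0.8).
#' @return object of class `column_stats`: list with numeric vectors
#'   `gap_fraction` and `conservation` (length L) and logical `coverage_pass`.
#' @export
column_stats <- function(m, max_gap = 0.5, min_coverage = 0.8) {
  aa <- aa_alphabet(gap = FALSE)
  cm <- msa_matrix(m)
  is_aa <- matrix(cm %in% aa, nrow = nrow(cm))
  gap_fraction <- 1 - colMeans(is_aa)
  cons <- vapply(seq_len(m$L), function(k) {
    col <- cm[is_aa[, k], k]
    if (length(col) == 0L) return(NA_real_)
    conservation(tabulate(match(col, aa), nbins = 20L) / length(col))
  }, numeric(1))
  structure(list(gap_fraction = gap_fraction, conservation = cons,
                 coverage_pass = mean(gap_fraction < max_gap) >= min_coverage),
            class = "column_stats")
}

#' @export
as.data.frame.column_stats <- function(x, ...) {
  data.frame(column = seq_along(x$gap_fraction),
             gap_fraction = x$gap_fraction,
             conservation = x$conservation)
}

#' Write column statistics as CSV (1-based column index)
#' @param x a `column_stats` object.
#' @param path output path.
#' @export
write_column_stats <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Remove rows dominated by gaps
#'
#' Drops sequences whose gap fraction exceeds `max_gap` (strictly); the
#' query row is never removed. Weights are invalidated and must be
#' recomputed.
#'
#' @param m an [msa()] object.
#' @param max_gap maximum tolerated row gap fraction (default 0.5).
#' @return filtered [msa()].
#' @export
filter_gappy_rows <- function(m, max_gap = 0.5) {
  aa <- aa_alphabet(gap = FALSE)
  cm <- msa_matrix(m)
  gapfrac <- 1 - rowMeans(matrix(cm %in% aa, nrow = nrow(cm)))
  keep <- gapfrac <= max_gap
  keep[m$query_index] <- TRUE
  if (!any(keep))
    stop_coevppi("filtering would empty the alignment",
                 "coevppi_degenerate_input")
  out <- msa(m$ids[keep], m$seqs[keep], m$species[keep],
             query_index = match(m$query_index, which(keep)),
             alphabet = m$alphabet)
  out
}

#' Select the best alignment among bit-score candidates
#'
#' Mirrors alignment selection across homology-search bit-score factors:
#' among candidates passing the column-coverage rule, the one with the
#' largest `n_eff` wins.
#'
#' @param candidates list of [msa()] objects with weights computed.
#' @return list of class `alignment_selection` with `eligible` (logical),
#'   `index` (chosen candidate, `NA` if none pass), `msa` (chosen alignment
#'   or NULL) and `n_eff`.
#' @export
select_best_alignment <- function(candidates) {
  if (length(candidates) == 0L)
    stop_coevppi("no candidate alignments", "coevppi_parameter_error")
  neff <- vapply(candidates, function(m) {
    if (is.null(m$n_eff))
      stop_coevppi("candidate lacks weights; run compute_weights()",
                   "coevppi_parameter_error")
    m$n_eff
  }, numeric(1))
  pass <- vapply(candidates, function(m) column_stats(m)$coverage_pass,
                 logical(1))
  if (!any(pass))
    return(structure(list(eligible = FALSE, index = NA_integer_, msa = NULL,
                          n_eff = NA_real_), class = "alignment_selection"))
  idx <- which(pass)[which.max(neff[pass])]
  structure(list(eligible = TRUE, index = idx, msa = candidates[[idx]],
                 n_eff = neff[idx]), class = "alignment_selection")
}

#' Monomer alignment eligibility
#'
#' A monomer alignment qualifies for coupling analysis when it passes the
#' 80% column-coverage rule and its diversity satisfies
#' `n_eff / L >= min_ratio` (default 2.5).
#'
#' @param m an [msa()] with weights computed.
#' @param min_ratio minimum `n_eff/L` (default 2.5).
#' @return logical.
#' @export
monomer_eligibility <- function(m, min_ratio = 2.5) {
  if (is.null(m$n_eff))
    stop_coevppi("weights not computed; run compute_weights()",
                 "coevppi_parameter_error")
  isTRUE(column_stats(m)$coverage_pass) && (m$n_eff / m$L >= min_ratio)
}
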