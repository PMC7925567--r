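#' Parse a species label from a sequence header
#'
#' Understands UniProt-style identifiers: the mnemonic after the underscore
#' in `NAME_SPECIES` ids (also inside `sp|ACC|NAME_SPECIES` / `tr|...`
#' headers), or an `OX=`/`OS=` field when present. Returns `NA` when no
#' species can be extracted.
#'
#' @param header a sequence identifier or full FASTA header line.
#' @return character species tag, or `NA_character_`.
#' @export
parse_species <- function(header) {
  if (is.na(header) || !nzchar(header)) return(NA_character_)
  ox <- regmatches(header, regexpr("OX=[0-9]+", header))
  if (length(ox) == 1L && nzchar(ox)) return(sub("OX=", "", ox))
  os <- regmatches(header, regexpr("OS=[^=]+?(?= [A-Z]{2}=|$)", header,
                                   perl = TRUE))
  if (length(os) == 1L && nzchar(os)) return(trimws(sub("OS=", "", os)))
  id <- strsplit(strsplit(header, "[ \t]")[[1]][1], "|", fixed = TRUE)[[1]]
  id <- id[nzchar(id)]
  id <- id[length(id)]
  if (grepl("_", id)) {
    tag <- sub(".*_", "", id)
    if (nzchar(tag)) return(tag)
  }
  NA_character_
}

#' Best hit per species by identity to the query
#'
#' For each species label in the alignment, the row with the highest
#' identity to the query sequence; ties break to the lowest row index.
#'
#' @param m an [msa()] with species labels.
#' @param exclude integer row indices excluded from consideration.
#' @return named integer vector (species -> row index) with the matching
#'   identities in attribute `identity`.
#' @export
best_hit_per_species <- function(m, exclude = integer()) {
  ident <- identity_to_ref(m)
  usable <- which(!is.na(m$species) & !(seq_along(m$ids) %in% exclude))
  sp <- m$species[usable]
  best <- vapply(split(usable, sp), function(rows) {
    rows[which.max(ident[rows])] # which.max takes the first on ties
  }, integer(1))
  structure(best, identity = ident[best])
}

#' Rows excluded as close query-genome paralogs
#'
#' Rows from the query's own species with identity to the query above
#' `threshold` (strictly) are excluded from pairing consideration; the query
#' itself is always retained.
#'
#' @param m an [msa()] with species labels and a known query species.
#' @param threshold identity cutoff (default 0.9).
#' @return integer vector of excluded row indices.
#' @export
exclude_query_paralogs <- function(m, threshold = 0.9) {
  qsp <- m$species[m$query_index]
  if (is.na(qsp))
    stop_coevppi("query species unknown", "coevppi_parameter_error")
  ident <- identity_to_ref(m)
  cand <- which(m$species == qsp & seq_along(m$ids) != m$query_index)
  cand[ident[cand] > threshold]
}

# Query-species paralog rows used in the reciprocity comparison: all rows of
# the query species other than the query itself.
query_paralog_rows <- function(m) {
  qsp <- m$species[m$query_index]
  if (is.na(qsp)) return(integer())
  which(m$species == qsp & seq_along(m$ids) != m$query_index)
}

# identity between two specific rows (both-non-gap columns)
row_identity <- function(X, gs, a, b) {
  both <- X[a, ] != gs & X[b, ] != gs
  if (!any(both)) return(0)
  sum(X[a, both] == X[b, both]) / sum(both)
}

#' Concatenate two monomer alignments by reciprocal highest identity
#'
#' For each species present in both alignments, the member closest to each
#' query is selected (ties to the lowest row). Close query-genome paralogs
#' (identity to the query above `paralog_threshold`) are excluded from
#' candidacy, and a candidate is only accepted if its identity to the query
#' exceeds its identity to every remaining query-species paralog in that
#' alignment. Species whose candidates pass both checks in both alignments
#' are concatenated; the two query rows are always concatenated as row 1.
#'
#' @param msa_a,msa_b monomer [msa()] objects with species labels.
#' @param paralog_threshold query-genome paralog exclusion cutoff
#'   (default 0.9).
#' @return object of class `paired_msa`: list with `msa` (the concatenated
#'   alignment), `L1`, `L2` and a `pairs` data frame
#'   (species, id_a, id_b, identity_a, identity_b).
#' @export
reciprocal_concatenate <- function(msa_a, msa_b, paralog_threshold = 0.9) {
  Xa <- msa_encode(msa_a); Xb <- msa_encode(msa_b)
  gsa <- attr(Xa, "gap_state"); gsb <- attr(Xb, "gap_state")
  ident_a <- identity_to_ref(msa_a); ident_b <- identity_to_ref(msa_b)

  excl_a <- exclude_query_paralogs(msa_a, paralog_threshold)
  excl_b <- exclude_query_paralogs(msa_b, paralog_threshold)
  par_a <- setdiff(query_paralog_rows(msa_a), excl_a)
  par_b <- setdiff(query_paralog_rows(msa_b), excl_b)

  best_a <- best_hit_per_species(msa_a, exclude = c(excl_a, msa_a$query_index))
  best_b <- best_hit_per_species(msa_b, exclude = c(excl_b, msa_b$query_index))

  passes_reciprocity <- function(row, X, gs, ident, paralogs) {
    if (length(paralogs) == 0L) return(TRUE)
    all(vapply(paralogs, function(p) {
      ident[row] > row_identity(X, gs, row, p)
    }, logical(1)))
  }

  qsp_a <- msa_a$species[msa_a$query_index]
  qsp_b <- msa_b$species[msa_b$query_index]
  shared <- sort(intersect(names(best_a), names(best_b)))
  shared <- setdiff(shared, c(qsp_a, qsp_b))

  keep <- vapply(shared, function(sp) {
    ra <- best_a[[sp]]; rb <- best_b[[sp]]
    passes_reciprocity(ra, Xa, gsa, ident_a, par_a) &&
      passes_reciprocity(rb, Xb, gsb, ident_b, par_b)
  }, logical(1))
  shared <- shared[keep]

  ra <- unname(best_a[shared]); rb <- unname(best_b[shared])
  ids <- c(sprintf("%s|%s|%s", qsp_a %||% "QUERY",
                   msa_a$ids[msa_a$query_index], msa_b$ids[msa_b$query_index]),
           sprintf("%s|%s|%s", shared, msa_a$ids[ra], msa_b$ids[rb]))
  seqs <- c(paste0(msa_a$seqs[msa_a$query_index],
                   msa_b$seqs[msa_b$query_index]),
            paste0(msa_a$seqs[ra], msa_b$seqs[rb]))
  if (length(seqs) < 2L)
    stop_coevppi("fewer than 2 concatenated sequences",
                 "coevppi_degenerate_output")
  species <- c(qsp_a, shared)
  pm <- msa(ids, seqs, species = species, query_index = 1L,
            alphabet = msa_a$alphabet)
  pairs <- data.frame(species = shared,
                      id_a = msa_a$ids[ra], id_b = msa_b$ids[rb],
                      identity_a = ident_a[ra], identity_b = ident_b[rb],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(msa = pm, L1 = msa_a$L, L2 = msa_b$L, pairs = pairs),
            class = "paired_msa")
}

#' Wrap an alignment as a paired alignment with a known segment boundary
#'
#' Used for alignments whose concatenation structure is already known (e.g.
#' synthetic paired alignments), bypassing species pairing.
#'
#' @param m an [msa()] over the concatenated columns.
#' @param L1 length of the first segment; `L2 = L - L1`.
#' @return a `paired_msa` object with an empty pairing record.
#' @export
as_paired_msa <- function(m, L1) {
  stopifnot(L1 >= 1, L1 < m$L)
  structure(list(msa = m, L1 = as.integer(L1), L2 = m$L - as.integer(L1),
                 pairs = data.frame(species = character(), id_a = character(),
                                    id_b = character(),
                                    identity_a = numeric(),
                                    identity_b = numeric())),
            class = "paired_msa")
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf("paired_msa: %d rows, segments %d + %d columns, %d pairs\n",
              length(x$msa$ids), x$L1, x$L2, nrow(x$pairs)))
  invisible(x)
}

#' Read a 2-column annotation table (protein id, annotation id)
#'
#' Supplies externally derived domain-family or structure-hit annotations to
#' [qc_concatenated()].
#'
#' @param path TSV path with two columns and no header.
#' @return data frame with columns `id`, `annotation`.
#' @export
read_annotation_tsv <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("id", "annotation")
  d[, 1:2]
}

#' Quality control of a concatenated alignment
#'
#' Applies the homology guards and the diversity/coverage filter for paired
#' alignments: shared domain families, overlapping hits to the same PDB
#' chain, an artifactual coevolution diagonal between the two segments,
#' nonstandard amino acids in either query, column coverage, and
#' `n_eff/L >= min_neff_per_l` (default 0.2).
#'
#' @param paired a `paired_msa` with weights computed on `paired$msa`
#'   (computed on the fly when absent).
#' @param domains_a,domains_b character vectors of domain-family identifiers
#'   for the two proteins.
#' @param struct_hits_a,struct_hits_b character vectors of structure-chain
#'   hit identifiers (e.g. `"1ABC_A"`) for the two proteins.
#' @param ec_table optional [build_ec_table()] result for the diagonal
#'   artifact check; skipped (FALSE) when NULL.
#' @param min_neff_per_l diversity threshold on `n_eff/L` (default 0.2).
#' @return object of class `qc_report` with fields `neff_over_l`,
#'   `coverage_pass`, `shared_domain`, `shared_structure_hit`,
#'   `diagonal_artifact`, `nonstandard_aa`, `eligible`.
#' @export
qc_concatenated <- function(paired, domains_a = character(),
                            domains_b = character(),
                            struct_hits_a = character(),
                            struct_hits_b = character(),
                            ec_table = NULL, min_neff_per_l = 0.2) {
  m <- paired$msa
  if (is.null(m$n_eff)) m <- compute_weights(m)
  stats <- column_stats(m)
  q <- strsplit(m$seqs[m$query_index], "")[[1]]
  nonstandard <- !all(q %in% aa_alphabet(gap = TRUE))
  rep <- list(
    neff_over_l = m$n_eff / m$L,
    coverage_pass = stats$coverage_pass,
    shared_domain = length(intersect(domains_a, domains_b)) > 0L,
    shared_structure_hit = length(intersect(struct_hits_a,
                                            struct_hits_b)) > 0L,
    diagonal_artifact = if (is.null(ec_table)) FALSE
                        else diagonal_artifact_check(ec_table),
    nonstandard_aa = nonstandard,
    min_neff_per_l = min_neff_per_l)
  rep$eligible <- rep$coverage_pass && rep$neff_over_l >= min_neff_per_l &&
    !rep$shared_domain && !rep$shared_structure_hit &&
    !rep$diagonal_artifact && !rep$nonstandard_aa
  structure(rep, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("concatenated-alignment QC:\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Failed QC guards of a report, in a fixed order
#' @param report a `qc_report`.
#' @return character vector of guard names that failed (empty if eligible).
#' @export
qc_failures <- function(report) {
  fails <- character()
  if (report$neff_over_l < report$min_neff_per_l) fails <- c(fails, "neff")
  if (!report$coverage_pass) fails <- c(fails, "coverage")
  if (report$shared_domain) fails <- c(fails, "shared_domain")
  if (report$shared_structure_hit) fails <- c(fails, "shared_structure_hit")
  if (report$diagonal_artifact) fails <- c(fails, "diagonal_artifact")
  if (report$nonstandard_aa) fails <- c(fails, "nonstandard_aa")
  fails
}
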