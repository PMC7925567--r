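# Shared helpers for the test suite. Everything is generated in code.

# rank-based AUC of scores for a logical/0-1 label vector
auc_of <- function(scores, labels) {
  y <- as.logical(labels)
  r <- rank(scores)
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}

# write a small FASTA and return its path
write_fasta_tmp <- function(ids, seqs) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), tf)
  tf
}

# a minimal PDB file: one chain, arbitrary residues/atoms.
# atoms: data.frame(resno, resname, atom, x, y, z, element)
write_pdb_tmp <- function(atoms, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), atoms$atom, atoms$resname, chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$element)
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

# an ec_table built directly from a score matrix (no fitting)
table_from_cn <- function(cn, L1, L2 = 0, n_eff = 100) {
  build_ec_table(cn, L1, L2, n_eff = n_eff)
}

# symmetric matrix with given upper-triangle values (row-by-row order)
sym_from_upper <- function(L, values) {
  S <- matrix(0, L, L)
  S[upper.tri(S)] <- NA
  k <- 1
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    S[i, j] <- S[j, i] <- values[k]; k <- k + 1
  }
  S
}

# brute-force O(n^2) sequence-weight oracle, independent of the C++ path
brute_weights <- function(m, theta = 0.8) {
  cm <- do.call(rbind, strsplit(m$seqs, ""))
  aa <- aa_alphabet(gap = FALSE)
  n <- nrow(cm)
  ident <- function(s, t) {
    both <- cm[s, ] %in% aa & cm[t, ] %in% aa
    if (!any(both)) return(0)
    mean(cm[s, both] == cm[t, both])
  }
  w <- numeric(n)
  for (s in seq_len(n)) {
    cnt <- 1L
    for (t in seq_len(n)) {
      if (t != s && ident(s, t) >= theta) cnt <- cnt + 1L
    }
    w[s] <- 1 / cnt
  }
  w
}

# random msa over the full alphabet with controlled redundancy
random_msa <- function(n, L, seed, dup_groups = 0) {
  withr::with_seed(seed, {
    aa <- aa_alphabet(gap = FALSE)
    seqs <- replicate(n, paste0(sample(aa, L, TRUE), collapse = ""))
    if (dup_groups > 0) { # make some near-duplicate clusters
      for (g in seq_len(dup_groups)) {
        base <- strsplit(seqs[g], "")[[1]]
        for (k in 1:3) {
          mut <- base
          pos <- sample(L, max(1, round(0.1 * L)))
          mut[pos] <- sample(aa, length(pos), TRUE)
          seqs <- c(seqs, paste0(mut, collapse = ""))
        }
      }
    }
    msa(sprintf("R%04d_SP%03d", seq_along(seqs), seq_along(seqs)), seqs)
  })
}
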