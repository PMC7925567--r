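#' Read a structure file
#'
#' Thin wrapper over bio3d: PDB via [bio3d::read.pdb()], mmCIF via
#' [bio3d::read.cif()] (by extension).
#'
#' @param path structure file path.
#' @return a `bio3d` `pdb` object.
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
  else bio3d::read.pdb(path)
}

# Van der Waals radii (Angstrom) by element; Bondi-style standard values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98)

# Theoretical maximum accessible surface areas per residue (Angstrom^2),
# Tien et al. 2013, used to normalize absolute to relative accessibility.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# heavy-atom records of a bio3d pdb object
heavy_atoms <- function(pdb) {
  at <- pdb$atom
  elt <- toupper(trimws(at$elesy %||% ""))
  miss <- is.na(elt) | !nzchar(elt)
  if (any(miss)) # fall back to the first letter of the atom name
    elt[miss] <- substr(gsub("[0-9]", "", toupper(trimws(at$elety[miss]))),
                        1, 1)
  keep <- elt != "H" & at$type %in% c("ATOM", "HETATM")
  at <- at[keep, , drop = FALSE]
  at$element <- elt[keep]
  at
}

#' Read an alignment-position to structure-residue mapping table
#'
#' TSV with header columns `alignment_pos` (1-based concatenated alignment
#' position), `chain`, `resnum`, and optionally `icode` and `aa`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_residue_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("alignment_pos", "chain", "resnum")
  if (!all(need %in% names(d)))
    stop_coevppi("mapping table needs alignment_pos, chain, resnum columns",
                 "coevppi_format_error")
  d
}

#' Minimum-atom inter-residue distance map across structures
#'
#' For every pair of mapped alignment positions, the minimum over structures
#' of the minimum heavy-atom pair distance between the two residues. A pair
#' is missing when either residue is unresolved in all structures.
#'
#' @param structures list of `bio3d` pdb objects or structure file paths.
#' @param mapping data frame per [read_residue_map()].
#' @return object of class `distance_map`: `dist` (symmetric matrix with
#'   `NA` for missing, dimnames = alignment positions), `positions`,
#'   `n_structures`.
#' @export
min_distance_map <- function(structures, mapping) {
  if (length(structures) == 0L)
    stop_coevppi("at least one structure required",
                 "coevppi_parameter_error")
  if (nrow(mapping) == 0L)
    stop_coevppi("empty residue mapping", "coevppi_parameter_error")
  structures <- lapply(structures, function(s) {
    if (is.character(s)) read_structure(s) else s
  })
  pos <- sort(unique(mapping$alignment_pos))
  n <- length(pos)
  dmin <- matrix(NA_real_, n, n, dimnames = list(pos, pos))

  for (pdb in structures) {
    at <- heavy_atoms(pdb)
    coords <- lapply(pos, function(p) {
      k <- which(mapping$alignment_pos == p)[1]
      sel <- at$chain == mapping$chain[k] & at$resno == mapping$resnum[k]
      if ("icode" %in% names(mapping) && !is.na(mapping$icode[k]) &&
          nzchar(mapping$icode[k]))
        sel <- sel & at$insert %in% mapping$icode[k]
      if (!any(sel)) return(NULL)
      cbind(at$x[sel], at$y[sel], at$z[sel])
    })
    for (a in seq_len(n - 1L)) {
      if (is.null(coords[[a]])) next
      for (b in (a + 1L):n) {
        if (is.null(coords[[b]])) next
        d2 <- outer(rowSums(coords[[a]]^2), rowSums(coords[[b]]^2), "+") -
          2 * coords[[a]] %*% t(coords[[b]])
        d <- sqrt(max(0, min(d2)))
        cur <- dmin[a, b]
        if (is.na(cur) || d < cur) dmin[a, b] <- dmin[b, a] <- d
      }
    }
  }
  structure(list(dist = dmin, positions = pos,
                 n_structures = length(structures)),
            class = "distance_map")
}

#' Distance between two alignment positions
#' @param dmap a `distance_map`.
#' @param i,j alignment positions (1-based, concatenated coordinates).
#' @return distance in Angstrom, or `NA` when unmapped/unresolved.
#' @export
dmap_distance <- function(dmap, i, j) {
  a <- match(i, dmap$positions); b <- match(j, dmap$positions)
  if (is.na(a) || is.na(b)) return(NA_real_)
  dmap$dist[a, b]
}

#' Contact labels from a distance map
#' @param dmap a `distance_map`.
#' @param cutoff contact cutoff in Angstrom, strict `<` (default 8).
#' @return logical matrix (NA preserved) with the map's dimnames.
#' @export
contact_labels <- function(dmap, cutoff = 8) {
  dmap$dist < cutoff
}

#' Number of close inter-segment residue pairs
#'
#' Counts inter-protein residue pairs closer than `cutoff` (default 5
#' Angstrom); a pair of proteins is conventionally called "contacting" when
#' this count reaches 20.
#'
#' @param dmap a `distance_map` over concatenated alignment positions.
#' @param L1 first-segment length (positions `<= L1` belong to protein A).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return integer count.
#' @export
interface_pair_count <- function(dmap, L1, cutoff = 5) {
  pos <- dmap$positions
  a <- which(pos <= L1); b <- which(pos > L1)
  if (length(a) == 0L || length(b) == 0L) return(0L)
  sum(dmap$dist[a, b, drop = FALSE] < cutoff, na.rm = TRUE)
}

#' Precision of top-ranked couplings against a distance map
#'
#' Among the top-`k` rows of the table, the fraction whose minimum-atom
#' distance is below `cutoff`; rows with unknown distance are excluded from
#' numerator and denominator.
#'
#' @param table an `ec_table` (subset it first to restrict to inter or
#'   intra rows).
#' @param dmap a `distance_map`.
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @param k number of top rows (by rank) to evaluate.
#' @return precision in \[0, 1\], or `NA` when no top-k row has a known
#'   distance.
#' @export
ec_precision <- function(table, dmap, cutoff = 8, k) {
  stopifnot(k >= 1)
  top <- table[order(table$rank), , drop = FALSE]
  top <- head(top, k)
  d <- mapply(function(i, j) dmap_distance(dmap, i, j), top$i, top$j)
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_real_)
  mean(d < cutoff)
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent accessible surface area (sphere sampling)
#'
#' Shrake-Rupley style: each atom's solvent-expanded sphere (radius + probe)
#' is sampled at `n_points` deterministic golden-spiral points; the
#' accessible area is the fraction of points outside every neighbouring
#' expanded sphere times the sphere area.
#'
#' @param xyz numeric matrix (n x 3) of atom coordinates.
#' @param radii per-atom van der Waals radii in Angstrom.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 960).
#' @return numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  pts <- sphere_points(n_points)
  R <- radii + probe
  # neighbour prefilter on pairwise distances
  dmat <- as.matrix(dist(xyz))
  areas <- numeric(n)
  for (a in seq_len(n)) {
    nb <- which(dmat[a, ] < R[a] + R & seq_len(n) != a)
    sp <- sweep(pts * R[a], 2, xyz[a, ], "+")
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (b in nb) {
        d2 <- (sp[, 1] - xyz[b, 1])^2 + (sp[, 2] - xyz[b, 2])^2 +
          (sp[, 3] - xyz[b, 3])^2
        buried <- buried | d2 < R[b]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    areas[a] <- 4 * pi * R[a]^2 * acc / n_points
  }
  areas
}

#' Relative solvent accessibility of residues
#'
#' Computes per-residue accessible surface areas by sphere sampling over
#' heavy atoms and normalizes by the residue's theoretical maximum area
#' (Tien et al. values). With several structures, the relative
#' accessibilities are averaged per residue across the structures in which
#' the residue is resolved.
#'
#' @param structures a `bio3d` pdb object, a path, or a list of either.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return object of class `accessibility_profile`: data frame with columns
#'   `chain`, `resnum`, `resname`, `area` (absolute, mean across
#'   structures), `rel` (relative), plus attribute `n_structures`.
#' @export
relative_sasa <- function(structures, probe = 1.4, n_points = 960) {
  if (!is.list(structures) || inherits(structures, "pdb"))
    structures <- list(structures)
  per_struct <- lapply(structures, function(s) {
    pdb <- if (is.character(s)) read_structure(s) else s
    at <- heavy_atoms(pdb)
    radii <- VDW_RADII[at$element]
    if (anyNA(radii)) {
      warning("unknown element radius; using 1.70 Angstrom default for: ",
              paste(unique(at$element[is.na(radii)]), collapse = ", "))
      radii[is.na(radii)] <- 1.70
    }
    areas <- sasa_atoms(cbind(at$x, at$y, at$z), radii, probe, n_points)
    key <- paste(at$chain, at$resno, sep = "|")
    res_area <- tapply(areas, key, sum)
    first <- !duplicated(key)
    data.frame(chain = at$chain[first], resnum = at$resno[first],
               resname = at$resid[first],
               area = as.numeric(res_area[key[first]]),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_struct)
  all$rel <- all$area / unname(MAX_ASA[all$resname])
  key <- paste(all$chain, all$resnum, sep = "|")
  first <- !duplicated(key)
  out <- data.frame(chain = all$chain[first], resnum = all$resnum[first],
                    resname = all$resname[first],
                    area = as.numeric(tapply(all$area, key, mean)[key[first]]),
                    rel = as.numeric(tapply(all$rel, key, mean)[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_structures = length(per_struct),
            class = c("accessibility_profile", "data.frame"))
}

#' Read a precomputed per-residue accessibility table
#'
#' Adapter for externally computed accessibilities (e.g. DSSP output
#' reduced to a table): TSV with header columns `chain`, `resnum`, `rel`
#' and optionally `area`, `resname`.
#'
#' @param path TSV path.
#' @return an `accessibility_profile` data frame.
#' @export
read_accessibility_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain", "resnum", "rel") %in% names(d)))
    stop_coevppi("accessibility table needs chain, resnum, rel columns",
                 "coevppi_format_error")
  if (is.null(d$area)) d$area <- NA_real_
  if (is.null(d$resname)) d$resname <- NA_character_
  structure(d[, c("chain", "resnum", "resname", "area", "rel")],
            n_structures = 1L,
            class = c("accessibility_profile", "data.frame"))
}

#' Map an accessibility profile onto alignment positions
#'
#' @param profile an `accessibility_profile`.
#' @param mapping data frame per [read_residue_map()].
#' @param L total number of alignment positions.
#' @return numeric vector of length `L` of relative accessibilities (`NA`
#'   where unmapped).
#' @export
rsa_by_position <- function(profile, mapping, L) {
  out <- rep(NA_real_, L)
  pk <- paste(profile$chain, profile$resnum, sep = "|")
  mk <- paste(mapping$chain, mapping$resnum, sep = "|")
  hit <- match(mk, pk)
  ok <- !is.na(hit) & mapping$alignment_pos >= 1 & mapping$alignment_pos <= L
  out[mapping$alignment_pos[ok]] <- profile$rel[hit[ok]]
  out
}
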