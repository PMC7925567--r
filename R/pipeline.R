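#' Pipeline configuration
#'
#' Collects every threshold of the per-pair pipeline with its default:
#' sequence-weighting identity 0.8, row/column gap filters 0.5, query
#' paralog exclusion 0.9, monomer and concatenated diversity floors
#' `n_eff/L` 2.5 and 0.2, 5-residue diagonal band, 8 Angstrom contact
#' cutoff, top-10 residue features and top-5 restraints. The configuration
#' round-trips losslessly through YAML.
#'
#' @param alignment_a,alignment_b monomer alignment paths (or [msa()]
#'   objects when calling [run_pair()] in memory).
#' @param output_dir directory for result files.
#' @param ... overrides of any default listed above (see
#'   `pipeline_defaults()`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment_a = NULL, alignment_b = NULL,
                            output_dir = ".", ...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop_coevppi(paste("unknown config fields:",
                       paste(unknown, collapse = ", ")),
                 "coevppi_configuration_error")
  cfg[names(dots)] <- dots
  cfg$alignment_a <- alignment_a
  cfg$alignment_b <- alignment_b
  cfg$output_dir <- output_dir
  structure(cfg, class = "pipeline_config")
}

#' Default pipeline thresholds
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(theta = 0.8, row_max_gap = 0.5, col_max_gap = 0.5,
       min_col_coverage = 0.8, paralog_threshold = 0.9,
       min_neff_per_l_monomer = 2.5, min_neff_per_l_concat = 0.2,
       diag_band = 5, contact_cutoff = 8, n_top_features = 10,
       n_top_restraints = 5, lambda_h = 0.01, lambda_base = 0.01,
       maxit = 500, seed = 1,
       check_monomer_eligibility = TRUE,
       residue_model = NULL, interaction_model = NULL,
       residue_threshold = NULL,
       structures = NULL, residue_map = NULL,
       domains_a = character(), domains_b = character(),
       struct_hits_a = character(), struct_hits_b = character(),
       export_restraints = FALSE,
       alignment_a = NULL, alignment_b = NULL, output_dir = ".")
}

#' Read / write pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  d <- yaml::read_yaml(path)
  do.call(pipeline_config, d)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

load_msa_input <- function(x, what) {
  if (inherits(x, "msa")) return(x)
  if (is.character(x)) return(read_alignment(x))
  stop_coevppi(paste("missing or invalid", what, "alignment"),
               "coevppi_configuration_error")
}

#' Run the end-to-end per-pair pipeline
#'
#' Orchestrates: monomer weighting and eligibility, reciprocal
#' concatenation, gap-row filtering, concatenated QC guards, Potts fit,
#' APC-corrected coupling table, EVcomplex transform, residue features,
#' optional model scoring, optional structure comparison, and optional
#' restraint export. All artifacts are written under the configured output
#' directory; the run is deterministic given the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param paired optionally a precomputed `paired_msa` (skips reading and
#'   pairing; used for synthetic fixtures).
#' @return list with `status` (`"ok"`, `"ineligible_monomer"`,
#'   `"qc_failed:<guard>"` or `"degenerate"`), `qc`, `ec_table`, `features`,
#'   `scores`, `precision`, and `paths` of the files written.
#' @export
run_pair <- function(config, paired = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  out <- function(name) file.path(config$output_dir, name)

  if (is.null(paired)) {
    msa_a <- compute_weights(load_msa_input(config$alignment_a, "A"),
                             config$theta)
    msa_b <- compute_weights(load_msa_input(config$alignment_b, "B"),
                             config$theta)
    if (isTRUE(config$check_monomer_eligibility)) {
      elig_a <- monomer_eligibility(msa_a, config$min_neff_per_l_monomer)
      elig_b <- monomer_eligibility(msa_b, config$min_neff_per_l_monomer)
      if (!elig_a || !elig_b)
        return(list(status = "ineligible_monomer", paths = paths))
    }
    paired <- reciprocal_concatenate(msa_a, msa_b,
                                     config$paralog_threshold)
  }

  # row filter + weights on the concatenated alignment
  paired$msa <- compute_weights(
    filter_gappy_rows(paired$msa, config$row_max_gap), config$theta)
  write_alignment(paired$msa, paths$paired <- out("paired.fasta"))

  qc <- qc_concatenated(paired, domains_a = config$domains_a,
                        domains_b = config$domains_b,
                        struct_hits_a = config$struct_hits_a,
                        struct_hits_b = config$struct_hits_b,
                        min_neff_per_l = config$min_neff_per_l_concat)
  model <- NULL; tab <- NULL
  pre_ok <- qc$eligible
  if (pre_ok) {
    model <- fit_plm(paired, lambda_h = config$lambda_h,
                     lambda_base = config$lambda_base,
                     maxit = config$maxit)
    fn <- frobenius_scores(model)
    tab <- build_ec_table(apc(fn), paired$L1, paired$L2,
                          n_eff = paired$msa$n_eff, fn = fn,
                          diag_band = config$diag_band)
    tab <- inter_zscores(tab)
    # re-run QC including the coupling-diagonal guard
    qc <- qc_concatenated(paired, domains_a = config$domains_a,
                          domains_b = config$domains_b,
                          struct_hits_a = config$struct_hits_a,
                          struct_hits_b = config$struct_hits_b,
                          ec_table = tab,
                          min_neff_per_l = config$min_neff_per_l_concat)
  }
  jsonlite::write_json(unclass(qc), paths$qc <- out("qc.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!qc$eligible) {
    fails <- qc_failures(qc)
    return(list(status = paste0("qc_failed:", fails[1]), qc = qc,
                paths = paths))
  }

  tab <- evcomplex_transform(tab)
  write_ec_table(tab, paths$ec_table <- out("ec_table.csv"))

  stats <- column_stats(paired$msa, config$col_max_gap,
                        config$min_col_coverage)

  dmap <- NULL; rsa <- NULL; precision <- NULL
  if (!is.null(config$structures) && !is.null(config$residue_map)) {
    mapping <- if (is.character(config$residue_map))
      read_residue_map(config$residue_map) else config$residue_map
    dmap <- min_distance_map(config$structures, mapping)
    prof <- relative_sasa(config$structures)
    rsa <- rsa_by_position(prof, mapping, paired$msa$L)
    inter_tab <- tab[tab$is_inter, , drop = FALSE]
    precision <- data.frame(
      k = c(5L, 10L),
      precision = c(ec_precision(inter_tab, dmap, config$contact_cutoff, 5),
                    ec_precision(inter_tab, dmap, config$contact_cutoff,
                                 10)))
    write.csv(precision, paths$precision <- out("precision.csv"),
              row.names = FALSE)
  }

  features <- build_residue_features(
    tab, conservation = stats$conservation, rsa = rsa, dmap = dmap,
    contact_cutoff = config$contact_cutoff,
    n_top = config$n_top_features)
  write.csv(features, paths$features <- out("features.csv"),
            row.names = FALSE)

  scores <- NULL
  scores_free <- NULL
  if (!is.null(config$residue_model)) {
    rmodel <- if (is.character(config$residue_model))
      read_logistic_model(config$residue_model) else config$residue_model
    fill <- features
    fill[is.na(fill$enrichment_max), "enrichment_max"] <- 0
    scores_free <- predict(rmodel, fill)
    top_rank <- features$inter_relative_rank[1]
    scores <- data.frame(i = features$i, j = features$j,
                         cn = features$cn, probability = scores_free)
    if (!is.null(config$interaction_model)) {
      imodel <- if (is.character(config$interaction_model))
        read_logistic_model(config$interaction_model)
        else config$interaction_model
      isc <- score_protein_interaction(scores_free, top_rank, imodel,
                                       config$residue_threshold)
      attr(scores, "interaction_probability") <- isc$probability
      attr(scores, "n_calls") <- isc$n_calls
    }
    write.csv(scores, paths$scores <- out("scores.csv"),
              row.names = FALSE)
  }

  if (isTRUE(config$export_restraints)) {
    if (is.null(config$residue_map))
      stop_coevppi("restraint export needs a residue_map",
                   "coevppi_configuration_error")
    mapping <- if (is.character(config$residue_map))
      read_residue_map(config$residue_map) else config$residue_map
    sc_all <- NULL
    if (!is.null(scores_free)) { # probabilities over all inter rows of tab
      inter_rows <- which(tab$is_inter)
      sc_all <- rep(-Inf, length(inter_rows))
      hit <- match(paste(features$i, features$j),
                   paste(tab$i[inter_rows], tab$j[inter_rows]))
      ok <- !is.na(hit)
      sc_all[hit[ok]] <- scores_free[ok]
    }
    lines <- export_restraints(tab, mapping, scores_free = sc_all,
                               n_top = config$n_top_restraints)
    writeLines(lines, paths$restraints <- out("restraints.tbl"))
  }

  list(status = "ok", qc = qc, ec_table = tab, features = features,
       scores = scores, precision = precision, paths = paths)
}
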