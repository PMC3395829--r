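# End-to-end chain: simulate -> delimit -> incidence matrices -> community
# statistics -> path model, writing plain-text outputs.  All randomness
# derives from one master seed, so two runs with the same seed are
# byte-identical.

.write_tsv <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- data.frame(stats::setNames(list(rownames(x)), row_label),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a planted-taxon sequence set with metadata, delimits virtual
#' taxa, builds incidence matrices for every category scheme, computes
#' rarefaction, endemism/specificity, location-level Bray-Curtis, NMDS and
#' a Mantel test of VT against host-order composition, derives PCA scores
#' per location and fits the recursive path model.  Every artefact is
#' written as plain text (FASTA/TSV/JSON) under \code{out_dir}.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param n_taxa,mean_members,n_locations,endemism_fraction Generator
#'   settings (see \code{\link{synth_config}}, \code{\link{meta_config}}).
#' @param vt_cfg A \code{\link{vt_config}} (its seed is overridden by the
#'   master seed).
#' @param n_iter Rarefaction iterations (default 1000).
#' @param n_perm Mantel permutations (default 999).
#' @param filter_mode Column filter for location-level matrices (default
#'   "none"; "location" applies the 12-sequence / 6-VT rule).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_taxa = 24, mean_members = 3,
                         n_locations = 24, endemism_fraction = 0.8,
                         vt_cfg = vt_config(), n_iter = 1000, n_perm = 999,
                         filter_mode = "none") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  scfg <- synth_config(n_taxa = n_taxa, mean_members = mean_members,
                       seed = seed)
  gen <- generate_taxa(scfg)
  write_fasta(gen$records, fp("sequences.fasta"))
  .write_json(list(taxa = gen$truth,
                   parameters = unclass(scfg)[c("n_taxa", "mean_members",
                                                "seq_length", "intra_mut",
                                                "inter_div", "seed")]),
              fp("truth.json"))
  mcfg <- meta_config(endemism_fraction = endemism_fraction,
                      n_locations = n_locations, seed = seed + 1)
  meta <- attach_metadata(gen$truth, mcfg)
  .write_tsv(meta, fp("metadata.tsv"))

  vt_cfg$seed <- seed + 2
  assignment <- delimit_vts(gen$records, vt_cfg)
  membership <- vt_membership(assignment)
  .write_tsv(data.frame(seq_id = names(membership), vt_id = membership,
                        provenance = assignment$provenance[names(membership)]),
             fp("vt_membership.tsv"))
  write_fasta(gen$records[assignment$representatives],
              fp("vt_representatives.fasta"))
  s <- vt_summary(assignment)
  .write_json(list(n_vts = s$n_vts, n_singletons = s$n_singletons,
                   n_doubletons = s$n_doubletons,
                   sizes = as.list(stats::setNames(as.integer(s$size_histogram),
                                                   names(s$size_histogram)))),
              fp("vt_summary.json"))
  if (!is.null(assignment$tree))
    ape::write.tree(assignment$tree$tree, fp("representatives.nwk"))

  schemes <- c("functional_group", "ecosystem", "continent", "realm",
               "climate", "supercontinent", "host_order", "location")
  matrices <- lapply(stats::setNames(schemes, schemes), function(sc)
    incidence_matrix(assignment, meta, sc))
  for (sc in schemes)
    .write_tsv(matrices[[sc]], fp(paste0("incidence_", sc, ".tsv")),
               row_label = "vt_id")

  spec_schemes <- setdiff(schemes, "location")
  spec_res <- lapply(matrices[spec_schemes], specificity)
  .write_json(lapply(spec_res, function(x)
    list(overall = x$overall, per_column = as.list(x$per_column))),
    fp("specificity.json"))

  curve <- rarefaction(membership, n_iter = n_iter, seed = seed + 3)
  .write_tsv(as.data.frame(curve), fp("rarefaction.tsv"))

  loc_vt <- apply_filters(matrices$location, mode = filter_mode)
  plant_loc <- cross_tabulate(meta, "host_order", "location")
  plant_loc <- plant_loc[, colnames(loc_vt), drop = FALSE]
  bc_vt <- bray_curtis(loc_vt, by = "columns")
  bc_plant <- bray_curtis(plant_loc, by = "columns")
  man <- mantel(bc_vt, bc_plant, n_perm = n_perm, seed = seed + 4)
  .write_json(list(r = man$r, p = man$p, n_perm = man$n_perm),
              fp("mantel_location.json"))
  ord <- nmds(bc_vt, k = 2, seed = seed + 5)
  .write_tsv(data.frame(location = rownames(ord$points),
                        NMDS1 = ord$points[, 1], NMDS2 = ord$points[, 2],
                        stress = ord$stress),
             fp("nmds_locations.tsv"))

  sem_out <- tryCatch({
    locs <- colnames(loc_vt)
    score_of <- function(m) composition_scores(t(m[, locs, drop = FALSE]))
    tab <- data.frame(
      ecosystem = score_of(cross_tabulate(meta, "ecosystem", "location")),
      climate = score_of(cross_tabulate(meta, "climate", "location")),
      continent = score_of(cross_tabulate(meta, "continent", "location")),
      biogeography = score_of(cross_tabulate(meta, "realm", "location")),
      plant = score_of(plant_loc),
      amf = score_of(loc_vt))
    spec <- path_spec()
    fitted <- fit_path_model(tab, spec)
    fit <- fit_indices(tab, spec, fitted)
    list(direct = as.list(fitted$direct), indirect = as.list(fitted$indirect),
         total = as.list(fitted$total), r_squared = as.list(fitted$r_squared),
         fit = fit, n = fitted$n)
  }, error = function(e) list(skipped = TRUE, reason = conditionMessage(e)))
  .write_json(sem_out, fp("path_model.json"))

  invisible(list(records = gen$records, truth = gen$truth, meta = meta,
                 assignment = assignment, matrices = matrices,
                 specificity = spec_res, rarefaction = curve, mantel = man,
                 nmds = ord, sem = sem_out))
}
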