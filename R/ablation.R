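# Feature-group ablation: remove one node/edge feature group at a time,
# retrain the chosen architecture from scratch, and tabulate the metrics.

# Resolve an ablation group name to (which matrix, column indices).
# Node groups: position3d, meiler, expasy, dssp (= dssp_sse + dssp_geom).
# Edge groups: distance, weak_bonds, strong_bonds (covalent chemistry).
.ablation_groups <- function() {
  list(position3d = list(kind = "node", schema = "position3d"),
       meiler = list(kind = "node", schema = "meiler"),
       expasy = list(kind = "node", schema = "expasy"),
       dssp = list(kind = "node", schema = c("dssp_sse", "dssp_geom")),
       distance = list(kind = "edge", cols = "distance"),
       weak_bonds = list(kind = "edge",
                         cols = c("hydrogen", "ionic", "aromatic",
                                  "aromatic_sulphur", "cation_pi",
                                  "hydrophobic", "vdw")),
       strong_bonds = list(kind = "edge",
                           cols = c("peptide", "disulfide",
                                    "other_covalent")))
}

#' Ablation group names
#' @return Character vector of the seven removable feature groups.
#' @export
ablation_group_names <- function() names(.ablation_groups())

.mask_graph <- function(g, groups) {
  defs <- .ablation_groups()
  for (nm in groups) {
    def <- defs[[nm]]
    if (is.null(def)) stop("unknown feature group: ", nm)
    if (def$kind == "node") {
      missing <- setdiff(def$schema, names(g$node_schema$groups))
      if (length(missing))
        stop("group ", nm, " already removed from the schema")
      drop_cols <- unlist(lapply(def$schema,
                                 function(s) schema_group_idx(g$node_schema,
                                                              s)))
      g$X <- g$X[, -drop_cols, drop = FALSE]
      g$node_schema <- schema_drop_groups(g$node_schema, def$schema)
    } else {
      present <- colnames(g$E)
      if (!all(def$cols %in% present))
        stop("group ", nm, " already removed from the schema")
      g$E <- g$E[, setdiff(present, def$cols), drop = FALSE]
      kept <- lapply(g$edge_schema$groups, function(v) setdiff(v, def$cols))
      kept <- kept[vapply(kept, length, integer(1)) > 0]
      if (length(kept) == 0L)
        stop("cannot remove every edge feature group")
      g$edge_schema <- new_feature_schema(kept)
    }
  }
  g
}

#' Remove feature groups from dataset samples
#'
#' Masked dimensions are deleted (not zeroed), so node/edge feature
#' dimensions shrink and a model cannot exploit a constant channel.
#' Masks apply to the pristine schema only: masking a group that is
#' already gone is an error.  Labels are untouched.
#'
#' @param samples List of `dataset_sample`s.
#' @param groups Character vector of group names among
#'   [ablation_group_names()]; empty means identity.
#' @return The masked sample list.
#' @export
mask_dataset <- function(samples, groups = character(0)) {
  if (length(groups) == 0L) return(samples)
  stopifnot(!anyDuplicated(groups))
  lapply(samples, function(s) {
    s$graph <- .mask_graph(s$graph, groups)
    s
  })
}

#' Run the feature-group ablation study
#'
#' Retrains the supplied configuration from scratch (same seed) once with
#' all features ("None" row) and once per excluded group, evaluating each
#' model on the test samples.  Rows are ordered None, 3D Position, Meiler,
#' ExPASy, DSSP, distance, weak bonds, strong bonds.
#'
#' @param config A [gnn_config()] -- normally the grid-search winner.
#' @param train_samples,val_samples,test_samples Dataset samples.
#' @param groups Groups to ablate (default all seven).
#' @param verbose Print progress.
#' @return data.frame with one row per setting and the six metric columns;
#'   attribute `models` holds the fitted models.
#' @export
run_ablation <- function(config, train_samples, val_samples, test_samples,
                         groups = ablation_group_names(),
                         verbose = FALSE) {
  stopifnot(length(groups) >= 1L,
            all(groups %in% ablation_group_names()))
  display <- c(none = "None", position3d = "3D Position", meiler = "Meiler",
               expasy = "ExPASy", dssp = "DSSP", distance = "distance",
               weak_bonds = "weak bonds", strong_bonds = "strong bonds")
  settings <- c("none", groups[order(match(groups, names(display)))])
  rows <- vector("list", length(settings))
  models <- vector("list", length(settings))
  for (k in seq_along(settings)) {
    gset <- if (settings[k] == "none") character(0) else settings[k]
    tr <- mask_dataset(train_samples, gset)
    va <- mask_dataset(val_samples, gset)
    te <- mask_dataset(test_samples, gset)
    fit <- gnn_train(tr, va, config)
    ev <- evaluate_model(fit$model, te)
    rows[[k]] <- data.frame(excluded = display[[settings[k]]],
                            accuracy = ev$accuracy,
                            balanced_accuracy = ev$balanced_accuracy,
                            precision = ev$precision, recall = ev$recall,
                            fscore = ev$fscore, auc = ev$auc,
                            stringsAsFactors = FALSE)
    models[[k]] <- fit$model
    if (verbose)
      message(sprintf("ablation %-12s F %.4f", display[[settings[k]]],
                      ev$fscore))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- stats::setNames(models, settings)
  out
}

#' Write an ablation table as TSV
#' @param tab Result of [run_ablation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ablation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
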