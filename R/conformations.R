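#' Classify side-chain in/out states and frame-level IN/OUT classes
#'
#' A tracked residue is `in` when its H-bond heavy-atom distance is below
#' `in_max`, `out` when above `out_min`, and `intermediate` in the gap.
#' A frame is class `OUT` when at least one tracked residue is out, `IN`
#' when all tracked residues are in, and `unassigned` otherwise (an
#' intermediate residue with no out residue).
#'
#' @param table distance table from [compute_distances()] (or the synthetic
#'   generator), with a `frame` column.
#' @param residue_map named character vector mapping each tracked residue to
#'   its distance column, e.g. `c(Q489 = "d1", N468 = "d2")`.
#' @param in_max in-state threshold (Angstrom).
#' @param out_min out-state threshold (Angstrom).
#' @return list with `states` (data.frame, one factor column per residue)
#'   and `class` (factor `IN`/`OUT`/`unassigned` per frame).
#' @export
classify_states <- function(table, residue_map, in_max = 4.0, out_min = 5.0) {
  if (in_max > out_min) stop("in_max must not exceed out_min")
  missing <- setdiff(unname(residue_map), names(table))
  if (length(missing) > 0)
    stop("unknown distance column(s): ", paste(missing, collapse = ", "))
  st <- data.frame(row.names = seq_len(nrow(table)))
  for (res in names(residue_map)) {
    d <- table[[residue_map[[res]]]]
    s <- ifelse(d < in_max, "in", ifelse(d > out_min, "out", "intermediate"))
    st[[res]] <- factor(s, levels = c("in", "intermediate", "out"))
  }
  any_out <- Reduce(`|`, lapply(st, function(s) s == "out"))
  all_in  <- Reduce(`&`, lapply(st, function(s) s == "in"))
  cls <- ifelse(any_out, "OUT", ifelse(all_in, "IN", "unassigned"))
  list(states = st,
       class = factor(cls, levels = c("IN", "OUT", "unassigned")))
}

#' Principal component analysis of the H-bond distance features
#'
#' Mean-centered covariance eigendecomposition of the selected (unscaled)
#' distance columns; all features share units (Angstrom), so no
#' standardization is applied. The smallest number of components whose
#' cumulative explained variance reaches `variance_target` is retained.
#'
#' @param table distance table with a `frame` column.
#' @param feature_labels columns to use (default: all non-`frame` columns).
#' @param variance_target cumulative explained-variance fraction in (0, 1].
#' @return object of class `pca_model` with elements `center`, `rotation`
#'   (all components), `explained` (fractions), `n_retained`, `scores`
#'   (retained-component projections of the input).
#' @export
fit_pca <- function(table, feature_labels = NULL, variance_target = 0.9) {
  if (is.null(feature_labels))
    feature_labels <- setdiff(names(table), "frame")
  missing <- setdiff(feature_labels, names(table))
  if (length(missing) > 0)
    stop("unknown feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, feature_labels, drop = FALSE])
  if (nrow(X) < 2) stop("PCA needs at least 2 frames")
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  total_var <- sum(apply(X, 2, stats::var))
  if (total_var <= 0) stop("degenerate input: all features have zero variance")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  k <- which(cumsum(explained) >= variance_target - 1e-12)[1]
  structure(list(center = p$center,
                 rotation = p$rotation,
                 explained = explained,
                 n_retained = k,
                 features = feature_labels,
                 scores = p$x[, seq_len(k), drop = FALSE]),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model a `pca_model`.
#' @param newdata distance table or matrix with the model's feature columns.
#' @param n_components number of components (default: retained count).
#' @export
project_pca <- function(model, newdata, n_components = model$n_retained) {
  X <- if (is.data.frame(newdata))
    as.matrix(newdata[, model$features, drop = FALSE]) else as.matrix(newdata)
  sweep(X, 2, model$center) %*%
    model$rotation[, seq_len(n_components), drop = FALSE]
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d features, %d retained components (%.1f%% variance)\n",
              length(x$features), x$n_retained,
              100 * sum(x$explained[seq_len(x$n_retained)])))
  invisible(x)
}

#' Density-based clustering of pocket conformations
#'
#' Hierarchical density-based clustering (mutual-reachability distances,
#' single-linkage hierarchy, condensed tree, excess-of-mass cluster
#' selection) of the retained principal-component projections, with a noise
#' label for points in no persistent density peak. Clusters whose population
#' falls below `min_population` (default 1% of all frames) are removed and
#' their frames relabeled noise.
#'
#' @param projected_data numeric matrix (frames x retained components).
#' @param min_cluster_size smallest cluster the hierarchy may report (>= 2).
#' @param min_population population-fraction filter applied after clustering.
#' @param min_samples neighborhood size for core distances (default
#'   `min_cluster_size`).
#' @return list with `assignment` (integer per frame, `NA` for noise; ids
#'   `0, 1, ...` by decreasing population) and `summary` (data.frame with
#'   `cluster`, `n`, `population`, plus attributes `noise_fraction` and
#'   `excluded_fraction`).
#' @export
cluster_density <- function(projected_data, min_cluster_size,
                            min_population = 0.01,
                            min_samples = min_cluster_size) {
  X <- as.matrix(projected_data)
  n <- nrow(X)
  if (min_cluster_size < 2) stop("min_cluster_size must be at least 2")
  if (n < min_cluster_size)
    stop("fewer points (", n, ") than min_cluster_size")
  raw <- hdbscan_eom(X, min_cluster_size, min_samples)
  assignment <- raw$labels          # integer, NA = noise
  # population filter: small clusters dissolve into noise
  ids <- sort(unique(assignment[!is.na(assignment)]))
  sizes <- vapply(ids, function(i) sum(assignment == i, na.rm = TRUE), 0L)
  pops <- sizes / n
  excluded <- ids[pops < min_population]
  excluded_fraction <- sum(pops[pops < min_population])
  assignment[assignment %in% excluded] <- NA
  # relabel retained clusters by decreasing population, 0 = largest
  keep <- ids[pops >= min_population]
  keep <- keep[order(-sizes[match(keep, ids)], keep)]
  new_id <- seq_along(keep) - 1L
  assignment <- new_id[match(assignment, keep)]
  sizes_kept <- vapply(seq_along(keep),
                       function(i) sum(assignment == new_id[i], na.rm = TRUE), 0L)
  summary <- data.frame(cluster = new_id, n = sizes_kept,
                        population = sizes_kept / n)
  attr(summary, "noise_fraction") <-
    sum(is.na(assignment)) / n - excluded_fraction
  attr(summary, "excluded_fraction") <- excluded_fraction
  list(assignment = assignment, summary = summary)
}

#' Label clusters IN/OUT by majority vote and summarize features
#'
#' Each cluster is labeled `IN` when the majority of its frames are class
#' IN, `OUT` when the majority are OUT, and `unassigned` on a tie. When a
#' distance table is supplied, per-feature median distances are added.
#'
#' @param clustering result of [cluster_density()].
#' @param states result of [classify_states()] covering the same frames.
#' @param table optional distance table for per-cluster feature medians.
#' @return the clustering summary data.frame with a `label` column (and
#'   `median_<feature>` columns when `table` is given).
#' @export
label_clusters <- function(clustering, states, table = NULL) {
  assignment <- clustering$assignment
  if (length(assignment) != length(states$class))
    stop("cluster assignment and state series cover different frame counts")
  summ <- clustering$summary
  lab <- character(nrow(summ))
  for (i in seq_len(nrow(summ))) {
    sel <- which(assignment == summ$cluster[i])
    if (length(sel) == 0) stop("internal error: empty cluster ", summ$cluster[i])
    n_in <- sum(states$class[sel] == "IN")
    n_out <- sum(states$class[sel] == "OUT")
    lab[i] <- if (n_in > n_out) "IN" else if (n_out > n_in) "OUT" else "unassigned"
  }
  summ$label <- lab
  if (!is.null(table)) {
    feats <- setdiff(names(table), "frame")
    for (f in feats)
      summ[[paste0("median_", f)]] <- vapply(summ$cluster, function(cid)
        stats::median(table[[f]][which(assignment == cid)]), numeric(1))
  }
  summ
}

#' Sample representative frames from each retained cluster
#'
#' Uniform random sample without replacement of up to `n_per_cluster` frames
#' per cluster (all frames when the cluster is smaller), reproducible under
#' the seed. Mirrors the practice of extracting a handful of structures per
#' conformational cluster for subsequent electronic-structure work.
#'
#' @param clustering result of [cluster_density()] (or any list with an
#'   `assignment` vector).
#' @param n_per_cluster sample size per cluster.
#' @param seed integer seed.
#' @return named list (by cluster id) of integer frame indices.
#' @export
sample_representatives <- function(clustering, n_per_cluster = 10, seed = 1L) {
  assignment <- clustering$assignment
  ids <- sort(unique(assignment[!is.na(assignment)]))
  set.seed(seed)
  out <- list()
  for (cid in ids) {
    members <- which(assignment == cid)
    k <- min(n_per_cluster, length(members))
    out[[as.character(cid)]] <- sort(sample(members, k))
  }
  out
}
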