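# Hierarchical density-based clustering with excess-of-mass cluster
# selection. The hierarchy is single linkage on mutual-reachability
# distances d_mr(a, b) = max(core_a, core_b, d(a, b)), where core_x is the
# distance from x to its min_samples-th nearest neighbor (counting x
# itself). The dendrogram is condensed with min_cluster_size: at each split,
# a child smaller than min_cluster_size "falls out" of its parent at
# lambda = 1/height, while two large children spawn new clusters. Cluster
# stability is sum_p (lambda_leave(p) - lambda_birth); clusters are selected
# bottom-up where a parent's stability beats the sum of its children's.
# Unlike some implementations the root is selectable, so degenerate inputs
# (e.g. one tight blob, or all points identical) yield a single cluster
# rather than all-noise.

hdbscan_eom <- function(X, min_cluster_size, min_samples = min_cluster_size) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(min_cluster_size >= 2, n >= min_cluster_size)
  D <- as.matrix(stats::dist(X))
  k <- min(min_samples, n)
  core <- apply(D, 1L, function(r) sort(r, partial = k)[k])
  M <- pmax(D, core)                 # column-major recycling: core by row
  M <- pmax(M, rep(core, each = n))  # and by column
  hc <- stats::hclust(stats::as.dist(M), method = "single")
  merge <- hc$merge
  height <- hc$height

  size <- integer(n - 1)
  for (m in seq_len(n - 1)) {
    a <- merge[m, 1]; b <- merge[m, 2]
    size[m] <- (if (a < 0) 1L else size[a]) + (if (b < 0) 1L else size[b])
  }
  node_size <- function(v) if (v < 0) 1L else size[v]
  leaves <- function(node) {
    if (node < 0) return(-node)
    out <- integer(size[node]); pos <- 0L
    stack <- node
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v < 0) { pos <- pos + 1L; out[pos] <- -v }
      else stack <- c(stack, merge[v, 1], merge[v, 2])
    }
    out
  }

  hp <- height[height > 0]
  h_floor <- if (length(hp) > 0) min(hp) * 1e-6 else 1
  lam <- function(h) 1 / max(h, h_floor)

  # condensed tree
  cl_parent <- 0L
  cl_birth <- 0
  cl_stab <- 0
  cl_points <- list(seq_len(n))
  cl_children <- list(integer(0))
  tasks_node <- n - 1L
  tasks_cl <- 1L
  while (length(tasks_node) > 0) {
    m <- tasks_node[length(tasks_node)]
    cc <- tasks_cl[length(tasks_cl)]
    tasks_node <- tasks_node[-length(tasks_node)]
    tasks_cl <- tasks_cl[-length(tasks_cl)]
    h <- height[m]; lh <- lam(h)
    a <- merge[m, 1]; b <- merge[m, 2]
    sa <- node_size(a); sb <- node_size(b)
    if (sa >= min_cluster_size && sb >= min_cluster_size) {
      # true split: cc dies, its remaining mass leaves at lh
      cl_stab[cc] <- cl_stab[cc] + size[m] * (lh - cl_birth[cc])
      for (child in c(a, b)) {
        nid <- length(cl_birth) + 1L
        cl_parent[nid] <- cc
        cl_birth[nid] <- lh
        cl_stab[nid] <- 0
        cl_points[[nid]] <- leaves(child)
        cl_children[[nid]] <- integer(0)
        cl_children[[cc]] <- c(cl_children[[cc]], nid)
        tasks_node <- c(tasks_node, child)
        tasks_cl <- c(tasks_cl, nid)
      }
    } else if (sa >= min_cluster_size || sb >= min_cluster_size) {
      small <- if (sa >= min_cluster_size) b else a
      big <- if (sa >= min_cluster_size) a else b
      cl_stab[cc] <- cl_stab[cc] + node_size(small) * (lh - cl_birth[cc])
      tasks_node <- c(tasks_node, big)
      tasks_cl <- c(tasks_cl, cc)
    } else {
      # cluster dissolves: everything below leaves at lh
      cl_stab[cc] <- cl_stab[cc] + size[m] * (lh - cl_birth[cc])
    }
  }

  # excess-of-mass selection (children have larger ids than parents)
  nc <- length(cl_birth)
  score <- numeric(nc)
  selected <- logical(nc)
  for (cc in nc:1) {
    kids <- cl_children[[cc]]
    if (length(kids) == 0) {
      score[cc] <- cl_stab[cc]
      selected[cc] <- TRUE
    } else {
      ks <- sum(score[kids])
      if (cl_stab[cc] >= ks) {
        selected[cc] <- TRUE
        score[cc] <- cl_stab[cc]
        stack <- kids
        while (length(stack) > 0) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[v] <- FALSE
          stack <- c(stack, cl_children[[v]])
        }
      } else {
        score[cc] <- ks
      }
    }
  }

  # assign each point to the deepest selected cluster containing it
  labels <- rep(NA_integer_, n)
  sel_ids <- which(selected)
  sel_ids <- sel_ids[order(-cl_birth[sel_ids], -sel_ids)]
  next_label <- 0L
  for (cc in sel_ids) {
    pts <- cl_points[[cc]]
    pts <- pts[is.na(labels[pts])]
    if (length(pts) == 0) next
    labels[pts] <- next_label
    next_label <- next_label + 1L
  }
  list(labels = labels,
       n_clusters = next_label,
       condensed = list(parent = cl_parent, birth = cl_birth,
                        stability = cl_stab, selected = selected))
}
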