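# Self-organizing-map clustering with consensus metaclustering.
#
# A rectangular SOM (default 5x5) is trained online on the clustering
# channels of the pooled baseline + healthy cells; nodes are then grouped
# into k metaclusters by consensus clustering (average-linkage hierarchical
# clustering of a co-assignment frequency matrix built over resampled
# clusterings of the node weights). Cells from any sample -- including
# post-treatment samples never seen in training -- are assigned to their
# Euclidean-nearest node and inherit its metacluster label.

#' SOM training configuration
#'
#' @param grid `c(rows, cols)` of the node grid (default 5x5).
#' @param epochs passes over the training data (default 10).
#' @param alpha `c(initial, final)` learning rate, decayed linearly.
#' @param radius `c(initial, final)` Gaussian neighborhood radius in grid
#'   units; default decays from about half the grid diagonal to 0.
#' @param seed integer seed controlling weight initialization and
#'   presentation order.
#' @return object of class `som_config`.
#' @export
som_config <- function(grid = c(5, 5), epochs = 10,
                       alpha = c(0.05, 0.01), radius = NULL, seed = 1) {
  validate_that(length(grid) == 2 && all(grid >= 1), "grid",
                "must be c(rows, cols) with positive entries")
  if (is.null(radius)) {
    radius <- c(sqrt(sum((grid - 1)^2)) / 2, 0)
  }
  validate_that(all(alpha > 0) && diff(alpha) <= 0, "alpha",
                "rates must be positive and non-increasing")
  validate_that(all(radius >= 0) && diff(radius) <= 0, "radius",
                "radii must be non-negative and non-increasing")
  structure(list(grid = as.integer(grid), epochs = as.integer(epochs),
                 alpha = alpha, radius = radius, seed = as.integer(seed)),
            class = "som_config")
}

#' Train a self-organizing map
#'
#' @param cells numeric matrix (cells x channels) on the normalized
#'   transformed scale, restricted to the clustering channels, or a
#'   [cell_table()] together with a `panel` from which clustering channels
#'   are taken.
#' @param config a [som_config()].
#' @param panel optional [panel_config()]; when `cells` is a `cell_table`
#'   its clustering channels are selected.
#' @return object of class `som_model`: trained node weights, training BMU
#'   labels, quantization error, provenance.
#' @export
train_som <- function(cells, config = som_config(), panel = NULL) {
  if (inherits(cells, "cell_table")) {
    chs <- if (!is.null(panel)) panel_channels(panel, "clustering") else colnames(cells$data)
    cells <- cells$data[, chs, drop = FALSE]
  }
  cells <- as.matrix(cells)
  n_nodes <- prod(config$grid)
  if (nrow(cells) < n_nodes) {
    stop(sprintf("need at least %d cells to train a %dx%d SOM",
                 n_nodes, config$grid[1], config$grid[2]), call. = FALSE)
  }
  if (!all(is.finite(cells))) stop("non-finite values in training data", call. = FALSE)
  res <- withr::with_seed(config$seed, {
    init <- cells[sample.int(nrow(cells), n_nodes), , drop = FALSE]
    order <- as.integer(replicate(config$epochs, sample.int(nrow(cells)) - 1L))
    som_train_cpp(cells, init, config$grid[1], config$grid[2], order,
                  config$alpha[1], config$alpha[2],
                  config$radius[1], config$radius[2])
  })
  colnames(res) <- colnames(cells)
  bmu <- nearest_node_cpp(cells, res)
  structure(list(weights = res, grid = config$grid,
                 channels = colnames(cells),
                 metacluster = NULL,
                 training_bmu = bmu,
                 quantization_error = quantization_error_cpp(cells, res),
                 config = config),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d grid (%d nodes), %d channels, QE %.4f\n",
              x$grid[1], x$grid[2], nrow(x$weights), length(x$channels),
              x$quantization_error))
  if (!is.null(x$metacluster)) {
    cat(sprintf("  metaclusters: %d (%s)\n", max(x$metacluster),
                paste(table(x$metacluster), collapse = "/")))
  }
  invisible(x)
}

#' Consensus metaclustering of SOM nodes
#'
#' Builds a node co-assignment frequency matrix over `n_resamples`
#' average-linkage hierarchical clusterings of random node subsets
#' (`subsample` fraction each), then cuts an average-linkage tree of
#' `1 - frequency` at k groups. Labels are relabeled 1..k in order of first
#' appearance. The per-node consensus score (mean within-metacluster
#' co-assignment frequency) is stored; low scores flag unstable splits.
#'
#' @param model a trained [train_som()] model.
#' @param k number of metaclusters (default 10).
#' @param n_resamples resampled clusterings (default 100).
#' @param subsample node subsample fraction per resample (default 0.9).
#' @param seed integer seed.
#' @return the model with `metacluster` (per-node labels 1..k) and
#'   `consensus` (matrix + mean score) filled in.
#' @export
metacluster <- function(model, k = 10, n_resamples = 100, subsample = 0.9,
                        seed = 1) {
  stopifnot(inherits(model, "som_model"))
  n_nodes <- nrow(model$weights)
  if (k > n_nodes) stop("k exceeds the number of SOM nodes", call. = FALSE)
  if (k == n_nodes) {
    model$metacluster <- seq_len(n_nodes)
    model$consensus <- list(matrix = diag(n_nodes), score = 1)
    return(model)
  }
  if (k == 1) {
    model$metacluster <- rep(1L, n_nodes)
    model$consensus <- list(matrix = matrix(1, n_nodes, n_nodes), score = 1)
    return(model)
  }
  co <- matrix(0, n_nodes, n_nodes)
  cnt <- matrix(0, n_nodes, n_nodes)
  m <- max(2L, min(n_nodes, round(subsample * n_nodes)))
  withr::with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n_nodes, m))
      hc <- hclust(stats::dist(model$weights[idx, , drop = FALSE]),
                   method = "average")
      lab <- cutree(hc, k = min(k, m))
      same <- outer(lab, lab, `==`)
      co[idx, idx] <- co[idx, idx] + same
      cnt[idx, idx] <- cnt[idx, idx] + 1
    }
  })
  freq <- ifelse(cnt > 0, co / cnt, 0)
  diag(freq) <- 1
  hc <- hclust(as.dist(1 - freq), method = "average")
  lab <- cutree(hc, k = k)
  lab <- as.integer(factor(lab, levels = unique(lab)))  # relabel 1..k
  score <- mean(vapply(seq_len(n_nodes), function(i) {
    same <- which(lab == lab[i])
    mean(freq[i, same])
  }, numeric(1)))
  model$metacluster <- lab
  model$consensus <- list(matrix = freq, score = score)
  model
}

#' Assign cells to their nearest SOM node
#'
#' Each cell is assigned to the Euclidean-nearest trained node (ties broken
#' by lowest node index) and inherits the node's metacluster label. With
#' `level = "metacluster_centroid"` cells are instead assigned to the
#' nearest metacluster centroid (mean of its node weights).
#'
#' @param model a [train_som()] model (metaclustered, unless only node
#'   assignments are wanted).
#' @param sample a [cell_table()] on the normalized transformed scale, or a
#'   plain matrix with the training channels.
#' @param level `"node"` (default, nearest cluster center read as nearest
#'   SOM node) or `"metacluster_centroid"`.
#' @return data frame with `node` and (when available) `metacluster` per cell.
#' @export
assign_cells <- function(model, sample, level = c("node", "metacluster_centroid")) {
  stopifnot(inherits(model, "som_model"))
  level <- match.arg(level)
  data <- if (inherits(sample, "cell_table")) sample$data else as.matrix(sample)
  missing <- setdiff(model$channels, colnames(data))
  if (length(missing) > 0) {
    stop(sprintf("sample lacks training channels: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  data <- data[, model$channels, drop = FALSE]
  if (nrow(data) == 0) {
    return(data.frame(node = integer(0), metacluster = integer(0)))
  }
  if (level == "node") {
    node <- nearest_node_cpp(data, model$weights)
    mc <- if (!is.null(model$metacluster)) model$metacluster[node] else NA_integer_
    data.frame(node = node, metacluster = mc)
  } else {
    if (is.null(model$metacluster)) stop("model has no metacluster labels", call. = FALSE)
    cent <- do.call(rbind, lapply(sort(unique(model$metacluster)), function(g) {
      colMeans(model$weights[model$metacluster == g, , drop = FALSE])
    }))
    mc <- nearest_node_cpp(data, cent)
    data.frame(node = NA_integer_, metacluster = mc)
  }
}

#' Sub-cluster cells of one metacluster
#'
#' Trains an independent SOM on a cell subset (typically all cells assigned
#' to one metacluster across samples) using all surface channels, including
#' those excluded from the top-level clustering, then consensus-metaclusters
#' into k sub-clusters.
#'
#' @param cells matrix of transformed intensities for the subset, or a
#'   `cell_table`.
#' @param panel a [panel_config()]; all surface channels are used.
#' @param config a [som_config()].
#' @param k number of sub-clusters (default 10).
#' @return list with `model` (a metaclustered [train_som()] model) and
#'   `assignment` (per-cell sub-cluster labels for the input cells).
#' @export
subcluster <- function(cells, panel, config = som_config(), k = 10) {
  data <- if (inherits(cells, "cell_table")) cells$data else as.matrix(cells)
  if (nrow(data) == 0) stop("empty cell subset", call. = FALSE)
  chs <- intersect(panel_channels(panel, "surface"), colnames(data))
  model <- train_som(data[, chs, drop = FALSE], config)
  model <- metacluster(model, k = min(k, nrow(model$weights)),
                       seed = config$seed)
  assignment <- assign_cells(model, data[, chs, drop = FALSE])
  list(model = model, assignment = assignment)
}
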