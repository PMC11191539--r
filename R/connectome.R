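#' Structural connectivity network
#'
#' Validates a binary, symmetric, zero-diagonal adjacency matrix and wraps it
#' as a `structural_network`, the coupling substrate of the neural mass
#' network. Disconnected graphs are accepted with a warning (simulation on a
#' disconnected substrate is usually unintended).
#'
#' @param adjacency square numeric 0/1 matrix.
#' @param labels optional character vector of region names; defaults to
#'   `ROI_1..ROI_N`.
#' @return An object of class `structural_network` with fields `n_nodes`,
#'   `adjacency`, `labels`, `density`.
#' @export
structural_network <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 2L || ncol(adjacency) != n)
    stop("adjacency must be a square matrix with N >= 2")
  if (!is.numeric(adjacency) || anyNA(adjacency))
    stop("adjacency must be numeric without missing values")
  if (any(diag(adjacency) != 0)) stop("nonzero diagonal")
  if (any(adjacency != t(adjacency))) stop("asymmetric matrix")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1 (supply a binarization threshold on load)")
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(n))
  if (length(labels) != n) stop("labels must have one entry per node")
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(labels, labels)
  m <- sum(adjacency) / 2
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  if (igraph::components(g)$no > 1L)
    warning("graph is disconnected (", igraph::components(g)$no,
            " components); simulation assumes a single component")
  structure(list(n_nodes = n, adjacency = adjacency, labels = labels,
                 density = m / choose(n, 2)),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  cat(sprintf("<structural_network> %d nodes, %d edges (density %.4f)\n",
              x$n_nodes, sum(x$adjacency) / 2, x$density))
  invisible(x)
}

#' Load a structural connectivity matrix from delimited text
#'
#' Reads an `N x N` numeric matrix (CSV, TSV or whitespace separated; header
#' row/column optional and auto-detected for named matrices). Non-binary
#' matrices are rejected unless a `binarize` threshold is given, in which
#' case entries strictly greater than the threshold become 1.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"csv"`, `"tsv"`, `"whitespace"`.
#' @param binarize optional numeric threshold for weighted input.
#' @param labels optional region labels overriding any in the file.
#' @return A [structural_network()].
#' @export
load_adjacency <- function(path, dialect = c("auto", "csv", "tsv", "whitespace"),
                           binarize = NULL, labels = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- switch(dialect,
                csv = ",", tsv = "\t", whitespace = "",
                auto = {
                  l1 <- readLines(path, n = 1L)
                  if (grepl(",", l1, fixed = TRUE)) "," else
                    if (grepl("\t", l1, fixed = TRUE)) "\t" else ""
                })
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  # header detection: first row non-numeric -> treat as column labels
  if (any(is.na(suppressWarnings(as.numeric(unlist(raw[1, ])))))) {
    hdr <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    if (any(is.na(suppressWarnings(as.numeric(raw[, 1]))))) {
      hdr <- hdr[-1]
      raw <- raw[, -1, drop = FALSE]
    }
    if (is.null(labels)) labels <- hdr
  }
  mat <- as.matrix(raw)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric entries in adjacency file")
  if (nrow(mat) != ncol(mat)) stop("non-square matrix")
  if (!is.null(binarize)) mat <- (mat > binarize) + 0
  structural_network(mat, labels = labels)
}

#' Write a structural network as delimited text
#'
#' Inverse of [load_adjacency()]; `load_adjacency(write_adjacency(net, f))`
#' round-trips exactly.
#'
#' @param net a [structural_network()].
#' @param path output path.
#' @param dialect `"tsv"`, `"csv"` or `"whitespace"`.
#' @param header write region labels as a header row.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path, dialect = c("tsv", "csv", "whitespace"),
                            header = FALSE) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, csv = ",", tsv = "\t", whitespace = " ")
  m <- net$adjacency
  lines <- apply(m, 1L, function(r) paste(format(r, trim = TRUE), collapse = sep))
  if (header) lines <- c(paste(net$labels, collapse = sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a surrogate structural connectome
#'
#' The published benchmark uses a 78-region tractography-derived binary graph
#' that is not publicly printed; this generator produces a seeded stand-in
#' with an exact edge count `round(density * N(N-1)/2)`, re-sampled until
#' connected. Models: `"modular"` (default; edges drawn with 8:1 preference
#' for within-module pairs over `n_modules` equal modules, emulating the
#' community structure of cortical connectomes), `"erdos_renyi"` (uniform
#' G(n,m)), and `"watts_strogatz"` (ring lattice with `p_rewire` rewiring,
#' adjusted to the exact edge count).
#'
#' @param n_nodes number of regions.
#' @param density fraction of possible edges, in (0, 1].
#' @param model surrogate family.
#' @param seed integer seed; the same seed yields the same network. The
#'   caller's RNG state is preserved.
#' @param n_modules module count for the modular model.
#' @param p_rewire rewiring probability for the small-world model.
#' @param labels optional region labels (e.g. [aal78_labels()]).
#' @return A connected [structural_network()].
#' @examples
#' net <- generate_surrogate(78, 0.10, "erdos_renyi", seed = 1)
#' sum(net$adjacency) / 2  # 300 edges
#' @export
generate_surrogate <- function(n_nodes, density,
                               model = c("modular", "erdos_renyi",
                                         "watts_strogatz"),
                               seed = 1L, n_modules = 5L, p_rewire = 0.1,
                               labels = NULL) {
  model <- match.arg(model)
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  m <- round(density * choose(n_nodes, 2))
  if (m < n_nodes - 1)
    stop("density infeasible for connectivity: ", m, " edges < ",
         n_nodes - 1, " needed for a spanning tree")
  pairs <- utils::combn(n_nodes, 2L)
  w <- rep(1, ncol(pairs))
  if (model == "modular") {
    mod <- rep_len(seq_len(n_modules), n_nodes)
    w[mod[pairs[1L, ]] == mod[pairs[2L, ]]] <- 8
  }
  with_seed(seed, {
    for (try in 1:200) {
      adj <- matrix(0, n_nodes, n_nodes)
      if (model == "watts_strogatz") {
        nei <- max(1L, round(m / n_nodes))
        g <- igraph::sample_smallworld(1L, n_nodes, nei, p_rewire)
        g <- igraph::simplify(g)
        adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
        adj <- adjust_edge_count(adj, m)
      } else {
        idx <- sample.int(ncol(pairs), m, prob = w)
        adj[cbind(pairs[1L, idx], pairs[2L, idx])] <- 1
        adj <- adj + t(adj)
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (igraph::components(g)$no == 1L)
        return(structural_network(adj, labels = labels))
    }
  })
  stop("could not sample a connected graph at this density; increase density")
}

# add/remove uniformly-chosen edges so that the undirected edge count is m
adjust_edge_count <- function(adj, m) {
  n <- nrow(adj)
  ut <- which(upper.tri(adj))
  have <- ut[adj[ut] == 1]
  miss <- ut[adj[ut] == 0]
  k <- length(have) - m
  if (k > 0) {
    drop <- sample(have, k)
    adj[drop] <- 0
  } else if (k < 0) {
    addl <- sample(miss, -k)
    adj[addl] <- 1
  }
  adj[lower.tri(adj)] <- 0
  adj + t(adj)
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rank the connections most damaged by degeneration
#'
#' Compares two weighted edge-strength matrices on the same support (e.g.
#' effective inter-mass strengths at simulation start and at a later
#' timestep) and tabulates the edges with the strongest absolute loss,
#' the tabular analogue of the published glass-brain damage maps.
#'
#' @param strengths_t0 baseline `N x N` symmetric weighted matrix.
#' @param strengths_t later matrix, same shape and support.
#' @param top_k rows to keep (default all edges).
#' @param labels optional region labels.
#' @return A data.frame `(node_i, node_j, label_i, label_j, strength_t0,
#'   strength_t, loss)` sorted by decreasing loss, class `edge_change_table`.
#'   Node indices are 1-based.
#' @export
edge_loss_map <- function(strengths_t0, strengths_t, top_k = Inf,
                          labels = NULL) {
  if (!identical(dim(strengths_t0), dim(strengths_t)))
    stop("shape mismatch between strength matrices")
  n <- nrow(strengths_t0)
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(n))
  sup0 <- strengths_t0 != 0
  if (any(strengths_t[!sup0 & upper.tri(sup0)] != 0))
    stop("strength matrices are not defined on the same support")
  idx <- which(sup0 & upper.tri(sup0), arr.ind = TRUE)
  tab <- data.frame(node_i = idx[, 1L], node_j = idx[, 2L],
                    label_i = labels[idx[, 1L]], label_j = labels[idx[, 2L]],
                    strength_t0 = strengths_t0[idx],
                    strength_t = strengths_t[idx],
                    stringsAsFactors = FALSE)
  tab$loss <- tab$strength_t0 - tab$strength_t
  tab <- tab[order(-tab$loss, tab$node_i, tab$node_j), , drop = FALSE]
  if (is.finite(top_k)) tab <- utils::head(tab, top_k)
  rownames(tab) <- NULL
  class(tab) <- c("edge_change_table", "data.frame")
  tab
}

#' AAL-style labels for a 78-region cortical parcellation
#'
#' Generic left/right cortical region names in the style of the 78-region
#' automated-anatomical-labelling cortical atlas, for annotating per-ROI
#' outputs of the default 78-node surrogate. The list is a synthetic
#' stand-in resource, not the atlas definition itself.
#'
#' @return Character vector of length 78.
#' @export
aal78_labels <- function() {
  path <- system.file("extdata", "aal78_labels_synthetic.txt",
                      package = "addbench")
  readLines(path)
}
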