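hamming_matrix <- function(m) {
  k <- nrow(m)
  D <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  D
}

# Epsilon-relaxed minimum spanning network: an edge (u, v) is kept iff its
# weight is within epsilon of the connection level of u and v — the smallest
# distance level at which their components merge when levels are processed
# in ascending order. Connection levels are single-linkage cophenetic
# (minimax-path) distances, so epsilon = 0 yields the classic minimum
# spanning network (all edges tied at their merging level, a superset of
# every minimum spanning tree).
msn_edges <- function(D, epsilon = 0) {
  k <- nrow(D)
  keep <- matrix(FALSE, k, k, dimnames = dimnames(D))
  if (k < 2) return(keep)
  conn <- as.matrix(cophenetic(hclust(as.dist(D), method = "single")))
  conn <- conn[rownames(D), rownames(D)]
  keep <- D <= conn + epsilon & upper.tri(D)
  keep | t(keep)
}

column_majority <- function(a, b, c) {
  out <- character(length(a))
  for (j in seq_along(a)) {
    s <- c(a[j], b[j], c[j])
    tab <- sort(table(s), decreasing = TRUE)
    if (tab[1] < 2) return(NULL)  # three-way disagreement: no majority median
    out[j] <- names(tab)[1]
  }
  out
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network over a catalog of haplotype profiles:
#' iteratively (i) form the epsilon-relaxed minimum spanning network over
#' the current node set under Hamming distance on the profile columns (gap
#' `-` is a fifth character state); (ii) for every triplet of nodes with at
#' least two of its three pairs linked, form the per-column
#' majority-consensus median (Steiner) vector and, among the new vectors,
#' add those whose connection cost (sum of distances to the triplet) is
#' within epsilon of the minimum; (iii) drop unobserved vectors of degree
#' <= 1; until no vector is added. Median vectors are named `mv1`,
#' `mv2`, ... in creation order; candidate triplets are processed in
#' lexicographic order of their sorted node names, so the construction is
#' deterministic.
#'
#' @param catalog A [haplotype_catalog()] of observed haplotypes (>= 2).
#' @param counts Optional per-haplotype sample counts: a named vector, a
#'   per-sample tibble with `haplotype` (and optionally `region`) columns,
#'   or `NULL` (counts of 1). Region composition, when available, is
#'   attached to the nodes.
#' @param epsilon Non-negative relaxation of the minimum spanning network
#'   and of median-vector admission (default 0).
#' @return An object of class `mj_network`: `graph` (an igraph graph whose
#'   vertices carry `type`, `count` and region shares, and whose edges
#'   carry `weight` = mutation count), plus `nodes` and `edges` tibbles.
#'   `tidy()` returns the edge tibble.
#' @examples
#' net <- median_joining_network(lion_haplotype_catalog())
#' igraph::is_connected(net$graph)
#' @export
median_joining_network <- function(catalog, counts = NULL, epsilon = 0) {
  if (nrow(catalog) < 2) abort("need at least 2 haplotypes")
  if (epsilon < 0) abort("epsilon must be >= 0")
  profiles <- catalog_states(catalog)
  observed <- rownames(profiles)
  mv_next <- 1L

  repeat {
    D <- hamming_matrix(profiles)
    E <- msn_edges(D, epsilon)
    nodes <- rownames(profiles)
    k <- length(nodes)
    cand <- list()
    if (k >= 3) {
      trips <- combn(sort(nodes), 3)
      for (t in seq_len(ncol(trips))) {
        u <- trips[1, t]; v <- trips[2, t]; w <- trips[3, t]
        linked <- E[u, v] + E[u, w] + E[v, w]
        if (linked < 2) next
        med <- column_majority(profiles[u, ], profiles[v, ], profiles[w, ])
        if (is.null(med)) next
        key <- paste(med, collapse = "")
        if (key %in% apply(profiles, 1, paste, collapse = "")) next
        cost <- sum(med != profiles[u, ]) + sum(med != profiles[v, ]) +
          sum(med != profiles[w, ])
        cand[[length(cand) + 1L]] <- list(key = key, med = med, cost = cost)
      }
    }
    if (length(cand) == 0) break
    costs <- vapply(cand, `[[`, numeric(1), "cost")
    admit <- cand[costs <= min(costs) + epsilon]
    keys_seen <- character(0)
    added <- FALSE
    for (cd in admit) {
      if (cd$key %in% keys_seen) next
      keys_seen <- c(keys_seen, cd$key)
      profiles <- rbind(profiles, matrix(cd$med, nrow = 1,
                                         dimnames = list(paste0("mv", mv_next),
                                                         colnames(profiles))))
      mv_next <- mv_next + 1L
      added <- TRUE
    }
    if (!added) break
    if (nrow(profiles) > 50 * nrow(catalog)) {
      abort("median-joining did not converge (runaway median vectors)")
    }
    # prune unobserved vectors that are leaves of the refreshed network
    repeat {
      D2 <- hamming_matrix(profiles)
      E2 <- msn_edges(D2, epsilon)
      deg <- rowSums(E2)
      drop <- setdiff(rownames(profiles)[deg <= 1], observed)
      if (length(drop) == 0) break
      profiles <- profiles[!rownames(profiles) %in% drop, , drop = FALSE]
    }
  }

  # final prune and graph assembly
  repeat {
    D <- hamming_matrix(profiles)
    E <- msn_edges(D, epsilon)
    deg <- rowSums(E)
    drop <- setdiff(rownames(profiles)[deg <= 1], observed)
    if (length(drop) == 0) break
    profiles <- profiles[!rownames(profiles) %in% drop, , drop = FALSE]
  }

  node_names <- rownames(profiles)
  node_tbl <- tibble(
    name = node_names,
    type = ifelse(node_names %in% observed, "haplotype", "median"),
    count = 0)
  shares <- NULL
  if (!is.null(counts)) {
    if (is.data.frame(counts) && "region" %in% names(counts)) {
      shares <- counts |>
        count(.data$haplotype, .data$region) |>
        tidyr::pivot_wider(names_from = "region", values_from = "n",
                           values_fill = 0, names_prefix = "n_")
    }
    cn <- as_hap_counts(counts)
    node_tbl$count <- as.numeric(cn[node_tbl$name])
    node_tbl$count[is.na(node_tbl$count)] <- 0
    if (!is.null(shares)) {
      node_tbl <- left_join(node_tbl, shares, by = c(name = "haplotype"))
      node_tbl <- mutate(node_tbl, across(dplyr::starts_with("n_"),
                                          ~ ifelse(is.na(.x), 0, .x)))
    }
  }
  idx <- which(E & upper.tri(E), arr.ind = TRUE)
  edge_tbl <- tibble(from = node_names[idx[, 1]],
                     to = node_names[idx[, 2]],
                     weight = D[idx])
  edge_tbl <- arrange(edge_tbl, .data$from, .data$to)
  g <- igraph::graph_from_data_frame(edge_tbl, directed = FALSE,
                                     vertices = node_tbl)
  structure(list(graph = g, nodes = node_tbl, edges = edge_tbl,
                 epsilon = epsilon),
            class = "mj_network")
}

#' @exportS3Method generics::tidy
tidy.mj_network <- function(x, ...) x$edges

#' @export
print.mj_network <- function(x, ...) {
  cat("# Median-joining network: ", sum(x$nodes$type == "haplotype"),
      " haplotypes + ", sum(x$nodes$type == "median"),
      " median vector(s), ", nrow(x$edges), " edges\n", sep = "")
  print(x$edges)
  invisible(x)
}

#' Export / import a haplotype network
#'
#' `format = "graphml"` writes a single GraphML file via igraph, preserving
#' all node and edge attributes. `format = "edgelist"` writes a tab-
#' separated edge list (`from`, `to`, `weight`) plus a companion
#' `<path>.nodes.tsv` with the node table, so the graph round-trips.
#'
#' @param network An `mj_network` from [median_joining_network()].
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly. `import_network()` returns an `mj_network`.
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    abort(paste0("output directory does not exist: ", dirname(path)))
  }
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    readr::write_tsv(network$edges, path, progress = FALSE)
    readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
    nodes <- rename(nodes, name = "name")
    edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
    edges <- rename(edges, from = "from", to = "to")
  } else {
    edges <- readr::read_tsv(path, col_types = readr::cols(
      from = "c", to = "c", weight = "d"), progress = FALSE)
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
                             col_types = readr::cols(.default = "d",
                                                     name = "c", type = "c"),
                             progress = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  structure(list(graph = g, nodes = nodes,
                 edges = arrange(edges, .data$from, .data$to),
                 epsilon = NA_real_),
            class = "mj_network")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mj_network <- function(object, ...) {
  g <- object$graph
  xy <- igraph::layout_with_kk(g)
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "name", "x", "y"), by = c(from = "name")) |>
    left_join(select(nodes, "name", "x", "y"), by = c(to = "name"),
              suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = pmax(.data$count, 0.5),
                                     colour = .data$type)) +
    ggplot2::geom_text(data = filter(nodes, .data$type == "haplotype"),
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(name = "samples") +
    ggplot2::labs(colour = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
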