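#' Read / write an interaction network as an edge-list TSV
#'
#' Two gene-id columns (header optional, an optional third provenance
#' column is kept as an edge attribute). Directed or duplicated records are
#' collapsed to an undirected simple graph on load; self-loops are dropped.
#'
#' @param path file path.
#' @return an undirected simple igraph graph with named vertices.
#' @export
read_interaction_graph <- function(path) {
  first <- utils::read.table(path, sep = "\t", nrows = 1L,
                             stringsAsFactors = FALSE)
  header <- !is.na(suppressWarnings(
    match(tolower(as.character(first[1, 1])),
          c("gene_a", "gene1", "from", "source", "node_a"))))
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  interaction_graph(df)
}

#' @rdname read_interaction_graph
#' @param edges data.frame whose first two columns are gene ids.
#' @export
interaction_graph <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' @rdname read_interaction_graph
#' @param graph an igraph graph.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  utils::write.table(data.frame(gene_a = el[, 1L], gene_b = el[, 2L]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the direct + one-bridge candidate subnetwork
#'
#' From a global interaction network and a candidate gene list, retains
#' exactly (a) every edge joining two candidate genes, and (b) every
#' non-candidate gene adjacent (in the global graph) to at least two
#' distinct candidates, together with its edges to those candidates — the
#' "computationally recruited" bridge genes. Every retained edge therefore
#' lies on a candidate-candidate edge or a candidate-bridge-candidate path
#' of length two; bridge-bridge edges are never kept. Candidates with no
#' retained edge do not appear in the extracted graph.
#'
#' @param global undirected simple igraph graph with named vertices.
#' @param candidates character vector of candidate gene ids; ids not found
#'   in the global graph are dropped with a message.
#' @return a list of class `subnetwork_result`: `graph` (the extracted
#'   igraph graph with vertex attribute `role` in candidate/recruited),
#'   `candidates` (matched ids), `unmatched`, `recruited`, `degree` (named,
#'   within the extracted graph), `component_sizes` (descending),
#'   `largest_cluster_size` (node count; 0 when nothing is retained), and
#'   `permutation` (`NULL` until [randomization_test()]).
#' @export
extract_subnetwork <- function(global, candidates) {
  stopifnot(igraph::is_igraph(global), !igraph::is_directed(global))
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  all_nodes <- igraph::V(global)$name
  matched <- intersect(candidates, all_nodes)
  unmatched <- setdiff(candidates, all_nodes)
  if (length(unmatched) > 0L) {
    message(length(unmatched), " candidate id(s) not in the global network")
  }
  if (length(matched) == 0L) {
    warning("no candidate gene present in the global network")
    empty <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = empty, candidates = character(0),
                          unmatched = unmatched, recruited = character(0),
                          degree = stats::setNames(numeric(0), character(0)),
                          component_sizes = integer(0),
                          largest_cluster_size = 0L, permutation = NULL),
                     class = "subnetwork_result"))
  }
  adj <- global_adjacency(global)
  ext <- one_bridge_edges(adj, match(matched, all_nodes))
  graph <- if (nrow(ext$edges) == 0L) {
    igraph::make_empty_graph(0, directed = FALSE)
  } else {
    igraph::graph_from_data_frame(
      data.frame(from = all_nodes[ext$edges[, 1L]],
                 to = all_nodes[ext$edges[, 2L]]), directed = FALSE)
  }
  in_graph <- igraph::V(graph)$name
  recruited <- intersect(in_graph, all_nodes[ext$bridges])
  igraph::V(graph)$role <- ifelse(in_graph %in% matched,
                                  "candidate", "recruited")
  comp <- if (igraph::vcount(graph) > 0L) {
    sort(igraph::components(graph)$csize, decreasing = TRUE)
  } else integer(0)
  structure(list(graph = graph, candidates = matched, unmatched = unmatched,
                 recruited = recruited,
                 degree = igraph::degree(graph),
                 component_sizes = comp,
                 largest_cluster_size = if (length(comp)) comp[1L] else 0L,
                 permutation = NULL),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf(paste0("subnetwork: %d nodes (%d candidate, %d recruited), ",
                     "%d edges, largest cluster %d\n"),
              igraph::vcount(x$graph), sum(igraph::V(x$graph)$role == "candidate"),
              length(x$recruited), igraph::ecount(x$graph),
              x$largest_cluster_size))
  if (!is.null(x$permutation)) {
    cat(sprintf("randomization: p = %g (add-one %g), %d draws, null %s\n",
                x$permutation$p_value, x$permutation$p_value_add_one,
                x$permutation$n_randomizations, x$permutation$null_model))
  }
  invisible(x)
}

# integer adjacency list, computed once per graph
global_adjacency <- function(global) {
  lapply(igraph::as_adj_list(global, mode = "all"), as.integer)
}

# one-bridge extraction on integer node indices; returns retained edges
# (2-col matrix) and the recruited bridge indices
one_bridge_edges <- function(adj, cand_idx) {
  n <- length(adj)
  is_cand <- logical(n)
  is_cand[cand_idx] <- TRUE
  nb_all <- unlist(adj[cand_idx], use.names = FALSE)
  # candidate-candidate edges (each appears twice in the neighbor dump)
  from <- rep(cand_idx, lengths(adj[cand_idx]))
  cc <- is_cand[nb_all]
  cc_edges <- cbind(from[cc], nb_all[cc])
  cc_edges <- cc_edges[cc_edges[, 1L] < cc_edges[, 2L], , drop = FALSE]
  # bridges: non-candidates seen >= 2 times among candidate neighbors
  nb_out <- nb_all[!cc]
  cnt <- tabulate(nb_out, nbins = n)
  bridges <- which(cnt >= 2L & !is_cand)
  cb <- cbind(from[!cc], nb_out)
  cb_edges <- cb[nb_out %in% bridges, , drop = FALSE]
  list(edges = rbind(cc_edges, cb_edges), bridges = bridges)
}

# largest-cluster size of the one-bridge extraction, without building an
# igraph object; used inside the randomization loop
largest_cluster_size_fast <- function(adj, cand_idx) {
  ext <- one_bridge_edges(adj, cand_idx)
  if (nrow(ext$edges) == 0L) return(0L)
  nodes <- unique(as.vector(ext$edges))
  idx <- match(ext$edges, nodes)
  dim(idx) <- dim(ext$edges)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1L]); b <- find(idx[e, 2L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  max(tabulate(roots))
}

#' Randomization test on the largest subnetwork cluster
#'
#' Assesses whether the largest connected cluster of the extracted candidate
#' subnetwork is larger than expected for a random gene set of the same
#' size: draws `n_randomizations` gene sets of `length(candidates-matched)`
#' nodes from the global network, extracts each one's one-bridge subnetwork,
#' and counts the draws whose largest cluster strictly exceeds the observed
#' size. The literal empirical p is `count / n_randomizations`; an add-one
#' corrected p `(count + 1) / (n + 1)` is reported alongside so a zero count
#' is never presented as p = 0.
#'
#' @param global undirected simple igraph graph with named vertices.
#' @param candidates candidate gene ids (unmatched ids dropped; null draws
#'   use the matched count so observed and null are comparable).
#' @param n_randomizations number of random draws (>= 100).
#' @param null_model `"uniform_nodes"` draws uniformly from all nodes;
#'   `"degree_matched"` draws, for each candidate, a node from the same
#'   global-degree decile — an option for degree-heterogeneous networks
#'   where hubs inflate cluster sizes.
#' @param seed integer seed for the draws.
#' @return the [extract_subnetwork()] result with `permutation` filled:
#'   `n_randomizations`, `count_exceeding`, `p_value`, `p_value_add_one`,
#'   `null_model`, `seed`, `null_sizes` (per-draw largest-cluster sizes).
#' @export
randomization_test <- function(global, candidates, n_randomizations = 1000L,
                               null_model = c("uniform_nodes",
                                              "degree_matched"),
                               seed = 1L) {
  null_model <- match.arg(null_model)
  if (n_randomizations < 100L) stop("n_randomizations must be >= 100")
  observed <- extract_subnetwork(global, candidates)
  k <- length(observed$candidates)
  n_nodes <- igraph::vcount(global)
  if (k > n_nodes) stop("more candidates than global nodes")
  if (k == 0L) stop("no candidate matched the global network")
  adj <- global_adjacency(global)
  set.seed(as.integer(seed))
  if (null_model == "degree_matched") {
    deg <- igraph::degree(global)
    bin <- findInterval(deg, stats::quantile(deg, probs = seq(0.1, 0.9, 0.1)),
                        left.open = TRUE)
    cand_bins <- bin[match(observed$candidates, igraph::V(global)$name)]
    by_bin <- split(seq_len(n_nodes), bin)
    bin_counts <- table(factor(cand_bins, levels = names(by_bin)))
  }
  null_sizes <- integer(n_randomizations)
  for (b in seq_len(n_randomizations)) {
    draw <- if (null_model == "uniform_nodes") {
      sample.int(n_nodes, k)
    } else {
      unlist(lapply(names(by_bin), function(bn) {
        need <- bin_counts[[bn]]
        if (need == 0L) integer(0)
        else by_bin[[bn]][sample.int(length(by_bin[[bn]]),
                                     min(need, length(by_bin[[bn]])))]
      }), use.names = FALSE)
    }
    null_sizes[b] <- largest_cluster_size_fast(adj, draw)
  }
  count <- sum(null_sizes > observed$largest_cluster_size)
  observed$permutation <- list(
    n_randomizations = as.integer(n_randomizations),
    count_exceeding = count,
    p_value = count / n_randomizations,
    p_value_add_one = (count + 1) / (n_randomizations + 1),
    null_model = null_model,
    seed = as.integer(seed),
    null_sizes = null_sizes)
  observed
}

#' Rank genes by connectivity within the extracted subnetwork
#'
#' Orders nodes by their degree in the extracted graph, descending, with
#' ties broken lexicographically by gene id. Candidate / recruited status is
#' carried along.
#'
#' @param result a [extract_subnetwork()] result.
#' @param top_k how many genes to return (default all).
#' @return data.frame `gene`, `degree`, `role`.
#' @export
hub_ranking <- function(result, top_k = Inf) {
  stopifnot(inherits(result, "subnetwork_result"))
  if (igraph::vcount(result$graph) == 0L) stop("extracted graph is empty")
  df <- data.frame(gene = igraph::V(result$graph)$name,
                   degree = unname(igraph::degree(result$graph)),
                   role = igraph::V(result$graph)$role,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}

#' Drop weakly connected genes from an extracted subnetwork
#'
#' Single-pass filter: removes every node whose degree in the extracted
#' graph is below `min_degree` (degrees are measured once, before any
#' removal — no iterative re-pruning), together with its incident edges.
#' Used to declutter network figures ("genes with three or more known
#' interactions").
#'
#' @param result a [extract_subnetwork()] result.
#' @param min_degree minimum extracted-graph degree to keep a node.
#' @return the filtered igraph graph.
#' @export
degree_filter <- function(result, min_degree = 3L) {
  stopifnot(inherits(result, "subnetwork_result"), min_degree >= 0)
  g <- result$graph
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) < min_degree])
}

#' Write an extracted subnetwork to a directory
#'
#' Emits the edge list TSV, a node attribute TSV (`gene`, `role`,
#' `degree`), the permutation record as JSON (when present), and a GraphML
#' export for network viewers.
#'
#' @param result a `subnetwork_result`.
#' @param dir output directory, created if needed.
#' @export
write_subnetwork <- function(result, dir) {
  stopifnot(inherits(result, "subnetwork_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(result$graph, file.path(dir, "subnetwork_edges.tsv"))
  utils::write.table(hub_ranking(result),
                     file.path(dir, "subnetwork_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$permutation)) {
    jsonlite::write_json(result$permutation,
                         file.path(dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  igraph::write_graph(result$graph, file.path(dir, "subnetwork.graphml"),
                      format = "graphml")
  invisible(dir)
}
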