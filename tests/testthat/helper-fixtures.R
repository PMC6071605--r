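# Shared fixture builders and independent oracles used across test files.

# balanced replicate table from a matrix of cell means (lines x treatments),
# residuals supplied explicitly so expected values stay hand-computable
toy_table <- function(cell_means, n_reps = 2L, resid = 0,
                      treatments = c("regular", "ethanol")) {
  lines <- rownames(cell_means)
  grid <- expand.grid(replicate = seq_len(n_reps), treatment = treatments,
                      line = lines, stringsAsFactors = FALSE)
  grid$value <- cell_means[cbind(grid$line, grid$treatment)] + resid
  replicate_table(grid, phenotype = "toy", units = "u")
}

# genotype matrix from a calls matrix (variants x lines), sequential positions
toy_geno <- function(calls, chrom = "chr1") {
  n_v <- nrow(calls)
  genotype_matrix(calls,
                  data.frame(id = sprintf("v%03d", seq_len(n_v)),
                             chrom = chrom, pos = seq_len(n_v) * 100L,
                             ref = "A", alt = "T",
                             stringsAsFactors = FALSE),
                  lines = sprintf("L%02d", seq_len(ncol(calls))))
}

# named undirected graph from an edge matrix/vector c(a,b, c,d, ...)
toy_graph <- function(edges, isolated = character(0)) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolated) > 0L) {
    g <- igraph::add_vertices(g, length(isolated), name = isolated)
  }
  g
}

# --- independent oracles -----------------------------------------------------

# textbook simple-regression slope/SE/p on (g, y)
ols_oracle <- function(g, y) {
  n <- length(g)
  sxx <- sum((g - mean(g))^2)
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(g)
  rss <- sum((y - intercept - slope * g)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, se = se, t = t,
       p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}

# brute-force one-bridge extraction by pairwise enumeration: for every pair
# of candidates keep a direct edge, or both legs through any single
# non-candidate common neighbour
bridge_oracle <- function(graph, candidates) {
  nodes <- igraph::V(graph)$name
  cand <- intersect(candidates, nodes)
  edges <- character(0)
  add_edge <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    edges <<- union(edges, key)
  }
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"),
                function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  if (length(cand) >= 2L) {
    pairs <- utils::combn(cand, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      if (b %in% adj[[a]]) add_edge(a, b)
      for (v in setdiff(intersect(adj[[a]], adj[[b]]), cand)) {
        add_edge(a, v)
        add_edge(v, b)
      }
    }
  }
  if (length(edges) == 0L) {
    return(list(edges = character(0), largest = 0L))
  }
  em <- do.call(rbind, strsplit(edges, "|", fixed = TRUE))
  sub <- igraph::graph_from_data_frame(as.data.frame(em), directed = FALSE)
  list(edges = sort(edges),
       largest = max(igraph::components(sub)$csize))
}

# canonical sorted edge keys of an igraph graph, for set comparison
edge_keys <- function(graph) {
  if (igraph::ecount(graph) == 0L) return(character(0))
  el <- igraph::as_edgelist(graph, names = TRUE)
  sort(apply(el, 1L, function(r) paste(sort(r), collapse = "|")))
}
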