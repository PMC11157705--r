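# Independent oracles and small fixture builders shared across test files.
# All oracles avoid the code paths they check: graph distances come from a
# hand-rolled Floyd-Warshall, ranking metrics from exhaustive loops.

# Random connected graph: random recursive tree + extra random edges.
random_connected_edges <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  edges <- data.frame(gene_a = nodes[parent], gene_b = nodes[2:n],
                      stringsAsFactors = FALSE)
  if (extra > 0) {
    a <- sample.int(n, extra, replace = TRUE)
    b <- sample.int(n, extra, replace = TRUE)
    keep <- a != b
    edges <- rbind(edges, data.frame(gene_a = nodes[a[keep]],
                                     gene_b = nodes[b[keep]]))
  }
  edges
}

# Dense all-pairs shortest paths by Floyd-Warshall on the edge list.
fw_distances <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    d <- pmin(d, outer(dk, d[k, ], `+`))
  }
  d
}

# Brute-force proximity measures by explicit double loops over gene pairs.
brute_asp <- function(H, D, dm) {
  tot <- 0
  for (h in H) for (dd in D) tot <- tot + dm[h, dd]
  tot / (length(H) * length(D))
}
brute_acp <- function(H, D, dm) {
  tot <- 0
  for (h in H) {
    best <- Inf
    for (dd in D) best <- min(best, dm[h, dd])
    tot <- tot + best
  }
  tot / length(H)
}
brute_wacp <- function(w, D, dm) {
  tot <- 0
  for (h in names(w)) {
    best <- Inf
    for (dd in D) best <- min(best, dm[h, dd])
    tot <- tot + best / w[[h]]
  }
  tot / length(w)
}

# AUROC by exhaustive positive-negative pair comparison (ties count 1/2);
# lower score = predicted positive.
auroc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p < q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUPRC by step summation: precision at each unique-threshold recall step.
auprc_step_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores)
  s <- scores[ord]; l <- labels[ord]
  n_pos <- sum(l)
  area <- 0
  prev_recall <- 0
  for (t in unique(s)) {
    called <- s <= t
    recall <- sum(l & called) / n_pos
    precision <- sum(l & called) / sum(called)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Fixed tiny association-table fixture written to a temp TSV.
write_fixture_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Tiny deterministic profiles for scoring tests on a named path graph.
path_graph_oracle <- function(nodes) {
  edges <- data.frame(gene_a = nodes[-length(nodes)], gene_b = nodes[-1],
                      stringsAsFactors = FALSE)
  distance_oracle(build_graph(edges))
}

make_herb_profile <- function(id, weights, compounds = paste0(id, "_c1")) {
  structure(list(herb_id = id, compounds = compounds, gene_weights = weights),
            class = "herb_profile")
}

make_disease_profile <- function(id, genes) {
  structure(list(disease_id = id, genes = genes), class = "disease_profile")
}
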