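# fixtures and independent brute-force oracles used across the suite

make_named_graph <- function(edges, n = max(edges), weights = NULL) {
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- if (is.null(weights)) rep(1, igraph::ecount(g)) else weights
  g
}

two_triangles <- function() make_named_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4))

disjoint_cliques <- function(sizes) {
  edges <- integer(0)
  off <- 0L
  for (s in sizes) {
    pairs <- utils::combn(off + seq_len(s), 2)
    edges <- c(edges, as.vector(pairs))
    off <- off + s
  }
  make_named_graph(edges, n = off)
}

random_weighted_graph <- function(n, p = 0.4, max_w = 4) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  make_named_graph(as.vector(pairs[, keep, drop = FALSE]), n = n,
                   weights = sample.int(max_w, sum(keep), replace = TRUE))
}

# direct double-sum evaluation of Q over all vertex pairs
modularity_bruteforce <- function(graph, membership) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  k <- rowSums(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  unname(q / (2 * m))
}

# quadratic token-scan tagging oracle, independent of the regex path:
# tokenize on non-alphanumeric characters and look for consecutive runs
tag_scan_oracle <- function(description, corpus) {
  toks <- strsplit(tolower(description), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  hits <- vapply(seq_len(nrow(corpus)), function(r) {
    phrase <- strsplit(corpus$surface[r], " ", fixed = TRUE)[[1]]
    L <- length(phrase)
    if (length(toks) < L) return(FALSE)
    any(vapply(seq_len(length(toks) - L + 1L), function(s)
      all(toks[s + seq_len(L) - 1L] == phrase), logical(1)))
  }, logical(1))
  sort(unique(corpus$tag[hits]))
}

# brute-force all-pairs shared-tag graph oracle
shared_tag_oracle <- function(assignments) {
  ids <- sort(assignments$app_id)
  tags <- assignments$tags[match(ids, assignments$app_id)]
  out <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    w <- length(intersect(tags[[i]], tags[[j]]))
    if (w > 0)
      out[[length(out) + 1L]] <- data.frame(a = ids[j], b = ids[i], w = w)
  }
  if (length(out) == 0)
    return(data.frame(a = character(), b = character(), w = numeric()))
  do.call(rbind, out)
}

# double-loop iota oracle following the definition literally
iota_bruteforce <- function(x) {
  n <- dim(x)[1]; J <- dim(x)[2]; K <- dim(x)[3]
  d <- function(r, s) mean(r != s)
  obs <- c()
  for (i in seq_len(n))
    for (g in seq_len(J - 1)) for (h in (g + 1):J)
      obs <- c(obs, d(x[i, g, ], x[i, h, ]))
  expd <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (g in seq_len(J)) for (h in seq_len(J)) {
      if (g == h) next
      expd <- c(expd, d(x[i, g, ], x[j, h, ]))
    }
  }
  1 - mean(obs) / mean(expd)
}

random_rating_array <- function(n, J, K = 5, levels = c("none", "low", "high")) {
  array(sample(levels, n * J * K, replace = TRUE), dim = c(n, J, K),
        dimnames = list(sprintf("c%02d", seq_len(n)),
                        sprintf("r%d", seq_len(J)), NULL))
}

# expand an archetype table into one row per member cluster, distributing the
# archetype's apps across its clusters
expand_reference_clusters <- function(arch) {
  rows <- list()
  cid <- 0L
  for (i in seq_len(nrow(arch))) {
    nc <- arch$n_clusters[i]
    na <- arch$n_apps[i]
    sizes <- rep(na %/% nc, nc)
    if (na %% nc > 0) sizes[seq_len(na %% nc)] <- sizes[seq_len(na %% nc)] + 1L
    for (j in seq_len(nc)) {
      cid <- cid + 1L
      rows[[cid]] <- data.frame(cluster_id = sprintf("cl%03d", cid),
                                specificity = arch$specificity[i],
                                leaks = arch$leaks[i], change = arch$change[i],
                                loss = arch$loss[i], value = arch$value[i],
                                n_apps = sizes[j], stringsAsFactors = FALSE)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
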