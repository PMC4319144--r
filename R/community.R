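#' @name community
#' @title Modularity and Louvain clustering of the app graph
#'
#' @description
#' Weighted Newman--Girvan modularity
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \frac{k_i k_j}{2m}\Big]\,
#'   \delta(c_i, c_j)}
#' where \eqn{A_{ij}} is the shared-tag edge weight, \eqn{k_i} the weighted
#' degree, and \eqn{m} the total edge weight, together with an in-package
#' Louvain optimiser (two phases per pass: seed-shuffled local vertex moves
#' maximising \eqn{\Delta Q}, then aggregation of communities into
#' super-vertices with self-loops), an exhaustive set-partition oracle for
#' graphs of at most 10 vertices, and an adjusted-Rand recovery score against
#' planted structure.
NULL

# edge arrays (1-based vertex indices) from an igraph object; self-loops kept.
graph_edges <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  list(i = as.integer(el[, 1]), j = as.integer(el[, 2]), w = as.numeric(w),
       n = igraph::vcount(graph))
}

# weighted degrees; a self-loop of weight w adds 2w to its vertex
edge_degrees <- function(ed) {
  loop <- ed$i == ed$j
  idx <- c(ed$i[!loop], ed$j[!loop], ed$i[loop])
  add <- c(ed$w[!loop], ed$w[!loop], 2 * ed$w[loop])
  k <- numeric(ed$n)
  if (length(idx) > 0) {
    agg <- rowsum(add, idx)
    k[as.integer(rownames(agg))] <- agg[, 1]
  }
  k
}

# Q for an integer membership vector over edge arrays
modularity_from_edges <- function(ed, comm, k = edge_degrees(ed)) {
  m <- sum(ed$w)
  if (m == 0) return(0)
  intra <- comm[ed$i] == comm[ed$j]
  e_in <- 2 * sum(ed$w[intra])
  K <- rowsum(k, comm)[, 1]
  e_in / (2 * m) - sum(K^2) / (4 * m^2)
}

# accept a partition as a tibble (app_id, cluster) or a named vector and
# return an integer membership aligned to the graph's vertex order
as_membership <- function(graph, partition) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  if (is.data.frame(partition)) {
    lab <- partition$cluster[match(nm, partition$app_id)]
  } else {
    lab <- unname(partition[nm])
  }
  if (any(is.na(lab)))
    stop("partition is missing vertices: ",
         paste(utils::head(nm[is.na(lab)], 5), collapse = ", "), call. = FALSE)
  match(lab, unique(lab))
}

# relabel memberships so cluster ids are 0-based, ordered by smallest member
# vertex name
canonicalize_membership <- function(comm, names) {
  first <- vapply(split(names, comm), min, character(1))
  ord_comms <- names(first)[order(first)]
  match(as.character(comm), ord_comms) - 1L
}

#' Modularity of a partition of the app graph
#'
#' Pure evaluation of weighted modularity for a given partition. The trivial
#' all-in-one partition scores exactly 0; values lie in \eqn{[-1, 1]}.
#'
#' @param graph an app graph ([build_graph()]).
#' @param partition a tibble with columns `app_id` and `cluster`, or a vector
#'   of cluster labels named by app id. Every vertex must be assigned.
#' @return the modularity score \eqn{Q}.
#' @export
graph_modularity <- function(graph, partition) {
  ed <- graph_edges(graph)
  if (sum(ed$w) == 0) {
    warning("graph has no edges; modularity defined as 0")
    return(0)
  }
  modularity_from_edges(ed, as_membership(graph, partition))
}

# adjacency lists (neighbours + weights, loops dropped) from edge arrays
edge_adjacency <- function(ed) {
  nl <- ed$i != ed$j
  src <- c(ed$i[nl], ed$j[nl])
  dst <- c(ed$j[nl], ed$i[nl])
  w <- c(ed$w[nl], ed$w[nl])
  ord <- order(src)
  idx <- split(seq_along(src)[ord], src[ord])
  nb <- vector("list", ed$n)
  wt <- vector("list", ed$n)
  for (v in names(idx)) {
    vi <- as.integer(v)
    nb[[vi]] <- dst[idx[[v]]]
    wt[[vi]] <- w[idx[[v]]]
  }
  list(nb = nb, wt = wt)
}

# one Louvain local-moving phase; returns membership over current vertices,
# incrementally maintained Q, and whether any move was accepted
louvain_local_move <- function(ed, max_sweeps = 200L) {
  n <- ed$n
  m <- sum(ed$w)
  k <- edge_degrees(ed)
  adj <- edge_adjacency(ed)
  comm <- seq_len(n)
  sigma_tot <- k
  loop_w <- numeric(n)
  lp <- ed$i == ed$j
  if (any(lp)) {
    agg <- rowsum(ed$w[lp], ed$i[lp])
    loop_w[as.integer(rownames(agg))] <- agg[, 1]
  }
  q_inc <- 2 * sum(loop_w) / (2 * m) - sum(k^2) / (4 * m^2)
  moved_any <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (v in sample.int(n)) {
      nb <- adj$nb[[v]]
      if (length(nb) == 0) next
      c0 <- comm[v]
      links <- rowsum(adj$wt[[v]], comm[nb])
      cand <- as.integer(rownames(links))
      lw <- links[, 1]
      if (!c0 %in% cand) { cand <- c(cand, c0); lw <- c(lw, 0) }
      sigma_tot[c0] <- sigma_tot[c0] - k[v]
      gain <- lw / m - k[v] * sigma_tot[cand] / (2 * m^2)
      top <- max(gain)
      target <- min(cand[gain >= top - 1e-13])
      sigma_tot[target] <- sigma_tot[target] + k[v]
      if (target != c0) {
        q_inc <- q_inc + unname(gain[match(target, cand)] - gain[match(c0, cand)])
        comm[v] <- target
        improved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(comm = comm, q_inc = q_inc, moved = moved_any)
}

# contract communities into super-vertices; parallel edges summed, intra
# edges become self-loops
louvain_aggregate <- function(ed, comm) {
  dense <- match(comm, sort(unique(comm)))
  nc <- max(dense)
  ci <- dense[ed$i]; cj <- dense[ed$j]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  key <- (lo - 1) * nc + hi
  agg <- rowsum(ed$w, key)
  kk <- as.numeric(rownames(agg))
  lo2 <- as.integer((kk - 1) %/% nc) + 1L
  hi2 <- as.integer((kk - 1) %% nc) + 1L
  list(ed = list(i = lo2, j = hi2, w = agg[, 1], n = nc), dense = dense)
}

#' Louvain community detection
#'
#' Two-phase modularity optimisation: seed-shuffled local vertex moves (each
#' vertex joins the neighbouring community with the largest positive
#' \eqn{\Delta Q}; ties go to the lowest community id), then contraction of
#' communities into super-vertices with self-loops, repeated until a full
#' pass improves modularity by no more than `tol`. Modularity is maintained
#' incrementally during local moves and recomputed from scratch on the
#' original graph after every pass; both series are returned in the trace and
#' must agree to numerical precision.
#'
#' @param graph a non-empty app graph.
#' @param seed integer seed controlling the vertex visiting order.
#' @param max_passes upper bound on move/aggregate passes.
#' @param tol minimum per-pass modularity improvement to continue.
#' @return a list with
#'   \describe{
#'     \item{partition}{tibble `app_id`, `cluster` (canonical 0-based ids,
#'       ordered by smallest member app id).}
#'     \item{modularity}{final \eqn{Q}, recomputed from scratch.}
#'     \item{n_clusters}{number of communities.}
#'     \item{trace}{tibble `pass`, `modularity` (from scratch),
#'       `modularity_incremental` (bookkeeping value); non-decreasing in
#'       `pass`.}
#'     \item{seed}{the seed used.}
#'   }
#' @export
louvain_cluster <- function(graph, seed = 1L, max_passes = 50L, tol = 1e-9) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  if (max_passes < 1) stop("max_passes must be positive", call. = FALSE)
  ed0 <- graph_edges(graph)
  if (sum(ed0$w) == 0) {
    # edgeless graph: every vertex its own community, Q defined as 0
    warning("graph has no edges; returning singleton partition with Q = 0")
    nm <- igraph::V(graph)$name %||% as.character(seq_len(ed0$n))
    comm <- canonicalize_membership(seq_len(ed0$n), nm)
    return(list(partition = tibble::tibble(app_id = nm, cluster = comm),
                modularity = 0, n_clusters = ed0$n,
                trace = tibble::tibble(pass = integer(), modularity = numeric(),
                                       modularity_incremental = numeric()),
                seed = as.integer(seed)))
  }
  set.seed(seed)
  ed <- ed0
  node_of_orig <- seq_len(ed0$n)
  trace <- list()
  q_prev <- -Inf
  pass <- 0L
  repeat {
    pass <- pass + 1L
    lm <- louvain_local_move(ed)
    comm_orig <- lm$comm[node_of_orig]
    q_scratch <- modularity_from_edges(ed0, comm_orig)
    trace[[pass]] <- c(pass = pass, modularity = q_scratch,
                       modularity_incremental = lm$q_inc)
    if (!lm$moved && pass > 1L) break
    if (q_scratch - q_prev <= tol && pass > 1L) break
    q_prev <- q_scratch
    if (pass >= max_passes) break
    agg <- louvain_aggregate(ed, lm$comm)
    node_of_orig <- agg$dense[node_of_orig]
    ed <- agg$ed
    if (ed$n == ed0$n && !lm$moved) break
  }
  tr <- do.call(rbind, trace)
  nm <- igraph::V(graph)$name %||% as.character(seq_len(ed0$n))
  comm_final <- lm$comm[node_of_orig]
  cluster <- canonicalize_membership(comm_final, nm)
  list(partition = tibble::tibble(app_id = nm, cluster = cluster),
       modularity = modularity_from_edges(ed0, comm_final),
       n_clusters = length(unique(cluster)),
       trace = tibble::tibble(pass = as.integer(tr[, "pass"]),
                              modularity = tr[, "modularity"],
                              modularity_incremental = tr[, "modularity_incremental"]),
       seed = as.integer(seed))
}

#' Exhaustive modularity-optimal partition (small-graph oracle)
#'
#' Enumerates every set partition of the vertex set (restricted-growth-string
#' order) and returns the modularity maximum. Refuses graphs with more than
#' 10 vertices (Bell-number blow-up). Ties resolve to the lexicographically
#' smallest canonical assignment, i.e. the first maximum in enumeration
#' order.
#'
#' @param graph an app graph with at most 10 vertices.
#' @return a list with `partition` (tibble `app_id`, `cluster`, canonical
#'   0-based ids) and `modularity`.
#' @export
exhaustive_best_partition <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph", call. = FALSE)
  if (n > 10) stop("refusing exhaustive search on more than 10 vertices",
                   call. = FALSE)
  ed <- graph_edges(graph)
  k <- edge_degrees(ed)
  best_q <- -Inf
  best <- integer(n)
  a <- integer(n)
  recurse <- function(pos, maxc) {
    if (pos > n) {
      q <- modularity_from_edges(ed, a[seq_len(n)], k)
      if (q > best_q) {
        best_q <<- q
        best <<- a[seq_len(n)]
      }
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) {
      a[pos] <<- c
      recurse(pos + 1L, max(maxc, c))
    }
  }
  a[1] <- 1L
  recurse(2L, 1L)
  if (n == 1) { best <- 1L; best_q <- modularity_from_edges(ed, 1L, k) }
  nm <- igraph::V(graph)$name %||% as.character(seq_len(n))
  list(partition = tibble::tibble(app_id = nm,
                                  cluster = canonicalize_membership(best, nm)),
       modularity = best_q)
}

#' Adjusted Rand index between a partition and planted labels
#'
#' Chance-corrected agreement between two labelings of the same objects: 1
#' for identical partitions up to relabeling, expectation approximately 0 for
#' independent random partitions.
#'
#' @param partition,truth partitions of the same objects: tibbles with
#'   `app_id` plus a label column (`cluster`, `planted_archetype` or the
#'   second column), or vectors of labels named by app id.
#' @return the adjusted Rand index.
#' @export
recovery_score <- function(partition, truth) {
  lab <- function(x) {
    if (is.data.frame(x)) {
      col <- intersect(c("cluster", "planted_archetype"), names(x))
      col <- if (length(col)) col[1] else names(x)[2]
      setNames(as.character(x[[col]]), x$app_id)
    } else setNames(as.character(x), names(x))
  }
  a <- lab(partition); b <- lab(truth)
  if (length(a) != length(b) || !setequal(names(a), names(b)))
    stop("partitions cover different object sets", call. = FALSE)
  b <- b[names(a)]
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Write a partition as CSV with a JSON run-metadata sidecar
#'
#' The CSV has columns `app_id`, `cluster`; the sidecar
#' (`<path>.meta.json`) records seed, modularity and pass count.
#'
#' @param result a [louvain_cluster()] result.
#' @param path CSV path.
#' @export
write_partition_csv <- function(result, path) {
  write.csv(result$partition, path, row.names = FALSE)
  meta <- list(seed = result$seed, modularity = result$modularity,
               n_clusters = result$n_clusters,
               passes = nrow(result$trace))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
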