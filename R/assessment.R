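#' @name assessment
#' @title Five-characteristic cluster assessment and archetype consolidation
#'
#' @description
#' Each informative cluster is rated on five nominal information-security and
#' privacy characteristics: health *specificity* of information available to
#' apps (standard, nonstandard, medical) and potential damage through
#' information *leaks*, *change* (manipulation), *loss*, plus *value* of the
#' information to third parties (none, low, high each). Agreement between two
#' or more raters is quantified with the Janson--Olsson iota coefficient, a
#' multivariate extension of Cohen's kappa; clusters with identical resolved
#' assessment vectors are consolidated into app archetypes.
NULL

#' Characteristic names and admissible levels
#' @return a named list of level vectors, in severity order.
#' @export
characteristic_levels <- function() {
  list(specificity = c("standard", "nonstandard", "medical"),
       leaks = c("none", "low", "high"),
       change = c("none", "low", "high"),
       loss = c("none", "low", "high"),
       value = c("none", "low", "high"))
}

characteristics <- function() names(characteristic_levels())

#' Build a complete rating matrix from per-rater cluster assessments
#'
#' @param assessments tibble with columns `cluster_id`, `rater_id`,
#'   `informative`, and the five characteristic columns (`specificity`,
#'   `leaks`, `change`, `loss`, `value`). Only clusters rated informative by
#'   every rater enter the matrix; a cluster rated informative by one rater
#'   but missing a characteristic is an error.
#' @return a 3-d character array `objects x judges x variables` of class
#'   `"rating_matrix"`.
#' @export
rating_matrix <- function(assessments) {
  a <- assessments
  raters <- sort(unique(a$rater_id))
  if (length(raters) < 2)
    stop("rating matrix needs at least 2 judges", call. = FALSE)
  inf_by_all <- tapply(a$informative, a$cluster_id, all)
  clusters <- sort(names(inf_by_all)[inf_by_all])
  if (length(clusters) < 2)
    stop("rating matrix needs at least 2 objects", call. = FALSE)
  vars <- characteristics()
  x <- array(NA_character_, dim = c(length(clusters), length(raters), length(vars)),
             dimnames = list(clusters, raters, vars))
  for (v in vars) {
    for (r in raters) {
      sub <- a[a$rater_id == r & a$cluster_id %in% clusters, ]
      x[match(sub$cluster_id, clusters), r, v] <- sub[[v]]
    }
  }
  if (anyNA(x)) {
    miss <- which(is.na(x), arr.ind = TRUE)
    stop("missing rating cells, e.g. cluster ", clusters[miss[1, 1]],
         ", judge ", raters[miss[1, 2]], ", characteristic ",
         vars[miss[1, 3]], call. = FALSE)
  }
  lv <- characteristic_levels()
  for (v in vars) {
    bad <- !x[, , v] %in% lv[[v]]
    if (any(bad))
      stop("invalid level '", x[, , v][bad][1], "' for characteristic ", v,
           call. = FALSE)
  }
  structure(x, class = c("rating_matrix", "array"))
}

#' Janson--Olsson iota: multivariate nominal inter-rater agreement
#'
#' \eqn{\iota = 1 - D_{obs}/D_{exp}} with the nominal mismatch distance
#' \eqn{d(r, s) = K^{-1} \sum_k 1[r_k \ne s_k]} over the \eqn{K} variables.
#' \eqn{D_{obs}} averages \eqn{d} over all objects and unordered pairs of
#' distinct judges rating the same object; \eqn{D_{exp}} averages \eqn{d}
#' over all ordered pairs of distinct objects and all ordered pairs of
#' distinct judges. Perfect agreement yields 1; if
#' every rating in the matrix is identical, \eqn{D_{exp} = 0} and iota is
#' reported as 1 with a degenerate-data warning.
#'
#' @param x a [rating_matrix()] or a 3-d array `objects x judges x
#'   variables` (a 2-d `objects x judges` matrix is treated as one
#'   variable).
#' @return the agreement coefficient.
#' @export
iota <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3)
    stop("expected an objects x judges x variables array", call. = FALSE)
  if (anyNA(x)) stop("rating matrix has missing cells", call. = FALSE)
  n <- dim(x)[1]; J <- dim(x)[2]; K <- dim(x)[3]
  if (n < 2 || J < 2)
    stop("iota needs at least 2 objects and 2 judges", call. = FALSE)
  # observed disagreement: unordered pairs of distinct judges, same object
  pairs <- combn(J, 2)
  d_obs_sum <- 0
  for (p in seq_len(ncol(pairs))) {
    g <- pairs[1, p]; h <- pairs[2, p]
    d_obs_sum <- d_obs_sum + sum(x[, g, , drop = FALSE] != x[, h, , drop = FALSE]) / K
  }
  d_obs <- d_obs_sum / (n * ncol(pairs))
  # expected disagreement by frequency counting: ordered pairs of distinct
  # objects x ordered pairs of distinct judges
  d_exp_sum <- 0
  for (k in seq_len(K)) {
    cells <- x[, , k, drop = TRUE]
    if (is.null(dim(cells))) cells <- matrix(cells, n, J)
    tot_mismatch <- (n * J)^2 - sum(table(cells)^2)
    same_obj <- sum(vapply(seq_len(n), function(i)
      J^2 - sum(table(cells[i, ])^2), numeric(1)))
    same_judge <- sum(vapply(seq_len(J), function(g)
      n^2 - sum(table(cells[, g])^2), numeric(1)))
    d_exp_sum <- d_exp_sum + (tot_mismatch - same_obj - same_judge)
  }
  d_exp <- d_exp_sum / (K * n * (n - 1) * J * (J - 1))
  if (d_exp == 0) {
    warning("degenerate ratings: all cells identical; iota reported as 1")
    return(1)
  }
  1 - d_obs / d_exp
}

#' Resolve inter-rater disagreements into one assessment per cluster
#'
#' Cells where all judges agree take the agreed value; disagreeing cells
#' take the adjudicated override (the recorded outcome of rater discussion).
#' A disagreement with no override is an error listing the offending
#' (cluster, characteristic) cells.
#'
#' @param x a [rating_matrix()].
#' @param adjudication optional tibble of overrides with columns
#'   `cluster_id`, `characteristic`, `value`.
#' @return a tibble with one resolved row per cluster: `cluster_id` plus the
#'   five characteristic columns.
#' @export
resolve_disagreements <- function(x, adjudication = NULL) {
  clusters <- dimnames(x)[[1]]
  vars <- dimnames(x)[[3]]
  if (!is.null(adjudication)) {
    bad <- !(adjudication$cluster_id %in% clusters &
               adjudication$characteristic %in% vars)
    if (any(bad))
      stop("adjudication references unknown cells: ",
           paste(adjudication$cluster_id[bad], adjudication$characteristic[bad],
                 sep = "/", collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(matrix(NA_character_, length(clusters), length(vars),
                              dimnames = list(NULL, vars)))
  unresolved <- character()
  for (ci in seq_along(clusters)) {
    for (v in vars) {
      vals <- unique(x[ci, , v])
      if (length(vals) == 1) {
        out[ci, v] <- vals
      } else {
        ov <- if (!is.null(adjudication))
          adjudication$value[adjudication$cluster_id == clusters[ci] &
                               adjudication$characteristic == v]
        else character()
        if (length(ov) == 1) out[ci, v] <- ov
        else unresolved <- c(unresolved, paste0("(", clusters[ci], ", ", v, ")"))
      }
    }
  }
  if (length(unresolved) > 0)
    stop("unresolved disagreements with no adjudication: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  tibble::as_tibble(cbind(data.frame(cluster_id = clusters,
                                     stringsAsFactors = FALSE), out))
}

#' Partition clusters by the informative flag
#'
#' Uninformative clusters (tags convey no interpretable security/privacy
#' content) are excluded before assessment; app totals of both parts are
#' reported for the selection flow.
#'
#' @param clusters tibble with columns `cluster_id`, `informative` and
#'   optionally `n_apps`.
#' @return a list with `informative` and `excluded` tibbles, and counts
#'   `n_informative`, `n_excluded`, `apps_informative`, `apps_excluded`.
#' @export
exclude_uninformative <- function(clusters) {
  if (!"informative" %in% names(clusters) || anyNA(clusters$informative))
    stop("every cluster needs an informative flag", call. = FALSE)
  flag <- as.logical(clusters$informative)
  sizes <- if ("n_apps" %in% names(clusters)) clusters$n_apps else
    rep(NA_integer_, nrow(clusters))
  list(informative = clusters[flag, , drop = FALSE],
       excluded = clusters[!flag, , drop = FALSE],
       n_informative = sum(flag), n_excluded = sum(!flag),
       apps_informative = sum(sizes[flag]),
       apps_excluded = sum(sizes[!flag]))
}

signature_key <- function(df) {
  do.call(paste, c(df[characteristics()], sep = "|"))
}

severity_rank <- function(df) {
  lv <- characteristic_levels()
  ranks <- lapply(characteristics(), function(v) match(df[[v]], lv[[v]]))
  do.call(order, ranks)
}

#' Consolidate identically assessed clusters into app archetypes
#'
#' Clusters sharing an identical resolved 5-characteristic vector form one
#' archetype. Archetypes are numbered in ascending severity order of their
#' signature (specificity, then leaks, change, loss, value; with
#' standard < nonstandard < medical and none < low < high), the convention
#' that also orders published archetype tables.
#'
#' @param resolved resolved per-cluster assessments
#'   ([resolve_disagreements()] output restricted to informative clusters).
#' @param cluster_sizes app counts per cluster: a tibble with `cluster_id`,
#'   `n_apps` or a named vector.
#' @param descriptors optional named character vector mapping signature keys
#'   or archetype ids to free-text descriptors.
#' @return a tibble with one row per archetype: `archetype`, the five
#'   characteristic columns, `n_clusters`, `n_apps`, `member_clusters`
#'   (list column) and `descriptor`.
#' @export
consolidate <- function(resolved, cluster_sizes, descriptors = NULL) {
  if (is.data.frame(cluster_sizes))
    cluster_sizes <- setNames(cluster_sizes$n_apps, cluster_sizes$cluster_id)
  missing_sz <- setdiff(resolved$cluster_id, names(cluster_sizes))
  if (length(missing_sz) > 0)
    stop("no size for clusters: ", paste(missing_sz, collapse = ", "),
         call. = FALSE)
  missing_as <- setdiff(names(cluster_sizes), resolved$cluster_id)
  if (length(missing_as) > 0)
    stop("clusters without resolved assessment: ",
         paste(missing_as, collapse = ", "), call. = FALSE)
  key <- signature_key(resolved)
  sig <- resolved[!duplicated(key), c("cluster_id", characteristics())]
  sig <- sig[severity_rank(sig), ]
  sig_keys <- signature_key(sig)
  members <- split(resolved$cluster_id, match(key, sig_keys))
  out <- tibble::tibble(archetype = seq_along(sig_keys))
  for (v in characteristics()) out[[v]] <- sig[[v]]
  out$n_clusters <- unname(lengths(members)[as.character(seq_along(sig_keys))])
  out$n_apps <- vapply(seq_along(sig_keys), function(i)
    sum(cluster_sizes[members[[as.character(i)]]]), numeric(1))
  out$member_clusters <- lapply(seq_along(sig_keys), function(i)
    sort(members[[as.character(i)]]))
  out$descriptor <- if (!is.null(descriptors)) {
    ifelse(!is.na(descriptors[sig_keys]), descriptors[sig_keys],
           descriptors[as.character(out$archetype)])
  } else NA_character_
  out
}

#' Read / write per-rater cluster assessments as CSV
#'
#' Columns: `cluster_id`, `rater_id`, `informative`, `specificity`, `leaks`,
#' `change`, `loss`, `value`, `annotation`. For uninformative clusters the
#' five characteristic columns are empty.
#'
#' @param assessments assessment tibble.
#' @param path file path.
#' @export
write_assessments_csv <- function(assessments, path) {
  write.csv(assessments, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assessments_csv
#' @export
read_assessments_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  df$informative <- as.logical(df$informative)
  for (v in characteristics()) df[[v]][!nzchar(df[[v]] %||% "")] <- NA
  tibble::as_tibble(df)
}

#' Render an archetype table as Markdown
#'
#' Mirrors the columns of published archetype tables: archetype id, the five
#' characteristics, cluster and app counts with percentages over the
#' informative totals.
#'
#' @param archetypes [consolidate()] output.
#' @return a character vector of Markdown lines.
#' @export
archetype_markdown <- function(archetypes) {
  tot_c <- sum(archetypes$n_clusters)
  tot_a <- sum(archetypes$n_apps)
  hdr <- c("| AT | Specificity | Leaks | Change | Loss | Value | Clusters n (%) | Apps n (%) |",
           "|---|---|---|---|---|---|---|---|")
  rows <- vapply(seq_len(nrow(archetypes)), function(i) {
    a <- archetypes[i, ]
    sprintf("| %d | %s | %s | %s | %s | %s | %d (%.1f) | %d (%.2f) |",
            a$archetype, a$specificity, a$leaks, a$change, a$loss, a$value,
            a$n_clusters, round_half_up(100 * a$n_clusters / tot_c, 1),
            a$n_apps, round_half_up(100 * a$n_apps / tot_a, 2))
  }, character(1))
  c(hdr, rows)
}
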