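#' Selection-flow report
#'
#' Tracks app counts through the pipeline: discovered in the stores, excluded
#' by the minimum-distinct-tag filter, clustered, excluded as members of
#' uninformative clusters, and finally assessed. Any derivable field may be
#' omitted; supplying all three of discovered / excluded / clustered checks
#' the identity `discovered - excluded_by_tagging = clustered` and fails
#' loudly if it does not hold.
#'
#' @param discovered apps found per store (named vector over stores, or a
#'   single total).
#' @param excluded_by_tagging apps failing the tag filter (same shape);
#'   computed from `discovered - clustered` when omitted.
#' @param clustered apps entering clustering; computed from
#'   `discovered - excluded_by_tagging` when omitted.
#' @param uninformative_apps apps in clusters excluded as uninformative.
#' @param clusters_total,clusters_uninformative optional cluster counts.
#' @return a list of class `"flow_report"` with per-store and total counts,
#'   `excluded_pct` (share of discovered apps removed by tagging),
#'   `uninformative_pct` (share of clustered apps removed with uninformative
#'   clusters) and `assessed`.
#' @export
build_flow <- function(discovered, excluded_by_tagging = NULL, clustered = NULL,
                       uninformative_apps = NA_real_,
                       clusters_total = NA_integer_,
                       clusters_uninformative = NA_integer_) {
  if (any(discovered < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  if (is.null(excluded_by_tagging) && is.null(clustered))
    stop("need at least one of excluded_by_tagging / clustered", call. = FALSE)
  if (is.null(excluded_by_tagging)) excluded_by_tagging <- discovered - clustered
  if (is.null(clustered)) clustered <- discovered - excluded_by_tagging
  if (any(excluded_by_tagging < 0) || any(clustered < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(abs(discovered - excluded_by_tagging - clustered) > 1e-9))
    stop("flow identity violated: discovered - excluded_by_tagging != clustered",
         call. = FALSE)
  d <- sum(discovered); e <- sum(excluded_by_tagging); c_ <- sum(clustered)
  assessed <- if (is.na(uninformative_apps)) NA_real_ else c_ - uninformative_apps
  if (!is.na(assessed) && assessed < 0)
    stop("flow identity violated: clustered - uninformative_apps < 0",
         call. = FALSE)
  structure(list(
    discovered = discovered, excluded_by_tagging = excluded_by_tagging,
    clustered = clustered, uninformative_apps = uninformative_apps,
    clusters_total = clusters_total,
    clusters_uninformative = clusters_uninformative,
    total_discovered = d, total_excluded = e, total_clustered = c_,
    assessed = assessed,
    excluded_pct = if (d > 0) round_half_up(100 * e / d, 2) else NA_real_,
    uninformative_pct = if (!is.na(uninformative_apps) && c_ > 0)
      round_half_up(100 * uninformative_apps / c_, 2) else NA_real_),
    class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat("App selection flow\n")
  cat("  discovered:          ", x$total_discovered, "\n")
  cat("  excluded by tagging: ", x$total_excluded,
      sprintf(" (%.2f%%)", x$excluded_pct), "\n")
  cat("  clustered:           ", x$total_clustered, "\n")
  if (!is.na(x$uninformative_apps))
    cat("  uninformative apps:  ", x$uninformative_apps,
        sprintf(" (%.2f%%)", x$uninformative_pct), "\n")
  if (!is.na(x$assessed))
    cat("  assessed:            ", x$assessed, "\n")
  invisible(x)
}

#' Aggregate archetypes into a per-characteristic level table
#'
#' For each of the five characteristics and each level, sums cluster and app
#' counts over the archetypes carrying that level and computes percentages
#' of the informative-cluster and assessed-app totals (cluster percentages
#' to 1 decimal, app percentages to 2, half-up).
#'
#' @param archetypes [consolidate()] output or the bundled reference table
#'   ([read_archetype_table()]): needs the five characteristic columns plus
#'   `n_clusters` and `n_apps`.
#' @return a tibble with columns `characteristic`, `level`, `clusters`,
#'   `cluster_pct`, `apps`, `app_pct`.
#' @export
characteristic_table <- function(archetypes) {
  if (!all(c(characteristics(), "n_clusters", "n_apps") %in% names(archetypes)))
    stop("archetype table is missing required columns", call. = FALSE)
  tot_c <- sum(archetypes$n_clusters)
  tot_a <- sum(archetypes$n_apps)
  lv <- characteristic_levels()
  rows <- list()
  for (v in characteristics()) {
    for (l in lv[[v]]) {
      sel <- archetypes[[v]] == l
      rows[[length(rows) + 1L]] <- tibble::tibble(
        characteristic = v, level = l,
        clusters = sum(archetypes$n_clusters[sel]),
        cluster_pct = round_half_up(100 * sum(archetypes$n_clusters[sel]) / tot_c, 1),
        apps = sum(archetypes$n_apps[sel]),
        app_pct = round_half_up(100 * sum(archetypes$n_apps[sel]) / tot_a, 2))
    }
  }
  do.call(rbind, rows)
}

#' Read the bundled reference archetype table
#'
#' The published 12-archetype table of the 2013 iOS/Android mHealth store
#' survey (five characteristic levels, cluster and app counts per archetype)
#' shipped as plain CSV; the worked examples and the acceptance script
#' recompute characteristic-level aggregates from it.
#'
#' @param path CSV path; defaults to the bundled copy.
#' @return a tibble with columns `archetype`, `descriptor`, the five
#'   characteristics, `n_clusters`, `n_apps`.
#' @export
read_archetype_table <- function(path = system.file("extdata",
                                                    "survey_archetypes.csv",
                                                    package = "mhealthscape")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(archetype = df$archetype, descriptor = df$descriptor,
                 specificity = df$specificity, leaks = df$leaks,
                 change = df$change, loss = df$loss, value = df$value,
                 n_clusters = df$clusters, n_apps = df$apps)
}

#' Read the bundled reference selection-flow counts
#'
#' Per-store app counts of the 2013 store-survey selection flow (discovered,
#' excluded by tagging, clustered, rating-coverage counts and
#' uninformative-cluster totals) as a long tibble.
#'
#' @param path CSV path; defaults to the bundled copy.
#' @return a tibble with columns `quantity`, `store`, `value`.
#' @export
read_flow_table <- function(path = system.file("extdata", "survey_flow.csv",
                                               package = "mhealthscape")) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Per-store rating summary
#'
#' Descriptive statistics of the 5-star ratings: mean/median/SD of the
#' rating mean over rated apps, and the fractions of apps unrated, rated
#' fewer than 10 times, rated more than 1000 times, and (among rated apps)
#' rated at least 4 or at most 2 stars.
#'
#' @param records app-record tibble.
#' @return a tibble with one row per store present in the records.
#' @export
rating_summary <- function(records) {
  out <- lapply(sort(unique(records$store)), function(st) {
    r <- records[records$store == st, ]
    rated <- r[r$rating_count > 0, ]
    tibble::tibble(
      store = st, n = nrow(r), n_rated = nrow(rated),
      mean_rating = if (nrow(rated)) mean(rated$rating_mean) else NA_real_,
      median_rating = if (nrow(rated)) median(rated$rating_mean) else NA_real_,
      sd_rating = if (nrow(rated) > 1) sd(rated$rating_mean) else NA_real_,
      frac_unrated = mean(r$rating_count == 0),
      frac_lt10 = mean(r$rating_count < 10),
      frac_gt1000 = mean(r$rating_count > 1000),
      frac_rated_ge4 = if (nrow(rated)) mean(rated$rating_mean >= 4) else NA_real_,
      frac_rated_le2 = if (nrow(rated)) mean(rated$rating_mean <= 2) else NA_real_)
  })
  do.call(rbind, out)
}

# Mann-Whitney U with tie-corrected normal approximation; U reported for the
# first-named group
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  list(U = u1, z = z, p = min(p, 1), r = abs(z) / sqrt(N), n = N)
}

#' Compare ratings between stores and relate rating count to download band
#'
#' Rank-sum (Mann--Whitney) comparison of rating means between the two
#' stores among rated apps, with tie-corrected normal approximation and the
#' effect size \eqn{r = |z|/\sqrt{n}}; `U` is reported for the first group
#' in `groups`. For Android records with download bands, the Spearman rank
#' correlation between rating count and band rank is reported.
#'
#' @param records app-record tibble.
#' @param groups character vector of the two store levels to compare; the
#'   first names the group whose `U` is reported.
#' @return a list with `rating_test` (U, z, p, r, n) and
#'   `count_band_spearman` (rho, n, p; `NULL` when no bands are present).
#' @export
compare_ratings <- function(records, groups = c("android", "ios")) {
  rated <- records[records$rating_count > 0 & !is.na(records$rating_mean), ]
  x <- rated$rating_mean[rated$store == groups[1]]
  y <- rated$rating_mean[rated$store == groups[2]]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups need at least one rated app", call. = FALSE)
  test <- mann_whitney(x, y)
  droid <- records[records$store == "android" & !is.na(records$download_band), ]
  spear <- NULL
  if (nrow(droid) > 1) {
    band_rank <- match(droid$download_band, download_bands()$labels)
    ct <- stats::cor.test(droid$rating_count, band_rank, method = "spearman",
                          exact = FALSE)
    spear <- list(rho = unname(ct$estimate), n = nrow(droid),
                  p = ct$p.value)
  }
  list(rating_test = test, count_band_spearman = spear)
}

#' Write the standard report files
#'
#' Writes the characteristic-level table (CSV), the archetype table (CSV and
#' Markdown) and the selection flow (CSV) into a directory.
#'
#' @param dir output directory (created if absent).
#' @param flow a [build_flow()] report.
#' @param archetypes [consolidate()] output.
#' @export
write_report <- function(dir, flow, archetypes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct <- characteristic_table(archetypes)
  write.csv(ct, file.path(dir, "characteristic_table.csv"), row.names = FALSE)
  arch_flat <- archetypes[setdiff(names(archetypes), "member_clusters")]
  write.csv(arch_flat, file.path(dir, "archetypes.csv"), row.names = FALSE)
  writeLines(archetype_markdown(archetypes), file.path(dir, "archetypes.md"))
  fl <- data.frame(quantity = c("discovered", "excluded_by_tagging",
                                "clustered", "uninformative_apps", "assessed"),
                   value = c(flow$total_discovered, flow$total_excluded,
                             flow$total_clustered, flow$uninformative_apps,
                             flow$assessed))
  write.csv(fl, file.path(dir, "flow.csv"), row.names = FALSE)
  invisible(dir)
}
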