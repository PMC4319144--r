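#' Configuration for the synthetic app-store corpus generator
#'
#' Bundles and validates every knob of [generate_corpus()]. Defaults emulate
#' the descriptive statistics of the 2013 iOS/Android mHealth store survey the
#' pipeline was designed around: a roughly 9:1 iOS:Android imbalance, about a
#' third of discovered apps failing the four-distinct-tag inclusion filter,
#' zero-inflated rating counts with a heavy log-normal tail (75.76% of iOS and
#' 42.37% of Android apps unrated; ~1.4--1.6% rated more than 1000 times),
#' per-store 5-star rating means of 3.1 (SD 1.01, iOS) and 3.7 (SD 1.08,
#' Android), and Android download bands strongly positively coupled to rating
#' count.
#'
#' @param n_apps number of app records to generate.
#' @param store_weights named probabilities over `c("ios", "android")`.
#' @param noise_fraction probability that an app is non-health "noise": it
#'   receives fewer planted corpus strings than the inclusion threshold and is
#'   later excluded by the tag filter.
#' @param archetype_count number of planted archetypes.
#' @param tags_per_archetype_pool tags in each archetype's pool (including the
#'   shared overlap tags).
#' @param tags_per_app_min,tags_per_app_lambda a non-noise app carries
#'   `tags_per_app_min + Poisson(tags_per_app_lambda)` planted tags (capped at
#'   the pool size).
#' @param pool_overlap_fraction fraction of each pool drawn from a tag set
#'   shared by all archetypes, keeping the app graph connected.
#' @param noise_tags_max noise apps carry 0..`noise_tags_max` planted tags;
#'   must stay below the inclusion threshold used downstream.
#' @param unrated_probability named per-store probability of a zero rating
#'   count.
#' @param rating_mean_params named list of `c(mean, sd)` per store: the
#'   *underlying* location/scale of the normal that is truncated to the 1--5
#'   star scale. Defaults are calibrated so the truncated draws reproduce the
#'   observed per-store rating moments (iOS mean 3.1, SD 1.01; Android mean
#'   3.7 with SD as close to 1.08 as the bounded scale allows, about 1.0).
#' @param rating_count_meanlog,rating_count_sdlog named per-store log-normal
#'   parameters of the positive rating-count tail.
#' @param download_noise_sdlog log-scale noise linking the latent Android
#'   download count to the rating count before banding.
#' @param seed integer seed; regeneration with an identical config is
#'   byte-identical.
#'
#' @return a validated list of class `"generator_config"`.
#' @seealso [generate_corpus()], [sample_rating_block()]
#' @export
generator_config <- function(n_apps = 2000L,
                             store_weights = c(ios = 0.9, android = 0.1),
                             noise_fraction = 0.3448,
                             archetype_count = 8L,
                             tags_per_archetype_pool = 20L,
                             tags_per_app_min = 4L,
                             tags_per_app_lambda = 2,
                             pool_overlap_fraction = 0.1,
                             noise_tags_max = 3L,
                             unrated_probability = c(ios = 0.7576, android = 0.4237),
                             rating_mean_params = list(ios = c(mean = 3.20, sd = 1.44),
                                                       android = c(mean = 7.9, sd = 2.9)),
                             rating_count_meanlog = c(ios = 3.77, android = 1.72),
                             rating_count_sdlog = c(ios = 1.99, android = 2.69),
                             download_noise_sdlog = 0.25,
                             seed = 1L) {
  cfg <- list(n_apps = as.integer(n_apps), store_weights = store_weights,
              noise_fraction = noise_fraction, archetype_count = as.integer(archetype_count),
              tags_per_archetype_pool = as.integer(tags_per_archetype_pool),
              tags_per_app_min = as.integer(tags_per_app_min),
              tags_per_app_lambda = tags_per_app_lambda,
              pool_overlap_fraction = pool_overlap_fraction,
              noise_tags_max = as.integer(noise_tags_max),
              unrated_probability = unrated_probability,
              rating_mean_params = rating_mean_params,
              rating_count_meanlog = rating_count_meanlog,
              rating_count_sdlog = rating_count_sdlog,
              download_noise_sdlog = download_noise_sdlog,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("configuration error: '", field, "' must lie in [0, 1]", call. = FALSE)
  }
  chk_pos <- function(x, field) {
    if (any(is.na(x)) || any(x <= 0))
      stop("configuration error: '", field, "' must be positive", call. = FALSE)
  }
  chk_pos(cfg$n_apps, "n_apps")
  chk_pos(cfg$archetype_count, "archetype_count")
  chk_pos(cfg$tags_per_archetype_pool, "tags_per_archetype_pool")
  chk_pos(cfg$tags_per_app_min, "tags_per_app_min")
  chk_prob(cfg$noise_fraction, "noise_fraction")
  chk_prob(cfg$pool_overlap_fraction, "pool_overlap_fraction")
  chk_prob(cfg$store_weights, "store_weights")
  chk_prob(cfg$unrated_probability, "unrated_probability")
  if (!all(c("ios", "android") %in% names(cfg$store_weights)))
    stop("configuration error: 'store_weights' must name both stores", call. = FALSE)
  if (abs(sum(cfg$store_weights) - 1) > 1e-8)
    stop("configuration error: 'store_weights' must sum to 1", call. = FALSE)
  if (cfg$noise_tags_max < 0)
    stop("configuration error: 'noise_tags_max' must be non-negative", call. = FALSE)
  invisible(cfg)
}

# Google Play dialect download bands, ordered
download_bands <- function() {
  breaks <- c(0, 1, 5, 10, 50, 100, 500, 1000, 5000, 10000, 50000,
              100000, 500000, 1000000, 5000000, Inf)
  fmt <- function(x) formatC(x, format = "d", big.mark = ",")
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  labels <- c(paste(fmt(lo[-length(lo)]), "–", fmt(hi[-length(hi)])),
              paste0(fmt(lo[length(lo)]), "+"))
  list(breaks = breaks, labels = labels)
}

#' Draw rating metadata for one store
#'
#' Rating counts are zero-inflated (per-store zero probability) with a
#' log-normal positive tail; rating means are truncated normal on the 1--5
#' star scale and absent when the count is zero. For Android, a latent
#' download count positively coupled to the rating count is banded
#' deterministically into ordered Google-Play-style download bands.
#'
#' @param config a [generator_config()].
#' @param store `"ios"` or `"android"`.
#' @param n number of draws.
#' @return a tibble with columns `rating_count`, `rating_mean` (`NA` when
#'   unrated) and `download_band` (`NA` for iOS).
#' @export
sample_rating_block <- function(config, store, n = 1L) {
  if (!store %in% c("ios", "android"))
    stop("unknown store: '", store, "'", call. = FALSE)
  p0 <- config$unrated_probability[[store]]
  unrated <- runif(n) < p0
  count <- integer(n)
  nr <- sum(!unrated)
  if (nr > 0) {
    tail_draw <- rlnorm(nr, meanlog = config$rating_count_meanlog[[store]],
                        sdlog = config$rating_count_sdlog[[store]])
    # heavy tail capped at the top download band to stay in integer range
    count[!unrated] <- pmax(1L, as.integer(round(pmin(tail_draw, 5e6))))
  }
  mp <- config$rating_mean_params[[store]]
  mean_vals <- rep(NA_real_, n)
  if (nr > 0) {
    lo <- pnorm((1 - mp[["mean"]]) / mp[["sd"]])
    hi <- pnorm((5 - mp[["mean"]]) / mp[["sd"]])
    u <- runif(nr, lo, hi)
    mean_vals[!unrated] <- mp[["mean"]] + mp[["sd"]] * qnorm(u)
  }
  band <- rep(NA_character_, n)
  if (store == "android") {
    latent <- 20 * (count + 1) * rlnorm(n, 0, config$download_noise_sdlog)
    bd <- download_bands()
    band <- as.character(cut(latent, breaks = bd$breaks, labels = bd$labels,
                             right = FALSE, include.lowest = TRUE))
  }
  tibble::tibble(rating_count = count, rating_mean = mean_vals,
                 download_band = band)
}

# deterministic pseudo-medical synonym surface strings for tag i; digits keep
# them disjoint from any natural-language filler vocabulary
tag_surfaces <- function(i) {
  roots <- c("medi", "cardi", "neuro", "derma", "pulmo", "gastro", "osteo",
             "hema", "nephro", "endo")
  suffixes <- c("zine", "trax", "olin")
  root <- roots[(i - 1L) %% length(roots) + 1L]
  paste0(root, i, suffixes)
}

#' Generate a synthetic app-store corpus with planted archetype structure
#'
#' Builds `n_apps` app records across both stores. Each non-noise app is
#' assigned to one of `archetype_count` planted archetypes and carries tags
#' drawn from that archetype's pool; its description embeds one synonym
#' surface string per planted tag (word boundaries intact) amid natural
#' filler words disjoint from the tag corpus. Noise apps carry fewer planted
#' strings than the inclusion threshold, so downstream tag filtering excludes
#' them. Every planted tag has at least two synonym surface strings in the
#' returned corpus, mirroring the many-to-one surface-to-tag mapping of
#' manually seeded tag corpora.
#'
#' @param config a [generator_config()].
#' @return a list with elements
#'   \describe{
#'     \item{apps}{tibble of app records: `app_id`, `store`, `category`,
#'       `title`, `description`, `rating_count`, `rating_mean`,
#'       `download_band`.}
#'     \item{truth}{tibble of ground truth: `app_id`, `planted_archetype`
#'       (`NA` for noise apps), `planted_tags` (list column).}
#'     \item{corpus}{tag-corpus tibble: `surface`, `tag`.}
#'   }
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  A <- config$archetype_count
  pool_size <- config$tags_per_archetype_pool
  n_shared <- round(config$pool_overlap_fraction * pool_size)
  n_unique <- pool_size - n_shared
  n_tags <- A * n_unique + n_shared
  tags <- sprintf("T%03d", seq_len(n_tags))
  shared <- if (n_shared > 0) tags[seq_len(n_shared)] else character()
  pools <- lapply(seq_len(A), function(a) {
    own <- tags[n_shared + (a - 1L) * n_unique + seq_len(n_unique)]
    c(shared, own)
  })

  surfaces <- lapply(seq_len(n_tags), tag_surfaces)
  corpus <- tibble::tibble(surface = unlist(surfaces),
                           tag = rep(tags, lengths(surfaces)))

  filler <- filler_vocabulary()
  n <- config$n_apps
  app_id <- sprintf("app%05d", seq_len(n))
  store <- sample(names(config$store_weights), n, replace = TRUE,
                  prob = config$store_weights)
  category <- sample(c("medical", "health_fitness"), n, replace = TRUE)
  is_noise <- runif(n) < config$noise_fraction
  archetype <- ifelse(is_noise, NA_integer_, sample.int(A, n, replace = TRUE))

  planted <- vector("list", n)
  description <- character(n)
  for (i in seq_len(n)) {
    if (is_noise[i]) {
      k <- sample.int(config$noise_tags_max + 1L, 1L) - 1L
      planted[[i]] <- if (k > 0) sample(tags, k) else character()
    } else {
      k <- min(pool_size,
               config$tags_per_app_min + rpois(1L, config$tags_per_app_lambda))
      planted[[i]] <- sample(pools[[archetype[i]]], k)
    }
    n_fill <- sample(25:50, 1L)
    words <- sample(filler, n_fill, replace = TRUE)
    if (length(planted[[i]]) > 0) {
      ins <- vapply(planted[[i]], function(tg) {
        syn <- surfaces[[match(tg, tags)]]
        syn[sample.int(length(syn), 1L)]
      }, character(1))
      pos <- sample.int(n_fill + 1L, length(ins), replace = TRUE) - 1L
      out <- words
      for (j in order(pos, decreasing = TRUE))
        out <- append(out, ins[j], after = pos[j])
      description[i] <- paste(out, collapse = " ")
    } else {
      # some zero-tag noise apps have no usable description at all
      description[i] <- if (runif(1) < 0.1) "" else paste(words, collapse = " ")
    }
  }

  ratings <- tibble::tibble(rating_count = integer(n),
                            rating_mean = rep(NA_real_, n),
                            download_band = rep(NA_character_, n))
  for (st in c("ios", "android")) {
    idx <- which(store == st)
    if (length(idx) > 0)
      ratings[idx, ] <- sample_rating_block(config, st, length(idx))
  }

  apps <- tibble::tibble(app_id = app_id, store = store, category = category,
                         title = paste("App", sub("^app", "", app_id)),
                         description = description,
                         rating_count = ratings$rating_count,
                         rating_mean = ratings$rating_mean,
                         download_band = ratings$download_band)
  truth <- tibble::tibble(app_id = app_id, planted_archetype = archetype,
                          planted_tags = planted)
  list(apps = apps, truth = truth, corpus = corpus)
}

filler_vocabulary <- function() {
  path <- system.file("extdata", "filler_words.txt", package = "mhealthscape")
  readLines(path, encoding = "UTF-8")
}

#' Write / read an app corpus as JSON Lines
#'
#' One UTF-8 JSON object per line; absent rating means and download bands are
#' written as `null`.
#'
#' @param apps tibble of app records as returned by [generate_corpus()].
#' @param path file path.
#' @return `read_corpus_jsonl()` returns the app tibble; the writer returns
#'   `path` invisibly.
#' @export
write_corpus_jsonl <- function(apps, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(apps))) {
    rec <- as.list(apps[i, ])
    if (is.na(rec$rating_mean)) rec$rating_mean <- NULL
    if (is.na(rec$download_band)) rec$download_band <- NULL
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    app_id = vapply(recs, `[[`, character(1), "app_id"),
    store = vapply(recs, `[[`, character(1), "store"),
    category = vapply(recs, `[[`, character(1), "category"),
    title = vapply(recs, `[[`, character(1), "title"),
    description = vapply(recs, `[[`, character(1), "description"),
    rating_count = vapply(recs, function(r) as.integer(r$rating_count), integer(1)),
    rating_mean = vapply(recs, function(r) r$rating_mean %||% NA_real_, numeric(1)),
    download_band = vapply(recs, function(r) r$download_band %||% NA_character_,
                           character(1)))
}

#' Write ground truth as CSV
#'
#' Planted tag sets are semicolon-joined.
#' @param truth ground-truth tibble from [generate_corpus()].
#' @param path file path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  out <- data.frame(app_id = truth$app_id,
                    planted_archetype = truth$planted_archetype,
                    planted_tags = vapply(truth$planted_tags, paste,
                                          character(1), collapse = ";"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a tag corpus as two-column TSV
#'
#' Format: `surface_string TAB tag_label`, no header — the on-disk exchange
#' format read back by [load_tag_corpus()].
#' @param corpus tag-corpus tibble (`surface`, `tag`).
#' @param path file path.
#' @export
write_tag_corpus <- function(corpus, path) {
  writeLines(paste(corpus$surface, corpus$tag, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}
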