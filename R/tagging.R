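#' Load a tag corpus from a two-column TSV
#'
#' Each line maps one surface string to one tag label
#' (`surface TAB tag`, no header). Surface strings are unique after
#' case-folding; many surface strings may map to the same tag (synonyms), but
#' a surface string mapping to two different tags is a format error. Exact
#' duplicate lines are deduplicated.
#'
#' @param path TSV file path.
#' @return a tibble with columns `surface` (case-folded) and `tag`.
#' @export
load_tag_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("empty tag corpus: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    stop("malformed tag corpus line ", bad[1], ": expected two tab-separated columns",
         call. = FALSE)
  surface <- tolower(vapply(parts, `[[`, character(1), 1L))
  tag <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(surface)) || any(!nzchar(tag)))
    stop("malformed tag corpus line ",
         which(!nzchar(surface) | !nzchar(tag))[1], ": empty field", call. = FALSE)
  dup <- duplicated(paste0(surface, "\r", tag))
  surface <- surface[!dup]; tag <- tag[!dup]
  conflict <- duplicated(surface)
  if (any(conflict))
    stop("conflicting tag corpus entry at line ",
         which(tolower(vapply(parts, `[[`, character(1), 1L)) == surface[conflict][1])[2],
         ": surface string '", surface[conflict][1],
         "' maps to multiple tags", call. = FALSE)
  tibble::tibble(surface = surface, tag = tag)
}

# one word-boundary regex per surface string, applied to case-folded text
surface_patterns <- function(corpus) {
  esc <- gsub("([][{}()^$.|?*+\\\\])", "\\\\\\1", corpus$surface)
  paste0("\\b", esc, "\\b")
}

#' Tag app descriptions against a tag corpus
#'
#' A surface string matches when it occurs in the description,
#' case-insensitively and delimited by word boundaries; multi-word phrases
#' are allowed and overlapping matches all count. Tags are deduplicated at
#' label level, so several matched synonyms of one tag contribute a single
#' distinct tag. An app is flagged `included` when it carries at least
#' `k_min` distinct tags.
#'
#' @param apps tibble of app records (needs `app_id`, `description`), or a
#'   single description string for `auto_tag()`.
#' @param corpus tag-corpus tibble from [load_tag_corpus()] or
#'   [generate_corpus()].
#' @param k_min inclusion threshold on distinct tags (default 4).
#' @return `auto_tag_corpus()`: a tibble of tag assignments with columns
#'   `app_id`, `tags` (list), `matched_strings` (list), `tag_count`,
#'   `included`. `auto_tag()`: one such row for a single description.
#' @export
auto_tag_corpus <- function(apps, corpus, k_min = 4L) {
  if (nrow(corpus) == 0) stop("empty tag corpus", call. = FALSE)
  if (anyDuplicated(apps$app_id))
    stop("duplicate app_id in input", call. = FALSE)
  desc <- tolower(apps$description)
  pats <- surface_patterns(corpus)
  hit <- matrix(FALSE, nrow(apps), nrow(corpus))
  nonempty <- nzchar(desc)
  for (s in seq_along(pats))
    hit[nonempty, s] <- grepl(pats[s], desc[nonempty], perl = TRUE)
  matched <- apply(hit, 1L, function(row) corpus$surface[row], simplify = FALSE)
  tags <- apply(hit, 1L, function(row) sort(unique(corpus$tag[row])),
                simplify = FALSE)
  tag_count <- lengths(tags)
  tibble::tibble(app_id = apps$app_id, tags = tags, matched_strings = matched,
                 tag_count = tag_count, included = tag_count >= k_min)
}

#' @rdname auto_tag_corpus
#' @param description a single description string.
#' @export
auto_tag <- function(description, corpus, k_min = 4L) {
  auto_tag_corpus(tibble::tibble(app_id = "app", description = description),
                  corpus, k_min = k_min)
}

#' Partition tag assignments by the minimum-distinct-tag filter
#'
#' Apps not matched by at least `k_min` distinct tags are excluded from
#' further assessment; both parts are returned together with their counts for
#' the selection-flow report.
#'
#' @param assignments assignment tibble from [auto_tag_corpus()].
#' @param k_min inclusion threshold (default 4).
#' @return a list with `included` and `excluded` assignment tibbles plus
#'   `n_included` and `n_excluded`.
#' @export
filter_min_tags <- function(assignments, k_min = 4L) {
  if (length(k_min) != 1 || is.na(k_min) || k_min < 0)
    stop("k_min must be a non-negative integer", call. = FALSE)
  keep <- assignments$tag_count >= k_min
  inc <- assignments[keep, , drop = FALSE]
  exc <- assignments[!keep, , drop = FALSE]
  inc$included <- TRUE
  exc$included <- FALSE
  list(included = inc, excluded = exc,
       n_included = sum(keep), n_excluded = sum(!keep))
}

#' Write tag assignments as CSV
#'
#' Columns: `app_id`, `included`, `tag_count`, `tags` (semicolon-joined).
#' @param assignments assignment tibble.
#' @param path file path.
#' @export
write_assignments_csv <- function(assignments, path) {
  out <- data.frame(app_id = assignments$app_id,
                    included = assignments$included,
                    tag_count = assignments$tag_count,
                    tags = vapply(assignments$tags, paste, character(1),
                                  collapse = ";"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
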