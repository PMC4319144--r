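mk_assessments <- function(m1, m2, clusters = sprintf("c%02d", seq_len(nrow(m1)))) {
  # two raters over the five characteristics from matrices of level indices
  lv <- characteristic_levels()
  mk1 <- function(m, rater) {
    df <- tibble::tibble(cluster_id = clusters, rater_id = rater,
                         informative = TRUE)
    for (j in seq_along(lv)) df[[names(lv)[j]]] <- lv[[j]][m[, j]]
    df
  }
  rbind(mk1(m1, "r1"), mk1(m2, "r2"))
}

test_that("rating matrices are complete 3-d arrays with validated levels", {
  m <- matrix(1, 3, 5)
  x <- rating_matrix(mk_assessments(m, m))
  expect_equal(dim(x), c(3, 2, 5))
  a <- mk_assessments(m, m)
  a$specificity[1] <- "bogus"
  expect_error(rating_matrix(a), "invalid level")
  expect_error(rating_matrix(mk_assessments(m, m)[1:3, ]), "at least 2 judges")
  one <- mk_assessments(matrix(1, 1, 5), matrix(1, 1, 5))
  expect_error(rating_matrix(one), "at least 2 objects")
})

test_that("iota is 1 under perfect agreement and 0 under constant disagreement", {
  m <- matrix(sample(1:3, 20, replace = TRUE), 4, 5)
  x <- rating_matrix(mk_assessments(m, m))
  expect_equal(iota(x), 1)
  # judge 1 all "a", judge 2 all "b", one variable
  x2 <- array(rep(c("a", "b"), each = 4), dim = c(4, 2, 1))
  expect_equal(iota(x2), 0)
})

test_that("iota reproduces the enumerated two-judge worked example", {
  x <- array(c("a", "a", "b", "b",    # judge 1
               "a", "b", "b", "b"),   # judge 2
             dim = c(4, 2, 1))
  # D_obs = 1/4, D_exp = 14/24 by enumeration of all object/judge pairs
  expect_equal(iota(x), 1 - 0.25 / (14 / 24), tolerance = 1e-12)
  expect_equal(iota(x), iota_bruteforce(x), tolerance = 1e-12)
})

test_that("iota equals the double-loop oracle on random matrices", {
  set.seed(73)
  for (i in 1:15) {
    x <- random_rating_array(sample(3:20, 1), sample(2:4, 1), K = sample(1:5, 1))
    expect_equal(iota(x), iota_bruteforce(x), tolerance = 1e-12)
  }
})

test_that("iota is invariant to relabeling categories and reordering objects/judges", {
  set.seed(79)
  x <- random_rating_array(10, 3, K = 5)
  base <- iota(x)
  relab <- array(c(none = "Z9", low = "Q1", high = "M5")[x], dim = dim(x))
  expect_equal(iota(relab), base, tolerance = 1e-12)
  expect_equal(iota(x[sample(10), , , drop = FALSE]), base, tolerance = 1e-12)
  expect_equal(iota(x[, sample(3), , drop = FALSE]), base, tolerance = 1e-12)
})

test_that("iota contract cases: degenerate data, missing cells, tiny inputs", {
  xg <- array("a", dim = c(3, 2, 2))
  expect_warning(v <- iota(xg), "degenerate")
  expect_equal(v, 1)
  xna <- array(c("a", NA, "b", "b"), dim = c(2, 2, 1))
  expect_error(iota(xna), "missing cells")
  expect_error(iota(array("a", dim = c(1, 2, 1))), "at least 2 objects")
})

test_that("disagreements resolve through adjudication or fail loudly", {
  m1 <- matrix(1, 3, 5); m2 <- m1
  x <- rating_matrix(mk_assessments(m1, m2))
  res <- resolve_disagreements(x)
  expect_equal(nrow(res), 3)
  expect_true(all(res$specificity == "standard"))

  m2[2, 3] <- 2  # raters disagree on cluster 2, characteristic "change"
  xd <- rating_matrix(mk_assessments(m1, m2))
  expect_error(resolve_disagreements(xd), "c02, change")
  adj <- tibble::tibble(cluster_id = "c02", characteristic = "change",
                        value = "high")
  resd <- resolve_disagreements(xd, adj)
  expect_equal(resd$change[2], "high")
  expect_equal(resd$change[1], "none")
  bad <- tibble::tibble(cluster_id = "c99", characteristic = "change",
                        value = "low")
  expect_error(resolve_disagreements(xd, bad), "unknown cells")
})

test_that("uninformative clusters split off with app totals", {
  cl <- tibble::tibble(cluster_id = sprintf("c%03d", 1:245),
                       informative = rep(c(FALSE, TRUE), c(70, 175)),
                       n_apps = c(rep(91, 70), rep(100, 175)))
  ex <- exclude_uninformative(cl)
  expect_equal(ex$n_informative, 175)
  expect_equal(ex$n_excluded, 70)
  expect_equal(ex$apps_excluded, 70 * 91)

  toy <- tibble::tibble(cluster_id = letters[1:5],
                        informative = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(exclude_uninformative(toy)$n_informative, 3)
  expect_equal(exclude_uninformative(tibble::tibble(
    cluster_id = "a", informative = TRUE))$n_excluded, 0)
  expect_error(exclude_uninformative(tibble::tibble(cluster_id = "a")),
               "informative flag")
})

test_that("consolidation groups identical signatures into ordered archetypes", {
  # all clusters share one signature -> one archetype
  res <- tibble::tibble(cluster_id = c("a", "b", "c"),
                        specificity = "medical", leaks = "high",
                        change = "high", loss = "high", value = "high")
  sizes <- setNames(c(10, 20, 30), c("a", "b", "c"))
  out <- consolidate(res, sizes)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_apps, 60)
  expect_setequal(out$member_clusters[[1]], c("a", "b", "c"))

  expect_error(consolidate(res, sizes[1:2]), "no size")
  expect_error(consolidate(res[1:2, ], sizes), "without resolved assessment")
})

test_that("the reference archetype table survives a full consolidation round-trip", {
  arch <- read_archetype_table()
  clusters <- expand_reference_clusters(arch)
  res <- clusters[, c("cluster_id", "specificity", "leaks", "change", "loss",
                      "value")]
  out <- consolidate(res, clusters[, c("cluster_id", "n_apps")])
  expect_equal(nrow(out), 12)
  expect_equal(out$n_clusters, arch$n_clusters)
  expect_equal(out$n_apps, arch$n_apps)
  expect_equal(sum(out$n_clusters), 175)
  # severity ordering reproduces the published archetype numbering
  for (v in c("specificity", "leaks", "change", "loss", "value"))
    expect_equal(out[[v]], arch[[v]])
  # idempotent under permutation of cluster order
  perm <- sample(nrow(res))
  out2 <- consolidate(res[perm, ], clusters[, c("cluster_id", "n_apps")])
  expect_equal(out2, out)
})

test_that("archetype count equals the number of distinct signatures", {
  set.seed(83)
  lv <- characteristic_levels()
  n <- 20
  res <- tibble::tibble(cluster_id = sprintf("c%02d", 1:n))
  for (v in names(lv)) res[[v]] <- sample(lv[[v]], n, replace = TRUE)
  sizes <- setNames(rep(1, n), res$cluster_id)
  out <- consolidate(res, sizes)
  sig <- do.call(paste, res[names(lv)])
  expect_equal(nrow(out), length(unique(sig)))
  expect_equal(sum(out$n_apps), n)
})

test_that("assessments round-trip through CSV", {
  m <- matrix(c(1, 2, 3), 3, 5)
  a <- mk_assessments(m, m)
  a$annotation <- "note"
  f <- withr::local_tempfile(fileext = ".csv")
  write_assessments_csv(a, f)
  back <- read_assessments_csv(f)
  expect_equal(back$cluster_id, a$cluster_id)
  expect_equal(back$specificity, a$specificity)
  expect_equal(back$informative, a$informative)
})
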