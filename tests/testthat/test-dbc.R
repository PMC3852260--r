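test_that("coincident points cluster exactly at the density threshold", {
  # n(p) counts the center itself, so 5 coincident DCs reach D = 5
  m5 <- make_dc_map(rep(0, 5), rep(0, 5))
  a5 <- dbc_cluster(m5, cluster_params(250, 5))
  expect_length(a5$clusters, 1L)
  expect_identical(a5$clusters[[1L]], 1:5)
  expect_false(anyNA(a5$labels))

  m4 <- make_dc_map(rep(0, 4), rep(0, 4))
  a4 <- dbc_cluster(m4, cluster_params(250, 5))
  expect_length(a4$clusters, 0L)
  expect_true(all(is.na(a4$labels)))
})

test_that("a bridge DC merges two blobs into one 13-member cluster", {
  a <- dbc_cluster(bridge_map(), cluster_params(250, 5))
  expect_length(a$clusters, 1L)
  expect_identical(a$clusters[[1L]], 1:13)
  o <- dbc_oracle(bridge_map(), cluster_params(250, 5))
  expect_same_partition(a, o)
})

test_that("degenerate inputs are handled", {
  empty <- make_dc_map(numeric(0), numeric(0))
  a <- dbc_cluster(empty)
  expect_length(a$dc_ids, 0L)
  expect_length(a$clusters, 0L)

  # a single DC at D = 1 is its own cluster
  one <- make_dc_map(0, 0)
  a1 <- dbc_cluster(one, cluster_params(250, 1))
  expect_identical(a1$clusters, list(1L))
  expect_same_partition(a1, dbc_oracle(one, cluster_params(250, 1)))

  expect_error(cluster_params(0, 5), "R must")
  expect_error(cluster_params(250, 0), "D must")
})

test_that("only DCs participate in clustering", {
  # add T/B/tumor/other cells on top of the 4-coincident-DC layout:
  # they must not push n(p) over the threshold
  cells <- data.frame(
    cell_id = 1:9,
    x = rep(0, 9), y = rep(0, 9),
    phenotype = c(rep("IMMATURE_DC", 4), "T_CELL", "B_CELL", "TUMOR",
                  "OTHER", "T_CELL"))
  a <- dbc_cluster(cell_map(cells), cluster_params(250, 5))
  expect_length(a$clusters, 0L)
  expect_identical(a$dc_ids, 1:4)
})

test_that("circle boundary is inclusive", {
  # 5 DCs: center plus 4 at exactly distance 250
  m <- make_dc_map(c(250, 500, 0, 250, 250), c(250, 250, 250, 500, 0))
  a <- dbc_cluster(m, cluster_params(250, 5))
  expect_length(a$clusters, 1L)
  expect_identical(a$clusters[[1L]], 1:5)
})

test_that("fast implementation matches the brute-force oracle on random layouts", {
  set.seed(101)
  kinds <- c("uniform", "clustered", "mixed")
  for (i in 1:30) {
    m <- random_layout_map(sample(20:400, 1L), kinds[1L + i %% 3L])
    for (D in c(3, 5)) {
      p <- cluster_params(250, D)
      expect_same_partition(dbc_cluster(m, p), dbc_oracle(m, p))
    }
  }
})

test_that("clusters partition the clustered DCs and exclude noise", {
  set.seed(202)
  for (i in 1:20) {
    m <- random_layout_map(sample(50:300, 1L), "mixed")
    a <- dbc_cluster(m)
    members <- unlist(a$clusters)
    expect_false(anyDuplicated(members) > 0)
    expect_setequal(members, a$dc_ids[!is.na(a$labels)])
    expect_setequal(c(members, a$dc_ids[is.na(a$labels)]), a$dc_ids)
    # every non-noise label appears in exactly one cluster
    expect_identical(sort(unique(a$labels[!is.na(a$labels)])),
                     seq_along(a$clusters) - 1L)
  }
})

test_that("clustered set shrinks in D and grows in R", {
  set.seed(303)
  for (i in 1:10) {
    m <- random_layout_map(200, "mixed")
    clustered_at <- function(R, D) {
      a <- dbc_cluster(m, cluster_params(R, D))
      a$dc_ids[!is.na(a$labels)]
    }
    for (D in 2:6) {
      expect_true(all(clustered_at(250, D + 1) %in% clustered_at(250, D)))
    }
    for (R in c(100, 200, 300)) {
      expect_true(all(clustered_at(R, 5) %in% clustered_at(R + 100, 5)))
    }
  }
})

test_that("labels are invariant to input row permutation", {
  set.seed(404)
  m <- random_layout_map(150, "mixed")
  a <- dbc_cluster(m)
  perm <- sample(nrow(m$cells))
  mp <- cell_map(m$cells[perm, ], node_id = m$node_id)
  ap <- dbc_cluster(mp)
  expect_identical(a$clusters, ap$clusters)
  # per-cell labels agree through the cell_id mapping
  expect_identical(a$labels[match(ap$dc_ids, a$dc_ids)], ap$labels)
})

test_that("cluster summaries report size, maturity and centroid", {
  m <- make_dc_map(c(rep(0, 5), 0), c(0, 0, 0, 0, 0, 100),
                   mature = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  a <- dbc_cluster(m, cluster_params(250, 5))
  s <- summarize_clusters(a, m)
  expect_identical(nrow(s), 1L)
  expect_identical(s$size, 6L)
  expect_identical(s$mature_count, 2L)
  expect_equal(s$centroid_x, 0)
  expect_equal(s$centroid_y, 100 / 6)

  expect_identical(nrow(summarize_clusters(
    dbc_cluster(make_dc_map(numeric(0), numeric(0))),
    make_dc_map(numeric(0), numeric(0)))), 0L)

  b <- bridge_map()
  sb <- summarize_clusters(dbc_cluster(b), b)
  expect_identical(sb$size, 13L)

  expect_error(summarize_clusters(a, bridge_map()), "does not match")
})
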