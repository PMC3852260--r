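# Build a cell map from parallel vectors, defaulting to sequential ids.
make_map <- function(x, y, phenotype, cell_id = seq_along(x),
                     node_id = "test", extent = NULL) {
  cell_map(data.frame(cell_id = cell_id, x = x, y = y,
                      phenotype = phenotype, stringsAsFactors = FALSE),
           node_id = node_id, extent = extent)
}

# All-DC map (for clustering geometry tests).
make_dc_map <- function(x, y, mature = rep(FALSE, length(x)), ...) {
  make_map(x, y, ifelse(mature, "MATURE_DC", "IMMATURE_DC"), ...)
}

# The 20-cell hand-enumerable fixture: 6 coincident DCs (3 mature) that
# form one cluster at R=250/D=5, one isolated DC 10,000 px away, 8 T
# cells and 5 OTHER cells placed far from everything.
fixture_20cell <- function() {
  make_map(
    x = c(rep(1000, 6), 11000, seq(20000, by = 500, length.out = 8),
          seq(30000, by = 500, length.out = 5)),
    y = rep(1000, 20),
    phenotype = c(rep(c("MATURE_DC", "IMMATURE_DC"), 3), "IMMATURE_DC",
                  rep("T_CELL", 8), rep("OTHER", 5))
  )
}

# Two 6-DC blobs 480 px apart joined by a mid-point bridge DC: the
# bridge lies in core circles of both blobs, forcing a transitive merge
# into a single 13-member cluster at R=250/D=5.
bridge_map <- function() {
  make_dc_map(x = c(rep(0, 6), rep(480, 6), 240), y = rep(0, 13))
}

# Random DC layouts used for oracle-equivalence properties.
random_layout_map <- function(n, kind = c("uniform", "clustered", "mixed"),
                              extent = 5000) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    x <- runif(n, 0, extent); y <- runif(n, 0, extent)
  } else {
    k <- max(1L, n %/% 60L)
    cx <- runif(k, 0, extent); cy <- runif(k, 0, extent)
    n_cl <- if (kind == "clustered") n else n %/% 2L
    of <- sample.int(k, n_cl, replace = TRUE)
    x <- rnorm(n_cl, cx[of], 100); y <- rnorm(n_cl, cy[of], 100)
    if (kind == "mixed") {
      x <- c(x, runif(n - n_cl, 0, extent))
      y <- c(y, runif(n - n_cl, 0, extent))
    }
  }
  make_dc_map(pmax(x, 0), pmax(y, 0),
              mature = runif(length(x)) < 0.5)
}

# Identical clustered/noise structure between two assignments.
expect_same_partition <- function(a, b) {
  expect_identical(a$dc_ids, b$dc_ids)
  expect_identical(a$labels, b$labels)
  expect_identical(a$clusters, b$clusters)
}
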