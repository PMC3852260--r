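#' Clustering parameters
#'
#' The density-based clustering (DBC) of dendritic cells uses two
#' parameters: a neighborhood radius `R` (pixels) and a minimum neighbor
#' count `D`. A DC whose radius-`R` circle contains at least `D` DCs
#' (itself included; the circle boundary is inclusive) seeds a provisional
#' cluster containing every DC in that circle; provisional clusters sharing
#' any member are merged transitively; DCs left unlabeled are noise.
#' The defaults `R = 250`, `D = 5` are the values calibrated against
#' biologist-annotated parafollicular DC aggregates.
#'
#' @param R neighborhood radius in pixels (> 0).
#' @param D minimum number of DCs inside the circle (>= 1), counting the
#'   center itself.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(R = 250, D = 5) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("R must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 1) {
    stop("D must be a single number >= 1", call. = FALSE)
  }
  structure(list(R = as.numeric(R), D = as.numeric(D)),
            class = "cluster_params")
}

# Neighbor lists for the DC point set under radius R, via grid bucketing
# (cell side R, so all neighbors of a point lie in the 3x3 surrounding
# buckets). Returns a list: element i = integer indices j (including i)
# with d(i, j) <= R.
dc_neighbor_lists <- function(x, y, R) {
  n <- length(x)
  if (n == 0L) return(list())
  bx <- as.integer(floor(x / R))
  by <- as.integer(floor(y / R))
  bx <- bx - min(bx)
  by <- by - min(by)
  nbx <- max(bx) + 1L
  key <- bx + by * nbx
  buckets <- split(seq_len(n), key)
  bucket_of <- match(key, as.integer(names(buckets)))
  r2 <- R * R

  # candidate pool per bucket = points in the 3x3 neighborhood
  ukeys <- as.integer(names(buckets))
  ubx <- ukeys %% nbx
  uby <- ukeys %/% nbx
  key_index <- new.env(hash = TRUE, size = length(ukeys))
  for (i in seq_along(ukeys)) {
    assign(as.character(ukeys[i]), i, envir = key_index)
  }
  pool <- vector("list", length(buckets))
  for (b in seq_along(buckets)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      kx <- ubx[b] + dx
      ky <- uby[b] + dy
      if (kx < 0 || ky < 0 || kx >= nbx) next
      k <- as.character(kx + ky * nbx)
      hit <- get0(k, envir = key_index, ifnotfound = NULL)
      if (!is.null(hit)) cand <- c(cand, buckets[[hit]])
    }
    pool[[b]] <- cand
  }

  nbrs <- vector("list", n)
  for (b in seq_along(buckets)) {
    idx <- buckets[[b]]
    cand <- pool[[b]]
    cx <- x[cand]; cy <- y[cand]
    for (i in idx) {
      d2 <- (cx - x[i])^2 + (cy - y[i])^2
      nbrs[[i]] <- cand[d2 <= r2]
    }
  }
  nbrs
}

# Assemble a dbc_assignment from per-DC component roots (NA = noise),
# applying the deterministic labeling rule: each cluster is keyed by its
# smallest member cell_id and clusters are numbered 0..k-1 in increasing
# key order.
finalize_assignment <- function(dc_ids, root, params) {
  labels <- rep(NA_integer_, length(dc_ids))
  clusters <- list()
  clustered <- which(!is.na(root))
  if (length(clustered) > 0L) {
    comp <- split(clustered, root[clustered])
    keys <- vapply(comp, function(ix) min(dc_ids[ix]), numeric(1L))
    ord <- order(keys)
    comp <- comp[ord]
    clusters <- lapply(comp, function(ix) sort(dc_ids[ix]))
    names(clusters) <- NULL
    for (k in seq_along(comp)) labels[comp[[k]]] <- k - 1L
  }
  structure(list(dc_ids = dc_ids, labels = labels, clusters = clusters,
                 params = params),
            class = "dbc_assignment")
}

#' Density-based clustering of dendritic cells
#'
#' Partitions the DC subset (immature plus mature DCs) of a cell map into
#' clusters and noise. Step 1: every DC `p` whose radius-`R` circle contains
#' `n(p) >= D` DCs (distance <= R, `p` itself counted) labels all DCs in the
#' circle as provisionally clustered together. Step 2: provisional clusters
#' sharing any member are merged to transitive closure (union-find).
#' Step 3: DCs covered by no such circle are noise. Non-DC phenotypes are
#' ignored entirely. Neighbor search uses grid bucketing so large maps
#' cluster quickly; [dbc_oracle] is the quadratic reference.
#'
#' Cluster labels are deterministic: each final cluster is keyed by its
#' smallest member `cell_id` and clusters are numbered `0..k-1` in
#' increasing key order, so the output is invariant to input row order.
#'
#' @param map a [cell_map].
#' @param params a [cluster_params] object.
#' @return An object of class `dbc_assignment`: list with `dc_ids`
#'   (cell ids of the DC subset, map order), `labels` (integer cluster
#'   label per DC, `NA` for noise), `clusters` (list of sorted member
#'   cell-id vectors) and `params`.
#' @seealso [dbc_oracle], [summarize_clusters]
#' @export
dbc_cluster <- function(map, params = cluster_params()) {
  stopifnot(inherits(map, "cell_map"), inherits(params, "cluster_params"))
  dcs <- dc_cells(map)
  dc_ids <- dcs$cell_id
  n <- nrow(dcs)
  if (n == 0L) return(finalize_assignment(dc_ids, integer(0), params))

  nbrs <- dc_neighbor_lists(dcs$x, dcs$y, params$R)
  np <- lengths(nbrs)
  cores <- which(np >= params$D)

  parent <- seq_len(n)
  find <- function(i) {  # path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  covered <- logical(n)
  for (p in cores) {
    members <- nbrs[[p]]
    covered[members] <- TRUE
    rp <- find(p)
    for (q in members) {
      rq <- find(q)
      if (rq != rp) parent[rq] <- rp
    }
  }

  root <- rep(NA_integer_, n)
  for (i in which(covered)) root[i] <- find(i)
  finalize_assignment(dc_ids, root, params)
}

#' Brute-force reference implementation of the DC clustering
#'
#' Computes the same partition as [dbc_cluster] by explicit construction:
#' the full pairwise distance matrix yields each DC's neighbor count; one
#' provisional member set is formed per core DC; a graph with provisional
#' sets as vertices and edges between intersecting sets is built and its
#' connected components (via \pkg{igraph}) are the clusters. Quadratic in
#' the number of DCs; intended for small inputs (up to a few thousand DCs)
#' as an independent test oracle.
#'
#' @inheritParams dbc_cluster
#' @return A `dbc_assignment`, identical in content to [dbc_cluster]'s.
#' @export
dbc_oracle <- function(map, params = cluster_params()) {
  stopifnot(inherits(map, "cell_map"), inherits(params, "cluster_params"))
  dcs <- dc_cells(map)
  dc_ids <- dcs$cell_id
  n <- nrow(dcs)
  if (n == 0L) return(finalize_assignment(dc_ids, integer(0), params))

  d2 <- outer(dcs$x, dcs$x, "-")^2 + outer(dcs$y, dcs$y, "-")^2
  within <- d2 <= params$R^2
  np <- rowSums(within)
  cores <- which(np >= params$D)

  root <- rep(NA_integer_, n)
  if (length(cores) > 0L) {
    # membership matrix: one row per provisional set (core circle)
    M <- within[cores, , drop = FALSE]
    overlap <- tcrossprod(M * 1) > 0  # sets i,j intersect
    g <- igraph::graph_from_adjacency_matrix(overlap, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    for (s in seq_along(cores)) {
      members <- which(M[s, ])
      root[members] <- comp[s]
    }
  }
  finalize_assignment(dc_ids, root, params)
}

#' Per-cluster summaries
#'
#' One record per cluster: member count, count of mature members, and the
#' arithmetic-mean centroid of member coordinates.
#'
#' @param assignment a `dbc_assignment` produced from `map`.
#' @param map the [cell_map] the assignment was derived from.
#' @return Data frame with columns `cluster_id`, `size`, `mature_count`,
#'   `centroid_x`, `centroid_y`; zero rows when there are no clusters.
#' @export
summarize_clusters <- function(assignment, map) {
  stopifnot(inherits(assignment, "dbc_assignment"),
            inherits(map, "cell_map"))
  dcs <- dc_cells(map)
  if (!setequal(assignment$dc_ids, dcs$cell_id)) {
    stop("assignment does not match the DC set of the cell map",
         call. = FALSE)
  }
  k <- length(assignment$clusters)
  if (k == 0L) {
    return(data.frame(cluster_id = integer(), size = integer(),
                      mature_count = integer(), centroid_x = numeric(),
                      centroid_y = numeric()))
  }
  pos <- match(unlist(assignment$clusters), dcs$cell_id)
  sizes <- lengths(assignment$clusters)
  grp <- rep(seq_len(k), sizes)
  mature <- dcs$phenotype[pos] == "MATURE_DC"
  data.frame(
    cluster_id = seq_len(k) - 1L,
    size = as.integer(sizes),
    mature_count = as.integer(tapply(mature, grp, sum)),
    centroid_x = as.numeric(tapply(dcs$x[pos], grp, mean)),
    centroid_y = as.numeric(tapply(dcs$y[pos], grp, mean))
  )
}

#' @export
print.dbc_assignment <- function(x, ...) {
  cat("dbc_assignment: ", length(x$dc_ids), " DCs, ",
      length(x$clusters), " clusters, ",
      sum(is.na(x$labels)), " noise (R=", x$params$R,
      ", D=", x$params$D, ")\n", sep = "")
  invisible(x)
}
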