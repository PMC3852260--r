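#' Co-localization parameters
#'
#' A T cell is considered associated with a DC when it lies within the
#' influence radius (default 100 pixels, approximately a DC diameter
#' including dendrites in the source images). Two counting modes exist:
#' `"nearest"` assigns each T cell to its nearest DC only (if within the
#' radius), so T cells are partitioned among DCs; `"all_within"` credits a
#' T cell to every DC within the radius.
#'
#' @param radius influence radius in pixels (> 0).
#' @param mode `"nearest"` (default) or `"all_within"`.
#' @return A list of class `coloc_params`.
#' @export
coloc_params <- function(radius = 100, mode = c("nearest", "all_within")) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("radius must be a single positive number", call. = FALSE)
  }
  mode <- match.arg(mode)
  structure(list(radius = as.numeric(radius), mode = mode),
            class = "coloc_params")
}

#' Associate T cells with nearby DCs
#'
#' In `"nearest"` mode each T cell is assigned to its nearest DC if and
#' only if that distance is at most the radius (boundary inclusive); ties
#' are broken by the smallest DC `cell_id`; T cells with no DC within the
#' radius are unassociated. In `"all_within"` mode a T cell counts toward
#' every DC within the radius. Distances are Euclidean, center to center.
#'
#' @param map a [cell_map].
#' @param params a [coloc_params] object.
#' @return An object of class `t_association`: list with `t_cells` (data
#'   frame `t_cell_id`, `nearest_dc_id` (`NA` if unassociated), `n_dc_within`),
#'   `dc_counts` (data frame `dc_id`, `t_count`), `params`.
#' @export
associate_t_cells <- function(map, params = coloc_params()) {
  stopifnot(inherits(map, "cell_map"), inherits(params, "coloc_params"))
  dcs <- dc_cells(map)
  tc <- map$cells[map$cells$phenotype == "T_CELL", , drop = FALSE]
  n_dc <- nrow(dcs)
  n_t <- nrow(tc)

  t_tab <- data.frame(t_cell_id = tc$cell_id,
                      nearest_dc_id = rep(NA_integer_, n_t),
                      n_dc_within = integer(n_t))
  dc_counts <- data.frame(dc_id = dcs$cell_id, t_count = integer(n_dc))
  if (n_dc == 0L || n_t == 0L) {
    return(structure(list(t_cells = t_tab, dc_counts = dc_counts,
                          params = params),
                     class = "t_association"))
  }

  # DCs are pre-sorted by cell_id so that which.min resolves distance ties
  # in favor of the smallest dc id.
  ord <- order(dcs$cell_id)
  dx <- dcs$x[ord]; dy <- dcs$y[ord]; did <- dcs$cell_id[ord]
  r2 <- params$radius^2
  counts <- integer(n_dc)

  block <- max(1L, floor(4e6 / n_dc))  # bound the distance-matrix size
  for (s in seq(1L, n_t, by = block)) {
    e <- min(s + block - 1L, n_t)
    d2 <- outer(tc$x[s:e], dx, "-")^2 + outer(tc$y[s:e], dy, "-")^2
    inside <- d2 <= r2
    t_tab$n_dc_within[s:e] <- rowSums(inside)
    hit <- which(t_tab$n_dc_within[s:e] > 0L)
    if (params$mode == "nearest") {
      for (i in hit) {
        j <- which.min(d2[i, ])  # first minimum = smallest dc id on ties
        if (d2[i, j] <= r2) {
          t_tab$nearest_dc_id[s + i - 1L] <- did[j]
          counts[j] <- counts[j] + 1L
        }
      }
    } else {
      counts <- counts + colSums(inside)
      for (i in hit) {
        j <- which.min(d2[i, ])
        t_tab$nearest_dc_id[s + i - 1L] <- did[j]
      }
    }
  }
  dc_counts$t_count <- as.integer(counts[match(dcs$cell_id, did)])
  structure(list(t_cells = t_tab, dc_counts = dc_counts, params = params),
            class = "t_association")
}

#' Mean T-cell counts around clustered versus unclustered DCs
#'
#' @param assoc a `t_association` from [associate_t_cells].
#' @param assignment the `dbc_assignment` for the same cell map.
#' @return List with `mean_t_clustered` (mean per-DC T count over clustered
#'   DCs), `mean_t_unclustered` (over noise DCs), and the stratum sizes
#'   `n_clustered_dcs`, `n_unclustered_dcs`. A mean is `NA` when its DC
#'   stratum is empty.
#' @export
coloc_summary <- function(assoc, assignment) {
  stopifnot(inherits(assoc, "t_association"),
            inherits(assignment, "dbc_assignment"))
  if (!setequal(assoc$dc_counts$dc_id, assignment$dc_ids)) {
    stop("association and cluster assignment cover different DC sets",
         call. = FALSE)
  }
  lab <- assignment$labels[match(assoc$dc_counts$dc_id, assignment$dc_ids)]
  clustered <- !is.na(lab)
  tc <- assoc$dc_counts$t_count
  list(
    mean_t_clustered = if (any(clustered)) mean(tc[clustered]) else NA_real_,
    mean_t_unclustered = if (any(!clustered)) mean(tc[!clustered]) else NA_real_,
    n_clustered_dcs = sum(clustered),
    n_unclustered_dcs = sum(!clustered)
  )
}
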