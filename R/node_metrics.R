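#' Per-node spatial and maturity metrics
#'
#' Computes the full vector of per-node quantities used for cohort
#' comparison. Cell-fraction denominators follow the counting convention of
#' the imaging analysis: the node total is T cells + DCs + OTHER
#' (hematoxylin-only) cells; tumor and B cells are excluded by default
#' (`denominator = "t_dc_other"`), with `denominator = "non_tumor"`
#' widening it to all non-tumor cells.
#'
#' Returned fields:
#' \describe{
#'   \item{pct_dcs}{100 * n_dcs / (n_T + n_dcs + n_other).}
#'   \item{pct_mature_dcs}{100 * mature DCs / all DCs (maturity = CD83+).}
#'   \item{pct_clustered_dcs}{100 * clustered DCs / all DCs.}
#'   \item{rel_cluster_count}{clusters per DC (dimensionless; multiply by
#'     1000 for the conventional x10^-3 scale).}
#'   \item{mean_cluster_size}{arithmetic mean of within-node cluster sizes.}
#'   \item{pct_mature_clustered}{100 * mature clustered DCs / clustered DCs.}
#'   \item{pct_t_cells}{100 * n_T / (n_T + n_dcs + n_other).}
#' }
#' Any field whose denominator is zero is returned as `NA` (missing), never
#' as 0.
#'
#' @param map a [cell_map].
#' @param assignment the `dbc_assignment` produced from `map`.
#' @param denominator `"t_dc_other"` (default) or `"non_tumor"`.
#' @return One-row data frame with the fields above plus the counts
#'   `n_total_cells` (denominator total), `n_dcs`, `n_clusters`.
#' @export
compute_node_metrics <- function(map, assignment,
                                 denominator = c("t_dc_other",
                                                 "non_tumor")) {
  stopifnot(inherits(map, "cell_map"),
            inherits(assignment, "dbc_assignment"))
  denominator <- match.arg(denominator)
  phen <- map$cells$phenotype
  dcs <- dc_cells(map)
  if (!setequal(assignment$dc_ids, dcs$cell_id)) {
    stop("assignment does not match the DC set of the cell map",
         call. = FALSE)
  }

  n_dc <- nrow(dcs)
  n_t <- sum(phen == "T_CELL")
  n_other <- sum(phen == "OTHER")
  n_total <- if (denominator == "t_dc_other") {
    n_t + n_dc + n_other
  } else {
    sum(phen != "TUMOR")
  }
  n_mature <- sum(dcs$phenotype == "MATURE_DC")

  clustered_ids <- unlist(assignment$clusters)
  n_clustered <- length(clustered_ids)
  n_clusters <- length(assignment$clusters)
  mature_clustered <- sum(
    dcs$phenotype[match(clustered_ids, dcs$cell_id)] == "MATURE_DC")

  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sizes <- lengths(assignment$clusters)

  data.frame(
    node_id = map$node_id,
    pct_dcs = frac(n_dc, n_total),
    pct_mature_dcs = frac(n_mature, n_dc),
    pct_clustered_dcs = frac(n_clustered, n_dc),
    rel_cluster_count = if (n_dc > 0) n_clusters / n_dc else NA_real_,
    mean_cluster_size = if (n_clusters > 0) mean(sizes) else NA_real_,
    pct_mature_clustered = frac(mature_clustered, n_clustered),
    pct_t_cells = frac(n_t, n_total),
    n_total_cells = as.integer(n_total),
    n_dcs = as.integer(n_dc),
    n_clusters = as.integer(n_clusters),
    stringsAsFactors = FALSE
  )
}

#' Node metrics for a whole cohort
#'
#' Runs [dbc_cluster] and [compute_node_metrics] on every node of a cohort
#' read by [read_cohort] (or an equivalent list of cell maps).
#'
#' @param maps named list of [cell_map] objects.
#' @param params [cluster_params] for the clustering step.
#' @param denominator passed to [compute_node_metrics].
#' @return Data frame, one row per node in input order.
#' @export
cohort_node_metrics <- function(maps, params = cluster_params(),
                                denominator = "t_dc_other") {
  rows <- lapply(maps, function(m) {
    compute_node_metrics(m, dbc_cluster(m, params),
                         denominator = denominator)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
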