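#' Configuration for a synthetic lymph-node cell map
#'
#' The generator emulates the coordinate output of a cell-classification
#' system on one node section: DC aggregates planted as hard-separated
#' Gaussian (Thomas-like) clumps in the interior of the section, isolated
#' background DCs, maturity fractions differing inside versus outside
#' aggregates, a homogeneous background of T cells plus extra T cells
#' enriched within the influence disc of each planted DC, and a
#' homogeneous field of other (hematoxylin-only) nuclei.
#'
#' Cluster centers are drawn by rejection sampling at least
#' `4 * cluster_sigma` from the border and from each other, so planted
#' identity is unambiguous. Cell densities are scaled down roughly
#' ten-fold relative to a full slide so that whole simulated cohorts run
#' in seconds; spatial structure (cluster scale vs. neighborhood radius,
#' enrichment within the 100-px disc) is preserved.
#'
#' @param extent `c(width, height)` in pixels.
#' @param n_planted_clusters number of planted DC aggregates.
#' @param cluster_sigma Gaussian scatter (pixels) of members about a center.
#' @param dcs_per_cluster mean member count per aggregate (Poisson).
#' @param background_dc_rate expected number of isolated background DCs.
#' @param p_mature_in_cluster,p_mature_background probability that a
#'   planted / background DC is mature (CD83+).
#' @param t_background_rate expected number of background T cells.
#' @param t_enrichment_per_clustered_dc mean number of extra T cells placed
#'   uniformly within `t_enrichment_radius` of each planted DC.
#' @param t_enrichment_radius radius (pixels) of the enrichment disc;
#'   default 100, the DC influence radius.
#' @param other_cell_rate expected number of OTHER cells.
#' @param seed integer seed; the map is deterministic given the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(extent = c(10000, 10000),
                         n_planted_clusters = 10,
                         cluster_sigma = 60,
                         dcs_per_cluster = 50,
                         background_dc_rate = 50,
                         p_mature_in_cluster = 0.6,
                         p_mature_background = 0.4,
                         t_background_rate = 2000,
                         t_enrichment_per_clustered_dc = 1,
                         t_enrichment_radius = 100,
                         other_cell_rate = 2000,
                         seed = 1L) {
  cfg <- list(extent = as.numeric(extent),
              n_planted_clusters = as.integer(n_planted_clusters),
              cluster_sigma = as.numeric(cluster_sigma),
              dcs_per_cluster = as.numeric(dcs_per_cluster),
              background_dc_rate = as.numeric(background_dc_rate),
              p_mature_in_cluster = as.numeric(p_mature_in_cluster),
              p_mature_background = as.numeric(p_mature_background),
              t_background_rate = as.numeric(t_background_rate),
              t_enrichment_per_clustered_dc =
                as.numeric(t_enrichment_per_clustered_dc),
              t_enrichment_radius = as.numeric(t_enrichment_radius),
              other_cell_rate = as.numeric(other_cell_rate),
              seed = as.integer(seed))
  stopifnot(length(cfg$extent) == 2L, all(cfg$extent > 0),
            cfg$n_planted_clusters >= 0L, cfg$cluster_sigma > 0)
  probs <- c(cfg$p_mature_in_cluster, cfg$p_mature_background)
  if (any(probs < 0 | probs > 1)) {
    stop("maturity probabilities must lie in [0, 1]", call. = FALSE)
  }
  rates <- c(cfg$dcs_per_cluster, cfg$background_dc_rate,
             cfg$t_background_rate, cfg$t_enrichment_per_clustered_dc,
             cfg$other_cell_rate)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Hard-separation rejection sampler for cluster centers: at least
# `sep` from every border and from every previously accepted center.
sample_centers <- function(k, extent, sep, max_tries = 2000L) {
  if (k == 0L) return(matrix(numeric(0), ncol = 2L))
  if (any(extent <= 2 * sep)) {
    stop("extent too small for the requested center separation",
         call. = FALSE)
  }
  centers <- matrix(NA_real_, nrow = k, ncol = 2L)
  placed <- 0L
  for (try in seq_len(max_tries * k)) {
    cand <- c(stats::runif(1L, sep, extent[1L] - sep),
              stats::runif(1L, sep, extent[2L] - sep))
    if (placed == 0L ||
        all((centers[seq_len(placed), 1L] - cand[1L])^2 +
            (centers[seq_len(placed), 2L] - cand[2L])^2 >= sep^2)) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == k) return(centers)
    }
  }
  stop("could not place ", k, " separated cluster centers; ",
       "extent too small", call. = FALSE)
}

#' Generate one synthetic node with ground truth
#'
#' Draws the planted-cluster point pattern described in [synth_config] and
#' returns both the resulting [cell_map] and the generating (ground-truth)
#' labels, for recovery testing of the clustering and co-localization
#' analyses. Deterministic given `config$seed`.
#'
#' @param config a [synth_config].
#' @param node_id node identifier for the emitted map.
#' @return List with:
#'   \describe{
#'     \item{map}{the [cell_map] (DCs first, then T cells, then OTHER).}
#'     \item{truth}{list with `dc` (data frame `cell_id`,
#'       `planted_cluster`: integer aggregate index or `NA` for
#'       background), `t` (data frame `cell_id`, `source_dc_id`: the
#'       planted DC whose enrichment disc spawned the T cell, `NA` for
#'       background), and `true_clustered_fraction` (planted DCs over all
#'       DCs; `NA` when the node has no DCs).}
#'   }
#' @export
generate_node <- function(config, node_id = "synth") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ext <- config$extent
  sigma <- config$cluster_sigma

  centers <- sample_centers(config$n_planted_clusters, ext, 4 * sigma)

  # planted DCs
  sizes <- if (config$n_planted_clusters > 0L) {
    stats::rpois(config$n_planted_clusters, config$dcs_per_cluster)
  } else integer(0)
  n_planted <- sum(sizes)
  cl_of <- rep(seq_along(sizes), sizes)
  px <- stats::rnorm(n_planted, centers[cl_of, 1L], sigma)
  py <- stats::rnorm(n_planted, centers[cl_of, 2L], sigma)

  # background DCs
  n_bg <- stats::rpois(1L, config$background_dc_rate)
  bx <- stats::runif(n_bg, 0, ext[1L])
  by <- stats::runif(n_bg, 0, ext[2L])

  dc_x <- pmin(pmax(c(px, bx), 0), ext[1L])
  dc_y <- pmin(pmax(c(py, by), 0), ext[2L])
  n_dc <- n_planted + n_bg
  mature <- c(stats::runif(n_planted) < config$p_mature_in_cluster,
              stats::runif(n_bg) < config$p_mature_background)
  dc_phen <- ifelse(mature, "MATURE_DC", "IMMATURE_DC")

  # background T cells
  n_tbg <- stats::rpois(1L, config$t_background_rate)
  tbx <- stats::runif(n_tbg, 0, ext[1L])
  tby <- stats::runif(n_tbg, 0, ext[2L])

  # enrichment T cells, uniform in the disc around each planted DC
  n_en <- if (n_planted > 0L) {
    stats::rpois(n_planted, config$t_enrichment_per_clustered_dc)
  } else integer(0)
  src <- rep(seq_len(n_planted), n_en)
  n_ten <- length(src)
  rr <- config$t_enrichment_radius * sqrt(stats::runif(n_ten))
  th <- stats::runif(n_ten, 0, 2 * pi)
  tex <- pmin(pmax(dc_x[src] + rr * cos(th), 0), ext[1L])
  tey <- pmin(pmax(dc_y[src] + rr * sin(th), 0), ext[2L])

  # OTHER cells
  n_other <- stats::rpois(1L, config$other_cell_rate)
  ox <- stats::runif(n_other, 0, ext[1L])
  oy <- stats::runif(n_other, 0, ext[2L])

  n_all <- n_dc + n_tbg + n_ten + n_other
  cells <- data.frame(
    cell_id = seq_len(n_all),
    x = c(dc_x, tbx, tex, ox),
    y = c(dc_y, tby, tey, oy),
    phenotype = c(dc_phen,
                  rep("T_CELL", n_tbg + n_ten),
                  rep("OTHER", n_other)),
    stringsAsFactors = FALSE
  )
  map <- cell_map(cells, node_id = node_id, extent = ext)

  dc_ids <- seq_len(n_dc)
  t_ids <- n_dc + seq_len(n_tbg + n_ten)
  truth <- list(
    dc = data.frame(cell_id = dc_ids,
                    planted_cluster = c(cl_of,
                                        rep(NA_integer_, n_bg))),
    t = data.frame(cell_id = t_ids,
                   source_dc_id = c(rep(NA_integer_, n_tbg),
                                    as.integer(src))),
    true_clustered_fraction = if (n_dc > 0) n_planted / n_dc else NA_real_
  )
  list(map = map, truth = truth)
}

#' Ground truth as a reference annotation
#'
#' Converts a [generate_node] ground truth into the per-DC annotation
#' format consumed by [clustered_label_f1] and [grid_search]: planted DCs
#' are aggregate members, background DCs are not.
#'
#' @param truth the `truth` element of a [generate_node] result.
#' @return Data frame with columns `cell_id`, `in_aggregate`.
#' @export
truth_annotation <- function(truth) {
  data.frame(cell_id = truth$dc$cell_id,
             in_aggregate = !is.na(truth$dc$planted_cluster))
}

#' Group presets for the three node populations
#'
#' Generator settings chosen to reproduce the qualitative contrasts
#' between healthy nodes (HLN), tumor-free non-sentinel nodes (NSLN-),
#' and tumor-invaded nodes (NSLN+): healthy-like nodes have fewer,
#' larger, denser and more mature DC aggregates and stronger T-cell
#' enrichment around clustered DCs; tumor-invaded-like nodes have small
#' sparse aggregates, more isolated DCs, low maturity and weak
#' enrichment. These are design choices that mirror the direction of the
#' published group differences, not estimates of any real cohort.
#'
#' @param group one of `"HLN"`, `"NSLN_NEG"`, `"NSLN_POS"`.
#' @param seed seed stored in the returned config.
#' @return A [synth_config].
#' @export
synth_preset <- function(group = c("HLN", "NSLN_NEG", "NSLN_POS"),
                         seed = 1L) {
  group <- match.arg(group)
  switch(group,
    HLN = synth_config(n_planted_clusters = 6, dcs_per_cluster = 120,
                       background_dc_rate = 30,
                       p_mature_in_cluster = 0.89,
                       p_mature_background = 0.60,
                       t_enrichment_per_clustered_dc = 1.5,
                       seed = seed),
    NSLN_NEG = synth_config(n_planted_clusters = 8, dcs_per_cluster = 50,
                            background_dc_rate = 60,
                            p_mature_in_cluster = 0.35,
                            p_mature_background = 0.30,
                            t_enrichment_per_clustered_dc = 1.2,
                            seed = seed),
    NSLN_POS = synth_config(n_planted_clusters = 8, dcs_per_cluster = 20,
                            background_dc_rate = 90,
                            p_mature_in_cluster = 0.33,
                            p_mature_background = 0.30,
                            t_enrichment_per_clustered_dc = 0.8,
                            seed = seed)
  )
}

#' Configuration for a synthetic cohort with survival outcomes
#'
#' Disease-free survival times are exponential with per-patient rate
#' `baseline_hazard * exp(-log_hazard_coef * f)`, where `f` is the node's
#' true planted (clustered) DC fraction, so a positive coefficient makes
#' higher clustering protective, mirroring the direction of the published
#' survival split. Follow-up is administratively censored at
#' `censor_years` after surgery.
#'
#' @param n_nodes named integer vector: nodes (one per patient) for each
#'   of `HLN`, `NSLN_NEG`, `NSLN_POS`.
#' @param baseline_hazard events per year at clustered fraction 0 (> 0).
#' @param log_hazard_coef log-hazard decrease per unit clustered fraction.
#' @param censor_years administrative censoring horizon (years).
#' @param seed root seed; per-patient streams are derived from it by a
#'   stable hash of (seed, patient index), so the cohort is reproducible
#'   regardless of generation order.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nodes = c(HLN = 6, NSLN_NEG = 33,
                                      NSLN_POS = 19),
                          baseline_hazard = 3,
                          log_hazard_coef = 4,
                          censor_years = 12,
                          seed = 1L) {
  groups <- c("HLN", "NSLN_NEG", "NSLN_POS")
  n_nodes <- n_nodes[groups]
  n_nodes[is.na(n_nodes)] <- 0L
  names(n_nodes) <- groups
  if (baseline_hazard <= 0) {
    stop("baseline_hazard must be > 0", call. = FALSE)
  }
  if (censor_years <= 0) stop("censor_years must be > 0", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes),
                 groups = groups,
                 baseline_hazard = as.numeric(baseline_hazard),
                 log_hazard_coef = as.numeric(log_hazard_coef),
                 censor_years = as.numeric(censor_years),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Stable per-patient seed from (root seed, patient index); < 2^31.
derive_seed <- function(root, idx) {
  as.integer(((root %% 9e7) * 131 + idx * 7919 + 1) %% 2147483647)
}

#' Generate a synthetic cohort with survival metadata
#'
#' One node (and one patient) per entry of `config$n_nodes`, generated
#' from the matching [synth_preset]. Each patient draws a disease-free
#' survival time from the exponential hazard model in [cohort_config];
#' `relapse_event` is `TRUE` when the event precedes the censoring
#' horizon, otherwise follow-up is censored at the horizon.
#'
#' @param config a [cohort_config].
#' @return List with `metadata` (data frame in the cell-map cohort
#'   format: `node_id`, `group`, `patient_id`, `followup_years`,
#'   `relapse_event`, `concurrent_cancer`), `maps` (named list of
#'   [cell_map]), and `truths` (named list of per-node ground truths).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  total <- sum(config$n_nodes)
  if (total == 0L) stop("cohort has no nodes", call. = FALSE)
  group_of <- rep(config$groups, config$n_nodes)

  maps <- vector("list", total)
  truths <- vector("list", total)
  md <- data.frame(node_id = character(total), group = group_of,
                   patient_id = sprintf("P%04d", seq_len(total)),
                   followup_years = numeric(total),
                   relapse_event = logical(total),
                   concurrent_cancer = FALSE,
                   stringsAsFactors = FALSE)
  for (i in seq_len(total)) {
    seed_i <- derive_seed(config$seed, i)
    preset <- synth_preset(group_of[i], seed = seed_i)
    nid <- sprintf("%s_%03d", tolower(group_of[i]), i)
    gen <- generate_node(preset, node_id = nid)
    maps[[i]] <- gen$map
    truths[[i]] <- gen$truth

    f <- gen$truth$true_clustered_fraction
    if (is.na(f)) f <- 0
    rate <- config$baseline_hazard * exp(-config$log_hazard_coef * f)
    t_event <- stats::rexp(1L, rate)  # continues the per-patient stream
    md$node_id[i] <- nid
    md$relapse_event[i] <- t_event < config$censor_years
    md$followup_years[i] <- min(t_event, config$censor_years)
  }
  names(maps) <- md$node_id
  names(truths) <- md$node_id
  list(metadata = md, maps = maps, truths = truths)
}
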