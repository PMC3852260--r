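#' Phenotype vocabulary
#'
#' The closed set of cell phenotype labels used throughout the package.
#' `IMMATURE_DC` encodes CD1a+/CD83- cells, `MATURE_DC` encodes CD83+ cells
#' (with or without CD1a; maturity is defined by CD83 positivity alone),
#' `T_CELL` encodes CD3+, `B_CELL` CD20+, `TUMOR` pan-cytokeratin+, and
#' `OTHER` hematoxylin-only nuclei.
#'
#' @export
dc_phenotypes <- c("IMMATURE_DC", "MATURE_DC", "T_CELL", "B_CELL",
                   "TUMOR", "OTHER")

dc_phenotype_set <- c("IMMATURE_DC", "MATURE_DC")

#' Construct a cell map
#'
#' A cell map holds every classified cell of one lymph-node section: an
#' integer cell id, continuous pixel coordinates (origin top-left, x
#' rightward, y downward), and a phenotype label from [dc_phenotypes].
#'
#' @param cells data frame with columns `cell_id`, `x`, `y`, `phenotype`
#'   (one row per cell; may have zero rows).
#' @param node_id character scalar identifying the node/section.
#' @param extent optional numeric `c(width, height)` in pixels; when given,
#'   all coordinates must lie within `[0, width] x [0, height]`.
#' @return An object of class `cell_map`: a list with elements `node_id`,
#'   `cells` (a data frame, row order preserved) and `extent`.
#' @export
cell_map <- function(cells, node_id = "node", extent = NULL) {
  required <- c("cell_id", "x", "y", "phenotype")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell map is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells <- as.data.frame(cells)[, required]
  cells$cell_id <- as.integer(cells$cell_id)
  cells$x <- as.numeric(cells$x)
  cells$y <- as.numeric(cells$y)
  cells$phenotype <- toupper(as.character(cells$phenotype))

  bad <- !(cells$phenotype %in% dc_phenotypes)
  if (any(bad)) {
    stop("unknown phenotype '", cells$phenotype[which(bad)[1L]],
         "' at row ", which(bad)[1L], call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1L]
    stop("duplicate cell_id: ", dup, call. = FALSE)
  }
  if (nrow(cells) > 0L && (anyNA(cells$x) || anyNA(cells$y) ||
                           any(cells$x < 0) || any(cells$y < 0))) {
    stop("coordinates must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(extent)) {
    extent <- as.numeric(extent)
    stopifnot(length(extent) == 2L, all(extent > 0))
    if (nrow(cells) > 0L &&
        (any(cells$x > extent[1L]) || any(cells$y > extent[2L]))) {
      stop("coordinates outside extent", call. = FALSE)
    }
  }
  rownames(cells) <- NULL
  structure(list(node_id = as.character(node_id), cells = cells,
                 extent = extent),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  tab <- table(factor(x$cells$phenotype, levels = dc_phenotypes))
  cat("cell_map '", x$node_id, "': ", nrow(x$cells), " cells (",
      paste(names(tab)[tab > 0], tab[tab > 0], sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Number of cells / DC subset helpers
#'
#' @param map a [cell_map].
#' @return `n_cells()` the number of cells; `dc_cells()` the data-frame
#'   subset of dendritic cells (immature plus mature), row order preserved.
#' @export
n_cells <- function(map) nrow(map$cells)

#' @rdname n_cells
#' @export
dc_cells <- function(map) {
  map$cells[map$cells$phenotype %in% dc_phenotype_set, , drop = FALSE]
}

#' Read a cell map from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row containing
#' `cell_id,x,y,phenotype`. Phenotype strings are matched case-insensitively
#' against [dc_phenotypes]; `phenotype_map` can translate a user vocabulary
#' (names = strings found in the file, values = canonical labels) first.
#'
#' @param path path to the CSV file.
#' @param node_id node identifier to attach; defaults to the file base name.
#' @param extent optional `c(width, height)` in pixels.
#' @param phenotype_map optional named character vector mapping file labels
#'   onto the canonical phenotype vocabulary.
#' @return A [cell_map]; row order of the file is preserved.
#' @export
read_cell_map <- function(path, node_id = NULL, extent = NULL,
                          phenotype_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(node_id)) {
    node_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         strip.white = TRUE, colClasses = "character")
  required <- c("cell_id", "x", "y", "phenotype")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cell map file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(cell_map(data.frame(cell_id = integer(), x = numeric(),
                               y = numeric(), phenotype = character()),
                    node_id = node_id, extent = extent))
  }
  phen <- toupper(raw$phenotype)
  if (!is.null(phenotype_map)) {
    names(phenotype_map) <- toupper(names(phenotype_map))
    hit <- phen %in% names(phenotype_map)
    phen[hit] <- unname(phenotype_map[phen[hit]])
    phen <- toupper(phen)
  }
  bad <- !(phen %in% dc_phenotypes)
  if (any(bad)) {
    stop("unknown phenotype '", raw$phenotype[which(bad)[1L]],
         "' at data row ", which(bad)[1L], " of '", path, "'",
         call. = FALSE)
  }
  cell_map(data.frame(cell_id = as.integer(raw$cell_id),
                      x = as.numeric(raw$x), y = as.numeric(raw$y),
                      phenotype = phen, stringsAsFactors = FALSE),
           node_id = node_id, extent = extent)
}

#' Write a cell map to CSV
#'
#' @param map a [cell_map].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(map, path) {
  utils::write.csv(map$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata from CSV
#'
#' Columns: `node_id,group,patient_id,followup_years,relapse_event,
#' concurrent_cancer`. `group` must be one of `HLN`, `NSLN_NEG`, `NSLN_POS`;
#' the logical columns accept `TRUE`/`FALSE`/`1`/`0`.
#'
#' @param path metadata CSV path.
#' @return A data frame, one row per node, in file order.
#' @export
read_node_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("node_id", "group", "patient_id", "followup_years",
                "relapse_event", "concurrent_cancer")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0L) {
    stop("metadata file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md$node_id <- as.character(md$node_id)
  md$group <- toupper(as.character(md$group))
  bad <- !(md$group %in% c("HLN", "NSLN_NEG", "NSLN_POS"))
  if (any(bad)) {
    stop("unknown group '", md$group[which(bad)[1L]], "' at row ",
         which(bad)[1L], call. = FALSE)
  }
  md$followup_years <- as.numeric(md$followup_years)
  if (anyNA(md$followup_years) || any(!is.finite(md$followup_years)) ||
      any(md$followup_years < 0)) {
    stop("followup_years must be finite and non-negative", call. = FALSE)
  }
  md$relapse_event <- as.logical(md$relapse_event)
  md$concurrent_cancer <- as.logical(md$concurrent_cancer)
  if (anyDuplicated(md$node_id)) {
    stop("duplicate node_id in metadata: ",
         md$node_id[duplicated(md$node_id)][1L], call. = FALSE)
  }
  md
}

#' Read a full cohort (metadata plus one cell map per node)
#'
#' Joins a metadata table to its per-node cell-map CSV files. Every
#' `node_id` in the metadata must have a map and vice versa; unmatched ids
#' on either side raise an error listing the offenders.
#'
#' @param path_metadata metadata CSV path (see [read_node_metadata]).
#' @param paths_maps character vector of cell-map CSV paths; each file's
#'   node id is its base name without the `.csv` extension.
#' @return A list with elements `metadata` (the data frame, in file order)
#'   and `maps` (a named list of [cell_map] objects in the same order).
#' @export
read_cohort <- function(path_metadata, paths_maps) {
  md <- read_node_metadata(path_metadata)
  maps <- lapply(paths_maps, read_cell_map)
  map_ids <- vapply(maps, function(m) m$node_id, character(1L))
  names(maps) <- map_ids
  missing_maps <- setdiff(md$node_id, map_ids)
  orphan_maps <- setdiff(map_ids, md$node_id)
  if (length(missing_maps) > 0L || length(orphan_maps) > 0L) {
    stop("cohort join failed; metadata rows without a map: [",
         paste(missing_maps, collapse = ", "),
         "]; maps without a metadata row: [",
         paste(orphan_maps, collapse = ", "), "]", call. = FALSE)
  }
  list(metadata = md, maps = maps[md$node_id])
}
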