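#' F1 score of predicted clustered labels against a reference annotation
#'
#' The calibration criterion operates per DC: a DC is "positive" when it
#' belongs to any cluster (prediction) or lies inside a reference-marked
#' aggregate (annotation). F1 is the harmonic mean of precision and recall
#' over these binary labels; it is insensitive to cluster identities, only
#' to clustered/unclustered status.
#'
#' @param assignment a `dbc_assignment`.
#' @param ref reference annotation: data frame with columns `cell_id` and
#'   logical `in_aggregate`, covering exactly the DC set of the assignment.
#' @return F1 in `[0, 1]`. Defined as 0 when precision and recall are both
#'   0; the perfect-empty case (no reference positives, no predicted
#'   positives) scores 1.
#' @export
clustered_label_f1 <- function(assignment, ref) {
  stopifnot(inherits(assignment, "dbc_assignment"),
            is.data.frame(ref),
            all(c("cell_id", "in_aggregate") %in% names(ref)))
  if (!setequal(ref$cell_id, assignment$dc_ids)) {
    stop("reference annotation does not cover the assignment's DC set",
         call. = FALSE)
  }
  pred <- !is.na(assignment$labels[match(ref$cell_id, assignment$dc_ids)])
  truth <- as.logical(ref$in_aggregate)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp == 0L && fp == 0L && fn == 0L) return(1)  # perfect-empty
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Grid search over clustering parameters against reference annotations
#'
#' For every candidate `(R, D)` pair the annotated maps are clustered with
#' [dbc_cluster] and scored with [clustered_label_f1]; the pair with the
#' highest mean F1 across maps is selected, ties broken by smaller `R`,
#' then smaller `D`.
#'
#' @param annotated list of `list(map = cell_map, ref = annotation)` pairs
#'   (see [clustered_label_f1] for the annotation format).
#' @param R_grid numeric vector of candidate radii (pixels). The defaults
#'   bracket the working value of 250 px.
#' @param D_grid numeric vector of candidate density thresholds.
#' @return List with `best` (a [cluster_params]) and `table` (data frame
#'   `R`, `D`, `mean_f1`, one row per grid point, grid order).
#' @export
grid_search <- function(annotated,
                        R_grid = c(100, 150, 200, 250, 300, 400),
                        D_grid = c(3, 4, 5, 6, 8)) {
  if (length(annotated) == 0L) {
    stop("annotated set must be non-empty", call. = FALSE)
  }
  if (length(R_grid) == 0L || length(D_grid) == 0L) {
    stop("parameter grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(R = as.numeric(R_grid), D = as.numeric(D_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    p <- cluster_params(grid$R[i], grid$D[i])
    mean(vapply(annotated, function(a) {
      clustered_label_f1(dbc_cluster(a$map, p), a$ref)
    }, numeric(1L)))
  }, numeric(1L))
  ord <- order(-grid$mean_f1, grid$R, grid$D)
  best <- grid[ord[1L], ]
  list(best = cluster_params(best$R, best$D), table = grid)
}
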