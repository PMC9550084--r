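# IDR taxonomy: Group 1-4 assignment, FOD-ordered/unordered labels,
# K-range segmentation, cohort regression analysis.

#' Classify an IDR / structural-unit pair into Groups 1--4
#'
#' Quadrant classification of the (RD_unit, RD_IDR) pair at the hydrophobic
#' core cut-off (default 0.5):
#' * Group 1 -- both below the cut-off (FOD-ordered): IDR and unit share a
#'   centric hydrophobic core.
#' * Group 2 -- both at/above (FOD-unordered): neither has a core.
#' * Group 3 -- unit below, IDR at/above (FOD-unordered): ordered unit with
#'   a locally unordered IDR.
#' * Group 4 -- IDR below, unit at/above (FOD-ordered): locally ordered IDR
#'   inside an unordered unit.
#'
#' RD exactly at the cut-off counts as "no core" (the core criterion is
#' strictly RD < cut-off).
#'
#' @param rd_unit,rd_idr RD values in \[0, 1\] for the structural unit and
#'   the IDR fragment.
#' @param cutoff Core cut-off (default 0.5).
#' @return List with `group` (integer 1--4) and `fod_status`
#'   (`"FOD-ordered"` or `"FOD-unordered"`).
#' @export
classify_group <- function(rd_unit, rd_idr, cutoff = 0.5) {
  for (v in c(rd_unit, rd_idr))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("RD values must lie in [0, 1]; got ", v)
  unit_core <- rd_unit < cutoff
  idr_core <- rd_idr < cutoff
  group <- if (unit_core && idr_core) 1L
  else if (!unit_core && !idr_core) 2L
  else if (unit_core && !idr_core) 3L
  else 4L
  list(group = group,
       fod_status = if (group %in% c(1L, 4L)) "FOD-ordered"
                    else "FOD-unordered")
}

#' Segment a (K_unit, K_IDR) pair into K ranges
#'
#' Bins each environment coefficient into three ranges: `low`
#' (0 <= K <= 0.5, water-dominated micelle-like), `mid` (0.5 < K < 1.5,
#' partial external modification), `high` (K >= 1.5, strong external field,
#' membrane-like). Boundaries: 0.5 belongs to `low`, 1.5 to `high`.
#'
#' @param k_unit,k_idr Nonnegative environment coefficients.
#' @return Character vector `c(unit = ..., idr = ...)` with levels
#'   low/mid/high.
#' @export
segment_by_k <- function(k_unit, k_idr) {
  bin1 <- function(k) {
    if (!is.finite(k) || k < 0) stop("K must be nonnegative; got ", k)
    if (k <= 0.5) "low" else if (k < 1.5) "mid" else "high"
  }
  c(unit = bin1(k_unit), idr = bin1(k_idr))
}

.check_cohort <- function(rows) {
  need <- c("rd_unit", "rd_idr")
  if (!all(need %in% names(rows)))
    stop("cohort table must have columns ", paste(need, collapse = ", "))
  rows
}

#' Split a cohort about the identity line RD_IDR = RD_unit
#'
#' @param rows Data frame with columns `rd_unit`, `rd_idr` (a cohort table).
#' @return List of data frames `upper` (rd_idr > rd_unit), `lower`
#'   (rd_idr < rd_unit) and `ties`.
#' @export
split_upper_lower <- function(rows) {
  rows <- .check_cohort(rows)
  list(upper = rows[rows$rd_idr > rows$rd_unit, , drop = FALSE],
       lower = rows[rows$rd_idr < rows$rd_unit, , drop = FALSE],
       ties = rows[rows$rd_idr == rows$rd_unit, , drop = FALSE])
}

#' Ordinary least squares of RD_IDR on RD_unit
#'
#' @param rows Data frame with columns `rd_unit`, `rd_idr`.
#' @return List with `slope`, `intercept`, `pearson_r`, `n`.
#' @export
fit_regression <- function(rows) {
  rows <- .check_cohort(rows)
  if (nrow(rows) < 2L || length(unique(rows$rd_unit)) < 2L)
    stop("degenerate fit: need >= 2 distinct rd_unit values")
  fit <- stats::lm(rd_idr ~ rd_unit, data = rows)
  r <- if (stats::sd(rows$rd_idr) == 0) 1
       else stats::cor(rows$rd_unit, rows$rd_idr)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = r,
       n = nrow(rows))
}

#' Stepwise outlier elimination toward a target correlation
#'
#' Deterministic surrogate for visual outlier pruning: while the Pearson
#' correlation of rd_idr with rd_unit is below `target_r`, remove the point
#' with the largest absolute residual from the current OLS fit, then refit.
#' Stops when the target is reached or `max_removed` points are gone.
#'
#' @param rows Data frame with columns `rd_unit`, `rd_idr` and (ideally) an
#'   id column named `protein_id` used in the eliminated list.
#' @param target_r Target Pearson correlation in (0, 1) (default 0.8).
#' @param max_removed Maximum number of points to drop (default
#'   `nrow(rows) - 3`).
#' @return List with `slope`, `intercept`, `pearson_r`, `reached`,
#'   `retained` (data frame), `eliminated` (data frame, in removal order).
#' @export
eliminate_to_target <- function(rows, target_r = 0.8,
                                max_removed = max(nrow(rows) - 3L, 0L)) {
  rows <- .check_cohort(rows)
  if (nrow(rows) < 3L) stop("need at least 3 rows")
  if (!is.finite(target_r) || target_r <= 0 || target_r >= 1)
    stop("target_r must be in (0, 1)")
  kept <- rows
  removed <- rows[0, , drop = FALSE]
  repeat {
    fit <- fit_regression(kept)
    if (fit$pearson_r >= target_r) {
      return(list(slope = fit$slope, intercept = fit$intercept,
                  pearson_r = fit$pearson_r, reached = TRUE,
                  retained = kept, eliminated = removed))
    }
    if (nrow(removed) >= max_removed || nrow(kept) <= 3L) {
      return(list(slope = fit$slope, intercept = fit$intercept,
                  pearson_r = fit$pearson_r, reached = FALSE,
                  retained = kept, eliminated = removed))
    }
    res <- abs(kept$rd_idr - (fit$intercept + fit$slope * kept$rd_unit))
    worst <- which.max(res)
    removed <- rbind(removed, kept[worst, , drop = FALSE])
    kept <- kept[-worst, , drop = FALSE]
  }
}

#' Cohort-level classification report
#'
#' Applies [classify_group()] and [segment_by_k()] to every row of a cohort
#' table, tabulates the 3 x 3 K-range matrix (rows: structural-unit K
#' ranges; columns: IDR K ranges), splits the cohort about the identity
#' line, and fits the upper/lower regression lines where possible.
#'
#' @param rows Data frame with columns `rd_unit`, `rd_idr`, `k_unit`,
#'   `k_idr`, optionally `protein_id` and `has_ss`.
#' @param cutoff RD core cut-off (default 0.5).
#' @return List with `labels` (per-row data frame: group, fod_status,
#'   k_cell_unit, k_cell_idr), `group_counts`, `k_matrix` (3 x 3 integer
#'   matrix low/mid/high), `split` sizes and `regressions` (upper/lower,
#'   `NULL` when a subset is too small).
#' @export
classify_cohort <- function(rows, cutoff = 0.5) {
  rows <- .check_cohort(rows)
  if (!all(c("k_unit", "k_idr") %in% names(rows)))
    stop("cohort table must have columns k_unit, k_idr")
  lab <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    g <- classify_group(rows$rd_unit[i], rows$rd_idr[i], cutoff = cutoff)
    kc <- segment_by_k(rows$k_unit[i], rows$k_idr[i])
    data.frame(protein_id = rows$protein_id[i] %||% as.character(i),
               group = g$group, fod_status = g$fod_status,
               k_cell_unit = kc[["unit"]], k_cell_idr = kc[["idr"]],
               stringsAsFactors = FALSE)
  }))
  lv <- c("low", "mid", "high")
  km <- table(factor(lab$k_cell_unit, levels = lv),
              factor(lab$k_cell_idr, levels = lv))
  km <- matrix(as.integer(km), 3L, 3L, dimnames = list(unit = lv, idr = lv))
  sp <- split_upper_lower(rows)
  reg <- lapply(sp[c("upper", "lower")], function(s) {
    if (nrow(s) >= 2L && length(unique(s$rd_unit)) >= 2L)
      fit_regression(s) else NULL
  })
  gc <- table(factor(lab$group, levels = 1:4))
  list(labels = lab,
       group_counts = stats::setNames(as.integer(gc), names(gc)),
       k_matrix = km,
       split = vapply(sp, nrow, integer(1)),
       regressions = reg)
}
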