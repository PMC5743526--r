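# Evaluation statistics and the parameter-selection sweeps.
# SD convention: population (divide by N) throughout.

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Root-mean-square error between two maps
#'
#' @param a,b volumes or arrays of matching shape.
#' @param mask logical/0-1 array restricting the comparison; whole volume
#'   when `NULL`.
#' @return Scalar RMSE.
#' @export
rmse <- function(a, b, mask = NULL) {
  x <- vol_data(a)
  y <- vol_data(b)
  if (!all(dim(x) == dim(y))) stop("rmse: shapes differ")
  d <- x - y
  if (!is.null(mask)) {
    m <- as.logical(vol_data(mask))
    if (!any(m)) stop("rmse: empty mask")
    d <- d[m]
  }
  sqrt(mean(d^2))
}

#' Coefficient of variation within an ROI
#'
#' Ratio of the population standard deviation to the mean over the ROI
#' voxels; used as a small-vein visibility score (a faithfully
#' reconstructed, uniform vein has CV near zero).
#'
#' @param chi volume or array.
#' @param roi integer voxel indices (non-empty).
#' @return Scalar SD/mean.
#' @export
cv <- function(chi, roi) {
  x <- vol_data(chi)
  if (!length(roi)) stop("cv: empty ROI")
  v <- x[roi]
  m <- mean(v)
  if (m == 0) stop("cv: ROI mean is zero, CV undefined")
  sd_pop(v) / m
}

#' Per-ROI means, SDs and calculation errors
#'
#' Summarizes a susceptibility map over a set of ROIs; when a reference
#' map is supplied, the calculation error is the absolute difference of
#' the ROI means.
#'
#' @param chi volume or array to evaluate.
#' @param rois named list of integer index vectors, or a `roi_set` (whose
#'   vein ROIs are used).
#' @param reference optional reference volume for the error column.
#' @return `data.frame` with columns `roi`, `n`, `mean`, `sd` and (with a
#'   reference) `ref_mean`, `error`.
#' @export
roi_stats <- function(chi, rois, reference = NULL) {
  if (inherits(rois, "roi_set")) rois <- rois$vein
  x <- vol_data(chi)
  out <- data.frame(
    roi = names(rois),
    n = vapply(rois, length, integer(1)),
    mean = vapply(rois, function(i) mean(x[i]), numeric(1)),
    sd = vapply(rois, function(i) sd_pop(x[i]), numeric(1)),
    row.names = NULL
  )
  if (!is.null(reference)) {
    r <- vol_data(reference)
    out$ref_mean <- vapply(rois, function(i) mean(r[i]), numeric(1))
    out$error <- abs(out$mean - out$ref_mean)
  }
  out
}

#' Regression slope between calculated and reference ROI means
#'
#' Ordinary least-squares slope (with intercept) of the calculated-map ROI
#' means against the reference-map ROI means across the supplied ROIs
#' (typically the four deep-gray nuclei).
#'
#' @param calc,ref volumes or arrays.
#' @param rois named list of integer index vectors.
#' @return Scalar slope.
#' @export
regression_slope <- function(calc, ref, rois) {
  x <- vol_data(ref)
  y <- vol_data(calc)
  mx <- vapply(rois, function(i) mean(x[i]), numeric(1))
  my <- vapply(rois, function(i) mean(y[i]), numeric(1))
  if (length(mx) < 2) stop("need at least two ROIs for a slope")
  unname(stats::coef(stats::lm(my ~ mx))[2])
}

#' Line profile through a volume
#'
#' Values along the discrete segment from `start` to `end` (1-based voxel
#' coordinates), sampled at the nearest voxel.
#'
#' @param chi volume or array.
#' @param start,end integer voxel triples.
#' @return Numeric vector of sampled values.
#' @export
line_profile <- function(chi, start, end) {
  x <- vol_data(chi)
  start <- as.numeric(start)
  end <- as.numeric(end)
  nstep <- max(abs(end - start)) + 1
  t <- seq(0, 1, length.out = nstep)
  idx <- vapply(t, function(s) {
    p <- round(start + s * (end - start))
    p[1] + (p[2] - 1) * dim(x)[1] + (p[3] - 1) * dim(x)[1] * dim(x)[2]
  }, numeric(1))
  x[idx]
}

#' Parameter sweep with a selection rule
#'
#' Evaluates a reconstruction-and-metric closure over a parameter grid and
#' applies one of the calibration rules:
#' \describe{
#'   \item{`"argmin"`}{grid value minimizing the metric (CV or RMSE).}
#'   \item{`"argmin_constrained"`}{metric argmin among grid values whose
#'     constraint value exceeds `constraint_min` (e.g. TKD threshold with
#'     nucleus slope > 0.8).}
#'   \item{`"smallest_within_decrease"`}{smallest grid value whose metric
#'     has decreased by at most `max_decrease` (fractional) relative to
#'     `baseline` (the `k_th` rule, with the no-replacement reconstruction
#'     as baseline).}
#' }
#'
#' @param f function of one grid value returning either a numeric metric
#'   or `list(metric = , constraint = )`.
#' @param grid strictly increasing numeric grid.
#' @param rule selection rule (see above).
#' @param constraint_min lower bound for `"argmin_constrained"`.
#' @param baseline reference metric for `"smallest_within_decrease"`.
#' @param max_decrease allowed fractional decrease (default 0.1).
#' @return A `sweep_result` with elements `grid`, `metric`, `constraint`,
#'   `selected`, `rule`, `status` (`"ok"` or `"no-feasible-value"`).
#' @export
sweep_parameter <- function(f, grid,
                            rule = c("argmin", "argmin_constrained",
                                     "smallest_within_decrease"),
                            constraint_min = NULL, baseline = NULL,
                            max_decrease = 0.1) {
  rule <- match.arg(rule)
  if (!length(grid)) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  res <- lapply(grid, f)
  metric <- vapply(res, function(r) {
    if (is.list(r)) r$metric else as.numeric(r)
  }, numeric(1))
  constraint <- vapply(res, function(r) {
    if (is.list(r) && !is.null(r$constraint)) r$constraint else NA_real_
  }, numeric(1))
  selected <- NA_real_
  status <- "ok"
  if (rule == "argmin") {
    selected <- grid[which.min(metric)]
  } else if (rule == "argmin_constrained") {
    if (is.null(constraint_min)) stop("constraint_min required")
    ok <- !is.na(constraint) & constraint > constraint_min
    if (!any(ok)) {
      status <- "no-feasible-value"
    } else {
      selected <- grid[ok][which.min(metric[ok])]
    }
  } else {
    if (is.null(baseline)) stop("baseline required")
    decrease <- (baseline - metric) / baseline
    ok <- decrease <= max_decrease
    if (!any(ok)) {
      status <- "no-feasible-value"
    } else {
      selected <- min(grid[ok])
    }
  }
  structure(list(grid = grid, metric = metric, constraint = constraint,
                 selected = selected, rule = rule, status = status),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> rule = %s, status = %s, selected = %s\n",
              x$rule, x$status, format(x$selected)))
  print(data.frame(grid = x$grid, metric = x$metric,
                   constraint = x$constraint))
  invisible(x)
}
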