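# Exposure of migration concentration areas to wind development potential:
# quantile recoding of both surfaces to {0, 0.25, 0.5, 0.75, 1}, cellwise
# product exposure with five named classes, SD-across-models uncertainty,
# and top-two-quantile overlap percentages with confidence intervals.

#' Recode a raster into five quantile levels 0, 0.25, 0.5, 0.75, 1
#'
#' The raster is classified into `k = 5` quantile bins and each bin mapped
#' to an ascending level, with 1 the quantile holding the highest 20 percent
#' of the data. When heavy ties merge bins, the remaining bins keep the top
#' levels (the highest bin always maps to 1).
#'
#' @param g a `grid`
#' @return a `grid` with values in {0, 0.25, 0.5, 0.75, 1}
#' @export
quantile_recode <- function(g) {
  k <- 5
  qc <- quantile_classify(g, k = k)
  lv <- (k - qc$k_effective + seq_len(qc$k_effective) - 1) / (k - 1)
  cls <- qc$classes$values
  out <- matrix(NA_real_, nrow(cls), ncol(cls))
  ok <- !is.na(cls)
  out[ok] <- lv[cls[ok]]
  grid_like(g, out)
}

recode_levels <- c(0, 0.25, 0.5, 0.75, 1)

check_recoded <- function(g) {
  v <- g$values[!is.na(g$values)]
  if (!all(vapply(v, function(x) any(abs(x - recode_levels) < 1e-9), TRUE)))
    stop("grid is not quantile-recoded to {0, 0.25, 0.5, 0.75, 1}")
  invisible(TRUE)
}

#' Exposure: product of recoded wind potential and migration concentration
#'
#' Cellwise product of the two quantile-recoded surfaces; symmetric in its
#' arguments, zero wherever either input is zero. (High wind potential, 0.75,
#' meeting high migratory concentration, 0.75, gives exposure 0.5625.)
#'
#' @param wind_q,mig_q `grid`s recoded to {0, 0.25, 0.5, 0.75, 1}
#' @return a `grid` in [0, 1]
#' @export
exposure_product <- function(wind_q, mig_q) {
  check_geometry(wind_q, mig_q)
  check_recoded(wind_q); check_recoded(mig_q)
  grid_like(wind_q, wind_q$values * mig_q$values)
}

#' Exposure class labels
#' @return character vector of the five class names, lowest first
#' @export
exposure_levels <- function()
  c("very_low", "low", "moderate", "high", "very_high")

#' Classify an exposure surface into five named levels
#'
#' Published thresholds regularized to a half-open cover of [0, 1]:
#' very_low [0, 0.1), low [0.1, 0.26), moderate [0.26, 0.56),
#' high [0.56, 0.75], very_high (0.75, 1]. Every attainable product of the
#' recode levels classifies; the bounds agree with all printed boundary
#' values.
#'
#' @param exposure a `grid` in [0, 1]
#' @return a `grid` of integer class codes 1..5 with the labels attached as
#'   attribute `levels`
#' @export
exposure_class <- function(exposure) {
  v <- exposure$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("exposure values must lie in [0, 1]")
  cls <- ifelse(v < 0.1, 1L, ifelse(v < 0.26, 2L, ifelse(v < 0.56, 3L,
         ifelse(v <= 0.75, 4L, 5L))))
  out <- grid_like(exposure, cls)
  attr(out, "levels") <- exposure_levels()
  out
}

#' Per-cell standard deviation of exposure across models
#'
#' Population standard deviation across the supplied exposure grids (the
#' full and partial models of one bird group).
#'
#' @param exposures list of at least two exposure `grid`s
#' @return a `grid` of standard deviations
#' @export
exposure_sd <- function(exposures) {
  if (length(exposures) < 2L) stop("at least two exposure grids are required")
  for (i in seq_along(exposures)[-1]) check_geometry(exposures[[1]], exposures[[i]])
  vs <- lapply(exposures, as.matrix)
  m <- Reduce(`+`, vs) / length(vs)
  ssq <- Reduce(`+`, lapply(vs, function(v) (v - m)^2)) / length(vs)
  grid_like(exposures[[1]], sqrt(ssq))
}

#' Mask of the top two quantile levels
#'
#' 1 where a quantile-recoded surface is at least 0.75 (the high and very
#' high quantile classes), else 0.
#'
#' @param recoded a quantile-recoded `grid`
#' @return a binary `grid`
#' @export
top2_mask <- function(recoded) {
  grid_like(recoded, ifelse(recoded$values >= 0.75, 1, 0))
}

#' Mutual overlap percentages of two binary masks
#'
#' A = share of the migration mask covered by the wind mask; B = share of
#' the wind mask covered by the migration mask (both in percent).
#'
#' @param mig_mask,wind_mask binary `grid`s
#' @return named numeric: `pct_of_migration_area`, `pct_of_wind_area`
#' @export
overlap_percentages <- function(mig_mask, wind_mask) {
  check_geometry(mig_mask, wind_mask)
  m <- mig_mask$values; w <- wind_mask$values
  if (!all(m %in% c(0, 1) | is.na(m)) || !all(w %in% c(0, 1) | is.na(w)))
    stop("masks must be binary")
  nm <- sum(m == 1, na.rm = TRUE); nw <- sum(w == 1, na.rm = TRUE)
  if (nm == 0 || nw == 0) stop("overlap percentage undefined for an empty mask")
  ni <- sum(m == 1 & w == 1, na.rm = TRUE)
  c(pct_of_migration_area = 100 * ni / nm, pct_of_wind_area = 100 * ni / nw)
}

#' Union of binary masks
#'
#' Cellwise union of the top-two-quantile masks of several bird groups: the
#' cumulative migration concentration raster.
#'
#' @param masks list of binary `grid`s
#' @return a binary `grid`
#' @export
cumulative_mask <- function(masks) {
  if (!length(masks)) stop("at least one mask is required")
  out <- masks[[1]]
  for (i in seq_along(masks)[-1]) {
    check_geometry(out, masks[[i]])
    out <- grid_like(out, pmax(out$values, masks[[i]]$values))
  }
  out
}

#' Mean and normal-approximation 95 percent confidence interval
#'
#' @param values numeric vector of at least two values
#' @return named numeric: `mean`, `ci_low`, `ci_high`
#' @export
mean_ci <- function(values) {
  if (length(values) < 2L) stop("at least two values are required")
  m <- mean(values); half <- 1.96 * stats::sd(values) / sqrt(length(values))
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Exposure report for one bird group
#'
#' Recodes the wind-potential surface and the full-model MIS into five
#' quantile levels, multiplies them into an exposure surface with its five
#' named classes, repeats the overlay for every partial model to get a
#' per-cell SD (uncertainty) surface, and summarizes the overlap of the
#' top-two-quantile masks: the percentage of the highest migration
#' concentration area inside the highest wind-potential area and vice versa,
#' for the full model and as mean with 95 percent CI across full and partial
#' models.
#'
#' @param model a `migration_model` (or full-model MIS `grid`)
#' @param wind wind-development-potential `grid`
#' @param partials optional named list of partial MIS grids (e.g. from
#'   [sensitivity()]); when NULL only the full model is summarized
#' @return object of class `exposure_report`
#' @export
exposure_report <- function(model, wind, partials = NULL) {
  mis <- as_mis_grid(model)
  check_geometry(mis, wind)
  wq <- quantile_recode(wind)
  wind_mask <- top2_mask(wq)
  overlay <- function(g) {
    mq <- quantile_recode(g)
    list(exposure = exposure_product(wq, mq), mask = top2_mask(mq))
  }
  full <- overlay(mis)
  all_exp <- list(full = full$exposure)
  all_overlap <- list(overlap_percentages(full$mask, wind_mask))
  if (length(partials)) {
    for (nm in names(partials)) {
      ov <- overlay(partials[[nm]])
      all_exp[[nm]] <- ov$exposure
      all_overlap[[length(all_overlap) + 1L]] <-
        tryCatch(overlap_percentages(ov$mask, wind_mask),
                 error = function(e) c(pct_of_migration_area = NA_real_,
                                       pct_of_wind_area = NA_real_))
    }
  }
  om <- do.call(rbind, all_overlap)
  summarize <- function(col) {
    v <- om[, col]
    v <- v[is.finite(v)]
    if (length(v) >= 2) mean_ci(v)
    else c(mean = v[1], ci_low = NA_real_, ci_high = NA_real_)
  }
  overlap <- data.frame(
    measure = c("pct_of_migration_area", "pct_of_wind_area"),
    full_model = c(all_overlap[[1]]["pct_of_migration_area"],
                   all_overlap[[1]]["pct_of_wind_area"]),
    rbind(summarize("pct_of_migration_area"), summarize("pct_of_wind_area")),
    row.names = NULL)
  structure(list(
    exposure = full$exposure,
    classes = exposure_class(full$exposure),
    sd = if (length(all_exp) >= 2) exposure_sd(all_exp) else NULL,
    overlap = overlap,
    mig_mask = full$mask, wind_mask = wind_mask),
    class = "exposure_report")
}

#' @export
print.exposure_report <- function(x, ...) {
  v <- x$exposure$values[!is.na(x$exposure$values)]
  cat(sprintf("Exposure surface: mean %.3f, %.1f%% of cells in high/very high classes\n",
              mean(v), 100 * mean(x$classes$values >= 4, na.rm = TRUE)))
  cat("Top-two-quantile overlap (percent):\n")
  print(x$overlap, row.names = FALSE, digits = 3)
  invisible(x)
}
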