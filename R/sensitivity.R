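# Drop-one-term sensitivity: every factor, modifier and non-unit weight is
# removed (or reset) one at a time, and each partial model is compared with
# the full model by mean/SD percent difference, 5-quantile classification
# accuracy, and a per-cell mean-percent-difference uncertainty surface.

#' Enumerate the drop-one-term partial models of a specification
#'
#' One partial per factor (term removed entirely), one per modifier (that
#' modifier removed from its term), and one per non-unit weight (weight
#' reset to 1). A spec whose weights are all 1 yields no weight partials.
#'
#' @param spec a `group_model_spec`
#' @return named list of `group_model_spec`s, one per partial; names are the
#'   dropped-term labels ("Wetland density", "Wetland density: elevation",
#'   "Weight for wetland density", ...)
#' @export
enumerate_partials <- function(spec) {
  out <- list()
  for (i in seq_along(spec$terms)) {
    t <- spec$terms[[i]]
    if (length(spec$terms) > 1L) {
      p <- spec; p$terms[[i]] <- NULL
      out[[t$label]] <- p
    }
    for (m in t$modifiers) {
      p <- spec
      p$terms[[i]]$modifiers <- setdiff(t$modifiers, m)
      out[[paste0(t$label, ": ", modifier_label(m))]] <- p
    }
  }
  for (i in seq_along(spec$terms)) {
    t <- spec$terms[[i]]
    if (t$weight != 1) {
      p <- spec; p$terms[[i]]$weight <- 1
      out[[paste0("Weight for ", tolower(t$label))]] <- p
    }
  }
  out
}

as_mis_grid <- function(x) {
  if (inherits(x, "migration_model")) x$mis else x
}

#' Per-cell percent difference between a full and a partial model
#'
#' For cells where the full model is positive, computes
#' `100 * |full - partial| / full`; cells where the full model is 0 are
#' excluded (the statistic is undefined there, and no cap is applied above
#' 100 percent). Returns the percent-difference grid and its mean and
#' standard deviation over the included cells.
#'
#' @param full,partial `migration_model`s or `grid`s in [0, 1]
#' @return list with `grid`, `mean`, `sd`
#' @export
percent_difference_stats <- function(full, partial) {
  fg <- as_mis_grid(full); pg <- as_mis_grid(partial)
  check_geometry(fg, pg)
  f <- fg$values; p <- pg$values
  ok <- !is.na(f) & !is.na(p) & f > 0
  if (!any(ok)) stop("percent difference undefined: full model has no positive cells")
  pd <- matrix(NA_real_, nrow(f), ncol(f))
  pd[ok] <- 100 * abs(f[ok] - p[ok]) / f[ok]
  list(grid = grid_like(fg, pd), mean = mean(pd[ok]), sd = stats::sd(pd[ok]))
}

#' Quantile-class agreement between a full and a partial model
#'
#' Both rasters are classified into `k` quantile bins independently; the
#' accuracy is the percentage of cells assigned the same bin in both (the
#' diagonal of the k x k cross-tabulation over all shared unmasked cells).
#'
#' @param full,partial `migration_model`s or `grid`s
#' @param k number of quantile classes (default 5)
#' @return percentage in [0, 100]
#' @export
classification_accuracy <- function(full, partial, k = 5) {
  fg <- as_mis_grid(full); pg <- as_mis_grid(partial)
  check_geometry(fg, pg)
  cf <- quantile_classify(fg, k)$classes$values
  cp <- quantile_classify(pg, k)$classes$values
  ok <- !is.na(cf) & !is.na(cp)
  100 * sum(cf[ok] == cp[ok]) / sum(ok)
}

#' Per-cell mean percent difference across all partial models
#'
#' @param full a `migration_model` or `grid`
#' @param partials list of partial-model grids/models
#' @return a `grid`: mean of the percent-difference surfaces, masked where
#'   the full model is 0
#' @export
uncertainty_surface <- function(full, partials) {
  if (!length(partials)) stop("at least one partial model is required")
  pds <- lapply(partials, function(p) percent_difference_stats(full, p)$grid$values)
  m <- Reduce(`+`, pds) / length(pds)
  grid_like(as_mis_grid(full), m)
}

#' Drop-one-term sensitivity analysis of a migration model
#'
#' Re-evaluates the model once per partial specification (using the cached
#' factor and modifier layers of the fitted model, so each partial is
#' exactly the full model minus one term) and summarizes each partial
#' against the full model.
#'
#' @param model a `migration_model`
#' @param k quantile classes for the accuracy statistic (default 5)
#' @return object of class `mis_sensitivity`: `table` (data.frame with
#'   dropped_label, mean_pct_diff, sd_pct_diff, classification_accuracy_pct),
#'   `uncertainty` (grid), `partials` (named list of partial MIS grids)
#' @export
sensitivity <- function(model, k = 5) {
  stopifnot(inherits(model, "migration_model"))
  specs <- enumerate_partials(model$spec)
  partials <- lapply(specs, evaluate_spec, layers = model$layers)
  rows <- lapply(names(specs), function(lbl) {
    ps <- percent_difference_stats(model$mis, partials[[lbl]])
    data.frame(dropped_label = lbl,
               mean_pct_diff = ps$mean, sd_pct_diff = ps$sd,
               classification_accuracy_pct =
                 classification_accuracy(model$mis, partials[[lbl]], k = k),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 uncertainty = uncertainty_surface(model$mis, partials),
                 partials = partials, group = model$spec$group),
            class = "mis_sensitivity")
}

#' @export
print.mis_sensitivity <- function(x, ...) {
  cat(sprintf("Drop-one-term sensitivity: %s bird model (%d partials)\n",
              x$group, nrow(x$table)))
  tb <- x$table
  tb$mean_pct_diff <- round(tb$mean_pct_diff, 1)
  tb$sd_pct_diff <- round(tb$sd_pct_diff, 1)
  tb$classification_accuracy_pct <- round(tb$classification_accuracy_pct, 1)
  print(tb, row.names = FALSE)
  invisible(x)
}
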