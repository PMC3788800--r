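# Occurrence-data preparation chain, Boyce-index evaluation with
# point-balanced bins, and expert-weighted Likert scoring.

#' Filter occurrences by positional accuracy and quality
#'
#' Retains records whose reported positional error does not exceed
#' `max_error` meters. The published wording ("spatial accuracy of less than
#' 400 m" removed) reads, taken literally, as discarding the most precise
#' records; the intended direction — dropping records with error *worse*
#' than the threshold — is the default, and the literal reading is available
#' via `direction = "min_error"`.
#'
#' @param records occurrence data.frame with an `accuracy_m` column
#' @param max_error threshold in meters (default 400)
#' @param max_quality_rank optional: drop records with quality_rank above
#'   this (rank 1 = best); `Inf` keeps all
#' @param direction "max_error" (default; keep error <= threshold) or
#'   "min_error" (literal reading: keep error >= threshold)
#' @return filtered data.frame
#' @export
filter_by_accuracy <- function(records, max_error = 400, max_quality_rank = Inf,
                               direction = c("max_error", "min_error")) {
  direction <- match.arg(direction)
  keep <- if (direction == "max_error") records$accuracy_m <= max_error
          else records$accuracy_m >= max_error
  if (is.finite(max_quality_rank) && "quality_rank" %in% names(records))
    keep <- keep & records$quality_rank <= max_quality_rank
  records[which(keep), , drop = FALSE]
}

#' Thin occurrences to a minimum inter-point distance
#'
#' Greedy pass in descending quality order (quality_rank 1 first; ties by
#' input order): a point is kept iff no already-kept point lies closer than
#' `min_dist`. Points closer than the threshold to a better-quality point are
#' thereby removed. Thinning is idempotent.
#'
#' @param records occurrence data.frame with `x`, `y`, `quality_rank`
#' @param min_dist minimum distance in meters (default 800)
#' @return thinned data.frame (original row order preserved)
#' @export
thin_min_distance <- function(records, min_dist = 800) {
  n <- nrow(records)
  if (n <= 1L) return(records)
  ord <- order(records$quality_rank, seq_len(n))
  kept <- integer(0)
  kx <- numeric(0); ky <- numeric(0)
  d2 <- min_dist^2
  for (i in ord) {
    if (!length(kept) ||
        all((kx - records$x[i])^2 + (ky - records$y[i])^2 >= d2)) {
      kept <- c(kept, i)
      kx <- c(kx, records$x[i]); ky <- c(ky, records$y[i])
    }
  }
  records[sort(kept), , drop = FALSE]
}

#' Species-stratified random subsample
#'
#' Selects up to `per_species_cap` records per species at random without
#' replacement (all records where fewer are available), to balance species
#' contributions. Warns, without failing, when the total falls below
#' `target_min`.
#'
#' @param records occurrence data.frame with a `species` column
#' @param per_species_cap maximum records per species (default 10)
#' @param target_min desired minimum total (default 50)
#' @param seed integer seed
#' @return subsampled data.frame (original row order preserved)
#' @export
stratified_subsample <- function(records, per_species_cap = 10, target_min = 50,
                                 seed = 1) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(records)), records$species),
                          function(idx) {
                            if (length(idx) <= per_species_cap) idx
                            else sample(idx, per_species_cap)
                          }), use.names = FALSE)
    keep <- sort(keep)
    if (length(keep) < target_min)
      warning(sprintf("only %d validation points available (target %d)",
                      length(keep), target_min))
    records[keep, , drop = FALSE]
  })
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

spearman_rho <- function(a, b) {
  suppressWarnings(stats::cor(a, b, method = "spearman"))
}

# One-sided (positive-association) permutation p-value for the Spearman
# correlation of `ratio` against 1..k. Exact enumeration for k <= exact_max,
# seeded Monte Carlo otherwise.
boyce_p_value <- function(ratio, rho, exact_max = 8, n_mc = 10000, seed = 1) {
  k <- length(ratio)
  if (!is.finite(rho)) return(NA_real_)
  # Spearman against the untied sequence 1..k reduces to a Pearson product
  # of permuted mid-ranks, so permutations vectorize as column sums.
  x <- rank(ratio); x <- x - mean(x)
  y <- seq_len(k) - (k + 1) / 2
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) return(NA_real_)
  if (k <= exact_max) {
    pm <- all_perms(k)
    rr <- colSums(matrix(x[t(pm)], nrow = k) * y) / denom
    mean(rr >= rho - 1e-12)
  } else {
    with_seed(seed, {
      X <- vapply(seq_len(n_mc), function(i) sample(x), numeric(k))
      rr <- colSums(X * y) / denom
      (1 + sum(rr >= rho - 1e-12)) / (n_mc + 1)
    })
  }
}

#' Boyce index of a model against presence-only validation points
#'
#' Points are scored on the model raster and ranked; the ranking is split
#' into `k` nearly point-balanced bins. The nominal threshold between two
#' bins is the midpoint of the scores straddling the break; bin membership
#' itself is decided by rank against the straddling scores (cells with
#' values strictly between two adjacent point scores join the lower bin), so
#' the whole index is invariant under strictly increasing transforms of the
#' raster. Breaks falling inside a run of tied scores are merged, reducing
#' the effective bin count. For each bin the area-adjusted frequency is the
#' bin's share of validation points divided by its share of study-area
#' cells; the Boyce index is the Spearman rank correlation between that
#' ratio and the bin rank, with a one-sided permutation p-value.
#'
#' @param object a `migration_model` or a score `grid`
#' @param points data.frame with columns `x`, `y`
#' @param k target number of bins (default 10)
#' @param p_seed seed for the Monte-Carlo p-value when the bin count exceeds
#'   the exact-enumeration limit
#' @param ... unused
#' @return object of class `boyce_result`: `bins` data.frame (rank,
#'   threshold, point_fraction, area_fraction, ratio), `rho`, `p_value`,
#'   `k`, `k_effective`
#' @export
boyce <- function(object, points, k = 10, p_seed = 1, ...) UseMethod("boyce")

#' @export
boyce.migration_model <- function(object, points, k = 10, p_seed = 1, ...)
  boyce(object$mis, points, k = k, p_seed = p_seed)

#' @export
boyce.grid <- function(object, points, k = 10, p_seed = 1, ...) {
  s <- grid_extract(object, points$x, points$y)
  s <- s[!is.na(s)]
  if (length(s) < k) stop("need at least k points with valid model scores")
  n <- length(s)
  o <- sort(s)
  cut_idx <- floor(seq_len(k - 1) * n / k)
  lo <- o[cut_idx]; hi <- o[cut_idx + 1L]
  keep <- hi > lo & !duplicated(lo)       # merge breaks inside tied runs
  lo <- lo[keep]; hi <- hi[keep]
  k_eff <- length(lo) + 1L
  bin_of <- function(v) 1L + rowSums(outer(v, hi, ">="))
  pf <- tabulate(bin_of(s), nbins = k_eff) / n
  cells <- object$values[!is.na(object$values)]
  af <- tabulate(bin_of(cells), nbins = k_eff) / length(cells)
  ratio <- pf / af
  rho <- if (k_eff >= 2) spearman_rho(ratio, seq_len(k_eff)) else NA_real_
  p <- boyce_p_value(ratio, rho, seed = p_seed)
  bins <- data.frame(rank = seq_len(k_eff),
                     threshold = c((lo + hi) / 2, NA),
                     point_fraction = pf, area_fraction = af, ratio = ratio)
  structure(list(bins = bins, rho = rho, p_value = p, k = k,
                 k_effective = k_eff, n_points = n),
            class = "boyce_result")
}

#' @export
print.boyce_result <- function(x, ...) {
  cat(sprintf("Boyce index: %.3f (p = %.4g), %d bins (target %d), %d points\n",
              x$rho, x$p_value, x$k_effective, x$k, x$n_points))
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Expertise-weighted mean of expert model ratings
#'
#' Each reviewer rates the model on a 5-point scale (-1 very poor, -0.5
#' poor, 0 okay, 0.5 good, 1 very good) and their own expertise on a 5-point
#' scale (1, 1.25, 1.5, 1.75, 2). The score is the mean over reviewers of
#' rating x expertise, in [-2, 2]; values below zero indicate a poor model.
#'
#' @param ratings data.frame with columns `model_rating` and `expertise`,
#'   or a list of such pairs
#' @return scalar weighted-average score
#' @export
expert_weighted_score <- function(ratings) {
  if (!is.data.frame(ratings))
    ratings <- do.call(rbind, lapply(ratings, function(r)
      data.frame(model_rating = r$model_rating, expertise = r$expertise)))
  if (!nrow(ratings)) stop("at least one rating is required")
  ok_r <- ratings$model_rating %in% c(-1, -0.5, 0, 0.5, 1)
  ok_e <- ratings$expertise %in% c(1, 1.25, 1.5, 1.75, 2)
  if (!all(ok_r)) stop("model ratings must be in {-1, -0.5, 0, 0.5, 1}")
  if (!all(ok_e)) stop("expertise must be in {1, 1.25, 1.5, 1.75, 2}")
  mean(ratings$model_rating * ratings$expertise)
}

#' Filter occurrences to each species' migration window
#'
#' Keeps records whose date (month-day) falls within the species' window;
#' windows that wrap the year end are supported. Species absent from the
#' window table are dropped.
#'
#' @param records occurrence data.frame with `species` and `date` columns
#' @param windows data.frame (species, start_mmdd, end_mmdd)
#' @return filtered data.frame
#' @export
filter_by_migration_window <- function(records, windows) {
  mmdd <- format(as.Date(records$date), "%m-%d")
  wi <- match(records$species, windows$species)
  s <- windows$start_mmdd[wi]; e <- windows$end_mmdd[wi]
  keep <- !is.na(wi) & ifelse(s <= e, mmdd >= s & mmdd <= e,
                              mmdd >= s | mmdd <= e)
  records[which(keep), , drop = FALSE]
}
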