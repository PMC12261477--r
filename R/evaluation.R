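#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A constant input vector has
#' no defined rank correlation and raises an error rather than silently
#' returning `NA`.
#'
#' @param pred,truth Numeric vectors of equal length (>= 2).
#' @return Spearman's rho in [-1, 1].
#' @export
spearman_rho <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) < 2L) stop("need at least 2 observations for correlation")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop("undefined correlation: constant input vector")
  }
  stats::cor(pred, truth, method = "spearman")
}

#' Weighted average of per-assay correlations
#'
#' @param rho Numeric vector of per-assay correlations.
#' @param weights Nonnegative weights, not all zero (default uniform).
#' @return `sum(w * rho) / sum(w)`.
#' @export
weighted_average <- function(rho, weights = NULL) {
  w <- weights %||% rep(1, length(rho))
  if (length(w) != length(rho)) stop("weights length does not match rho")
  stopifnot(all(w >= 0))
  if (sum(w) == 0) stop("weights must not all be zero")
  sum(w * rho) / sum(w)
}

#' Bootstrap standard deviation of the aggregate correlation
#'
#' Mutants are resampled with replacement within each assay; the per-assay
#' Spearman correlations and their weighted average are recomputed for each
#' of `B` replicates, and the standard deviation over replicates is reported.
#' Assays with fewer than 2 distinct rows are excluded with a warning. Within
#' a replicate, an assay whose resample is constant is dropped from that
#' replicate's average.
#'
#' @param assays Named list of data frames, each with numeric columns `pred`
#'   and `truth`.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param weights Optional per-assay weights for the aggregate.
#' @return List with `sd`, `mean`, `replicates` (length-B vector), and
#'   `point` (the non-resampled aggregate).
#' @export
bootstrap_sd <- function(assays, B = 1000L, seed = 1L, weights = NULL) {
  stopifnot(B >= 2L)
  ok <- vapply(assays, function(a) {
    nrow(a) >= 2L && nrow(unique(a[, c("pred", "truth")])) >= 2L &&
      stats::sd(a$pred) > 0 && stats::sd(a$truth) > 0
  }, logical(1))
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " assay(s) with < 2 distinct rows")
    assays <- assays[ok]
    if (!is.null(weights)) weights <- weights[ok]
  }
  if (length(assays) == 0L) stop("no usable assays")
  w <- weights %||% rep(1, length(assays))
  point <- weighted_average(
    vapply(assays, function(a) spearman_rho(a$pred, a$truth), numeric(1)), w)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    rhos <- rep(NA_real_, length(assays))
    for (k in seq_along(assays)) {
      a <- assays[[k]]
      idx <- sample.int(nrow(a), nrow(a), replace = TRUE)
      p <- a$pred[idx]; t <- a$truth[idx]
      if (stats::sd(p) > 0 && stats::sd(t) > 0) {
        rhos[k] <- stats::cor(p, t, method = "spearman")
      }
    }
    keep <- !is.na(rhos)
    if (!any(keep)) return(NA_real_)
    weighted_average(rhos[keep], w[keep])
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  list(sd = stats::sd(reps), mean = mean(reps), replicates = reps,
       point = point)
}

#' Validation subsample of an assay table
#'
#' Per-assay simple random sample without replacement of
#' `ceiling(fraction * n)` rows, deterministic under `seed`. The selected
#' rows keep their original order; `fraction = 1` is the identity.
#'
#' @param assay Data frame of assay rows.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed RNG seed.
#' @return The subsampled data frame.
#' @export
validation_split <- function(assay, fraction = 0.10, seed = 1L) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n <- nrow(assay)
  if (n == 0L) stop("empty assay")
  if (fraction == 1) return(assay)
  set.seed(seed)
  take <- sort(sample.int(n, ceiling(fraction * n)))
  assay[take, , drop = FALSE]
}

#' Retrieval-ratio sweep
#'
#' Evaluates the aggregate correlation at each retrieval ratio in `grid`,
#' holding all other inputs fixed.
#'
#' @param grid Numeric vector of ratios in [0, 1].
#' @param score_fn Function `alpha -> named list of prediction vectors`,
#'   names matching `assays`.
#' @param assays Named list of data frames each with a numeric `truth`
#'   column (and one row per mutant, in the order `score_fn` predicts).
#' @param weights Optional per-assay weights.
#' @return Data frame with columns `alpha` and `rho`.
#' @export
alpha_sweep <- function(grid, score_fn, assays, weights = NULL) {
  stopifnot(all(grid >= 0 & grid <= 1), length(grid) >= 1L)
  rho <- vapply(grid, function(a) {
    preds <- score_fn(a)
    per <- vapply(names(assays), function(nm) {
      spearman_rho(preds[[nm]], assays[[nm]]$truth)
    }, numeric(1))
    weighted_average(per, weights)
  }, numeric(1))
  data.frame(alpha = grid, rho = rho)
}

#' Read / write assay tables (DMS CSV dialect)
#'
#' Comma-separated, UTF-8, header required; columns `mutant` and `DMS_score`
#' (plus optional extras such as `DMS_score_bin`, which are preserved).
#'
#' @param path CSV path.
#' @return Data frame with at least `mutant` and `DMS_score`.
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mutant", "DMS_score") %in% colnames(df))) {
    stop("assay table must have 'mutant' and 'DMS_score' columns")
  }
  df
}

#' @rdname read_assay_csv
#' @param assay Data frame to write.
#' @export
write_assay_csv <- function(assay, path) {
  utils::write.csv(assay, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate predictions against assay tables
#'
#' @param assays Named list of data frames with `pred` and `truth` columns.
#' @param weights Optional per-assay weights; if `groups` is given, assays
#'   are first averaged within group and then across groups.
#' @param groups Optional character vector of group labels per assay.
#' @param bootstrap Number of bootstrap replicates for the aggregate SD
#'   (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return List of class `eval_report`: `per_assay` (data frame of assay,
#'   n, rho), `aggregate`, `bootstrap_sd`, `config`.
#' @export
evaluate_assays <- function(assays, weights = NULL, groups = NULL,
                            bootstrap = 0L, seed = 1L) {
  per <- data.frame(
    assay = names(assays),
    n = vapply(assays, nrow, integer(1)),
    rho = vapply(assays, function(a) spearman_rho(a$pred, a$truth),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(assays))
    by_group <- tapply(per$rho, groups, mean)
    aggregate <- mean(by_group)
  } else {
    aggregate <- weighted_average(per$rho, weights)
  }
  bs <- if (bootstrap >= 2L) {
    bootstrap_sd(assays, B = bootstrap, seed = seed, weights = weights)$sd
  } else NA_real_
  structure(list(per_assay = per, aggregate = aggregate, bootstrap_sd = bs,
                 config = list(weights = weights, groups = groups,
                               bootstrap = bootstrap, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d assays, aggregate rho = %.4f (bootstrap SD %s)\n",
              nrow(x$per_assay), x$aggregate,
              ifelse(is.na(x$bootstrap_sd), "n/a",
                     sprintf("%.4f", x$bootstrap_sd))))
  invisible(x)
}
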