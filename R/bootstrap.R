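# run code with a private RNG state so package functions are deterministic
# given their seed argument without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Datasets programmatically identified as wild
#'
#' A dataset counts as programmatically wild when every member sample is
#' classified `wild` -- the dataset-level analogue of removing domesticated
#' species and captive material. Unlinked singleton pseudo-datasets are
#' excluded.
#'
#' @param corpus a wildness-classified corpus.
#' @param rules a [scope_rules()] (used if wildness must be computed).
#' @return character vector of dataset accessions, sorted.
#' @export
wild_dataset_pool <- function(corpus, rules = scope_rules()) {
  if (is.null(corpus$wildness)) corpus <- classify_corpus_wildness(corpus, rules)
  mem <- corpus$memberships[!corpus$memberships$unlinked, , drop = FALSE]
  tab <- mem |>
    dplyr::inner_join(corpus$wildness, by = "sample_accession") |>
    dplyr::group_by(.data$dataset_accession) |>
    dplyr::summarise(all_wild = all(.data$call == "wild"), .groups = "drop")
  sort(tab$dataset_accession[tab$all_wild])
}

#' Randomly subsample wild datasets for validation
#'
#' Draws `n` datasets uniformly without replacement from the pool of
#' programmatically wild datasets -- the design for checking, against the
#' literature, how often the wild filter is right. Deterministic given the
#' seed.
#'
#' @param corpus a wildness-classified corpus.
#' @param n number of datasets to draw.
#' @param seed integer seed.
#' @param rules a [scope_rules()].
#' @return object of class `validation_sample`: `dataset_accessions`
#'   (in draw order), `n`, `seed`, `pool_size`.
#' @export
subsample_datasets <- function(corpus, n, seed, rules = scope_rules()) {
  pool <- wild_dataset_pool(corpus, rules)
  if (n > length(pool)) {
    stop("requested ", n, " datasets but the wild pool has only ",
         length(pool))
  }
  drawn <- with_seed(seed, sample(pool, n, replace = FALSE))
  structure(list(dataset_accessions = drawn, n = n, seed = seed,
                 pool_size = length(pool)), class = "validation_sample")
}

#' Precision of the wild filter on a validation sample
#'
#' The fraction of subsampled programmatically-wild datasets whose truth
#' label says they really are from wild populations.
#'
#' @param sample a `validation_sample` from [subsample_datasets()].
#' @param truth_labels tibble with columns `dataset_accession`, `is_wild`
#'   (logical), or a named logical vector.
#' @return proportion in \[0, 1\].
#' @export
filter_precision <- function(sample, truth_labels) {
  if (missing(truth_labels) || is.null(truth_labels)) {
    stop("truth labels are required to compute filter precision")
  }
  if (is.data.frame(truth_labels)) {
    lab <- setNames(truth_labels$is_wild, truth_labels$dataset_accession)
  } else {
    lab <- truth_labels
  }
  v <- lab[sample$dataset_accessions]
  if (anyNA(v)) {
    stop("truth labels missing for: ",
         paste(head(sample$dataset_accessions[is.na(v)], 5), collapse = ", "))
  }
  mean(as.logical(v))
}

#' Bootstrap confidence interval for a proportion
#'
#' Percentile bootstrap (the default): the indicator list is resampled with
#' replacement `n_reps` times and the interval is read off the
#' `(1-level)/2` and `1-(1-level)/2` quantiles of the resampled
#' proportions, with type-7 (linear interpolation between order statistics)
#' quantiles -- the convention is recorded in the result so independent
#' implementations can agree exactly. The full resampling index matrix is
#' drawn in a single `sample.int(n, n * n_reps, replace = TRUE)` call, so
#' the draw stream is reproducible from the seed alone. A
#' bias-corrected-and-accelerated (`"bca"`) variant is available.
#'
#' @param indicator logical (or 0/1) vector; the sampling unit of whatever
#'   was subsampled -- here datasets, not individuals.
#' @param n_reps number of bootstrap resamples (>= 1).
#' @param seed integer seed.
#' @param ci_level confidence level (default 0.95).
#' @param method `"percentile"` (default) or `"bca"`.
#' @return object of class `bootstrap_result`: `point_estimate`, `ci_low`,
#'   `ci_high`, `n`, `n_reps`, `ci_level`, `method`, `seed`.
#' @export
bootstrap_proportion <- function(indicator, n_reps = 10000, seed = 1,
                                 ci_level = 0.95,
                                 method = c("percentile", "bca")) {
  method <- match.arg(method)
  x <- as.numeric(indicator)
  n <- length(x)
  if (n == 0) stop("indicator list is empty")
  if (n_reps < 1) stop("n_reps must be at least 1")
  point <- mean(x)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * n_reps, replace = TRUE)
    colMeans(matrix(x[idx], nrow = n, ncol = n_reps))
  })
  alpha <- (1 - ci_level) / 2
  if (method == "percentile") {
    qs <- quantile(means, c(alpha, 1 - alpha), type = 7, names = FALSE)
    method_label <- "percentile bootstrap, type-7 quantiles"
  } else {
    z0 <- qnorm((sum(means < point) + 0.5 * sum(means == point)) / n_reps)
    loo <- (point * n - x) / (n - 1)
    d <- mean(loo) - loo
    a <- sum(d^3) / (6 * sum(d^2)^1.5)
    if (!is.finite(z0) || !is.finite(a)) {
      # degenerate resampling distribution: fall back to raw percentiles
      qs <- quantile(means, c(alpha, 1 - alpha), type = 7, names = FALSE)
    } else {
      zq <- qnorm(c(alpha, 1 - alpha))
      adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
      qs <- quantile(means, adj, type = 7, names = FALSE)
    }
    method_label <- "BCa bootstrap, type-7 quantiles"
  }
  structure(list(point_estimate = point,
                 ci_low = qs[1], ci_high = qs[2],
                 n = n, n_reps = as.integer(n_reps),
                 ci_level = ci_level, method = method_label,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.1f%% (bootstrapped %d%% CI: %.1f to %.1f%%; %s, %d reps)\n",
              100 * x$point_estimate, round(100 * x$ci_level),
              100 * x$ci_low, 100 * x$ci_high, x$method, x$n_reps))
  invisible(x)
}

#' End-to-end validation report for the wild filter
#'
#' Subsamples `n` programmatically wild datasets, computes the filter
#' precision against truth labels, and bootstraps the proportion of
#' sampled datasets whose metadata status indicator is true. Both the
#' all-sampled and the truly-wild-only bases are reported, since a
#' validation CI can reasonably be computed over either.
#'
#' @param corpus a wildness-classified, parsed corpus.
#' @param truth_labels tibble (`dataset_accession`, `is_wild`).
#' @param indicator named logical vector or tibble (`dataset_accession`,
#'   `indicator`) of the per-dataset property of interest (e.g. "has
#'   spatiotemporal metadata").
#' @param n subsample size.
#' @param seed integer seed (drives both the subsample and the bootstrap).
#' @param n_reps bootstrap replicates.
#' @param ci_level confidence level.
#' @param rules a [scope_rules()].
#' @return list: `sample`, `precision`, `bootstrap_all`,
#'   `bootstrap_truly_wild`.
#' @export
validate_wild_filter <- function(corpus, truth_labels, indicator, n, seed,
                                 n_reps = 10000, ci_level = 0.95,
                                 rules = scope_rules()) {
  vs <- subsample_datasets(corpus, n, seed, rules)
  prec <- filter_precision(vs, truth_labels)
  if (is.data.frame(indicator)) {
    ind <- setNames(indicator$indicator, indicator$dataset_accession)
  } else {
    ind <- indicator
  }
  iv <- as.logical(ind[vs$dataset_accessions])
  if (anyNA(iv)) stop("indicator missing for some sampled datasets")
  if (is.data.frame(truth_labels)) {
    lab <- setNames(truth_labels$is_wild, truth_labels$dataset_accession)
  } else {
    lab <- truth_labels
  }
  truly_wild <- as.logical(lab[vs$dataset_accessions])
  list(sample = vs,
       precision = prec,
       bootstrap_all = bootstrap_proportion(iv, n_reps, seed + 1L, ci_level),
       bootstrap_truly_wild = bootstrap_proportion(iv[truly_wild], n_reps,
                                                   seed + 2L, ci_level))
}
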