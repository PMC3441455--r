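#' Free-energy surface from equilibrium samples
#'
#' Bins per-frame observable samples and converts occupancies to free
#' energies `F_b = -kT ln(n_b / N)`, shifted so the minimum over occupied
#' bins is zero. Empty bins are masked (no F value), never interpolated.
#' Samples outside the bin range are clamped into the edge bins and
#' counted.
#'
#' @param data Data frame of per-frame observables (e.g. from
#'   [compute_observables()]).
#' @param x Name of the observable for the first axis.
#' @param y Optional second-axis observable name (2D surface).
#' @param bins Named list of bin-edge vectors or bin widths per axis; a
#'   single number is a width, a vector is explicit edges. Defaults: 1 for
#'   `delta` (Angstrom) and `nc` (contacts), 0.05 for `helix_fraction`.
#' @param kT Thermal energy in reduced units (free energies are in units of
#'   kT when this is 1).
#' @param run Optional name of a run-id column; when present, per-bin
#'   jackknife errors over runs are attached.
#' @return Object of class `bs_fes`: a list with `bins` (tibble with bin
#'   centers, counts, `F`, `err`, `occupied`), axis metadata and totals.
#' @export
fes_from_samples <- function(data, x, y = NULL, bins = list(), kT = 1,
                             run = NULL) {
  axes <- c(x, y)
  for (ax in axes) {
    if (!ax %in% names(data)) {
      stop("unknown observable '", ax, "'; available: ",
           paste(names(data), collapse = ", "))
    }
  }
  vals <- data[axes]
  keep <- stats::complete.cases(vals)
  vals <- vals[keep, , drop = FALSE]
  n <- nrow(vals)
  if (n < 1) stop("no complete samples to bin")

  edges <- lapply(axes, function(ax) {
    b <- bins[[ax]]
    if (is.null(b)) b <- default_bin_width(ax)
    if (length(b) == 1) {
      lo <- floor(min(vals[[ax]]) / b) * b
      hi <- ceiling(max(vals[[ax]]) / b) * b
      if (hi <= lo) hi <- lo + b
      seq(lo, hi, by = b)
    } else {
      sort(b)
    }
  })
  names(edges) <- axes

  idx <- lapply(axes, function(ax) {
    e <- edges[[ax]]
    i <- findInterval(vals[[ax]], e, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(i, 1L), length(e) - 1L)
  })
  n_clamped <- sum(vapply(seq_along(axes), function(k) {
    v <- vals[[axes[k]]]; e <- edges[[k]]
    sum(v < e[1] | v > e[length(e)])
  }, numeric(1)))

  dims <- vapply(edges, function(e) length(e) - 1L, 1L)
  flat <- idx[[1]]
  if (length(axes) == 2) flat <- flat + (idx[[2]] - 1L) * dims[1]
  counts <- tabulate(flat, nbins = prod(dims))

  grid <- expand.grid(lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- axes
  occ <- counts > 0
  F <- rep(NA_real_, length(counts))
  F[occ] <- -kT * log(counts[occ] / n)
  F <- F - min(F, na.rm = TRUE)

  err <- rep(NA_real_, length(counts))
  if (!is.null(run) && run %in% names(data)) {
    run_id <- data[[run]][keep]
    runs <- unique(run_id)
    if (length(runs) >= 2) {
      for (b in which(occ)) {
        per_run_f <- function(drop_run) {
          sel <- run_id != drop_run
          nn <- sum(sel)
          cb <- sum(flat[sel] == b)
          if (cb == 0) return(NA_real_)
          -kT * log(cb / nn)
        }
        theta <- vapply(runs, per_run_f, numeric(1))
        if (!anyNA(theta)) {
          m <- length(theta)
          err[b] <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
        }
      }
    }
  }
  if (sum(occ) == 1) {
    warning("all samples fall into a single bin")
  }
  structure(list(
    bins = tibble::tibble(grid, counts = counts, F = F, err = err,
                          occupied = occ),
    axes = axes, edges = edges, kT = kT, n_samples = n,
    n_clamped = n_clamped), class = "bs_fes")
}

default_bin_width <- function(axis) {
  switch(axis, delta = 1, nc = 1, helix_fraction = 0.05, rmsd_opt = 0.5, 1)
}

#' @export
print.bs_fes <- function(x, ...) {
  cat("<bs_fes> ", length(x$axes), "D surface over ",
      paste(x$axes, collapse = " x "), ": ", nrow(x$bins), " bins (",
      sum(x$bins$occupied), " occupied), ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Delete-one jackknife standard error over independent runs
#'
#' Given per-run inputs and an estimator, computes the delete-one jackknife
#' standard error `sqrt((m-1)/m * sum((theta_(-i) - theta_bar)^2))` where
#' `theta_(-i)` is the estimator applied with run `i` removed. The unit of
#' resampling is the independent simulation run.
#'
#' @param runs A list of per-run data (vectors or data frames), one element
#'   per independent run, or a numeric vector of per-run values (for which
#'   the estimator sees the pooled remaining values).
#' @param estimator Function mapping the pooled retained data to a scalar.
#'   Defaults to the mean of pooled values.
#' @return Jackknife standard error; `NA_real_` with fewer than 2 runs
#'   (never 0).
#' @export
jackknife_error <- function(runs, estimator = NULL) {
  if (is.numeric(runs) && is.null(dim(runs))) runs <- as.list(runs)
  m <- length(runs)
  if (m < 2) return(NA_real_)
  pool <- function(lst) {
    if (all(vapply(lst, is.data.frame, TRUE))) dplyr::bind_rows(lst)
    else unlist(lst, use.names = FALSE)
  }
  if (is.null(estimator)) estimator <- function(x) mean(x)
  theta <- vapply(seq_len(m), function(i) estimator(pool(runs[-i])), numeric(1))
  sqrt((m - 1) / m * sum((theta - mean(theta))^2))
}

#' One-dimensional free-energy profile with jackknife errors
#'
#' @param table Observable table (tibble), optionally with a `run` column
#'   identifying independent runs.
#' @param observable Column name to profile.
#' @param bins Bin width (scalar) or explicit edge vector.
#' @param kT Thermal energy in reduced units.
#' @param run Name of the run-id column (errors are missing-flagged when
#'   absent or a single run is supplied).
#' @return A `bs_fes` with one axis.
#' @export
profile_1d <- function(table, observable, bins = NULL, kT = 1, run = "run") {
  b <- list()
  if (!is.null(bins)) b[[observable]] <- bins
  use_run <- !is.null(run) && run %in% names(table) &&
    length(unique(table[[run]])) >= 2
  fes_from_samples(table, x = observable, bins = b, kT = kT,
                   run = if (use_run) run)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free-energy surface into a tibble of bins
#' @param x A `bs_fes`.
#' @param ... Unused.
#' @return Tibble with bin centers, `counts`, `F`, `err`, `occupied`.
#' @method tidy bs_fes
#' @export
tidy.bs_fes <- function(x, ...) x$bins

#' One-row summary of a free-energy surface
#' @param x A `bs_fes`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance bs_fes
#' @export
glance.bs_fes <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples,
                 n_bins = nrow(x$bins),
                 n_occupied = sum(x$bins$occupied),
                 n_clamped = x$n_clamped,
                 max_F = max(x$bins$F, na.rm = TRUE),
                 kT = x$kT)
}

#' Serialize / read a free-energy surface as TSV
#'
#' @param fes A `bs_fes`.
#' @param path TSV path (bin-center columns followed by counts, F, err).
#' @return Invisibly, `path`.
#' @export
write_fes <- function(fes, path) {
  readr::write_tsv(fes$bins, path, na = "NA")
  invisible(path)
}
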