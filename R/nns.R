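#' Nearest-neighbour-search baseline index
#'
#' Stores the max-normalized moduli of a reference library (typically the
#' training split) for brute-force look-up of the best-matching pattern by
#' chi-squared modulus error. The matched sample's ground-truth amplitude and
#' phase then serve as a reconstruction (and as an initial guess for
#' iterative refinement). Queries are normalized identically to references.
#'
#' @param dataset A `cdi_dataset`.
#' @param idx Reference sample indices (default: the training split).
#' @return An `nns_index`.
#' @export
nns_index <- function(dataset, idx = dataset$split$train) {
  if (!length(idx)) stop("reference library must contain at least one pattern")
  mods <- vapply(dataset$samples[idx],
                 function(s) as.numeric(normalize_pattern(s$pattern$intensity)),
                 numeric(length(dataset$samples[[idx[1]]]$pattern$intensity)))
  structure(list(moduli = mods, idx = as.integer(idx), dataset = dataset),
            class = "nns_index")
}

#' @export
print.nns_index <- function(x, ...) {
  cat(sprintf("<nns_index> %d reference patterns of %d pixels\n",
              ncol(x$moduli), nrow(x$moduli)))
  invisible(x)
}

#' Query the NNS baseline
#'
#' Exhaustive scan minimizing [chi2_modulus()] between the query's
#' max-normalized modulus and every reference modulus.
#'
#' @param index An [nns_index()].
#' @param pattern A `diffraction_pattern` (or intensity matrix).
#' @return List: `match` (index into the dataset), `chi2` (best error),
#'   `amplitude`, `phase_scaled` (the matched ground truth), `chi2_all`.
#' @export
nns_query <- function(index, pattern) {
  I <- if (inherits(pattern, "diffraction_pattern")) pattern$intensity else pattern
  q <- as.numeric(normalize_pattern(I))
  if (length(q) != nrow(index$moduli)) stop("query shape does not match the library")
  d2 <- colSums((index$moduli - q)^2) / sum(q^2)
  j <- which.min(d2)
  s <- index$dataset$samples[[index$idx[j]]]
  list(match = index$idx[j], chi2 = d2[j],
       amplitude = s$target_amplitude,
       phase_scaled = s$target_phase_scaled,
       chi2_all = d2)
}

#' NNS errors over a set of query patterns
#'
#' @param index An [nns_index()].
#' @param dataset Dataset holding the queries.
#' @param idx Query sample indices (default: validation split).
#' @return Tibble with `sample`, `match`, `chi2_modulus`.
#' @export
nns_evaluate <- function(index, dataset, idx = dataset$split$validation) {
  rows <- lapply(idx, function(i) {
    r <- nns_query(index, dataset$samples[[i]]$pattern)
    c(sample = i, match = r$match, chi2_modulus = r$chi2)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
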