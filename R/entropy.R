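#' Occurrence probability of a region from its area
#'
#' The occurrence-probability model assigns each polygon x the probability
#' p(x) = 1/x with x the polygon's area in square pixels. The literal
#' model (`"inverse-area"`) does not sum to 1 across a region set by
#' design; the `"inverse-area-normalized"` variant rescales the
#' reciprocals to a proper distribution over the set being profiled, which
#' is the default for profile comparisons because entropy monotonicity in
#' beta holds only for normalized distributions.
#'
#' @param area Numeric vector of region areas, each at least 1 square
#'   pixel (a sub-pixel region signals a degenerate tiling and errors).
#' @param model `"inverse-area"` or `"inverse-area-normalized"`.
#' @return Probability vector, same length as `area`.
#' @export
#' @examples
#' region_probability(c(2, 3), "inverse-area")            # 1/2 1/3
#' region_probability(c(2, 2), "inverse-area-normalized") # 0.5 0.5
region_probability <- function(area,
                               model = c("inverse-area-normalized",
                                         "inverse-area")) {
  model <- match.arg(model)
  if (length(area) == 0L) stop_mnctess("empty area set", "empty_set")
  if (any(area < 1)) {
    stop_mnctess("region area < 1 square pixel: degenerate tiling",
                 "subpixel_region")
  }
  p <- 1 / area
  if (model == "inverse-area-normalized") p <- p / sum(p)
  p
}

#' Renyi entropy of a probability vector
#'
#' H_beta(X) = 1/(1 - beta) * log2( sum_i p_i^beta ), the one-parameter
#' generalization of Shannon entropy, in bits. The sum is evaluated in
#' log space, so large sets and large beta do not underflow. The vector
#' may be an unnormalized occurrence-probability vector (values in (0, 1]
#' that need not sum to 1), matching the literal inverse-area model.
#'
#' @param p Numeric vector of probabilities in (0, 1], non-empty.
#' @param beta Entropy order: positive and different from 1 (use
#'   [shannon_entropy()] for the beta -> 1 limit).
#' @return Entropy in bits.
#' @export
#' @examples
#' renyi_entropy(rep(1/8, 8), 2)        # 3 bits
#' renyi_entropy(c(1/2, 1/3), 2)        # log2(36/13), unnormalized model
renyi_entropy <- function(p, beta) {
  if (length(p) == 0L) stop_mnctess("empty probability vector", "empty_set")
  if (any(p <= 0 | p > 1)) {
    stop_mnctess("probabilities must lie in (0, 1]", "bad_probability")
  }
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0 || beta == 1) {
    stop_mnctess("beta must be > 0 and != 1", "bad_beta")
  }
  (1 / (1 - beta)) * logsumexp(beta * log(p)) / log(2)
}

#' Shannon entropy of a normalized probability vector
#'
#' -sum p_i log2 p_i, in bits; the beta -> 1 limit of Renyi entropy,
#' used as a property check on the Renyi implementation.
#'
#' @param p Probability vector summing to 1 (within 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (length(p) == 0L) stop_mnctess("empty probability vector", "empty_set")
  if (any(p <= 0 | p > 1)) {
    stop_mnctess("probabilities must lie in (0, 1]", "bad_probability")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_mnctess("Shannon entropy requires a normalized vector", "unnormalized")
  }
  -sum(p * log2(p))
}

#' Renyi entropy profile of MNC vs non-MNC region sets
#'
#' Splits the tiling's regions into X_MNC - every region belonging to any
#' maximal nucleus cluster (nucleus or adjacent) - and X_nonMNC, the
#' remaining regions, and computes the Renyi entropy of each set under the
#' area-based occurrence-probability model for every beta on the grid
#' (default 1.1 to 2.5 in steps of 0.1).
#'
#' @param tiling A [build_tessellation()] result.
#' @param mncs Maximal clusters, as from [find_maximal_nucleus_clusters()];
#'   computed from the tiling when omitted.
#' @param betas Strictly increasing grid of entropy orders, all positive
#'   and different from 1.
#' @param model Probability model passed to [region_probability()].
#' @return An `entropy_profile`: list with `profile` (tibble `beta`,
#'   `h_mnc`, `h_nonmnc` in bits), `model`, counts `n_mnc`/`n_nonmnc`, and
#'   the two area vectors.
#' @export
entropy_profile <- function(tiling, mncs = NULL,
                            betas = seq(1.1, 2.5, by = 0.1),
                            model = c("inverse-area-normalized",
                                      "inverse-area")) {
  model <- match.arg(model)
  if (is.null(mncs)) mncs <- find_maximal_nucleus_clusters(tiling)
  if (length(betas) == 0L || any(betas <= 0) || any(betas == 1) ||
      is.unsorted(betas, strictly = TRUE)) {
    stop_mnctess("betas must be strictly increasing, > 0 and != 1", "bad_beta")
  }
  ids_mnc <- sort(unique(c(mncs$nucleus_id, unlist(mncs$adjacent_ids))))
  ids_non <- setdiff(seq_along(tiling$regions), ids_mnc)
  if (length(ids_mnc) == 0L) stop_mnctess("tiling has no MNC regions", "empty_set")
  if (length(ids_non) == 0L) {
    stop_mnctess("every region belongs to a maximal cluster: empty complement",
                 "empty_set")
  }
  a_mnc <- tiling$areas[ids_mnc]
  a_non <- tiling$areas[ids_non]
  p_mnc <- region_probability(a_mnc, model)
  p_non <- region_probability(a_non, model)
  structure(list(
    profile = tibble(
      beta = betas,
      h_mnc = vapply(betas, function(b) renyi_entropy(p_mnc, b), numeric(1)),
      h_nonmnc = vapply(betas, function(b) renyi_entropy(p_non, b), numeric(1))
    ),
    model = model,
    n_mnc = length(ids_mnc), n_nonmnc = length(ids_non),
    areas_mnc = a_mnc, areas_nonmnc = a_non,
    mnc_ids = ids_mnc
  ), class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile> model %s; %d MNC vs %d non-MNC regions; beta in [%g, %g]\n",
              x$model, x$n_mnc, x$n_nonmnc,
              min(x$profile$beta), max(x$profile$beta)))
  print(x$profile, n = 5)
  invisible(x)
}

#' Tidy an entropy profile into long format
#'
#' @param x An `entropy_profile`.
#' @param ... Unused.
#' @return Tibble with columns `beta`, `set` (`"mnc"`/`"nonmnc"`),
#'   `entropy` (bits), `model`, `n`.
#' @method tidy entropy_profile
#' @export
tidy.entropy_profile <- function(x, ...) {
  tidyr::pivot_longer(x$profile, c("h_mnc", "h_nonmnc"),
                      names_to = "set", names_prefix = "h_",
                      values_to = "entropy") |>
    dplyr::mutate(model = x$model,
                  n = ifelse(.data$set == "mnc", x$n_mnc, x$n_nonmnc))
}

#' One-row summary of an entropy profile
#'
#' @param x An `entropy_profile`.
#' @param ... Unused.
#' @return Tibble: model, set sizes, mean areas, mean entropy gap
#'   (`h_mnc - h_nonmnc`), and whether `h_mnc > h_nonmnc` holds at every
#'   beta on the grid.
#' @method glance entropy_profile
#' @export
glance.entropy_profile <- function(x, ...) {
  tibble(model = x$model, n_mnc = x$n_mnc, n_nonmnc = x$n_nonmnc,
         mean_area_mnc = mean(x$areas_mnc),
         mean_area_nonmnc = mean(x$areas_nonmnc),
         mean_gap = mean(x$profile$h_mnc - x$profile$h_nonmnc),
         mnc_higher_all_beta = all(x$profile$h_mnc > x$profile$h_nonmnc))
}
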