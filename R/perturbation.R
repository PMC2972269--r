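#' Simulate a loss- or gain-of-function mutant
#'
#' Loss of function clamps the gene to 0, gain of function to 1; the clamp
#' applies from `t = 0` (the initial value is overridden too).  The clamped
#' model is searched exhaustively and the attractors are labeled by the
#' nearest wild-type cell-type profile (the clamped gene is ignored in the
#' match).
#'
#' @param model A `bnet`.
#' @param node Gene to perturb.
#' @param kind `"loss"` or `"gain"`.
#' @param profiles Optional reference profiles for labeling (e.g.
#'   [scn_reference_profiles()]).
#' @return An `attractor_set` of the mutant.
#' @export
simulate_mutant <- function(model, node, kind = c("loss", "gain"),
                            profiles = NULL) {
  kind <- match.arg(kind)
  mut <- clamp(model, node, if (kind == "loss") 0 else 1)
  aset <- find_attractors(mut)
  if (!is.null(profiles)) aset <- label_attractors(aset, profiles, exclude = node)
  aset
}

#' Mutant matrix: every gene, loss and gain
#'
#' Convenience wrapper running [simulate_mutant()] for every node in both
#' directions.
#'
#' @param model A `bnet`.
#' @param profiles Optional profiles for labeling.
#' @param kinds Perturbation kinds to include.
#' @return A tibble: `node`, `kind`, `n_attractors`, `attractors` (list of
#'   `attractor_set`s), `labels` (comma-separated per-attractor labels).
#' @export
mutant_matrix <- function(model, profiles = NULL, kinds = c("loss", "gain")) {
  grid <- tidyr::expand_grid(node = model$nodes, kind = kinds)
  sets <- purrr::map2(grid$node, grid$kind,
                      ~ simulate_mutant(model, .x, .y, profiles = profiles))
  grid |>
    dplyr::mutate(
      n_attractors = vapply(sets, n_attractors, integer(1)),
      labels = vapply(sets, function(a) paste(a$labels, collapse = ","), ""),
      attractors = sets
    )
}

#' Single-output rule-flip robustness scan
#'
#' Flips, one at a time, every output bit of every node's truth table,
#' recomputes the exhaustive attractor set of the altered network, and
#' classifies the flip as *unchanged* when the set of attractor states is
#' identical to the wild type (basin sizes are ignored).  The bit is restored
#' before the next flip.
#'
#' @param model A `bnet` small enough for exhaustive search per flip.
#' @return A `robustness_summary`: counts plus a per-flip tibble
#'   (`node`, `row`, `unchanged`).
#' @export
rule_flip_scan <- function(model) {
  stopifnot(inherits(model, "bnet"))
  wt_keys <- .attractor_keys(find_attractors(model, keep_assignment = FALSE))
  flips <- purrr::map_dfr(seq_along(model$rules), function(j) {
    r <- model$rules[[j]]
    purrr::map_dfr(seq_along(r$outputs), function(row) {
      alt <- model
      alt$rules[[j]]$outputs[row] <- 1L - alt$rules[[j]]$outputs[row]
      alt$rules[[j]]$expr <- NULL
      keys <- .attractor_keys(find_attractors(alt, keep_assignment = FALSE))
      tibble(node = r$target, row = row,
             unchanged = identical(keys, wt_keys))
    })
  })
  total <- nrow(flips)
  unchanged <- sum(flips$unchanged)
  structure(list(
    total_flips = total,
    unchanged = unchanged,
    changed = total - unchanged,
    fraction_unchanged = unchanged / total,
    flips = flips
  ), class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat("Rule-flip robustness scan:", x$total_flips, "single-bit flips\n")
  cat(sprintf("  unchanged attractor set: %d (%.1f%%)\n",
              x$unchanged, 100 * x$fraction_unchanged))
  cat(sprintf("  changed attractor set:   %d (%.1f%%)\n",
              x$changed, 100 * (1 - x$fraction_unchanged)))
  invisible(x)
}

#' @method tidy robustness_summary
#' @export
tidy.robustness_summary <- function(x, ...) x$flips

#' @method glance robustness_summary
#' @export
glance.robustness_summary <- function(x, ...) {
  tibble(total_flips = x$total_flips, unchanged = x$unchanged,
         changed = x$changed, fraction_unchanged = x$fraction_unchanged)
}

#' Empirical Derrida map of a Boolean network
#'
#' For each initial normalized Hamming distance class `d / N`, draws seeded
#' random state pairs at exactly that distance (a uniform state plus `d`
#' flipped distinct bits), advances both one synchronous step, and records the
#' mean normalized distance after the step.  A curve near the identity line at
#' small distances is the signature of critical dynamics.
#'
#' @param model A `bnet`.
#' @param n_pairs Pairs per distance class (default 10000).
#' @param seed Integer seed (required).
#' @param distances Integer Hamming distances to probe (default `1:N`).
#' @return A `derrida_curve`: tibble of points `h_t` (initial normalized
#'   distance), `h_t1` (mean next-step distance), `se` (standard error),
#'   plus `n_pairs` and `seed`.
#' @export
derrida_map <- function(model, n_pairs = 10000, seed = NULL, distances = NULL) {
  stopifnot(inherits(model, "bnet"))
  if (is.null(seed)) abort("derrida_map requires an integer seed")
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  N <- length(model$nodes)
  distances <- distances %||% seq_len(N)
  pts <- withr::with_seed(seed, {
    purrr::map_dfr(distances, function(d) {
      A <- matrix(sample(c(0L, 1L), n_pairs * N, replace = TRUE), n_pairs, N)
      B <- A
      # flip exactly d distinct positions per row
      ranks <- matrix(stats::runif(n_pairs * N), n_pairs, N)
      for (i in seq_len(n_pairs)) {
        pos <- order(ranks[i, ])[seq_len(d)]
        B[i, pos] <- 1L - B[i, pos]
      }
      h1 <- rowMeans(.step_matrix(model, A) != .step_matrix(model, B))
      tibble(d = d, h_t = d / N, h_t1 = mean(h1),
             se = stats::sd(h1) / sqrt(n_pairs))
    })
  })
  structure(list(points = pts, n_pairs = n_pairs, seed = as.integer(seed),
                 n_nodes = N),
            class = "derrida_curve")
}

#' @export
print.derrida_curve <- function(x, ...) {
  cat("Derrida map over", nrow(x$points), "distance classes (",
      x$n_pairs, "pairs each, seed", x$seed, ")\n")
  print(x$points)
  invisible(x)
}

#' @method tidy derrida_curve
#' @export
tidy.derrida_curve <- function(x, ...) x$points

#' Plot a Derrida curve against the identity line
#'
#' @param object A `derrida_curve`.
#' @param annealed Optional tibble with columns `h_t`, `h_t1` (e.g. from
#'   [annealed_derrida_curve()]) drawn as a reference curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot derrida_curve
#' @export
autoplot.derrida_curve <- function(object, annealed = NULL, ...) {
  p <- ggplot2::ggplot(object$points, ggplot2::aes(x = .data$h_t, y = .data$h_t1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "H(t)", y = "mean H(t+1)") +
    ggplot2::theme_minimal()
  if (!is.null(annealed)) {
    p <- p + ggplot2::geom_line(data = as_tibble(annealed), color = "red3")
  }
  p
}
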