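#' Generate a seeded random NK Boolean network
#'
#' Standard NK random Boolean network ensemble: every node receives `K`
#' distinct inputs drawn uniformly without replacement (self-inputs allowed)
#' and an independent random output column in which each truth-table row is 1
#' with probability `p`.  Identical seeds give identical networks.
#'
#' @param N Node count.
#' @param K In-degree per node (`0 <= K <= N`).
#' @param p Output bias, the probability a row outputs 1.
#' @param seed Integer seed (required).
#' @param node_names Optional node names (default `n1..nN`).
#' @return A `bnet`.
#' @export
random_network <- function(N, K, p = 0.5, seed = NULL, node_names = NULL) {
  if (is.null(seed)) abort("random_network requires an integer seed")
  if (K > N) abort("K must not exceed N")
  if (K < 0 || N < 1) abort("need N >= 1 and K >= 0")
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  nodes <- node_names %||% paste0("n", seq_len(N))
  withr::with_seed(seed, {
    rules <- tibble(
      target = nodes,
      inputs = lapply(seq_len(N), function(i) nodes[sample.int(N, K)]),
      outputs = lapply(seq_len(N), function(i) {
        as.integer(stats::runif(2^K) < p)
      })
    )
    build_network(rules, nodes = nodes)
  })
}

#' Annealed Derrida map for the NK ensemble
#'
#' Closed-form expectation of the one-step Derrida map under the annealed
#' approximation: `H(t+1) = 2 p (1 - p) * (1 - (1 - H(t))^K)`, with slope
#' `2 K p (1 - p)` at the origin (the criticality parameter).  This is the
#' independent analytic oracle for [derrida_map()] on networks from
#' [random_network()]; it assumes large `N` (input choices independent of the
#' flipped positions).
#'
#' @param K In-degree.
#' @param p Output bias.
#' @param h_t Initial normalized Hamming distances (default a fine grid).
#' @return A tibble with `h_t` and the expected `h_t1`.
#' @export
annealed_derrida_curve <- function(K, p, h_t = seq(0, 1, by = 0.01)) {
  if (K < 0) abort("K must be >= 0")
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  tibble(h_t = h_t, h_t1 = 2 * p * (1 - p) * (1 - (1 - h_t)^K))
}

#' Slope of the annealed Derrida map at the origin
#'
#' `2 K p (1 - p)`: below 1 ordered, 1 critical, above 1 chaotic.
#'
#' @inheritParams annealed_derrida_curve
#' @return Numeric scalar.
#' @export
derrida_slope <- function(K, p) 2 * K * p * (1 - p)
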