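# State <-> integer code helpers.  A state (x_1..x_N) is encoded MSB-first:
# code = sum_i x_i * 2^(N - i), so codes run 0 .. 2^N - 1 and the
# lexicographically smallest state has the smallest code.  Codes are exact in
# doubles for N <= 52.

#' Encode 0/1 states as integer codes
#'
#' @param states A 0/1 matrix with one state per row (or a single state vector).
#' @return Numeric vector of codes in `0 .. 2^N - 1`, most significant bit first.
#' @export
encode_states <- function(states) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  N <- ncol(states)
  as.vector(states %*% 2^((N - 1):0))
}

#' Decode integer codes to 0/1 states
#'
#' @param codes Numeric vector of state codes.
#' @param nodes Character vector of node names (sets N and the column names).
#' @return An integer 0/1 matrix, one state per row.
#' @export
decode_states <- function(codes, nodes) {
  N <- length(nodes)
  m <- vapply(seq_len(N), function(j) (codes %/% 2^(N - j)) %% 2,
              numeric(length(codes)))
  m <- matrix(as.integer(m), ncol = N)
  colnames(m) <- nodes
  m
}

.state_key <- function(state) paste(state, collapse = "")

# Canonicalize a cycle (matrix period x N): rotate so the lexicographically
# smallest state comes first.
.canonical_cycle <- function(states) {
  if (nrow(states) == 1L) return(states)
  keys <- apply(states, 1, .state_key)
  i <- which.min(keys)
  if (i > 1L) states <- states[c(i:nrow(states), 1:(i - 1L)), , drop = FALSE]
  states
}

.cycle_key <- function(states) paste(apply(states, 1, .state_key), collapse = "|")

# Seeded uniform random 0/1 matrix (n x N).
.random_states <- function(n, N, seed) {
  withr::with_seed(seed, {
    matrix(sample(c(0L, 1L), n * N, replace = TRUE), nrow = n, ncol = N)
  })
}
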