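#' Find the attractors of a synchronous Boolean network
#'
#' In `exhaustive` mode every one of the `2^N` initial configurations is
#' followed to its attractor (fixed point or cycle of any period), giving exact
#' basin sizes.  In `sampled` mode `n_samples` seeded uniform random initial
#' states are followed instead; the returned attractor set is then a subset of
#' the exhaustive one and `basin_counts` counts sampled visits.  Clamped nodes
#' are overridden from `t = 0` onwards, so states that disagree with a clamp
#' are projected onto their clamped version before iteration.
#'
#' @param model A `bnet`.
#' @param mode `"exhaustive"` (default, requires `N <= exhaustive_cap`) or
#'   `"sampled"`.
#' @param n_samples Number of sampled initial states (sampled mode).
#' @param seed Integer seed (required in sampled mode).
#' @param exhaustive_cap Largest `N` allowed for exhaustive enumeration.
#' @param max_steps Safety cap on trajectory length (the state space guarantees
#'   termination within `2^N` steps).
#' @param keep_assignment In exhaustive mode, keep the per-initial-state
#'   attractor assignment (enables basin membership queries).  Defaults to
#'   `TRUE` for `N <= 16`.
#' @return An `attractor_set`: attractor state matrices (canonicalized so the
#'   lexicographically smallest state comes first), periods, basin counts,
#'   exploration mode, and space/sample size.
#' @examples
#' net <- build_network(c("A = A"))
#' find_attractors(net)
#' @export
find_attractors <- function(model, mode = c("exhaustive", "sampled"),
                            n_samples = 10000, seed = NULL,
                            exhaustive_cap = 24, max_steps = 10000,
                            keep_assignment = NULL) {
  stopifnot(inherits(model, "bnet"))
  mode <- match.arg(mode)
  N <- length(model$nodes)
  if (mode == "exhaustive") {
    if (N > exhaustive_cap) {
      abort(paste0("N = ", N, " exceeds the exhaustive cap (", exhaustive_cap,
                   "); use mode = \"sampled\" with a seed"))
    }
    keep_assignment <- keep_assignment %||% (N <= 16)
    .attractors_exhaustive(model, keep_assignment)
  } else {
    if (is.null(seed)) abort("sampled mode requires an integer seed")
    if (n_samples < 1) abort("n_samples must be >= 1")
    .attractors_sampled(model, n_samples, seed, max_steps)
  }
}

.attractors_exhaustive <- function(model, keep_assignment) {
  N <- length(model$nodes)
  M <- 2^N
  codes <- 0:(M - 1)
  succ <- numeric(M)
  chunk <- 2^16
  for (lo in seq(1, M, by = chunk)) {
    hi <- min(lo + chunk - 1, M)
    S <- decode_states(codes[lo:hi], model$nodes)
    succ[lo:hi] <- encode_states(.step_matrix(model, S)) + 1
  }
  # Clamps replace the initial value too: each raw initial state starts its
  # trajectory from its clamped projection.
  if (length(model$clamps)) {
    S0 <- decode_states(codes, model$nodes)
    start <- encode_states(.apply_clamps(model, S0)) + 1
  } else {
    start <- seq_len(M)
  }

  comp <- integer(M)   # attractor id per state (0 = not yet resolved)
  pos <- integer(M)    # position on the current walk
  cycles <- list()
  n_att <- 0L
  for (s0 in seq_len(M)) {
    if (comp[s0]) next
    path <- integer(0)
    cur <- s0
    repeat {
      if (comp[cur]) { id <- comp[cur]; break }
      if (pos[cur]) {
        cyc <- path[pos[cur]:length(path)]
        n_att <- n_att + 1L
        cycles[[n_att]] <- cyc
        id <- n_att
        break
      }
      path[length(path) + 1L] <- cur
      pos[cur] <- length(path)
      cur <- succ[cur]
    }
    comp[path] <- id
    pos[path] <- 0L
  }

  atts <- lapply(cycles, function(cyc) {
    .canonical_cycle(decode_states(cyc - 1, model$nodes))
  })
  assignment <- comp[start]
  basin <- tabulate(assignment, nbins = n_att)
  ord <- order(vapply(atts, function(a) encode_states(a[1, , drop = FALSE]), numeric(1)))
  atts <- atts[ord]
  basin <- basin[ord]
  assignment <- match(assignment, ord)
  new_attractor_set(
    attractors = atts, basin_counts = basin, nodes = model$nodes,
    mode = "exhaustive", space_size = M, seed = NA_integer_,
    assignment = if (keep_assignment) assignment else NULL
  )
}

.attractors_sampled <- function(model, n_samples, seed, max_steps) {
  N <- length(model$nodes)
  S0 <- .apply_clamps(model, .random_states(n_samples, N, seed))
  .batch_attractors(model, S0, max_steps, seed = as.integer(seed))
}

# Follow a batch of initial states (rows of S0) to their attractors.
# Fixed points are frozen as soon as the state repeats; longer cycles are
# caught with per-row Brent checkpointing and extracted individually.
.batch_attractors <- function(model, S0, max_steps = 10000, seed = NA_integer_) {
  att_key <- character(0)
  atts <- list()
  counts <- numeric(0)
  record <- function(states) {
    states <- .canonical_cycle(states)
    key <- .cycle_key(states)
    i <- match(key, att_key)
    if (is.na(i)) {
      att_key <<- c(att_key, key)
      atts[[length(atts) + 1L]] <<- states
      counts <<- c(counts, 0)
      i <- length(atts)
    }
    counts[i] <<- counts[i] + 1
    invisible(i)
  }

  cur <- S0
  active <- seq_len(nrow(cur))
  chk <- cur                 # Brent checkpoints (per active row)
  power <- 1L
  since <- 0L
  steps <- 0L
  while (length(active) && steps < max_steps) {
    nxt <- .step_matrix(model, cur)
    fixed <- rowSums(nxt != cur) == 0
    if (any(fixed)) {
      for (i in which(fixed)) record(cur[i, , drop = FALSE])
    }
    cycled <- !fixed & rowSums(nxt != chk) == 0
    if (any(cycled)) {
      for (i in which(cycled)) {
        record(.extract_cycle(model, nxt[i, ], max_steps))
      }
    }
    done <- fixed | cycled
    keep <- !done
    cur <- nxt[keep, , drop = FALSE]
    chk <- chk[keep, , drop = FALSE]
    active <- active[keep]
    steps <- steps + 1L
    since <- since + 1L
    if (since == power) {
      chk <- cur
      power <- power * 2L
      since <- 0L
    }
  }
  if (length(active)) {
    abort("trajectories failed to reach an attractor within max_steps")
  }
  ord <- order(vapply(atts, function(a) encode_states(a[1, , drop = FALSE]), numeric(1)))
  new_attractor_set(
    attractors = atts[ord], basin_counts = counts[ord], nodes = model$nodes,
    mode = "sampled", space_size = nrow(S0), seed = seed,
    assignment = NULL
  )
}

# Walk a single state known to lie on a cycle until it recurs.
.extract_cycle <- function(model, state, max_steps) {
  start_key <- .state_key(state)
  states <- matrix(state, nrow = 1)
  cur <- state
  for (i in seq_len(max_steps)) {
    cur <- sync_step(model, cur)
    if (.state_key(cur) == start_key) return(states)
    states <- rbind(states, cur)
  }
  abort("cycle extraction exceeded max_steps")
}

new_attractor_set <- function(attractors, basin_counts, nodes, mode,
                              space_size, seed, assignment = NULL,
                              labels = NULL) {
  attractors <- lapply(attractors, function(a) {
    colnames(a) <- nodes
    a
  })
  structure(list(
    attractors = attractors,
    periods = vapply(attractors, nrow, integer(1)),
    basin_counts = as.numeric(basin_counts),
    nodes = nodes,
    mode = mode,
    space_size = space_size,
    seed = seed,
    assignment = assignment,
    labels = labels %||% rep(NA_character_, length(attractors))
  ), class = "attractor_set")
}

#' Number of attractors
#' @param aset An `attractor_set`.
#' @return Integer count.
#' @export
n_attractors <- function(aset) length(aset$attractors)

#' @export
print.attractor_set <- function(x, ...) {
  cat(length(x$attractors), "attractor(s) over", length(x$nodes), "nodes (",
      x$mode, "mode,", format(x$space_size, big.mark = ","), "initial states )\n")
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy an attractor set
#'
#' @param x An `attractor_set`.
#' @param ... Unused.
#' @return A tibble with one row per attractor state: `attractor`, `label`,
#'   `period`, `phase` (position within the cycle), `basin`, `basin_fraction`
#'   and one 0/1 column per node.
#' @method tidy attractor_set
#' @export
tidy.attractor_set <- function(x, ...) {
  rows <- purrr::map_dfr(seq_along(x$attractors), function(i) {
    a <- x$attractors[[i]]
    dplyr::bind_cols(
      tibble(attractor = i, label = x$labels[i], period = nrow(a),
             phase = seq_len(nrow(a)), basin = x$basin_counts[i],
             basin_fraction = x$basin_counts[i] / x$space_size),
      as_tibble(a)
    )
  })
  rows
}

#' @method glance attractor_set
#' @export
glance.attractor_set <- function(x, ...) {
  tibble(
    n_attractors = length(x$attractors),
    n_fixed_points = sum(x$periods == 1L),
    max_period = max(x$periods),
    mode = x$mode,
    space_size = x$space_size,
    basin_total = sum(x$basin_counts)
  )
}

#' Plot an attractor set as a state heatmap
#'
#' @param object An `attractor_set`.
#' @param ... Unused.
#' @return A ggplot: nodes on the x axis, attractor states on the y axis,
#'   fill = on/off, faceted is not needed since cycles are stacked by phase.
#' @method autoplot attractor_set
#' @export
autoplot.attractor_set <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(row = paste0("#", .data$attractor,
                               ifelse(.data$period > 1, paste0(".", .data$phase), ""),
                               ifelse(is.na(.data$label), "", paste0(" ", .data$label)))) |>
    tidyr::pivot_longer(dplyr::all_of(object$nodes),
                        names_to = "node", values_to = "state")
  df$node <- factor(df$node, levels = object$nodes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$row,
                                   fill = factor(.data$state))) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               name = "state") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Label attractors by matching reference expression profiles
#'
#' Each attractor (fixed points only) is compared to the reference profiles
#' over their shared, non-excluded nodes.  An exact match assigns the profile's
#' cell-type label; otherwise the nearest profile (minimum Hamming distance) is
#' reported with its distance, or `NA` on a tie.
#'
#' @param aset An `attractor_set`.
#' @param profiles A data frame with a `cell_type` column plus one 0/1 column
#'   per node (e.g. [scn_reference_profiles()]).
#' @param exclude Node names to ignore in the comparison (e.g. a clamped
#'   mutant gene).
#' @return `aset` with `labels` filled; the tibble from [tidy()] then carries
#'   them.  Attributes `label_distance` (per attractor) records the Hamming
#'   distance to the assigned profile.
#' @export
label_attractors <- function(aset, profiles, exclude = character(0)) {
  stopifnot(inherits(aset, "attractor_set"))
  if (isTRUE(attr(profiles, "vascular_clex_free")) && "CLEX" %in% names(profiles)) {
    vasc0 <- profiles[profiles$cell_type == "vascular", ]
    vasc0$CLEX <- 0
    profiles <- dplyr::bind_rows(profiles, vasc0)
  }
  profiles <- as.data.frame(profiles)
  shared <- setdiff(intersect(aset$nodes, names(profiles)), exclude)
  if (!length(shared)) abort("no shared nodes between attractors and profiles")
  pm <- as.matrix(profiles[, shared, drop = FALSE])
  labels <- rep(NA_character_, length(aset$attractors))
  dist <- rep(NA_integer_, length(aset$attractors))
  for (i in seq_along(aset$attractors)) {
    a <- aset$attractors[[i]]
    if (nrow(a) != 1L) next
    d <- rowSums(sweep(pm, 2, a[1, shared], `!=`))
    j <- which(d == min(d))
    # ties between rows of the same cell type (e.g. vascular with either
    # CLEX value) still label unambiguously
    if (length(unique(profiles$cell_type[j])) == 1L) {
      labels[i] <- profiles$cell_type[j[1]]
      dist[i] <- d[j[1]]
    }
  }
  aset$labels <- labels
  attr(aset, "label_distance") <- dist
  aset
}

#' Basin membership of every initial configuration
#'
#' Only available for exhaustive searches run with `keep_assignment = TRUE`.
#'
#' @param aset An `attractor_set`.
#' @return A tibble with one row per initial configuration: its 0/1 node
#'   columns and the `attractor` index it reaches.
#' @export
basin_membership <- function(aset) {
  stopifnot(inherits(aset, "attractor_set"))
  if (is.null(aset$assignment)) {
    abort("basin membership was not kept; rerun exhaustively with keep_assignment = TRUE")
  }
  S <- decode_states(seq_along(aset$assignment) - 1, aset$nodes)
  dplyr::bind_cols(as_tibble(S), tibble(attractor = aset$assignment))
}

# Canonical state-set keys of an attractor set, optionally projected onto a
# subset of nodes (used for "same attractors" comparisons).
.attractor_keys <- function(aset, exclude = character(0)) {
  keep <- setdiff(aset$nodes, exclude)
  ji <- match(keep, aset$nodes)
  sort(vapply(aset$attractors, function(a) {
    .cycle_key(.canonical_cycle(a[, ji, drop = FALSE]))
  }, ""))
}

#' Compare two attractor sets as sets of attractor states
#'
#' Basin sizes are ignored; two sets are equal when their (canonicalized)
#' attractor state sets coincide after dropping `exclude` nodes.
#'
#' @param a,b `attractor_set` objects over the same node universe.
#' @param exclude Node names to ignore (e.g. a clamped gene).
#' @return Logical scalar.
#' @export
same_attractors <- function(a, b, exclude = character(0)) {
  identical(.attractor_keys(a, exclude), .attractor_keys(b, exclude))
}

#' Follow a single trajectory to its attractor
#'
#' @param model A `bnet`.
#' @param state Initial 0/1 state (clamps are applied at `t = 0`).
#' @param max_steps Safety cap.
#' @return A list with `states` (matrix, the visited states from `t = 0` up to
#'   and including the first state of the attractor), `transient_length`
#'   (steps before entering the attractor) and `attractor` (canonical cycle
#'   matrix).
#' @export
simulate_trajectory <- function(model, state, max_steps = 10000) {
  stopifnot(inherits(model, "bnet"))
  N <- length(model$nodes)
  if (length(state) != N) abort("state length must equal N")
  cur <- drop(.apply_clamps(model, matrix(as.integer(state), nrow = 1)))
  seen <- new.env(parent = emptyenv())
  path <- matrix(cur, nrow = 1)
  assign(.state_key(cur), 1L, envir = seen)
  for (t in seq_len(max_steps)) {
    cur <- sync_step(model, cur)
    key <- .state_key(cur)
    hit <- mget(key, envir = seen, ifnotfound = list(NULL))[[1]]
    if (!is.null(hit)) {
      cycle <- path[hit:nrow(path), , drop = FALSE]
      colnames(cycle) <- model$nodes
      colnames(path) <- model$nodes
      return(list(states = rbind(path, cur),
                  transient_length = hit - 1L,
                  attractor = .canonical_cycle(cycle),
                  period = nrow(cycle)))
    }
    path <- rbind(path, cur)
    assign(key, nrow(path), envir = seen)
  }
  abort("trajectory did not close within max_steps")
}
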