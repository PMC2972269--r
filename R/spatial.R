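#' Default mobility specification of the four-cell niche
#'
#' Cell layout: V (vascular initials), C (cortex-endodermis initials),
#' Q (quiescent center), E (columella/epidermis initials), with undirected
#' adjacency V–Q, V–C, C–Q, Q–E reflecting root anatomy.  Four intracellular
#' components act non-cell-autonomously: SHR protein moves between neighbours
#' but only out of cells without SCR (SCR sequesters it), auxin flows
#' acropetally (sources in V and C, then Q, then E), and WOX5 and CLEX act at
#' long range across the whole niche.
#'
#' @return A `mobility_spec` list with `cells`, `adjacency` (list of cell
#'   pairs) and `mobile` node names.
#' @export
scn_mobility_spec <- function() {
  structure(list(
    cells = c("V", "C", "Q", "E"),
    adjacency = list(c("V", "Q"), c("V", "C"), c("C", "Q"), c("Q", "E")),
    mobile = c("SHR", "auxin", "WOX5", "CLEX")
  ), class = "mobility_spec")
}

.check_mobility <- function(mobility) {
  ok <- is.list(mobility) &&
    setequal(mobility$cells, c("V", "C", "Q", "E")) &&
    length(mobility$adjacency) == 4 &&
    all(vapply(mobility$adjacency, length, integer(1)) == 2) &&
    setequal(vapply(mobility$adjacency, function(p) paste(sort(p), collapse = "-"), ""),
             c("Q-V", "C-V", "C-Q", "E-Q")) &&
    setequal(mobility$mobile, c("SHR", "auxin", "WOX5", "CLEX"))
  if (!ok) abort("malformed mobility spec: need cells V,C,Q,E, adjacency {V-Q, V-C, C-Q, Q-E} and mobile nodes SHR, auxin, WOX5, CLEX")
  invisible(TRUE)
}

.meta_var <- function(node, cell) paste0(node, "_", cell)

#' Build the four-cell coupled meta-network
#'
#' Couples four copies of single-cell model B' — one per niche position — into
#' a 40-variable synchronous network whose rules embed the mobility terms:
#' SHR enters a cell from any neighbour that expresses SHR without SCR
#' (`SHR_V` is clamped on, it is the source); auxin is clamped on in V and C
#' and flows to Q and then E; WOX5 in the QC escapes CLEX repression (the
#' local activator loop) while everywhere else WOX5 is shut off by CLEX from
#' any cell (long-range inhibition); WOX5 activates CLEX non-cell-autonomously
#' outside the QC only, and CLEX is structurally absent from the QC.  The only
#' topological change relative to single-cell B' is that SCR transcription is
#' impossible in the vascular initials (`SCR_V` clamped off).
#'
#' @param variant Must be `"B_prime"` (the other variants are rejected).
#' @param mobility A mobility spec, [scn_mobility_spec()] by default.
#' @return A `meta_grn` (also a `bnet`) over variables named `node_cell`,
#'   grouped by cell in the order V, C, Q, E.
#' @export
build_meta_grn <- function(variant = "B_prime", mobility = scn_mobility_spec()) {
  if (!identical(variant, "B_prime")) {
    abort("the coupled meta-network is defined for variant B_prime only")
  }
  .check_mobility(mobility)
  cells <- c("V", "C", "Q", "E")
  neigh <- lapply(stats::setNames(cells, cells), function(x) {
    unique(unlist(lapply(mobility$adjacency, function(p) {
      if (x %in% p) setdiff(p, x)
    })))
  })
  any_wox5 <- paste(vapply(cells, function(x) .meta_var("WOX5", x), ""),
                    collapse = " OR ")
  any_clex <- paste(vapply(cells, function(x) .meta_var("CLEX", x), ""),
                    collapse = " OR ")
  v <- .meta_var

  rules <- character(0)
  for (x in cells) {
    shr_rule <- if (x == "V") {
      paste0(v("SHR", x), " = ", v("SHR", x))
    } else {
      terms <- vapply(neigh[[x]], function(y) {
        paste0("(", v("SHR", y), " AND NOT ", v("SCR", y), ")")
      }, "")
      paste0(v("SHR", x), " = ", paste(terms, collapse = " OR "))
    }
    auxin_rule <- switch(x,
      V = paste0(v("auxin", x), " = 1"),
      C = paste0(v("auxin", x), " = 1"),
      Q = paste0(v("auxin", "Q"), " = ", v("auxin", "V"), " OR ", v("auxin", "C")),
      E = paste0(v("auxin", "E"), " = ", v("auxin", "Q"))
    )
    scr_rule <- if (x == "V") {
      paste0(v("SCR", x), " = 0")
    } else {
      paste0(v("SCR", x), " = ", v("SHR", x), " AND ", v("SCR", x),
             " AND (", v("JKD", x), " OR NOT ", v("MGP", x),
             " OR (", v("MGP", x), " AND NOT ", v("JKD", x), "))")
    }
    wox5_rule <- if (x == "Q") {
      paste0(v("WOX5", x), " = ", v("ARF", x), " AND ", v("SHR", x),
             " AND ", v("SCR", x))
    } else {
      paste0(v("WOX5", x), " = ", v("ARF", x), " AND ", v("SHR", x),
             " AND ", v("SCR", x), " AND NOT (", any_clex, ")")
    }
    clex_rule <- if (x == "Q") {
      paste0(v("CLEX", x), " = 0")
    } else {
      paste0(v("CLEX", x), " = ", v("SHR", x), " AND (", v("MGP", x),
             " OR ", v("CLEX", x), " OR ", any_wox5, ")")
    }
    rules <- c(rules,
      paste0(v("PLT", x), " = ", v("ARF", x)),
      auxin_rule,
      paste0(v("ARF", x), " = NOT ", v("AuxIAA", x)),
      paste0(v("AuxIAA", x), " = NOT (", v("auxin", x), " OR ", v("WOX5", x), ")"),
      shr_rule,
      scr_rule,
      paste0(v("JKD", x), " = ", v("SHR", x), " AND ", v("SCR", x)),
      paste0(v("MGP", x), " = ", v("SHR", x), " AND ", v("SCR", x),
             " AND NOT ", v("WOX5", x)),
      wox5_rule,
      clex_rule
    )
  }
  cell_nodes <- .scn_node_order("B_prime")
  node_order <- unlist(lapply(cells, function(x) vapply(cell_nodes, v, "", cell = x)))
  net <- build_network(parse_rules(rules), nodes = node_order)
  net <- clamp(net, "SHR_V", 1)
  net <- clamp(net, "SCR_V", 0)
  net <- clamp(net, "auxin_V", 1)
  net <- clamp(net, "auxin_C", 1)
  net$cells <- cells
  net$cell_nodes <- cell_nodes
  class(net) <- c("meta_grn", "bnet")
  net
}

.scr_force_idx <- function(meta) {
  idx <- match(vapply(meta$cells, function(x) .meta_var("SCR", x), ""),
               meta$nodes)
  # clamped SCR variables (SCR_V, or a mutant clamp) are never forced
  idx[!meta$nodes[idx] %in% names(meta$clamps)]
}

# Apply clamps and, under the convention, force unclamped SCR variables on.
.spatial_initial <- function(meta, S, scr_convention) {
  S <- .apply_clamps(meta, S)
  if (scr_convention == "on") {
    for (j in .scr_force_idx(meta)) S[, j] <- 1L
  }
  S
}

# Advance the forced-SCR step: states at t=1 with SCR held on.
.spatial_after_convention <- function(meta, S0, scr_convention) {
  S <- .spatial_initial(meta, S0, scr_convention)
  if (scr_convention == "on") {
    S <- .step_matrix(meta, S)
    for (j in .scr_force_idx(meta)) S[, j] <- 1L
  }
  S
}

#' Run the coupled meta-network from one initial configuration
#'
#' Under the SCR initialization convention (`scr_convention = "on"`), every
#' unclamped SCR variable is forced on at `t = 0` and `t = 1` — standing in
#' for the basal SCR expression a Boolean model cannot represent — after which
#' SCR follows its rule.  The trajectory is then iterated to its attractor.
#'
#' @param meta A `meta_grn`.
#' @param initial 0/1 state over the 40 variables.
#' @param scr_convention `"on"` (default) or `"off"`.
#' @param max_steps Safety cap.
#' @return A list with `trajectory` (states matrix from `t = 0`),
#'   `attractor` (canonical cycle matrix), `period`, and `pattern` (the
#'   per-cell projection with cell-type labels, see [spatial_pattern()]).
#' @export
run_spatial <- function(meta, initial, scr_convention = c("on", "off"),
                        max_steps = 10000) {
  stopifnot(inherits(meta, "meta_grn"))
  scr_convention <- match.arg(scr_convention)
  if (length(initial) != length(meta$nodes)) {
    abort("initial state must cover all 40 variables")
  }
  s0 <- drop(.spatial_initial(meta, matrix(as.integer(initial), nrow = 1),
                              scr_convention))
  s1 <- drop(.spatial_after_convention(meta, matrix(as.integer(initial), nrow = 1),
                                       scr_convention))
  traj <- simulate_trajectory(meta, s1, max_steps = max_steps)
  states <- if (scr_convention == "on") {
    rbind(s0, traj$states)
  } else {
    traj$states
  }
  colnames(states) <- meta$nodes
  list(trajectory = states,
       attractor = traj$attractor,
       period = traj$period,
       pattern = spatial_pattern(meta, traj$attractor))
}

#' Per-cell projection and labeling of a meta-network state
#'
#' Projects a 40-variable state onto each cell's 10 intracellular nodes and
#' labels each cell by exact match to the single-cell reference profiles
#' (vascular matches with either CLEX value; `exclude` nodes are ignored, e.g.
#' a clamped mutant gene).
#'
#' @param meta A `meta_grn`.
#' @param state A state vector over the meta variables, or a 1-row matrix
#'   (fixed-point attractor).
#' @param exclude Intracellular node names ignored in the match.
#' @return A `spatial_pattern` tibble: `cell`, `label`, plus the 10 node
#'   columns.
#' @export
spatial_pattern <- function(meta, state, exclude = character(0)) {
  stopifnot(inherits(meta, "meta_grn"))
  if (is.matrix(state)) {
    if (nrow(state) != 1) abort("spatial_pattern expects a fixed-point state")
    state <- drop(state)
  }
  expected <- scn_expected_attractors("B_prime")
  keep <- setdiff(meta$cell_nodes, exclude)
  exp_keys <- apply(as.matrix(expected[, keep, drop = FALSE]), 1, .state_key)
  rows <- purrr::map_dfr(meta$cells, function(x) {
    idx <- match(vapply(meta$cell_nodes, .meta_var, "", cell = x), meta$nodes)
    proj <- stats::setNames(as.integer(state[idx]), meta$cell_nodes)
    j <- match(.state_key(proj[keep]), exp_keys)
    dplyr::bind_cols(
      tibble(cell = x,
             label = if (is.na(j)) NA_character_ else expected$cell_type[j]),
      as_tibble(as.list(proj))
    )
  })
  structure(rows, class = c("spatial_pattern", class(rows)))
}

#' Sampled global attractor search of the meta-network
#'
#' Follows `n_samples` seeded uniform random 40-bit initial configurations
#' (full enumeration of the `2^40` space is out of reach) through
#' [run_spatial()] dynamics and returns the distinct attractors reached.
#'
#' @param meta A `meta_grn`.
#' @param n_samples Number of initial states (default 100000).
#' @param seed Integer seed (required).
#' @param scr_convention `"on"` or `"off"`.
#' @param max_steps Safety cap per trajectory.
#' @return An `attractor_set` over the 40 variables.
#' @export
find_global_attractors <- function(meta, n_samples = 100000, seed = NULL,
                                   scr_convention = c("on", "off"),
                                   max_steps = 10000) {
  stopifnot(inherits(meta, "meta_grn"))
  scr_convention <- match.arg(scr_convention)
  if (is.null(seed)) abort("find_global_attractors requires an integer seed")
  if (n_samples < 1) abort("n_samples must be >= 1")
  S0 <- .random_states(n_samples, length(meta$nodes), seed)
  S1 <- .spatial_after_convention(meta, S0, scr_convention)
  .batch_attractors(meta, S1, max_steps, seed = as.integer(seed))
}

#' Simulate a spatial mutant
#'
#' Clamps an intracellular gene in all four cells (loss -> 0, gain -> 1) and
#' samples the global attractors under both SCR-initialization conventions,
#' reporting each run and their union: the gain-of-SHR phenotype (two
#' alternative columella/epidermis outcomes) is only reachable when SCR may
#' start off, while the convention-on run is the canonical wild-type-like
#' regime.
#'
#' @param meta A `meta_grn`.
#' @param node Intracellular node name (e.g. `"SCR"`).
#' @param kind `"loss"` or `"gain"`.
#' @param n_samples Samples per convention.
#' @param seed Integer seed.
#' @param conventions Which SCR conventions to run.
#' @return A `spatial_mutant` list: `node`, `kind`, `runs` (named list of
#'   `attractor_set`s per convention), `patterns` (tibble of distinct per-cell
#'   label patterns across the union, with `convention` provenance).
#' @export
simulate_spatial_mutant <- function(meta, node, kind = c("loss", "gain"),
                                    n_samples = 20000, seed = NULL,
                                    conventions = c("on", "off")) {
  stopifnot(inherits(meta, "meta_grn"))
  kind <- match.arg(kind)
  if (!node %in% meta$cell_nodes) {
    abort(paste0("unknown intracellular node: ", node))
  }
  if (is.null(seed)) abort("simulate_spatial_mutant requires an integer seed")
  value <- if (kind == "loss") 0 else 1
  mut <- meta
  for (x in meta$cells) mut <- clamp(mut, .meta_var(node, x), value)
  runs <- lapply(stats::setNames(conventions, conventions), function(cv) {
    find_global_attractors(mut, n_samples = n_samples, seed = seed,
                           scr_convention = cv)
  })
  patterns <- purrr::map_dfr(names(runs), function(cv) {
    aset <- runs[[cv]]
    purrr::map_dfr(seq_along(aset$attractors), function(i) {
      a <- aset$attractors[[i]]
      if (nrow(a) != 1) {
        return(tibble(convention = cv, attractor = i, period = nrow(a)))
      }
      pat <- spatial_pattern(mut, a, exclude = node)
      tibble(convention = cv, attractor = i, period = 1L,
             V = pat$label[pat$cell == "V"], C = pat$label[pat$cell == "C"],
             Q = pat$label[pat$cell == "Q"], E = pat$label[pat$cell == "E"],
             basin = aset$basin_counts[i],
             key = .state_key(a[1, ]))
    })
  })
  structure(list(node = node, kind = kind, model = mut,
                 runs = runs, patterns = patterns),
            class = "spatial_mutant")
}

#' @export
print.spatial_mutant <- function(x, ...) {
  cat("Spatial", x$kind, "mutant of", x$node, "\n")
  print(x$patterns)
  invisible(x)
}

#' Continuous check of the spatial model
#'
#' Converts the meta-network to its logistic ODE counterpart and integrates it
#' from seeded random interior points whose SCR levels start at 1 (the
#' continuous analogue of the SCR initialization convention; clamped levels
#' stay fixed).  Each terminal state is rounded and compared to the discrete
#' global attractor.
#'
#' @param meta A `meta_grn`.
#' @param n_starts Number of random interior starts (default 100).
#' @param seed Integer seed.
#' @param h Activation steepness.
#' @param t_end Integration horizon.
#' @return A tibble with one row per start: `start`, `matches_discrete`, and
#'   the rounded terminal state columns.
#' @export
spatial_continuous_check <- function(meta, n_starts = 100, seed = NULL,
                                     h = 50, t_end = 100) {
  stopifnot(inherits(meta, "meta_grn"))
  if (is.null(seed)) abort("spatial_continuous_check requires an integer seed")
  cm <- to_continuous(meta, h = h)
  N <- length(meta$nodes)
  scr_idx <- match(vapply(meta$cells, function(x) .meta_var("SCR", x), ""),
                   meta$nodes)
  scr_idx <- scr_idx[!meta$nodes[scr_idx] %in% names(meta$clamps)]
  X0 <- withr::with_seed(seed, matrix(stats::runif(n_starts * N), n_starts, N))
  X0[, scr_idx] <- 1
  # discrete reference attractor
  disc <- run_spatial(meta, rep(0L, N), scr_convention = "on")$attractor
  ref_key <- .state_key(disc[1, ])
  purrr::map_dfr(seq_len(n_starts), function(i) {
    term <- terminal_state(integrate_grn(cm, X0[i, ], t_end = t_end, n_out = 2,
                                         rtol = 1e-6, atol = 1e-8))
    rounded <- round_state(term)
    dplyr::bind_cols(
      tibble(start = i, matches_discrete = .state_key(rounded) == ref_key),
      as_tibble(as.list(stats::setNames(rounded, meta$nodes)))
    )
  })
}

#' Plot a spatial pattern
#'
#' @param object A `spatial_pattern`.
#' @param ... Unused.
#' @return A ggplot tile map of the four cells' gene states.
#' @method autoplot spatial_pattern
#' @export
autoplot.spatial_pattern <- function(object, ...) {
  nodes <- setdiff(names(object), c("cell", "label"))
  df <- tidyr::pivot_longer(object, dplyr::all_of(nodes),
                            names_to = "node", values_to = "state")
  df$node <- factor(df$node, levels = nodes)
  df$cell <- factor(df$cell, levels = c("V", "C", "Q", "E"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$cell,
                                   fill = factor(.data$state))) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               name = "state") +
    ggplot2::labs(x = NULL, y = "cell") +
    ggplot2::theme_minimal()
}
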