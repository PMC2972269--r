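#' Logistic activation function
#'
#' `f(w) = 1 / (1 + exp(-h (w - w_thr)))`: a differentiable step that tends to
#' the Heaviside function `Theta(w - w_thr)` as `h` grows; `f(w_thr) = 1/2`
#' for any steepness.
#'
#' @param w Input level(s) in `[0, 1]`.
#' @param h Activation steepness (`> 0`).
#' @param w_thr Activation threshold (default 1/2).
#' @return Activation level(s) in `(0, 1)`.
#' @export
activation_level <- function(w, h, w_thr = 0.5) {
  if (any(h <= 0)) abort("h must be > 0")
  stats::plogis(h * (w - w_thr))
}

# Environment in which logical connectives act as fuzzy operators on [0,1]:
# AND -> min, OR -> max, NOT -> 1 - x.
.fuzzy_ops_env <- function() {
  e <- new.env(parent = baseenv())
  assign("&", function(a, b) pmin(a, b), envir = e)
  assign("|", function(a, b) pmax(a, b), envir = e)
  assign("!", function(a) 1 - a, envir = e)
  e
}

#' Convert a Boolean network to its logistic ODE counterpart
#'
#' Builds the Glass-type continuous system
#' `dX_k/dt = f[w_k(X)] - gamma_k X_k` where `w_k` is a structural fuzzy
#' rendering of node `k`'s logical rule (AND -> min, OR -> max,
#' NOT -> `1 - x`, constants -> 0/1) and `f` is [activation_level()].  On
#' Boolean corners `w_k` coincides with the Boolean rule output.  Rules parsed
#' from expressions keep their structure; rules known only as truth tables are
#' rendered through their disjunctive normal form.  Clamped nodes become fixed
#' levels.
#'
#' @param model A `bnet`.
#' @param h Activation steepness (default 50).
#' @param gamma Per-node decay rate(s) (default 1).
#' @param w_thr Activation threshold (default 1/2).
#' @return A `continuous_grn`.
#' @export
to_continuous <- function(model, h = 50, gamma = 1, w_thr = 0.5) {
  stopifnot(inherits(model, "bnet"))
  N <- length(model$nodes)
  gamma <- rep_len(gamma, N)
  if (any(gamma <= 0)) abort("gamma must be > 0")
  if (h <= 0) abort("h must be > 0")
  w_exprs <- lapply(model$rules, function(r) {
    if (!is.null(r$expr)) return(r$expr)
    if (length(r$inputs) == 0) return(r$outputs[1])
    .parse_logic_expr(.table_to_dnf(r))
  })
  clamp_levels <- if (length(model$clamps)) {
    stats::setNames(as.numeric(model$clamps), names(model$clamps))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  ops <- .fuzzy_ops_env()
  big <- as.call(c(quote(c), unname(w_exprs)))
  nodes <- model$nodes
  w_fun <- function(x) {
    env <- list2env(stats::setNames(as.list(x), nodes), parent = ops)
    as.numeric(eval(big, envir = env))
  }
  # batch form: rows of X are states; the fuzzy operators are elementwise, so
  # each w_k can be evaluated for all states at once
  w_matrix <- function(X) {
    env <- list2env(stats::setNames(lapply(seq_len(N), function(j) X[, j]), nodes),
                    parent = ops)
    out <- vapply(w_exprs, function(e) {
      v <- eval(e, envir = env)
      if (length(v) == 1L) rep(as.numeric(v), nrow(X)) else as.numeric(v)
    }, numeric(nrow(X)))
    matrix(out, nrow = nrow(X), ncol = N)
  }
  structure(list(
    nodes = nodes,
    w_exprs = w_exprs,
    w_fun = w_fun,
    w_matrix = w_matrix,
    gamma = gamma,
    h = h,
    w_thr = w_thr,
    clamps = clamp_levels,
    boolean_model = model
  ), class = "continuous_grn")
}

#' @export
print.continuous_grn <- function(x, ...) {
  cat("Logistic ODE system:", length(x$nodes), "nodes; h =", x$h,
      "; w_thr =", x$w_thr, "\n")
  if (length(x$clamps)) {
    cat("  fixed levels:", paste0(names(x$clamps), "=", x$clamps, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate the input functions w_k at a continuous state
#'
#' @param cmodel A `continuous_grn`.
#' @param x Levels in `[0,1]^N` (canonical node order).
#' @return Numeric vector `w` of length `N`.
#' @export
input_levels <- function(cmodel, x) {
  stopifnot(inherits(cmodel, "continuous_grn"))
  cmodel$w_fun(as.numeric(x))
}

# Right-hand side dX/dt with clamped coordinates pinned.
.cont_deriv <- function(cmodel) {
  ci <- match(names(cmodel$clamps), cmodel$nodes)
  cv <- as.numeric(cmodel$clamps)
  function(x) {
    if (length(ci)) x[ci] <- cv
    d <- activation_level(cmodel$w_fun(x), cmodel$h, cmodel$w_thr) -
      cmodel$gamma * x
    if (length(ci)) d[ci] <- 0
    d
  }
}

#' Integrate the continuous system
#'
#' @param cmodel A `continuous_grn`.
#' @param x0 Initial levels in `[0,1]^N`; clamped coordinates are overridden.
#' @param t_end Final time.
#' @param n_out Number of output time points.
#' @param rtol,atol Solver tolerances (lsoda).
#' @return A tibble: `time` plus one column per node.
#' @export
integrate_grn <- function(cmodel, x0, t_end = 100, n_out = 51,
                          rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(cmodel, "continuous_grn"))
  N <- length(cmodel$nodes)
  if (length(x0) != N) abort("x0 length must equal N")
  x0 <- as.numeric(x0)
  if (any(!is.finite(x0)) || any(x0 < -1e-9) || any(x0 > 1 + 1e-9)) {
    abort("x0 must lie in [0,1]^N")
  }
  ci <- match(names(cmodel$clamps), cmodel$nodes)
  if (length(ci)) x0[ci] <- as.numeric(cmodel$clamps)
  deriv <- .cont_deriv(cmodel)
  rhs <- function(t, y, parms) list(deriv(y))
  times <- seq(0, t_end, length.out = max(2, n_out))
  sol <- deSolve::ode(y = stats::setNames(x0, cmodel$nodes), times = times,
                      func = rhs, parms = NULL, rtol = rtol, atol = atol)
  if (any(!is.finite(sol))) abort("integration produced non-finite values")
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out
}

#' Terminal state of an integration
#' @param trajectory A tibble from [integrate_grn()].
#' @return Named numeric vector of final levels.
#' @export
terminal_state <- function(trajectory) {
  last <- trajectory[nrow(trajectory), -1, drop = FALSE]
  stats::setNames(as.numeric(last), names(last))
}

#' Round continuous levels to a Boolean state
#' @param x Levels in `[0,1]`.
#' @return Integer 0/1 vector (`1` where `x > 0.5`).
#' @export
round_state <- function(x) as.integer(x > 0.5)

#' Find and classify steady states of the continuous system
#'
#' Damped Newton iteration on `F(X) = f[w(X)] - gamma X` from every Boolean
#' corner (for `N <= corner_cap`), the all-0.5 midpoint, and — in a second
#' pass — the pairwise midpoints of the roots already found (this seeds the
#' saddle points that sit between pairs of stable states).  Roots closer than
#' `merge_tol` in sup-norm are merged.  Each root is classified by the real
#' parts of its numerical Jacobian eigenvalues and matched against the
#' discrete attractor set where possible.
#'
#' @param cmodel A `continuous_grn`.
#' @param corner_cap Largest `N` for full corner seeding; above it,
#'   `n_corner_samples` seeded random corners are used.
#' @param n_corner_samples,seed Corner sampling controls for large `N`.
#' @param tol Residual tolerance for accepting a root.
#' @param merge_tol Sup-norm radius for de-duplicating roots.
#' @param extra_seeds Optional matrix of additional seed states (rows).
#' @return A `steady_state_set`: `states` (matrix), `stable` (logical, all
#'   Jacobian eigenvalue real parts negative), `max_re` (leading real part),
#'   `residual`, `matched_boolean` (label of the discrete attractor the
#'   rounded state equals, or `NA`), and bookkeeping on skipped seeds.
#' @export
find_steady_states <- function(cmodel, corner_cap = 12, n_corner_samples = 512,
                               seed = 1, tol = 1e-8, merge_tol = 1e-4,
                               extra_seeds = NULL) {
  stopifnot(inherits(cmodel, "continuous_grn"))
  N <- length(cmodel$nodes)
  ci <- match(names(cmodel$clamps), cmodel$nodes)
  free <- setdiff(seq_len(N), ci)
  deriv <- .cont_deriv(cmodel)
  embed <- function(xf) {
    x <- numeric(N)
    if (length(ci)) x[ci] <- as.numeric(cmodel$clamps)
    x[free] <- xf
    x
  }
  Ffree <- function(xf) deriv(embed(xf))[free]

  nf <- length(free)
  corners <- if (nf <= corner_cap) {
    decode_states(0:(2^nf - 1), paste0("f", seq_len(nf)))
  } else {
    .random_states(n_corner_samples, nf, seed)
  }
  seeds <- rbind(corners, rep(0.5, nf))
  if (!is.null(extra_seeds)) {
    seeds <- rbind(seeds, as.matrix(extra_seeds)[, free, drop = FALSE])
  }

  roots <- list()
  skipped <- 0L
  add_root <- function(x) {
    for (r in roots) if (max(abs(r - x)) < merge_tol) return(invisible(FALSE))
    roots[[length(roots) + 1L]] <<- x
    invisible(TRUE)
  }
  run_seeds <- function(S) {
    for (i in seq_len(nrow(S))) {
      res <- .damped_newton(Ffree, as.numeric(S[i, ]), tol = tol)
      if (res$converged) add_root(res$x) else skipped <<- skipped + 1L
    }
  }

  # First resolve the corner seeds with a vectorized fixed-point sweep
  # x <- f(w(x)) / gamma (contracting towards the stable near-corner roots);
  # unresolved seeds fall through to Newton.
  X <- matrix(0, nrow(seeds), N)
  X[, free] <- seeds
  if (length(ci)) X[, ci] <- matrix(as.numeric(cmodel$clamps), nrow(seeds),
                                    length(ci), byrow = TRUE)
  for (it in seq_len(200)) {
    Xn <- activation_level(cmodel$w_matrix(X), cmodel$h, cmodel$w_thr) /
      matrix(cmodel$gamma, nrow(X), N, byrow = TRUE)
    if (length(ci)) Xn[, ci] <- X[, ci, drop = FALSE]
    if (max(abs(Xn - X)) < tol * 1e-2) { X <- Xn; break }
    X <- Xn
  }
  res_row <- apply(abs(activation_level(cmodel$w_matrix(X), cmodel$h, cmodel$w_thr) -
                         X * matrix(cmodel$gamma, nrow(X), N, byrow = TRUE))[, free, drop = FALSE],
                   1, max)
  conv <- res_row < tol
  for (i in which(conv)) add_root(X[i, free])
  if (any(!conv)) {
    # de-duplicate the stragglers before the expensive Newton polish
    left <- unique(round(X[!conv, free, drop = FALSE], 3))
    run_seeds(left)
  }
  # second pass: midpoints between every pair of found roots
  if (length(roots) >= 2) {
    rm <- do.call(rbind, roots)
    pairs <- utils::combn(nrow(rm), 2)
    mids <- t(apply(pairs, 2, function(ij) (rm[ij[1], ] + rm[ij[2], ]) / 2))
    run_seeds(mids)
  }

  states <- do.call(rbind, lapply(roots, embed))
  if (is.null(states)) states <- matrix(numeric(0), 0, N)
  colnames(states) <- cmodel$nodes
  n_roots <- nrow(states)
  residual <- vapply(seq_len(n_roots), function(i) max(abs(deriv(states[i, ]))),
                     numeric(1))
  max_re <- vapply(seq_len(n_roots), function(i) {
    J <- pracma::jacobian(Ffree, states[i, free])
    max(Re(eigen(J, only.values = TRUE)$values))
  }, numeric(1))
  stable <- max_re < -1e-6

  matched <- rep(NA_character_, n_roots)
  bm <- cmodel$boolean_model
  if (!is.null(bm) && length(bm$nodes) <= 24) {
    aset <- find_attractors(bm, keep_assignment = FALSE)
    keys <- vapply(aset$attractors, function(a) {
      if (nrow(a) == 1L) .state_key(a[1, ]) else NA_character_
    }, "")
    for (i in seq_len(n_roots)) {
      xr <- states[i, ]
      if (all(pmin(xr, 1 - xr) < 0.25)) {
        k <- .state_key(round_state(xr))
        j <- match(k, keys)
        if (!is.na(j)) matched[i] <- k
      }
    }
  }

  ord <- order(encode_states(matrix(as.integer(states > 0.5), ncol = N)))
  structure(list(
    states = states[ord, , drop = FALSE],
    stable = stable[ord],
    max_re = max_re[ord],
    residual = residual[ord],
    matched_boolean = matched[ord],
    skipped_seeds = skipped,
    cmodel = cmodel
  ), class = "steady_state_set")
}

.damped_newton <- function(F, x0, tol = 1e-8, maxit = 200) {
  x <- x0
  fx <- F(x)
  for (it in seq_len(maxit)) {
    r <- max(abs(fx))
    if (r < tol * 1e-2) break
    J <- tryCatch(pracma::jacobian(F, x), error = function(e) NULL)
    if (is.null(J) || any(!is.finite(J))) return(list(converged = FALSE))
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE))
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- F(xn)
      if (max(abs(fn)) < r || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(fn)) >= r && max(abs(fn)) >= tol) return(list(converged = FALSE))
    x <- xn
    fx <- fn
  }
  list(x = x, converged = max(abs(F(x))) < tol)
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat(nrow(x$states), "steady state(s):", sum(x$stable), "stable,",
      sum(!x$stable), "unstable\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a steady-state set
#' @param x A `steady_state_set`.
#' @param ... Unused.
#' @return A tibble: `steady_state` index, `stable`, `max_re`, `residual`,
#'   `matched_boolean`, plus one level column per node.
#' @method tidy steady_state_set
#' @export
tidy.steady_state_set <- function(x, ...) {
  dplyr::bind_cols(
    tibble(steady_state = seq_len(nrow(x$states)),
           stable = x$stable, max_re = x$max_re,
           residual = x$residual, matched_boolean = x$matched_boolean),
    as_tibble(x$states)
  )
}

#' @method glance steady_state_set
#' @export
glance.steady_state_set <- function(x, ...) {
  tibble(n_steady_states = nrow(x$states),
         n_stable = sum(x$stable),
         n_unstable = sum(!x$stable),
         max_residual = if (nrow(x$states)) max(x$residual) else NA_real_,
         skipped_seeds = x$skipped_seeds)
}

#' Probe a steady state with random restarts
#'
#' Runs the dynamics `n_trials` times from seeded random perturbations of the
#' steady state (each coordinate shifted by up to `± max_perturb` of its own
#' value, clipped to `[0, 1]`) and reports where each trial ends.
#'
#' @param cmodel A `continuous_grn`.
#' @param s Steady-state levels (named or in canonical node order).
#' @param n_trials Number of restarts.
#' @param max_perturb Maximum relative perturbation (e.g. 0.30).
#' @param seed Integer seed (required when `n_trials > 0`).
#' @param targets Optional matrix of reference states (rows, with rownames as
#'   labels) to which terminal states are matched by sup-norm distance;
#'   defaults to the state itself.
#' @param match_tol Sup-norm radius for a terminal state to count as a target.
#' @param t_end Integration horizon per trial.
#' @return A tibble with one row per trial: terminal levels, `terminal_label`
#'   (matched target or `NA`), and `returned` (matched the probed state).
#' @export
assess_stability <- function(cmodel, s, n_trials = 1000, max_perturb = 0.30,
                             seed = NULL, targets = NULL, match_tol = 0.1,
                             t_end = 100) {
  stopifnot(inherits(cmodel, "continuous_grn"))
  N <- length(cmodel$nodes)
  s <- as.numeric(s)
  if (length(s) != N) abort("steady state length must equal N")
  if (n_trials == 0) {
    return(tibble(trial = integer(0), terminal_label = character(0),
                  returned = logical(0)))
  }
  if (is.null(seed)) abort("assess_stability requires an integer seed")
  if (is.null(targets)) {
    targets <- matrix(s, nrow = 1, dimnames = list("self", cmodel$nodes))
  }
  targets <- as.matrix(targets)
  if (is.null(rownames(targets))) {
    rownames(targets) <- paste0("target", seq_len(nrow(targets)))
  }
  perturbed <- withr::with_seed(seed, {
    shift <- matrix(stats::runif(n_trials * N, -max_perturb, max_perturb),
                    n_trials, N)
    pmin(pmax(matrix(s, n_trials, N, byrow = TRUE) * (1 + shift), 0), 1)
  })
  self_key <- .state_key(round_state(s))
  rows <- purrr::map_dfr(seq_len(n_trials), function(i) {
    term <- terminal_state(integrate_grn(cmodel, perturbed[i, ], t_end = t_end,
                                         n_out = 2, rtol = 1e-6, atol = 1e-8))
    d <- apply(targets, 1, function(tg) max(abs(tg - term)))
    j <- which.min(d)
    lab <- if (d[j] <= match_tol) rownames(targets)[j] else NA_character_
    dplyr::bind_cols(
      tibble(trial = i, terminal_label = lab,
             returned = max(abs(term - s)) <= match_tol),
      as_tibble(as.list(term))
    )
  })
  rows
}
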