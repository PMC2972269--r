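#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Valid node identifiers: a letter followed by letters, digits, '_' or '.'
.node_name_rx <- "^[A-Za-z][A-Za-z0-9_.]*$"

#' Build a synchronous Boolean network model
#'
#' Assembles an immutable network model from a tabular rule set.  Each node is
#' updated synchronously: the state of every node at time `t + 1` is its rule's
#' output evaluated on the full state at time `t`.  Clamped nodes (see
#' [clamp()]) override their rule at every step, including `t = 0`.
#'
#' Truth-table rows are enumerated with the declared inputs most-significant
#' first: row `r` (1-based) corresponds to the input pattern given by the
#' `k`-bit binary expansion of `r - 1`.  Under input order `(SHR, SCR, JKD,
#' MGP)`, row 14 is the pattern `1101`.
#'
#' @param rules A data frame with one row per node and columns
#'   `target` (node name), `inputs` (comma-separated input node names, or a
#'   list-column of character vectors; empty for a constant) and `outputs`
#'   (a string of `2^k` bits, most-significant-input-first row order).
#'   Alternatively a character vector of rule expressions
#'   `"TARGET = <expr>"` parsed by [parse_rules()].
#' @param nodes Optional character vector fixing the canonical node order.
#'   Defaults to the order of `target` in `rules`.
#'
#' @return An object of class `bnet` with fields `nodes`, `rules`, `clamps`.
#' @examples
#' net <- build_network(c("A = B", "B = NOT A"))
#' sync_step(net, c(A = 0, B = 0))
#' @export
build_network <- function(rules, nodes = NULL) {
  if (is.character(rules)) rules <- parse_rules(rules)
  rules <- as_tibble(rules)
  if (!all(c("target", "inputs", "outputs") %in% names(rules))) {
    abort("`rules` needs columns `target`, `inputs`, `outputs`.")
  }
  targets <- as.character(rules$target)
  if (anyDuplicated(targets)) {
    abort(paste0("duplicate rule for node ", targets[duplicated(targets)][1]))
  }
  nodes <- nodes %||% targets
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("node names must be unique")
  bad <- nodes[!grepl(.node_name_rx, nodes)]
  if (length(bad)) abort(paste0("invalid node name: ", bad[1]))
  missing <- setdiff(nodes, targets)
  if (length(missing)) abort(paste0("missing rule for node ", missing[1]))
  extra <- setdiff(targets, nodes)
  if (length(extra)) abort(paste0("rule for undeclared node ", extra[1]))

  in_list <- rules$inputs
  if (!is.list(in_list)) {
    in_list <- lapply(as.character(in_list), function(s) {
      s <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
      s[nzchar(s)]
    })
  }
  out_list <- rules$outputs
  if (!is.list(out_list)) out_list <- lapply(as.character(out_list), .parse_bits)
  expr_list <- if ("expr" %in% names(rules)) rules$expr else vector("list", nrow(rules))

  ord <- match(nodes, targets)
  rule_objs <- lapply(seq_along(nodes), function(i) {
    j <- ord[i]
    ins <- as.character(in_list[[j]])
    outs <- as.integer(out_list[[j]])
    dangling <- setdiff(ins, nodes)
    if (length(dangling)) {
      abort(paste0("rule for ", nodes[i], " references undeclared node ",
                   dangling[1]))
    }
    if (anyDuplicated(ins)) {
      abort(paste0("rule for ", nodes[i], " lists a duplicate input"))
    }
    if (length(outs) != 2^length(ins) || !all(outs %in% c(0L, 1L))) {
      abort(paste0("rule for ", nodes[i], " needs 2^k = ",
                   2^length(ins), " Boolean outputs"))
    }
    list(target = nodes[i], inputs = ins,
         input_idx = match(ins, nodes), outputs = outs,
         expr = expr_list[[j]])
  })
  names(rule_objs) <- nodes
  structure(list(nodes = nodes, rules = rule_objs,
                 clamps = integer(0)),
            class = "bnet")
}

.parse_bits <- function(s) {
  s <- gsub("[^01]", "", s)
  as.integer(strsplit(s, "")[[1]])
}

#' Parse logical update rules from text
#'
#' One rule per line, `TARGET = <expr>` where `<expr>` uses `AND`, `OR`, `NOT`,
#' parentheses and the constants `0`/`1`.  The rule's inputs are the distinct
#' node names in order of first appearance in the expression; its truth table
#' enumerates them most-significant-first (see [build_network()]).
#'
#' @param text Character vector of rule lines (blank lines and `#` comments are
#'   skipped).
#' @return A tibble with columns `target`, `inputs` (list), `outputs` (list)
#'   and `expr` (list of quoted R expressions), suitable for [build_network()].
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parsed <- lapply(lines, .parse_rule_line)
  tibble(
    target = vapply(parsed, `[[`, "", "target"),
    inputs = lapply(parsed, `[[`, "inputs"),
    outputs = lapply(parsed, `[[`, "outputs"),
    expr = lapply(parsed, `[[`, "expr")
  )
}

.parse_rule_line <- function(line) {
  m <- regmatches(line, regexec("^([A-Za-z][A-Za-z0-9_.]*)[[:space:]]*=(.*)$", line))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse rule line: ", line))
  target <- m[2]
  rhs <- m[3]
  expr <- .parse_logic_expr(rhs, line)
  inputs <- .expr_symbols(expr)
  outputs <- .truth_table(expr, inputs)
  list(target = target, inputs = inputs, outputs = outputs, expr = expr)
}

.parse_logic_expr <- function(rhs, context = rhs) {
  s <- rhs
  s <- gsub("\\bAND\\b", "&", s)
  s <- gsub("\\bOR\\b", "|", s)
  s <- gsub("\\bNOT\\b", "!", s)
  expr <- tryCatch(str2lang(s), error = function(e) {
    abort(paste0("cannot parse rule expression: ", context))
  })
  .check_logic_expr(expr, context)
  expr
}

.check_logic_expr <- function(e, context) {
  if (is.symbol(e)) {
    if (!grepl(.node_name_rx, as.character(e))) {
      abort(paste0("invalid node name in rule: ", context))
    }
    return(invisible(TRUE))
  }
  if (is.numeric(e)) {
    if (!e %in% c(0, 1)) abort(paste0("constants must be 0 or 1: ", context))
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.check_logic_expr(e[[2]], context))
    if (op == "!") return(.check_logic_expr(e[[2]], context))
    if (op %in% c("&", "|")) {
      .check_logic_expr(e[[2]], context)
      .check_logic_expr(e[[3]], context)
      return(invisible(TRUE))
    }
  }
  abort(paste0("only AND, OR, NOT, parentheses and 0/1 are allowed: ", context))
}

# Symbols in left-to-right first-appearance order.
.expr_symbols <- function(e) {
  out <- character(0)
  walk <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!nm %in% out) out <<- c(out, nm)
    } else if (is.call(e)) {
      for (i in seq_along(e)[-1]) walk(e[[i]])
    }
  }
  walk(e)
  out
}

# Truth table of `expr` over `inputs`, rows enumerated MSB-first from
# all-zeros (row 1) to all-ones (row 2^k).
.truth_table <- function(expr, inputs) {
  k <- length(inputs)
  if (k == 0) {
    v <- eval(expr, envir = baseenv())
    return(as.integer(v != 0))
  }
  combos <- .row_patterns(k)
  vapply(seq_len(2^k), function(r) {
    env <- as.list(as.logical(combos[r, ]))
    names(env) <- inputs
    as.integer(eval(expr, envir = env, enclos = baseenv()) != 0)
  }, integer(1))
}

# 2^k x k matrix of input patterns; column 1 is the most significant input.
.row_patterns <- function(k) {
  idx <- 0:(2^k - 1)
  m <- vapply(seq_len(k), function(j) (idx %/% 2^(k - j)) %% 2, numeric(2^k))
  matrix(as.integer(m), ncol = k)
}

#' Advance a Boolean network one synchronous step
#'
#' Every node simultaneously takes its rule's output evaluated on the time-`t`
#' state; clamped nodes take their clamp value instead.
#'
#' @param model A `bnet`.
#' @param state A 0/1 vector of length `N` (canonical node order), or a matrix
#'   with `N` columns holding one state per row.
#' @return The successor state, in the same shape as `state`.
#' @export
sync_step <- function(model, state) {
  stopifnot(inherits(model, "bnet"))
  if (is.matrix(state)) {
    if (ncol(state) != length(model$nodes)) {
      abort("state matrix must have one column per node")
    }
    return(.step_matrix(model, state))
  }
  if (length(state) != length(model$nodes)) {
    abort(paste0("state length ", length(state), " != N = ", length(model$nodes)))
  }
  drop(.step_matrix(model, matrix(as.integer(state), nrow = 1)))
}

# Vectorized synchronous update of an m x N 0/1 matrix.
.step_matrix <- function(model, S) {
  storage.mode(S) <- "integer"
  out <- S
  for (j in seq_along(model$rules)) {
    r <- model$rules[[j]]
    k <- length(r$input_idx)
    if (k == 0L) {
      out[, j] <- r$outputs[1L]
    } else {
      idx <- 1 + as.vector(S[, r$input_idx, drop = FALSE] %*% 2^((k - 1):0))
      out[, j] <- r$outputs[idx]
    }
  }
  .apply_clamps(model, out)
}

.apply_clamps <- function(model, S) {
  cl <- model$clamps
  if (length(cl)) {
    ci <- match(names(cl), model$nodes)
    for (i in seq_along(ci)) S[, ci[i]] <- cl[[i]]
  }
  S
}

#' Clamp a node to a constant value
#'
#' Returns a model in which `node` is held at `value` at every step, including
#' replacement of its initial value at `t = 0`.  Used for in silico
#' loss-of-function (`value = 0`) and gain-of-function (`value = 1`) mutants.
#'
#' @param model A `bnet`.
#' @param node Node name.
#' @param value 0 or 1.
#' @return A new `bnet` with the clamp added.
#' @export
clamp <- function(model, node, value) {
  stopifnot(inherits(model, "bnet"))
  if (!node %in% model$nodes) abort(paste0("unknown node: ", node))
  if (!value %in% c(0, 1)) abort("clamp value must be 0 or 1")
  cl <- model$clamps
  cl[[node]] <- as.integer(value)
  model$clamps <- cl
  model
}

#' Remove all clamps from a model
#' @param model A `bnet`.
#' @return The unclamped model.
#' @export
unclamp <- function(model) {
  stopifnot(inherits(model, "bnet"))
  model$clamps <- integer(0)
  model
}

#' @export
print.bnet <- function(x, ...) {
  cat("Synchronous Boolean network:", length(x$nodes), "nodes\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (length(x$clamps)) {
    cat("  clamps:", paste0(names(x$clamps), "=", x$clamps, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a Boolean network's rule set
#'
#' @param x A `bnet`.
#' @param ... Unused.
#' @return A tibble with one row per node: `target`, `k` (arity), `inputs`
#'   (comma-separated), `outputs` (bit string in MSB-first row order).
#' @method tidy bnet
#' @export
tidy.bnet <- function(x, ...) {
  tibble(
    target = x$nodes,
    k = unname(vapply(x$rules, function(r) length(r$inputs), integer(1))),
    inputs = unname(vapply(x$rules, function(r) paste(r$inputs, collapse = ","), "")),
    outputs = unname(vapply(x$rules, function(r) paste(r$outputs, collapse = ""), ""))
  )
}

#' @method glance bnet
#' @export
glance.bnet <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_clamped = length(x$clamps),
    total_rule_rows = sum(vapply(x$rules, function(r) length(r$outputs), integer(1))),
    space_size = 2^length(x$nodes)
  )
}

#' Read update rules from a file
#'
#' Two dialects are supported: the expression format (`TARGET = <expr>`, one
#' per line) and a TSV truth-table format with header
#' `target<TAB>inputs<TAB>outputs` where `inputs` is comma-separated and
#' `outputs` is a `2^k` bit string in MSB-first row order.  The dialect is
#' auto-detected from the first non-empty line unless `format` is given.
#'
#' @param path File path.
#' @param format `"auto"`, `"expr"` or `"tsv"`.
#' @param nodes Optional canonical node order (defaults to rule order).
#' @return A `bnet`.
#' @export
read_rules <- function(path, format = c("auto", "expr", "tsv"), nodes = NULL) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  nonblank <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(nonblank)) abort("empty rule file")
  if (format == "auto") {
    format <- if (grepl("^target\\t", nonblank[1])) "tsv" else "expr"
  }
  if (format == "expr") {
    build_network(parse_rules(nonblank), nodes = nodes)
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          comment = "#")
    df$inputs[is.na(df$inputs)] <- ""
    build_network(df, nodes = nodes)
  }
}

#' Write update rules to a file
#'
#' The TSV dialect serializes the truth tables losslessly and round-trips
#' through [read_rules()] bit-for-bit.  The expression dialect writes each
#' node's stored expression when available, otherwise a disjunctive normal form
#' of its table; the round-trip preserves the truth table (not the text).
#'
#' @param model A `bnet`.
#' @param path File path.
#' @param format `"tsv"` or `"expr"`.
#' @return `path`, invisibly.
#' @export
write_rules <- function(model, path, format = c("tsv", "expr")) {
  stopifnot(inherits(model, "bnet"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- tidy(model)[, c("target", "inputs", "outputs")]
    readr::write_tsv(df, path)
  } else {
    lines <- vapply(model$rules, function(r) {
      rhs <- if (!is.null(r$expr)) .deparse_logic(r$expr) else .table_to_dnf(r)
      paste0(r$target, " = ", rhs)
    }, "")
    readr::write_lines(lines, path)
  }
  invisible(path)
}

.deparse_logic <- function(e) {
  s <- paste(deparse(e), collapse = " ")
  s <- gsub("&", " AND ", s, fixed = TRUE)
  s <- gsub("|", " OR ", s, fixed = TRUE)
  s <- gsub("!", " NOT ", s, fixed = TRUE)
  gsub("[[:space:]]+", " ", trimws(s))
}

# Disjunctive normal form of a truth table (for rules without an expression).
.table_to_dnf <- function(r) {
  k <- length(r$inputs)
  if (k == 0) return(as.character(r$outputs[1]))
  on <- which(r$outputs == 1L)
  if (!length(on)) return("0")
  if (length(on) == 2^k) return("1")
  pats <- .row_patterns(k)
  terms <- vapply(on, function(row) {
    lits <- ifelse(pats[row, ] == 1L, r$inputs, paste0("NOT ", r$inputs))
    paste0("(", paste(lits, collapse = " AND "), ")")
  }, "")
  paste(terms, collapse = " OR ")
}
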