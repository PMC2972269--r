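# Independent brute-force oracle: rules are plain R functions of a named 0/1
# state, attractors are found by following every initial state with a visited
# list.  No engine internals are used.

oracle_step <- function(funs, state, clamps = NULL) {
  nxt <- vapply(names(funs), function(n) as.integer(funs[[n]](state) != 0),
                integer(1))
  names(nxt) <- names(funs)
  if (!is.null(clamps)) nxt[names(clamps)] <- as.integer(clamps)
  nxt
}

# Returns the attractors as a sorted character vector; each attractor is the
# sorted set of its state strings joined with "|" (cycle order irrelevant).
oracle_attractor_keys <- function(funs, clamps = NULL) {
  nodes <- names(funs)
  N <- length(nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), N)))
  colnames(grid) <- nodes
  found <- character(0)
  for (i in seq_len(nrow(grid))) {
    s <- grid[i, ]
    if (!is.null(clamps)) s[names(clamps)] <- as.integer(clamps)
    keys <- character(0)
    repeat {
      k <- paste(s, collapse = "")
      hit <- match(k, keys)
      if (!is.na(hit)) {
        cyc <- keys[hit:length(keys)]
        found <- c(found, paste(sort(cyc), collapse = "|"))
        break
      }
      keys <- c(keys, k)
      s <- oracle_step(funs, s, clamps)
    }
  }
  sort(unique(found))
}

# Engine attractor set -> the same sorted-set representation.
engine_attractor_keys <- function(aset) {
  sort(vapply(aset$attractors, function(a) {
    paste(sort(apply(a, 1, paste, collapse = "")), collapse = "|")
  }, ""))
}

# Rule functions for an engine network, built from its truth tables through
# an independently written MSB-first row decoder.
funs_from_rules <- function(net) {
  td <- tidy(net)
  funs <- lapply(seq_len(nrow(td)), function(i) {
    ins <- strsplit(td$inputs[i], ",", fixed = TRUE)[[1]]
    outs <- as.integer(strsplit(td$outputs[i], "")[[1]])
    k <- length(ins)
    force(ins); force(outs); force(k)
    function(state) {
      if (k == 0) return(outs[1])
      bits <- as.integer(state[ins])
      outs[1 + sum(bits * 2^((k - 1):0))]
    }
  })
  names(funs) <- td$target
  funs
}

# Hand-written rule functions for the reference model A (independent of the
# packaged rule text).
scn_A_funs <- list(
  PLT = function(s) s[["ARF"]],
  auxin = function(s) 1L,
  ARF = function(s) 1L - s[["AuxIAA"]],
  AuxIAA = function(s) 1L - s[["auxin"]],
  SHR = function(s) s[["SHR"]],
  SCR = function(s) s[["SHR"]] * s[["SCR"]] * max(s[["JKD"]], 1L - s[["MGP"]]),
  JKD = function(s) s[["SHR"]] * s[["SCR"]],
  MGP = function(s) s[["SHR"]] * s[["SCR"]] * (1L - s[["WOX5"]]),
  WOX5 = function(s) s[["ARF"]] * s[["SHR"]] * s[["SCR"]] *
    max(1L - s[["MGP"]], s[["WOX5"]])
)
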