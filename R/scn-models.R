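#' @name scn_models
#' @title Root stem-cell-niche network variants
#'
#' @description
#' Four alternative single-cell Boolean models of the *Arabidopsis thaliana*
#' root stem cell niche over the nodes PLT, auxin, ARF, Aux/IAA (written
#' `AuxIAA`), SHR, SCR, JKD, MGP, WOX5 and — in the B variants — the
#' hypothetical CLE-like gene CLEX.  Variants A and A' close the WOX5/MGP
#' mutual repression; B and B' instead let CLEX repress WOX5.  The primed
#' variants differ from their base model in a single output bit of the SCR
#' truth table (line 14, input pattern SHR=1, SCR=1, JKD=0, MGP=1), which
#' makes SCR transcription independent of JKD.
NULL

#' The four model variant identifiers
#' @export
scn_variants <- function() c("A", "A_prime", "B", "B_prime")

.scn_node_order <- function(variant) {
  base <- c("PLT", "auxin", "ARF", "AuxIAA", "SHR", "SCR", "JKD", "MGP", "WOX5")
  if (variant %in% c("B", "B_prime")) c(base, "CLEX") else base
}

# Reference rule text per variant.  SCR in the primed variants is written so
# that its 16-row table over (SHR, SCR, JKD, MGP) equals the base table with
# line 14 flipped to 1 (i.e. SHR AND SCR on every input corner).
.scn_rule_text <- function(variant) {
  scr <- if (variant %in% c("A", "B")) {
    "SCR = SHR AND SCR AND (JKD OR NOT MGP)"
  } else {
    "SCR = SHR AND SCR AND (JKD OR NOT MGP OR (MGP AND NOT JKD))"
  }
  wox5 <- if (variant %in% c("A", "A_prime")) {
    "WOX5 = ARF AND SHR AND SCR AND (NOT MGP OR WOX5)"
  } else {
    "WOX5 = ARF AND SHR AND SCR AND (NOT CLEX OR WOX5)"
  }
  rules <- c(
    "PLT = ARF",
    "auxin = 1",
    "ARF = NOT AuxIAA",
    "AuxIAA = NOT auxin",
    "SHR = SHR",
    scr,
    "JKD = SHR AND SCR",
    "MGP = SHR AND SCR AND NOT WOX5",
    wox5
  )
  if (variant %in% c("B", "B_prime")) {
    rules <- c(rules, "CLEX = SHR AND NOT WOX5 AND (MGP OR CLEX)")
  }
  rules
}

#' Build a single-cell stem-cell-niche model
#'
#' @param variant One of `"A"`, `"A_prime"`, `"B"`, `"B_prime"`.
#' @return A `bnet` with 9 nodes (A variants) or 10 nodes (B variants, CLEX
#'   appended last), in the canonical order
#'   PLT, auxin, ARF, AuxIAA, SHR, SCR, JKD, MGP, WOX5 (, CLEX).
#' @examples
#' net <- build_scn_model("A")
#' find_attractors(net)
#' @export
build_scn_model <- function(variant = scn_variants()) {
  variant <- match.arg(variant)
  build_network(parse_rules(.scn_rule_text(variant)),
                nodes = .scn_node_order(variant))
}

#' Rule set of a stem-cell-niche variant as a tibble
#'
#' @inheritParams build_scn_model
#' @return The tidy rule table (see [tidy.bnet()]).
#' @export
scn_rules <- function(variant = scn_variants()) {
  tidy(build_scn_model(variant))
}

#' Reference cell-type expression profiles
#'
#' The simulated wild-type configurations of the four niche cell types:
#' quiescent center (QC), vascular initials, cortex-endodermis initials (CEI)
#' and columella/epidermis initials (CEpI).  For the B variants the vascular
#' profile admits either CLEX value (two distinct attractors); the returned
#' tibble lists CLEX = 1 for vascular and carries the attribute
#' `vascular_clex_free = TRUE`, and [scn_expected_attractors()] expands the
#' profile set to the full expected attractor list.
#'
#' @inheritParams build_scn_model
#' @return A tibble with `cell_type` plus one 0/1 column per node.
#' @export
scn_reference_profiles <- function(variant = scn_variants()) {
  variant <- match.arg(variant)
  base <- tibble(
    cell_type = c("QC", "vascular", "CEI", "CEpI"),
    PLT   = c(1, 1, 1, 1),
    auxin = c(1, 1, 1, 1),
    ARF   = c(1, 1, 1, 1),
    AuxIAA = c(0, 0, 0, 0),
    SHR   = c(1, 1, 1, 0),
    SCR   = c(1, 0, 1, 0),
    JKD   = c(1, 0, 1, 0),
    MGP   = c(0, 0, 1, 0),
    WOX5  = c(1, 0, 0, 0)
  )
  if (variant %in% c("B", "B_prime")) {
    base$CLEX <- c(0, 1, 1, 0)
    attr(base, "vascular_clex_free") <- TRUE
  } else {
    attr(base, "vascular_clex_free") <- FALSE
  }
  base
}

#' Expected attractor states of a variant
#'
#' Expands [scn_reference_profiles()] into the exact expected attractor list:
#' four fixed points for the A variants, five for the B variants (vascular
#' duplicated with CLEX on and off).
#'
#' @inheritParams build_scn_model
#' @return A tibble with `cell_type` plus one 0/1 column per node, one row per
#'   expected attractor.
#' @export
scn_expected_attractors <- function(variant = scn_variants()) {
  variant <- match.arg(variant)
  prof <- scn_reference_profiles(variant)
  if (isTRUE(attr(prof, "vascular_clex_free"))) {
    vasc0 <- prof[prof$cell_type == "vascular", ]
    vasc0$CLEX <- 0
    prof <- dplyr::bind_rows(prof, vasc0)
  }
  dplyr::arrange(prof, .data$cell_type)
}

#' Validate a model against reference profiles
#'
#' Runs an exhaustive attractor search and compares the attractor states with
#' the expected set derived from the profiles.  For B-variant profiles the
#' vascular configuration must be present with both CLEX values.
#'
#' @param model A `bnet` whose nodes include the profile nodes.
#' @param profiles Profiles as from [scn_reference_profiles()]; defaults
#'   require `variant`.
#' @param variant Used to fetch default profiles.
#' @return A list of class `scn_validation`: `pass` (logical), `matched`,
#'   `missing`, `spurious` (tibbles of states) and the labeled
#'   `attractor_set`.
#' @export
validate_against_reference <- function(model, profiles = NULL,
                                       variant = scn_variants()) {
  stopifnot(inherits(model, "bnet"))
  if (is.null(profiles)) {
    variant <- match.arg(variant)
    profiles <- scn_reference_profiles(variant)
  }
  prof_nodes <- setdiff(names(profiles), "cell_type")
  extra_nodes <- setdiff(model$nodes, prof_nodes)
  missing_nodes <- setdiff(prof_nodes, model$nodes)
  expected <- profiles
  if (isTRUE(attr(profiles, "vascular_clex_free")) && "CLEX" %in% prof_nodes) {
    vasc0 <- expected[expected$cell_type == "vascular", ]
    vasc0$CLEX <- 0
    expected <- dplyr::bind_rows(expected, vasc0)
  }
  aset <- find_attractors(model)
  aset <- label_attractors(aset, profiles)
  ok_nodes <- length(missing_nodes) == 0 && length(extra_nodes) == 0
  fixed <- aset$periods == 1L
  found_keys <- vapply(seq_along(aset$attractors), function(i) {
    if (!fixed[i]) return(NA_character_)
    a <- aset$attractors[[i]]
    .state_key(a[1, intersect(prof_nodes, model$nodes)])
  }, "")
  exp_keys <- apply(as.matrix(expected[, intersect(prof_nodes, model$nodes), drop = FALSE]),
                    1, .state_key)
  matched <- expected[exp_keys %in% found_keys, , drop = FALSE]
  missing <- expected[!exp_keys %in% found_keys, , drop = FALSE]
  spurious_idx <- which(!(found_keys %in% exp_keys) | !fixed)
  spurious <- tidy(aset) |> dplyr::filter(.data$attractor %in% spurious_idx)
  pass <- ok_nodes && nrow(missing) == 0 && nrow(spurious) == 0 &&
    length(aset$attractors) == nrow(expected)
  structure(list(pass = pass,
                 matched = as_tibble(matched),
                 missing = as_tibble(missing),
                 spurious = spurious,
                 extra_nodes = extra_nodes,
                 missing_nodes = missing_nodes,
                 attractors = aset),
            class = "scn_validation")
}

#' @export
print.scn_validation <- function(x, ...) {
  cat("Reference validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  matched:", nrow(x$matched), " missing:", nrow(x$missing),
      " spurious:", nrow(x$spurious), "\n")
  if (length(x$extra_nodes)) cat("  extra nodes:", paste(x$extra_nodes, collapse = ", "), "\n")
  if (length(x$missing_nodes)) cat("  missing nodes:", paste(x$missing_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Add the PINX and QC46 marker genes
#'
#' Appends two pure output nodes used to validate PLT activity: the efflux
#' facilitator stand-in `PINX = PLT` and the quiescent-center marker
#' `QC46 = PLT AND SHR AND SCR AND WOX5`.  Neither feeds back, so the
#' projection of the attractors onto the original nodes is unchanged.
#'
#' @param model An SCN `bnet` (must contain PLT, SHR, SCR, WOX5).
#' @return A `bnet` with the two extra nodes appended.
#' @export
extend_with_markers <- function(model) {
  stopifnot(inherits(model, "bnet"))
  if (any(c("PINX", "QC46") %in% model$nodes)) {
    abort("model already contains PINX or QC46")
  }
  need <- c("PLT", "SHR", "SCR", "WOX5")
  if (!all(need %in% model$nodes)) {
    abort("marker extension requires PLT, SHR, SCR and WOX5 nodes")
  }
  rules <- tidy(model)[, c("target", "inputs", "outputs")]
  exprs <- lapply(model$rules, function(r) r$expr)
  marker <- parse_rules(c("PINX = PLT",
                          "QC46 = PLT AND SHR AND SCR AND WOX5"))
  combined <- dplyr::bind_rows(
    tibble(target = rules$target,
           inputs = lapply(model$rules, `[[`, "inputs"),
           outputs = lapply(model$rules, `[[`, "outputs"),
           expr = unname(exprs)),
    marker
  )
  out <- build_network(combined, nodes = c(model$nodes, "PINX", "QC46"))
  out$clamps <- model$clamps
  out
}
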