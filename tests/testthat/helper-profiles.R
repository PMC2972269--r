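# Expected wild-type attractor states, frozen from the published simulated
# configurations (node order PLT, auxin, ARF, AuxIAA, SHR, SCR, JKD, MGP,
# WOX5, and CLEX last for the B variants).

expected_states_A <- rbind(
  QC       = c(1, 1, 1, 0, 1, 1, 1, 0, 1),
  vascular = c(1, 1, 1, 0, 1, 0, 0, 0, 0),
  CEI      = c(1, 1, 1, 0, 1, 1, 1, 1, 0),
  CEpI     = c(1, 1, 1, 0, 0, 0, 0, 0, 0)
)
colnames(expected_states_A) <-
  c("PLT", "auxin", "ARF", "AuxIAA", "SHR", "SCR", "JKD", "MGP", "WOX5")

expected_states_B <- rbind(
  QC        = c(1, 1, 1, 0, 1, 1, 1, 0, 1, 0),
  vascular1 = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 1),
  vascular0 = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0),
  CEI       = c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1),
  CEpI      = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
)
colnames(expected_states_B) <- c(colnames(expected_states_A), "CLEX")
storage.mode(expected_states_A) <- "integer"
storage.mode(expected_states_B) <- "integer"

expected_states_for <- function(variant) {
  if (variant %in% c("A", "A_prime")) expected_states_A else expected_states_B
}

state_keys <- function(m) sort(apply(m, 1, paste, collapse = ""))

# Per-cell projection of a 40-variable meta state.
cell_projection <- function(meta, state, cell) {
  idx <- match(paste0(meta$cell_nodes, "_", cell), meta$nodes)
  stats::setNames(as.integer(state[idx]), meta$cell_nodes)
}
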