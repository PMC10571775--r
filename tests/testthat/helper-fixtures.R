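# shared fixtures: small/fast parameterizations used across test files

fast_bsm_config <- function(...) {
  bsm_config(horizon = 10, dt_couple = 1, ...)
}

# a minimal two-node network with a single belt edge, built by hand so that
# closed-form spring/tension checks are exact
two_node_network <- function(stretch = 0, K = 100, Xi = 50, FA = 0,
                             rest = 1) {
  empty <- data.frame(from = integer(0), to = integer(0),
                      rest = numeric(0), K = numeric(0),
                      Xi = numeric(0), FA = numeric(0))
  structure(list(
    pos = rbind(c(0, 0), c(rest + stretch, 0)),
    vel = matrix(0, 2, 2),
    mass = c(1, 1),
    belt = data.frame(from = 1L, to = 2L, rest = rest, K = K, Xi = Xi,
                      FA = FA),
    transverse = empty,
    cells = list(),
    boundary = integer(0),
    belt_nodes = 1:2,
    centroid = c(rest / 2, 0),
    Xi = Xi), class = "mech_network")
}

# total Wts material in a hippo state (cytosolic + all complexes)
wts_total <- function(state, Nm = 6) {
  names(state) <- hippomech:::hippo_state_names(cell_geometry(Nm))
  state[["Wts_c"]] + sum(state[paste0("WA.", seq_len(Nm))]) +
    sum(state[paste0("WR.", seq_len(Nm))]) +
    sum(state[paste0("EW.", seq_len(Nm))])
}
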