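# Shared fixtures: tiny lattices, fast rate sets, and brute-force
# continuous-time Markov chain (CTMC) oracles for micro-models small enough
# to enumerate exactly.  All fixtures are built in code at test time.

tiny_lattice <- function() build_lattice(1, 1)      # 18 dimers, 3 complexes
small_lattice <- function() build_lattice(2, 2)     # 72 dimers, 12 complexes

# a single 6-dimer MWC complex with no internal adjacency: the geometry of
# the well-mixed (B1) micro-model, where only modification-site chemistry
# acts.  Built directly (it is not a tileable hexagonal-unit lattice).
single_complex_geometry <- function() {
  structure(list(n_dimers = 6L, n_complexes = 1L, units = c(NA, NA),
                 nrow = NA_integer_, ncol = NA_integer_,
                 neighbors = rep(list(integer(0)), 6L),
                 complex_of = rep(1L, 6L),
                 complexes = matrix(1:6, nrow = 1)),
            class = "receptor_lattice")
}

# MWC parameters for micro-models with methyl_max = 1: activity spans a wide
# range as complex methylation runs over 0..6
micro_mwc <- function() mwc_params(N = 6, eps_m = 1, K_off = 18.2,
                                   K_on = 3000, m_half = 3)

# -------------------------------------------------------------------------
# CTMC oracle 1: occupancy chain of a single CheR on a frozen-methylation
# (k_cat = 0) lattice with the full M1 rule set.  States: bulk, tether-only
# at d, modsite-only at d, doubly bound (t, m) with m in the assistance
# neighborhood of t.  Returns the state table and the stationary
# distribution.
occupancy_ctmc <- function(geometry, rates, mwc, methyl, L = 0) {
  n <- geometry$n_dimers
  act <- lattice_activity(methyl, geometry, mwc, L)$per_complex
  a_of <- act[geometry$complex_of]
  states <- data.frame(type = "bulk", teth = NA_integer_, mod = NA_integer_,
                       stringsAsFactors = FALSE)
  for (d in seq_len(n)) states <- rbind(states, data.frame(type = "teth", teth = d, mod = NA))
  for (d in seq_len(n)) states <- rbind(states, data.frame(type = "mod", teth = NA, mod = d))
  for (t in seq_len(n)) for (m in assistance_neighborhood(geometry, t))
    states <- rbind(states, data.frame(type = "both", teth = t, mod = m))
  ns <- nrow(states)
  idx <- function(type, t = NA, m = NA) {
    which(states$type == type &
            (is.na(t) & is.na(states$teth) | !is.na(states$teth) & states$teth %in% t) &
            (is.na(m) & is.na(states$mod) | !is.na(states$mod) & states$mod %in% m))
  }
  id_bulk <- 1L
  id_teth <- function(d) 1L + d
  id_mod <- function(d) 1L + n + d
  both_key <- paste(states$teth, states$mod)
  id_both <- function(t, m) 1L + 2L * n + match(paste(t, m), both_key[states$type == "both"])
  Q <- matrix(0, ns, ns)
  w <- 1 - a_of  # CheR weight
  # bulk entry
  for (d in seq_len(n)) {
    Q[id_bulk, id_teth(d)] <- rates$k_t_bind_r / n
    Q[id_bulk, id_mod(d)] <- rates$k_m_bind_bulk_r * w[d] / n
  }
  for (t in seq_len(n)) {
    Q[id_teth(t), id_bulk] <- rates$k_t_unbind_r * rates$tether_unbind_scale
    targets <- if (rates$neighbor_binding) assistance_neighborhood(geometry, t) else t
    for (m in targets)
      Q[id_teth(t), id_both(t, m)] <- rates$k_m_bind_local_r * w[m]
  }
  for (m in seq_len(n)) {
    Q[id_mod(m), id_bulk] <- rates$k_m_unbind_r
    targets <- if (rates$neighbor_binding) assistance_neighborhood(geometry, m) else m
    for (t in targets)
      Q[id_mod(m), id_both(t, m)] <- rates$k_t_bind_local_r
  }
  bi <- which(states$type == "both")
  for (i in bi) {
    t <- states$teth[i]; m <- states$mod[i]
    Q[i, id_mod(m)] <- rates$k_t_unbind_r * rates$tether_unbind_scale
    Q[i, id_teth(t)] <- rates$k_m_unbind_r
  }
  diag(Q) <- -rowSums(Q)
  pi <- ctmc_stationary(Q)
  list(states = states, Q = Q, pi = pi,
       id = list(bulk = id_bulk, teth = id_teth, mod = id_mod))
}

# stationary distribution of a CTMC generator (rows sum to zero)
ctmc_stationary <- function(Q) {
  ns <- nrow(Q)
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

# -------------------------------------------------------------------------
# CTMC oracle 2: joint (methylation, occupancy) chain of the well-mixed
# micro-model: a single 6-dimer complex with per-dimer methylation capped at
# 1, one CheR and one CheB-P (phosphorylation frozen), B1 rules.
b1_micro_rates <- function() {
  b1_rate_set(k_m_bind_bulk_r = 2, k_m_bind_bulk_b = 2,
              k_m_unbind_r = 1, k_m_unbind_b = 1,
              k_cat_r = 1, k_cat_b = 1, a_p = 0, d_p = 0,
              methyl_max = 1L)
}

b1_micro_ctmc <- function(mwc = micro_mwc(), L = 0, rates = b1_micro_rates()) {
  n <- 6L
  # state: methyl bits m1..m6 (code 0..63), rloc, bloc in 0 (bulk) or 1..6,
  # rloc != bloc unless both 0
  enc <- function(code, r, b) code * 49L + r * 7L + b + 1L
  ns <- 64L * 49L
  valid <- rep(TRUE, ns)
  trans <- list(); nt <- 0L
  add <- function(i, j, rate) {
    nt <<- nt + 1L; trans[[nt]] <<- c(i, j, rate)
  }
  act <- function(code) {
    mwc_activity(sum(bitwAnd(bitwShiftR(code, 0:5), 1L)), L, mwc)
  }
  for (code in 0:63) {
    a <- act(code)
    mbit <- bitwAnd(bitwShiftR(code, 0:5), 1L)
    for (r in 0:6) for (b in 0:6) {
      if (r > 0 && r == b) { valid[enc(code, r, b)] <- FALSE; next }
      i <- enc(code, r, b)
      if (r == 0) {           # CheR in bulk: bind any free modsite
        for (d in 1:6) if (d != b)
          add(i, enc(code, d, b), rates$k_m_bind_bulk_r * (1 - a) / 6)
      } else {
        add(i, enc(code, 0L, b), rates$k_m_unbind_r)
        if (mbit[r] == 0)     # methylate dimer r, release
          add(i, enc(code + bitwShiftL(1L, r - 1L), 0L, b), rates$k_cat_r)
      }
      if (b == 0) {
        for (d in 1:6) if (d != r)
          add(i, enc(code, r, d), rates$k_m_bind_bulk_b * a / 6)
      } else {
        add(i, enc(code, r, 0L), rates$k_m_unbind_b)
        if (mbit[b] == 1)     # demethylate dimer b, release
          add(i, enc(code - bitwShiftL(1L, b - 1L), r, 0L), rates$k_cat_b)
      }
    }
  }
  Q <- matrix(0, ns, ns)
  for (k in seq_len(nt)) {
    tr <- trans[[k]]
    Q[tr[1], tr[2]] <- Q[tr[1], tr[2]] + tr[3]
  }
  keep <- which(valid)
  Q <- Q[keep, keep]
  diag(Q) <- -rowSums(Q)
  pi <- ctmc_stationary(Q)
  decode <- data.frame(
    code = (keep - 1L) %/% 49L,
    r = ((keep - 1L) %% 49L) %/% 7L,
    b = (keep - 1L) %% 7L)
  decode$m_total <- vapply(decode$code, function(cd)
    sum(bitwAnd(bitwShiftR(cd, 0:5), 1L)), numeric(1))
  list(pi = pi, states = decode)
}

# initial state for the two-enzyme micro-model (one CheR, one CheB-P, all
# bulk, phosphorylation frozen by a_p = d_p = 0)
micro_init <- function(methyl) {
  list(methyl = as.integer(methyl), species = c(0L, 1L), phos = c(1L, 1L),
       teth0 = c(-1L, -1L), mod0 = c(-1L, -1L))
}
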