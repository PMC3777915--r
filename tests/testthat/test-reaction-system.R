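test_that("enzyme and receptor bookkeeping is conserved under random kinetics", {
  lat <- tiny_lattice()
  set.seed(99)
  for (rep in 1:5) {
    r <- rate_set(
      k_t_bind_r = runif(1, 0.05, 2), k_t_bind_b = runif(1, 0.05, 2),
      k_t_unbind_r = runif(1, 0.1, 5), k_t_unbind_b = runif(1, 0.1, 5),
      k_m_bind_local_r = runif(1, 5, 200), k_m_bind_local_b = runif(1, 5, 200),
      k_t_bind_local_r = runif(1, 5, 200), k_t_bind_local_b = runif(1, 5, 200),
      k_m_unbind_r = runif(1, 1, 20), k_m_unbind_b = runif(1, 1, 20),
      k_cat_r = runif(1, 0.5, 5), k_cat_b = runif(1, 0.5, 5),
      a_p = runif(1, 0.5, 3), d_p = runif(1, 0.5, 3))
    cp <- list(cheR = 3L, cheB = 5L, dimers = lat$n_dimers)
    tr <- simulate_lattice(lat, r, cp, duration = 60, seed = 1000 + rep,
                           init_methyl = sample(0:8, 1))
    fin <- attr(tr, "final_state")
    # methylation within bounds after an arbitrary event stream
    expect_true(all(fin$methyl >= 0 & fin$methyl <= 8))
    # species conservation (the engine also audits internally every run)
    expect_equal(sum(fin$species == 0), 3)
    expect_equal(sum(fin$species == 1), 5)
    # site exclusivity: each occupied site names a single enzyme
    teth <- fin$teth0[fin$teth0 >= 0]
    mod <- fin$mod0[fin$mod0 >= 0]
    expect_equal(anyDuplicated(teth), 0)
    expect_equal(anyDuplicated(mod), 0)
    # unphosphorylated CheB never on the lattice
    onlat <- fin$teth0 >= 0 | fin$mod0 >= 0
    expect_true(all(fin$phos[fin$species == 1 & onlat] == 1))
    # localized counts in the trace consistent with pools
    expect_true(all(tr$loc_cheR + tr$loc_cheBp >= 0))
    expect_true(all(tr$bulk_cheBp >= 0 & tr$bulk_cheB >= 0))
  }
})

test_that("M2 disables neighbor moves: one dimer per residence", {
  lat <- tiny_lattice()
  r <- rate_set(variant = "M2")
  expect_false(r$neighbor_binding)
  cp <- list(cheR = 2L, cheB = 3L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, r, cp, duration = 300, seed = 7,
                         log_contacts = TRUE)
  log <- attr(tr, "contacts")
  # between a localization (kind 1) and a return to bulk (kind 2), an M2
  # enzyme contacts exactly one distinct dimer
  for (e in unique(log$enzyme)) {
    le <- log[log$enzyme == e, ]
    res <- 0; seen <- integer(0)
    for (i in seq_len(nrow(le))) {
      if (le$kind[i] == 1) seen <- integer(0)
      else if (le$kind[i] == 0) seen <- union(seen, le$dimer[i])
      else if (le$kind[i] == 2) expect_length(seen, 1)
    }
  }
  # and the doubly bound state never spans two dimers
  pr <- processivity_rate(tr)
  expect_true(all(pr$visits >= 0))
})

test_that("catalysis respects the 0..8 bounds and frees the modification site", {
  lat <- tiny_lattice()
  # CheR only, starting fully methylated: no catalysis possible, methylation
  # frozen at the ceiling
  r <- rate_set()
  cp <- list(cheR = 4L, cheB = 0L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, r, cp, duration = 100, seed = 3,
                         init_methyl = 8L)
  fin <- attr(tr, "final_state")
  expect_true(all(fin$methyl == 8))
  expect_equal(unname(attr(tr, "event_counts")[["catalysis"]]), 0)
  expect_true(all(tr$m_mean == 48))
  # CheB-P only, starting fully demethylated: inert but still occupying sites
  r2 <- rate_set(a_p = 5, d_p = 0.01)  # keep CheB phosphorylated
  cp2 <- list(cheR = 0L, cheB = 4L, dimers = lat$n_dimers)
  tr2 <- simulate_lattice(lat, r2, cp2, duration = 100, seed = 3,
                          init_methyl = 0L)
  expect_equal(unname(attr(tr2, "event_counts")[["catalysis"]]), 0)
  expect_true(all(tr2$m_mean == 0))
  # localized CheB-P in a fully demethylated lattice is flagged inert
  expect_true(any(tr2$loc_cheBp > 0))
  expect_true(all(tr2$loc_cheBp_active == 0))
})

test_that("activity weighting shuts CheR binding as complexes saturate", {
  # fully methylated lattice at L = 0: every complex near a = 1, so the
  # CheR modification-site binding weight (1 - a) is ~ 0 while tether
  # binding is unaffected
  lat <- tiny_lattice()
  r <- rate_set(k_m_bind_bulk_r = 10, k_t_bind_r = 0)
  cp <- list(cheR = 5L, cheB = 0L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, r, cp, duration = 50, seed = 5,
                         init_methyl = 8L)
  ec <- attr(tr, "event_counts")
  w <- 1 - mwc_activity(48, 0, mwc_params())  # ~ 4e-19
  expect_equal(unname(ec[["bulk_mod_bind_R"]]), 0)
  # same setup fully demethylated: binding proceeds at full weight
  tr2 <- simulate_lattice(lat, r, cp, duration = 50, seed = 5,
                          init_methyl = 0L)
  expect_gt(unname(attr(tr2, "event_counts")[["bulk_mod_bind_R"]]), 10)
})

test_that("zero enzymes leave the lattice silent", {
  lat <- tiny_lattice()
  cp <- list(cheR = 0L, cheB = 0L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, rate_set(), cp, duration = 30, seed = 1)
  expect_true(all(tr$a_mean == tr$a_mean[1]))
  expect_equal(unname(attr(tr, "n_events")), 0)
})

test_that("mean trace activity equals the from-scratch lattice average", {
  lat <- tiny_lattice()
  cp <- list(cheR = 3L, cheB = 5L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, rate_set(), cp, duration = 40, seed = 21)
  fin <- attr(tr, "final_state")
  act <- lattice_activity(fin$methyl, lat, mwc_params(), L = 0)
  expect_equal(tr$a_mean[nrow(tr)], act$mean, tolerance = 1e-12)
  # anchor: complexes at m_total = 6 give exactly 1/2
  expect_equal(tr$a_mean[1], 0.5)
})
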