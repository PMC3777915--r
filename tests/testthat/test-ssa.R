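test_that("identical seeds give bit-identical traces", {
  lat <- small_lattice()
  cp <- copy_numbers(lat)
  tr1 <- simulate_lattice(lat, rate_set(), cp, duration = 80, seed = 42)
  tr2 <- simulate_lattice(lat, rate_set(), cp, duration = 80, seed = 42)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  tr3 <- simulate_lattice(lat, rate_set(), cp, duration = 80, seed = 43)
  expect_false(identical(tr1$a_mean, tr3$a_mean))
})

test_that("tether exchange waiting times match their exponential rates", {
  # single CheR, modification-site binding disabled: pure bulk <-> tether
  # hopping, so residence and waiting times are exponential with the
  # configured rates
  lat <- tiny_lattice()
  r <- rate_set(k_m_bind_local_r = 0, k_m_bind_bulk_r = 0,
                k_t_bind_r = 0.5, k_t_unbind_r = 1.25)
  cp <- list(cheR = 1L, cheB = 0L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, r, cp, duration = 4000, seed = 9,
                         log_contacts = TRUE)
  log <- attr(tr, "contacts")
  tl <- log$time[log$kind == 1]   # localization times
  td <- log$time[log$kind == 2]   # delocalization times
  n <- min(length(tl), length(td))
  expect_gt(n, 300)
  res <- td[seq_len(n)] - tl[seq_len(n)]       # tether residences
  wait <- tl[-1][seq_len(n - 1)] - td[seq_len(n - 1)]  # bulk waits
  expect_equal(mean(res), 1 / 1.25, tolerance = 4 / sqrt(n))
  expect_equal(mean(wait), 1 / 0.5, tolerance = 4 / sqrt(n))
})

test_that("occupancy statistics of one CheR match the exact CTMC", {
  # frozen methylation (no catalysis), full M1 rule set on an 18-dimer
  # lattice: the enzyme's position chain is exactly enumerable
  lat <- tiny_lattice()
  mwc <- mwc_params()
  r <- rate_set(k_t_bind_r = 0.5, k_t_unbind_r = 1.0,
                k_m_bind_bulk_r = 0.3, k_m_bind_local_r = 6,
                k_t_bind_local_r = 6, k_m_unbind_r = 3, k_cat_r = 0)
  # heterogeneous frozen methylation: three complexes at different activity
  methyl <- rep(c(0L, 1L, 3L), each = 6)[order(rep(1:3, 6))]
  methyl <- integer(18)
  for (cx in 1:3) methyl[lat$complexes[cx, ]] <- c(0L, 1L, 3L)[cx]
  oracle <- occupancy_ctmc(lat, r, mwc, methyl)
  # aggregate to state-type x complex classes
  cls_exact <- c(bulk = oracle$pi[1])
  st <- oracle$states
  for (cx in 1:3) {
    dset <- lat$complexes[cx, ]
    cls_exact[paste0("teth", cx)] <-
      sum(oracle$pi[st$type == "teth" & st$teth %in% dset])
    cls_exact[paste0("mod", cx)] <-
      sum(oracle$pi[st$type == "mod" & st$mod %in% dset])
    cls_exact[paste0("both", cx)] <-
      sum(oracle$pi[st$type == "both" & st$mod %in% dset])
  }
  expect_equal(sum(cls_exact), 1, tolerance = 1e-9)
  # sample stationary states from independent short runs
  nrun <- 600
  cp <- list(cheR = 1L, cheB = 0L, dimers = lat$n_dimers)
  counts <- setNames(numeric(length(cls_exact)), names(cls_exact))
  for (k in seq_len(nrun)) {
    tr <- simulate_lattice(lat, r, cp, duration = 40, seed = 5000 + k,
                           init_methyl = methyl, record_dt = 40)
    fin <- attr(tr, "final_state")
    teth <- fin$teth0[1] + 1L; mod <- fin$mod0[1] + 1L
    cls <- if (teth == 0 && mod == 0) "bulk"
      else if (mod == 0) paste0("teth", lat$complex_of[teth])
      else if (teth == 0) paste0("mod", lat$complex_of[mod])
      else paste0("both", lat$complex_of[mod])
    counts[cls] <- counts[cls] + 1
  }
  phat <- counts / nrun
  # chi-square distance against the exact distribution
  keep <- cls_exact > 1e-4
  chi2 <- sum((counts[keep] - nrun * cls_exact[keep])^2 /
                (nrun * cls_exact[keep]))
  expect_lt(chi2, qchisq(0.9999, df = sum(keep) - 1))
  # and total variation is small
  expect_lt(0.5 * sum(abs(phat - cls_exact)), 0.08)
})

test_that("joint methylation-occupancy law matches the exact CTMC (micro B1)", {
  # one CheR and one CheB-P on a single 6-dimer complex, methylation capped
  # at one group per dimer: the full (methylation, occupancy) chain is
  # enumerable and the SSA must reproduce its stationary law
  geom <- single_complex_geometry()
  mwc <- micro_mwc()
  r <- b1_micro_rates()
  oracle <- b1_micro_ctmc(mwc = mwc, rates = r)
  exact_m <- vapply(0:6, function(k)
    sum(oracle$pi[oracle$states$m_total == k]), numeric(1))
  exact_occ <- vapply(0:3, function(k) {
    rb <- (oracle$states$r > 0) + 2 * (oracle$states$b > 0)
    sum(oracle$pi[rb == k])
  }, numeric(1))
  nrun <- 600
  cm <- numeric(7); cocc <- numeric(4)
  for (k in seq_len(nrun)) {
    tr <- simulate_lattice(geom, r, list(cheR = 1L, cheB = 1L, dimers = 6L),
                           duration = 60, seed = 9000 + k, record_dt = 60,
                           mwc = mwc, init_state = micro_init(rep(0L, 6)))
    fin <- attr(tr, "final_state")
    mt <- sum(fin$methyl)
    cm[mt + 1] <- cm[mt + 1] + 1
    occ <- (fin$mod0[1] >= 0) + 2 * (fin$mod0[2] >= 0)
    cocc[occ + 1] <- cocc[occ + 1] + 1
  }
  keep <- exact_m > 1e-4
  chi2_m <- sum((cm[keep] - nrun * exact_m[keep])^2 / (nrun * exact_m[keep]))
  expect_lt(chi2_m, qchisq(0.9999, df = sum(keep) - 1))
  chi2_o <- sum((cocc - nrun * exact_occ)^2 / (nrun * exact_occ))
  expect_lt(chi2_o, qchisq(0.9999, df = 3))
})

test_that("stationary activity is independent of the initial methylation", {
  lat <- small_lattice()
  cp <- copy_numbers(lat)
  a0s <- sapply(c(0L, 8L), function(m0) {
    eq <- equilibrate_lattice(lat, rate_set(), cp, burn_in = 600,
                              duration = 600, seed = 31, init_methyl = m0)
    noise_stats(eq$trace)$a0
  })
  # small lattice, few enzymes: generous Monte-Carlo tolerance
  expect_lt(abs(a0s[1] - a0s[2]), 0.12)
})

test_that("equilibrate chains engine state and flags a zero burn-in", {
  lat <- tiny_lattice()
  cp <- list(cheR = 2L, cheB = 4L, dimers = lat$n_dimers)
  eq <- equilibrate_lattice(lat, rate_set(), cp, burn_in = 100,
                            duration = 50, seed = 12)
  expect_s3_class(eq$trace, "lattice_trace")
  expect_false(is.null(eq$state))
  # the recorded trace starts from the equilibrated state, not the anchor
  expect_false(isTRUE(all.equal(eq$trace$a_mean[1], 0.5)))
  expect_warning(
    equilibrate_lattice(lat, rate_set(), cp, burn_in = 0, duration = 20,
                        seed = 12),
    "burn_in")
})
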