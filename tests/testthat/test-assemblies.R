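test_that("component counting matches planted rank under both null models", {
  # i.i.d. noise: ~0 components (both the shift-surrogate and the analytic
  # Marchenko-Pastur bound)
  for (s in 1:3) {
    set.seed(s)
    z <- zscore_traces(matrix(rnorm(100 * 5000), 100))
    expect_lte(select_significant_pcs(z, seed = s), 1)
    expect_lte(select_significant_pcs(z, method = "marchenko_pastur"), 1)
  }
  # five planted strongly co-activating assemblies: exactly 5
  z5 <- planted_z(default_assemblies(60, 5, 10), 60, 4000, seed = 6)
  expect_equal(select_significant_pcs(z5), 5)
  # a duplicated neuron with no other structure: at least 1 component
  set.seed(5)
  x <- matrix(rnorm(10 * 2000), 10)
  x <- rbind(x, x[1, ] + rnorm(2000, sd = 0.01))
  expect_gte(select_significant_pcs(zscore_traces(x)), 1)
})

test_that("Promax rotation recovers planted memberships including overlap", {
  z <- planted_z(list(1:8, 9:16), 24, 2000, seed = 3)
  mod <- promax_assemblies(z, 2)
  got <- lapply(mod$memberships, as.integer)
  expect_setequal(got[order(vapply(got, min, 1L))][[1]], 1:8)
  expect_setequal(got[order(vapply(got, min, 1L))][[2]], 9:16)
  # a neuron planted in two assemblies appears in both memberships
  z2 <- planted_z(list(1:8, 8:15), 24, 2000, seed = 4)
  mod2 <- promax_assemblies(z2, 2)
  expect_true(all(vapply(mod2$memberships, function(m) 8L %in% m, logical(1))))
  # z_max override above all loadings: empty memberships, flagged
  expect_warning(mod3 <- promax_assemblies(z, 2, z_max = 100), "empty")
  expect_true(all(lengths(mod3$memberships) == 0))
})

test_that("assembly merging follows the normalized indicator dot product", {
  mk <- function(mems) structure(
    list(memberships = mems, loadings = NULL, z_max = 1, n_pcs = length(mems),
         merge_log = tibble::tibble(a = integer(), b = integer(),
                                    dot = numeric()),
         synchrony_p = rep(NA_real_, length(mems)), n_neurons = 50),
    class = "ca_assemblies")
  # identical memberships: dot 1, merged to one
  m1 <- merge_assemblies(mk(list(1:5, 1:5)))
  expect_length(m1$memberships, 1)
  expect_equal(m1$merge_log$dot, 1)
  # disjoint: dot 0, unchanged
  m2 <- merge_assemblies(mk(list(1:5, 6:10)))
  expect_length(m2$memberships, 2)
  # sizes 9 and 16 sharing 3: dot 3/sqrt(9*16) = 0.25, not merged
  a <- 1:9; b <- c(7:9, 10:22)
  expect_equal(catraces:::membership_dot(a, b), 0.25)
  m3 <- merge_assemblies(mk(list(a, b)))
  expect_length(m3$memberships, 2)
  # lowering the threshold never increases the assembly count
  mems <- list(1:10, 6:15, 20:29, 25:34)
  counts <- vapply(c(0.9, 0.6, 0.3, 0.1), function(th)
    length(merge_assemblies(mk(mems), th)$memberships), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("circular-shift surrogates certify joint firing and do not over-reject independence", {
  # members that fire only jointly: p at the resolution floor
  spikes <- matrix(FALSE, 6, 2000)
  joint <- c(100, 500, 900, 1300, 1700)
  spikes[, joint] <- TRUE
  mk <- function(n) structure(
    list(memberships = list(seq_len(n)), loadings = NULL, z_max = 1, n_pcs = 1,
         merge_log = tibble::tibble(), synchrony_p = NA_real_, n_neurons = n),
    class = "ca_assemblies")
  mod <- test_assembly_synchrony(mk(6), spikes, n_surrogates = 500, seed = 2)
  expect_length(mod$memberships, 1)
  expect_lte(mod$synchrony_p, 1 / 501)
  # determinism
  mod_b <- test_assembly_synchrony(mk(6), spikes, n_surrogates = 500, seed = 2)
  expect_identical(mod$synchrony_p, mod_b$synchrony_p)
  # independent members: valid test, rejection rate at or below nominal
  set.seed(7)
  ps <- vapply(1:40, function(r) {
    sp <- matrix(runif(8 * 3000) < 0.005, 8, 3000)
    m <- test_assembly_synchrony(mk(8), sp, n_surrogates = 200, seed = r)
    if (length(m$synchrony_p)) m$synchrony_p else m$dropped$synchrony_p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))
})

test_that("the matching index is the fraction of co-active members", {
  active <- matrix(FALSE, 10, 4)
  active[1:10, 2] <- TRUE          # all members active
  active[1:5, 3] <- TRUE           # half active
  mi <- matching_index_series(active, list(1:10))
  expect_equal(mi[1, ], c(0, 1, 0.5, 0))
  # invariant under permutation of non-member neurons
  active2 <- matrix(runif(20 * 50) < 0.3, 20, 50)
  mi_a <- matching_index_series(active2, list(1:8))
  perm <- c(1:8, sample(9:20))
  mi_b <- matching_index_series(active2[perm, ], list(1:8))
  expect_equal(mi_a, mi_b)
  # jaccard variant bounded by the proportion variant
  mi_j <- matching_index_series(active2, list(1:8), method = "jaccard")
  expect_true(all(mi_j <= mi_a + 1e-12))
})

test_that("hypergeometric activation significance matches exact enumeration and is valid under the null", {
  # no active members: p = 1
  act <- matrix(FALSE, 20, 3)
  sig0 <- activation_significance(act, list(1:5))
  expect_equal(sig0$p[1, ], rep(1, 3))
  # all m = 10 active neurons inside a 10-member assembly of N = 100
  act1 <- matrix(FALSE, 100, 1); act1[1:10, 1] <- TRUE
  sig1 <- activation_significance(act1, list(1:10))
  expect_equal(sig1$p[1, 1], 1 / choose(100, 10), tolerance = 1e-12)
  expect_true(sig1$significant[1, 1])
  # exact tail equals brute-force enumeration for N <= 30
  for (N in c(12, 20, 30)) for (K in c(4, 7)) for (m in c(3, 8)) {
    act_nm <- matrix(FALSE, N, 1); act_nm[seq_len(m), 1] <- TRUE
    # enumeration oracle over the overlap count j
    for (k in 1:min(K, m)) {
      js <- k:min(K, m)
      tail_enum <- sum(choose(K, js) * choose(N - K, m - js)) / choose(N, m)
      expect_equal(phyper(k - 1, K, N - K, m, lower.tail = FALSE), tail_enum,
                   tolerance = 1e-12)
    }
  }
  # null: empirical significant fraction matches the attainable discrete
  # rejection rate and never exceeds the nominal level
  N <- 100; K <- 10; p_act <- 0.3
  set.seed(42)
  act_null <- matrix(runif(N * 20000) < p_act, N, 20000)
  frac <- mean(activation_significance(act_null, list(1:K))$significant)
  ms <- 0:N
  rej <- vapply(ms, function(m) {
    tails <- phyper((0:min(K, m)) - 1, K, N - K, m, lower.tail = FALSE)
    ok <- tails[tails < 0.05]
    if (length(ok)) max(ok) else 0
  }, numeric(1))
  expected <- sum(dbinom(ms, N, p_act) * rej)
  expect_lte(frac, 0.05)
  expect_lt(abs(frac - expected), 0.01)
})

test_that("assembly-assembly correlations separate co-activating from independent assemblies", {
  set.seed(11)
  n_frames <- 4000
  active <- matrix(runif(30 * n_frames) < 0.01, 30, n_frames)
  ev_a <- sample.int(n_frames, 60)
  co <- runif(60) < 0.8
  ev_b_shared <- ev_a[co]
  ev_b <- c(ev_b_shared, sample.int(n_frames, 60 - length(ev_b_shared)))
  ev_c <- sample.int(n_frames, 60)
  active[1:8, ev_a] <- TRUE
  active[9:16, ev_b] <- TRUE
  active[17:24, ev_c] <- TRUE
  acts <- assembly_activation(active, list(1:8, 9:16, 17:24),
                              frame_rate_hz = 12.5)
  res <- assembly_assembly_correlation(acts, n_iterations = 300, seed = 5)
  r_ab <- res$pairs$r[res$pairs$i == 1 & res$pairs$j == 2]
  r_ac <- res$pairs$r[res$pairs$i == 1 & res$pairs$j == 3]
  expect_gt(r_ab, 0.5)
  expect_true(res$pairs$significant[res$pairs$i == 1 & res$pairs$j == 2])
  expect_lt(abs(r_ac), 0.1)
  # identical activation series: r = 1
  acts_dup <- assembly_activation(active, list(1:8, 1:8), frame_rate_hz = 12.5)
  res_dup <- assembly_assembly_correlation(acts_dup, n_iterations = 200, seed = 6)
  expect_equal(res_dup$pairs$r, 1, tolerance = 1e-10)
})

test_that("assembly-speed correlation flags movement-locked assemblies and degenerate speed", {
  set.seed(12)
  n_frames <- 4000
  moving <- rep(FALSE, n_frames)
  for (st in seq(200, 3800, by = 500)) moving[st:(st + 100)] <- TRUE
  active <- matrix(runif(20 * n_frames) < 0.01, 20, n_frames)
  ev <- sample(which(moving), 80)   # assembly activates only while moving
  active[1:8, ev] <- TRUE
  acts <- assembly_activation(active, list(1:8), frame_rate_hz = 12.5)
  speed <- ifelse(moving, 60, 5) + rnorm(n_frames)
  res <- assembly_speed_correlation(acts, speed, n_iterations = 300, seed = 2)
  expect_gt(res$r[1], 0)
  expect_true(res$significant[1])
  expect_warning(res0 <- assembly_speed_correlation(acts, rep(5, n_frames)),
                 "Constant speed")
  expect_true(all(is.na(res0$r)))
})

test_that("end-to-end detection recovers planted assemblies from raw fluorescence", {
  for (s in c(7, 21)) {
    gt <- ground_truth(seed = s)   # study conditions: 100 neurons, 5 x 10
    rec <- simulate_population(gt)
    dff <- preprocess_traces(rec)
    z <- zscore_traces(dff)
    ras <- detect_transients(dff, estimate_noise(dff))
    mod <- find_assemblies(z, ras, seed = s)
    expect_equal(length(mod$memberships), 5)
    expect_gte(mean(best_match_jaccard(gt$assembly_memberships,
                                       mod$memberships)), 0.8)
    expect_true(all(mod$synchrony_p < 0.05))
    expect_true(all(lengths(mod$memberships) >= 2))
  }
})
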