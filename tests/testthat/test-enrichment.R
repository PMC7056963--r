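toy_ranked <- function() {
  make_ranked(c(G1 = 3, G2 = 2, G3 = 1, G4 = -1, G5 = -2))
}

test_that("compute_es reproduces hand-enumerated walks", {
  rk <- toy_ranked()
  # NR = |3| + |1| = 4; walk: 0.75, 0.41667, 0.66667, 0.33333, 0
  expect_identical(compute_es(rk, c("G1", "G3")), 0.75)
  # all hits at the bottom: walk descends to -1 then returns; max excursion
  # before the terminal zero is the first step
  expect_identical(compute_es(rk, "G5"), -0.25)
  # a single hit at the very top attains the ES upper bound of 1
  expect_identical(compute_es(rk, "G1"), 1)
})

test_that("compute_es agrees with the brute-force prefix walk on random instances", {
  set.seed(41)
  for (rep in 1:60) {
    N <- sample(5:50, 1)
    k <- sample(1:(N - 1), 1)
    stats <- rnorm(N)
    names(stats) <- sprintf("G%03d", 1:N)
    rk <- make_ranked(stats)
    members <- sample(names(stats), k)
    w <- sample(c(0, 0.5, 1, 2), 1)
    if (w == 0 || sum(abs(rk$stats[rk$genes %in% members])) > 0) {
      expect_equal(compute_es(rk, members, w),
                   brute_es(rk$stats, rk$genes %in% members, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("w = 0 reduces to the classic unweighted KS-like statistic", {
  set.seed(43)
  for (rep in 1:20) {
    N <- sample(10:60, 1)
    stats <- rnorm(N); names(stats) <- sprintf("G%03d", 1:N)
    rk <- make_ranked(stats)
    members <- sample(names(stats), sample(2:5, 1))
    expect_equal(compute_es(rk, members, w = 0),
                 brute_es_unweighted(rk$genes %in% members),
                 tolerance = 1e-12)
  }
})

test_that("the running sum is conserved and bounds the score", {
  set.seed(47)
  rk <- toy_ranked()
  expect_equal(running_sum(rk, c("G1", "G3")),
               c(0.75, 0.75 - 1/3, 0.75 - 1/3 + 0.25, 0.75 - 2/3 + 0.25, 0),
               tolerance = 1e-12)
  for (rep in 1:50) {
    N <- sample(10:200, 1)
    stats <- rnorm(N); names(stats) <- sprintf("G%04d", 1:N)
    rk <- make_ranked(stats)
    members <- sample(names(stats), sample(1:(N - 1), 1))
    rs <- running_sum(rk, members)
    expect_lt(abs(rs[N]), 1e-9)
    es <- compute_es(rk, members)
    expect_equal(es, max(rs[-N]), tolerance = 1e-12)
    expect_lte(es, 1)
    expect_gt(es, -1)
  }
})

test_that("scale invariance at w = 1: rescaling statistics leaves ES unchanged", {
  set.seed(53)
  stats <- rnorm(40); names(stats) <- sprintf("G%03d", 1:40)
  members <- sample(names(stats), 6)
  es1 <- compute_es(make_ranked(stats), members, w = 1)
  es2 <- compute_es(make_ranked(stats * 13.7), members, w = 1)
  expect_equal(es1, es2, tolerance = 1e-12)
})

test_that("degenerate sets and weights raise classed errors", {
  rk <- toy_ranked()
  expect_error(compute_es(rk, "NOT_THERE"), class = "cgsea_degenerate_set_error")
  expect_error(compute_es(rk, paste0("G", 1:5)),
               class = "cgsea_degenerate_set_error")
  rk0 <- make_ranked(c(A = 1, B = 0, C = -1))
  expect_error(compute_es(rk0, "B", w = 1),
               class = "cgsea_degenerate_weight_error")
  expect_error(compute_es(rk, "G1", w = -1), class = "cgsea_config_error")
})

test_that("normalize_es standardizes against the null", {
  # sample SD of [0.1, 0.3] is 0.1414214; (0.4 - 0.2) / 0.1414214
  nm <- normalize_es(0.4, c(0.1, 0.3))
  expect_equal(nm$nes_obs, sqrt(2), tolerance = 1e-6)
  expect_equal(nm$nes_obs, 1.414214, tolerance = 1e-6)

  # centering identity
  expect_equal(normalize_es(0.2, c(0.1, 0.3))$nes_obs, 0)

  # standardized null has mean 0, sd 1
  set.seed(59)
  null <- rnorm(100, 0.3, 0.2)
  nm2 <- normalize_es(0.9, null)
  expect_equal(mean(nm2$nes_null), 0, tolerance = 1e-12)
  expect_equal(sd(nm2$nes_null), 1, tolerance = 1e-12)

  # affine invariance: a*x + b (a > 0) leaves NES unchanged
  a <- 3.2; b <- -0.7
  nm3 <- normalize_es(a * 0.9 + b, a * null + b)
  expect_equal(nm3$nes_obs, nm2$nes_obs, tolerance = 1e-9)

  expect_error(normalize_es(0.5, rep(0.2, 10)),
               class = "cgsea_degenerate_null_error")
  expect_error(normalize_es(0.5, 0.2), class = "cgsea_config_error")
})

test_that("empirical_p uses the add-one upper-tail convention", {
  expect_equal(empirical_p(2.0, c(0.5, 1.0, 1.5)), 0.25)
  expect_equal(empirical_p(0.4, c(0.5, 1.0, 1.5)), 1)     # saturates at 1
  expect_equal(empirical_p(1.0, c(0.5, 1.0, 1.5)), 0.75)  # ties count
  set.seed(61)
  null <- rnorm(200)
  p <- empirical_p(rnorm(1), null)
  expect_gte(p, 1 / 201)
  expect_lte(p, 1)
})

test_that("bh_fdr matches textbook BH arithmetic and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)                      # m = 1 identity
  set.seed(67)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_fdr(c(0.5, 0)), class = "cgsea_input_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "cgsea_input_error")
})

test_that("permute_null is seed-reproducible and supports per-set shuffles", {
  set.seed(71)
  stats <- rnorm(30); names(stats) <- sprintf("G%03d", 1:30)
  rk <- make_ranked(stats)
  rec <- data.frame(chemical_name = rep(c("a", "b"), each = 4),
                    chemical_id = rep(c("DA", "DB"), each = 4),
                    gene_symbol = c(sample(names(stats), 4),
                                    sample(names(stats), 4)),
                    gene_id = "", organism_id = "9606",
                    interaction_actions = "x")
  sets <- build_gene_sets(rec, min_size = 1)

  cfg <- cgsea_config(permutations = 25, seed = 9)
  m1 <- permute_null(rk, sets, cfg)
  m2 <- permute_null(rk, sets, cfg)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(25L, 2L))
  expect_identical(colnames(m1), c("DA", "DB"))

  m3 <- permute_null(rk, sets, cgsea_config(permutations = 25, seed = 10))
  expect_false(identical(m1, m3))

  ps <- permute_null(rk, sets,
                     cgsea_config(permutations = 25, seed = 9,
                                  per_set_null = TRUE))
  expect_identical(dim(ps), dim(m1))
  expect_error(cgsea_config(permutations = 0), class = "cgsea_config_error")
})

test_that("the permutation null matches exhaustive enumeration over member positions", {
  # N = 5 universe, set of 2: the null ES depends only on which 2 of the 5
  # positions the members occupy, so full enumeration over the 10 position
  # pairs gives the exact null mean.
  stats <- c(A = 3, B = 2, C = 1, D = -1, E = -2)
  rk <- make_ranked(stats)
  enum <- apply(utils::combn(5, 2), 2, function(pos) {
    mask <- seq_len(5) %in% pos
    brute_es(rk$stats, mask, w = 1)
  })
  exact_mean <- mean(enum)

  rec <- data.frame(chemical_name = "a", chemical_id = "DA",
                    gene_symbol = c("A", "D"), gene_id = "",
                    organism_id = "9606", interaction_actions = "x")
  sets <- build_gene_sets(rec, min_size = 1)
  mc <- permute_null(rk, sets, cgsea_config(permutations = 20000, seed = 3))
  se <- sd(enum) / sqrt(20000)
  expect_lt(abs(mean(mc) - exact_mean), 3 * se)
  # every Monte-Carlo draw must be one of the 10 enumerated values
  expect_true(all(vapply(mc[, 1],
                         function(v) any(abs(v - enum) < 1e-12), logical(1))))

  # exchangeable case: all |stats| equal, so the null support again comes
  # only from member positions and must match enumeration exactly
  stats_eq <- c(A = 1, B = 1, C = 1, D = -1, E = -1)
  rk_eq <- make_ranked(stats_eq)
  enum_eq <- apply(utils::combn(5, 2), 2, function(pos) {
    brute_es(rk_eq$stats, seq_len(5) %in% pos, w = 1)
  })
  mc_eq <- permute_null(rk_eq, sets,
                        cgsea_config(permutations = 5000, seed = 5))
  expect_true(all(vapply(mc_eq[, 1],
                         function(v) any(abs(v - enum_eq) < 1e-12),
                         logical(1))))
  expect_lt(abs(mean(mc_eq) - mean(enum_eq)),
            3 * sd(enum_eq) / sqrt(5000) + 1e-12)
})
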