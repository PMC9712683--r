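test_that("GAAC computes five group frequencies", {
  expect_equal(unname(encode_gaac("AAAAA")), c(1, 0, 0, 0, 0))
  expect_equal(unname(encode_gaac("DE")), c(0, 1, 0, 0, 0))
  expect_equal(unname(encode_gaac("ADFHC")), rep(0.2, 5))
  expect_error(encode_gaac(""), "empty")

  set.seed(21)
  for (i in 1:25) {
    s <- random_sequence(sample(5:80, 1))
    v <- encode_gaac(s)
    expect_equal(unname(v), unname(oracle_gaac(s)), tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("DPC computes 400 dipeptide frequencies summing to one", {
  v <- encode_dpc("AAA")
  expect_length(v, 400)
  expect_equal(unname(v["DPC.AA"]), 1)
  expect_equal(sum(v), 1)

  v <- encode_dpc("ACAC")
  expect_equal(unname(v["DPC.AC"]), 2 / 3)
  expect_equal(unname(v["DPC.CA"]), 1 / 3)
  expect_equal(sum(v != 0), 2)

  expect_error(encode_dpc("M"), "too short")

  set.seed(22)
  s <- random_sequence(50)
  v <- encode_dpc(s)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  for (dp in sample(names(v), 8)) {
    expect_equal(unname(v[dp]) * 49,
                 oracle_dpc_count(s, sub("^DPC\\.", "", dp)))
  }
})

test_that("slice composition is the per-column mean of the slice", {
  rows <- matrix(rep(seq(0.05, 1, length.out = 20), each = 6), nrow = 6,
                 byrow = FALSE)
  p <- pssm(rows, rep("A", 6), "c", normalized = TRUE)
  plan <- plan_partition(6, "slice")
  expect_equal(unname(slice_composition(p, plan, 1)), rows[1, ])

  two <- matrix(0.4, nrow = 6, ncol = 20)
  two[1, 3] <- 0.2; two[2, 3] <- 0.6
  p2 <- pssm(two, rep("A", 6), "c2", normalized = TRUE)
  expect_equal(unname(slice_composition(p2, plan, 1))[3], 0.4)

  set.seed(23)
  p3 <- random_norm_pssm(21)
  plan3 <- plan_partition(21, "slice")
  part <- p3$scores[15:21, ]
  expect_equal(unname(slice_composition(p3, plan3, 3)),
               unname(apply(part, 2, mean)), tolerance = 1e-12)
})

test_that("pseudo correlation factors match hand evaluation", {
  const <- matrix(0.7, nrow = 5, ncol = 20)
  expect_equal(unname(pse_correlation(const, 1)), rep(0, 20))

  alt <- matrix(rep(c(0, 1, 0, 1), 20), ncol = 20)
  expect_equal(unname(pse_correlation(alt, 1)), rep(1, 20))
  expect_equal(unname(pse_correlation(alt, 2)), rep(0, 20))
  expect_error(pse_correlation(alt, 4), "rank exceeds")
})

test_that("segment autocovariance matches hand evaluation", {
  const <- pssm(matrix(0.3, nrow = 9, ncol = 20), rep("A", 9), "c",
                normalized = TRUE)
  plan <- plan_partition(9, "segment")
  expect_equal(unname(segment_act(const, plan, 2, 1)), rep(0, 20))

  alt <- pssm(matrix(rep(c(0, 1, 0, 1), 20), ncol = 20),
              rep("A", 4), "alt", normalized = TRUE)
  one_part <- structure(list(mode = "segment", sizes = c(4L, 0L, 0L),
                             rows = list(1:4, integer(0), integer(0))),
                        class = "partition_plan")
  expect_equal(unname(segment_act(alt, one_part, 1, 1)), rep(-0.25, 20))

  # minimal length 2: (a - mu)(b - mu) = -((a - b) / 2)^2
  ab <- matrix(runif(40), nrow = 2)
  p2 <- pssm(ab, c("A", "C"), "ab", normalized = TRUE)
  two_part <- structure(list(mode = "segment", sizes = c(2L, 0L, 0L),
                             rows = list(1:2, integer(0), integer(0))),
                        class = "partition_plan")
  expect_equal(unname(segment_act(p2, two_part, 1, 1)),
               -((ab[1, ] - ab[2, ]) / 2)^2, tolerance = 1e-12)
  expect_error(segment_act(p2, two_part, 1, 2), "exceed")
})

test_that("profile descriptors agree with brute-force oracles", {
  set.seed(24)
  for (i in 1:40) {
    L <- sample(6:60, 1)
    p <- random_norm_pssm(L)
    plan <- plan_partition(L, "segment")
    seg <- sample(1:3, 1)
    part <- p$scores[plan$rows[[seg]], , drop = FALSE]
    max_lag <- nrow(part) - 1L
    lag <- sample(seq_len(min(3, max_lag)), 1)
    expect_equal(unname(segment_act(p, plan, seg, lag)),
                 oracle_segment_act(part, lag), tolerance = 1e-10)
    expect_equal(unname(pse_correlation(part, lag)),
                 oracle_pse_correlation(part, lag), tolerance = 1e-10)
  }
})

test_that("PseTS-PSSM dimensionality follows the configuration", {
  const <- pssm(matrix(0, nrow = 12, ncol = 20), rep("A", 12), "c")
  const <- normalize_pssm(const)  # all entries 0.5
  v <- encode_psets_pssm(const)
  expect_length(v, 60)
  expect_true(all(v == 0.5))

  set.seed(25)
  p <- random_norm_pssm(31)
  expect_length(encode_psets_pssm(p), 60)
  v <- encode_psets_pssm(p, encoder_config(pse_ranks = c(1, 2),
                                           pse_mode = "means+corr"))
  expect_length(v, 180)
  expect_length(encode_psets_pssm(p, encoder_config(pse_ranks = 1,
                                                    pse_mode = "corr")), 60)
  expect_error(encoder_config(pse_mode = "corr"), "requires")

  short <- random_norm_pssm(5)
  expect_error(encode_psets_pssm(short, encoder_config(pse_ranks = 1,
                                                       pse_mode = "corr")),
               "too short")
})

test_that("Sg-PSSM-ACT dimensionality follows the lag set", {
  set.seed(26)
  p <- random_norm_pssm(30)
  expect_length(encode_sg_pssm_act(p), 60)
  expect_length(encode_sg_pssm_act(p, encoder_config(act_lags = c(1, 2))), 120)

  const <- normalize_pssm(pssm(matrix(2, 12, 20), rep("A", 12), "c"))
  expect_true(all(encode_sg_pssm_act(const) == 0))

  short <- random_norm_pssm(5)
  expect_error(encode_sg_pssm_act(short), "too short")
})

test_that("encoders are deterministic and name-stable", {
  set.seed(27)
  s <- random_sequence(45)
  expect_identical(encode_gaac(s), encode_gaac(s))
  expect_identical(encode_dpc(s), encode_dpc(s))
  p <- random_norm_pssm(45)
  expect_identical(encode_psets_pssm(p), encode_psets_pssm(p))
  expect_identical(encode_sg_pssm_act(p), encode_sg_pssm_act(p))

  # golden default 525-name list (feature names are a stable API)
  cfg <- synth_config("strong", n_pos = 1, n_neg = 1,
                      length_range = c(60, 60), seed = 5)
  ds <- generate_dataset(cfg)
  x <- encode_features(ds, generate_pssms(ds, cfg))
  expect_identical(colnames(x),
                   readLines(test_path("feature-names-default.txt")))
})

test_that("column permutation permutes feature blocks consistently", {
  set.seed(28)
  L <- 24
  raw <- matrix(rnorm(L * 20, sd = 2), nrow = L)
  perm <- sample(20)
  res <- sample(aa_alphabet, L, replace = TRUE)
  p1 <- normalize_pssm(pssm(raw, res, "p1"))
  p2 <- normalize_pssm(pssm(raw[, perm], res, "p2"))
  v1 <- encode_sg_pssm_act(p1); v2 <- encode_sg_pssm_act(p2)
  for (seg in 1:3) {
    for (j in 1:20) {
      expect_equal(
        unname(v2[sprintf("SGACT.seg%d.lag1.%s", seg, pssm_column_order[j])]),
        unname(v1[sprintf("SGACT.seg%d.lag1.%s", seg,
                          pssm_column_order[perm[j]])])
      )
    }
  }

  # shuffling rows within one segment changes the descriptor (generically;
  # note pure reversal would not, by time-reversal symmetry of the
  # autocovariance)
  plan <- plan_partition(L, "segment")
  raw3 <- raw
  raw3[plan$rows[[2]], ] <- raw[sample(plan$rows[[2]]), ]
  p3 <- normalize_pssm(pssm(raw3, res, "p3"))
  expect_false(isTRUE(all.equal(encode_sg_pssm_act(p3), v1)))
  # but slice means are permutation-invariant within a slice
  expect_equal(encode_psets_pssm(p3), encode_psets_pssm(p1))
})

test_that("fusion concatenates blocks by record and keeps names unique", {
  set.seed(29)
  cfg <- synth_config("strong", n_pos = 3, n_neg = 3, seed = 9)
  ds <- generate_dataset(cfg)
  pssms <- generate_pssms(ds, cfg)
  gaac_dpc <- encode_features(ds, encoders = c("GAAC", "DPC"))
  expect_equal(ncol(gaac_dpc), 405)
  all4 <- encode_features(ds, pssms)
  expect_equal(ncol(all4), 525)
  expect_false(anyDuplicated(colnames(all4)) > 0)
  expect_equal(attr(all4, "labels"), ds$label)

  solo <- encode_features(ds, encoders = "GAAC")
  expect_equal(ncol(solo), 5)
  expect_true(all(startsWith(colnames(solo), "GAAC.")))

  blocks <- list(GAAC = solo, DPC = encode_features(ds, encoders = "DPC"))
  expect_equal(dim(fuse_features(blocks)), c(6, 405))
  blocks$DPC <- blocks$DPC[-2, , drop = FALSE]
  expect_error(fuse_features(blocks), "missing or misordered")
  expect_error(encode_features(ds, pssms[-1]), "no PSSM")
})
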