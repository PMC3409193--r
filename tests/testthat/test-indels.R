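test_that("shared gaps become characters; unequal lengths stay distinct", {
  x <- toy_msa(c(a_1 = "ACGT---ACGTT",
                 b_1 = "ACGT---ACGTT",
                 c_1 = "ACGTAATACGTT",
                 d_1 = "ACGTAATACGTT"))
  mim <- extract_indels(x)
  expect_equal(nrow(mim$chars), 1L)
  expect_equal(mim$chars$start, 4L)
  expect_equal(mim$chars$length, 3L)
  expect_equal(unname(mim$states[, 1]), c("1", "1", "0", "0"))
  expect_true(mim$chars$informative)

  # overlapping but unequal-length gaps are different characters
  y <- toy_msa(c(a_1 = "AC---TACGT", b_1 = "AC----ACGT", c_1 = "ACGTATACGT"))
  mim2 <- extract_indels(y)
  expect_equal(nrow(mim2$chars), 2L)
  expect_false(any(mim2$chars$shared))
  expect_equal(sort(mim2$chars$length), c(3L, 4L))
})

test_that("engulfing gaps give missing state and gapless input gives none", {
  x <- toy_msa(c(a_1 = "ACGT---ACGTT",
                 b_1 = "ACGT---ACGTT",
                 c_1 = "AC--------TT",
                 d_1 = "ACGTAATACGTT"))
  mim <- extract_indels(x, max_len = 5)
  ch <- mim$chars[mim$chars$start == 4 & mim$chars$length == 3, ]
  expect_equal(nrow(ch), 1L)
  expect_equal(unname(mim$states[, ch$char_id]), c("1", "1", ".", "0"))
  z <- extract_indels(toy_msa(c(a_1 = "ACGT", b_1 = "ACGT")))
  expect_equal(nrow(z$chars), 0L)
})

test_that("hand-checked binary Fitch counts with and without missing data", {
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  m1 <- toy_indel_matrix(matrix(c("1", "1", "0", "0"), 4, 1,
                                dimnames = list(paste0("t", 1:4), "c1")))
  expect_equal(fitch_steps(m1, tr)$steps, 1L)
  m2 <- toy_indel_matrix(matrix(c("1", "0", "1", "0"), 4, 1,
                                dimnames = list(paste0("t", 1:4), "c1")))
  r2 <- fitch_steps(m2, tr)
  expect_equal(r2$steps, 2L)
  expect_true(r2$homoplasic)
  m3 <- toy_indel_matrix(matrix(c("1", "1", "1", "1"), 4, 1,
                                dimnames = list(paste0("t", 1:4), "c1")))
  r3 <- fitch_steps(m3, tr)
  expect_equal(r3$steps, 0L)
  expect_true(r3$degenerate)
  # missing leaves are pruned (free)
  m4 <- toy_indel_matrix(matrix(c("1", ".", "0", "."), 4, 1,
                                dimnames = list(paste0("t", 1:4), "c1")))
  expect_equal(fitch_steps(m4, tr)$steps, 1L)
})

test_that("Fitch totals equal brute force on random binary matrices", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr <- random_tree(n)
    states <- matrix(sample(c("0", "1", "."), n * 4, TRUE,
                            prob = c(0.4, 0.4, 0.2)),
                     n, 4, dimnames = list(tr$tip.label, NULL))
    mim <- toy_indel_matrix(states)
    rep_f <- fitch_steps(mim, tr)
    for (k in 1:4) {
      tips <- stats::setNames(ifelse(states[, k] == ".", NA, states[, k]),
                              rownames(states))
      oracle <- if (all(is.na(tips))) 0 else
        brute_force_parsimony(tr, tips, state_space = c("0", "1"))
      expect_equal(rep_f$steps[k], oracle)
    }
  }
})

test_that("topology comparison ranks the generating tree first", {
  gen <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  alt <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  states <- matrix(c("1", "1", "0", "0"), 4, 1,
                   dimnames = list(paste0("t", 1:4), "c1"))
  mim <- toy_indel_matrix(states)
  cmp <- compare_topologies(mim, list(generating = gen, swapped = alt))
  expect_equal(cmp$topology, c("generating", "swapped"))
  expect_equal(cmp$total_steps, c(1L, 2L))
  expect_equal(cmp$delta, c(0L, 1L))
  same <- compare_topologies(mim, list(a = gen, b = gen))
  expect_equal(same$total_steps[1], same$total_steps[2])
})

test_that("parsimony totals are invariant to leaf order and rerooting", {
  set.seed(9)
  tr <- random_tree(7)
  states <- matrix(sample(c("0", "1", "."), 7 * 30, TRUE, prob = c(.45, .45, .1)),
                   7, 30, dimnames = list(tr$tip.label, NULL))
  mim <- toy_indel_matrix(states)
  base <- attr(fitch_steps(mim, tr), "total_steps")
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(attr(fitch_steps(mim, rot), "total_steps"), base)
  rr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[4], resolve.root = TRUE)
  expect_equal(attr(fitch_steps(mim, rr), "total_steps"), base)
})

test_that("planted shared indels are recovered from simulation truth", {
  cfg <- sim_config("(A:2e6,B:2e6)anc:40e6;", root_length = 8000,
                    subst = list(rate = 1.4e-9, pi = rep(0.25, 4), k1 = 1, k2 = 1),
                    indel = list(rate = 1.9e-10, mean_len = 4, max_len = 100),
                    seed = 424)
  sim <- simulate_family(cfg)
  truth <- sim$truth$indels
  # deletions on the long shared stem appear as identical gaps in both tips
  stem_dels <- truth[truth$type == "del" & truth$time <= 40e6, ]
  expect_gt(nrow(stem_dels), 15L)
  mim <- extract_indels(sim$msa)
  shared <- mim$chars[mim$chars$shared, ]
  key_obs <- paste(shared$start, shared$length)
  key_truth <- paste(truth$start, truth$n_cols)
  key_stem <- paste(stem_dels$start, stem_dels$n_cols)
  # recall: nearly all stem deletions recovered exactly (a few may be
  # destroyed by later overlapping events); precision: shared characters
  # trace back to recorded events
  expect_gte(mean(key_stem %in% key_obs), 0.9)
  expect_gte(mean(key_obs %in% key_truth), 0.9)
})

test_that("conversion can transplant indels that then co-localize", {
  # gaps shared through conversion corroborate the called region
  tr <- ape::read.tree(text = "((x_a,x_b),(x_c,x_d));")
  x <- toy_msa(c(x_a = "AAAA---AAAAACCCCC",
                 x_c = "AAAA---AAAAACCCCG",
                 x_b = "AAAATTTAAAAACCCCC",
                 x_d = "AAAATTTAAAAATCCCC"))
  mim <- extract_indels(x)
  regions <- tibble::tibble(label_a = "x_a", label_b = "x_c",
                            start = 0L, end = 12L, peak_score = 0.99,
                            n_windows = 3L)
  co <- colocalize_indels(mim, tr, regions)
  expect_equal(nrow(co), 1L)
  expect_true(co$corroborating)
  expect_equal(co$carriers, "x_a,x_c")
  orphan <- colocalize_indels(mim, tr, regions[0, ])
  expect_equal(nrow(orphan), 1L)
  expect_true(is.na(orphan$region_start))
})
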