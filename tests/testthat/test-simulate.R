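test_that("identical config and seed give identical bytes", {
  a <- make_family("fourparalog_oneloss", seed = 5)
  b <- make_family("fourparalog_oneloss", seed = 5)
  expect_identical(a$msa$mat, b$msa$mat)
  expect_identical(a$truth$gene_tree, b$truth$gene_tree)
  expect_identical(a$truth$indels, b$truth$indels)
  c_ <- make_family("fourparalog_oneloss", seed = 6)
  expect_false(identical(a$msa$mat, c_$msa$mat))
})

test_that("zero rates leave every tip identical to the root", {
  cfg <- sim_config("(A:1e6,B:1e6);", root_length = 300,
                    subst = list(rate = 0, pi = rep(0.25, 4), k1 = 1, k2 = 1),
                    seed = 8)
  sim <- simulate_family(cfg)
  expect_equal(nrow(sim$msa$mat), 2L)
  expect_identical(sim$msa$mat[1, ], sim$msa$mat[2, ])
  expect_false(any(sim$msa$mat == "-"))
})

test_that("substitution-only divergence matches the closed-form expectation", {
  pi <- c(0.3, 0.2, 0.2, 0.3)
  cfg <- sim_config("(A:2.5e7,B:2.5e7);", root_length = 60000,
                    subst = list(rate = 2e-9, pi = pi, k1 = 2, k2 = 3),
                    seed = 17)
  sim <- simulate_family(cfg)
  d_true <- 2 * 2.5e7 * 2e-9  # 0.1 substitutions/site total path
  model <- paralogr:::tn93_model(pi, 2, 3)
  p_expected <- model$pdiff(d_true)
  p_obs <- pairwise_distance(sim$msa, "p")$d[1, 2]
  se <- sqrt(p_expected * (1 - p_expected) / 60000)
  expect_lt(abs(p_obs - p_expected), 3 * se)
})

test_that("event times outside their branch are fatal", {
  expect_error(
    simulate_family(sim_config(
      "(A:1e6,B:1e6)anc:1e6;", root_length = 100,
      duplications = tibble::tibble(species = "anc", time = 1.5e6,
                                    gene = "P1", new_name = "P2"),
      seed = 1)),
    "outside branch")
})

test_that("gap columns in the emitted alignment match the indel truth", {
  cfg <- sim_config("(A:2e6,B:2e6)anc:20e6;", root_length = 4000,
                    subst = list(rate = 1.4e-9, pi = rep(0.25, 4), k1 = 1, k2 = 1),
                    indel = list(rate = 3e-10, mean_len = 4, max_len = 100),
                    seed = 33)
  sim <- simulate_family(cfg)
  truth <- sim$truth$indels
  # alignment width = root length + total inserted columns
  ins_cols <- sum(truth$n_cols[truth$type == "ins"])
  expect_equal(msa_width(sim$msa), 4000L + ins_cols)
  # every gap character lies inside some recorded indel's final extent
  gap_cols <- which(apply(sim$msa$mat == "-", 2, any)) - 1L
  covered <- rep(FALSE, msa_width(sim$msa))
  for (i in seq_len(nrow(truth))) {
    covered[(truth$start[i] + 1L):truth$end[i]] <- TRUE
  }
  expect_true(all(covered[gap_cols + 1L]))
})

test_that("conversion records carry configured length and tract coordinates", {
  lens <- vapply(1:40, function(s) {
    sim <- make_family("small_family", seed = 3000 + s, conversion_len = 600)
    sim$truth$conversions$length
  }, numeric(1))
  expect_true(all(lens == 600))
  # geometric tract lengths reproduce the configured mean
  set.seed(2)
  draws <- vapply(1:200, function(s) {
    cfg <- sim_config("(A:44e6,B:44e6)anc:1e6;", root_length = 6000,
                      conversions = tibble::tibble(
                        species = "A", time = 43e6, donor = NA_character_,
                        recipient = "P2", start = NA_integer_,
                        mean_len = 500, fixed = FALSE),
                      duplications = tibble::tibble(
                        species = "anc", time = 0.5e6, gene = "P1",
                        new_name = "P2"),
                      seed = 5000 + s)
    simulate_family(cfg)$truth$conversions$length
  }, numeric(1))
  expect_lt(abs(mean(draws) - 500) / 500, 0.10)
})

test_that("presets build the advertised family structures", {
  fam <- make_family("fourparalog_oneloss", seed = 4)
  labs <- fam$msa$labels
  expect_setequal(labs, c(paste0("Hum_P", 2:4), paste0("Mac_P", 1:4),
                          paste0("Cal_P", 1:4)))
  gt <- ape::read.tree(text = fam$truth$gene_tree)
  expect_setequal(gt$tip.label, labs)
  # orthologs diverge at speciations, paralogs at their duplications
  dv <- fam$truth$divergence
  hm <- dv[dv$label_a == "Hum_P2" & dv$label_b == "Mac_P2", ]
  expect_equal(hm$t_divergence, 18e6)
  pp <- dv[dv$label_a == "Hum_P2" & dv$label_b == "Hum_P3", ]
  expect_equal(pp$t_divergence, 1e6)
})

test_that("intron-scale NJ recovery loop finds the true duplication topology", {
  hits <- vapply(1:20, function(s) {
    fam <- make_family("no_conversion", seed = 7000 + s)
    dm <- pairwise_distance(fam$msa, "tn93cl")
    tr <- neighbor_joining(dm)
    gt <- ape::read.tree(text = fam$truth$gene_tree)
    phangorn::RF.dist(ape::unroot(tr), ape::unroot(gt)) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
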