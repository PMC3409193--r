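test_that("polymorphic sites: identical group empty, variation located", {
  x <- toy_msa(c(x_a = "ACGTACGTAC", x_b = "ACGTACGTAC", x_c = "ACGTACGTAC"))
  expect_length(polymorphic_sites(x, x$labels), 0L)
  y <- toy_msa(c(x_a = "ACGTACGTAC", x_b = "ACGAACGTAC",
                 x_c = "ACGTACGTAG", x_d = "ACGTACGTAC"))
  expect_equal(polymorphic_sites(y, y$labels), c(3L, 9L))
  # matches a naive per-column scan on random input
  set.seed(3)
  mat <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 200, TRUE,
                       prob = c(.24, .24, .24, .24, .04)), 4, 200,
                dimnames = list(c("x_a", "x_b", "x_c", "x_d"), NULL))
  z <- msa(mat)
  naive <- which(apply(mat, 2, function(col) {
    length(unique(col[col != "-"])) >= 2
  })) - 1L
  expect_equal(polymorphic_sites(z, z$labels), naive)
  # all-gap columns are skipped
  expect_false(any(apply(mat[, polymorphic_sites(z, z$labels) + 1L], 2,
                         function(col) all(col == "-"))))
})

test_that("fragment scores: pure runs, thresholds, empty input", {
  # pair identical at 10 consecutive polymorphic sites, mismatching elsewhere
  a <- paste0(strrep("A", 5), strrep("C", 10), strrep("A", 5))
  b <- paste0(strrep("G", 5), strrep("C", 10), strrep("G", 5))
  c_ <- paste0(strrep("T", 5), strrep("T", 10), strrep("T", 5))
  x <- toy_msa(c(x_a = a, x_b = b, x_c = c_))
  sites <- polymorphic_sites(x, x$labels)
  fr <- sawyer_fragments(x, c("x_a", "x_b"), sites, sawyer_params())
  best <- fr[which.max(fr$score), ]
  expect_equal(best$score, 10)
  expect_equal(best$start, 5L)
  expect_equal(best$end, 15L)
  # no two consecutive matches with min_polymorphisms = 2 -> empty
  y <- toy_msa(c(x_a = "ACACAC", x_b = "AGAGAG", x_c = "TTTTTT"))
  sy <- polymorphic_sites(y, y$labels)
  fr2 <- sawyer_fragments(y, c("x_a", "x_b"), sy,
                          sawyer_params(min_polymorphisms = 2, min_frag_score = 2))
  expect_lte(max(c(0, fr2$n_match)), 1L)
  expect_equal(nrow(sawyer_fragments(y, c("x_a", "x_b"), integer(),
                                     sawyer_params())), 0L)
})

test_that("fragment statistic ignores monomorphic columns", {
  set.seed(11)
  mat <- matrix(sample(c("A", "C", "G", "T"), 4 * 120, TRUE), 4, 120,
                dimnames = list(c("x_a", "x_b", "x_c", "x_d"), NULL))
  x <- msa(mat)
  sites <- polymorphic_sites(x, x$labels)
  fr0 <- sawyer_fragments(x, c("x_a", "x_b"), sites, sawyer_params())
  # intersperse monomorphic columns
  ins <- matrix("A", 4, 40, dimnames = list(rownames(mat), NULL))
  mat2 <- cbind(mat[, 1:60], ins, mat[, 61:120])
  x2 <- msa(mat2)
  sites2 <- polymorphic_sites(x2, x2$labels)
  fr2 <- sawyer_fragments(x2, c("x_a", "x_b"), sites2, sawyer_params())
  expect_equal(nrow(fr0), nrow(fr2))
  expect_equal(fr0$score, fr2$score)
  expect_equal(fr0$n_sites, fr2$n_sites)
})

test_that("permutation p-values are seeded-reproducible and need permutations", {
  sim <- make_family("small_family", seed = 2, conversion_len = 700)
  grp <- sim$msa$labels[sim$msa$species == "A"]
  p1 <- sawyer_test(sim$msa, grp, sawyer_params(n_permutations = 200, seed = 42))
  p2 <- sawyer_test(sim$msa, grp, sawyer_params(n_permutations = 200, seed = 42))
  expect_equal(p1$p, p2$p)
  expect_error(sawyer_test(sim$msa, grp, sawyer_params(n_permutations = 0)),
               "n_permutations")
})

test_that("a strongly clustered planted tract is significant, null is calm", {
  sim <- make_family("small_family", seed = 31, conversion_len = 700)
  truth <- sim$truth$conversions
  grp <- sim$msa$labels[sim$msa$species == "A"]
  sw <- sawyer_test(sim$msa, grp, sawyer_params(n_permutations = 500, seed = 7))
  want <- sort(paste0("A_", c(truth$donor, truth$recipient)))
  hit <- sw[paste(pmin(sw$label_a, sw$label_b), pmax(sw$label_a, sw$label_b)) ==
              paste(want[1], want[2]), ]
  expect_true(hit$significant)
  expect_lt(hit$p_corrected, 0.05)
  # best fragment overlaps the true tract
  expect_true(hit$start < truth$end && hit$end > truth$start)
  # null family: no significant pair at alpha with Bonferroni
  null_sig <- vapply(1:10, function(s) {
    sim0 <- make_family("small_family", seed = 100 + s)
    g0 <- sim0$msa$labels[sim0$msa$species == "A"]
    any(sawyer_test(sim0$msa, g0,
                    sawyer_params(n_permutations = 200, seed = s))$significant)
  }, logical(1))
  expect_lte(mean(null_sig), 0.2)
})

test_that("two-tier evidence integration follows the calling rules", {
  cands <- tibble::tibble(label_a = "x_a", label_b = "x_b", start = 100L,
                          end = 600L, peak_score = 0.98, n_windows = 20L)
  coloc <- tibble::tibble(char_id = "c1", start = 200L, length = 4L,
                          carriers = "x_a,x_b", region_start = 100L,
                          region_end = 600L, region_pair = "x_a|x_b",
                          corroborating = TRUE)
  sawyer <- tibble::tibble(label_a = "x_c", label_b = "x_d", observed = 30,
                           start = 900L, end = 1300L, p = 0.001,
                           p_corrected = 0.006, significant = TRUE)
  calls <- integrate_calls(cands, coloc, sawyer)
  recent <- calls[calls$tier == "recent", ]
  expect_equal(nrow(recent), 1L)
  expect_true(recent$ev_similarity && recent$ev_microindel)
  ancient <- calls[calls$tier == "ancient", ]
  expect_equal(nrow(ancient), 1L)
  expect_equal(ancient$label_a, "x_c")
  expect_true(ancient$called)
  # super-threshold region without corroboration is not a call
  calls2 <- integrate_calls(cands, NULL, NULL)
  expect_equal(calls2$tier, "uncorroborated")
  expect_false(calls2$called)
  # overlapping same-pair calls merge with union extent and evidence
  cands3 <- tibble::tibble(label_a = "x_a", label_b = "x_b",
                           start = c(100L, 400L), end = c(500L, 900L),
                           peak_score = 0.99, n_windows = 5L)
  calls3 <- integrate_calls(cands3, coloc, NULL)
  expect_equal(nrow(calls3), 1L)
  expect_equal(calls3$start, 100L)
  expect_equal(calls3$end, 900L)
})

test_that("observed percentile under a permuted null is uniform", {
  # exchangeability: on column-permuted input the statistic is typical of
  # its own permutation null (KS test across replicate families)
  set.seed(404)
  pvals <- vapply(1:60, function(s) {
    sim <- make_family("small_family", seed = 2000 + s)
    grp <- sim$msa$labels[sim$msa$species == "A"]
    # permute polymorphic columns first: destroys any residual clustering
    sites <- polymorphic_sites(sim$msa, grp) + 1L
    perm <- sample(sites)
    mat <- sim$msa$mat
    mat[, sites] <- mat[, perm]
    x <- msa(mat, species = sim$msa$species)
    sw <- sawyer_test(x, grp, sawyer_params(n_permutations = 99, seed = s))
    sw$p[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
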