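test_that("hand-checked distances: identity, p-distance, gap deletion", {
  x <- toy_msa(c(a_1 = "ACGT", b_1 = "ACGT", c_2 = "AGGT"))
  dm <- pairwise_distance(x, model = "p")
  expect_equal(dm$d["a_1", "b_1"], 0)
  expect_equal(dm$d["a_1", "c_2"], 0.25)  # 1 mismatch of 4
  # a column gapped in either member is ignored for that pair
  y <- toy_msa(c(a_1 = "AC-TT", b_1 = "ACGTA"))
  dmy <- pairwise_distance(y, model = "p")
  expect_equal(dmy$n_sites["a_1", "b_1"], 4L)
  expect_equal(dmy$d["a_1", "b_1"], 0.25)
})

test_that("matrices are symmetric and corrections order p <= JC <= TN93-CL", {
  sim <- make_family("small_family", seed = 3)
  x <- sim$msa
  dp <- pairwise_distance(x, "p")
  dj <- pairwise_distance(x, "jc")
  dt <- pairwise_distance(x, "tn93cl")
  for (dm in list(dp, dj, dt)) {
    expect_lt(max(abs(dm$d - t(dm$d)), na.rm = TRUE), 1e-12)
    expect_true(all(diag(dm$d) == 0))
    expect_true(all(dm$d >= 0, na.rm = TRUE))
    expect_true(all(dm$var >= 0, na.rm = TRUE))
  }
  ut <- upper.tri(dp$d)
  expect_true(all(dp$d[ut] <= dj$d[ut] + 1e-12))
  expect_true(all(dj$d[ut] <= dt$d[ut] + 1e-12))
})

test_that("TN93-CL recovers a known divergence within 3 SE at 100 kb", {
  cfg <- sim_config("(A:5.357e7,B:5.357e7);", root_length = 100000,
                    subst = list(rate = 1.4e-9, pi = c(0.3, 0.2, 0.2, 0.3),
                                 k1 = 2, k2 = 2),
                    seed = 99)
  # total path = 2 * 5.357e7 * 1.4e-9 = 0.150 substitutions/site
  sim <- simulate_family(cfg)
  dm <- pairwise_distance(sim$msa, "tn93cl")
  d <- dm$d[1, 2]
  se <- sqrt(dm$var[1, 2])
  expect_lt(abs(d - 0.15), 3 * se)
})

test_that("group averages handle single-pair and empty contrasts", {
  d <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.3, 0.2, 0.3, 0), 3, 3,
              dimnames = list(c("a_1", "b_1", "c_2"), c("a_1", "b_1", "c_2")))
  dm <- as_paralog_dist(d)
  groups <- c(a_1 = "g1", b_1 = "g1", c_2 = "g2")
  out <- group_averages(dm, groups, tibble::tibble(
    contrast = c("within_g1", "within_g2", "between"),
    group_a = c("g1", "g2", "g1"), group_b = c("g1", "g2", "g2")))
  expect_equal(out$mean, c(0.1, NA, 0.25))
  expect_true(is.na(out$sd[1]))  # single pair
  expect_equal(out$n_pairs, c(1L, 0L, 2L))
})

test_that("ortholog assignment: unique minimum, ties flagged ambiguous", {
  d <- matrix(0, 4, 4, dimnames = rep(list(c("a_x", "b_x", "a_y", "b_y")), 2))
  d["a_x", "a_y"] <- d["a_y", "a_x"] <- 0.10
  d["a_x", "b_y"] <- d["b_y", "a_x"] <- 0.30
  d["b_x", "a_y"] <- d["a_y", "b_x"] <- 0.25
  d["b_x", "b_y"] <- d["b_y", "b_x"] <- 0.12
  d["a_x", "b_x"] <- d["b_x", "a_x"] <- 0.4
  d["a_y", "b_y"] <- d["b_y", "a_y"] <- 0.4
  dm <- as_paralog_dist(d, species = c(a_x = "x", b_x = "x", a_y = "y", b_y = "y"))
  om <- assign_orthologs(dm)
  ax <- om[om$label == "a_x", ]
  expect_equal(ax$partner, "a_y")
  expect_equal(ax$margin, 0.2)
  expect_true(all(om$reciprocal))
  expect_false(any(om$conflict))
  # symmetric tie
  d2 <- d
  d2["a_x", "b_y"] <- d2["b_y", "a_x"] <- 0.10
  dm2 <- as_paralog_dist(d2, species = dm$species)
  om2 <- assign_orthologs(dm2)
  expect_true(any(om2$ambiguous[om2$label == "a_x"]))
  expect_equal(sum(om2$label == "a_x" & om2$partner_species == "y"), 2L)
})

test_that("NJ: 3-taxon closed form, exact recovery of additive matrices, NA fatal", {
  d <- matrix(0, 3, 3, dimnames = rep(list(c("a_1", "b_1", "c_2")), 2))
  d["a_1", "b_1"] <- d["b_1", "a_1"] <- 0.3
  d["a_1", "c_2"] <- d["c_2", "a_1"] <- 0.5
  d["b_1", "c_2"] <- d["c_2", "b_1"] <- 0.6
  tr <- neighbor_joining(as_paralog_dist(d))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a_1"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b_1"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c_2"]), (0.5 + 0.6 - 0.3) / 2)

  set.seed(7)
  for (rep in 1:5) {
    gen <- random_tree(5, labels = paste0("t", 1:5, "_s"))
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 0.3)
    dm <- as_paralog_dist(tree_distance_matrix(gen))
    rec <- neighbor_joining(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), ape::unroot(rec)), 0)
    # additive matrix is realised exactly
    expect_lt(max(abs(tree_distance_matrix(rec)[rownames(dm$d), colnames(dm$d)] -
                        dm$d)), 1e-8)
  }

  dna <- as_paralog_dist(matrix(c(0, NA, 0.1, NA, 0, 0.1, 0.1, 0.1, 0), 3, 3,
                                dimnames = rep(list(c("a_1", "b_1", "c_2")), 2)))
  expect_error(neighbor_joining(dna), "NA distances")
})

test_that("worked-example matrix yields the published sister pairings", {
  dm <- adh1_distance_example(drop_incomplete = TRUE)
  expect_false("Mac_ADH1.2" %in% dm$labels)
  tr <- neighbor_joining(dm)
  sister <- function(a, b) {
    pr <- ape::prop.part(ape::unroot(tr))
    any(vapply(pr, function(p) setequal(tr$tip.label[p], c(a, b)), logical(1))) ||
      ape::is.monophyletic(tr, c(a, b))
  }
  expect_true(sister("Hum_ADH1A", "Mac_ADH1.1"))
  expect_true(sister("Hum_ADH1B", "Mac_ADH1.3"))
  expect_true(sister("Hum_ADH1C", "Mac_ADH1.4"))
})

test_that("per-region nearest parent flags chimeric duplicates only", {
  sim <- make_family("chimeric_dup", seed = 5)
  prn <- per_region_nearest(sim$msa, model = "p")
  cs <- chimera_signals(prn)
  expect_true(cs$flagged[cs$label == "Mac_PX"])
  px <- cs[cs$label == "Mac_PX", ]
  expect_equal(px$parent_5p, "Mac_P2")
  expect_equal(px$parent_3p, "Mac_P3")
  # breakpoint falls near the configured fusion point (column 6250)
  expect_gt(px$breakpoint, 4500)
  expect_lt(px$breakpoint, 8000)
  expect_false(any(cs$flagged[cs$label != "Mac_PX"]))
})

test_that("regions under 100 sites are low-confidence and excluded from flags", {
  set.seed(1)
  base <- paste(sample(c("A", "C", "G", "T"), 260, TRUE), collapse = "")
  mutate_seq <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    i <- which(stats::runif(length(v)) < rate)
    v[i] <- sample(c("A", "C", "G", "T"), length(i), TRUE)
    paste(v, collapse = "")
  }
  regions <- tibble::tibble(region = c("r1", "r2"), start = c(0L, 200L),
                            end = c(200L, 260L), frame = NA_integer_)
  x <- msa(c(x_f = base, x_p1 = mutate_seq(base, 0.05), x_p2 = mutate_seq(base, 0.3)),
           regions = regions)
  prn <- per_region_nearest(x, model = "p")
  expect_true(all(prn$low_confidence[prn$region == "r2"]))
  cs <- chimera_signals(prn)
  expect_false(any(cs$flagged))
})
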