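# Diet-group summaries, the mass-rate permutation test, and Brownian-motion
# ancestral state reconstruction.

test_that("group summaries exclude minima from means but not ranges", {
  traits <- data.frame(
    taxon = c("A", "B", "C", "D", "E"),
    diet = c("herbivore", "herbivore", "herbivore", "herbivore", "carnivore"),
    rate_days = c(391, 431, 459, 381, 105),
    rate_is_min = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    longevity_days = c(506, 628, 628, 506, 459),
    longevity_is_min = FALSE
  )
  gs <- group_summary(traits)
  herb <- gs[gs$diet == "herbivore" & gs$trait == "rate", ]
  expect_identical(herb$min, 381)
  expect_identical(herb$max, 459)
  expect_equal(herb$mean, mean(c(391, 431, 459, 381)))
  expect_false(herb$range_includes_minimum)

  # a minimum participates in the range with the lower-bound annotation,
  # but not in the mean
  traits$rate_is_min[4] <- TRUE
  gs2 <- group_summary(traits)
  herb2 <- gs2[gs2$diet == "herbivore" & gs2$trait == "rate", ]
  expect_identical(herb2$min, 381)
  expect_true(herb2$range_includes_minimum)
  expect_equal(herb2$mean, mean(c(391, 431, 459)))

  # single-taxon group: mean = min = max; empty groups omitted
  carn <- gs[gs$diet == "carnivore" & gs$trait == "rate", ]
  expect_true(carn$mean == carn$min && carn$min == carn$max)
  expect_false("omnivore" %in% gs$diet)
})

test_that("mass-rate association is exact under exhaustive permutation", {
  mass <- c(0.5, 4, 60, 300)
  rate <- c(100, 40, 380, 105)
  traits <- data.frame(taxon = letters[1:4], diet = "carnivore",
                       body_mass_kg = mass, rate_days = rate)
  res <- mass_rate_association(traits)
  expect_true(res$exhaustive)
  expect_equal(res$r, stats::cor(log10(mass), rate))
  expect_equal(res$p_perm, brute_force_perm_p(mass, rate))

  # a second configuration, including ties in the null distribution
  mass2 <- c(1, 10, 100, 1000)
  rate2 <- c(10, 20, 30, 25)
  traits2 <- data.frame(taxon = letters[1:4], diet = "carnivore",
                        body_mass_kg = mass2, rate_days = rate2)
  expect_equal(mass_rate_association(traits2)$p_perm,
               brute_force_perm_p(mass2, rate2))
})

test_that("association handles perfect, degenerate, and minimum-rate input", {
  lin <- data.frame(taxon = letters[1:5], diet = "carnivore",
                    body_mass_kg = 10^(1:5), rate_days = seq(10, 50, 10))
  expect_equal(mass_rate_association(lin)$r, 1.0)
  const <- data.frame(taxon = letters[1:4], diet = "carnivore",
                      body_mass_kg = c(1, 2, 4, 8), rate_days = 100)
  expect_error(mass_rate_association(const), class = "undefined_correlation")
  # minimum-only rates are excluded, and too few remaining taxa error out
  few <- data.frame(taxon = letters[1:4], diet = "carnivore",
                    body_mass_kg = c(1, 2, 4, 8),
                    rate_days = c(100, 120, 80, 90),
                    rate_is_min = c(FALSE, FALSE, TRUE, TRUE))
  expect_error(mass_rate_association(few), class = "invalid_traits")
})

test_that("Monte-Carlo permutation p is reproducible under a fixed seed", {
  set.seed(77)
  traits <- data.frame(taxon = letters[1:9], diet = "carnivore",
                       body_mass_kg = 10^runif(9, -1, 2.5),
                       rate_days = sample(40:460, 9))
  a <- mass_rate_association(traits, n_permutations = 999, seed = 5)
  b <- mass_rate_association(traits, n_permutations = 999, seed = 5)
  expect_false(a$exhaustive)
  expect_identical(a$p_perm, b$p_perm)
  expect_gt(a$p_perm, 0)
  expect_lte(a$p_perm, 1)
})

test_that("fixture regression: no significant mass-rate relationship", {
  res <- mass_rate_association(trait_fixture(), n_permutations = 9999, seed = 1)
  expect_gt(res$p_perm, 0.05)
})

test_that("BM ancestral states match hand-computable cases", {
  # two tips, equal branches: the root splits the difference
  t2 <- ape::read.tree(text = "(A:1.5,B:1.5);")
  expect_equal(unname(bm_ancestral_states(t2, c(A = 1, B = 3))$node_states), 2)
  # three tips, closed form 9/7
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  asr <- bm_ancestral_states(t3, c(A = 0, B = 0, C = 3))
  expect_equal(unname(asr$node_states[["4"]]), 9 / 7, tolerance = 1e-12)
  # star tree with equal branches: the root is the tip mean
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  vals <- c(A = 1, B = 4, C = 2, D = 9)
  expect_equal(unname(bm_ancestral_states(star, vals)$node_states), mean(vals))
})

test_that("pruning ASR equals the GLS closed form on random trees", {
  for (ntip in 5:8) {
    tr <- random_test_tree(ntip, seed = 100 + ntip)
    set.seed(200 + ntip)
    vals <- stats::setNames(stats::rnorm(ntip, 50, 20), tr$tip.label)
    mine <- bm_ancestral_states(tr, vals)$node_states
    oracle <- gls_ancestral_states(tr, vals)
    expect_equal(mine, oracle[names(mine)], tolerance = 1e-9)
    # every node state lies inside the tip range
    expect_true(all(mine >= min(vals) - 1e-9 & mine <= max(vals) + 1e-9))
  }
})

test_that("pruning ASR agrees with phytools::fastAnc", {
  tr <- random_test_tree(7, seed = 3)
  set.seed(4)
  vals <- stats::setNames(stats::rnorm(7, 100, 30), tr$tip.label)
  mine <- bm_ancestral_states(tr, vals)$node_states
  fa <- phytools::fastAnc(tr, vals)
  expect_equal(unname(mine[names(fa)]), unname(as.numeric(fa)), tolerance = 1e-6)
})

test_that("ASR is equivariant under shift and scale of tip values", {
  tr <- random_test_tree(6, seed = 11)
  set.seed(12)
  vals <- stats::setNames(stats::rnorm(6), tr$tip.label)
  base <- bm_ancestral_states(tr, vals)$node_states
  shifted <- bm_ancestral_states(tr, vals + 7)$node_states
  scaled <- bm_ancestral_states(tr, vals * 3)$node_states
  expect_equal(shifted, base + 7, tolerance = 1e-10)
  expect_equal(scaled, base * 3, tolerance = 1e-10)
})

test_that("ASR rejects incomplete or invalid input", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(bm_ancestral_states(tr, c(A = 1, B = 2)),
               class = "incomplete_data")
  tr0 <- tr; tr0$edge.length[2] <- 0
  expect_error(bm_ancestral_states(tr0, c(A = 1, B = 2, C = 3)),
               class = "invalid_tree")
})

test_that("branch gradients interpolate linearly and join continuously", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  asr <- bm_ancestral_states(tr, c(A = 0, B = 0, C = 3))
  g <- branch_gradient(asr, samples_per_branch = 3)
  # hand-checkable: a branch from state 0 to state 10 sampled at quarters
  synth <- asr
  synth$node_states[] <- c(0, 0)
  synth$tip_values[] <- c(10, 10, 10)
  gs <- branch_gradient(synth, samples_per_branch = 3)
  tip_rows <- gs[gs$child <= 3, ]
  expect_equal(tip_rows$value, rep(c(2.5, 5, 7.5), 3))
  # constant trait: every sample equals that constant
  flat <- bm_ancestral_states(tr, c(A = 5, B = 5, C = 5))
  expect_true(all(abs(branch_gradient(flat, 4)$value - 5) < 1e-12))
  # every sampled value matches the independent endpoint interpolation, so
  # consecutive branches sharing a node converge to the same node state
  state_of <- function(n) {
    if (n <= 3) asr$tip_values[[n]] else asr$node_states[[as.character(n)]]
  }
  expected <- mapply(function(p, c, f) state_of(p) + f * (state_of(c) - state_of(p)),
                     g$parent, g$child, g$fraction)
  expect_equal(g$value, unname(expected), tolerance = 1e-12)
})
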