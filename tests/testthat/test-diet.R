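test_that("phylogenetic Hill diversity matches the worked 3-tip value", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  ab <- c(A = 1, B = 1, C = 2)
  # frozen from the independent branch-enumeration oracle
  expect_equal(hill_phylo(ab, tr, q = 1), 2.3784142, tolerance = 1e-7)
  expect_equal(hill_phylo(ab, tr, q = 1), hill_phylo_oracle(ab, tr, 1),
               tolerance = 1e-12)
})

test_that("star-tree diversity reduces to the ordinary Hill number", {
  st <- star_tree(paste0("s", 1:4), depth = 2.5)
  expect_equal(hill_phylo(setNames(rep(2, 4), paste0("s", 1:4)), st, 1), 4)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    st <- star_tree(paste0("s", 1:n), depth = runif(1, 0.5, 5))
    ab <- setNames(rexp(n), paste0("s", 1:n))
    for (q in c(0, 0.5, 1, 2)) {
      expect_equal(hill_phylo(ab, st, q), hill_taxonomic(ab, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("hill_phylo agrees with the branch-enumeration oracle on random trees", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    tr <- random_ultrametric(n)
    ab <- setNames(rexp(n), tr$tip.label)
    ab[sample(n, 1)] <- 0   # exercise zero-abundance tips
    for (q in c(0, 1, 2)) {
      expect_equal(hill_phylo(ab, tr, q), hill_phylo_oracle(ab, tr, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("hill_phylo handles degenerate abundance vectors", {
  expect_equal(hill_phylo(c(H1 = 5, H2 = 0), host_tree, 1), 1)  # single lineage
  expect_true(is.na(hill_phylo(c(H1 = 0, H2 = 0), host_tree, 1)))
})

test_that("chronological sets take replicate k of every host", {
  d <- small_design(replicates_per_cell = 7)
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 9)
  trt <- v[v$parasitoid != "CONTROL", ]
  sets <- assign_sets(trt, n_sets = 7)
  expect_equal(attr(sets, "n_unused"), 0L)
  one <- sets[sets$parasitoid == "Asobara" & sets$temperature == 24 & sets$set == 3, ]
  expect_setequal(one$host, d$hosts)
  src <- trt[trt$parasitoid == "Asobara" & trt$temperature == 24 & trt$replicate == 3, ]
  expect_equal(one$abundance[match(src$host, one$host)], src$P)
})

test_that("shuffling preserves the pooled abundance multiset per cell", {
  d <- small_design(replicates_per_cell = 9)
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 10)
  trt <- v[v$parasitoid != "CONTROL", ]
  chron <- assign_sets(trt, n_sets = 9)
  shuf <- assign_sets(trt, n_sets = 9, order = "shuffled", seed = 4)
  key <- function(s) split(s$abundance, paste(s$parasitoid, s$temperature, s$host))
  a <- lapply(key(chron), sort); b <- lapply(key(shuf), sort)
  expect_equal(a, b[names(a)])
  # same seed reproduces the same permutation
  shuf2 <- assign_sets(trt, n_sets = 9, order = "shuffled", seed = 4)
  expect_equal(shuf, shuf2, ignore_attr = TRUE)
})

test_that("surplus replicates are unused and short cells are an error", {
  d <- small_design(replicates_per_cell = 10)
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 12)
  trt <- v[v$parasitoid != "CONTROL", ]
  sets <- assign_sets(trt, n_sets = 7)
  expect_equal(attr(sets, "n_unused"),
               3L * length(unique(paste(trt$host, trt$parasitoid, trt$temperature))))
  expect_true(all(sets$set <= 7))
  expect_error(assign_sets(trt[trt$replicate <= 5, ], n_sets = 7),
               "fewer than 7 replicates")
})

test_that("diversity bounds, scale invariance and q-continuity hold", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(3:9, 1)
    tr <- random_ultrametric(n)
    ab <- setNames(rpois(n, 4) + c(1, numeric(n - 1)), tr$tip.label)
    D <- hill_phylo(ab, tr, 1)
    expect_gte(D, 1 - 1e-9)
    expect_lte(D, sum(ab > 0) + 1e-9)
    expect_equal(hill_phylo(2 * ab, tr, 1), D, tolerance = 1e-12)
    expect_lt(abs(hill_phylo(ab, tr, 1 + 1e-4) - D), 1e-3)
    expect_lt(abs(hill_phylo(ab, tr, 1 - 1e-4) - D), 1e-3)
  }
})

test_that("balanced-table OLS contrasts match closed form", {
  # identical diversities: zero contrasts, p = 1
  flat <- expand.grid(parasitoid = c("A", "G"), temperature = c(20, 24, 28),
                      set = 1:7)
  flat$diversity <- 3
  f <- fit_breadth_lm(flat)
  expect_true(all(f$contrasts$estimate == 0))
  expect_true(all(f$contrasts$p_value == 1))

  # shift of -1 at 28C with known residuals: estimate -1, SE = sigma*sqrt(2/n)
  tab <- expand.grid(set = 1:7, temperature = c(20, 24, 28), parasitoid = "A")
  resid_pattern <- c(-3, -2, -1, 0, 1, 2, 3) / 10
  tab$diversity <- 4 + resid_pattern[tab$set] + ifelse(tab$temperature == 28, -1, 0)
  f2 <- fit_breadth_lm(tab)
  c28 <- f2$contrasts[f2$contrasts$comparison == "28/24", ]
  expect_equal(c28$estimate, -1, tolerance = 1e-9)
  sigma2 <- sum(resid_pattern^2) * 3 / (21 - 3)   # SSE / df
  expect_equal(c28$se, sqrt(sigma2 * 2 / 7), tolerance = 1e-9)

  # balanced design: marginal means equal raw cell means
  em <- f2$emmeans
  expect_equal(em$emmean[em$temperature == "24"], 4, tolerance = 1e-9)
})

test_that("undefined sets are dropped from the model but counted", {
  tab <- expand.grid(parasitoid = "A", temperature = c(20, 24, 28), set = 1:7)
  tab$diversity <- 2
  tab$diversity[1] <- NA
  f <- fit_breadth_lm(tab)
  expect_equal(f$n_dropped, 1L)
})

test_that("available diversity drops when hosts crash at warming", {
  d <- experiment_design(parasitoids = c(Asobara = "larval"),
                         replicates_per_cell = 7)
  p <- true_params(d)
  surv <- p$survival_probs
  surv[c("H6", "H7"), "28"] <- 0   # two hosts driven extinct under warming
  p2 <- true_params(d, survival_probs = surv)
  v <- simulate_experiment(d, p2, host_tree, seed = 15)
  av <- available_diversity(v, host_tree)
  warm <- av$diversity[av$temperature == 28]
  amb <- av$diversity[av$temperature == 24]
  expect_true(all(warm < amb))
})

test_that("identical replicates make every shuffle identical; n_rand = 0 works", {
  d <- small_design(replicates_per_cell = 7)
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 16)
  trt <- v[v$parasitoid != "CONTROL", ]
  # clone replicate 1 into all replicates: shuffling cannot matter
  base <- trt[trt$replicate == 1, ]
  clones <- do.call(rbind, lapply(1:7, function(r) { b <- base; b$replicate <- r; b }))
  rs <- randomization_sensitivity(clones, host_tree, n_rand = 10, seed = 2)
  expect_true(all(abs(rs$draws - rs$chronological$estimate) < 1e-9))

  rs0 <- randomization_sensitivity(clones, host_tree, n_rand = 0, seed = 2)
  expect_equal(ncol(rs0$draws), 0L)
  expect_equal(rs0$chronological$estimate, rs$chronological$estimate)
})
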