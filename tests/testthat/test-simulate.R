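test_that("degenerate probabilities give fully deterministic vials", {
  d <- experiment_design(hosts = paste0("H", 1:7), replicates_per_cell = 2,
                         controls_per_cell = 2)
  surv <- matrix(1, 7, 3, dimnames = list(d$hosts, d$temperatures))
  p <- true_params(d, beta_temp = c(`20` = 20, `24` = 20, `28` = 20),
                   host_sd = 0, parasitoid_sd = 0, slope_sds = 0, phylo_sd = 0,
                   survival_probs = surv, escape_prob = 0)
  v <- simulate_experiment(d, p, host_tree, seed = 1)
  trt <- v[v$parasitoid != "CONTROL", ]
  expect_true(all(trt$P == trt$eggs))
  expect_true(all(trt$H == 0))
  ctl <- v[v$parasitoid == "CONTROL", ]
  expect_true(all(ctl$H == ctl$eggs))
})

test_that("default design produces the configured cell bookkeeping", {
  d <- experiment_design()
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 3)
  expect_equal(nrow(v), 7 * 3 * (4 * 10 + 7))
  trt <- v[v$parasitoid != "CONTROL", ]
  counts <- table(trt$host, trt$parasitoid, trt$temperature)
  expect_true(all(counts == 10))
  ctl <- v[v$parasitoid == "CONTROL", ]
  expect_true(all(table(ctl$host, ctl$temperature) == 7))
  expect_true(all(v$H + v$P <= v$eggs))
  expect_true(all(v$P[v$parasitoid == "CONTROL"] == 0))
})

test_that("identical seed and design give byte-identical output files", {
  d <- small_design(replicates_per_cell = 3, controls_per_cell = 2)
  p <- true_params(d)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_vials(simulate_experiment(d, p, host_tree, seed = 11), f1)
  write_vials(simulate_experiment(d, p, host_tree, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".csv")
  write_vials(simulate_experiment(d, p, host_tree, seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("adding cells to the design never perturbs existing vials", {
  d1 <- experiment_design(parasitoids = c(Asobara = "larval"),
                          replicates_per_cell = 4, controls_per_cell = 3)
  d2 <- experiment_design(parasitoids = c(Asobara = "larval", Extra = "pupal"),
                          replicates_per_cell = 4, controls_per_cell = 3)
  p1 <- true_params(d1, host_sd = 0, parasitoid_sd = 0, slope_sds = 0, phylo_sd = 0)
  p2 <- true_params(d2, host_sd = 0, parasitoid_sd = 0, slope_sds = 0, phylo_sd = 0)
  v1 <- simulate_experiment(d1, p1, host_tree, seed = 5)
  v2 <- simulate_experiment(d2, p2, host_tree, seed = 5)
  key <- function(v) paste(v$host, v$parasitoid, v$temperature, v$replicate)
  shared <- v2[match(key(v1), key(v2)), c("H", "P")]
  expect_equal(unname(as.matrix(shared)), unname(as.matrix(v1[, c("H", "P")])))
})

test_that("control emergence matches survival probabilities at 200 replicates", {
  d <- experiment_design(hosts = c("H1", "H4", "H7"),
                         parasitoids = c(Asobara = "larval"),
                         replicates_per_cell = 1, controls_per_cell = 200)
  p <- true_params(d)
  v <- simulate_experiment(d, p, host_tree, seed = 21)
  ctl <- v[v$parasitoid == "CONTROL", ]
  for (h in d$hosts) for (tt in d$temperatures) {
    prob <- p$survival_probs[h, as.character(tt)]
    x <- ctl$H[ctl$host == h & ctl$temperature == tt]
    se <- sqrt(prob * (1 - prob) / d$eggs_per_vial / length(x))
    expect_lt(abs(mean(x) / d$eggs_per_vial - prob), 3 * se + 1e-12)
  }
})

test_that("empirical logits recover beta_temp when all random effects vanish", {
  d <- experiment_design(hosts = c("H1", "H2"),
                         parasitoids = c(Asobara = "larval"),
                         replicates_per_cell = 500, controls_per_cell = 1)
  surv <- matrix(1, 2, 3, dimnames = list(d$hosts, d$temperatures))
  beta <- c(`20` = -0.4, `24` = 0.2, `28` = -1.5)
  p <- true_params(d, beta_temp = beta, host_sd = 0, parasitoid_sd = 0,
                   slope_sds = 0, phylo_sd = 0, survival_probs = surv,
                   escape_prob = 0.1)
  v <- simulate_experiment(d, p, host_tree, seed = 31)
  trt <- v[v$parasitoid != "CONTROL", ]
  for (tt in names(beta)) {
    sub <- trt[trt$temperature == as.numeric(tt), ]
    expect_lt(abs(qlogis(sum(sub$P) / sum(sub$eggs)) - beta[[tt]]), 0.05)
  }
})

test_that("a strong phylogenetic effect makes related hosts respond alike", {
  d <- experiment_design(parasitoids = c(Asobara = "larval"),
                         replicates_per_cell = 10, controls_per_cell = 1)
  surv <- matrix(1, 7, 3, dimnames = list(d$hosts, d$temperatures))
  p <- true_params(d, beta_temp = c(`20` = 0, `24` = 0, `28` = 0),
                   host_sd = 0, parasitoid_sd = 0, slope_sds = 0,
                   phylo_sd = 2, survival_probs = surv, escape_prob = 0)
  pd <- ape::cophenetic.phylo(host_tree)
  cors <- vapply(1:20, function(s) {
    v <- simulate_experiment(d, p, host_tree, seed = 40 + s)
    trt <- v[v$parasitoid != "CONTROL", ]
    rate <- tapply(trt$P, trt$host, sum) / tapply(trt$eggs, trt$host, sum)
    hosts <- names(rate)
    pairs <- which(upper.tri(pd[hosts, hosts]), arr.ind = TRUE)
    rdiff <- abs(rate[pairs[, 1]] - rate[pairs[, 2]])
    dist <- pd[hosts, hosts][upper.tri(pd[hosts, hosts])]
    stats::cor(rdiff, dist, method = "spearman")
  }, 0)
  expect_gt(mean(cors), 0)
  expect_gt(mean(cors > 0), 0.7)
})

test_that("invalid generator parameters are rejected up front", {
  d <- small_design(replicates_per_cell = 1, controls_per_cell = 1)
  expect_error(true_params(d, escape_prob = 1.5))
  expect_error(true_params(d, host_sd = -1))
  expect_error(true_params(d, beta_temp = c(a = 1, b = 2, c = 3)),
               "named by temperature")
  p <- true_params(d, phylo_sd = 1)
  expect_error(simulate_experiment(d, p, tree = NULL, seed = 1),
               "tree is required")
})

test_that("vial CSV io round-trips, preserves extras, and validates", {
  d <- small_design(replicates_per_cell = 2, controls_per_cell = 2)
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 8)
  v$note <- paste0("x", seq_len(nrow(v)))
  f <- tempfile(fileext = ".csv")
  write_vials(v, f)
  attr(v, "true_effects") <- NULL   # in-memory generator metadata, not schema
  expect_equal(read_vials(f), v)

  empty <- v[0, ]
  write_vials(empty, f)
  expect_equal(nrow(read_vials(f)), 0L)

  bad <- v[1:3, ]
  bad$H[2] <- bad$eggs[2] + 10
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_vials(f), "rows: 2")
  expect_error(validate_vials(v[, -match("eggs", names(v))]), "missing columns")
})
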