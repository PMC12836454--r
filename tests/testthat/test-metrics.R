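test_that("control baselines are arithmetic means per host x temperature", {
  vials <- data.frame(
    host = "H1", parasitoid = c("CONTROL", "CONTROL", "CONTROL", "Asobara"),
    temperature = 24, replicate = c(1, 2, 3, 1), eggs = 50,
    H = c(40, 42, 44, 10), P = c(0, 0, 0, 5))
  base <- control_baselines(vials)
  expect_equal(base$Hc, 42)
  expect_equal(base$n_control, 3L)

  one <- vials[c(1, 4), ]; one$H[1] <- 0
  expect_equal(control_baselines(one)$Hc, 0)
})

test_that("a missing control cell is an error naming the cell", {
  vials <- data.frame(host = "H2", parasitoid = "Asobara", temperature = 28,
                      replicate = 1, eggs = 50, H = 5, P = 3)
  expect_error(control_baselines(vials), "H2 x 28C")
})

test_that("baseline adjustment takes the larger of H, P and Hc", {
  expect_equal(adjust_baseline(3, 12, 10), data.frame(Hc_adj = 12, adjusted = TRUE))
  expect_equal(adjust_baseline(3, 5, 10), data.frame(Hc_adj = 10, adjusted = FALSE))
  expect_equal(adjust_baseline(15, 2, 10), data.frame(Hc_adj = 15, adjusted = TRUE))
})

test_that("outcome indices follow the defining formulas and stay in [0,1]", {
  idx <- outcome_indices(10, 20, 40)
  expect_equal(idx$parasitism_success, 0.25)
  expect_equal(idx$degree_of_infestation, 0.5)
  expect_equal(unlist(outcome_indices(0, 30, 30)), c(parasitism_success = 0,
                                                     degree_of_infestation = 0))
  expect_equal(unlist(outcome_indices(30, 0, 30)), c(parasitism_success = 1,
                                                     degree_of_infestation = 1))
  expect_true(all(is.na(outcome_indices(0, 0, 0))))
  expect_error(outcome_indices(12, 2, 10), "internal error")
})

test_that("model observations use round-half-up trials and valid outcomes", {
  oc <- data.frame(host = "H1", parasitoid = "A", temperature = 24,
                   replicate = 1, P = 10, H = 20, Hc_adj = 40,
                   adjusted = FALSE, excluded = FALSE)
  par_obs <- model_observations(oc, "parasitism")
  expect_equal(par_obs$successes, 10); expect_equal(par_obs$trials, 40)
  inf_obs <- model_observations(oc, "infestation")
  expect_equal(inf_obs$successes, 20); expect_equal(inf_obs$trials, 40)

  oc2 <- oc; oc2$Hc_adj <- 41.5; oc2$P <- 41
  m <- model_observations(oc2, "parasitism")
  expect_equal(m$trials, 42)   # round half up, not banker's
  expect_equal(m$successes, 41)
})

test_that("indices and model outcomes are valid on every synthetic dataset", {
  for (s in 1:3) {
    d <- small_design()
    v <- simulate_experiment(d, true_params(d), host_tree, seed = 60 + s)
    oc <- treatment_outcomes(v)
    ok <- !oc$excluded
    expect_true(all(oc$parasitism_success[ok] >= 0 & oc$parasitism_success[ok] <= 1))
    expect_true(all(oc$degree_of_infestation[ok] >= 0 &
                      oc$degree_of_infestation[ok] <= 1))
    for (kind in c("parasitism", "infestation")) {
      m <- model_observations(oc, kind)
      expect_true(all(m$successes >= 0 & m$successes <= m$trials))
    }
  }
})

test_that("adjustment frequency decreases with true parasitoid impact", {
  d <- small_design()
  # strong impact: most survivors parasitized or killed, H stays far below Hc.
  # weak impact: attack is inconsequential (escape certain), so H is
  # distributed like a control vial and exceeds the mean Hc half the time.
  strong <- true_params(d, beta_temp = c(`20` = 1, `24` = 1, `28` = 1),
                        host_sd = 0.1, parasitoid_sd = 0.1, slope_sds = 0.1,
                        phylo_sd = 0, escape_prob = 0.05)
  weak <- true_params(d, beta_temp = c(`20` = -5, `24` = -5, `28` = -5),
                      host_sd = 0.1, parasitoid_sd = 0.1, slope_sds = 0.1,
                      phylo_sd = 0, escape_prob = 1)
  frac <- function(p, s) {
    oc <- treatment_outcomes(simulate_experiment(d, p, host_tree, seed = s))
    mean(oc$adjusted)
  }
  fr <- vapply(1:5, function(s) c(frac(strong, s), frac(weak, s)), numeric(2))
  expect_true(all(fr[1, ] <= fr[2, ]))
})

test_that("indices ignore vial order and duplicated identical controls", {
  d <- small_design(replicates_per_cell = 3, controls_per_cell = 3)
  v <- simulate_experiment(d, true_params(d), host_tree, seed = 77)
  oc1 <- treatment_outcomes(v)
  set.seed(1)
  v2 <- v[sample(nrow(v)), ]
  oc2 <- treatment_outcomes(v2)
  key <- function(d) paste(d$host, d$parasitoid, d$temperature, d$replicate)
  oc2 <- oc2[match(key(oc1), key(oc2)), ]
  expect_equal(oc2$parasitism_success, oc1$parasitism_success)

  # duplicating a control vial with identical H leaves Hc unchanged
  ctl <- v[v$parasitoid == "CONTROL", ]
  dup <- ctl[ctl$host == "H1" & ctl$temperature == 24, ][1, ]
  dup$replicate <- 99
  base1 <- control_baselines(v)
  dup$H <- base1$Hc[base1$host == "H1" & base1$temperature == 24]
  if (dup$H == round(dup$H)) {
    base2 <- control_baselines(rbind(v, dup))
    expect_equal(base2$Hc[base2$host == "H1" & base2$temperature == 24],
                 dup$H)
  }
})

test_that("host developmental success pairs emergence with egg trials", {
  vials <- data.frame(host = c("H1", "H1"), parasitoid = "CONTROL",
                      temperature = 24, replicate = 1:2, eggs = 50,
                      H = c(30, 0), P = 0)
  hd <- host_dev_success(vials)
  expect_equal(hd$successes, c(30, 0))
  expect_equal(hd$trials, c(50, 50))
})
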