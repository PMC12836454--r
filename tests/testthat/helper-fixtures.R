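# shared fixtures: everything is generated in code, nothing read from disk

host_tree <- example_host_tree()

# a compact design for fast simulation-based tests
small_design <- function(replicates_per_cell = 8, ...) {
  experiment_design(
    parasitoids = c(Asobara = "larval", Leptopilina = "larval",
                    Ganaspis = "larval"),
    replicates_per_cell = replicates_per_cell, ...
  )
}

quick_mcmc <- function(chains = 2, warmup = 400, draws = 400) {
  list(chains = chains, warmup = warmup, draws_per_chain = draws, adapt = 300)
}

# random ultrametric tree with n tips on unique labels
random_ultrametric <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rcoal(n, tip.label = labels)
  validate_tree(tr, ultrametric = TRUE)
}

# ordinary (taxonomic) Hill number, closed form
hill_taxonomic <- function(x, q) {
  p <- x[x > 0] / sum(x)
  if (abs(q - 1) < 1e-12) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

# independent branch-enumeration oracle for phylogenetic Hill diversity:
# walks every tip's root path through the raw edge matrix, never using
# branch_segments()
hill_phylo_oracle <- function(abundances, tree, q) {
  rel <- abundances / sum(abundances)
  root <- ape::Ntip(tree) + 1L
  a <- numeric(nrow(tree$edge))
  for (tip in seq_len(ape::Ntip(tree))) {
    w <- rel[tree$tip.label[tip]]
    if (is.na(w) || w == 0) next
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      a[e] <- a[e] + w
      node <- tree$edge[e, 1]
    }
  }
  keep <- a > 0
  L <- tree$edge.length[keep]; a <- a[keep]
  Tbar <- sum(L * a)
  if (abs(q - 1) < 1e-12) exp(-sum((L / Tbar) * a * log(a)))
  else sum((L / Tbar) * a^q)^(1 / (1 - q))
}

# minimal hand-built posterior for contrast algebra tests: fixed beta draws,
# all random effects identically zero
fake_fit <- function(beta_draws, temps = c(20, 24, 28), hosts = c("h1", "h2"),
                     baseline = 24) {
  n <- nrow(beta_draws)
  cols <- c(sprintf("beta[%d]", seq_along(temps)),
            sprintf("a[%d]", seq_along(hosts)),
            as.vector(outer(seq_along(hosts), seq_along(temps),
                            function(s, t) sprintf("b[%d,%d]", s, t))),
            "sd_a", "sd_b")
  m <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  m[, seq_along(temps)] <- beta_draws
  structure(list(
    draws = coda::as.mcmc.list(list(coda::mcmc(m))),
    data = NULL,
    spec = model_spec("parasitism", "pupal", include_phylo = FALSE,
                      baseline_temperature = baseline),
    levels = list(hosts = hosts, parasitoids = character(), temperatures = temps)
  ), class = "pg_fit")
}
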