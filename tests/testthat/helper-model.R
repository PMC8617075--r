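## Shared fixtures, built once per test run.

REG <- species_registry()
GUILDS <- guild_definitions()
MATS <- build_matrices(GUILDS, REG)
ELEMS <- c("C", "H", "O", "N", "S", "Fe", "Mn")

## independent element/charge oracle: dot product of each reaction column
## with the registry composition maps (never uses reaction_balance)
balance_residuals <- function(A, registry, mats) {
  st <- c(mats$species, rep("biomass", mats$n_guilds))
  comp <- as.matrix(registry[st, ELEMS])
  chg <- registry[st, "charge"]
  cbind(t(A) %*% comp, charge = drop(t(A) %*% chg))
}

## toy registry for activity-independent reaction-energy tests: gaseous
## reference convention (dGf(H2) = dGf(O2) = 0)
toy_registry <- function() {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "name,phase,charge,C,H,O,N,S,Fe,Mn,dGf0,dHf0",
    "H2,gas,0,0,2,0,0,0,0,0,0,0",
    "O2,gas,0,0,0,2,0,0,0,0,0,0",
    "H2O,liquid,0,0,2,1,0,0,0,0,-237.1,-285.8",
    "Na+,aqueous,1,0,0,0,0,0,0,0,-262,-240",
    "solidX,solid,0,0,0,0,0,1,0,0,-10,-12"
  ), f)
  species_registry(f)
}

## total carbon over a trajectory (independent of the model's bookkeeping)
carbon_total <- function(traj, registry, mats) {
  Cw <- c(registry[mats$species, "C"], rep(1, mats$n_guilds))
  as.matrix(traj[, mats$state]) %*% Cw
}

fixture_sites <- function() {
  read_site_table(system.file("extdata", "tag_like_site_synthetic.csv",
                              package = "plumeMTS"))
}
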