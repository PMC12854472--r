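# Shared fixtures and independent oracles for the suite.

tree_from_text <- function(txt, strict = TRUE) {
  validate_phylogeny(ape::read.tree(text = txt), strict = strict)
}

# small trees used across files
fix_two_tip <- function() tree_from_text("(A:1,B:3);")
fix_three_tip <- function() tree_from_text("((A:1,B:1):1,C:2);")
fix_star4 <- function() tree_from_text("(A:1,B:1,C:1,D:1);", strict = FALSE)
fix_four_asym <- function() tree_from_text("(((A:0.5,B:2):1,C:3):0.7,D:1.2);")
fix_five_tip <- function()
  tree_from_text("((((A:0.4,B:1.1):0.6,C:2):0.3,D:0.9):1,E:2.5);")

# brute-force oracle for Brownian-motion ancestral states: numerically
# minimize the branch-length-weighted sum of squared changes over the
# internal-node values, independent of the package's linear solve.
oracle_ancestral <- function(phy, z_tip) {
  n_tip <- length(phy$tip.label)
  z_tip <- z_tip[phy$tip.label]
  fn <- function(u) {
    zz <- c(z_tip, u)
    sum((zz[phy$edge[, 1]] - zz[phy$edge[, 2]])^2 / phy$edge.length)
  }
  o <- stats::optim(rep(mean(z_tip), phy$Nnode), fn, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))
  o$par
}

# trait table builder: one row per specimen from a matrix + labels
make_traits <- function(z, taxon, sex, trait_names = NULL) {
  z <- as.matrix(z)
  if (is.null(trait_names)) trait_names <- paste0("tr", seq_len(ncol(z)))
  df <- data.frame(specimen_id = paste0("s", seq_len(nrow(z))),
                   taxon = taxon, sex = sex, z,
                   stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- trait_names
  as_trait_table(df)
}

# balanced-cell random trait table: n per (taxon, sex) cell
random_traits <- function(taxa, n_per_cell = 5, p = 3, seed = 1,
                          sd = 1) {
  set.seed(seed)
  rows <- expand.grid(taxon = taxa, sex = c("F", "M"),
                      i = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  z <- matrix(rnorm(nrow(rows) * p, sd = sd), nrow(rows), p)
  make_traits(z, rows$taxon, rows$sex)
}

# demographic parameter builder: same Ne/t structure at every node
make_params <- function(node_ids, Ne = 10000, div = 250000, gen = 25) {
  as_branch_params(data.frame(node_id = node_ids,
                              Ne_mean = Ne, Ne_lower = Ne / 2,
                              Ne_upper = Ne * 2,
                              divergence_time = div,
                              generation_length = gen,
                              stringsAsFactors = FALSE))
}

table1_fixture <- function() {
  path <- system.file("extdata", "hominoid_table1.tsv",
                      package = "ggdrift")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# collapse the package's 5-level regime to the 3 categories recoverable
# from the published table's text emphasis
coarse_regime <- function(x) {
  x <- as.character(x)
  x[x %in% c("very_slow", "slow")] <- "slow"
  x[x %in% c("fast", "very_fast")] <- "fast"
  x
}

strong_scenario <- function(seed = 101, c_shift = 6) {
  simulation_scenario(selected_branch = "t1",
                      beta_true = c(2, -1.5, 1, 0, 0, 0),
                      shift_scale = c_shift, seed = seed)
}
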