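#' Default balanced 8-tip simulation tree
#'
#' Fully bifurcating, all branch lengths 1; tips `t1..t8`.
#'
#' @return A `phylo` object.
#' @export
default_sim_tree <- function() {
  txt <- paste0("(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
                "((t5:1,t6:1):1,(t7:1,t8:1):1):1);")
  validate_phylogeny(ape::read.tree(text = txt))
}

# compound-symmetric covariance
cs_matrix <- function(p, var = 1, cov = 0.3) {
  m <- matrix(cov, p, p)
  diag(m) <- var
  m
}

#' Construct a simulation scenario
#'
#' A stated world for the whole pipeline: a tree, a true phenotypic
#' covariance `P_true` and genetic covariance `G_true = h2 * P_true`,
#' per-node demographic parameters, sampling sizes, and optionally a
#' single branch carrying a deterministic directional-selection shift
#' `c * G_true %*% beta_true` in its drift increment. Defaults: a
#' balanced 8-tip tree, p = 6 traits, compound-symmetric P (variance 1,
#' covariance 0.3), h2 = 0.4, 50 specimens per taxon, and Ne/t = 1 on
#' every branch (Ne = 10000, divergence 250000 years, generation 25
#' years), so that a neutral branch's GGD computed with the true
#' quantities is exactly chi-square(p).
#'
#' @param phy Tree; default [default_sim_tree()].
#' @param p Number of traits.
#' @param P_true Phenotypic covariance matrix (p x p).
#' @param h2 True heritability; `G_true = h2 * P_true`.
#' @param Ne,divergence_time,generation_length Demography shared by all
#'   nodes (scalars), with `Ne_lower`/`Ne_upper` defaulting to
#'   0.5x / 2x the mean.
#' @param n_per_taxon Specimens per tip taxon (>= 2).
#' @param sex_effect Length-p vector added to one sex's mean; default 0.
#' @param selected_branch Descendant id of the branch under selection
#'   (a tip label or internal node id), or `NULL` for pure drift.
#' @param beta_true Length-p true selection gradient for the selected
#'   branch.
#' @param shift_scale Non-negative scalar c multiplying the
#'   deterministic shift `G_true %*% beta_true`.
#' @param root_mean Length-p root state; default 0. With logged traits
#'   in mind the default keeps means near 0; a constant offset passes
#'   through every stage unchanged.
#' @param seed Integer seed governing all randomness in the scenario.
#' @return A list of class `sim_scenario`.
#' @export
simulation_scenario <- function(phy = default_sim_tree(), p = 6,
                                P_true = cs_matrix(p),
                                h2 = 0.4,
                                Ne = 10000, divergence_time = 250000,
                                generation_length = 25,
                                n_per_taxon = 50,
                                sex_effect = rep(0, p),
                                selected_branch = NULL,
                                beta_true = NULL,
                                shift_scale = 0,
                                root_mean = rep(0, p),
                                seed = 1L) {
  phy <- validate_phylogeny(phy, strict = FALSE)
  if (nrow(P_true) != p) stop("P_true dimension != p")
  ev <- eigen((P_true + t(P_true)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(ev)) stop("P_true is not PSD")
  if (shift_scale < 0) stop("shift_scale must be >= 0")
  if (!is.null(selected_branch)) {
    ids <- c(phy$tip.label, unname(internal_node_ids(phy)))
    if (!selected_branch %in% ids)
      stop("selected_branch not a node of the tree: ", selected_branch)
    if (is.null(beta_true) || length(beta_true) != p)
      stop("beta_true of length p required with selected_branch")
  }
  ids <- unname(internal_node_ids(phy))
  params <- as_branch_params(data.frame(
    node_id = ids,
    Ne_mean = Ne, Ne_lower = Ne / 2, Ne_upper = Ne * 2,
    divergence_time = divergence_time,
    generation_length = generation_length,
    stringsAsFactors = FALSE))
  structure(list(phy = phy, p = p, P_true = P_true,
                 G_true = h2 * P_true, h2_true = h2,
                 params = params, n_per_taxon = n_per_taxon,
                 sex_effect = sex_effect,
                 selected_branch = selected_branch,
                 beta_true = beta_true, shift_scale = shift_scale,
                 root_mean = root_mean, seed = as.integer(seed)),
            class = "sim_scenario")
}

# edge list with character ids: parent_id (internal id), child_id
# (tip label or internal id), in preorder
edge_ids <- function(phy) {
  ids <- internal_node_ids(phy)
  n_tip <- length(phy$tip.label)
  e <- stats::reorder(phy, "cladewise")$edge
  data.frame(parent = e[, 1], child = e[, 2],
             parent_id = unname(ids[as.character(e[, 1])]),
             child_id = ifelse(e[, 2] <= n_tip,
                               phy$tip.label[pmin(e[, 2], n_tip)],
                               unname(ids[as.character(e[, 2])])),
             stringsAsFactors = FALSE)
}

# draw n MVN(0, Sigma) rows given the upper Cholesky factor
rmvn_chol <- function(n, R) {
  p <- ncol(R)
  matrix(stats::rnorm(n * p), n, p) %*% R
}

#' Simulate node trait means under drift (plus an optional shift)
#'
#' The root mean is fixed; each branch adds an increment drawn from
#' `MVN(0, (t/Ne) * G_true)` using its ancestral node's parameters. On
#' the selected branch the deterministic shift
#' `shift_scale * G_true %*% beta_true` (the expected response to one
#' generation-aggregate of selection beta) is added. Constructed so
#' that, on a neutral branch, `GGD = (Ne/t) * dz' G_true^-1 dz` is
#' chi-square(p) exactly.
#'
#' @param scn A `sim_scenario`.
#' @param seed Seed; defaults to the scenario's. Pass explicitly when
#'   drawing replicate worlds.
#' @return Matrix (tips + internal nodes) x p of true node means,
#'   rownames = tip labels and internal node ids.
#' @export
simulate_drift_means <- function(scn, seed = scn$seed) {
  phy <- scn$phy
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  ids <- internal_node_ids(phy)
  net <- stats::setNames(ne_over_t(scn$params, "mean"),
                         scn$params$node_id)
  R <- chol((scn$G_true + t(scn$G_true)) / 2 +
              diag(1e-12, scn$p))
  shift <- if (!is.null(scn$selected_branch))
    scn$shift_scale * drop(scn$G_true %*% scn$beta_true)
  else NULL
  e <- edge_ids(phy)
  m <- matrix(NA_real_, n_all, scn$p)
  root <- n_tip + 1L
  m[root, ] <- scn$root_mean
  with_seed(seed, {
    inc <- rmvn_chol(nrow(e), R)
    for (k in seq_len(nrow(e))) {
      sd_scale <- sqrt(1 / net[[e$parent_id[k]]])  # sqrt(t/Ne)
      step <- inc[k, ] * sd_scale
      if (!is.null(shift) && e$child_id[k] == scn$selected_branch)
        step <- step + shift
      m[e$child[k], ] <- m[e$parent[k], ] + step
    }
  })
  rownames(m) <- c(phy$tip.label,
                   unname(ids[as.character(n_tip + seq_len(phy$Nnode))]))
  colnames(m) <- paste0("tr", seq_len(scn$p))
  m
}

#' Simulate specimen-level data around tip means
#'
#' Per taxon, `n_per_taxon` multivariate-normal draws centered on the
#' taxon mean with covariance `P_true`; half the specimens are assigned
#' each sex and `sex_effect` is added to sex `"M"`.
#'
#' @param scn A `sim_scenario`.
#' @param means Node-mean matrix from [simulate_drift_means()] (only
#'   tip rows are used).
#' @param seed Seed; defaults to the scenario's plus 1.
#' @return A `trait_table`.
#' @export
simulate_specimens <- function(scn, means, seed = scn$seed + 1L) {
  n <- scn$n_per_taxon
  if (n < 2) stop("n_per_taxon must be >= 2")
  phy <- scn$phy
  R <- chol((scn$P_true + t(scn$P_true)) / 2 + diag(1e-12, scn$p))
  sex <- rep(c("F", "M"), length.out = n)
  rows <- with_seed(seed, {
    lapply(phy$tip.label, function(tx) {
      x <- rmvn_chol(n, R)
      x <- sweep(x, 2, means[tx, ], `+`)
      x[sex == "M", ] <- sweep(x[sex == "M", , drop = FALSE], 2,
                               scn$sex_effect, `+`)
      data.frame(specimen_id = paste0(tx, "_", seq_len(n)),
                 taxon = tx, sex = sex, x,
                 stringsAsFactors = FALSE)
    })
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:3)] <- colnames(means)
  as_trait_table(df)
}

#' Null-calibration experiment for the drift test
#'
#' Repeatedly simulates pure drift (requires `shift_scale = 0`) and
#' records, per branch, how often the GGD test rejects neutrality. With
#' `estimate = FALSE` (default) the GGD uses the true node means, the
#' true W (= G_true) and the true Ne/t, so the statistic is exactly
#' chi-square(p) and the observed rates should match the nominal ones.
#' With `estimate = TRUE` the full estimation pipeline is run per
#' replicate (specimen sampling, ancestral reconstruction, estimated
#' W); the resulting inflation is reported, not asserted.
#'
#' @param scn A `sim_scenario` with no selected branch.
#' @param n_reps Number of replicate worlds.
#' @param alpha_levels Two-tailed levels, as in [ggd_config()].
#' @param estimate Run the estimation pipeline instead of using truth.
#' @return List: `rates` (per-branch data frame with rejection
#'   proportions at each level), `overall` (pooled across branches),
#'   `ggd` (n_reps x n_branches matrix of mean-Ne/t GGD draws),
#'   `alpha_levels`, `n_reps`.
#' @export
null_calibration_experiment <- function(scn, n_reps = 500,
                                        alpha_levels = c(0.05, 0.001),
                                        estimate = FALSE) {
  if (scn$shift_scale != 0 || !is.null(scn$selected_branch))
    stop("null calibration requires a pure-drift scenario")
  e <- edge_ids(scn$phy)
  g <- matrix(NA_real_, n_reps, nrow(e))
  colnames(g) <- e$child_id
  for (r in seq_len(n_reps)) {
    seed_r <- scn$seed + 7L * r
    g[r, ] <- if (estimate)
      pipeline_branch_ggd(scn, seed_r)
    else {
      m <- simulate_drift_means(scn, seed = seed_r)
      true_branch_ggd(scn, m, e)
    }
  }
  df <- scn$p
  regime <- classify_rate(g, df = df, alpha_levels = alpha_levels)
  rej1 <- matrix(regime != "neutral", n_reps, nrow(e))
  rej2 <- matrix(regime %in% c("very_slow", "very_fast"),
                 n_reps, nrow(e))
  rates <- data.frame(branch = e$child_id,
                      reject_alpha1 = colMeans(rej1),
                      reject_alpha2 = colMeans(rej2),
                      stringsAsFactors = FALSE)
  list(rates = rates,
       overall = c(reject_alpha1 = mean(rej1), reject_alpha2 = mean(rej2)),
       ggd = g, alpha_levels = alpha_levels, n_reps = n_reps)
}

# GGD per branch from true node means / true W / true Ne/t
true_branch_ggd <- function(scn, means, e = edge_ids(scn$phy)) {
  Ginv <- solve(scn$G_true)
  net <- stats::setNames(ne_over_t(scn$params, "mean"),
                         scn$params$node_id)
  vapply(seq_len(nrow(e)), function(k) {
    d <- means[e$child_id[k], ] - means[e$parent_id[k], ]
    net[[e$parent_id[k]]] * drop(crossprod(d, Ginv %*% d))
  }, numeric(1))
}

# one full estimation pipeline pass; returns mean-Ne/t GGD per branch
# (order of edge_ids) — used by the calibration and recovery experiments
pipeline_branch_ggd <- function(scn, seed, return_all = FALSE) {
  m <- simulate_drift_means(scn, seed = seed)
  traits <- simulate_specimens(scn, m, seed = seed + 1L)
  tm <- tip_means(traits)
  anc <- estimate_ancestral_states(scn$phy, tm)
  res <- residualize(traits)
  w <- suppressWarnings(pooled_within_cov(res))
  w <- apply_heritability(w, scn$h2_true)
  winv <- invert_w(w)$inv
  cfg <- ggd_config(h2 = scn$h2_true, pooling = "all")
  rates <- branch_rates(scn$phy, anc, tm, winv, scn$params, cfg)
  e <- edge_ids(scn$phy)
  ord <- match(e$child_id, rates$descendant)
  if (return_all)
    list(rates = rates[ord, ], anc = anc, tips = tm, winv = winv,
         means = m, traits = traits)
  else
    rates$ggd_mean[ord]
}

#' Power and gradient-recovery experiment under directional selection
#'
#' Repeatedly simulates the scenario (which should carry a selected
#' branch with `shift_scale > 0`), runs the full estimation pipeline,
#' and records whether the selected branch is flagged fast/very_fast at
#' the mean Ne/t, the sign agreement between the reconstructed and true
#' gradients on the non-null traits, and their Pearson correlation.
#' With `shift_scale = 0` this reduces to the null and the flag rate
#' approaches the upper-tail test size.
#'
#' @param scn A `sim_scenario`.
#' @param n_reps Number of replicate worlds.
#' @return List: `per_rep` data frame (`flagged`, `sign_agree`,
#'   `correlation`), and `summary` with `flag_rate`,
#'   `mean_sign_agree`, `mean_correlation`.
#' @export
recovery_experiment <- function(scn, n_reps = 200) {
  e <- edge_ids(scn$phy)
  target <- scn$selected_branch
  strong <- if (!is.null(scn$beta_true)) which(scn$beta_true != 0)
  else integer(0)
  out <- data.frame(flagged = logical(n_reps),
                    sign_agree = NA_real_,
                    correlation = NA_real_)
  for (r in seq_len(n_reps)) {
    pr <- pipeline_branch_ggd(scn, seed = scn$seed + 11L * r,
                              return_all = TRUE)
    rr <- pr$rates
    if (!is.null(target)) {
      row <- rr[rr$descendant == target, ]
      out$flagged[r] <- row$regime_mean %in% c("fast", "very_fast")
      z_anc <- pr$anc$estimate[row$anc_node, ]
      z_desc <- if (target %in% rownames(pr$tips)) pr$tips[target, ]
      else pr$anc$estimate[target, ]
      beta_hat <- selection_gradient(z_anc, z_desc, pr$winv)
      if (length(strong))
        out$sign_agree[r] <- mean(sign(beta_hat[strong]) ==
                                    sign(scn$beta_true[strong]))
      out$correlation[r] <- stats::cor(beta_hat, scn$beta_true)
    }
  }
  list(per_rep = out,
       summary = c(flag_rate = mean(out$flagged),
                   mean_sign_agree = mean(out$sign_agree, na.rm = TRUE),
                   mean_correlation = mean(out$correlation,
                                           na.rm = TRUE)))
}

#' Write a simulated dataset to disk
#'
#' Emits the Newick tree, a specimen trait CSV, a branch-parameter TSV
#' and a truth JSON (node means, selected branch, true gradient) so a
#' full pipeline run needs no external download.
#'
#' @param scn A `sim_scenario`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  means <- simulate_drift_means(scn)
  traits <- simulate_specimens(scn, means)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.csv"),
             params = file.path(dir, "params.tsv"),
             truth = file.path(dir, "truth.json"))
  ape::write.tree(scn$phy, file = paths[["tree"]])
  utils::write.csv(as.data.frame(traits), paths[["traits"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(scn$params), paths[["params"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- list(node_means = data.frame(node = rownames(means),
                                        as.data.frame(means),
                                        stringsAsFactors = FALSE),
                selected_branch = scn$selected_branch,
                beta_true = scn$beta_true,
                shift_scale = scn$shift_scale,
                h2_true = scn$h2_true, seed = scn$seed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
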