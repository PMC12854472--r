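#' Run the full drift/selection pipeline from a config file
#'
#' Stages, in order: read and cross-validate inputs; per-taxon means;
#' Brownian-motion ancestral reconstruction; pooled within-group
#' covariance (sex- and taxon-corrected, heritability-scaled) and its
#' inverse; per-branch GGD drift tests under the mean/lower/upper Ne
#' bounds; and, only for branches whose mean-Ne/t regime is `fast` or
#' `very_fast` (the drift null is rejected in the upper tail),
#' selection-gradient reconstruction with bootstrap CIs. Gradient
#' bootstrapping needs specimens, so flagged branches ending in an
#' internal node are reported in the manifest but not bootstrapped.
#'
#' The config is a JSON object with fields `tree`, `traits`, `params`
#' (paths, resolved relative to the config file), optional
#' `log_transform` (default false), and any of the [ggd_config()]
#' fields (`h2`, `bootstrap_reps`, `alpha_levels`, `rng_seed`,
#' `pooling`, `tail_convention`, `cov_divisor`), plus optional
#' `trait_groups` (object: group -> array of trait names).
#'
#' @param config Path to a JSON config file, or an equivalent named
#'   list (then paths are taken as-is).
#' @param out_dir Output directory; receives `ancestral.tsv`,
#'   `rates.tsv`, `gradients.tsv` and `manifest.json`.
#' @param all_branches Compute gradients for every tip branch rather
#'   than only drift-rejecting ones.
#' @return Invisibly, a list with the computed objects (`anc`, `rates`,
#'   `gradients`, `manifest`) and the output paths.
#' @export
run_pipeline <- function(config, out_dir, all_branches = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); warns <- character()
  note <- function(w) { warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning") }
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    r <- tryCatch(withCallingHandlers(expr, warning = note),
                  error = function(e)
                    stop("stage '", name, "' failed: ",
                         conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    r
  }

  if (is.character(config)) {
    cfg_path <- config
    cj <- jsonlite::read_json(config, simplifyVector = TRUE)
    base <- dirname(normalizePath(config))
    for (f in c("tree", "traits", "params"))
      if (!is.null(cj[[f]]) && !file.exists(cj[[f]]))
        cj[[f]] <- file.path(base, cj[[f]])
  } else {
    cfg_path <- NULL
    cj <- config
  }
  for (f in c("tree", "traits", "params"))
    if (is.null(cj[[f]])) stop("config missing '", f, "'")
  take <- function(nm, default) if (is.null(cj[[nm]])) default else cj[[nm]]
  cfg <- ggd_config(h2 = take("h2", 0.4),
                    bootstrap_reps = take("bootstrap_reps", 1000L),
                    alpha_levels = unlist(take("alpha_levels",
                                               c(0.05, 0.001))),
                    tail_convention = take("tail_convention", "alpha"),
                    rng_seed = take("rng_seed", 1L),
                    pooling = take("pooling", "descendants"),
                    cov_divisor = take("cov_divisor", "n_minus_g"))

  phy <- stage("read_tree", read_phylogeny(cj$tree))
  traits <- stage("read_traits",
                  read_trait_table(cj$traits,
                                   log_transform = isTRUE(cj$log_transform)))
  params <- stage("read_params", read_branch_params(cj$params))
  stage("validate", validate_traits_vs_tree(traits, phy))

  tm <- stage("tip_means", tip_means(traits))
  anc <- stage("ancestral", estimate_ancestral_states(phy, tm))
  winv <- stage("covariance", branch_winv(phy, traits, cfg))
  rates <- stage("rates", branch_rates(phy, anc, tm, winv, params, cfg))

  n_tip <- length(phy$tip.label)
  fast <- rates$regime_mean %in% c("fast", "very_fast")
  pick <- if (all_branches) rates$descendant %in% phy$tip.label
  else fast & rates$descendant %in% phy$tip.label
  skipped <- rates$descendant[fast & !(rates$descendant %in% phy$tip.label)]
  if (length(skipped))
    warns <- c(warns, paste0("flagged internal-node branch not ",
                             "bootstrapped: ",
                             paste(skipped, collapse = ", ")))
  grads <- stage("gradients", {
    blocks <- lapply(which(pick), function(k) {
      br <- rates[k, ]
      sel <- branch_selection(traits, br$descendant,
                              anc$estimate[br$anc_node, ],
                              winv[[br$anc_node]]$inv,
                              B = cfg$bootstrap_reps,
                              seed = cfg$rng_seed)
      bounds_agree <- all(c(br$regime_lower, br$regime_upper) %in%
                            c("fast", "very_fast"))
      cbind(branch = paste0(br$anc_node, ":", br$descendant),
            sel, bounds_agree = bounds_agree,
            stringsAsFactors = FALSE)
    })
    if (length(blocks)) do.call(rbind, blocks)
    else data.frame(branch = character(), trait = character(),
                    beta = numeric(), ci_lower = numeric(),
                    ci_upper = numeric(), response_pct = numeric(),
                    response_pct_logged = numeric(),
                    significant = logical(),
                    classification = character(),
                    bounds_agree = logical())
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ancestral = file.path(out_dir, "ancestral.tsv"),
             rates = file.path(out_dir, "rates.tsv"),
             gradients = file.path(out_dir, "gradients.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_ancestral_tsv(anc, paths[["ancestral"]])
  write_rates_tsv(rates, paths[["rates"]])
  utils::write.table(grads, paths[["gradients"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    inputs = lapply(stats::setNames(nm = c("tree", "traits", "params")),
                    function(f) list(path = cj[[f]],
                                     md5 = unname(tools::md5sum(cj[[f]])))),
    config_file = if (!is.null(cfg_path))
      list(path = cfg_path, md5 = unname(tools::md5sum(cfg_path)))
    else "inline",
    settings = unclass(cfg),
    seed = cfg$rng_seed,
    package_version = as.character(utils::packageVersion("ggdrift")),
    timings_sec = as.list(timings),
    warnings = warns,
    outputs = as.list(paths[c("ancestral", "rates", "gradients")]),
    total_sec = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  for (w in warns) message("[warn] ", w)
  invisible(list(anc = anc, rates = rates, gradients = grads,
                 manifest = manifest, paths = paths))
}

# minimal --key value / --flag parser for the CLI
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    } else { out[[key]] <- TRUE; i <- i + 1L }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--out DIR [--seed N] [--selected BRANCH --shift C]
#'     [--n-per-taxon N]` — write a synthetic dataset with truth.}
#'   \item{run}{`--config FILE --out DIR [--all-branches]` — full
#'     pipeline.}
#'   \item{reconstruct}{`--tree F --traits F --out F [--log]` —
#'     ancestral states TSV only.}
#'   \item{rates}{`--tree F --traits F --params F --out F [--h2 X]
#'     [--pooling descendants|all] [--log]` — drift-test table only.}
#'   \item{gradients}{`--tree F --traits F --params F --branch
#'     ANC:DESC --out F [--reps B] [--seed N] [--h2 X] [--log]` —
#'     selection analysis for one branch.}
#'   \item{report}{`--rates F` — regime summary of a rates TSV to
#'     stdout.}
#' }
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status 0 invisibly; errors propagate.
#' @export
ggd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: ggdrift <simulate|run|reconstruct|",
                          "rates|gradients|report> [options]")
  cmd <- args[[1L]]
  opt <- parse_cli_args(args[-1L])
  need <- function(...) {
    for (k in c(...)) if (is.null(opt[[k]]))
      stop("'", cmd, "' requires --", k)
  }
  load_inputs <- function() {
    need("tree", "traits")
    phy <- read_phylogeny(opt$tree)
    traits <- read_trait_table(opt$traits,
                               log_transform = isTRUE(opt$log))
    validate_traits_vs_tree(traits, phy)
    list(phy = phy, traits = traits)
  }
  switch(cmd,
    simulate = {
      need("out")
      seed <- as.integer(if (is.null(opt$seed)) 1L else opt$seed)
      scn <- if (!is.null(opt$selected)) {
        p <- 6
        simulation_scenario(selected_branch = opt$selected,
                            beta_true = c(2, -1.5, 1, rep(0, p - 3)),
                            shift_scale = as.numeric(
                              if (is.null(opt$shift)) 6 else opt$shift),
                            n_per_taxon = as.integer(
                              if (is.null(opt[["n-per-taxon"]])) 50
                              else opt[["n-per-taxon"]]),
                            seed = seed)
      } else {
        simulation_scenario(n_per_taxon = as.integer(
          if (is.null(opt[["n-per-taxon"]])) 50
          else opt[["n-per-taxon"]]), seed = seed)
      }
      paths <- write_scenario(scn, opt$out)
      message("wrote: ", paste(paths, collapse = ", "))
    },
    run = {
      need("config", "out")
      run_pipeline(opt$config, opt$out,
                   all_branches = isTRUE(opt[["all-branches"]]))
      message("pipeline complete: ", opt$out)
    },
    reconstruct = {
      inp <- load_inputs(); need("out")
      anc <- estimate_ancestral_states(inp$phy, tip_means(inp$traits))
      write_ancestral_tsv(anc, opt$out)
      message("wrote ", opt$out)
    },
    rates = {
      inp <- load_inputs(); need("params", "out")
      params <- read_branch_params(opt$params)
      cfg <- ggd_config(h2 = as.numeric(if (is.null(opt$h2)) 0.4
                                        else opt$h2),
                        pooling = if (is.null(opt$pooling)) "descendants"
                        else opt$pooling)
      tm <- tip_means(inp$traits)
      anc <- estimate_ancestral_states(inp$phy, tm)
      winv <- branch_winv(inp$phy, inp$traits, cfg)
      write_rates_tsv(branch_rates(inp$phy, anc, tm, winv, params, cfg),
                      opt$out)
      message("wrote ", opt$out)
    },
    gradients = {
      inp <- load_inputs(); need("params", "branch", "out")
      parts <- strsplit(opt$branch, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("--branch must be ANC:DESC")
      cfg <- ggd_config(h2 = as.numeric(if (is.null(opt$h2)) 0.4
                                        else opt$h2),
                        bootstrap_reps = as.integer(
                          if (is.null(opt$reps)) 1000L else opt$reps),
                        rng_seed = as.integer(
                          if (is.null(opt$seed)) 1L else opt$seed))
      tm <- tip_means(inp$traits)
      anc <- estimate_ancestral_states(inp$phy, tm)
      winv <- branch_winv(inp$phy, inp$traits, cfg)
      sel <- branch_selection(inp$traits, parts[2L],
                              anc$estimate[parts[1L], ],
                              winv[[parts[1L]]]$inv,
                              B = cfg$bootstrap_reps,
                              seed = cfg$rng_seed)
      utils::write.table(sel, opt$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      message("wrote ", opt$out)
    },
    report = {
      need("rates")
      r <- utils::read.table(opt$rates, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      for (w in c("mean", "lower", "upper")) {
        tab <- table(r[[paste0("regime_", w)]])
        cat(w, "Ne/t:", paste(names(tab), tab, sep = "=",
                              collapse = " "), "\n")
      }
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
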