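#' Read and validate a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the structural
#' contract the downstream analysis relies on: the tree must be rooted,
#' carry a branch length on every edge, have unique tip labels, and (by
#' default) be fully resolved.
#'
#' @param path Path to a Newick file with branch lengths.
#' @param strict Logical; when `TRUE` (default) a polytomy is an error.
#'   Relaxing it is intended only for star-tree simulation checks.
#' @return An object of class `phylo`, validated.
#' @seealso [validate_phylogeny()]
#' @export
read_phylogeny <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("phylogeny file not found: ", path)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("unparseable Newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("unparseable Newick: ", path)
  validate_phylogeny(phy, strict = strict)
}

#' Validate a `phylo` object against the pipeline's structural contract
#'
#' @param phy A `phylo` object.
#' @param strict Logical; require a fully bifurcating tree.
#' @return `phy`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(phy, strict = TRUE) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("missing branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (strict) {
    # a basal polytomy reads as "unrooted" to ape, so test resolution
    # first for the clearer message; star trees are allowed only in
    # non-strict (simulation) use, where the parsed root is taken as is
    if (!ape::is.binary(phy))
      stop("tree is not fully resolved (polytomy present); ",
           "use strict = FALSE only for star-tree checks")
    if (!ape::is.rooted(phy)) stop("tree is not rooted")
  }
  phy
}

#' Read a specimen-level trait table
#'
#' Expects delimited text (comma or tab, chosen by file extension unless
#' `sep` is given) with a header row: `specimen_id`, `taxon`, `sex`, then
#' one numeric column per trait. Trait values must be finite with no
#' missing cells, and `sex` must take exactly two levels.
#'
#' @param path Path to a CSV/TSV file.
#' @param log_transform Apply a log to the raw measurements. Values must
#'   be strictly positive. Linear measurements are conventionally logged
#'   before covariance-based analysis so that differences are relative.
#' @param log_base Base of the log; default natural log.
#' @param sep Field separator; inferred from the extension if `NULL`.
#' @return A `data.frame` of class `trait_table` with columns
#'   `specimen_id`, `taxon`, `sex` and the trait columns, and an
#'   attribute `trait_names`.
#' @export
read_trait_table <- function(path, log_transform = FALSE,
                             log_base = exp(1), sep = NULL) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_trait_table(df, log_transform = log_transform, log_base = log_base)
}

#' Coerce a data frame to a validated trait table
#'
#' @param df Data frame with `specimen_id`, `taxon`, `sex` and numeric
#'   trait columns.
#' @inheritParams read_trait_table
#' @return A `trait_table`.
#' @export
as_trait_table <- function(df, log_transform = FALSE, log_base = exp(1)) {
  need <- c("specimen_id", "taxon", "sex")
  if (!all(need %in% names(df)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  trait_names <- setdiff(names(df), need)
  if (length(trait_names) == 0L) stop("no trait columns found")
  z <- as.matrix(df[, trait_names, drop = FALSE])
  if (!is.numeric(z)) stop("non-numeric trait column")
  if (anyNA(z)) stop("missing trait values")
  if (any(!is.finite(z))) stop("non-finite trait values")
  if (log_transform) {
    if (any(z <= 0))
      stop("log transform requested but non-positive measurement present")
    z <- log(z, base = log_base)
  }
  sexes <- unique(as.character(df$sex))
  if (length(sexes) > 2L)
    stop("'sex' must take at most two levels, found: ",
         paste(sexes, collapse = ", "))
  out <- data.frame(specimen_id = as.character(df$specimen_id),
                    taxon = as.character(df$taxon),
                    sex = as.character(df$sex),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(z))
  names(out) <- c(need, trait_names)
  attr(out, "trait_names") <- trait_names
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Trait names of a trait table
#' @param traits A `trait_table`.
#' @return Character vector of trait column names.
#' @export
trait_names <- function(traits) {
  tn <- attr(traits, "trait_names")
  if (is.null(tn)) tn <- setdiff(names(traits),
                                 c("specimen_id", "taxon", "sex"))
  tn
}

#' Trait value matrix of a trait table
#' @param traits A `trait_table`.
#' @return Numeric matrix, n specimens x p traits.
#' @export
trait_matrix <- function(traits) {
  as.matrix(traits[, trait_names(traits), drop = FALSE])
}

#' Check that every taxon in a trait table is a tip of the tree
#'
#' Run before any downstream stage: unmatched labels are a hard error.
#'
#' @param traits A `trait_table`.
#' @param phy A `phylo` object.
#' @return `TRUE` invisibly, or an error naming the offending taxa.
#' @export
validate_traits_vs_tree <- function(traits, phy) {
  bad <- setdiff(unique(traits$taxon), phy$tip.label)
  if (length(bad))
    stop("taxa absent from the tree: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read per-node demographic parameters
#'
#' One row per ancestral node: effective population size Ne (mean and
#' lower/upper interval bounds, individuals), divergence time (years) and
#' generation length (years). Both branches descending from a node share
#' that node's parameters. The lower/mean/upper bounds are stored
#' agnostically (sources differ on whether they are 90% or 95% limits).
#'
#' @param path Path to a CSV/TSV file with columns `node_id`, `Ne_mean`,
#'   `Ne_lower`, `Ne_upper`, `divergence_time`, `generation_length`.
#' @param sep Field separator; inferred from the extension if `NULL`.
#' @return A `data.frame` of class `branch_params`.
#' @export
read_branch_params <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_branch_params(df)
}

#' Coerce and validate a branch-parameter data frame
#' @param df Data frame with the columns documented in
#'   [read_branch_params()].
#' @return A validated `branch_params` data frame.
#' @export
as_branch_params <- function(df) {
  need <- c("node_id", "Ne_mean", "Ne_lower", "Ne_upper",
            "divergence_time", "generation_length")
  if (!all(need %in% names(df)))
    stop("branch params must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  num <- df[, -1]
  if (anyNA(num) || any(!is.finite(as.matrix(num))))
    stop("non-finite branch parameter")
  if (any(as.matrix(num) <= 0)) stop("branch parameters must be positive")
  if (any(df$Ne_lower > df$Ne_mean | df$Ne_mean > df$Ne_upper))
    stop("require Ne_lower <= Ne_mean <= Ne_upper")
  if (anyDuplicated(df$node_id)) stop("duplicate node_id")
  df$node_id <- as.character(df$node_id)
  class(df) <- c("branch_params", "data.frame")
  df
}

#' Effective population size over generations since divergence
#'
#' `Ne / t` where `t = divergence_time / generation_length` is the number
#' of generations since divergence. This dimensionless ratio scales the
#' squared Mahalanobis distance into the generalized genetic distance.
#'
#' @param params A `branch_params` data frame (one or more rows).
#' @param which One of `"mean"`, `"lower"`, `"upper"`: which Ne bound.
#' @return Numeric vector of Ne/t, one per row of `params`.
#' @export
ne_over_t <- function(params, which = c("mean", "lower", "upper")) {
  which <- match.arg(which)
  ne <- params[[paste0("Ne_", which)]]
  if (any(params$generation_length <= 0)) stop("zero generation length")
  if (any(params$divergence_time <= 0)) stop("non-positive divergence time")
  t_gen <- params$divergence_time / params$generation_length
  ne / t_gen
}

#' Analysis configuration
#'
#' Bundles the tunable scalars of the pipeline with validation.
#'
#' @param h2 Heritability scalar in (0, 1] multiplying the pooled
#'   phenotypic covariance to approximate the additive-genetic one
#'   (Cheverud's conjecture). Default 0.4, the average reported for
#'   primate cranial traits.
#' @param bootstrap_reps Number of bootstrap resamples for selection
#'   gradient confidence intervals.
#' @param alpha_levels Two-tailed significance levels, outer and inner:
#'   `c(0.05, 0.001)` gives regime thresholds at chi-square quantiles
#'   {0.001, 0.05, 0.95, 0.999}.
#' @param tail_convention `"alpha"` (default) places thresholds at
#'   quantiles {a, 1-a}; `"alpha_half"` at {a/2, 1-a/2}.
#' @param rng_seed Integer seed for all stochastic stages.
#' @param pooling Covariance pooling rule: `"descendants"` pools
#'   specimens of the taxa descending from the branch's ancestral node;
#'   `"all"` pools every taxon in the table.
#' @param cov_divisor `"n_minus_g"` (unbiased pooled within-group,
#'   default) or `"n"`.
#' @return A list of class `ggd_config`.
#' @export
ggd_config <- function(h2 = 0.4, bootstrap_reps = 1000L,
                       alpha_levels = c(0.05, 0.001),
                       tail_convention = c("alpha", "alpha_half"),
                       rng_seed = 1L,
                       pooling = c("descendants", "all"),
                       cov_divisor = c("n_minus_g", "n")) {
  tail_convention <- match.arg(tail_convention)
  pooling <- match.arg(pooling)
  cov_divisor <- match.arg(cov_divisor)
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (bootstrap_reps < 1) stop("bootstrap_reps must be >= 1")
  a1 <- alpha_levels[1]; a2 <- alpha_levels[2]
  if (!(a2 > 0 && a2 < a1 && a1 < 0.5))
    stop("need 0 < alpha2 < alpha1 < 0.5")
  structure(list(h2 = h2, bootstrap_reps = as.integer(bootstrap_reps),
                 alpha_levels = c(a1, a2),
                 tail_convention = tail_convention,
                 rng_seed = as.integer(rng_seed), pooling = pooling,
                 cov_divisor = cov_divisor),
            class = "ggd_config")
}
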