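#' Differential selection gradient along a branch
#'
#' `beta = W^-1 (z_desc - z_anc)`: the vector of partial regression
#' coefficients of relative fitness on the traits that would be needed
#' to move the ancestral mean to the descendant mean in one bout of
#' selection, given the (heritability-scaled) covariance W.
#'
#' @param z_anc,z_desc Ancestral and descendant trait mean vectors.
#' @param w_inv p x p inverse covariance matrix.
#' @return Numeric vector beta, named like `z_desc` when names exist.
#' @export
selection_gradient <- function(z_anc, z_desc, w_inv) {
  if (length(z_anc) != length(z_desc)) stop("trait vectors differ in length")
  if (!is.matrix(w_inv) || any(dim(w_inv) != length(z_anc)))
    stop("w_inv dimensions do not match trait vectors")
  b <- drop(w_inv %*% (as.numeric(z_desc) - as.numeric(z_anc)))
  names(b) <- names(z_desc)
  b
}

#' Bootstrap confidence intervals for a selection gradient
#'
#' Resamples the descendant taxon's specimens with replacement, recomputes
#' the taxon mean and the gradient `W^-1 (mean - z_anc)` per replicate,
#' and returns per-trait percentile intervals. The ancestral estimate is
#' held fixed: it is a model quantity, not a sample. Deterministic given
#' `seed` (RNG state is restored on exit).
#'
#' @param traits A `trait_table` (only rows of `taxon` are used).
#' @param taxon Descendant taxon label; must have >= 2 specimens.
#' @param z_anc Ancestral trait mean vector (length p, order of
#'   [trait_names()]).
#' @param w_inv p x p inverse covariance matrix.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile interval.
#' @return List with `beta` (point estimate from the observed mean),
#'   `ci` (p x 2 matrix `lower`/`upper`) and `B`.
#' @export
bootstrap_gradient_ci <- function(traits, taxon, z_anc, w_inv,
                                  B = 1000L, seed = 1L,
                                  conf_level = 0.95) {
  if (B < 1) stop("B must be >= 1")
  x <- trait_matrix(traits[traits$taxon == taxon, , drop = FALSE])
  n <- nrow(x)
  if (n < 1) stop("no specimens for taxon ", taxon)
  if (n < 2) stop("need >= 2 specimens for taxon ", taxon)
  beta_hat <- selection_gradient(z_anc, colMeans(x), w_inv)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    cnt <- apply(idx, 2, tabulate, nbins = n)      # n x B resample counts
    means <- t(crossprod(x, cnt) / n)              # B x p bootstrap means
    sweep(means, 2, as.numeric(z_anc)) %*% t(w_inv)  # B x p gradients
  })
  a <- (1 - conf_level) / 2
  ci <- t(apply(boot, 2, stats::quantile, probs = c(a, 1 - a),
                names = FALSE, type = 7))
  dimnames(ci) <- list(trait_names(traits), c("lower", "upper"))
  list(beta = beta_hat, ci = ci, B = as.integer(B))
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Percent response of a trait mean along a branch
#'
#' On the default `"geometric"` scale the logged means are
#' back-transformed, so the response is the percent change of the
#' geometric mean of the raw measurement:
#' `100 * (exp(z_desc) - exp(z_anc)) / exp(z_anc)`. The `"logged"`
#' scale reports `100 * (z_desc - z_anc) / z_anc` on the log scale
#' itself (undefined at `z_anc = 0`).
#'
#' @param z_anc,z_desc Ancestral and descendant (logged) trait means;
#'   vectorized.
#' @param scale `"geometric"` (default) or `"logged"`.
#' @return Numeric percent change(s); sign always matches
#'   `z_desc - z_anc` on the geometric scale.
#' @export
response_pct <- function(z_anc, z_desc, scale = c("geometric", "logged")) {
  scale <- match.arg(scale)
  if (any(!is.finite(z_anc)) || any(!is.finite(z_desc)))
    stop("non-finite input")
  if (scale == "geometric") {
    100 * expm1(z_desc - z_anc)
  } else {
    if (any(z_anc == 0)) stop("z_anc = 0 undefined on the logged scale")
    100 * (z_desc - z_anc) / z_anc
  }
}

#' Classify a trait's selection regime on a branch
#'
#' `none` when the gradient CI contains zero (the reconstructed gradient
#' is negligible). Otherwise `direct_increase`/`direct_decrease` when
#' the gradient and the realized response share a sign (selection on the
#' trait itself, answered by the trait), and `indirect` when they
#' oppose: the trait's change is then driven by covariance with other
#' selected traits, not by its own relationship with fitness. A zero
#' response with a significant gradient is classified `indirect`.
#'
#' @param beta Gradient value(s).
#' @param ci_lower,ci_upper Confidence bounds (vectorized with `beta`).
#' @param response Percent (or any sign-preserving) response value(s).
#' @return Character vector in
#'   `{direct_increase, direct_decrease, indirect, none}`.
#' @export
classify_selection <- function(beta, ci_lower, ci_upper, response) {
  if (any(ci_lower > ci_upper)) stop("malformed CI (lower > upper)")
  sig <- ci_lower > 0 | ci_upper < 0
  out <- rep("none", length(beta))
  up <- sig & beta > 0 & response > 0
  dn <- sig & beta < 0 & response < 0
  out[sig] <- "indirect"
  out[up] <- "direct_increase"
  out[dn] <- "direct_decrease"
  out
}

#' Full selection analysis for one branch
#'
#' Computes the gradient, bootstrap CIs, per-trait responses on both
#' scales and the direct/indirect classification for the branch from an
#' ancestral node to a descendant tip taxon.
#'
#' @param traits A `trait_table`.
#' @param taxon Descendant tip taxon.
#' @param z_anc Ancestral mean vector for the branch's ancestral node.
#' @param w_inv Inverse covariance for the branch.
#' @param B,seed,conf_level Passed to [bootstrap_gradient_ci()].
#' @return A data frame of class `selection_result`: `trait`, `beta`,
#'   `ci_lower`, `ci_upper`, `response_pct` (geometric),
#'   `response_pct_logged`, `significant`, `classification`.
#' @export
branch_selection <- function(traits, taxon, z_anc, w_inv,
                             B = 1000L, seed = 1L, conf_level = 0.95) {
  x <- trait_matrix(traits[traits$taxon == taxon, , drop = FALSE])
  z_desc <- colMeans(x)
  bs <- bootstrap_gradient_ci(traits, taxon, z_anc, w_inv,
                              B = B, seed = seed,
                              conf_level = conf_level)
  resp <- response_pct(as.numeric(z_anc), z_desc, scale = "geometric")
  resp_log <- ifelse(as.numeric(z_anc) == 0, NA_real_,
                     100 * (z_desc - as.numeric(z_anc)) /
                       as.numeric(z_anc))
  cls <- classify_selection(bs$beta, bs$ci[, "lower"], bs$ci[, "upper"],
                            resp)
  out <- data.frame(trait = trait_names(traits),
                    beta = unname(bs$beta),
                    ci_lower = unname(bs$ci[, "lower"]),
                    ci_upper = unname(bs$ci[, "upper"]),
                    response_pct = unname(resp),
                    response_pct_logged = unname(resp_log),
                    significant = unname(bs$ci[, "lower"] > 0 |
                                           bs$ci[, "upper"] < 0),
                    classification = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("selection_result", "data.frame")
  out
}

#' Grouped selection report for one branch
#'
#' Sorts traits in descending gradient within user-defined groups
#' (e.g., cranial vs mandibular, or a focal symphyseal subset) and
#' summarizes direct/indirect/none counts per group.
#'
#' @param results A `selection_result` data frame.
#' @param trait_groups Named list: group label -> character vector of
#'   trait names. Empty groups are omitted. Traits in no group are
#'   collected under `"ungrouped"`.
#' @return A data frame with a `group` column, rows sorted by
#'   descending `beta` within group, and an attribute `summary`
#'   (data frame: group, n, direct, indirect, none, summary line like
#'   `"3/9 direct"`).
#' @export
selection_report <- function(results, trait_groups = NULL) {
  if (is.null(trait_groups)) trait_groups <- list()
  trait_groups <- trait_groups[vapply(trait_groups, length, 0L) > 0]
  assigned <- unlist(trait_groups, use.names = FALSE)
  left <- setdiff(results$trait, assigned)
  if (length(left)) trait_groups$ungrouped <- left
  blocks <- lapply(names(trait_groups), function(g) {
    sub <- results[results$trait %in% trait_groups[[g]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(-sub$beta), , drop = FALSE]
    cbind(group = g, sub, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(names(trait_groups), function(g) {
    sub <- out[out$group == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    n_dir <- sum(startsWith(sub$classification, "direct"))
    data.frame(group = g, n = nrow(sub), direct = n_dir,
               indirect = sum(sub$classification == "indirect"),
               none = sum(sub$classification == "none"),
               line = sprintf("%d/%d direct", n_dir, nrow(sub)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summ
  out
}
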