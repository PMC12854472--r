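#' Residualize a trait table for sex and taxon structure
#'
#' Subtracts from each specimen its (taxon x sex) cell mean. With the
#' full factorial mean model this equals the residuals of a MANOVA with
#' sex and taxon as independent variables; residuals sum to zero within
#' every cell.
#'
#' @param traits A `trait_table`.
#' @param taxa Optional character vector restricting to a taxon subset
#'   (used by the per-branch pooling rule).
#' @return Numeric n x p residual matrix with attributes `n_groups`
#'   (number of non-empty taxon-by-sex cells) and `n_specimens`.
#' @export
residualize <- function(traits, taxa = NULL) {
  if (!is.null(taxa)) {
    traits <- traits[traits$taxon %in% taxa, , drop = FALSE]
    if (!nrow(traits)) stop("no specimens for taxa: ",
                            paste(taxa, collapse = ", "))
  }
  z <- trait_matrix(traits)
  cell <- interaction(traits$taxon, traits$sex, drop = TRUE)
  cnt <- table(cell)
  if (any(cnt < 1)) stop("empty taxon x sex cell")
  cm <- rowsum(z, cell) / as.vector(cnt)
  res <- z - cm[as.character(cell), , drop = FALSE]
  attr(res, "n_groups") <- nlevels(cell)
  attr(res, "n_specimens") <- nrow(z)
  res
}

#' Pooled within-group covariance from residuals
#'
#' Cross-product of the residuals divided by (n - g) where g is the
#' number of groups (unbiased pooled within-group estimator), or by n
#' when `divisor = "n"`. Below 50 pooled specimens phenotypic-for-genetic
#' substitution is considered unstable; a warning is emitted when
#' n < 40, the conventional adequacy threshold.
#'
#' @param residuals Matrix from [residualize()] (or any centered n x p
#'   matrix with an `n_groups` attribute).
#' @param n_groups Number of groups pooled over; defaults to the
#'   attribute on `residuals`.
#' @param divisor `"n_minus_g"` or `"n"`.
#' @return An object of class `pooled_w`: list with the p x p matrix
#'   `W`, `n_specimens`, `n_groups`, `h2_applied`, `condition_number`.
#' @export
pooled_within_cov <- function(residuals, n_groups = attr(residuals, "n_groups"),
                              divisor = c("n_minus_g", "n")) {
  divisor <- match.arg(divisor)
  n <- nrow(residuals)
  if (is.null(n_groups)) stop("n_groups not supplied")
  d <- if (divisor == "n_minus_g") n - n_groups else n
  if (d <= 0) stop("non-positive divisor: n = ", n, ", groups = ", n_groups)
  if (n < 40)
    warning("pooled sample size ", n,
            " is below 40; phenotypic covariance may be unstable")
  W <- crossprod(residuals) / d
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  kappa <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  structure(list(W = W, n_specimens = n, n_groups = n_groups,
                 h2_applied = FALSE, condition_number = kappa),
            class = "pooled_w")
}

#' Scale a pooled phenotypic covariance by heritability
#'
#' `W' = h2 * W`, the usual approximation of the additive-genetic
#' covariance from the phenotypic one. Every downstream Mahalanobis
#' distance and selection gradient therefore scales by 1/h2.
#'
#' @param w A `pooled_w` object.
#' @param h2 Heritability in (0, 1].
#' @return The rescaled `pooled_w` with `h2_applied = TRUE`.
#' @export
apply_heritability <- function(w, h2) {
  if (!inherits(w, "pooled_w")) stop("not a 'pooled_w' object")
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (isTRUE(w$h2_applied)) warning("heritability already applied")
  w$W <- h2 * w$W
  w$h2_applied <- TRUE
  w
}

#' Invert a pooled covariance matrix with conditioning diagnostics
#'
#' Uses the exact inverse when the matrix is well conditioned; falls
#' back to the Moore-Penrose pseudo-inverse (eigenvalues below
#' `rcond_tol` x the largest treated as zero) with a warning otherwise.
#' With p traits approaching the pooled sample size the matrix can be
#' near-singular, so the fallback is part of the contract.
#'
#' @param w A `pooled_w` object or symmetric matrix.
#' @param rcond_tol Reciprocal-condition threshold below which the
#'   pseudo-inverse is used.
#' @return List with `inv` (p x p), `condition_number`, and logical
#'   `pseudo`.
#' @export
invert_w <- function(w, rcond_tol = 1e-10) {
  W <- if (inherits(w, "pooled_w")) w$W else w
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W))))
    stop("W is not symmetric")
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  lam <- e$values
  kappa <- if (min(lam) > 0) max(lam) / min(lam) else Inf
  if (min(lam) <= rcond_tol * max(lam)) {
    warning("near-singular W (condition number ", format(kappa, digits = 3),
            "); using Moore-Penrose pseudo-inverse")
    keep <- lam > rcond_tol * max(lam)
    inv <- e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) / lam[keep])
    pseudo <- TRUE
  } else {
    inv <- e$vectors %*% (t(e$vectors) / lam)
    pseudo <- FALSE
  }
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- dimnames(W)
  list(inv = inv, condition_number = kappa, pseudo = pseudo)
}

#' Per-branch heritability-scaled inverse covariance matrices
#'
#' Applies the pooling rule: `"descendants"` pools the specimens of the
#' taxa descending from each branch's ancestral node (the worked
#' convention: the covariance for an ancestor-to-tip branch inside one
#' genus uses that genus's specimens); `"all"` pools every taxon once.
#' An explicit per-node taxon list can be supplied to override.
#'
#' @param phy A `phylo` object.
#' @param traits A `trait_table`.
#' @param cfg A `ggd_config`.
#' @param explicit Optional named list: ancestral node id -> character
#'   vector of taxa to pool for branches from that node.
#' @return Named list keyed by ancestral node id, each element the
#'   result of [invert_w()] plus `n_specimens` and the pooled `W`.
#' @export
branch_winv <- function(phy, traits, cfg = ggd_config(), explicit = NULL) {
  ids <- internal_node_ids(phy)
  n_tip <- length(phy$tip.label)
  build <- function(taxa) {
    res <- residualize(traits, taxa = taxa)
    w <- pooled_within_cov(res, divisor = cfg$cov_divisor)
    w <- apply_heritability(w, cfg$h2)
    out <- invert_w(w)
    out$W <- w$W
    out$n_specimens <- w$n_specimens
    out
  }
  if (cfg$pooling == "all" && is.null(explicit)) {
    shared <- build(NULL)
    return(stats::setNames(rep(list(shared), phy$Nnode), unname(ids)))
  }
  out <- vector("list", phy$Nnode)
  names(out) <- unname(ids)
  for (k in seq_len(phy$Nnode)) {
    node <- n_tip + k
    id <- unname(ids[as.character(node)])
    taxa <- if (!is.null(explicit) && !is.null(explicit[[id]]))
      explicit[[id]]
    else
      phy$tip.label[clade_tips(phy, node)]
    out[[id]] <- build(taxa)
  }
  out
}

# tip indices descending from a node (the node itself if a tip)
clade_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  sort(unlist(lapply(kids, clade_tips, phy = phy)))
}
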