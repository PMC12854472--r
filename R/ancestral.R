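#' Per-taxon trait means
#'
#' Ancestral estimation operates on taxon means of the (logged) traits.
#'
#' @param traits A `trait_table`.
#' @return Numeric matrix, taxa x traits, rownames = taxon labels.
#' @export
tip_means <- function(traits) {
  z <- trait_matrix(traits)
  g <- factor(traits$taxon, levels = unique(traits$taxon))
  m <- rowsum(z, g) / as.vector(table(g))
  rownames(m) <- levels(g)
  m
}

# Character ids for internal nodes: node labels when present, else
# "node<k>" with k = 1..Nnode in ape numbering (root = node1 only by
# coincidence of numbering; ids are metadata, not topology).
internal_node_ids <- function(phy) {
  n_tip <- length(phy$tip.label)
  ids <- phy$node.label
  if (is.null(ids) || !length(ids) || any(!nzchar(ids)))
    ids <- paste0("node", seq_len(phy$Nnode))
  names(ids) <- as.character(n_tip + seq_len(phy$Nnode))
  ids
}

# Internal node numbers in preorder from the root (stable reporting order).
preorder_internal <- function(phy) {
  n_tip <- length(phy$tip.label)
  e <- stats::reorder(phy, "cladewise")$edge
  seen <- unique(c(e[1, 1], as.vector(t(e))))
  seen[seen > n_tip]
}

#' Ancestral trait means under single-rate Brownian motion
#'
#' Per trait, the maximum-likelihood internal-node values: the vector
#' minimizing the sum over branches of (squared change) / (branch
#' length). This is the GLS reconstruction; it is solved exactly as a
#' sparse linear system on the branch-length-weighted graph Laplacian.
#' Confidence intervals use the conditional normal variance of each
#' internal node given the tips, at the ML (not REML) estimate of the
#' Brownian rate sigma^2 fitted per trait.
#'
#' Zero-length branches are perturbed to 1e-8 x tree height with a
#' warning rather than failing. Point estimates are invariant to a
#' common rescaling of all branch lengths; only the CIs change.
#'
#' @param phy A validated `phylo` object.
#' @param means Taxon x trait matrix (see [tip_means()]); rownames must
#'   cover every tip label.
#' @param conf_level Confidence level for the per-node intervals.
#' @return An object of class `ancestral_states`: list with matrices
#'   `estimate`, `lower`, `upper` (internal nodes in preorder from the
#'   root x traits), per-trait `sigma2`, and the node id mapping.
#' @export
estimate_ancestral_states <- function(phy, means, conf_level = 0.95) {
  if (is.null(rownames(means))) stop("'means' must have taxon rownames")
  miss <- setdiff(phy$tip.label, rownames(means))
  if (length(miss)) stop("no means for tips: ", paste(miss, collapse = ", "))
  if (any(!is.finite(means))) stop("non-finite tip means")
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  n_all <- n_tip + n_node

  bl <- phy$edge.length
  height <- max(ape::node.depth.edgelength(phy))
  eps <- 1e-8 * max(height, 1)
  if (any(bl <= 0)) {
    warning(sum(bl <= 0), " zero-length branch(es) perturbed to ",
            format(eps))
    bl[bl <= 0] <- eps
  }

  # Weighted Laplacian over all nodes, weights 1/branch length
  w <- 1 / bl
  L <- matrix(0, n_all, n_all)
  p1 <- phy$edge[, 1]; p2 <- phy$edge[, 2]
  for (k in seq_along(w)) {
    i <- p1[k]; j <- p2[k]
    L[i, i] <- L[i, i] + w[k]; L[j, j] <- L[j, j] + w[k]
    L[i, j] <- L[i, j] - w[k]; L[j, i] <- L[j, i] - w[k]
  }
  idx_int <- (n_tip + 1):n_all
  idx_tip <- 1:n_tip
  z_tip <- means[phy$tip.label, , drop = FALSE]
  L_II <- L[idx_int, idx_int, drop = FALSE]
  L_IT <- L[idx_int, idx_tip, drop = FALSE]
  est <- tryCatch(solve(L_II, -L_IT %*% z_tip),
                  error = function(e) stop("singular reconstruction system: ",
                                           conditionMessage(e)))

  # ML sigma^2 per trait from the tip distribution under BM
  C <- ape::vcv(phy)[phy$tip.label, phy$tip.label]
  diag(C) <- diag(C) + ifelse(diag(C) == 0, eps, 0)
  Ci <- solve(C)
  one <- rep(1, n_tip)
  denom <- drop(crossprod(one, Ci %*% one))
  sigma2 <- apply(z_tip, 2, function(z) {
    mu <- drop(crossprod(one, Ci %*% z)) / denom
    r <- z - mu
    drop(crossprod(r, Ci %*% r)) / n_tip
  })

  cond_var <- diag(solve(L_II))          # x sigma2 = conditional variance
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- sqrt(outer(cond_var, sigma2, `*`)) * zq

  ord <- preorder_internal(phy)
  pos <- match(ord, idx_int)
  ids <- internal_node_ids(phy)
  out_ids <- unname(ids[as.character(ord)])
  shape <- function(m) {
    m <- m[pos, , drop = FALSE]
    dimnames(m) <- list(out_ids, colnames(means))
    m
  }
  structure(list(estimate = shape(est),
                 lower = shape(est - half),
                 upper = shape(est + half),
                 sigma2 = sigma2,
                 node_numbers = stats::setNames(ord, out_ids),
                 conf_level = conf_level),
            class = "ancestral_states")
}

#' Write ancestral estimates as a TSV
#'
#' Rows are internal nodes (preorder from the root); columns are, per
#' trait, the estimate and the lower and upper confidence bounds.
#'
#' @param anc An `ancestral_states` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ancestral_tsv <- function(anc, path) {
  traits <- colnames(anc$estimate)
  out <- data.frame(node_id = rownames(anc$estimate),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[tr]] <- anc$estimate[, tr]
    out[[paste0(tr, "_lo")]] <- anc$lower[, tr]
    out[[paste0(tr, "_hi")]] <- anc$upper[, tr]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
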