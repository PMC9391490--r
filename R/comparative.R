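# Comparative analysis of dental life-history traits: diet-group summaries,
# the body-mass association, and Brownian-motion ancestral state
# reconstruction on a time-calibrated phylogeny.

#' Diet categories
#' @format Character vector of the recognised feeding-behaviour categories.
#' @export
DIET_CATEGORIES <- c("hypercarnivore", "carnivore", "herbivore",
                     "insectivore", "omnivore")

validate_traits <- function(traits) {
  stopifnot(is.data.frame(traits))
  needed <- c("taxon", "diet")
  missing <- setdiff(needed, names(traits))
  if (length(missing) > 0L) {
    tc_stop("invalid_traits", paste("traits table lacks columns:",
                                    paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(traits$diet), DIET_CATEGORIES)
  if (length(bad) > 0L) {
    tc_stop("invalid_traits", paste("unknown diet categories:",
                                    paste(bad, collapse = ", ")))
  }
  invisible(traits)
}

#' Summarize dental traits by diet category
#'
#' For each diet category present, reports `n`, `mean`, `min`, and `max` of
#' tooth longevity and replacement rate. Values flagged as minima (lower
#' bounds from incomplete teeth or absent replacement evidence) are
#' excluded from means but included in ranges; `range_includes_minimum`
#' marks ranges that should be read with a "greater-or-equal" caveat.
#' Empty groups are omitted.
#'
#' @param traits Data frame with columns `taxon`, `diet`, and any of
#'   `longevity_days` (+ optional `longevity_is_min`) and `rate_days`
#'   (+ optional `rate_is_min`).
#' @return Data frame with one row per (diet, trait) combination:
#'   `diet`, `trait`, `n`, `n_minimum`, `mean`, `min`, `max`,
#'   `range_includes_minimum`.
#' @export
group_summary <- function(traits) {
  validate_traits(traits)
  if (nrow(traits) == 0L) tc_stop("invalid_traits", "traits table is empty")
  pieces <- list()
  for (trait in c("longevity", "rate")) {
    col <- paste0(trait, "_days")
    if (!col %in% names(traits)) next
    flag_col <- paste0(trait, "_is_min")
    is_min <- if (flag_col %in% names(traits)) {
      isTRUE_vec(traits[[flag_col]])
    } else rep(FALSE, nrow(traits))
    for (d in intersect(DIET_CATEGORIES, unique(traits$diet))) {
      sel <- traits$diet == d & !is.na(traits[[col]])
      if (!any(sel)) next
      vals <- traits[[col]][sel]
      mins <- is_min[sel]
      pieces[[length(pieces) + 1L]] <- data.frame(
        diet = d, trait = trait,
        n = length(vals), n_minimum = sum(mins),
        mean = if (any(!mins)) mean(vals[!mins]) else NA_real_,
        min = min(vals), max = max(vals),
        range_includes_minimum = any(mins),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, pieces)
}

isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

# All permutations of 1..n in deterministic (lexicographic-ish) order.
# Used for the exhaustive permutation null at small n; n is capped upstream.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Body mass versus replacement rate association
#'
#' Pearson correlation between `log10(body mass)` and replacement rate,
#' with a two-sided permutation p-value: masses span orders of magnitude
#' (hence the log), and with roughly ten taxa a permutation null avoids any
#' normality assumption. Taxa whose rate is only a lower bound are
#' excluded. The null is exhaustive (all `n!` pairings) when `n <= 7`,
#' otherwise Monte-Carlo with `n_permutations` draws under `seed`.
#'
#' @param traits Data frame with columns `taxon`, `diet`, `body_mass_kg`,
#'   `rate_days`, and optionally `rate_is_min`.
#' @param n_permutations Monte-Carlo permutation count (used when `n > 7`).
#' @param seed Integer seed for the Monte-Carlo null.
#' @return List with `r`, `p_perm`, `n`, `exhaustive`.
#' @export
mass_rate_association <- function(traits, n_permutations = 9999, seed = 1L) {
  validate_traits(traits)
  is_min <- if ("rate_is_min" %in% names(traits)) {
    isTRUE_vec(traits$rate_is_min)
  } else rep(FALSE, nrow(traits))
  sel <- !is.na(traits$body_mass_kg) & !is.na(traits$rate_days) & !is_min
  mass <- traits$body_mass_kg[sel]
  rate <- traits$rate_days[sel]
  n <- length(mass)
  if (n < 3L) {
    tc_stop("invalid_traits", "need at least 3 taxa with mass and a non-minimum rate")
  }
  if (any(mass <= 0)) tc_stop("invalid_traits", "body masses must be positive")
  x <- log10(mass)
  if (stats::sd(x) == 0 || stats::sd(rate) == 0) {
    tc_stop("undefined_correlation",
            "correlation undefined: masses or rates have zero variance")
  }
  r_obs <- stats::cor(x, rate)
  eps <- 1e-12
  if (n <= 7L) {
    perms <- all_permutations(n)
    r_null <- vapply(perms, function(p) stats::cor(x, rate[p]), numeric(1))
    p_perm <- mean(abs(r_null) >= abs(r_obs) - eps)
    exhaustive <- TRUE
  } else {
    set.seed(as.integer(seed))
    r_null <- vapply(seq_len(n_permutations),
                     function(i) stats::cor(x, sample(rate)), numeric(1))
    # observed ordering counts as one realisation of the null
    p_perm <- (1 + sum(abs(r_null) >= abs(r_obs) - eps)) / (1 + n_permutations)
    exhaustive <- FALSE
  }
  list(r = r_obs, p_perm = p_perm, n = n, exhaustive = exhaustive)
}

# --- Brownian-motion ancestral state reconstruction ------------------------

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs ancestral states of a continuous trait on a rooted tree
#' with branch lengths, under Brownian motion, by two-pass Gaussian message
#' passing on the tree (a pruning algorithm). The downward pass combines
#' each clade's tip information into a (mean, variance) message; the upward
#' pass propagates the rest-of-tree message through each node, so every
#' node state is the precision-weighted combination of all its incident
#' messages. The resulting states are the maximum-likelihood estimates and
#' equal the generalized-least-squares solution on the BM covariance
#' matrix; they do not depend on the BM rate, which is profiled out.
#'
#' @param tree A rooted `phylo` object (see [ape::read.tree()]) with
#'   strictly positive branch lengths and unique tip labels.
#' @param tip_values Named numeric vector of trait values; names must cover
#'   every tip label of `tree`.
#' @return An object of class `asr_result`: list with `node_states` (named
#'   by ape internal-node number, root first), `tree`, and `tip_values`
#'   (reordered to the tree's tip order).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' bm_ancestral_states(tr, c(A = 0, B = 0, C = 3))$node_states
#' @export
bm_ancestral_states <- function(tree, tip_values) {
  if (!inherits(tree, "phylo")) tc_stop("invalid_tree", "tree must be a phylo object")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    tc_stop("invalid_tree", "all branch lengths must be positive")
  }
  if (anyDuplicated(tree$tip.label)) {
    tc_stop("invalid_tree", "tip labels must be unique")
  }
  # any phylo edge matrix defines a root node; a multifurcating (e.g. star)
  # root is fine for the pruning, so no binary-root requirement is imposed
  missing <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing) > 0L) {
    tc_stop("incomplete_data", paste("missing tip values for:",
                                     paste(missing, collapse = ", ")))
  }
  x <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(x)) tc_stop("incomplete_data", "tip values must be finite")

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nn <- ntip + nnode
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length
  children <- vector("list", nn)
  parent_edge <- integer(nn)  # edge index whose child is the node
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; c <- edge[e, 2L]
    children[[p]] <- c(children[[p]], e)
    parent_edge[c] <- e
  }

  # Downward pass (post-order): msg_down[node] = (mean, extra variance) of
  # the tip data below the node, measured at the node.
  mu_dn <- numeric(nn); v_dn <- numeric(nn)
  post <- rev(reorder_nodes_preorder(edge, root))
  for (node in post) {
    kids <- children[[node]]
    if (length(kids) == 0L) {          # tip
      mu_dn[node] <- x[node]; v_dn[node] <- 0
    } else {
      vs <- v_dn[edge[kids, 2L]] + elen[kids]
      mus <- mu_dn[edge[kids, 2L]]
      prec <- 1 / vs
      mu_dn[node] <- sum(mus * prec) / sum(prec)
      v_dn[node] <- 1 / sum(prec)
    }
  }

  # Upward pass (pre-order): msg_up[node] = rest-of-tree message arriving at
  # the node through its parent branch; undefined at the root.
  mu_up <- rep(NA_real_, nn); v_up <- rep(NA_real_, nn)
  pre <- reorder_nodes_preorder(edge, root)
  for (node in pre) {
    kids <- children[[node]]
    if (length(kids) == 0L) next
    for (e in kids) {
      child <- edge[e, 2L]
      sibs <- setdiff(kids, e)
      mus <- mu_dn[edge[sibs, 2L]]
      vs <- v_dn[edge[sibs, 2L]] + elen[sibs]
      if (node != root) {
        mus <- c(mus, mu_up[node]); vs <- c(vs, v_up[node])
      }
      prec <- 1 / vs
      mu_up[child] <- sum(mus * prec) / sum(prec)
      v_up[child] <- 1 / sum(prec) + elen[e]
    }
  }

  # Node ML state: precision-weighted combination of all incident messages.
  internal <- root:nn
  states <- vapply(internal, function(node) {
    kids <- children[[node]]
    mus <- mu_dn[edge[kids, 2L]]
    vs <- v_dn[edge[kids, 2L]] + elen[kids]
    if (node != root) {
      mus <- c(mus, mu_up[node]); vs <- c(vs, v_up[node])
    }
    prec <- 1 / vs
    sum(mus * prec) / sum(prec)
  }, numeric(1))
  names(states) <- as.character(internal)

  structure(
    list(node_states = states, tree = tree,
         tip_values = stats::setNames(x, tree$tip.label)),
    class = "asr_result"
  )
}

# Pre-order (parents before children) traversal of node numbers from the
# edge matrix, without relying on the phylo object's internal edge order.
reorder_nodes_preorder <- function(edge, root) {
  children <- split(edge[, 2L], edge[, 1L])
  out <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    node <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, node)
    kids <- children[[as.character(node)]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  out
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("<asr_result> %d tips, %d internal nodes; root state %.4g\n",
              length(x$tip_values), length(x$node_states), x$node_states[[1L]]))
  invisible(x)
}

#' Interpolated trait values along branches
#'
#' Linear interpolation of the reconstructed state along every branch, at
#' `samples_per_branch` evenly spaced interior points (endpoints excluded),
#' supporting gradient-coloured tree figures in the style of a continuous
#' character map.
#'
#' @param result An `asr_result` from [bm_ancestral_states()].
#' @param samples_per_branch Number of interior sample points per branch.
#' @return Data frame with columns `parent`, `child`, `sample`, `fraction`
#'   (position along the branch from the parent), and `value`.
#' @export
branch_gradient <- function(result, samples_per_branch = 10L) {
  stopifnot(inherits(result, "asr_result"))
  k <- as.integer(samples_per_branch)
  if (k < 1L) tc_stop("invalid_input", "samples_per_branch must be >= 1")
  tree <- result$tree
  ntip <- length(tree$tip.label)
  state_at <- function(node) {
    if (node <= ntip) result$tip_values[[node]] else
      result$node_states[[as.character(node)]]
  }
  frac <- seq_len(k) / (k + 1)
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    sp <- state_at(p); sc <- state_at(c)
    data.frame(parent = p, child = c, sample = seq_len(k), fraction = frac,
               value = sp + frac * (sc - sp))
  })
  do.call(rbind, rows)
}
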