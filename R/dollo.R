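#' Infer the single gain branch of a family under the Dollo assumption
#'
#' Under Dollo evolution a family originates exactly once, on the terminal
#' branch for singletons or on the branch subtending the least-inclusive clade
#' of taxa exhibiting presence.  When that clade is the whole tree the gain is
#' placed on the root stem; trees without a root stem then fail with guidance.
#'
#' @param states named 0/1 vector over the tree's tips (one family's column).
#' @param tree a [timetree].
#' @return Branch id (child node id) hosting the gain.
#' @export
infer_gain_branch <- function(states, tree) {
  present <- names(states)[states == 1]
  if (length(present) == 0) stop("all-absent family has no gain branch")
  tipno <- match(present, tree$phy$tip.label)
  if (anyNA(tipno)) stop("states name tips not in the tree")
  if (length(tipno) == 1) return(tipno)          # singleton: terminal branch
  mrca <- ape::getMRCA(tree$phy, tipno)
  if (mrca == tree$root && is.na(tree$stem_age))
    stop("family spans the root but the tree has no root stem; ",
         "add a root.edge to host root-clade gains")
  mrca
}

#' Infer the deterministic Dollo loss branches of a family
#'
#' With a single gain fixed at the least-inclusive clade and losses
#' irreversible, internal states are forced: a node within the gain clade is
#' present iff any descendant tip is present.  Each maximal all-absent subtree
#' inside the clade contributes exactly one loss, on its stem branch, so the
#' loss branch set (and the loss count) is deterministic; only event times are
#' stochastic.  Singletons have no losses by construction.
#'
#' @inheritParams infer_gain_branch
#' @param gain gain branch id from [infer_gain_branch()] (computed if missing).
#' @return Integer vector of loss branch ids (child node ids), possibly empty.
#' @export
infer_loss_branches <- function(states, tree, gain = NULL) {
  if (is.null(gain)) gain <- infer_gain_branch(states, tree)
  ntip <- length(tree$phy$tip.label)
  if (gain <= ntip) return(integer(0))           # singleton
  below <- .tips_below(tree)
  tipno <- match(names(states)[states == 1], tree$phy$tip.label)
  if (!all(tipno %in% below[[gain]]))
    stop("gain clade inconsistent with presence pattern")
  # node presence within the clade: any present descendant tip
  clade_nodes <- c(gain, unlist(.descendant_nodes(tree, gain)))
  pres <- vapply(clade_nodes, function(n) any(below[[n]] %in% tipno), logical(1))
  names(pres) <- clade_nodes
  kids <- .children(tree)
  losses <- integer(0)
  for (n in clade_nodes[pres]) {
    for (k in kids[[n]]) if (!pres[[as.character(k)]]) losses <- c(losses, k)
  }
  sort(losses)
}

# all descendant node ids (internal + tips) strictly below a node
.descendant_nodes <- function(tree, node) {
  kids <- .children(tree)
  out <- integer(0)
  stack <- kids[[node]]
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    out <- c(out, n)
    stack <- c(stack, kids[[n]])
  }
  out
}

#' Minimum and maximum loss counts compatible with an observed pattern
#'
#' The minimum is always zero.  The maximum follows the terminal-loss rule:
#' zero for singletons and for families present in both tips of a two-tip
#' least-inclusive clade; otherwise N - 2 where N is the number of taxa in the
#' least-inclusive clade (all losses on terminal branches, with at least two
#' presences needed to define the clade).
#'
#' @param x a `presence_matrix` (or coercible matrix) bound to `tree`.
#' @param tree a [timetree].
#' @return Data frame with columns `family`, `clade_size`, `min_losses`,
#'   `max_losses`, plus a `"total_max"` attribute summing the maxima.
#' @export
loss_bounds <- function(x, tree) {
  x <- check_binding(x, tree)
  below <- .tips_below(tree)
  fams <- rownames(x)
  n <- vapply(fams, function(f) {
    g <- infer_gain_branch(x[f, ], tree)
    length(below[[g]])
  }, numeric(1))
  out <- data.frame(
    family = fams,
    clade_size = as.integer(n),
    min_losses = 0L,
    max_losses = as.integer(ifelse(n <= 2, 0L, n - 2L)),
    row.names = NULL
  )
  attr(out, "total_max") <- sum(out$max_losses)
  out
}

# uniform (default) or start-anchored truncated-exponential draw on [end, start];
# vectorized over branches, zero-length branches collapse to the node age
.draw_time <- function(n, start, end, timing = "uniform", rate = NULL) {
  if (n == 0) return(numeric(0))
  d <- start - end
  u <- stats::runif(n)
  if (timing == "uniform") {
    t <- end + u * d
  } else {
    stopifnot(!is.null(rate), rate > 0)
    # elapsed time from the older end, Exp(rate) truncated to (0, d)
    t <- start - (-log(1 - u * (1 - exp(-rate * d))) / rate)
  }
  t[d <= 0] <- end[d <= 0]
  t
}

#' Dollo stochastic character mapping of gains and losses on a timetree
#'
#' The central estimator.  For every family the gain branch and the loss
#' branch set are placed deterministically (see [infer_gain_branch()] and
#' [infer_loss_branches()]); event times are then sampled along their branches
#' -- uniformly by default -- and the whole map is replicated to quantify
#' timing uncertainty.  Branch assignments, and therefore all event counts,
#' are identical across replicates; only times differ.
#'
#' Because irreversibility forces every internal state, this deterministic
#' placement plus stochastic timing is equivalent, for counts, to stochastic
#' mapping under a losses-only model with presence fixed at the gain-clade
#' root.
#'
#' @param x a `presence_matrix` (families x taxa) bound to `tree`.
#' @param tree a [timetree].
#' @param n_reps number of stochastic replicates (default 1000).
#' @param seed master RNG seed; replicate r runs on a stream seed derived from
#'   (seed, r) so any replicate is individually reproducible.
#' @param loss_timing `"uniform"` (default) or `"exponential"` (truncated
#'   exponential from the older end of the branch at `loss_timing_rate`,
#'   mirroring rate-dependent waiting times); recorded in the result.
#' @param loss_timing_rate rate (per Myr) for `loss_timing = "exponential"`.
#' @return An object of class `dollo_map`: list with `events` (data frame:
#'   `replicate`, `family`, `type`, `branch`, `time`), `gain_branch`,
#'   `loss_branches`, `loss_counts`, `bounds`, `tree`, `n_reps`, `seed`,
#'   `loss_timing`.
#' @examples
#' tr <- timetree(ape::read.tree(text = "((A:100,B:100):100,(C:100,D:100):100):50;"))
#' m <- presence_matrix(rbind(f1 = c(A=1,B=1,C=0,D=1), f2 = c(A=1,B=0,C=0,D=0)))
#' dm <- dollo_map(m, tr, n_reps = 10, seed = 1)
#' summary(dm)
#' @export
dollo_map <- function(x, tree, n_reps = 1000, seed = 1,
                      loss_timing = c("uniform", "exponential"),
                      loss_timing_rate = NULL) {
  loss_timing <- match.arg(loss_timing)
  x <- check_binding(x, tree)
  fams <- rownames(x)
  br <- tree$branches
  idx <- match(seq_len(max(br$branch)), br$branch)   # branch id -> row

  gain_branch <- vapply(fams, function(f) infer_gain_branch(x[f, ], tree),
                        numeric(1))
  loss_branches <- lapply(fams, function(f)
    infer_loss_branches(x[f, ], tree, gain = gain_branch[[f]]))
  names(loss_branches) <- fams
  loss_counts <- lengths(loss_branches)

  # a loss branch is always a strict descendant of the gain node, so its age
  # interval lies entirely below the gain branch's: gains precede losses
  for (f in fams) {
    if (length(loss_branches[[f]]))
      stopifnot(all(br$start[idx[loss_branches[[f]]]] <=
                    br$end[idx[gain_branch[[f]]]] + 1e-9))
  }

  n_loss <- sum(loss_counts)
  loss_fam <- rep(fams, loss_counts)
  loss_br  <- unlist(loss_branches, use.names = FALSE)
  if (is.null(loss_br)) loss_br <- integer(0)

  g_start <- br$start[idx[gain_branch]]
  g_end   <- br$end[idx[gain_branch]]
  l_start <- br$start[idx[loss_br]]
  l_end   <- br$end[idx[loss_br]]

  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(.stream_seed(seed, r))
    gt <- g_end + stats::runif(length(fams)) * (g_start - g_end)
    lt <- .draw_time(n_loss, l_start, l_end, loss_timing, loss_timing_rate)
    reps[[r]] <- data.frame(
      replicate = r,
      family = c(fams, loss_fam),
      type = c(rep("gain", length(fams)), rep("loss", n_loss)),
      branch = c(as.integer(gain_branch), as.integer(loss_br)),
      time = c(gt, lt)
    )
  }
  events <- do.call(rbind, reps)
  rownames(events) <- NULL

  structure(
    list(events = events, gain_branch = gain_branch,
         loss_branches = loss_branches, loss_counts = loss_counts,
         bounds = loss_bounds(x, tree), tree = tree,
         n_reps = n_reps, seed = seed, loss_timing = loss_timing,
         loss_timing_rate = loss_timing_rate,
         n_families = length(fams)),
    class = "dollo_map"
  )
}

# deterministic per-replicate stream seed, kept within 32-bit signed range
.stream_seed <- function(master, r) {
  as.integer((as.double(master) * 48271 + r * 16807) %% 2147483647)
}

#' @export
print.dollo_map <- function(x, ...) {
  cat("Dollo stochastic character map\n")
  cat("  ", x$n_families, " families on ", length(x$tree$phy$tip.label),
      " tips; ", x$n_reps, " replicates (seed ", x$seed, ")\n", sep = "")
  cat("  gains:", x$n_families, " losses:", sum(x$loss_counts),
      sprintf("(max possible %d)", attr(x$bounds, "total_max")), "\n")
  cat("  loss timing:", x$loss_timing, "\n")
  invisible(x)
}

#' @export
summary.dollo_map <- function(object, ...) {
  h <- loss_count_distribution(object)
  out <- list(
    n_families = object$n_families,
    n_reps = object$n_reps,
    total_losses = sum(object$loss_counts),
    total_max_losses = attr(object$bounds, "total_max"),
    loss_histogram = h,
    families_with_loss = sum(object$loss_counts > 0)
  )
  class(out) <- "summary.dollo_map"
  out
}

#' @export
print.summary.dollo_map <- function(x, ...) {
  cat("Dollo map of", x$n_families, "families,", x$n_reps, "replicates\n")
  cat("  total losses:", x$total_losses, "of a possible", x$total_max_losses, "\n")
  cat("  families with >=1 loss:", x$families_with_loss,
      sprintf("(%.1f%% never lost)\n",
              100 * (1 - x$families_with_loss / x$n_families)))
  cat("  losses per family:\n")
  print(x$loss_histogram)
  invisible(x)
}

#' Plot a Dollo map as binned gain/loss rate series
#'
#' @param x a `dollo_map`.
#' @param bin_width,horizon passed to [rate_series()].
#' @param ... further arguments to [plot.rate_series()].
#' @export
plot.dollo_map <- function(x, bin_width = 10, horizon = NULL, ...) {
  rs <- rate_series(x, bin_width = bin_width, horizon = horizon)
  plot(rs, ...)
}
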