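# Independent brute-force oracles used across the suite.  All enumerate over
# internal-node state assignments, so they share no code with the package's
# traversal-based implementations.

# small fixture trees
tree4 <- function() timetree(ape::read.tree(
  text = "((A:100,B:100):100,(C:100,D:100):100):50;"))

fixture_tree35 <- function() {
  read_timetree(system.file("extdata", "timetree35_synthetic.nwk",
                            package = "dollomap"))
}

# all internal-state assignments of a rooted tree as a matrix (rows = cases)
.state_grid <- function(k) as.matrix(expand.grid(rep(list(0:1), k)))

# minimal irreversible-loss history: gain node fixed at the MRCA of presence
# tips (terminal branch for singletons); enumerate states of internal nodes
# below the gain node under irreversibility (0 -> 0 only), tips fixed; return
# minimal loss count and the loss-branch sets attaining it
oracle_dollo <- function(states, tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  pres <- match(names(states)[states == 1], phy$tip.label)
  if (length(pres) == 1) return(list(min_losses = 0L, branch_sets = list(integer(0)),
                                     gain = pres))
  gain <- ape::getMRCA(phy, pres)
  desc <- function(n) {
    out <- integer(0); stack <- phy$edge[phy$edge[, 1] == n, 2]
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      out <- c(out, x)
      stack <- c(stack, phy$edge[phy$edge[, 1] == x, 2])
    }
    out
  }
  clade <- c(gain, desc(gain))
  internal <- setdiff(clade, seq_len(ntip))
  free <- setdiff(internal, gain)                # gain node fixed present
  s <- integer(ntip + phy$Nnode)
  s[seq_len(ntip)] <- -1L
  s[pres] <- 1L
  s[setdiff(intersect(clade, seq_len(ntip)), pres)] <- 0L
  s[gain] <- 1L
  edges_in <- which(phy$edge[, 1] %in% clade & phy$edge[, 2] %in% clade)
  best <- Inf; sets <- list()
  grid <- .state_grid(length(free))
  if (length(free) == 0) grid <- matrix(0L, nrow = 1, ncol = 0)
  for (r in seq_len(nrow(grid))) {
    if (length(free)) s[free] <- grid[r, ]
    ok <- TRUE; losses <- integer(0)
    for (i in edges_in) {
      a <- s[phy$edge[i, 1]]; b <- s[phy$edge[i, 2]]
      if (a == 0 && b == 1) { ok <- FALSE; break }
      if (a == 1 && b == 0) losses <- c(losses, phy$edge[i, 2])
    }
    if (!ok) next
    if (length(losses) < best) { best <- length(losses); sets <- list(sort(losses)) }
    else if (length(losses) == best) sets <- c(sets, list(sort(losses)))
  }
  list(min_losses = as.integer(best), branch_sets = unique(sets), gain = gain)
}

# Fitch/Wagner minimum changes for a binary character by full enumeration
oracle_fitch <- function(states, tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  s <- integer(ntip + phy$Nnode)
  s[seq_len(ntip)] <- states[phy$tip.label]
  internal <- ntip + seq_len(phy$Nnode)
  grid <- .state_grid(length(internal))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    s[internal] <- grid[r, ]
    ch <- sum(s[phy$edge[, 1]] != s[phy$edge[, 2]])
    best <- min(best, ch)
  }
  as.integer(best)
}

# brute-force log-likelihood of the 2-state model with root (or stem top)
# fixed to absence
oracle_loglik <- function(x, tree, g, l) {
  pmat <- dollomap:::.pmat
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  internal <- ntip + seq_len(phy$Nnode)
  tot <- 0
  grid <- .state_grid(length(internal))
  for (f in seq_len(nrow(x))) {
    s <- integer(ntip + phy$Nnode)
    s[seq_len(ntip)] <- x[f, phy$tip.label]
    lik <- 0
    for (r in seq_len(nrow(grid))) {
      s[internal] <- grid[r, ]
      root_s <- s[tree$root]
      p <- if (!is.na(tree$stem_age))
        pmat(g, l, tree$stem_age - tree$root_age)[1, root_s + 1]
      else as.numeric(root_s == 0)
      if (p == 0) next
      for (i in seq_len(nrow(phy$edge)))
        p <- p * pmat(g, l, phy$edge.length[i])[s[phy$edge[i, 1]] + 1,
                                                s[phy$edge[i, 2]] + 1]
      lik <- lik + p
    }
    tot <- tot + log(lik)
  }
  tot
}

# brute-force marginal posterior of presence at every node
oracle_marginals <- function(states, tree, g, l) {
  pmat <- dollomap:::.pmat
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  internal <- ntip + seq_len(phy$Nnode)
  s <- integer(nn)
  s[seq_len(ntip)] <- states[phy$tip.label]
  grid <- .state_grid(length(internal))
  w1 <- numeric(nn); z <- 0
  for (r in seq_len(nrow(grid))) {
    s[internal] <- grid[r, ]
    p <- if (!is.na(tree$stem_age))
      pmat(g, l, tree$stem_age - tree$root_age)[1, s[tree$root] + 1]
    else as.numeric(s[tree$root] == 0)
    if (p == 0) next
    for (i in seq_len(nrow(phy$edge)))
      p <- p * pmat(g, l, phy$edge.length[i])[s[phy$edge[i, 1]] + 1,
                                              s[phy$edge[i, 2]] + 1]
    z <- z + p
    w1 <- w1 + p * (s == 1)
  }
  w1 / z
}

# random rooted binary timetree with branch lengths; optionally a root stem
rand_timetree <- function(ntip, stem = FALSE) {
  phy <- ape::rtree(ntip, rooted = TRUE)
  phy$edge.length <- stats::runif(nrow(phy$edge), 10, 100)
  if (stem) phy$root.edge <- stats::runif(1, 10, 50)
  timetree(phy)
}

# all nonconstant presence patterns with >= 1 presence on ntip tips
all_patterns <- function(tips) {
  n <- length(tips)
  pats <- .state_grid(n)
  pats <- pats[rowSums(pats) >= 1, , drop = FALSE]
  colnames(pats) <- tips
  pats
}
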