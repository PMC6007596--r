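# Independent dynamic-programming oracle for the minimal number of
# irreversible losses compatible with a tip pattern: cost-based DP over the
# edge table, usable on trees far beyond enumeration size.  Shares no
# traversal code with the package (which propagates presence sets instead).
dp_min_losses <- function(states, tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  pres <- match(names(states)[states == 1], phy$tip.label)
  if (length(pres) <= 1) return(0L)
  m <- ape::getMRCA(phy, pres)
  kids_of <- function(n) phy$edge[phy$edge[, 1] == n, 2]
  cost <- function(v, s) {
    if (v <= ntip) {
      st <- unname(states[phy$tip.label[v]])
      return(if (st == s) 0 else Inf)
    }
    tot <- 0
    for (k in kids_of(v)) {
      keep <- cost(k, s)                       # no transition
      flip <- if (s == 1) 1 + cost(k, 0) else Inf   # loss allowed, gain not
      tot <- tot + min(keep, flip)
    }
    tot
  }
  as.integer(cost(m, 1))
}
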