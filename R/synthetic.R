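#' Simulate a presence/absence matrix under a Dollo gain/loss process
#'
#' Family origins are drawn as a Poisson process over branch time: the number
#' of families is Poisson with mean `gain_intensity` times the (weighted)
#' total branch time, each origin falls on a branch with probability
#' proportional to its weighted duration, and uniformly in time within the
#' branch.  After its gain a family is lost irreversibly along each lineage
#' at `loss_rate` per Myr (exponential waiting times); a loss silences the
#' whole subtree below it.  Families with no surviving presence are excluded
#' from the emitted matrix -- mimicking the unobservability of fully lost
#' families in real annotation data -- but retained in the ground truth, so
#' ascertainment effects are measurable.
#'
#' Branch weights may be modulated by per-branch burst multipliers and by a
#' step function of time (e.g. per 10-Myr interval), which is enough to
#' emulate episodic bursts of acquisition without modeling diversification.
#'
#' @param tree a [timetree].
#' @param gain_intensity expected new families per Myr of total branch time.
#' @param loss_rate per-family loss rate per lineage per Myr (irreversible).
#' @param seed RNG seed.
#' @param burst optional named numeric vector of gain multipliers keyed by
#'   branch id (unlisted branches have multiplier 1).
#' @param gain_profile optional data frame `start`, `end`, `multiplier`
#'   (ages in Ma) defining a step-function time modulation of the gain
#'   intensity; unlisted ages have multiplier 1.
#' @return Object of class `sim_gainloss`: list with `matrix` (a
#'   `presence_matrix` of surviving families), `truth_events` (data frame
#'   `family`, `type`, `branch`, `time` for all families, including fully
#'   lost ones), `tip_states` (full truth matrix including unobservable
#'   families), `loss_counts_true` (named, all families), `config`.
#' @export
sim_gainloss_matrix <- function(tree, gain_intensity, loss_rate, seed = 1,
                                burst = NULL, gain_profile = NULL) {
  stopifnot(inherits(tree, "timetree"), gain_intensity >= 0, loss_rate >= 0)
  br <- tree$branches
  if (sum(br$duration) <= 0) stop("tree has zero total branch time")
  set.seed(seed)

  mult <- rep(1, nrow(br))
  if (!is.null(burst)) {
    stopifnot(all(burst > 0))
    i <- match(as.integer(names(burst)), br$branch)
    stopifnot(!anyNA(i))
    mult[i] <- burst
  }
  # piecewise-constant time weight of each branch
  seg_weight <- function(start, end) {
    if (is.null(gain_profile)) return(start - end)
    w <- start - end
    for (j in seq_len(nrow(gain_profile))) {
      ov <- max(0, min(start, gain_profile$start[j]) -
                   max(end, gain_profile$end[j]))
      w <- w + ov * (gain_profile$multiplier[j] - 1)
    }
    w
  }
  w <- mult * vapply(seq_len(nrow(br)),
                     function(i) seg_weight(br$start[i], br$end[i]), numeric(1))
  W <- sum(w)
  n_fam <- stats::rpois(1, gain_intensity * W)
  if (n_fam == 0) {
    warning("no families generated (gain intensity ", gain_intensity, ")")
    n_fam <- 0
  }
  fams <- sprintf("fam%04d", seq_len(n_fam))

  ntip <- length(tree$phy$tip.label)
  kids <- .children(tree)
  ev <- list()
  tip_states <- matrix(0L, nrow = n_fam, ncol = ntip,
                       dimnames = list(fams, tree$phy$tip.label))
  gb <- if (n_fam > 0) sample.int(nrow(br), n_fam, replace = TRUE, prob = w)
        else integer(0)
  for (i in seq_len(n_fam)) {
    b <- gb[i]
    gt <- .profile_draw(br$start[b], br$end[b], gain_profile)
    ev[[length(ev) + 1]] <- data.frame(family = fams[i], type = "gain",
                                       branch = br$branch[b], time = gt)
    # propagate presence from (branch, gt) downward with exponential losses
    stack <- list(list(node = br$branch[b], from = gt))
    while (length(stack)) {
      seg <- stack[[1]]; stack <- stack[-1]
      node_age <- tree$ages[seg$node]
      span <- seg$from - node_age
      wait <- if (loss_rate > 0) stats::rexp(1, loss_rate) else Inf
      if (wait < span) {
        ev[[length(ev) + 1]] <- data.frame(
          family = fams[i], type = "loss", branch = seg$node,
          time = seg$from - wait)
      } else if (seg$node <= ntip) {
        tip_states[i, seg$node] <- 1L
      } else {
        for (k in kids[[seg$node]])
          stack <- c(stack, list(list(node = k, from = node_age)))
      }
    }
  }
  truth <- if (length(ev)) do.call(rbind, ev) else
    data.frame(family = character(), type = character(),
               branch = integer(), time = numeric())
  loss_counts_true <- table(factor(truth$family[truth$type == "loss"],
                                   levels = fams))
  surviving <- rowSums(tip_states) > 0
  m <- if (any(surviving))
    presence_matrix(tip_states[surviving, , drop = FALSE]) else NULL
  structure(
    list(matrix = m, truth_events = truth, tip_states = tip_states,
         loss_counts_true = loss_counts_true,
         config = list(gain_intensity = gain_intensity, loss_rate = loss_rate,
                       seed = seed, burst = burst, gain_profile = gain_profile)),
    class = "sim_gainloss"
  )
}

# draw a time on [end, start] with density proportional to the step profile
.profile_draw <- function(start, end, profile) {
  if (is.null(profile)) return(stats::runif(1, end, start))
  cuts <- sort(unique(c(end, start,
                        pmax(pmin(c(profile$start, profile$end), start), end))))
  lo <- cuts[-length(cuts)]; hi <- cuts[-1]
  mids <- (lo + hi) / 2
  m <- rep(1, length(mids))
  for (j in seq_len(nrow(profile))) {
    inside <- mids < profile$start[j] & mids > profile$end[j]
    m[inside] <- profile$multiplier[j]
  }
  wseg <- (hi - lo) * m
  i <- sample.int(length(wseg), 1, prob = wseg)
  stats::runif(1, lo[i], hi[i])
}

#' @export
print.sim_gainloss <- function(x, ...) {
  cat("Simulated Dollo gain/loss data set\n")
  cat("  families generated:", nrow(x$tip_states),
      " observable:", if (is.null(x$matrix)) 0 else nrow(x$matrix), "\n")
  cat("  true losses:", sum(x$truth_events$type == "loss"), "\n")
  invisible(x)
}

#' Simulate a presence matrix under the two-state Markov model
#'
#' Each of `n_families` characters evolves independently down the tree from
#' absence at the root (or stem top) under the chain with the given gain and
#' loss rates; only tip states are returned.  All-absent families are kept by
#' default, since they are informative for (and simulated by) the
#' maximum-likelihood model.
#'
#' @param tree a [timetree].
#' @param gain,loss rates per Myr.
#' @param n_families number of characters.
#' @param seed RNG seed.
#' @param drop_all_absent drop all-absent rows (default `FALSE`).
#' @return Binary matrix, families x taxa.
#' @export
sim_markov_matrix <- function(tree, gain, loss, n_families, seed = 1,
                              drop_all_absent = FALSE) {
  set.seed(seed)
  nn <- length(tree$ages)
  ntip <- length(tree$phy$tip.label)
  state <- matrix(0L, nrow = nn, ncol = n_families)
  root_p <- if (!is.na(tree$stem_age))
    .pmat(gain, loss, tree$stem_age - tree$root_age)[1, 2] else 0
  state[tree$root, ] <- stats::rbinom(n_families, 1, root_p)
  e <- tree$phy$edge
  ord <- rev(ape::postorder(tree$phy))            # parents before children
  for (i in ord) {
    P <- .pmat(gain, loss, tree$phy$edge.length[i])
    p1 <- ifelse(state[e[i, 1], ] == 1L, P[2, 2], P[1, 2])
    state[e[i, 2], ] <- stats::rbinom(n_families, 1, p1)
  }
  m <- t(state[seq_len(ntip), , drop = FALSE])
  dimnames(m) <- list(sprintf("fam%04d", seq_len(n_families)),
                      tree$phy$tip.label)
  if (drop_all_absent) m <- m[rowSums(m) > 0, , drop = FALSE]
  m
}

#' Inject annotation noise into a presence matrix
#'
#' Emulates the two corruption modes of uncurated archives: false negatives
#' (a present family recorded absent, as with low-coverage genomes or shallow
#' small-RNA sampling) and false positives (spurious families annotated in a
#' single taxon).  Every corruption is recorded in a manifest.
#'
#' @param x a `presence_matrix` (or coercible matrix).
#' @param fn_rate probability a presence is masked, scalar or named per-taxon
#'   vector.
#' @param fp_per_tip number of spurious singleton families appended per taxon,
#'   scalar or named per-taxon vector.
#' @param seed RNG seed.
#' @return List with `matrix` (the corrupted `presence_matrix`; families
#'   masked to all-absent are removed, as they would be unobservable) and
#'   `manifest` (list `masked` data frame, `dropped_families`,
#'   `added_families`).
#' @export
inject_noise <- function(x, fn_rate = 0, fp_per_tip = 0, seed = 1) {
  if (!inherits(x, "presence_matrix")) x <- presence_matrix(x)
  set.seed(seed)
  taxa <- colnames(x)
  fn <- if (length(fn_rate) == 1) stats::setNames(rep(fn_rate, length(taxa)), taxa)
        else fn_rate[taxa]
  fp <- if (length(fp_per_tip) == 1)
          stats::setNames(rep(fp_per_tip, length(taxa)), taxa)
        else fp_per_tip[taxa]
  stopifnot(all(fn >= 0 & fn <= 1), all(fp >= 0))
  m <- unclass(x)
  masked <- list()
  for (tp in taxa) {
    pres <- which(m[, tp] == 1L)
    if (length(pres) == 0 || fn[[tp]] == 0) next
    hit <- pres[stats::runif(length(pres)) < fn[[tp]]]
    if (length(hit)) {
      m[hit, tp] <- 0L
      masked[[length(masked) + 1]] <-
        data.frame(family = rownames(m)[hit], taxon = tp)
    }
  }
  masked <- if (length(masked)) do.call(rbind, masked) else
    data.frame(family = character(), taxon = character())
  dropped <- rownames(m)[rowSums(m) == 0]
  added <- character(0)
  for (tp in taxa) {
    if (fp[[tp]] == 0) next
    ids <- sprintf("fp_%s_%03d", tp, seq_len(fp[[tp]]))
    block <- matrix(0L, nrow = length(ids), ncol = length(taxa),
                    dimnames = list(ids, taxa))
    block[, tp] <- 1L
    m <- rbind(m, block)
    added <- c(added, ids)
  }
  out <- suppressWarnings(presence_matrix(m))
  list(matrix = out,
       manifest = list(masked = masked, dropped_families = dropped,
                       added_families = added, fn_rate = fn, fp_per_tip = fp,
                       seed = seed))
}

#' End-to-end simulation and recovery experiment
#'
#' Runs the full pipeline on data with known ground truth: (a) simulates a
#' Dollo process and checks the mapped per-family loss counts against the
#' truth (Dollo parsimony is a lower bound, attained whenever the true
#' history is minimal); (b) optionally simulates under the two-state Markov
#' model and refits its rates; (c) optionally injects annotation noise and
#' contrasts recent binned loss/gain rates between the clean and corrupted
#' runs, the direction expected of uncurated archives.
#'
#' @param tree a [timetree].
#' @param gain_intensity,loss_rate Dollo-process parameters for part (a); see
#'   [sim_gainloss_matrix()].
#' @param n_reps Dollo-map replicates (default 100).
#' @param seed master seed.
#' @param ml_gain_rate,ml_loss_rate,ml_n_families when `ml_gain_rate` is not
#'   `NULL`, part (b) simulates `ml_n_families` characters at these rates and
#'   refits them.
#' @param noise optional list with elements `fn_rate` and/or `fp_per_tip` for
#'   part (c).
#' @param recent_ma age window (Ma) treated as "recent" in the noise contrast
#'   (default 100).
#' @return Object of class `recovery_report` (a list; see components).
#' @export
recovery_experiment <- function(tree, gain_intensity = 0.13, loss_rate = 8e-4,
                                n_reps = 100, seed = 1,
                                ml_gain_rate = NULL, ml_loss_rate = NULL,
                                ml_n_families = 2000,
                                noise = NULL, recent_ma = 100) {
  sim <- sim_gainloss_matrix(tree, gain_intensity, loss_rate,
                             seed = .stream_seed(seed, 101))
  if (is.null(sim$matrix)) stop("simulation produced no observable families")
  dm <- dollo_map(sim$matrix, tree, n_reps = n_reps,
                  seed = .stream_seed(seed, 102))
  true_counts <- as.integer(sim$loss_counts_true[rownames(sim$matrix)])
  inferred <- as.integer(dm$loss_counts[rownames(sim$matrix)])
  out <- list(
    sim = sim, dollo = dm,
    loss_recovery = data.frame(
      family = rownames(sim$matrix),
      true = true_counts, inferred = inferred),
    dollo_bound_ok = all(inferred <= true_counts),
    exact_families = sum(inferred == true_counts)
  )

  if (!is.null(ml_gain_rate)) {
    if (is.null(ml_loss_rate)) ml_loss_rate <- loss_rate
    mm <- sim_markov_matrix(tree, ml_gain_rate, ml_loss_rate, ml_n_families,
                            seed = .stream_seed(seed, 103))
    fit <- fit_gainloss(mm, tree)
    out$ml <- list(
      truth = c(gain = ml_gain_rate, loss = ml_loss_rate),
      fit = fit,
      rel_error = c(gain = fit$gain / ml_gain_rate - 1,
                    loss = fit$loss / ml_loss_rate - 1))
  }

  if (!is.null(noise)) {
    noisy <- inject_noise(sim$matrix,
                          fn_rate = noise$fn_rate %||% 0,
                          fp_per_tip = noise$fp_per_tip %||% 0,
                          seed = .stream_seed(seed, 104))
    dmn <- dollo_map(noisy$matrix, tree, n_reps = n_reps,
                     seed = .stream_seed(seed, 105))
    out$noise <- list(
      manifest = noisy$manifest, dollo = dmn,
      recent = data.frame(
        run = c("clean", "noisy"),
        losses = c(.recent_events(dm, "loss", recent_ma),
                   .recent_events(dmn, "loss", recent_ma)),
        gains = c(.recent_events(dm, "gain", recent_ma),
                  .recent_events(dmn, "gain", recent_ma))))
  }
  class(out) <- "recovery_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean event count per replicate younger than `recent_ma`
.recent_events <- function(dm, type, recent_ma) {
  ev <- dm$events
  sum(ev$type == type & ev$time <= recent_ma) / dm$n_reps
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment\n")
  cat("  observable families:", nrow(x$loss_recovery),
      " (", nrow(x$sim$tip_states) - nrow(x$loss_recovery),
      "unobservable )\n")
  cat("  Dollo lower bound respected:", x$dollo_bound_ok,
      sprintf("; loss count exact for %d/%d families\n",
              x$exact_families, nrow(x$loss_recovery)))
  if (!is.null(x$ml))
    cat(sprintf("  ML recovery: gain %.4g (truth %.4g, %+.1f%%), loss %.4g (truth %.4g, %+.1f%%)\n",
                x$ml$fit$gain, x$ml$truth[["gain"]], 100 * x$ml$rel_error[["gain"]],
                x$ml$fit$loss, x$ml$truth[["loss"]], 100 * x$ml$rel_error[["loss"]]))
  if (!is.null(x$noise)) {
    r <- x$noise$recent
    cat(sprintf("  recent (<= window) losses/replicate: clean %.2f vs noisy %.2f\n",
                r$losses[1], r$losses[2]))
    cat(sprintf("  recent gains/replicate: clean %.2f vs noisy %.2f\n",
                r$gains[1], r$gains[2]))
  }
  invisible(x)
}
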