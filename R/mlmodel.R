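# 2x2 transition probability matrix for the asymmetric binary chain with
# generator Q = [[-g, g], [l, -l]] over duration t (states: 1 = absent,
# 2 = present)
.pmat <- function(g, l, t) {
  s <- g + l
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c((l + g * e) / s, l * (1 - e) / s,
           g * (1 - e) / s, (g + l * e) / s),
         nrow = 2, byrow = FALSE,
         dimnames = list(from = c("0", "1"), to = c("0", "1")))
}

# postorder node sequence (children before parents) for a timetree
.postorder_nodes <- function(tree) {
  e <- tree$phy$edge
  ord <- ape::postorder(tree$phy)
  unique(c(e[ord, 2], tree$root))
}

# conditional likelihoods below each node for all families at once.
# Returns list(loglik = per-family log-likelihood at the top of the tree
# conditioned on root absence, L = nodes x 2 x F partial likelihood array,
# logscale = per-family log rescaling accumulated into loglik).
.prune <- function(x, tree, gain, loss) {
  ntip <- length(tree$phy$tip.label)
  nn <- length(tree$ages)
  nf <- nrow(x)
  L <- array(1, dim = c(nn, 2, nf))
  obs <- t(x)                                     # taxa x families, tree order
  for (i in seq_len(ntip)) {
    L[i, 1, ] <- 1 - obs[i, ]
    L[i, 2, ] <- obs[i, ]
  }
  logscale <- numeric(nf)
  kids <- .children(tree)
  br <- tree$branches
  dur <- numeric(nn)
  dur[br$branch[!is.na(br$parent)]] <- br$duration[!is.na(br$parent)]
  for (n in .postorder_nodes(tree)) {
    if (n <= ntip) next
    for (k in kids[[n]]) {
      P <- .pmat(gain, loss, dur[k])
      msg <- P %*% L[k, , ]                       # 2 x F
      L[n, 1, ] <- L[n, 1, ] * msg[1, ]
      L[n, 2, ] <- L[n, 2, ] * msg[2, ]
    }
    mx <- pmax(L[n, 1, ], L[n, 2, ])
    mx[mx == 0] <- 1
    L[n, 1, ] <- L[n, 1, ] / mx
    L[n, 2, ] <- L[n, 2, ] / mx
    logscale <- logscale + log(mx)
  }
  # root conditioned on absence; with a root stem, absence holds at the stem
  # top and the stem branch is part of the process
  if (!is.na(tree$stem_age)) {
    P <- .pmat(gain, loss, tree$stem_age - tree$root_age)
    top <- P[1, , drop = TRUE] %*% L[tree$root, , ]
    ll <- log(as.numeric(top)) + logscale
  } else {
    ll <- log(L[tree$root, 1, ]) + logscale
  }
  list(loglik = ll, L = L, logscale = logscale)
}

#' Log-likelihood of a presence matrix under the two-state gain/loss model
#'
#' Felsenstein pruning over the asymmetric binary chain with gain rate `gain`
#' (0 to 1) and loss rate `loss` (1 to 0), both per Myr on the timetree, with
#' the state at the root (or at the top of the root stem, when one is present)
#' fixed to absence.  Families share the two rates; the result is the sum of
#' per-family log-likelihoods.  All-absent families are permitted here (they
#' are informative under a root-absent model), unlike in the Dollo stage.
#'
#' @param x binary matrix, families x taxa (taxa must match the tree's tips).
#' @param tree a [timetree].
#' @param gain,loss non-negative rates per Myr.
#' @return Total log-likelihood (scalar).  A family that is present somewhere
#'   has likelihood 0 when `gain = 0`, giving `-Inf`.
#' @export
gainloss_loglik <- function(x, tree, gain, loss) {
  stopifnot(gain >= 0, loss >= 0)
  x <- .bind_ml_matrix(x, tree)
  sum(.prune(x, tree, gain, loss)$loglik)
}

# ML-stage binding: taxa must match, cells binary; all-absent rows allowed
.bind_ml_matrix <- function(x, tree) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% c(0L, 1L))) stop("cells must be 0 or 1")
  tips <- tree$phy$tip.label
  if (!setequal(colnames(x), tips))
    stop("matrix taxa do not match tree tips: ",
         paste(c(setdiff(tips, colnames(x)), setdiff(colnames(x), tips)),
               collapse = ", "))
  x[, tips, drop = FALSE]
}

#' Maximum-likelihood estimation of global gain and loss rates
#'
#' Fits the two-state model of [gainloss_loglik()] by bounded quasi-Newton
#' optimization on log-rates from a deterministic grid of starting points,
#' returning the best optimum.  Rates are per Myr on the supplied timetree;
#' the equivalent rates per unit of total tree length are reported alongside,
#' since published estimates do not always state their normalization.
#'
#' @param x binary matrix, families x taxa.
#' @param tree a [timetree].
#' @param starts matrix of starting values (columns `gain`, `loss`); default a
#'   5-point log-spaced grid.
#' @param lower,upper box constraints on the rates (per Myr).
#' @param reltol convergence tolerance on the log-likelihood.
#' @return Object of class `gainloss_fit` with components `gain`, `loss`
#'   (rates per Myr), `loglik`, `converged`, `iterations`, `starts` (per-start
#'   results), `tree_scale` (rates multiplied by total tree length in Myr),
#'   `x`, `tree`.
#' @examples
#' tr <- timetree(ape::read.tree(text = "((A:100,B:100):100,(C:100,D:100):100):50;"))
#' m <- rbind(f1 = c(A=1,B=1,C=0,D=0), f2 = c(A=0,B=0,C=0,D=1))
#' fit <- fit_gainloss(m, tr)
#' coef(fit)
#' @export
fit_gainloss <- function(x, tree, starts = NULL,
                         lower = 1e-8, upper = 100, reltol = 1e-8) {
  x <- .bind_ml_matrix(x, tree)
  if (nrow(x) == 0) stop("empty matrix")
  if (is.null(starts)) {
    g0 <- c(1e-3, 1e-2, 1e-2, 1e-1, 1)
    l0 <- c(1e-3, 1e-2, 1e-1, 1e-2, 1)
    starts <- cbind(gain = g0, loss = l0)
  }
  nll <- function(p) {
    v <- -sum(.prune(x, tree, exp(p[1]), exp(p[2]))$loglik)
    if (!is.finite(v)) 1e12 else v
  }
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(log(pmax(starts[i, ], lower)), nll, method = "L-BFGS-B",
                 lower = log(lower), upper = log(upper),
                 control = list(factr = reltol / .Machine$double.eps))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  best$par <- unname(best$par)
  total_time <- sum(tree$branches$duration)
  structure(
    list(gain = exp(best$par[1]), loss = exp(best$par[2]),
         loglik = -best$value,
         converged = best$convergence == 0,
         iterations = best$counts[["function"]],
         starts = data.frame(start_gain = starts[, 1], start_loss = starts[, 2],
                             loglik = -vals),
         tree_scale = c(gain = exp(best$par[1]) * total_time,
                        loss = exp(best$par[2]) * total_time),
         total_tree_time = total_time,
         n_families = nrow(x), x = x, tree = tree),
    class = "gainloss_fit"
  )
}

#' @export
print.gainloss_fit <- function(x, ...) {
  cat("Two-state gain/loss model, root fixed to absence\n")
  cat(sprintf("  gain rate: %.6g /Myr   loss rate: %.6g /Myr\n", x$gain, x$loss))
  cat(sprintf("  log-likelihood: %.4f over %d families%s\n", x$loglik,
              x$n_families, if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
summary.gainloss_fit <- function(object, ...) {
  cat("Two-state gain/loss model, root fixed to absence\n")
  cat(sprintf("  families: %d   total tree time: %.1f Myr\n",
              object$n_families, object$total_tree_time))
  cat(sprintf("  gain rate: %.6g /Myr  (%.4g per total tree length)\n",
              object$gain, object$tree_scale[["gain"]]))
  cat(sprintf("  loss rate: %.6g /Myr  (%.4g per total tree length)\n",
              object$loss, object$tree_scale[["loss"]]))
  cat(sprintf("  loss:gain ratio: %.3f\n", object$loss / object$gain))
  cat(sprintf("  log-likelihood: %.4f   converged: %s (%d evaluations)\n",
              object$loglik, object$converged, object$iterations))
  cat("  starts reaching the optimum (within 1e-4):",
      sum(abs(object$starts$loglik - object$loglik) < 1e-4), "of",
      nrow(object$starts), "\n")
  invisible(object)
}

#' @export
coef.gainloss_fit <- function(object, ...) {
  c(gain = object$gain, loss = object$loss)
}

#' @export
logLik.gainloss_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n_families, class = "logLik")
}

#' Marginal maximum-likelihood ancestral states
#'
#' Up-down pruning gives, for every internal node and family, the marginal
#' posterior probability of presence under the fitted (or supplied) rates,
#' with the root (or stem top) fixed to absence.  Tip rows reproduce the
#' observations.  Hard states are derived by thresholding at 0.5, with
#' probability exactly 0.5 resolved to absence (conservative against
#' inferring presence).
#'
#' @param x binary matrix, families x taxa, or a `gainloss_fit`.
#' @param tree a [timetree] (taken from the fit when `x` is a fit).
#' @param gain,loss rates per Myr (taken from the fit when `x` is a fit).
#' @return Object of class `ancestral_states`: list with `prob` (nodes x
#'   families matrix of presence probabilities; rows 1..Ntip are tips in tree
#'   order), `hard` (0/1 matrix), `tree`, `gain`, `loss`.
#' @export
ancestral_states <- function(x, tree = NULL, gain = NULL, loss = NULL) {
  if (inherits(x, "gainloss_fit")) {
    tree <- x$tree; gain <- x$gain; loss <- x$loss; x <- x$x
  }
  stopifnot(!is.null(tree), !is.null(gain), !is.null(loss))
  x <- .bind_ml_matrix(x, tree)
  ntip <- length(tree$phy$tip.label)
  nn <- length(tree$ages)
  nf <- nrow(x)
  pr <- .prune(x, tree, gain, loss)
  L <- pr$L
  kids <- .children(tree)
  br <- tree$branches
  dur <- numeric(nn)
  dur[br$branch[!is.na(br$parent)]] <- br$duration[!is.na(br$parent)]

  # outside (down) messages; D[n, s, f] = P(evidence outside subtree of n,
  # state(n) = s | root constraint), up to per-family scaling
  D <- array(0, dim = c(nn, 2, nf))
  if (!is.na(tree$stem_age)) {
    P <- .pmat(gain, loss, tree$stem_age - tree$root_age)
    D[tree$root, 1, ] <- P[1, 1]
    D[tree$root, 2, ] <- P[1, 2]
  } else {
    D[tree$root, 1, ] <- 1
    D[tree$root, 2, ] <- 0
  }
  for (n in rev(.postorder_nodes(tree))) {         # parents before children
    if (n <= ntip) next
    for (k in kids[[n]]) {
      # message into k excludes k's own subtree: combine D[n] with siblings
      excl <- rbind(D[n, 1, ], D[n, 2, ])          # 2 x F
      for (sib in setdiff(kids[[n]], k)) {
        Ps <- .pmat(gain, loss, dur[sib])
        msg <- Ps %*% L[sib, , ]
        excl <- excl * msg
      }
      Pk <- .pmat(gain, loss, dur[k])
      down <- t(Pk) %*% excl                       # 2 x F, state of k
      mx <- pmax(down[1, ], down[2, ])
      mx[mx == 0] <- 1
      D[k, 1, ] <- down[1, ] / mx
      D[k, 2, ] <- down[2, ] / mx
    }
  }
  joint0 <- D[, 1, , drop = FALSE][, 1, ] * L[, 1, , drop = FALSE][, 1, ]
  joint1 <- D[, 2, , drop = FALSE][, 1, ] * L[, 2, , drop = FALSE][, 1, ]
  prob <- joint1 / (joint0 + joint1)
  prob <- matrix(prob, nrow = nn, ncol = nf,
                 dimnames = list(NULL, rownames(x)))
  hard <- (prob > 0.5) * 1L                        # exactly 0.5 -> absent
  structure(list(prob = prob, hard = hard, tree = tree,
                 gain = gain, loss = loss),
            class = "ancestral_states")
}

#' @export
predict.gainloss_fit <- function(object, ...) {
  ancestral_states(object)
}

#' Simulate presence matrices from a fitted gain/loss model
#'
#' @param object a `gainloss_fit`.
#' @param nsim number of matrices.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A list of binary matrices (families x taxa), each simulated under
#'   the fitted rates with [sim_markov_matrix()] at the fitted family count.
#' @export
simulate.gainloss_fit <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(i)
    sim_markov_matrix(object$tree, gain = object$gain, loss = object$loss,
                      n_families = object$n_families,
                      seed = .stream_seed(seed, i)))
}

#' Event mapping from hard maximum-likelihood ancestral states
#'
#' Converts thresholded ancestral states into per-branch gain (0 to 1) and
#' loss (1 to 0) counts, the likelihood-based robustness check to the Dollo
#' mapping.  The stem top, when present, counts as absent, so a present root
#' registers a gain on the stem.
#'
#' @param anc an [ancestral_states] object.
#' @return Object of class `ml_event_map`: list with `per_branch` (data frame
#'   `branch`, `gains`, `losses`), `per_family` (data frame `family`, `type`,
#'   `branch`), and `tree`; usable with [branch_rates()] and
#'   [lineage_summary()].
#' @export
ml_event_map <- function(anc) {
  stopifnot(inherits(anc, "ancestral_states"))
  tree <- anc$tree
  hard <- anc$hard
  br <- tree$branches
  recs <- list()
  for (i in seq_len(nrow(br))) {
    child <- br$branch[i]
    pstate <- if (is.na(br$parent[i])) 0L else hard[br$parent[i], ]
    cstate <- hard[child, ]
    gains <- which(pstate == 0L & cstate == 1L)
    losses <- which(pstate == 1L & cstate == 0L)
    if (length(gains))
      recs[[length(recs) + 1]] <- data.frame(
        family = colnames(hard)[gains], type = "gain", branch = child)
    if (length(losses))
      recs[[length(recs) + 1]] <- data.frame(
        family = colnames(hard)[losses], type = "loss", branch = child)
  }
  per_family <- if (length(recs)) do.call(rbind, recs) else
    data.frame(family = character(), type = character(), branch = integer())
  structure(list(per_family = per_family, tree = tree), class = "ml_event_map")
}

#' @export
branch_rates.ml_event_map <- function(x, ...) {
  lev <- x$tree$branches$branch
  pf <- x$per_family
  .branch_rates_from_counts(
    x$tree,
    gains  = table(factor(pf$branch[pf$type == "gain"], levels = lev)),
    losses = table(factor(pf$branch[pf$type == "loss"], levels = lev))
  )
}

#' @export
print.ml_event_map <- function(x, ...) {
  cat("Likelihood-based event mapping:",
      sum(x$per_family$type == "gain"), "gains,",
      sum(x$per_family$type == "loss"), "losses\n")
  invisible(x)
}
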