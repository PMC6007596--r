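#' Per-branch gain and loss counts and rates
#'
#' Counts events per branch (replicate-invariant for a Dollo map, since branch
#' assignments never vary) and divides by branch duration to give birth/death
#' per million years.  Zero-length branches keep their counts but report `NA`
#' rates.  Branches with any change are classified as in the field's summaries:
#' `gains_only` (no losses), `ge75_gains` (at least 75\% gains but some
#' losses), `loss_majority` (more losses than gains), or `mixed`.
#'
#' @param x a [dollo_map] or [ml_event_map] object.
#' @param ... unused.
#' @return Data frame with one row per branch: `branch`, `parent`, `start`,
#'   `end`, `duration`, `gains`, `losses`, `gain_rate`, `loss_rate`, `class`.
#' @export
branch_rates <- function(x, ...) UseMethod("branch_rates")

#' @export
branch_rates.dollo_map <- function(x, ...) {
  .branch_rates_from_counts(
    x$tree,
    gains  = table(factor(x$gain_branch, levels = x$tree$branches$branch)),
    losses = table(factor(unlist(x$loss_branches, use.names = FALSE),
                          levels = x$tree$branches$branch))
  )
}

.branch_rates_from_counts <- function(tree, gains, losses) {
  br <- tree$branches
  out <- data.frame(
    branch = br$branch, parent = br$parent,
    start = br$start, end = br$end, duration = br$duration,
    gains = as.integer(gains), losses = as.integer(losses)
  )
  out$gain_rate <- ifelse(out$duration > 0, out$gains / out$duration, NA_real_)
  out$loss_rate <- ifelse(out$duration > 0, out$losses / out$duration, NA_real_)
  ch <- out$gains + out$losses
  out$class <- ifelse(ch == 0, "unchanged",
               ifelse(out$losses == 0, "gains_only",
               ifelse(out$losses > out$gains, "loss_majority",
               ifelse(out$gains / ch >= 0.75, "ge75_gains", "mixed"))))
  out
}

#' Binned time series of gain and loss counts with Monte-Carlo intervals
#'
#' Bins event times into half-open bins `[older, younger)` of `bin_width` Myr
#' from the horizon to the present, labeled by the older edge; an event
#' exactly on an edge belongs to the younger bin.  Means and 95\% intervals
#' (2.5/97.5 empirical quantiles) are taken across replicates.
#'
#' @param x a [dollo_map].
#' @param bin_width bin width in Myr (default 10).
#' @param horizon oldest bin edge in Ma (default 720, or the stem/root age
#'   rounded up to a bin edge when that exceeds 720).
#' @return Object of class `rate_series`: a data frame with columns `type`,
#'   `bin_start`, `bin_end`, `mean`, `lo`, `hi`, with the per-replicate count
#'   matrices in `attr(, "counts")`.
#' @export
rate_series <- function(x, bin_width = 10, horizon = NULL) {
  stopifnot(inherits(x, "dollo_map"))
  tree <- x$tree
  oldest <- max(tree$branches$start)
  if (is.null(horizon))
    horizon <- max(720, ceiling(oldest / bin_width) * bin_width)
  ev <- x$events
  too_old <- ev$time > horizon
  if (any(too_old)) {
    i <- which(too_old)[1]
    stop("event older than the ", horizon, " Ma horizon: family ",
         ev$family[i], " ", ev$type[i], " at ", format(ev$time[i]), " Ma")
  }
  nbins <- ceiling(horizon / bin_width)
  # bin index counted from the present: bin i covers ((i-1)*w, i*w]
  bin <- ceiling(ev$time / bin_width)
  bin[bin == 0L] <- 1L                            # events exactly at 0 Ma
  counts <- lapply(c(gain = "gain", loss = "loss"), function(tp) {
    sel <- ev$type == tp
    tab <- table(factor(ev$replicate[sel], levels = seq_len(x$n_reps)),
                 factor(bin[sel], levels = seq_len(nbins)))
    matrix(as.integer(tab), nrow = x$n_reps, ncol = nbins)
  })
  per_type <- lapply(names(counts), function(tp) {
    m <- counts[[tp]]
    q <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(
      type = tp,
      bin_start = seq_len(nbins) * bin_width,     # older edge
      bin_end = (seq_len(nbins) - 1) * bin_width,
      mean = colMeans(m),
      lo = q[1, ], hi = q[2, ]
    )
  })
  out <- do.call(rbind, per_type)
  out <- out[order(out$type, -out$bin_start), ]
  rownames(out) <- NULL
  structure(out, counts = counts, bin_width = bin_width, horizon = horizon,
            class = c("rate_series", "data.frame"))
}

#' @export
plot.rate_series <- function(x, ...) {
  types <- unique(x$type)
  op <- graphics::par(mfrow = c(length(types), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (tp in types) {
    d <- x[x$type == tp, ]
    mid <- (d$bin_start + d$bin_end) / 2
    plot(mid, d$mean, type = "s", xlim = rev(range(c(d$bin_start, d$bin_end))),
         ylim = c(0, max(d$hi, 1)), xlab = "Age (Ma)",
         ylab = sprintf("%ss per %g-Myr bin", tp, attr(x, "bin_width")), ...)
    graphics::lines(mid, d$lo, lty = 3)
    graphics::lines(mid, d$hi, lty = 3)
    graphics::title(main = tp)
  }
  invisible(x)
}

# ratio and percentage-loss conventions used in root-to-tip summaries;
# percentage loss is losses as a percentage of gains (the convention that
# reproduces published lineage tables), with losses/(gains+losses) reported
# alongside as pct_loss_of_changes
gain_loss_stats <- function(gains, losses) {
  data.frame(
    gains = gains, losses = losses,
    ratio = ifelse(losses > 0, gains / losses, NA_real_),
    pct_loss = ifelse(losses > 0, 100 * losses / gains, NA_real_),
    pct_loss_of_changes = ifelse(losses > 0, 100 * losses / (gains + losses),
                                 NA_real_)
  )
}

#' Root-to-tip lineage summaries of cumulative gains and losses
#'
#' Sums gain and loss counts over every branch on the path from the root (and
#' root stem, when present) to each tip, so changes on deep shared branches
#' are recorded in all descendant taxa.  The gain:loss ratio and percentage
#' loss (100 x losses/gains) are reported per lineage; both are `NA` for
#' lineages without losses.
#'
#' @param x a [dollo_map] or [ml_event_map].
#' @param tips tip labels to summarize (default: all tips).
#' @return Data frame with columns `tip`, `gains`, `losses`, `ratio`,
#'   `pct_loss`, `pct_loss_of_changes`, ordered by decreasing ratio as in the
#'   field's lineage tables.
#' @export
lineage_summary <- function(x, tips = NULL) {
  br <- branch_rates(x)
  tree <- x$tree
  if (is.null(tips)) tips <- tree$phy$tip.label
  res <- lapply(tips, function(tp) {
    path <- .root_path(tree, tp)
    ids <- path[-1]                                # branches subtending path nodes
    if (!is.na(tree$stem_age)) ids <- c(tree$root, ids)
    rows <- br[br$branch %in% ids, ]
    gain_loss_stats(sum(rows$gains), sum(rows$losses))
  })
  out <- cbind(tip = tips, do.call(rbind, res))
  out <- out[order(-out$ratio, na.last = FALSE), ]
  rownames(out) <- NULL
  out
}

#' Distribution of per-family loss counts
#'
#' @param x a [dollo_map].
#' @return A table: number of families by number of losses (0, 1, 2, ...).
#' @export
loss_count_distribution <- function(x) {
  stopifnot(inherits(x, "dollo_map"))
  table(losses = factor(x$loss_counts, levels = 0:max(x$loss_counts, 0)))
}

#' Flag branches with outlying gain rates
#'
#' The published analyses report branches with significantly high or low
#' acquisition rates without stating a procedure; the default rule here flags
#' branches whose gain rate falls outside the 2.5--97.5 empirical percentiles
#' of per-branch gain rates, and the rule in force is recorded in the output.
#'
#' @param rates data frame from [branch_rates()].
#' @param probs lower/upper percentile bounds (default `c(0.025, 0.975)`).
#' @return `rates` with added logical columns `high_gain_rate`,
#'   `low_gain_rate`; the method is stored in `attr(, "method")`.  With fewer
#'   than 5 usable branches, flagging is disabled with a warning.
#' @export
flag_rate_outliers <- function(rates, probs = c(0.025, 0.975)) {
  ok <- !is.na(rates$gain_rate)
  rates$high_gain_rate <- FALSE
  rates$low_gain_rate <- FALSE
  if (sum(ok) < 5) {
    warning("fewer than 5 branches with defined rates; outlier flagging disabled")
    attr(rates, "method") <- "disabled"
    return(rates)
  }
  q <- stats::quantile(rates$gain_rate[ok], probs = probs, names = FALSE)
  if (q[2] > q[1]) {                               # equal rates: flag nothing
    rates$high_gain_rate[ok] <- rates$gain_rate[ok] > q[2]
    rates$low_gain_rate[ok] <- rates$gain_rate[ok] < q[1]
  }
  attr(rates, "method") <- sprintf("empirical percentiles [%g, %g]",
                                   probs[1], probs[2])
  rates
}
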