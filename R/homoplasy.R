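#' Fitch parsimony step count for one binary character on a fixed tree
#'
#' Unordered-state Fitch counting on the rooted tree; for binary characters
#' this equals Wagner counting and is independent of root placement.
#'
#' @param states named 0/1 vector over the tree's tips.
#' @param tree a [timetree].
#' @return Integer number of state changes required.
#' @export
fitch_steps <- function(states, tree) {
  ntip <- length(tree$phy$tip.label)
  s <- states[tree$phy$tip.label]
  if (anyNA(s)) stop("states missing for tips: ",
                     paste(tree$phy$tip.label[is.na(s)], collapse = ", "))
  # state sets encoded as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  set <- integer(length(tree$ages))
  set[seq_len(ntip)] <- ifelse(s == 1, 2L, 1L)
  kids <- .children(tree)
  steps <- 0L
  for (n in .postorder_nodes(tree)) {
    if (n <= ntip) next
    acc <- 3L
    for (k in kids[[n]]) {
      inter <- bitwAnd(acc, set[k])
      if (inter == 0L) {
        steps <- steps + 1L
        acc <- bitwOr(acc, set[k])
      } else acc <- inter
    }
    set[n] <- acc
  }
  steps
}

#' Ensemble consistency index of a presence/absence matrix on a fixed tree
#'
#' The consistency index is the minimum number of changes a data set requires
#' divided by the number it actually requires on the tree; 1 means zero
#' homoplasy.  For a variable binary family the minimum is 1; actual changes
#' are Fitch counts.  Invariant (all-present) families require no changes and
#' are excluded from both sums, the conventional treatment.
#'
#' @param x a `presence_matrix` (or coercible) bound to `tree`.
#' @param tree a [timetree].
#' @param expected_taxa taxon count for the expected-CI reference values
#'   (default: the tree's tip count).
#' @return Object of class `ci_report`: list with `per_family` (data frame
#'   `family`, `min_changes`, `actual_changes`, `ci`), `ensemble_ci`,
#'   `expected_categorical`, `expected_molecular`, `n_taxa`.  `ensemble_ci`
#'   is `NA` for an all-constant matrix.
#' @export
ensemble_ci <- function(x, tree, expected_taxa = NULL) {
  x <- check_binding(x, tree)
  if (is.null(expected_taxa)) expected_taxa <- ncol(x)
  fams <- rownames(x)
  actual <- vapply(fams, function(f) fitch_steps(x[f, ], tree), integer(1))
  minc <- ifelse(apply(x, 1, function(r) length(unique(r))) > 1, 1L, 0L)
  stopifnot(all(actual >= minc))
  variable <- minc > 0
  ens <- if (any(variable)) sum(minc[variable]) / sum(actual[variable]) else NA_real_
  per_family <- data.frame(
    family = fams, min_changes = minc, actual_changes = actual,
    ci = ifelse(actual > 0, minc / actual, NA_real_),
    row.names = NULL
  )
  structure(
    list(per_family = per_family, ensemble_ci = ens, n_taxa = expected_taxa,
         expected_categorical = expected_ci(expected_taxa, "categorical"),
         expected_molecular = expected_ci(expected_taxa, "molecular")),
    class = "ci_report"
  )
}

#' @export
print.ci_report <- function(x, ...) {
  cat("Consistency index report\n")
  cat(sprintf("  ensemble CI: %s over %d variable families\n",
              format(x$ensemble_ci, digits = 4),
              sum(x$per_family$min_changes > 0)))
  cat(sprintf("  expected for %d taxa: categorical ~%.2f, molecular ~%.2f\n",
              x$n_taxa, x$expected_categorical, x$expected_molecular))
  cat("  homoplastic families:", sum(x$per_family$actual_changes >
                                       x$per_family$min_changes), "\n")
  invisible(x)
}

# default expected-CI curves: log-linear in taxon count, anchored to published
# reference levels for ~35-taxon categorical (~0.50) and molecular (~0.64)
# matrices and to typical small-matrix CIs near n = 10
.expected_ci_coefs <- list(
  categorical = c(intercept = 1.29461, slope = -0.22350),
  molecular   = c(intercept = 1.23598, slope = -0.16762)
)

#' Expected consistency index for a data set of a given size
#'
#' Empirical regressions of CI on taxon count decline with sampling; the
#' built-in coefficient sets are log-linear curves calibrated to reference
#' levels reported for comparative compilations of categorical (morphological
#' and presence/absence) and molecular matrices.  Supply `coefficients` to
#' use a different curve; the coefficients in force are recorded in the
#' result's attributes.
#'
#' @param n_taxa number of taxa.
#' @param class `"categorical"` or `"molecular"`.
#' @param coefficients optional `c(intercept, slope)` for
#'   `CI = intercept + slope * log(n_taxa)`.
#' @return Expected CI (clamped to (0, 1]); attributes record the curve used.
#' @export
expected_ci <- function(n_taxa, class = c("categorical", "molecular"),
                        coefficients = NULL) {
  class <- match.arg(class)
  if (is.null(coefficients)) coefficients <- .expected_ci_coefs[[class]]
  stopifnot(length(coefficients) == 2)
  if (n_taxa < 4 || n_taxa > 100)
    warning("taxon count ", n_taxa,
            " is outside the calibrated range (4-100) of the expected-CI curve")
  v <- coefficients[[1]] + coefficients[[2]] * log(n_taxa)
  v <- min(max(v, .Machine$double.eps), 1)
  structure(v, coefficients = coefficients, class_of_data = class)
}
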