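#' Validate a binary presence/absence matrix of families by taxa
#'
#' Checks that cells are strictly 0/1, family and taxon identifiers are unique,
#' and every family is present in at least one taxon.  All-absent families
#' carry no signal under a single-origin model (they are unobservable in real
#' annotation data) and are dropped with a warning.
#'
#' @param x a matrix or data frame with families as rows and taxa as columns;
#'   row names are family ids, column names taxon ids.
#' @param drop_all_absent drop families with no presence (default `TRUE`);
#'   if `FALSE`, all-absent families are an error.
#' @return An integer matrix of class `presence_matrix` (families x taxa).
#' @examples
#' m <- presence_matrix(rbind(f1 = c(A = 1, B = 1, C = 0),
#'                            f2 = c(A = 0, B = 0, C = 1)))
#' summary(m)
#' @export
presence_matrix <- function(x, drop_all_absent = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must carry family (row) and taxon (column) names")
  rownames(x) <- trimws(rownames(x))
  colnames(x) <- trimws(colnames(x))
  if (anyDuplicated(rownames(x)))
    stop("duplicate family ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("cells must be 0 or 1; use read_presence_matrix() to map unknown codes")
  absent <- rowSums(x) == 0
  if (any(absent)) {
    if (!drop_all_absent)
      stop(sum(absent), " all-absent families present and drop_all_absent = FALSE")
    warning("dropping ", sum(absent), " all-absent families: ",
            paste(utils::head(rownames(x)[absent], 5), collapse = ", "),
            if (sum(absent) > 5) ", ...")
    x <- x[!absent, , drop = FALSE]
  }
  class(x) <- c("presence_matrix", class(x))
  x
}

#' Read a presence/absence matrix from CSV, TSV or NEXUS
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"nexus"` (characters block, symbols
#'   `"01"`).
#' @param orientation whether families are rows (`"families_rows"`, default)
#'   or columns (`"taxa_rows"`); never guessed from the file.
#' @param unknown policy for unknown cells (`"?"` or `NA`): `"reject"`
#'   (default; complete curated data sets have none) or `"absent"`.
#' @param drop_all_absent passed to [presence_matrix()].
#' @return A `presence_matrix`.  Counts of families, taxa and singletons are
#'   reported via [summary.presence_matrix()].
#' @export
read_presence_matrix <- function(path,
                                 format = c("csv", "tsv", "nexus"),
                                 orientation = c("families_rows", "taxa_rows"),
                                 unknown = c("reject", "absent"),
                                 drop_all_absent = TRUE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "nexus") {
    dat <- ape::read.nexus.data(path)              # list: taxon -> state vector
    x <- do.call(rbind, lapply(dat, function(s) suppressWarnings(as.integer(s))))
    rownames(x) <- names(dat)
    colnames(x) <- paste0("char", seq_len(ncol(x)))
    raw <- do.call(rbind, dat)
    x[raw %in% c("?", "-")] <- NA_integer_
    x <- t(x)                                      # families x taxa
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("NA", "?"))
    x <- as.matrix(df)
    if (orientation == "taxa_rows") x <- t(x)
  }
  if (anyNA(x)) {
    if (unknown == "reject")
      stop(sum(is.na(x)), " unknown cells ('?'/NA) found and unknown = \"reject\"")
    x[is.na(x)] <- 0L
  }
  presence_matrix(x, drop_all_absent = drop_all_absent)
}

#' @export
summary.presence_matrix <- function(object, ...) {
  counts <- rowSums(object)
  out <- list(
    n_families  = nrow(object),
    n_taxa      = ncol(object),
    n_singleton = sum(counts == 1),
    n_universal = sum(counts == ncol(object)),
    presences   = sum(object)
  )
  class(out) <- "summary.presence_matrix"
  out
}

#' @export
print.summary.presence_matrix <- function(x, ...) {
  cat("Presence/absence matrix:", x$n_families, "families x", x$n_taxa, "taxa\n")
  cat("  singletons:", x$n_singleton,
      " universal:", x$n_universal,
      " total presences:", x$presences, "\n")
  invisible(x)
}

#' @export
print.presence_matrix <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

# check a matrix against a tree's tip set; returns the matrix with columns
# ordered as the tree's tips
check_binding <- function(x, tree) {
  stopifnot(inherits(tree, "timetree"))
  if (!inherits(x, "presence_matrix")) x <- presence_matrix(x)
  tips <- tree$phy$tip.label
  extra   <- setdiff(colnames(x), tips)
  missing <- setdiff(tips, colnames(x))
  if (length(extra) || length(missing))
    stop("matrix taxa do not match tree tips.",
         if (length(missing)) paste0(" Missing from matrix: ",
                                     paste(missing, collapse = ", "), "."),
         if (length(extra)) paste0(" Not in tree: ",
                                   paste(extra, collapse = ", "), "."))
  x[, tips, drop = FALSE]
}
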