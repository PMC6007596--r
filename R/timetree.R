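#' Time-calibrated phylogeny with node ages and branch intervals
#'
#' A `timetree` wraps an [ape::phylo] tree whose branch lengths are absolute
#' time in millions of years (Myr), adding node ages in Ma and a branch table
#' giving, for every branch, its child node, parent node, start age (older
#' end), end age (younger end) and duration.  Ages are anchored by placing the
#' deepest root-to-tip path's tip at 0 Ma, so non-contemporaneous tips are
#' permitted.  If the `phylo` object carries a `root.edge`, it is treated as a
#' root stem branch (identified by the root node id) extending the analysis
#' horizon above the root node.
#'
#' @param phy an object of class `phylo`, rooted, with branch lengths in Myr.
#' @return An object of class `timetree`: a list with components
#'   \describe{
#'     \item{phy}{the `phylo` object}
#'     \item{ages}{numeric vector of node ages in Ma, indexed by node id}
#'     \item{root}{root node id}
#'     \item{root_age}{age of the root node (Ma)}
#'     \item{stem_age}{age of the top of the root stem, or `NA` if the tree
#'       has no root edge}
#'     \item{branches}{data frame with columns `branch` (child node id, the
#'       branch identifier), `parent`, `start`, `end`, `duration`; the root
#'       stem, when present, appears with `branch` equal to the root id and
#'       `parent` `NA`}
#'   }
#' @examples
#' tr <- timetree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' tr$root_age
#' tr$branches
#' @export
timetree <- function(phy) {
  if (!inherits(phy, "phylo"))
    stop("'phy' must be an object of class 'phylo'")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; a timetree requires durations in Myr")
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed in a timetree")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy))
    stop("tree must be rooted")
  phy$tip.label <- trimws(phy$tip.label)

  ntip  <- length(phy$tip.label)
  root  <- ntip + 1L
  depth <- ape::node.depth.edgelength(phy)   # distance from root, per node
  ages  <- max(depth) - depth                # deepest tip sits at 0 Ma
  root_age <- ages[root]

  br <- data.frame(
    branch   = phy$edge[, 2],
    parent   = phy$edge[, 1],
    start    = ages[phy$edge[, 1]],
    end      = ages[phy$edge[, 2]],
    duration = phy$edge.length
  )
  stem_age <- NA_real_
  if (!is.null(phy$root.edge) && phy$root.edge > 0) {
    stem_age <- root_age + phy$root.edge
    br <- rbind(
      data.frame(branch = root, parent = NA_integer_, start = stem_age,
                 end = root_age, duration = phy$root.edge),
      br
    )
  }
  stopifnot(all(abs(br$duration - (br$start - br$end)) < 1e-9))

  structure(
    list(phy = phy, ages = ages, root = root, root_age = root_age,
         stem_age = stem_age, branches = br),
    class = "timetree"
  )
}

#' Read a timetree from a Newick or NEXUS file
#'
#' Branch lengths are interpreted as durations in Myr; node ages are derived
#' by root-to-tip accumulation with the deepest tip anchored at 0 Ma.
#'
#' @param path path to the tree file.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return A [timetree] object.
#' @export
read_timetree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (is.null(phy))
    stop("could not parse tree file: ", path)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1)
      stop("file contains ", length(phy), " trees; expected exactly one")
    phy <- phy[[1]]
  }
  timetree(phy)
}

#' Write a timetree to Newick
#'
#' @param tree a [timetree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timetree <- function(tree, path) {
  stopifnot(inherits(tree, "timetree"))
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

#' @export
print.timetree <- function(x, ...) {
  ntip <- length(x$phy$tip.label)
  cat("Timetree with", ntip, "tips and", x$phy$Nnode, "internal nodes\n")
  cat("  root age:", format(x$root_age, digits = 6), "Ma",
      if (!is.na(x$stem_age)) paste0("(stem to ", format(x$stem_age, digits = 6), " Ma)"),
      "\n")
  cat("  total branch time:", format(sum(x$branches$duration), digits = 6), "Myr\n")
  invisible(x)
}

# children of each node as a list indexed by node id
.children <- function(tree) {
  nn <- length(tree$ages)
  kids <- vector("list", nn)
  e <- tree$phy$edge
  for (i in seq_len(nrow(e))) kids[[e[i, 1]]] <- c(kids[[e[i, 1]]], e[i, 2])
  kids
}

# tip ids (integers) descending from each node
.tips_below <- function(tree) {
  ntip <- length(tree$phy$tip.label)
  nn <- length(tree$ages)
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- i
  ord <- rev(ape::postorder(tree$phy))          # edges, root-most first
  for (i in rev(ord)) {                         # process child before parent
    e <- tree$phy$edge[i, ]
    below[[e[1]]] <- c(below[[e[1]]], below[[e[2]]])
  }
  below
}

# nodes on the root -> tip path, root first, tip last
.root_path <- function(tree, tip) {
  ntip <- length(tree$phy$tip.label)
  if (is.character(tip)) {
    tip <- match(tip, tree$phy$tip.label)
    if (is.na(tip)) stop("unknown tip label")
  }
  stopifnot(tip >= 1, tip <= ntip)
  parent <- integer(length(tree$ages))
  e <- tree$phy$edge
  parent[e[, 2]] <- e[, 1]
  path <- tip
  while (path[1] != tree$root) path <- c(parent[path[1]], path)
  path
}
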