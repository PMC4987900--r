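# Conformer clustering in dihedral space: pairwise circular distances over
# the selected (position, angle) variables, complete-linkage agglomeration
# with deterministic tie-breaking, and a radius cut where the radius is the
# minimum inter-cluster distance allowed to survive.

#' Dihedral-space distance between two torsion maps
#'
#' Aggregates the circular distances over the variables where both
#' structures have a defined value: arithmetic mean by default (keeps the
#' result in degrees, directly comparable to the cluster radius), with RMS
#' and maximum as alternatives.
#'
#' @param t1,t2 numeric vectors of torsion values in degrees over the same
#'   variables, `NA` marking undefined or gapped entries.
#' @param aggregation `"mean"` (default), `"rms"` or `"max"`.
#' @return a list with `distance` (degrees) and `n_used` (variables
#'   compared).
#' @export
structure_distance <- function(t1, t2, aggregation = c("mean", "rms", "max")) {
  aggregation <- match.arg(aggregation)
  if (length(t1) != length(t2))
    stop("torsion maps differ in length")
  ok <- !is.na(t1) & !is.na(t2)
  if (!any(ok))
    stop("no comparable dihedral variables between the two structures")
  d <- circ_dist(t1[ok], t2[ok])
  dist <- switch(aggregation,
                 mean = mean(d),
                 rms = sqrt(mean(d^2)),
                 max = max(d))
  list(distance = dist, n_used = sum(ok))
}

# torsion value matrix: structures x selected (position, angle) variables
torsion_value_matrix <- function(torsions, alignment, selection) {
  long <- torsions_by_position(torsions, alignment)
  positions <- alignment_positions(alignment)
  angles <- c("phi", "psi")
  if (!is.null(selection)) {
    angles <- selection$angles
    if (!is.null(selection$ranges))
      positions <- positions[positions %in% selection_positions(selection)]
  }
  if (!length(positions) || !length(angles))
    stop("empty dihedral variable selection")
  vars <- expand.grid(angle = angles, position = positions,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  varkey <- paste(vars$position, vars$angle)
  V <- matrix(NA_real_, nrow = length(alignment$labels),
              ncol = nrow(vars),
              dimnames = list(alignment$labels, varkey))
  sel <- !is.na(long$position) & long$angle %in% angles &
    long$position %in% positions
  long <- long[sel, , drop = FALSE]
  V[cbind(match(long$label, alignment$labels),
          match(paste(long$position, long$angle), varkey))] <- long$value
  V
}

#' Pairwise dihedral distance matrix of an ensemble
#'
#' Builds the structure x structure distance matrix from the torsion table
#' restricted to the Position list selection (default: all positions, phi
#' and psi).  A warning is raised when the number of comparable variables
#' varies by more than 50% across pairs.
#'
#' @param torsions torsion table from [ensemble_torsions()].
#' @param alignment the `ensemble_alignment`.
#' @param selection optional `position_selection` (see
#'   [parse_position_list()]).
#' @param aggregation per-pair aggregation, see [structure_distance()].
#' @return a `dihedral_dist`: list with `labels`, `d` (symmetric matrix,
#'   degrees, zero diagonal), `n_used` (matrix of variable counts) and
#'   `aggregation`.
#' @export
dihedral_distance_matrix <- function(torsions, alignment, selection = NULL,
                                     aggregation = c("mean", "rms", "max")) {
  aggregation <- match.arg(aggregation)
  V <- torsion_value_matrix(torsions, alignment, selection)
  n <- nrow(V)
  if (n < 2L) stop("at least 2 structures are required")
  d <- matrix(0, n, n, dimnames = list(rownames(V), rownames(V)))
  nu <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(nu) <- as.integer(rowSums(!is.na(V)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sd <- tryCatch(structure_distance(V[i, ], V[j, ], aggregation),
                     error = function(e)
                       stop("structures '", rownames(V)[i], "' and '",
                            rownames(V)[j], "': ", conditionMessage(e)))
      d[i, j] <- d[j, i] <- sd$distance
      nu[i, j] <- nu[j, i] <- sd$n_used
    }
  }
  off <- nu[upper.tri(nu)]
  if (min(off) < 0.5 * max(off))
    warning("number of comparable dihedral variables varies by more than ",
            "50% across structure pairs (", min(off), "-", max(off), ")")
  structure(list(labels = rownames(V), d = d, n_used = nu,
                 aggregation = aggregation),
            class = "dihedral_dist")
}

#' Complete-linkage hierarchical clustering
#'
#' Naive agglomerative clustering where the distance between clusters is
#' the maximum pairwise member distance ("maximum linkage").  Ties are
#' broken deterministically towards the pair whose smallest leaf indices
#' are smallest, so the tree is reproducible.
#'
#' @param d a `dihedral_dist`, a symmetric matrix or a [stats::dist]
#'   object (>= 2 items).
#' @param labels optional leaf labels (taken from `d` when available).
#' @return a `cluster_tree`: list with `merge` (in [stats::hclust] merge
#'   encoding), `height` (degrees, non-decreasing), `order`, `labels`.
#' @export
linkage_complete <- function(d, labels = NULL) {
  if (inherits(d, "dihedral_dist")) {
    labels <- d$labels
    d <- d$d
  } else if (inherits(d, "dist")) {
    if (is.null(labels)) labels <- attr(d, "Labels")
    d <- as.matrix(d)
  } else {
    d <- as.matrix(d)
    if (is.null(labels)) labels <- rownames(d)
  }
  n <- nrow(d)
  if (n < 2L) stop("clustering needs at least 2 items")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- d
  id <- -seq_len(n)          # hclust encoding: negative = leaf
  rep_leaf <- seq_len(n)     # smallest member leaf index per active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; best_d <- Inf
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in seq(ii + 1L, length(act))) {
        i <- act[ii]; j <- act[jj]
        dij <- D[i, j]
        cand <- sort(c(rep_leaf[i], rep_leaf[j]))
        if (dij < best_d ||
            (dij == best_d && (cand[1L] < best[1L] ||
                               (cand[1L] == best[1L] && cand[2L] < best[2L])))) {
          best_d <- dij; best <- cand; best_pair <- c(i, j)
        }
      }
    }
    i <- best_pair[1L]; j <- best_pair[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # complete linkage update: new cluster lives in slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- max(D[i, k], D[j, k])
    }
    active[j] <- FALSE
    id[i] <- step
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
    members[[i]] <- c(members[[i]], members[[j]])
  }
  structure(list(merge = merge, height = height,
                 order = tree_leaf_order(merge), labels = labels),
            class = "cluster_tree")
}

# left-to-right leaf order by traversing the merge encoding
tree_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @export
as.hclust.cluster_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 call = match.call(), dist.method = "circular"),
            class = "hclust")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> complete linkage, ", length(x$labels),
      " leaves, merge heights ", sprintf("%.2f", min(x$height)), "..",
      sprintf("%.2f", max(x$height)), " deg\n", sep = "")
  invisible(x)
}

#' Cut a cluster tree at a radius
#'
#' Applies every merge with height strictly below `radius` and refuses the
#' rest, so that any two surviving clusters are at least `radius` apart in
#' complete-linkage distance: the radius is the minimum distance allowed
#' between clusters (default 60 degrees).  Cluster ids are 1-based, ordered
#' by decreasing size, ties towards the smallest member index.
#'
#' @param tree a `cluster_tree`.
#' @param radius cut radius in degrees (> 0).
#' @return a `cluster_result`: list with `labels` (named integer vector of
#'   cluster ids per structure), `radius`, `sizes`, `tree`.
#' @export
cut_tree <- function(tree, radius = 60) {
  stopifnot(inherits(tree, "cluster_tree"), radius > 0)
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_root <- integer(n - 1L)  # leaf representative of each merge node
  get_rep <- function(node) if (node < 0L) -node else node_root[node]
  for (step in seq_len(nrow(tree$merge))) {
    a <- get_rep(tree$merge[step, 1L])
    b <- get_rep(tree$merge[step, 2L])
    node_root[step] <- a
    if (tree$height[step] < radius) {
      ra <- find(a); rb <- find(b)
      parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), roots)
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, min, integer(1L)))
  ids <- integer(n)
  for (k in seq_along(ord)) ids[groups[[ord[k]]]] <- k
  names(ids) <- tree$labels
  structure(list(labels = ids, radius = radius,
                 sizes = as.integer(table(ids)), tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$sizes), " cluster(s) at radius ",
      x$radius, " deg; sizes ", paste(x$sizes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Structure list with cluster ids in the family column
#'
#' Regenerates the Structure list text with the cluster number as the
#' family label, ready to seed a second analysis run stratified by
#' cluster.
#'
#' @param result a `cluster_result`.
#' @param entries Structure list data frame (from
#'   [parse_structure_list()]); `basename`s must match the clustered
#'   labels.
#' @return the Structure list text, one line per entry, re-parseable by
#'   [parse_structure_list()].
#' @export
emit_cluster_families <- function(result, entries) {
  stopifnot(inherits(result, "cluster_result"))
  ids <- result$labels[entries$basename]
  if (anyNA(ids))
    stop("entries without a cluster label: ",
         paste(entries$basename[is.na(ids)], collapse = ", "))
  paste(entries$basename, entries$chain, ids)
}

#' Newick serialization of a cluster tree
#'
#' Ultrametric Newick text: each internal node sits at its merge height,
#' branch lengths are the height differences, leaves at height 0.
#'
#' @param tree a `cluster_tree`.
#' @param path optional file path; when given the text is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  node_h <- function(node) if (node < 0L) 0 else tree$height[node]
  render <- function(node) {
    if (node < 0L) return(tree$labels[-node])
    h <- tree$height[node]
    kids <- tree$merge[node, ]
    paste0("(", paste(vapply(kids, function(k)
      paste0(render(k), ":", format(h - node_h(k), digits = 10)),
      character(1L)), collapse = ","), ")")
  }
  txt <- paste0(render(nrow(tree$merge)), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
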