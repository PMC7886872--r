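#' Synthetic hepatic arterial trees
#'
#' A truncated hepatic arterial tree is represented as a rooted binary tree
#' of straight cylindrical vessels. Each node carries a length, radius and
#' unit direction vector; leaves are the outlets of the computational
#' domain. Daughter radii follow Murray's law
#' \eqn{r_p^m = r_{d1}^m + r_{d2}^m} (default exponent m = 3) with a
#' configurable daughter asymmetry ratio, the standard generative rule for
#' arterial trees when patient-specific geometry is unavailable.
#'
#' @param depth number of generations including the root; a full binary
#'   tree of `depth` generations has `2^(depth-1)` outlets. Must be >= 2.
#' @param root_radius root vessel radius in metres (> 0).
#' @param murray_exponent branching exponent m (default 3).
#' @param asymmetry daughter radius ratio r2/r1 in (0, 1]; 1 gives a
#'   symmetric bifurcation.
#' @param lambda length-to-radius ratio: each vessel has
#'   `length = lambda * radius` (default 8, anatomically typical).
#' @param seed integer seed controlling the (random) branching directions;
#'   the same seed always yields the same tree.
#' @return An object of class `arterial_tree`: a list with `nodes` (a
#'   data.frame with columns `id`, `parent_id`, `length_m`, `radius_m`,
#'   `dir_x`, `dir_y`, `dir_z`, `is_outlet`), `root_id`, `outlet_ids` and
#'   the `murray_exponent` used at generation time.
#' @examples
#' tr <- generate_tree(depth = 3, root_radius = 2e-3, seed = 1)
#' validate_tree(tr)
#' @export
generate_tree <- function(depth, root_radius, murray_exponent = 3,
                          asymmetry = 1, lambda = 8, seed = NULL) {
  check_scalar(depth, "depth", min = 2, integer = TRUE)
  check_scalar(root_radius, "root_radius", min = 0, strict_min = TRUE)
  check_scalar(murray_exponent, "murray_exponent", min = 1)
  check_scalar(asymmetry, "asymmetry", min = 0, max = 1, strict_min = TRUE)
  check_scalar(lambda, "lambda", min = 0, strict_min = TRUE)

  with_seed(seed, {
    id <- character(0); parent <- character(0)
    radius <- numeric(0); dirs <- matrix(numeric(0), ncol = 3)
    # breadth-first construction; ids encode the root-to-node path so that
    # lexicographic id order is deterministic and structure-revealing
    queue <- list(list(id = "b", parent = NA_character_,
                       radius = root_radius, dir = c(1, 0, 0), gen = 1L))
    while (length(queue)) {
      nd <- queue[[1]]; queue <- queue[-1]
      id <- c(id, nd$id); parent <- c(parent, nd$parent)
      radius <- c(radius, nd$radius); dirs <- rbind(dirs, nd$dir)
      if (nd$gen < depth) {
        r1 <- nd$radius / (1 + asymmetry^murray_exponent)^(1 / murray_exponent)
        r2 <- asymmetry * r1
        dd <- branch_directions(nd$dir)
        queue <- c(queue, list(
          list(id = paste0(nd$id, "1"), parent = nd$id, radius = r1,
               dir = dd[1, ], gen = nd$gen + 1L),
          list(id = paste0(nd$id, "2"), parent = nd$id, radius = r2,
               dir = dd[2, ], gen = nd$gen + 1L)))
      }
    }
    nodes <- data.frame(
      id = id, parent_id = parent,
      length_m = lambda * radius, radius_m = radius,
      dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
      is_outlet = !(id %in% parent),
      stringsAsFactors = FALSE)
    tree <- structure(
      list(nodes = nodes, root_id = "b",
           outlet_ids = sort(nodes$id[nodes$is_outlet]),
           murray_exponent = murray_exponent),
      class = "arterial_tree")
    tree
  })
}

# Two daughter unit directions: parent direction tilted by random angles
# (20-40 degrees) to opposite sides of a randomly oriented branching plane.
branch_directions <- function(d) {
  w <- cross_basis(d)
  phi <- stats::runif(1, 0, 2 * pi)
  u <- cos(phi) * w$e1 + sin(phi) * w$e2
  th <- stats::runif(2, 20, 40) * pi / 180
  d1 <- cos(th[1]) * d + sin(th[1]) * u
  d2 <- cos(th[2]) * d - sin(th[2]) * u
  rbind(d1 / sqrt(sum(d1^2)), d2 / sqrt(sum(d2^2)))
}

# Deterministic orthonormal basis (e1, e2) of the plane normal to unit d.
cross_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(d[2] * ref[3] - d[3] * ref[2],
          d[3] * ref[1] - d[1] * ref[3],
          d[1] * ref[2] - d[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Validate the structural invariants of an arterial tree
#'
#' Checks: exactly one root; connected and acyclic; outlets coincide with
#' the leaves; positive radii and lengths; unit direction vectors
#' (tolerance 1e-9); and Murray's law at every bifurcation within relative
#' tolerance `tol_murray`.
#'
#' @param tree an `arterial_tree`.
#' @param tol_murray relative tolerance on
#'   \eqn{|r_p^m - \sum r_d^m| / r_p^m}.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_tree <- function(tree, tol_murray = 1e-6) {
  stopifnot(inherits(tree, "arterial_tree"))
  nd <- tree$nodes
  if (anyDuplicated(nd$id)) stop_input("duplicated node ids")
  roots <- nd$id[is.na(nd$parent_id)]
  if (length(roots) != 1L || roots != tree$root_id)
    stop_input("tree must have exactly one root matching root_id")
  if (!all(nd$parent_id[!is.na(nd$parent_id)] %in% nd$id))
    stop_input("dangling parent reference")
  # n nodes with n-1 parent edges and all nodes reachable from the root
  # implies acyclic + connected
  reach <- tree$root_id
  repeat {
    nxt <- nd$id[nd$parent_id %in% reach & !(nd$id %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (length(reach) != nrow(nd)) stop_input("tree is not connected")
  if (any(nd$radius_m <= 0) || any(nd$length_m <= 0))
    stop_input("non-positive radius or length")
  nrm <- sqrt(nd$dir_x^2 + nd$dir_y^2 + nd$dir_z^2)
  if (any(abs(nrm - 1) > 1e-9)) stop_input("direction vectors must be unit")
  leaves <- sort(nd$id[!(nd$id %in% nd$parent_id)])
  if (!identical(leaves, sort(tree$outlet_ids)))
    stop_input("outlet_ids must be exactly the leaves")
  m <- tree$murray_exponent %||% 3
  kids <- split(nd$radius_m, nd$parent_id)
  for (p in names(kids)) {
    if (length(kids[[p]]) == 1L) next
    rp <- nd$radius_m[nd$id == p]
    if (abs(rp^m - sum(kids[[p]]^m)) > tol_murray * rp^m)
      stop_input("Murray's law violated at node ", p)
  }
  invisible(TRUE)
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat("arterial_tree:", nrow(x$nodes), "vessels,",
      length(x$outlet_ids), "outlets, root radius",
      format(x$nodes$radius_m[x$nodes$id == x$root_id], digits = 4),
      "m\n")
  invisible(x)
}

# named list: parent id -> character vector of daughter ids (sorted)
tree_daughters <- function(tree) {
  nd <- tree$nodes
  dd <- split(nd$id, nd$parent_id)
  lapply(dd, sort)
}

#' Node start positions (root at the origin)
#'
#' Start coordinate of every vessel, computed by walking the tree: a
#' daughter starts where its parent ends.
#'
#' @param tree an `arterial_tree`.
#' @return matrix with one row per node (rownames = node ids), columns
#'   x, y, z in metres.
#' @export
tree_node_positions <- function(tree) {
  nd <- tree$nodes
  pos <- matrix(NA_real_, nrow(nd), 3, dimnames = list(nd$id, c("x", "y", "z")))
  pos[tree$root_id, ] <- 0
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  pending <- nd$id[!is.na(nd$parent_id)]
  while (length(pending)) {
    ready <- pending[!is.na(pos[nd$parent_id[idx[pending]], 1])]
    for (i in ready) {
      p <- nd$parent_id[idx[i]]
      j <- idx[p]
      pos[i, ] <- pos[p, ] + nd$length_m[j] *
        c(nd$dir_x[j], nd$dir_y[j], nd$dir_z[j])
    }
    pending <- setdiff(pending, ready)
  }
  pos
}

#' Write / read an arterial tree as a JSON graph document
#'
#' The document holds one record per node (`id`, `parent`, `length_m`,
#' `radius_m`, `direction`, `daughters`, `is_outlet`) plus top-level
#' `root_id`, `outlet_ids` and `schema_version`. Writing the same tree
#' twice produces byte-identical files, and `read_tree_json()` inverts
#' `write_tree_json()` exactly.
#'
#' @param tree an `arterial_tree`.
#' @param path file path.
#' @return `read_tree_json` returns the `arterial_tree`; `write_tree_json`
#'   returns `path` invisibly.
#' @export
write_tree_json <- function(tree, path) {
  validate_tree(tree)
  nd <- tree$nodes
  dts <- tree_daughters(tree)
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    n <- list(
      id = nd$id[i],
      length_m = nd$length_m[i],
      radius_m = nd$radius_m[i],
      direction = c(nd$dir_x[i], nd$dir_y[i], nd$dir_z[i]),
      daughters = as.list(dts[[nd$id[i]]] %||% character(0)),
      is_outlet = nd$is_outlet[i])
    if (!is.na(nd$parent_id[i])) n$parent <- nd$parent_id[i]
    n
  })
  doc <- list(schema_version = 1L, root_id = tree$root_id,
              outlet_ids = as.list(tree$outlet_ids),
              murray_exponent = tree$murray_exponent %||% 3,
              nodes = nodes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$nodes) || is.null(doc$root_id))
    stop_input("not a tree document: missing 'nodes' or 'root_id'")
  nd <- do.call(rbind, lapply(doc$nodes, function(n) {
    p <- n$parent
    data.frame(id = n$id,
               parent_id = if (is.null(p) || !length(p)) NA_character_
                           else as.character(p),
               length_m = n$length_m, radius_m = n$radius_m,
               dir_x = n$direction[[1]], dir_y = n$direction[[2]],
               dir_z = n$direction[[3]],
               is_outlet = isTRUE(n$is_outlet),
               stringsAsFactors = FALSE)
  }))
  tree <- structure(
    list(nodes = nd, root_id = doc$root_id,
         outlet_ids = sort(unlist(doc$outlet_ids)),
         murray_exponent = doc$murray_exponent %||% 3),
    class = "arterial_tree")
  validate_tree(tree)
  tree
}
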