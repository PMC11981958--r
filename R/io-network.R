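#' Construct a river network
#'
#' A drainage network is a rooted tree directed toward a single outlet.
#' Each non-outlet node carries a pointer to its downstream (parent) node
#' and the length of the connecting reach.
#'
#' @param child Character vector of child (upstream) node names, one per
#'   edge.
#' @param parent Character vector of the corresponding downstream nodes.
#' @param length_km Numeric vector of reach lengths in km (> 0).
#' @param coords Optional data frame with columns `node`, `lat`, `lon`.
#' @return An object of class `river_network` with elements `nodes`,
#'   `parent` (named, `NA` at the outlet), `edge_length` (named by child),
#'   `outlet` and optionally `coords`.
#' @export
river_network <- function(child, parent, length_km, coords = NULL) {
  if (length(child) != length(parent) || length(child) != length(length_km)) {
    stop("child, parent and length_km must have equal length", call. = FALSE)
  }
  if (anyDuplicated(child)) {
    stop("node '", child[duplicated(child)][1],
         "' has more than one downstream edge", call. = FALSE)
  }
  if (any(length_km <= 0)) stop("reach lengths must be positive", call. = FALSE)
  nodes <- union(child, parent)
  roots <- setdiff(nodes, child)
  if (length(roots) != 1) {
    stop("network must have exactly one outlet (node with no parent); found ",
         length(roots), call. = FALSE)
  }
  par <- setNames(rep(NA_character_, length(nodes)), nodes)
  par[child] <- parent
  len <- setNames(rep(NA_real_, length(nodes)), nodes)
  len[child] <- length_km
  # cycle check: every node must reach the root (integer walk, O(n))
  pidx <- match(par, nodes)
  state <- integer(length(nodes))   # 0 unseen, 1 on current walk, 2 cleared
  for (i in seq_along(nodes)) {
    if (state[i] == 2L) next
    walk <- integer()
    cur <- i
    repeat {
      if (state[cur] == 1L) {
        stop("cycle detected at node '", nodes[cur], "'", call. = FALSE)
      }
      if (state[cur] == 2L || is.na(pidx[cur])) break
      state[cur] <- 1L
      walk <- c(walk, cur)
      cur <- pidx[cur]
    }
    state[walk] <- 2L
  }
  if (!is.null(coords)) {
    stopifnot(all(c("node", "lat", "lon") %in% names(coords)))
    coords <- coords[match(nodes, coords$node), , drop = FALSE]
  }
  structure(list(nodes = nodes, parent = par, edge_length = len,
                 outlet = roots, coords = coords),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat("River network:", length(x$nodes), "nodes,",
      sum(!is.na(x$parent)), "reaches, outlet", x$outlet, "\n")
  invisible(x)
}

#' Read a river network edge list
#'
#' @param path TSV with columns `child_node`, `parent_node`, `length_km`.
#' @return A [river_network()].
#' @export
read_network <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("child_node", "parent_node", "length_km")
  if (!all(need %in% names(df))) {
    stop(path, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  river_network(as.character(df$child_node), as.character(df$parent_node),
                as.numeric(df$length_km))
}

#' Write a river network edge list
#'
#' @param net A [river_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  ch <- names(net$parent)[!is.na(net$parent)]
  df <- data.frame(child_node = ch, parent_node = unname(net$parent[ch]),
                   length_km = unname(net$edge_length[ch]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
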