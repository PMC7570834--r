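## Wireless node network: one gateway (ID 0) plus radio nodes with 8-bit
## IDs 1..254 (255 is the broadcast/diffusion ID).  The radio chip can
## hold at most six simultaneous connections, so topologies are trees
## with at most five children per node (one pipe is the uplink).

.MAX_CHILDREN <- 5L
.MAX_NODES <- 254L
.BROADCAST_ID <- 255L

#' Create a network
#'
#' @param mode \code{"STATIC"} (fixed 5-ary tree; losing an internal
#'   node strands its subtree) or \code{"DYNAMIC"} (orphans reroute to
#'   surviving nodes, the network is immune to sudden death).
#' @param channel Radio frequency channel, 0..125.
#' @return A \code{network_state} with the gateway (ID 0) as root.
#' @export
network_new <- function(mode = c("DYNAMIC", "STATIC"), channel = 76L) {
  mode <- match.arg(mode)
  stopifnot(channel %in% 0:125)
  structure(list(mode = mode, channel = as.integer(channel),
                 parent = integer(),      # named: node id -> parent id
                 stranded = integer(),    # STATIC-mode orphans
                 routing_table = list()), # gateway map: id -> path from 0
            class = "network_state")
}

.live_nodes <- function(net) as.integer(names(net$parent))

.children_of <- function(net, id) .live_nodes(net)[net$parent == id]

.depth_of <- function(net, id) {
  d <- 0L
  while (id != 0L) {
    id <- net$parent[[as.character(id)]]
    d <- d + 1L
  }
  d
}

# path of node ids from the gateway down to `id` (inclusive)
.path_from_gateway <- function(net, id) {
  path <- integer()
  while (id != 0L) {
    path <- c(id, path)
    id <- net$parent[[as.character(id)]]
  }
  c(0L, path)
}

.refresh_routes <- function(net) {
  net$routing_table <- lapply(
    stats::setNames(.live_nodes(net), names(net$parent)),
    function(id) .path_from_gateway(net, id))
  net
}

#' Maximum module count of the static addressing scheme
#'
#' Counts, by exhaustive enumeration of the address strings, how many
#' modules the static tree addressing admits on one frequency channel:
#' every node at the full depth is reachable by a distinct string of
#' \code{levels} child indices, each in \code{1..branching}.  With five
#' children over five levels this is 3125 modules.
#'
#' @param branching Children per node (>= 1).
#' @param levels Address depth (>= 1).
#' @return Integer count of addressable modules.
#' @examples
#' static_capacity(5, 5)  # 3125
#' @export
static_capacity <- function(branching, levels) {
  stopifnot(branching >= 1, levels >= 1,
            branching == floor(branching), levels == floor(levels))
  # enumerate all full-depth address strings and count the distinct ones
  digits <- rep(list(seq_len(branching)), levels)
  nrow(unique(do.call(expand.grid, digits)))
}

#' Join a node to the network
#'
#' @param net A \code{network_state}.
#' @param node Node ID, 1..254, not yet live.
#' @param preferred_parent Parent to attach under (required in STATIC
#'   mode); in DYNAMIC mode a full or missing parent falls back to the
#'   closest-to-gateway node with free capacity (ties to the lowest ID).
#' @return The modified network.
#' @export
join <- function(net, node, preferred_parent = NULL) {
  stopifnot(inherits(net, "network_state"))
  node <- as.integer(node)
  if (node < 1L || node > .MAX_NODES)
    stop("node ID must be in 1..254 (0 is the gateway, 255 broadcast)",
         call. = FALSE)
  if (node %in% .live_nodes(net))
    stop("ID collision: node ", node, " is already live", call. = FALSE)
  if (length(net$parent) >= .MAX_NODES)
    stop("capacity exceeded: the 8-bit ID space holds 254 nodes; ",
         "connect more gateways, each on a different frequency channel",
         call. = FALSE)
  parent <- .pick_parent(net, preferred_parent)
  net$parent[[as.character(node)]] <- parent
  .refresh_routes(net)
}

.has_capacity <- function(net, id) length(.children_of(net, id)) < .MAX_CHILDREN

.pick_parent <- function(net, preferred) {
  if (!is.null(preferred)) {
    preferred <- as.integer(preferred)
    if (preferred != 0L && !preferred %in% .live_nodes(net))
      stop("preferred parent ", preferred, " is not live", call. = FALSE)
    if (.has_capacity(net, preferred)) return(preferred)
    if (net$mode == "STATIC")
      stop("parent ", preferred, " already has ", .MAX_CHILDREN,
           " children (six-connection radio limit)", call. = FALSE)
  } else if (net$mode == "STATIC") {
    stop("STATIC mode requires an explicit parent with free capacity",
         call. = FALSE)
  }
  .auto_parent(net)
}

# nearest-to-gateway live node with a free pipe, ties to the lowest ID
.auto_parent <- function(net) {
  cand <- c(0L, .live_nodes(net))
  cand <- cand[vapply(cand, function(i) .has_capacity(net, i), logical(1))]
  if (length(cand) == 0L) stop("no node has free capacity", call. = FALSE)
  depths <- vapply(cand, function(i) .depth_of(net, i), integer(1))
  cand[order(depths, cand)][1]
}

#' Remove a node from the network
#'
#' In DYNAMIC mode every orphaned descendant re-attaches to the
#' closest-to-gateway surviving node with free capacity and regains
#' gateway reachability; in STATIC mode the orphaned subtree is stranded
#' (that part of the tree collapses) until those nodes re-join.
#'
#' @param net A \code{network_state}.
#' @param node A live node ID (dropping the gateway is a fatal outage).
#' @return The modified network.
#' @export
drop_node <- function(net, node) {
  node <- as.integer(node)
  if (node == 0L)
    stop("fatal simulated outage: the gateway was dropped", call. = FALSE)
  if (!node %in% .live_nodes(net))
    stop("node ", node, " is not live", call. = FALSE)
  # orphans: the dropped node's whole subtree, minus the node itself
  sub <- setdiff(.subtree_nodes(net, node), node)
  depths <- vapply(sub, function(i) .depth_of(net, i), integer(1))
  keep <- setdiff(.live_nodes(net), c(node, sub))
  net$parent <- net$parent[as.character(keep)]
  if (net$mode == "DYNAMIC") {
    # re-attach formerly-shallowest orphans first, deterministically
    for (o in sub[order(depths, sub)]) {
      net$parent[[as.character(o)]] <- .pick_parent(net, NULL)
    }
  } else {
    net$stranded <- sort(unique(c(net$stranded, sub)))
  }
  .refresh_routes(net)
}

.subtree_nodes <- function(net, id) {
  out <- id
  for (ch in .children_of(net, id)) out <- c(out, .subtree_nodes(net, ch))
  out
}

#' Reachability of nodes from the gateway
#'
#' @param net A \code{network_state}.
#' @return Integer vector of live node IDs with a path to the gateway.
#' @export
reachable_nodes <- function(net) sort(.live_nodes(net))

#' Route a message through the tree
#'
#' Delivery follows the tree path between source and destination (up to
#' their closest common ancestor and down again), using the gateway's
#' routing table; only IDs are needed to communicate.  Destination 255
#' is the diffusion ID: the payload reaches every live node except the
#' sender exactly once.
#'
#' @param net A \code{network_state}.
#' @param src Source ID (0 = gateway, or a live node).
#' @param dst Destination ID, broadcast 255, or \code{"BROADCAST"}.
#' @param payload Arbitrary payload (carried in the trace).
#' @return A delivery trace: list with \code{delivered},
#'   \code{receipts} (IDs that received the payload), \code{hops}
#'   (data frame \code{from, to}) and \code{n_hops}.
#' @export
route_message <- function(net, src, dst, payload = NULL) {
  src <- as.integer(src)
  live <- c(0L, .live_nodes(net))
  if (!src %in% live) stop("source ", src, " is not live", call. = FALSE)
  if (identical(dst, "BROADCAST")) dst <- .BROADCAST_ID
  dst <- as.integer(dst)
  if (dst == .BROADCAST_ID) {
    receipts <- setdiff(live, src)
    # flood: every tree edge is traversed away from the source
    hops <- do.call(rbind, lapply(receipts, function(r) {
      p <- .tree_path(net, src, r)
      data.frame(from = p[length(p) - 1L], to = r)
    }))
    return(list(delivered = TRUE, receipts = sort(receipts),
                hops = unique(hops), n_hops = nrow(unique(hops)),
                payload = payload))
  }
  if (!dst %in% live)
    return(list(delivered = FALSE, receipts = integer(),
                hops = data.frame(from = integer(), to = integer()),
                n_hops = NA_integer_, payload = payload,
                error = paste("destination", dst, "unreachable")))
  p <- .tree_path(net, src, dst)
  hops <- if (length(p) > 1L) {
    data.frame(from = p[-length(p)], to = p[-1])
  } else {
    data.frame(from = integer(), to = integer())
  }
  list(delivered = TRUE, receipts = dst, hops = hops,
       n_hops = nrow(hops), payload = payload)
}

# unique path between two ids on the tree (through the common ancestor)
.tree_path <- function(net, a, b) {
  pa <- .path_from_gateway(net, a)   # 0 ... a
  pb <- .path_from_gateway(net, b)
  common <- max(which(pa[seq_len(min(length(pa), length(pb)))] ==
                        pb[seq_len(min(length(pa), length(pb)))]))
  c(rev(pa[seq(common, length(pa))]), pb[-seq_len(common)])
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> mode", x$mode, "| channel", x$channel, "|",
      length(x$parent), "live node(s)",
      if (length(x$stranded)) paste("|", length(x$stranded), "stranded"),
      "\n")
  invisible(x)
}
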