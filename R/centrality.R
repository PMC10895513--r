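# Node-importance indices: strength / expected influence, their bridge
# (cross-community) variants, and top-proportion bridge flagging.

#' Strength or expected-influence centrality
#'
#' Strength is the absolute sum of the edge weights between one symptom and
#' all other symptoms; expected influence is the signed sum.
#'
#' @param net A `ggm_network`.
#' @param signed `FALSE` (default) for strength, `TRUE` for expected
#'   influence.
#' @return Named numeric vector, one value per node.
#' @export
node_centrality <- function(net, signed = FALSE) {
  stopifnot(inherits(net, "ggm_network"))
  w <- if (signed) net$weights else abs(net$weights)
  setNames(rowSums(w), net$labels)
}

#' Bridge strength or bridge expected influence
#'
#' Sum of (absolute or signed) edge weights from each node to all nodes in
#' communities other than its own.
#'
#' @param net A `ggm_network`.
#' @param communities Named community vector; defaults to the one stored in
#'   the network.
#' @param signed `FALSE` (default) for bridge strength, `TRUE` for bridge
#'   expected influence.
#' @return Named numeric vector.
#' @export
bridge_centrality <- function(net, communities = net$communities,
                              signed = FALSE) {
  stopifnot(inherits(net, "ggm_network"))
  if (is.null(communities) || !all(net$labels %in% names(communities)))
    stop("bridge_centrality: every node needs a community")
  comm <- communities[net$labels]
  w <- if (signed) net$weights else abs(net$weights)
  out <- vapply(seq_along(net$labels), function(i) {
    sum(w[i, comm != comm[i]])
  }, numeric(1))
  setNames(out, net$labels)
}

#' Flag the top-proportion scoring nodes as bridges
#'
#' Marks the `ceiling(top_prop * n)` highest-scoring nodes; ties at the cut
#' are broken by including all tied nodes.
#'
#' @param values Named numeric vector of centrality scores.
#' @param top_prop Fraction in (0, 1). Default 0.30.
#' @return Named logical vector.
#' @export
flag_bridges <- function(values, top_prop = 0.30) {
  if (top_prop <= 0 || top_prop >= 1)
    stop("flag_bridges: top_prop must lie in (0, 1)")
  k <- ceiling(top_prop * length(values))
  cut <- sort(values, decreasing = TRUE)[k]
  setNames(values >= cut, names(values))
}

#' Full centrality table with bridge flags
#'
#' Computes strength, expected influence, bridge strength and bridge
#' expected influence for every node, and flags the top-proportion bridge
#' nodes. Flagging is restricted to `bridge_communities` (by default the
#' two parent communities, so a child factor node never enters the
#' top-proportion denominator).
#'
#' @param net A `ggm_network` with communities.
#' @param top_prop Bridge flagging proportion. Default 0.30.
#' @param bridge_communities Communities eligible for flagging.
#' @return A `centrality_table` data.frame: node, community, strength,
#'   expected_influence, bridge_strength, bridge_expected_influence,
#'   is_bridge.
#' @export
centrality_table <- function(net, top_prop = 0.30,
                             bridge_communities = c("mother", "father")) {
  stopifnot(inherits(net, "ggm_network"))
  comm <- net$communities[net$labels]
  bs <- bridge_centrality(net, signed = FALSE)
  eligible <- comm %in% bridge_communities
  flags <- setNames(rep(FALSE, length(net$labels)), net$labels)
  if (any(eligible))
    flags[eligible] <- flag_bridges(bs[eligible], top_prop)
  out <- data.frame(node = net$labels,
                    community = unname(comm),
                    strength = unname(node_centrality(net, signed = FALSE)),
                    expected_influence = unname(node_centrality(net, signed = TRUE)),
                    bridge_strength = unname(bs),
                    bridge_expected_influence =
                      unname(bridge_centrality(net, signed = TRUE)),
                    is_bridge = unname(flags),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", class(out))
  out
}
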