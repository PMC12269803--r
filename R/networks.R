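#' Default cortical output-network definitions
#'
#' The four cortical networks used to profile prefrontal (ACA) projections:
#' prefrontal, lateral, central and medial. Members are mid-level Allen
#' acronyms; a leaf region counts toward a network if its own acronym or any
#' ancestor's acronym is in the member list (so SSp falls under SS, hence
#' central). Member lists are disjoint across networks.
#'
#' @return Named list of character vectors (network -> member acronyms).
#' @export
default_networks <- function() {
  list(
    prefrontal = c("FRP", "PL", "ILA", "ORB", "ACA", "MOs", "AId", "AIv"),
    lateral    = c("AIp", "GU", "VISC", "TEa", "PERI", "ECT", "ENT"),
    central    = c("MOp", "SS"),
    medial     = c("PTLp", "RSP", "VIS", "AUD")
  )
}

validate_networks <- function(networks) {
  stopifnot(is.list(networks), !is.null(names(networks)))
  all_members <- unlist(networks, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("network member lists must be disjoint; duplicated: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  networks
}

#' Restrict network definitions to the acronyms present in a tree
#'
#' Toy or partial ontologies rarely carry every member of the full network
#' definitions; this drops absent members explicitly (rather than silently
#' inside the profiling step, which treats unknown members as a configuration
#' error).
#'
#' @param networks named list of member acronym vectors.
#' @param tree a [structure_tree()].
#' @param drop_empty drop networks left with no members (default TRUE).
#' @return Pruned network list.
#' @export
prune_networks <- function(networks, tree, drop_empty = TRUE) {
  validate_networks(networks)
  out <- lapply(networks, function(m) intersect(m, tree$acronym))
  if (drop_empty) out <- out[vapply(out, length, 1L) > 0L]
  out
}

# leaf ids belonging to a network: leaf counts iff its acronym or any
# ancestor's acronym is a member
network_leaves <- function(tree, members) {
  unknown <- setdiff(members, tree$acronym)
  if (length(unknown) > 0L) {
    stop("network member(s) absent from tree: ", paste(unknown, collapse = ", "))
  }
  unique(unlist(lapply(members, function(a) tree_leaves(tree, a)),
                use.names = FALSE))
}
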