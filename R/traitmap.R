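#' Minimum-change (Fitch/Sankoff) reconstruction of a discrete character
#'
#' Computes the minimum number of state changes a discrete character
#' requires on a rooted cladogram under unit costs, by the Sankoff dynamic
#' program (exact on polytomies as well as binary nodes), together with
#' one optimal internal-state labeling and the set of equally parsimonious
#' root states. Leaves with state `nd` (or `NA`) carry no constraint.
#'
#' This is the machinery behind statements of the form "at least two
#' evolutionary changes in mating position are required" on the nannoptera
#' species-group cladogram.
#'
#' @param tree A rooted [ape::phylo] tree (see [read_cladogram()]);
#'   polytomies allowed.
#' @param states Named character vector or two-column data frame
#'   (`leaf`, `state`) mapping every leaf to one state symbol.
#' @param character_name Optional label stored with the result.
#' @return An object of class `parsimony_fit`: a list with
#'   `min_changes`, `labeling` (tibble: `node`, `label`, `state`, `is_leaf`),
#'   `root_states` (character vector of equally parsimonious root states),
#'   `character_name`, `tree`.
#' @export
#' @examples
#' tr <- read_cladogram("((nan,(aca,pac)),mac,bro,moj,buz);")
#' st <- c(nan = "tilted_right", pac = "upright_right", aca = "symmetric",
#'         mac = "symmetric", bro = "symmetric", moj = "symmetric",
#'         buz = "symmetric")
#' fitch_min_changes(tr, st)$min_changes
fitch_min_changes <- function(tree, states, character_name = NA_character_) {
  st <- as_state_map(states, tree)
  alphabet <- sort(unique(st[!is.na(st)]))
  if (!length(alphabet)) abort("all leaf states missing")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  # Sankoff costs: cost[v, s] = min changes in the subtree of v given
  # state s at v; missing leaves cost 0 for every state
  cost <- matrix(0, nrow = n_node, ncol = length(alphabet),
                 dimnames = list(NULL, alphabet))
  for (i in seq_len(n_tip)) {
    s <- st[tree$tip.label[i]]
    if (!is.na(s)) cost[i, ] <- ifelse(alphabet == s, 0, Inf)
  }
  edges <- tree$edge
  po <- rev(order_nodes_preorder(tree))  # children before parents
  for (v in po) {
    if (v <= n_tip) next
    kids <- edges[edges[, 1] == v, 2]
    for (ch in kids) {
      # child contribution under each parental state: stay or switch (+1)
      contrib <- pmin(cost[ch, ], min(cost[ch, ]) + 1)
      cost[v, ] <- cost[v, ] + contrib
    }
  }
  min_changes <- min(cost[root, ])
  root_states <- alphabet[cost[root, ] == min_changes]
  # witness labeling, top-down; ties resolved toward the parent state,
  # else first alphabetically, so the labeling is deterministic
  assign <- character(n_node)
  assign[root] <- root_states[1]
  for (v in order_nodes_preorder(tree)) {
    if (v == root) next
    parent_state <- assign[edges[edges[, 2] == v, 1]]
    opts <- cost[v, ] + (alphabet != parent_state)
    best <- alphabet[opts == min(opts)]
    assign[v] <- if (parent_state %in% best) parent_state else best[1]
  }
  labeling <- tibble(
    node = seq_len(n_node),
    label = c(tree$tip.label,
              tree$node.label %||% rep(NA_character_, tree$Nnode)),
    state = assign,
    is_leaf = seq_len(n_node) <= n_tip
  )
  structure(list(min_changes = as.integer(min_changes),
                 labeling = labeling,
                 root_states = root_states,
                 character_name = character_name,
                 tree = tree),
            class = "parsimony_fit")
}

# node ids in preorder (parents before children), root first
order_nodes_preorder <- function(tree) {
  edges <- tree$edge
  root <- length(tree$tip.label) + 1L
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(edges[edges[, 1] == v, 2]))
  }
  out
}

as_state_map <- function(states, tree) {
  if (is.data.frame(states)) {
    stopifnot(all(c("leaf", "state") %in% names(states)))
    st <- stats::setNames(as.character(states$state),
                          as.character(states$leaf))
  } else {
    st <- as.character(states)
    names(st) <- names(states)
  }
  if (is.null(names(st))) abort("states must be named by leaf label")
  extra <- setdiff(names(st), tree$tip.label)
  if (length(extra)) {
    abort(paste0("state(s) for unknown leaf label(s): ",
                 paste(extra, collapse = ", ")))
  }
  missing_leaves <- setdiff(tree$tip.label, names(st))
  if (length(missing_leaves)) {
    abort(paste0("leaf (leaves) without state: ",
                 paste(missing_leaves, collapse = ", ")))
  }
  st[st %in% c("nd", "ND")] <- NA_character_
  st[tree$tip.label]
}

#' Enumerate near-optimal ancestral-state scenarios
#'
#' Exhaustively lists all internal-node labelings whose change count is
#' within `max_extra` of the parsimony minimum, to support gain/loss
#' narratives (e.g. whether a right-sided mating posture arose twice
#' independently or arose once and was lost in one lineage). Leaves with
#' missing state are assigned, per scenario, the cost-free state equal to
#' their parent's. Restricted to small trees (<= 12 leaves) and alphabets;
#' larger inputs are rejected.
#'
#' @inheritParams fitch_min_changes
#' @param max_extra Non-negative integer: admit scenarios with up to this
#'   many changes above the minimum.
#' @return Tibble with one row per scenario: `scenario`, `changes`, and
#'   one column per internal node (`node<N>` by node id) holding its
#'   state.
#' @export
enumerate_scenarios <- function(tree, states, max_extra = 0L) {
  st <- as_state_map(states, tree)
  n_tip <- length(tree$tip.label)
  if (n_tip > 12L) abort("enumeration restricted to trees with <= 12 leaves")
  alphabet <- sort(unique(st[!is.na(st)]))
  n_int <- tree$Nnode
  if (length(alphabet)^n_int > 5e5) {
    abort("state space too large to enumerate (limit 5e5 labelings)")
  }
  fit <- fitch_min_changes(tree, states)
  grid <- expand.grid(rep(list(alphabet), n_int), stringsAsFactors = FALSE)
  internal_ids <- n_tip + seq_len(n_int)
  edges <- tree$edge
  costs <- apply(grid, 1, function(lab) {
    full <- unname(c(st[tree$tip.label], lab))
    scenario_cost(edges, full, n_tip)
  })
  keep <- costs <= fit$min_changes + max_extra
  out <- as_tibble(grid[keep, , drop = FALSE])
  names(out) <- paste0("node", internal_ids)
  out <- mutate(out, scenario = dplyr::row_number(),
                changes = as.integer(costs[keep]), .before = 1)
  arrange(out, .data$changes)
}

# changes implied on the tree by a full state vector (leaves then internal
# nodes, by node id); missing leaf states are free (match the parent)
scenario_cost <- function(edges, full_states, n_tip) {
  parent_state <- full_states[edges[, 1]]
  child_state <- full_states[edges[, 2]]
  free <- edges[, 2] <= n_tip & is.na(child_state)
  sum(parent_state != child_state & !free, na.rm = TRUE)
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat("Small-parsimony reconstruction",
      if (!is.na(x$character_name)) paste0(" of '", x$character_name, "'"),
      "\n", sep = "")
  cat("  leaves: ", length(x$tree$tip.label),
      "   minimum changes: ", x$min_changes, "\n", sep = "")
  cat("  equally parsimonious root state(s): ",
      paste(x$root_states, collapse = ", "), "\n", sep = "")
  invisible(x)
}
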