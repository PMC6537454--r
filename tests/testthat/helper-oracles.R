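# Independent oracles and generators used across test files.

# Brute-force small-parsimony oracle: minimum number of state changes over
# every possible assignment of observed states to internal nodes. Written
# from the definition (count mismatched edges), independent of the
# package's dynamic program.
brute_force_min_changes <- function(tree, states) {
  st <- states[tree$tip.label]
  alphabet <- sort(unique(st[!is.na(st)]))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  combos <- expand.grid(rep(list(alphabet), n_int),
                        stringsAsFactors = FALSE)
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    full <- c(st, unlist(combos[i, ], use.names = FALSE))
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- full[tree$edge[e, 1]]
      b <- full[tree$edge[e, 2]]
      if (!is.na(b) && a != b) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# random rooted tree over given leaf names, with random polytomies,
# emitted as newick text
random_tree_newick <- function(leaves) {
  build <- function(lv) {
    if (length(lv) == 1) return(lv)
    k <- sample(2:min(3, length(lv)), 1)
    cuts <- sort(sample(seq_len(length(lv) - 1), k - 1))
    parts <- split(lv, cumsum(seq_along(lv) %in% (cuts + 1)))
    paste0("(", paste(vapply(parts, build, character(1)), collapse = ","),
           ")")
  }
  paste0(build(sample(leaves)), ";")
}

# random planar similarity pose (rotation/translation/positive scale)
random_similarity <- function() {
  phi <- runif(1, 0, 2 * pi)
  s <- runif(1, 0.2, 5)
  t <- complex(real = runif(1, -500, 500), imaginary = runif(1, -500, 500))
  function(p) {
    z <- s * exp(1i * phi) * complex(real = p[1], imaginary = p[2]) + t
    c(Re(z), Im(z))
  }
}

fig4_tree <- function() {
  read_cladogram(system.file("extdata", "cladogram.nwk",
                             package = "matingasym"))
}

fig4_characters <- function() {
  read_characters(system.file("extdata", "characters.csv",
                              package = "matingasym"))
}

mating_position_states <- function() {
  ch <- fig4_characters()
  st <- ch[ch$character == "mating_position", ]
  stats::setNames(st$state, st$leaf)
}
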