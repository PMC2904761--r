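# Synthetic annotated pathways: scale-free-ish sparse graphs with
# localization tags, plus the default compartment scene and admissible
# random starting layouts.

#' Default localization mix
#'
#' Proportions emulating curated signalling pathways: most species in the
#' cytoplasm, a substantial membrane and nuclear contingent, a few
#' extracellular ligands and mitochondrial species.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_localization_mix <- function() {
  c(extracellular = 0.05, plasma_membrane = 0.15, cytoplasm = 0.50,
    nucleus = 0.20, mitochondria = 0.10)
}

#' Generate a synthetic annotated pathway
#'
#' Builds a connected sparse graph by preferential attachment (each new node
#' attaches to an existing node with probability proportional to degree + 1,
#' giving the heavy-tailed degree distribution typical of biological
#' networks), then adds uniform random extra edges up to `n_edges`.
#' Localization tags are sampled from `localization_mix`. Node ids are
#' zero-padded (`n001`, `n002`, ...) so lexicographic and numeric order
#' agree.
#'
#' @param n_nodes,n_edges node and edge counts; `n_edges >= n_nodes - 1`.
#' @param localization_mix named probabilities over tags; must sum to 1.
#' @param seed RNG seed.
#' @return A [pathway_graph()].
#' @export
generate_pathway <- function(n_nodes, n_edges,
                             localization_mix = default_localization_mix(),
                             seed = NULL) {
  if (abs(sum(localization_mix) - 1) > 1e-8)
    stop("localization_mix must sum to 1")
  if (n_edges < n_nodes - 1)
    stop("need at least n_nodes - 1 edges for a connected pathway")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%0*d", nchar(n_nodes), seq_len(n_nodes))
  deg <- rep(0L, n_nodes)
  from <- integer(0); to <- integer(0)
  for (i in 2:n_nodes) {
    j <- sample.int(i - 1, 1, prob = deg[seq_len(i - 1)] + 1)
    from <- c(from, j); to <- c(to, i)
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  key <- paste(pmin(from, to), pmax(from, to))
  while (length(from) < n_edges) {
    cand <- sample.int(n_nodes, 2)
    k <- paste(min(cand), max(cand))
    if (k %in% key) next
    from <- c(from, cand[1]); to <- c(to, cand[2]); key <- c(key, k)
  }
  tags <- sample(names(localization_mix), n_nodes, replace = TRUE,
                 prob = localization_mix)
  pathway_graph(
    nodes = data.frame(id = ids, label = ids, localization = tags),
    edges = cbind(ids[from], ids[to]))
}

#' Default compartment scene
#'
#' The bundled cell geometry: an extracellular margin around a rectangular
#' cell whose plasma membrane is a one-unit-wide rectangular ring (a torus
#' region), a cytoplasm filling the cell interior with the organelles carved
#' out, and movable nucleus and mitochondria ovals. Compartments are nested
#' via `within`, so the no-overlap rule applies between the two organelles.
#'
#' @param grid a [layout_grid()].
#' @return List of [compartment()]s.
#' @export
default_compartments <- function(grid) {
  H <- grid$h - 1; W <- grid$w - 1
  ctr <- c(H / 2, W / 2)
  m <- max(2, round(0.12 * min(H, W)))
  cell <- c(H - 2 * m, W - 2 * m)
  list(
    compartment("extracellular", "rectangle", center = ctr, size = c(H, W),
                exclude = c("plasma_membrane", "cytoplasm_full")),
    compartment("plasma_membrane", "annulus", center = ctr, size = cell,
                inner_size = cell - 2, within = "extracellular"),
    # helper region: full cell interior, used only for exclusion
    compartment("cytoplasm_full", "rectangle", center = ctr, size = cell,
                tags = character(0), within = "extracellular"),
    compartment("cytoplasm", "rectangle", center = ctr, size = cell - 2,
                exclude = c("nucleus", "mitochondria"),
                within = "plasma_membrane"),
    compartment("nucleus", "oval", center = c(H * 0.5, W * 0.33),
                size = c(0.34 * H, 0.30 * W), movable = TRUE,
                within = "cytoplasm"),
    compartment("mitochondria", "oval", center = c(H * 0.30, W * 0.72),
                size = c(0.22 * H, 0.20 * W), movable = TRUE,
                within = "cytoplasm"))
}

#' Random admissible layout
#'
#' Assigns nodes, in random order, to grid points drawn uniformly from the
#' vacant admissible region of each node's localization tag. Restarts on
#' dead ends; errors if a tag's region is smaller than its node count.
#'
#' @param graph a [pathway_graph()].
#' @param grid a [layout_grid()].
#' @param constraints a [build_constraints()] result.
#' @param seed RNG seed; the same seed always yields the same layout.
#' @param max_restarts dead-end retries before giving up.
#' @return A [grid_layout()].
#' @export
random_layout <- function(graph, grid, constraints, seed = NULL,
                          max_restarts = 20) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(graph)
  for (tag in unique(graph$nodes$localization)) {
    need <- sum(graph$nodes$localization == tag)
    have <- length(constraints$admissible[[tag]])
    if (have < need)
      stop(sprintf("region '%s' has %d points for %d nodes",
                   tag, have, need))
  }
  for (attempt in seq_len(max_restarts)) {
    ord <- sample.int(n)
    taken <- rep(FALSE, grid$h * grid$w)
    idx <- integer(n)
    ok <- TRUE
    for (i in ord) {
      pts <- constraints$admissible[[graph$nodes$localization[i]]]
      pts <- pts[!taken[pts]]
      if (!length(pts)) { ok <- FALSE; break }
      p <- if (length(pts) == 1) pts else pts[sample.int(length(pts), 1)]
      idx[i] <- p
      taken[p] <- TRUE
    }
    if (ok) {
      pts <- index_point(idx, grid)
      rownames(pts) <- graph$nodes$id
      return(grid_layout(pts, grid))
    }
  }
  stop("could not place all nodes after ", max_restarts, " restarts")
}
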