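# Replicated layout experiments: grid vs grid without constraints vs
# dynamic-compartment mode vs the spring baseline.

run_one <- function(mode, graph, grid, compartments, params, seed,
                    max_steps, spring_iters) {
  t0 <- proc.time()[["elapsed"]]
  if (mode == "spring") {
    lay <- spring_run(graph, grid, iters = spring_iters, seed = seed)
    cr <- count_all_crossings(graph, lay)
    bk <- list(total = NA_real_)
    steps <- spring_iters
  } else {
    cons <- if (mode == "grid-nl") build_constraints(NULL, grid, graph)
            else build_constraints(compartments, grid, graph)
    if (mode == "gdc") {
      fit <- gdc_layout(graph, grid, compartments, params, seed = seed)
    } else {
      fit <- optimize_layout(graph, grid, cons, params, seed = seed,
                             max_steps = max_steps)
    }
    cr <- count_all_crossings(graph, fit$layout)
    bk <- fit$cost
    steps <- fit$steps
  }
  data.frame(mode = mode, seed = seed, total = as.numeric(bk$total),
             ee = unname(cr["ee"]), ne = unname(cr["ne"]), steps = steps,
             seconds = proc.time()[["elapsed"]] - t0)
}

#' Run a replicated layout experiment
#'
#' For each requested mode, generates `replicates` random starting layouts
#' (seeds `seed`, `seed + 1`, ...) and records per-replicate total cost and
#' crossing counts, plus box-plot summary statistics (quartiles) per mode.
#' Modes: `"grid"` (constrained grid layout), `"grid-nl"` (no localization
#' constraints), `"gdc"` (dynamic compartments), `"spring"` (continuous
#' baseline; crossings measured on the continuous segments).
#'
#' @param graph a [pathway_graph()].
#' @param grid a [layout_grid()]; default from [grid_dims()].
#' @param compartments compartment list; default [default_compartments()].
#' @param params a [cost_params()].
#' @param modes subset of `c("grid", "grid-nl", "gdc", "spring")`.
#' @param replicates random restarts per mode (default 10).
#' @param seed base seed.
#' @param max_steps accepted-move cap per grid run.
#' @param spring_iters spring-baseline iterations.
#' @return List of class `pathgrid_experiment`: `results` (one row per run)
#'   and `summary` (quartiles of ee, ne, total per mode).
#' @export
run_experiment <- function(graph, grid = NULL, compartments = NULL,
                           params = cost_params(),
                           modes = c("grid", "grid-nl", "spring"),
                           replicates = 10, seed = 1,
                           max_steps = 10 * n_nodes(graph),
                           spring_iters = 300) {
  ok <- c("grid", "grid-nl", "gdc", "spring")
  if (!all(modes %in% ok))
    stop("unknown mode(s): ", paste(setdiff(modes, ok), collapse = ", "))
  if (is.null(grid)) grid <- grid_dims(n_nodes(graph))
  if (is.null(compartments) && any(modes != "grid-nl"))
    compartments <- default_compartments(grid)
  rows <- list()
  for (mode in modes)
    for (rep_i in seq_len(replicates))
      rows[[length(rows) + 1]] <-
        run_one(mode, graph, grid, compartments, params,
                seed = seed + rep_i - 1, max_steps = max_steps,
                spring_iters = spring_iters)
  results <- do.call(rbind, rows)
  qs <- function(x) {
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), na.rm = TRUE)
    names(q) <- c("min", "q1", "median", "q3", "max")
    q
  }
  summ <- do.call(rbind, lapply(split(results, results$mode), function(d)
    data.frame(mode = d$mode[1],
               metric = c("ee", "ne", "total"),
               rbind(qs(d$ee), qs(d$ne), qs(d$total)))))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ),
            class = "pathgrid_experiment")
}

#' @export
print.pathgrid_experiment <- function(x, ...) {
  cat("<pathgrid_experiment>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
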