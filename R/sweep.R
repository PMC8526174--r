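# Sweep drivers: SC/FC correlations of both classes as a function of a
# control axis (topology randomization, coupling strength, or an intrinsic
# parameter of the dynamics), averaged over graph seeds or runs with the
# aggregation convention of each dynamics class.

#' Specify an SC/FC sweep
#'
#' @param dynamics one of `"ser"`, `"kuramoto"`, `"logistic"`, `"fhn"`.
#' @param graph either an adjacency matrix (fixed substrate) or a list with a
#'   `model` field: `"modular"` (fields `n_cliques`, `clique_size`,
#'   `rewire_p`), `"erdos_renyi"`/`"barabasi_albert"`/`"watts_strogatz"`
#'   (fields `n`, `param`), `"hierarchical"` (field `levels`), or `"file"`
#'   (field `path`).
#' @param axis `"randomization"` (grid = randomization levels),
#'   `"coupling"` (grid = coupling strengths k; Kuramoto/logistic only), or
#'   `"intrinsic"` (grid = recovery probability p for SER, natural-frequency
#'   interval width for Kuramoto, R-interval midpoint for logistic maps).
#' @param grid ordered numeric vector of axis values.
#' @param grid_unit for the randomization axis: `"fraction"` (of
#'   `swaps_full`; the benchmark convention maps 10% to 50 swaps on the
#'   60-node substrates and 20 on the hierarchical graph) or `"swaps"`
#'   (absolute counts).
#' @param n_graph_seeds independent initial graphs per grid point.
#' @param params dynamics parameter object (`ser_params()` etc.); defaults to
#'   the model's benchmark configuration.
#' @param master_seed integer seed; every random stage derives a child seed
#'   from it via [derive_seed()], so sweeps are fully reproducible.
#' @param swaps_full swap/rewire count corresponding to 100% randomization
#'   (default 200 for the hierarchical substrate, 500 otherwise).
#' @param randomize_method `"swap"` (degree-preserving double-edge swaps) or
#'   `"rewire"` (one-endpoint rewiring; default for the ring lattice).
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(dynamics = c("ser", "kuramoto", "logistic", "fhn"),
                       graph = list(model = "modular"),
                       axis = c("randomization", "coupling", "intrinsic"),
                       grid, grid_unit = c("fraction", "swaps"),
                       n_graph_seeds = 10, params = NULL, master_seed = 1,
                       swaps_full = NULL, randomize_method = NULL) {
  dynamics <- match.arg(dynamics)
  axis <- match.arg(axis)
  grid_unit <- match.arg(grid_unit)
  if (length(grid) == 0 || is.unsorted(grid) && is.unsorted(rev(grid))) {
    stop("grid must be non-empty and monotone", call. = FALSE)
  }
  if (axis == "coupling" && dynamics %in% c("ser")) {
    stop("the SER model has no coupling parameter", call. = FALSE)
  }
  model <- if (is.matrix(graph)) "matrix" else graph$model
  if (is.null(swaps_full)) {
    swaps_full <- if (identical(model, "hierarchical")) 200L else 500L
  }
  if (is.null(randomize_method)) {
    randomize_method <- if (identical(model, "watts_strogatz")) "rewire" else "swap"
  }
  if (is.null(params)) {
    params <- switch(dynamics, ser = ser_params(), kuramoto = kuramoto_params(),
                     logistic = logistic_params(), fhn = fhn_params())
  }
  structure(list(dynamics = dynamics, graph = graph, axis = axis,
                 grid = as.numeric(grid), grid_unit = grid_unit,
                 n_graph_seeds = as.integer(n_graph_seeds), params = params,
                 master_seed = as.integer(master_seed),
                 swaps_full = as.integer(swaps_full),
                 randomize_method = match.arg(randomize_method,
                                              c("swap", "rewire"))),
            class = "sweep_spec")
}

build_base_graph <- function(graph, seed) {
  if (is.matrix(graph)) return(as_adjacency(graph))
  switch(graph$model,
    modular = make_modular(graph$n_cliques %||% 4, graph$clique_size %||% 15,
                           graph$rewire_p %||% 0.23, seed = seed,
                           connected = TRUE),
    erdos_renyi = ,
    barabasi_albert = ,
    watts_strogatz = make_standard(graph$model, graph$n %||% 60,
                                   graph$param, seed = seed,
                                   connected = graph$model != "watts_strogatz"),
    hierarchical = make_hierarchical(graph$levels %||% 3),
    file = read_graph_file(graph$path),
    stop("unknown graph model '", graph$model, "'", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# set the axis value on a copy of the dynamics params
apply_axis <- function(spec, value) {
  p <- spec$params
  if (spec$axis == "coupling") {
    p$k <- value
  } else if (spec$axis == "intrinsic") {
    if (spec$dynamics == "ser") {
      p$p <- value
    } else if (spec$dynamics == "kuramoto") {
      # widen the natural-frequency interval symmetrically about its midpoint
      mid <- mean(p$omega_range)
      p$omega_range <- c(mid - value / 2, mid + value / 2)
    } else if (spec$dynamics == "logistic") {
      # shift the R interval midpoint, holding width 0.2
      p$r_range <- c(value - 0.1, value + 0.1)
    } else {
      stop("no intrinsic axis defined for ", spec$dynamics, call. = FALSE)
    }
  }
  p
}

#' Run an SC/FC sweep
#'
#' For every grid point and every graph seed the substrate is (re)built,
#' randomized if the axis asks for it, the dynamics ensemble is run, and the
#' SC/FC correlation of both FC classes is computed. SER and Kuramoto
#' aggregate FC over runs and report mean and sd of the per-graph-seed
#' coefficients; logistic maps and FitzHugh-Nagumo compute the coefficient
#' per run and report mean and sd across the pooled runs. An infeasible grid
#' point is recorded as a missing row with a diagnostic and the sweep
#' continues. Output is deterministic given `master_seed`.
#'
#' @param spec a [sweep_spec()].
#' @return a data frame of class `scfc_sweep` with one row per grid point:
#'   `axis_value`, `mean_r_sim`, `sd_r_sim`, `mean_r_seq`, `sd_r_seq`, `n`
#'   (coefficients aggregated), `diagnostics`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$grid))
  for (gi in seq_along(spec$grid)) {
    value <- spec$grid[gi]
    rows[[gi]] <- tryCatch(
      sweep_grid_point(spec, gi, value),
      error = function(e) {
        data.frame(axis_value = value, mean_r_sim = NA_real_,
                   sd_r_sim = NA_real_, mean_r_seq = NA_real_,
                   sd_r_seq = NA_real_, n = 0L,
                   diagnostics = conditionMessage(e),
                   stringsAsFactors = FALSE)
      }
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("scfc_sweep", "data.frame")
  out
}

sweep_grid_point <- function(spec, gi, value) {
  params <- apply_axis(spec, value)
  per_graph <- spec$dynamics %in% c("ser", "kuramoto")
  r_sim <- numeric(0)
  r_seq <- numeric(0)
  notes <- character(0)
  for (si in seq_len(spec$n_graph_seeds)) {
    gseed <- derive_seed(spec$master_seed, gi, si, 1)
    A <- build_base_graph(spec$graph, gseed)
    if (spec$axis == "randomization") {
      n_changes <- if (spec$grid_unit == "fraction") {
        as.integer(round(value * spec$swaps_full))
      } else as.integer(round(value))
      rseed <- derive_seed(spec$master_seed, gi, si, 2)
      if (n_changes > 0) {
        A <- if (spec$randomize_method == "swap") {
          randomize_degree_preserving(A, n_changes, seed = rseed)
        } else {
          rewire_one_endpoint(A, n_changes, seed = rseed)
        }
      }
    }
    dseed <- derive_seed(spec$master_seed, gi, si, 3)
    if (spec$dynamics == "ser") {
      fc <- ser_ensemble_fc(A, params, seed = dseed)
      s1 <- scfc_correlation(A, fc$sim)
      s2 <- scfc_correlation(A, fc$seq)
      r_sim <- c(r_sim, s1$r); r_seq <- c(r_seq, s2$r)
      if (s1$status != "ok" || s2$status != "ok") notes <- c(notes, "degenerate FC")
    } else if (spec$dynamics == "kuramoto") {
      fc <- kuramoto_ensemble_fc(A, params, seed = dseed)
      s1 <- scfc_correlation(A, fc$sim)
      s2 <- scfc_correlation(A, fc$seq)
      r_sim <- c(r_sim, s1$r); r_seq <- c(r_seq, s2$r)
      if (any(fc$n_missing > 0)) {
        notes <- c(notes, sprintf("missing FC entries (sim %d, seq %d)",
                                  fc$n_missing[["sim"]], fc$n_missing[["seq"]]))
      }
      if (s1$status != "ok" || s2$status != "ok") notes <- c(notes, "degenerate FC")
    } else if (spec$dynamics == "logistic") {
      res <- logistic_ensemble_scfc(A, params, seed = dseed)
      r_sim <- c(r_sim, res$r_sim); r_seq <- c(r_seq, res$r_seq)
    } else { # fhn
      for (run in seq_len(params$n_runs)) {
        traces <- fhn_simulate(A, params,
                               seed = derive_seed(spec$master_seed, gi, si, 3, run))
        fc <- fhn_fc_pair(traces, params)
        r_sim <- c(r_sim, scfc_correlation(A, fc$sim)$r)
        r_seq <- c(r_seq, scfc_correlation(A, fc$seq)$r)
      }
    }
  }
  n_agg <- if (per_graph) spec$n_graph_seeds else length(r_sim)
  data.frame(axis_value = value,
             mean_r_sim = mean(r_sim, na.rm = TRUE), sd_r_sim = sd0(r_sim),
             mean_r_seq = mean(r_seq, na.rm = TRUE), sd_r_seq = sd0(r_seq),
             n = as.integer(n_agg),
             diagnostics = paste(unique(notes), collapse = "; "),
             stringsAsFactors = FALSE)
}

#' @export
print.scfc_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("SC/FC sweep:", spec$dynamics, "dynamics,", spec$axis, "axis,",
      nrow(x), "grid points\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
summary.scfc_sweep <- function(object, ...) {
  spec <- attr(object, "spec")
  cat("SC/FC sweep summary\n")
  cat("  dynamics:   ", spec$dynamics, "\n")
  cat("  axis:       ", spec$axis, " (", length(spec$grid), " grid points)\n",
      sep = "")
  cat("  graph seeds:", spec$n_graph_seeds, "\n")
  ok <- !is.na(object$mean_r_sim)
  cat(sprintf("  r_sim range: [%.3f, %.3f]   r_seq range: [%.3f, %.3f]\n",
              min(object$mean_r_sim[ok]), max(object$mean_r_sim[ok]),
              min(object$mean_r_seq[ok]), max(object$mean_r_seq[ok])))
  bad <- which(!ok)
  if (length(bad)) cat("  missing rows:", paste(bad, collapse = ", "), "\n")
  invisible(object)
}

#' Plot an SC/FC sweep
#'
#' Two curves (co-activation and sequential activation) with +-1 sd error
#' bars against the swept axis, mirroring the standard panel layout of
#' SC/FC randomization and parameter-sweep figures.
#'
#' @param x a `scfc_sweep` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scfc_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  ok <- !is.na(x$mean_r_sim) | !is.na(x$mean_r_seq)
  d <- x[ok, , drop = FALSE]
  ylim <- range(c(d$mean_r_sim - d$sd_r_sim, d$mean_r_sim + d$sd_r_sim,
                  d$mean_r_seq - d$sd_r_seq, d$mean_r_seq + d$sd_r_seq),
                na.rm = TRUE)
  graphics::plot(d$axis_value, d$mean_r_sim, type = "b", pch = 16,
                 col = "#2166ac", ylim = ylim,
                 xlab = switch(spec$axis,
                               randomization = "randomization level",
                               coupling = "coupling strength k",
                               intrinsic = "intrinsic parameter"),
                 ylab = "SC/FC correlation", ...)
  graphics::lines(d$axis_value, d$mean_r_seq, type = "b", pch = 17,
                  col = "#b2182b")
  err <- function(xv, m, s, col) {
    use <- !is.na(m) & s > 0
    if (any(use)) {
      graphics::arrows(xv[use], (m - s)[use], xv[use], (m + s)[use],
                       angle = 90, code = 3, length = 0.03, col = col)
    }
  }
  err(d$axis_value, d$mean_r_sim, d$sd_r_sim, "#2166ac")
  err(d$axis_value, d$mean_r_seq, d$sd_r_seq, "#b2182b")
  graphics::abline(h = 0, lty = 3, col = "grey50")
  graphics::legend("topright", legend = c("SC/FCsim", "SC/FCseq"),
                   col = c("#2166ac", "#b2182b"), pch = c(16, 17), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Write sweep results as tidy CSV (and optionally a figure)
#'
#' The CSV has one row per grid point per FC class with columns
#' `axis_value, fc_class, mean_r, sd_r, n, diagnostics`; rewriting the same
#' result produces a byte-identical file. When `plot = TRUE` a PNG figure
#' with both curves and error bars is written next to it.
#'
#' @param result a `scfc_sweep` object.
#' @param out_prefix output path prefix; writes `<prefix>.csv` (and
#'   `<prefix>.png`).
#' @param plot also write the figure.
#' @return invisibly, the paths written.
#' @export
sweep_report <- function(result, out_prefix, plot = FALSE) {
  stopifnot(inherits(result, "scfc_sweep"), nrow(result) > 0)
  tidy <- rbind(
    data.frame(axis_value = result$axis_value, fc_class = "sim",
               mean_r = result$mean_r_sim, sd_r = result$sd_r_sim,
               n = result$n, diagnostics = result$diagnostics,
               stringsAsFactors = FALSE),
    data.frame(axis_value = result$axis_value, fc_class = "seq",
               mean_r = result$mean_r_seq, sd_r = result$sd_r_seq,
               n = result$n, diagnostics = result$diagnostics,
               stringsAsFactors = FALSE)
  )
  tidy <- tidy[order(tidy$axis_value, tidy$fc_class), , drop = FALSE]
  csv <- paste0(out_prefix, ".csv")
  utils::write.table(tidy, csv, sep = ",", row.names = FALSE, quote = TRUE)
  paths <- csv
  if (plot) {
    png_path <- paste0(out_prefix, ".png")
    grDevices::png(png_path, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(result)
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
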