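#' Full topophysical analysis of a network and its rewired baselines
#'
#' Runs the complete analysis -- recursive-partition topological Rent
#' exponent and dimension, box-sampled physical Rent exponent, and wiring
#' statistics -- on the observed network, on `n_random` uniformly rewired
#' variants (node positions fixed; their estimates are averaged), and on the
#' minimally rewired variant. Per-stage seeds are derived deterministically
#' from the master seed by hashing the stage name, so any stage can be rerun
#' independently and the whole report is reproducible bit for bit.
#'
#' @param net a [spatial_network()].
#' @param seed master integer seed.
#' @param n_random number of random instantiations to average (default 10).
#' @param n_boxes boxes for the physical fit (default 5000).
#' @param restarts,exclude_top,min_partition_size partitioning and fitting
#'   controls (see [recursive_partition()], [fit_topological_rent()]).
#' @return object of class `topophys_report`: a list with one entry per
#'   variant (`observed`, `random`, `minimal`), each holding `N`, `density`,
#'   `D_E`, `p_T` with CI, `D_T` with CI, `p` with CI, `L_bar`,
#'   `mean_edge_length` and `kappa` (NA where `D_T <= D_E`), plus `seed`
#'   and `config`. The `random` entry aggregates the instantiations as
#'   mean and standard deviation.
#' @export
run_full_analysis <- function(net, seed = 1, n_random = 10, n_boxes = 5000,
                              restarts = 10, exclude_top = 2,
                              min_partition_size = 2) {
  analyse <- function(x, stage) {
    out <- list(N = n_nodes(x), m = n_edges(x),
                density = connection_density(x), D_E = x$D_E)
    res <- tryCatch({
      pl <- recursive_partition(x, min_partition_size = min_partition_size,
                                restarts = restarts,
                                seed = stage_seed(seed, paste0(stage, "_topo")))
      ft <- fit_topological_rent(pl, exclude_top = exclude_top)
      # p_T >= 1 (possible on dense unstructured rewirings) has no finite
      # dimension; report NA rather than abort the variant
      dt <- if (ft$exponent < 1) topological_dimension(ft) else
        c(D_T = NA_real_, lo = NA_real_, hi = NA_real_)
      bx <- sample_boxes(x, n_boxes = n_boxes,
                         seed = stage_seed(seed, paste0(stage, "_phys")))
      fp <- fit_physical_rent(bx, n_nodes(x))
      wr <- wiring_report(x, D_T = dt[["D_T"]])
      list(p_T = ft$exponent, p_T_ci = ft$ci95,
           D_T = dt[["D_T"]], D_T_ci = unname(dt[c("lo", "hi")]),
           p = fp$exponent, p_ci = fp$ci95,
           delta = wr$delta, L_bar = wr$L_bar,
           mean_edge_length = wr$mean_edge_length, kappa = wr$kappa)
    }, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    c(out, res)
  }

  report <- list(observed = analyse(net, "observed"))

  rand_runs <- lapply(seq_len(n_random), function(i) {
    analyse(rewire_random(net, seed = stage_seed(seed, paste0("random", i))),
            paste0("random", i))
  })
  num <- c("density", "p_T", "D_T", "p", "delta", "L_bar",
           "mean_edge_length", "kappa")
  agg <- list(N = n_nodes(net), m = n_edges(net), D_E = net$D_E,
              n_instantiations = n_random)
  for (f in num) {
    vals <- vapply(rand_runs, function(r) r[[f]], 0)
    agg[[f]] <- mean(vals, na.rm = TRUE)
    agg[[paste0(f, "_sd")]] <- stats::sd(vals, na.rm = TRUE)
  }
  report$random <- agg
  report$minimal <- analyse(rewire_minimal(net), "minimal")

  report$seed <- seed
  report$config <- list(n_random = n_random, n_boxes = n_boxes,
                        restarts = restarts, exclude_top = exclude_top,
                        min_partition_size = min_partition_size)
  class(report) <- "topophys_report"
  report
}

#' Deterministic per-stage seed from a master seed
#'
#' Hashes the stage name onto the master seed so that every pipeline stage
#' has its own reproducible stream below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147480009
  as.integer((h + as.numeric(seed)) %% 2147480009)
}

#' @export
print.topophys_report <- function(x, ...) {
  row <- function(nm, v) {
    kap <- if (is.na(v$kappa)) "N/A" else sprintf("%.3g", v$kappa)
    cat(sprintf("%-10s N=%4d dens=%.3g  p_T=%.3f  D_T=%.3g  p=%.3f  L=%.4g  kappa=%s\n",
                nm, v$N, v$density, v$p_T, v$D_T, v$p, v$L_bar, kap))
  }
  cat("Topophysical analysis report\n")
  row("observed", x$observed)
  row("random", x$random)
  row("minimal", x$minimal)
  cat(sprintf("(random row: mean over %d instantiations; seed %d)\n",
              x$random$n_instantiations, x$seed))
  invisible(x)
}

#' Write a report as JSON
#'
#' @param report a `topophys_report`.
#' @param path output path.
#' @return the report, invisibly.
#' @export
write_report_json <- function(report, path) {
  doc <- unclass(report)
  doc$schema <- "netrent/report/v1"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
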