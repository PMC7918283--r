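# Parameter-scan driver: run the protocol over one scanned axis with
# replicates, extract networks, and tabulate per-replicate and aggregate
# metrics.

#' Run a one-axis parameter scan
#'
#' Executes the full melt-cool protocol for every value of one scanned
#' parameter times `replicates` seeds, extracts the network and its metrics
#' from each final snapshot, and returns tidy per-replicate rows plus
#' per-value aggregates. Only one parameter is varied per scan; all other
#' parameters stay at the configured values.
#'
#' Replicate seeds are `base_seed + 0 ... replicates - 1`, identical across
#' scan values. With an `out_dir` the scan is resumable: each completed
#' (value, replicate) cell is written as a small CSV and skipped on re-run.
#' A replicate whose network violates the polygon-assignment precondition is
#' logged and marked (`ok = FALSE`), and the scan continues; its
#' non-polygon metrics (mean_k, mu2_k) are still reported.
#'
#' @param config base [run_config()]
#' @param axis one of "kl", "k_theta", "tcool", "p", "eps_hh", "f_tangle"
#'   ("f_tangle" varies `f_b`, or `f_c` when `tangle_template = "tangle_c"`)
#' @param values numeric vector of scanned values (user units: N/m, J, us,
#'   Pa, or a fraction)
#' @param replicates runs per value
#' @param out_dir optional directory for resumable per-cell CSVs and the
#'   tidy/aggregate outputs
#' @param rc head-clustering cutoff for extraction (nm)
#' @param tangle_template which template `f_tangle` substitutes
#' @return list with `per_run` (tibble, one row per value x replicate) and
#'   `aggregate` (one row per value: means and standard deviations)
#' @export
run_scan <- function(config, axis = c("kl", "k_theta", "tcool", "p",
                                      "eps_hh", "f_tangle"),
                     values, replicates = 10, out_dir = NULL, rc = 75,
                     tangle_template = c("tangle_b", "tangle_c")) {
  axis <- match.arg(axis)
  tangle_template <- match.arg(tangle_template)
  stopifnot(inherits(config, "cw_config"), length(values) >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  cell_path <- function(iv, rep)
    file.path(out_dir, sprintf("scan_%s_v%02d_r%02d.csv", axis, iv, rep))

  one_run <- function(iv, rep) {
    cfg <- config
    value <- values[iv]
    pp <- cfg$params
    switch(axis,
           kl = { pp$kl <- value },
           k_theta = { pp$k_theta <- value },
           eps_hh = { pp$eps_hh <- value },
           tcool = { cfg$t_cool <- value },
           p = { cfg$sim$p_target <- value },
           f_tangle = if (tangle_template == "tangle_b")
             cfg$f_b <- value else cfg$f_c <- value)
    cfg$params <- pp
    if (axis == "kl") { # keep the timestep resolving the stiffest bond
      cfg$sim <- sim_params(m = cfg$sim$m, kl = value,
                            tau_p = cfg$sim$tau_p,
                            p_target = cfg$sim$p_target, lz0 = cfg$sim$lz0,
                            scale_clamp = cfg$sim$scale_clamp,
                            max_disp = cfg$sim$max_disp)
    }
    cfg$seed <- config$seed + rep - 1
    traj <- run_protocol(cfg)
    net <- build_network(traj$final, rc = rc)
    pol <- tryCatch(delaunay_polygons(net), error = function(e) e)
    ok <- !inherits(pol, "error")
    m <- if (ok) network_metrics(net, pol) else {
      cs <- coordination_stats(net)
      ea <- edge_and_area_stats(net)
      tibble::tibble(Npolygon = NA_integer_, mean_n = NA_real_,
                     mean_k = cs$mean_k, mu2_k = cs$mu2_k,
                     assortativity = NA_real_, mean_SRC = NA_real_,
                     sd_SRC = NA_real_, mean_l_nm = ea$mean_l,
                     sd_l_nm = ea$sd_l, mean_area_nm2 = NA_real_,
                     dangling_pct = NA_real_)
    }
    dplyr::bind_cols(
      tibble::tibble(axis = axis, value = value, replicate = rep,
                     seed = cfg$seed, ok = ok), m)
  }

  rows <- list()
  for (iv in seq_along(values)) {
    for (rep in seq_len(replicates)) {
      if (!is.null(out_dir) && file.exists(cell_path(iv, rep))) {
        rows[[length(rows) + 1]] <-
          readr::read_csv(cell_path(iv, rep), show_col_types = FALSE)
        next
      }
      row <- one_run(iv, rep)
      if (!row$ok)
        message("scan cell value=", values[iv], " replicate=", rep,
                ": polygon assignment unavailable (marked, scan continues)")
      if (!is.null(out_dir)) readr::write_csv(row, cell_path(iv, rep))
      rows[[length(rows) + 1]] <- row
    }
  }
  per_run <- dplyr::bind_rows(rows)
  aggregate <- per_run |>
    dplyr::group_by(.data$axis, .data$value) |>
    dplyr::summarise(
      n_ok = sum(.data$ok),
      dplyr::across(c("Npolygon", "mean_n", "mean_k", "mu2_k",
                      "assortativity", "mean_SRC", "mean_l_nm",
                      "mean_area_nm2", "dangling_pct"),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
  if (!is.null(out_dir)) {
    readr::write_csv(per_run, file.path(out_dir,
                                        sprintf("scan_%s_tidy.csv", axis)))
    readr::write_csv(aggregate, file.path(out_dir,
                                          sprintf("scan_%s_aggregate.csv",
                                                  axis)))
  }
  list(per_run = per_run, aggregate = aggregate)
}
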