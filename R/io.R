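# File formats: LAMMPS-style text dumps for bead snapshots, node/edge CSV
# pairs for networks (the format digitized micrographs arrive in), JSON/YAML
# run configurations, and the metrics CSV.

#' Write bead states as a LAMMPS-style text dump
#'
#' Multi-frame plain-text trajectory: ITEM: TIMESTEP / NUMBER OF ATOMS /
#' BOX BOUNDS pp pp pp / ATOMS id type mol x y vx vy. Units: nm and nm/us;
#' the timestep field carries the time in us. Full double precision, so
#' write-then-read round-trips exactly at the printed precision.
#'
#' @param states a `cw_state`, a list of them, or a `cw_trajectory` (final
#'   state)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dump <- function(states, path) {
  if (inherits(states, "cw_trajectory")) states <- list(states$final)
  if (inherits(states, "cw_state")) states <- list(states)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$pos)
    writeLines(c("ITEM: TIMESTEP",
                 sprintf("%.17g", st$time),
                 "ITEM: NUMBER OF ATOMS",
                 as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.17g", st$cell[1]),
                 sprintf("0 %.17g", st$cell[2]),
                 "-0.5 0.5",
                 "ITEM: ATOMS id type mol x y vx vy"), con)
    writeLines(sprintf("%d %d %d %.17g %.17g %.17g %.17g",
                       seq_len(n), st$type, st$mol,
                       st$pos[, 1], st$pos[, 2],
                       st$vel[, 1], st$vel[, 2]), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style text dump
#'
#' @param path dump file written by [write_dump()] or an external tool with
#'   the same columns
#' @param topology optional `cw_state` supplying bonds/angles (a dump file
#'   carries none); without it the states have empty bonded topology
#' @return list of `cw_state` objects, one per frame
#' @export
read_dump <- function(path, topology = NULL) {
  lines <- readLines(path)
  states <- list()
  i <- 1
  frame <- 0
  while (i <= length(lines)) {
    frame <- frame + 1
    fail <- function(what)
      stop("malformed dump frame ", frame, ": ", what, call. = FALSE)
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) fail("expected TIMESTEP")
    if (i + 8 > length(lines)) fail("truncated header")
    time <- as.numeric(lines[i + 1])
    if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
      fail("expected NUMBER OF ATOMS")
    n <- as.integer(lines[i + 3])
    if (!startsWith(lines[i + 4], "ITEM: BOX BOUNDS")) fail("expected BOX BOUNDS")
    bx <- as.numeric(strsplit(trimws(lines[i + 5]), "\\s+")[[1]])
    by <- as.numeric(strsplit(trimws(lines[i + 6]), "\\s+")[[1]])
    hdr <- lines[i + 8]
    if (!startsWith(hdr, "ITEM: ATOMS")) fail("expected ATOMS")
    cols <- strsplit(sub("ITEM: ATOMS ", "", hdr), "\\s+")[[1]]
    if (i + 8 + n > length(lines)) fail("truncated atom block")
    block <- lines[(i + 9):(i + 8 + n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                nrow = n, byrow = TRUE)
    if (ncol(m) != length(cols)) fail("column count mismatch")
    if (anyNA(m)) fail("non-numeric atom data")
    colnames(m) <- cols
    ord <- order(m[, "id"])
    m <- m[ord, , drop = FALSE]
    vel <- if (all(c("vx", "vy") %in% cols)) m[, c("vx", "vy")] else NULL
    empty_b <- matrix(numeric(), 0, 3,
                      dimnames = list(NULL, c("i", "j", "rest")))
    empty_a <- matrix(numeric(), 0, 4,
                      dimnames = list(NULL, c("i", "j", "k", "theta0")))
    st <- system_state(m[, c("x", "y")], vel,
                       type = as.integer(m[, "type"]),
                       mol = as.integer(m[, "mol"]),
                       bonds = if (is.null(topology)) empty_b else
                         topology$bonds,
                       angles = if (is.null(topology)) empty_a else
                         topology$angles,
                       cell = c(bx[2] - bx[1], by[2] - by[1]),
                       time = time)
    states[[length(states) + 1]] <- st
    i <- i + 9 + n
  }
  states
}

#' Write a network as a nodes/edges CSV pair
#'
#' `nodes.csv` holds id, x, y, k (with the cell lengths in a header comment);
#' `edges.csv` holds u, v (and the periodic shifts sx, sy). This is also the
#' entry format for externally digitized networks.
#'
#' @param network a `cw_network`
#' @param nodes_path,edges_path output files
#' @return invisibly, the two paths
#' @export
write_network <- function(network, nodes_path, edges_path) {
  hdr <- sprintf("# Lx=%.17g Ly=%.17g", network$cell[1], network$cell[2])
  con <- file(nodes_path, "w")
  writeLines(hdr, con)
  writeLines("id,x,y,k", con)
  writeLines(sprintf("%d,%.17g,%.17g,%d", network$nodes$id,
                     network$nodes$x, network$nodes$y, network$nodes$k), con)
  close(con)
  readr::write_csv(network$edges[, c("u", "v", "sx", "sy")], edges_path)
  invisible(c(nodes_path, edges_path))
}

#' Read a network from a nodes/edges CSV pair
#'
#' @param nodes_path CSV with id,x,y(,k) and a `# Lx=... Ly=...` comment, or
#'   `cell` given explicitly
#' @param edges_path CSV with u,v(,sx,sy)
#' @param cell optional c(Lx, Ly), overriding the header comment
#' @return a `cw_network`
#' @export
read_network <- function(nodes_path, edges_path, cell = NULL) {
  first <- readLines(nodes_path, n = 1)
  if (is.null(cell)) {
    m <- regmatches(first, regexec(
      "Lx=([0-9eE+.-]+)\\s+Ly=([0-9eE+.-]+)", first))[[1]]
    if (length(m) != 3)
      stop("nodes file has no '# Lx=... Ly=...' header and no `cell` given",
           call. = FALSE)
    cell <- as.numeric(m[2:3])
  }
  nodes <- readr::read_csv(nodes_path, comment = "#", show_col_types = FALSE)
  edges <- readr::read_csv(edges_path, comment = "#", show_col_types = FALSE)
  nodes <- nodes[order(nodes$id), ]
  if (!identical(as.integer(nodes$id), seq_len(nrow(nodes))))
    stop("node ids must be 1..n (rows ",
         paste(which(as.integer(nodes$id) != seq_len(nrow(nodes))),
               collapse = ", "), " violate this)", call. = FALSE)
  as_network(nodes, edges, cell)
}

#' Export a polygon set as JSON
#'
#' @param polygons a `cw_polygons`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_polygons_json <- function(polygons, path) {
  out <- list(
    cell = polygons$cell,
    n_edges = polygons$n_edges,
    dangling = polygons$dangling,
    polygons = lapply(polygons$polygons, function(p)
      list(nodes = p$nodes, x = p$x, y = p$y, n = p$n, area = p$area,
           perimeter = p$perimeter)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Configurations serialise as JSON or YAML (by file extension). Unknown
#' keys are rejected rather than silently ignored.
#'
#' @param path config file (.json, .yaml or .yml)
#' @return a [run_config()] object
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known_pp <- names(formals(potential_params))
  known_sim <- setdiff(names(formals(sim_params)), "kl")
  known_cfg <- setdiff(names(formals(run_config)), c("params", "sim"))
  unknown <- setdiff(names(raw), c(known_pp, known_sim, known_cfg,
                                   "params", "sim"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pp_args <- raw[intersect(names(raw), known_pp)]
  if (!is.null(raw$params)) pp_args <- utils::modifyList(pp_args, raw$params)
  sim_args <- raw[intersect(names(raw), known_sim)]
  if (!is.null(raw$sim)) sim_args <- utils::modifyList(sim_args, raw$sim)
  cfg_args <- raw[intersect(names(raw), known_cfg)]
  params <- do.call(potential_params, pp_args)
  sim <- do.call(sim_params, c(sim_args, list(kl = params$kl)))
  do.call(run_config, c(cfg_args, list(params = params, sim = sim)))
}

#' @rdname read_config
#' @param config a `cw_config`
#' @return `write_config`: `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cw_config"))
  out <- config
  class(out) <- NULL
  out$params <- unclass(out$params)
  out$sim <- unclass(out$sim)
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(out, path, precision = 15) else
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' Write the scalar log of a trajectory as CSV
#'
#' @param trajectory a `cw_trajectory`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_log_csv <- function(trajectory, path) {
  readr::write_csv(trajectory$log, path)
  invisible(path)
}
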