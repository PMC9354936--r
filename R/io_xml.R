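#' Parse a simulation configuration document
#'
#' Reads the XML simulation dialect into a `simulation_document`. The
#' document describes algorithms (grid model/matrix file pairs with a
#' refractory period and a start position), population nodes, external
#' Poisson drives (`IncomingConnection`, which carries a constant `rate`),
#' inter-population connections (`Connection`, with `num_connections`,
#' `efficacy`, `delay` and the 0-based `dimension` the jump acts on),
#' reporting requests and the run parameters (`master_steps`, `t_end`,
#' `t_step`, `name_log`). Unknown elements or attributes raise an error
#' naming the location; the Algorithm `TimeStep` must equal the run
#' `t_step`.
#'
#' @param xml path to an XML file, or a literal XML string.
#' @return an object of class `simulation_document`.
#' @export
parse_simulation <- function(xml) {
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_name(doc)
  if (root != "Simulation") stop("root element must be <Simulation>, got <",
                                 root, ">")
  known_top <- c("WeightType", "Algorithms", "Nodes", "Connections",
                 "Reporting", "SimulationRunParameter")
  for (ch in xml2::xml_children(doc)) {
    if (!(xml2::xml_name(ch) %in% known_top))
      stop("unknown element <", xml2::xml_name(ch), "> under <Simulation>")
  }
  attrs_or_stop <- function(node, allowed, where) {
    a <- xml2::xml_attrs(node)
    bad <- setdiff(names(a), allowed)
    if (length(bad)) stop("unknown attribute(s) ", paste(bad, collapse = ", "),
                          " on <", where, ">")
    a
  }
  num_attr <- function(a, name, default = NULL, where = "") {
    if (!name %in% names(a)) {
      if (is.null(default)) stop("missing attribute '", name, "' on <",
                                 where, ">")
      return(default)
    }
    as.numeric(a[[name]])
  }
  weight_type <- {
    wt <- xml2::xml_find_first(doc, "./WeightType")
    if (inherits(wt, "xml_missing")) "CustomConnectionParameters"
    else trimws(xml2::xml_text(wt))
  }
  # --- algorithms ---
  algorithms <- list()
  for (alg in xml2::xml_find_all(doc, "./Algorithms/Algorithm")) {
    a <- xml2::xml_attrs(alg)
    req <- c("type", "name", "modelfile", "transformfile")
    allowed <- c(req, "tau_refractive",
                 grep("^start_", names(a), value = TRUE))
    bad <- setdiff(names(a), allowed)
    if (length(bad) || !all(req %in% names(a)))
      stop("bad attributes on <Algorithm ", a[["name"]] %||% "?", ">")
    ts_node <- xml2::xml_find_first(alg, "./TimeStep")
    algorithms[[a[["name"]]]] <- list(
      type = a[["type"]], name = a[["name"]],
      modelfile = a[["modelfile"]], transformfile = a[["transformfile"]],
      tau_refractive = num_attr(a, "tau_refractive", 0, "Algorithm"),
      start = a[grep("^start_", names(a))],
      time_step = if (inherits(ts_node, "xml_missing")) NA_real_
                  else as.numeric(xml2::xml_text(ts_node)))
  }
  # --- nodes ---
  nodes <- data.frame(name = character(0), algorithm = character(0),
                      type = character(0))
  for (nd in xml2::xml_find_all(doc, "./Nodes/Node")) {
    a <- attrs_or_stop(nd, c("algorithm", "name", "type"), "Node")
    if (!a[["algorithm"]] %in% names(algorithms))
      stop("node '", a[["name"]], "' references undeclared algorithm '",
           a[["algorithm"]], "'")
    if (!a[["type"]] %in% c("EXCITATORY", "INHIBITORY", "NEUTRAL"))
      stop("node type must be EXCITATORY, INHIBITORY or NEUTRAL")
    nodes <- rbind(nodes, data.frame(name = a[["name"]],
                                     algorithm = a[["algorithm"]],
                                     type = a[["type"]]))
  }
  # --- connections ---
  incoming <- NULL
  connections <- NULL
  for (cn in xml2::xml_find_all(doc, "./Connections/*")) {
    nm <- xml2::xml_name(cn)
    if (nm == "IncomingConnection") {
      a <- attrs_or_stop(cn, c("Node", "num_connections", "efficacy",
                               "delay", "dimension", "rate"),
                         "IncomingConnection")
      incoming <- rbind(incoming, data.frame(
        target = a[["Node"]],
        num_connections = num_attr(a, "num_connections", 1,
                                   "IncomingConnection"),
        efficacy = num_attr(a, "efficacy", where = "IncomingConnection"),
        delay = num_attr(a, "delay", 0, "IncomingConnection"),
        dimension = as.integer(num_attr(a, "dimension",
                                        where = "IncomingConnection")),
        rate = num_attr(a, "rate", where = "IncomingConnection")))
    } else if (nm == "Connection") {
      a <- attrs_or_stop(cn, c("In", "Out", "num_connections", "efficacy",
                               "delay", "dimension"), "Connection")
      connections <- rbind(connections, data.frame(
        source = a[["In"]], target = a[["Out"]],
        num_connections = num_attr(a, "num_connections", 1, "Connection"),
        efficacy = num_attr(a, "efficacy", where = "Connection"),
        delay = num_attr(a, "delay", 0, "Connection"),
        dimension = as.integer(num_attr(a, "dimension",
                                        where = "Connection"))))
    } else {
      stop("unknown element <", nm, "> under <Connections>")
    }
  }
  endpoint_check <- function(x, what) {
    bad <- setdiff(unique(x), nodes$name)
    if (length(bad)) stop("connection in ", what,
                          " references undeclared node(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(incoming)) endpoint_check(incoming$target,
                                         "IncomingConnection")
  if (!is.null(connections)) {
    endpoint_check(connections$source, "Connection")
    endpoint_check(connections$target, "Connection")
  }
  # --- reporting ---
  reporting <- NULL
  for (rp in xml2::xml_find_all(doc, "./Reporting/*")) {
    nm <- xml2::xml_name(rp)
    if (!nm %in% c("Display", "Average", "Rate"))
      stop("unknown element <", nm, "> under <Reporting>")
    a <- attrs_or_stop(rp, c("node", "t_interval"), nm)
    reporting <- rbind(reporting, data.frame(
      what = nm, node = a[["node"]],
      t_interval = num_attr(a, "t_interval", NA_real_, nm)))
  }
  if (!is.null(reporting)) endpoint_check(reporting$node, "Reporting")
  # --- run parameters ---
  rp <- xml2::xml_find_first(doc, "./SimulationRunParameter")
  if (inherits(rp, "xml_missing"))
    stop("missing <SimulationRunParameter>")
  rp_num <- function(name, default = NULL) {
    nd <- xml2::xml_find_first(rp, paste0("./", name))
    if (inherits(nd, "xml_missing")) {
      if (is.null(default)) stop("missing <", name,
                                 "> in SimulationRunParameter")
      return(default)
    }
    as.numeric(xml2::xml_text(nd))
  }
  log_node <- xml2::xml_find_first(rp, "./name_log")
  run <- list(master_steps = as.integer(rp_num("master_steps", 10)),
              t_end = rp_num("t_end"), t_step = rp_num("t_step"),
              name_log = if (inherits(log_node, "xml_missing")) "sim.log"
                         else trimws(xml2::xml_text(log_node)))
  for (alg in algorithms) {
    if (!is.na(alg$time_step) && abs(alg$time_step - run$t_step) > 1e-15)
      stop("Algorithm '", alg$name, "' TimeStep (", alg$time_step,
           ") does not equal SimulationRunParameter t_step (", run$t_step,
           ")")
  }
  structure(list(weight_type = weight_type, algorithms = algorithms,
                 nodes = nodes, incoming = incoming,
                 connections = connections, reporting = reporting,
                 run = run),
            class = "simulation_document")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a simulation document back to XML
#' @param doc a `simulation_document`.
#' @param path output path, or `NULL` to return the XML text.
#' @return invisibly the path, or the XML string when `path` is `NULL`.
#' @export
write_simulation <- function(doc, path = NULL) {
  if (!inherits(doc, "simulation_document"))
    stop("expected a simulation_document")
  esc <- function(x) gsub("\"", "&quot;", as.character(x))
  lines <- c("<Simulation>",
             paste0("<WeightType>", doc$weight_type, "</WeightType>"),
             "<Algorithms>")
  for (alg in doc$algorithms) {
    starts <- paste(sprintf(' %s="%s"', names(alg$start), esc(alg$start)),
                    collapse = "")
    lines <- c(lines, sprintf(
      '<Algorithm type="%s" name="%s" modelfile="%s" transformfile="%s" tau_refractive="%.17g"%s>',
      alg$type, alg$name, alg$modelfile, alg$transformfile,
      alg$tau_refractive, starts),
      sprintf("<TimeStep>%.17g</TimeStep>",
              if (is.na(alg$time_step)) doc$run$t_step else alg$time_step),
      "</Algorithm>")
  }
  lines <- c(lines, "</Algorithms>", "<Nodes>")
  for (r in seq_len(nrow(doc$nodes))) {
    lines <- c(lines, sprintf('<Node algorithm="%s" name="%s" type="%s" />',
                              doc$nodes$algorithm[r], doc$nodes$name[r],
                              doc$nodes$type[r]))
  }
  lines <- c(lines, "</Nodes>", "<Connections>")
  if (!is.null(doc$incoming)) {
    for (r in seq_len(nrow(doc$incoming))) {
      x <- doc$incoming[r, ]
      lines <- c(lines, sprintf(
        '<IncomingConnection Node="%s" num_connections="%.17g" efficacy="%.17g" delay="%.17g" dimension="%d" rate="%.17g" />',
        x$target, x$num_connections, x$efficacy, x$delay, x$dimension,
        x$rate))
    }
  }
  if (!is.null(doc$connections)) {
    for (r in seq_len(nrow(doc$connections))) {
      x <- doc$connections[r, ]
      lines <- c(lines, sprintf(
        '<Connection In="%s" Out="%s" num_connections="%.17g" efficacy="%.17g" delay="%.17g" dimension="%d" />',
        x$source, x$target, x$num_connections, x$efficacy, x$delay,
        x$dimension))
    }
  }
  lines <- c(lines, "</Connections>", "<Reporting>")
  if (!is.null(doc$reporting)) {
    for (r in seq_len(nrow(doc$reporting))) {
      x <- doc$reporting[r, ]
      ti <- if (is.na(x$t_interval)) "" else
        sprintf(' t_interval="%.17g"', x$t_interval)
      lines <- c(lines, sprintf('<%s node="%s"%s />', x$what, x$node, ti))
    }
  }
  lines <- c(lines, "</Reporting>", "<SimulationRunParameter>",
             sprintf("<master_steps>%d</master_steps>",
                     doc$run$master_steps),
             sprintf("<t_end>%.17g</t_end>", doc$run$t_end),
             sprintf("<t_step>%.17g</t_step>", doc$run$t_step),
             sprintf("<name_log>%s</name_log>", doc$run$name_log),
             "</SimulationRunParameter>", "</Simulation>")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

# assemble the start position from start_* attributes; potential is last.
# start_v -> last dimension, start_w -> N-2, start_u -> N-3; any dimension
# can also be addressed explicitly as start_d<i> (0-based).
assemble_start <- function(start_attrs, n_dims) {
  out <- numeric(n_dims)
  lettermap <- c(v = n_dims - 1L, w = n_dims - 2L, u = n_dims - 3L)
  for (nm in names(start_attrs)) {
    key <- sub("^start_", "", nm)
    idx <- if (grepl("^d[0-9]+$", key)) {
      as.integer(sub("^d", "", key))
    } else if (key %in% names(lettermap)) {
      lettermap[[key]]
    } else {
      stop("unrecognized start attribute '", nm, "'")
    }
    if (is.na(idx) || idx < 0L || idx >= n_dims)
      stop("start attribute '", nm, "' addresses dimension ", idx,
           " outside the ", n_dims, "-dimensional model")
    out[idx + 1L] <- as.numeric(start_attrs[[nm]])
  }
  out
}

#' Execute a parsed simulation document
#'
#' Loads the model and matrix files referenced by each algorithm (relative
#' to `dir`), assembles the network and runs it. Rate and average-potential
#' time series are returned and, when `out_dir` is given, written as CSV
#' (one row per reporting time, one column per node), along with density
#' snapshots (`flat_index mass` lines) for nodes with a `Display` request.
#'
#' @param doc a `simulation_document` or a path to an XML file.
#' @param dir directory the model/matrix file names are relative to.
#' @param out_dir `NULL`, or a directory to write CSV/snapshot outputs to.
#' @param display_interval snapshot interval (s) for `Display` requests.
#' @return the [run_network()] result, invisibly when `out_dir` is given.
#' @export
run_simulation <- function(doc, dir = ".", out_dir = NULL,
                           display_interval = 0.1) {
  if (is.character(doc)) {
    if (dir == "." && file.exists(doc)) dir <- dirname(doc)
    doc <- parse_simulation(doc)
  }
  nodes <- list()
  for (r in seq_len(nrow(doc$nodes))) {
    alg <- doc$algorithms[[doc$nodes$algorithm[r]]]
    model_path <- file.path(dir, alg$modelfile)
    tmat_path <- file.path(dir, alg$transformfile)
    if (!file.exists(model_path)) stop("model file not found: ", model_path)
    if (!file.exists(tmat_path)) stop("matrix file not found: ", tmat_path)
    grid <- read_model_file(model_path)
    if (abs(grid$time_step - doc$run$t_step) > 1e-15)
      stop("grid time step (", grid$time_step, ") of '", alg$modelfile,
           "' does not match t_step (", doc$run$t_step, ")")
    tm <- read_matrix_file(tmat_path, grid)
    start <- assemble_start(alg$start, grid$n_dims)
    for (cset in list(doc$connections, doc$incoming)) {
      if (is.null(cset)) next
      sel <- cset$target == doc$nodes$name[r]
      if (any(cset$dimension[sel] >= grid$n_dims |
                cset$dimension[sel] < 0))
        stop("connection dimension out of range for node '",
             doc$nodes$name[r], "' (model has ", grid$n_dims,
             " dimensions)")
    }
    nodes[[doc$nodes$name[r]]] <- population_node(
      doc$nodes$name[r], tm, start, tau_ref = alg$tau_refractive)
  }
  intervals <- if (!is.null(doc$reporting))
    doc$reporting$t_interval[!is.na(doc$reporting$t_interval)] else numeric(0)
  rec_interval <- if (length(intervals)) min(intervals) else doc$run$t_step
  display_nodes <- if (!is.null(doc$reporting))
    unique(doc$reporting$node[doc$reporting$what == "Display"]) else
    character(0)
  snapshot_times <- if (length(display_nodes)) {
    if (display_interval <= doc$run$t_end)
      unique(c(seq(display_interval, doc$run$t_end,
                   by = display_interval), doc$run$t_end))
    else doc$run$t_end
  } else NULL
  res <- run_network(nodes, connections = doc$connections,
                     externals = doc$incoming, t_end = doc$run$t_end,
                     master_steps = doc$run$master_steps,
                     record_interval = rec_interval,
                     snapshot_times = snapshot_times)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    prefix <- sub("\\.log$", "", doc$run$name_log)
    rate_nodes <- if (!is.null(doc$reporting))
      unique(doc$reporting$node[doc$reporting$what == "Rate"]) else
      colnames(res$rates)
    avg_nodes <- if (!is.null(doc$reporting))
      unique(doc$reporting$node[doc$reporting$what == "Average"]) else
      colnames(res$rates)
    if (length(rate_nodes)) {
      df <- data.frame(time = res$time,
                       res$rates[, rate_nodes, drop = FALSE])
      utils::write.csv(df, file.path(out_dir, paste0(prefix, "_rate.csv")),
                       row.names = FALSE)
    }
    if (length(avg_nodes)) {
      av <- sapply(avg_nodes, function(nd) {
        g <- nodes[[nd]]$matrix$grid
        res$averages[[nd]][, g$n_dims]
      })
      df <- data.frame(time = res$time, av)
      names(df) <- c("time", avg_nodes)
      utils::write.csv(df, file.path(out_dir, paste0(prefix, "_avg_v.csv")),
                       row.names = FALSE)
    }
    for (nd in display_nodes) {
      for (tm_name in names(res$snapshots[[nd]])) {
        mass <- res$snapshots[[nd]][[tm_name]]
        nz <- which(mass > 0)
        writeLines(sprintf("%d %.17g", nz - 1L, mass[nz]),
                   file.path(out_dir, sprintf("%s_density_%s_%s.txt",
                                              prefix, nd, tm_name)))
      }
    }
    writeLines(c("popgrid simulation log",
                 sprintf("nodes: %s", paste(names(nodes), collapse = ", ")),
                 sprintf("t_end %g t_step %g master_steps %d",
                         doc$run$t_end, doc$run$t_step,
                         doc$run$master_steps),
                 sprintf("max mass error %.3e", res$mass_error)),
               file.path(out_dir, doc$run$name_log))
    return(invisible(res))
  }
  res
}
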