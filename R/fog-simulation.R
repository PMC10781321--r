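# Discrete-event latency simulation of the three-layer architecture:
# sensors (EEG headsets) at the edge, a fog node close by, a cloud node far
# away, and the actuator (the controlled cyber-physical system). Every node
# is a single-server FIFO queue; because each routing sends all messages
# along one fixed path, the event-driven dynamics reduce exactly to the
# tandem-queue recursion
#   departure[i, node] = max(arrival[i, node], departure[i-1, node]) + service
# which this module implements.

#' Fog/cloud network topology
#'
#' @param nodes Data frame with columns `id`, `kind` (one of sensor, fog,
#'   cloud, actuator) and `service_time` (ms per message).
#' @param links Data frame with columns `from`, `to`, `propagation_delay`
#'   (ms) and `bandwidth` (bits/ms).
#' @return An object of class `fog_topology`.
#' @export
fog_topology <- function(nodes, links) {
  stopifnot(all(c("id", "kind", "service_time") %in% names(nodes)),
            all(c("from", "to", "propagation_delay", "bandwidth") %in% names(links)))
  if (any(nodes$service_time < 0)) stop("service times must be non-negative")
  if (any(links$propagation_delay < 0)) stop("link delays must be non-negative")
  if (any(links$bandwidth <= 0)) stop("link bandwidth must be positive")
  bad <- setdiff(c(links$from, links$to), nodes$id)
  if (length(bad)) stop("links reference unknown node(s): ",
                        paste(unique(bad), collapse = ", "))
  structure(list(nodes = nodes, links = links), class = "fog_topology")
}

#' Default topology: a nearby fog node versus a distant cloud
#'
#' Sensor-fog and fog-actuator links have 2 ms propagation delay; any link
#' touching the cloud has 50 ms. All links carry 1e4 bits/ms; fog and cloud
#' spend the same 5 ms classifying a message, so the comparison isolates
#' proximity, not compute.
#'
#' @param fog_delay_ms,cloud_delay_ms Per-link propagation delays.
#' @param bandwidth Link bandwidth in bits/ms.
#' @param fog_service_ms,cloud_service_ms Node service times.
#' @return A [fog_topology()].
#' @export
default_fog_topology <- function(fog_delay_ms = 2, cloud_delay_ms = 50,
                                 bandwidth = 1e4, fog_service_ms = 5,
                                 cloud_service_ms = 5) {
  nodes <- data.frame(
    id = c("sensor", "fog", "cloud", "actuator"),
    kind = c("sensor", "fog", "cloud", "actuator"),
    service_time = c(0, fog_service_ms, cloud_service_ms, 0))
  links <- data.frame(
    from = c("sensor", "fog", "sensor", "cloud"),
    to = c("fog", "actuator", "cloud", "actuator"),
    propagation_delay = c(fog_delay_ms, fog_delay_ms,
                          cloud_delay_ms, cloud_delay_ms),
    bandwidth = bandwidth)
  fog_topology(nodes, links)
}

#' Message workload for the latency simulation
#'
#' @param n_messages Number of messages (EEG windows) emitted by the sensor.
#' @param message_size Message size in bits.
#' @param interarrival `"exponential"` (rate `rate` per ms) or `"fixed"`
#'   (every `interval` ms).
#' @param rate Arrival rate per ms for exponential interarrivals.
#' @param interval Fixed interarrival in ms.
#' @param seed Seed for the exponential draws.
#' @return An object of class `fog_workload`.
#' @export
fog_workload <- function(n_messages = 1000L, message_size = 1e4,
                         interarrival = c("exponential", "fixed"),
                         rate = 0.05, interval = 20, seed = 1L) {
  interarrival <- match.arg(interarrival)
  stopifnot(n_messages >= 1, message_size > 0, rate > 0, interval >= 0)
  structure(list(n_messages = as.integer(n_messages),
                 message_size = message_size, interarrival = interarrival,
                 rate = rate, interval = interval, seed = as.integer(seed)),
            class = "fog_workload")
}

.arrival_times <- function(workload) {
  if (workload$interarrival == "fixed")
    return(cumsum(rep(workload$interval, workload$n_messages)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(workload$seed)
  cumsum(stats::rexp(workload$n_messages, rate = workload$rate))
}

.routing_path <- function(routing) {
  switch(routing,
         fog = c("sensor", "fog", "actuator"),
         cloud_only = c("sensor", "cloud", "actuator"),
         stop("routing must be 'fog' or 'cloud_only'"))
}

#' Simulate end-to-end command latency
#'
#' Runs all messages of the workload through the chosen route. Per-message
#' latency is the sum over traversed links of propagation delay plus
#' transmission time (`message_size / bandwidth`) and over nodes of queueing
#' wait plus service time, from sensor emission to delivery at the actuator.
#'
#' @param topology A [fog_topology()].
#' @param workload A [fog_workload()].
#' @param routing `"fog"` (sensor - fog - actuator) or `"cloud_only"`
#'   (sensor - cloud - actuator).
#' @return An object of class `latency_result`: list with `latency_ms`
#'   (per message), `mean`, `median`, `max`, `routing`, plus per-node
#'   `completion` times (messages x nodes matrix).
#' @export
simulate_fog <- function(topology, workload, routing = c("fog", "cloud_only")) {
  stopifnot(inherits(topology, "fog_topology"), inherits(workload, "fog_workload"))
  routing <- match.arg(routing)
  path <- .routing_path(routing)
  service <- stats::setNames(topology$nodes$service_time, topology$nodes$id)
  if (!all(path %in% names(service)))
    stop("topology lacks node(s): ", paste(setdiff(path, names(service)), collapse = ", "))
  link_key <- paste(topology$links$from, topology$links$to)
  emit <- .arrival_times(workload)
  n <- workload$n_messages
  completion <- matrix(NA_real_, n, length(path),
                       dimnames = list(NULL, path))
  arrive <- emit
  for (k in seq_along(path)) {
    node <- path[k]
    dep <- numeric(n)
    prev <- -Inf
    st <- service[[node]]
    for (i in seq_len(n)) {
      start <- max(arrive[i], prev)
      prev <- start + st
      dep[i] <- prev
    }
    completion[, k] <- dep
    if (k < length(path)) {
      li <- match(paste(node, path[k + 1L]), link_key)
      if (is.na(li))
        stop("topology has no link ", node, " -> ", path[k + 1L],
             " required by routing '", routing, "'")
      arrive <- dep + topology$links$propagation_delay[li] +
        workload$message_size / topology$links$bandwidth[li]
    }
  }
  latency <- completion[, length(path)] - emit
  structure(list(latency_ms = latency, mean = mean(latency),
                 median = stats::median(latency), max = max(latency),
                 routing = routing, emit = emit, completion = completion),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("Latency (%s route, %d messages): mean %.3f ms, median %.3f ms, max %.3f ms\n",
              x$routing, length(x$latency_ms), x$mean, x$median, x$max))
  invisible(x)
}

#' Closed-form single-message path latency
#'
#' The queueing-free latency of one message: sum over links of propagation
#' delay plus transmission time, plus the sum of node service times.
#'
#' @inheritParams simulate_fog
#' @param message_size Message size in bits.
#' @return Latency in ms.
#' @export
path_latency <- function(topology, routing = c("fog", "cloud_only"),
                         message_size = 1e4) {
  routing <- match.arg(routing)
  path <- .routing_path(routing)
  service <- stats::setNames(topology$nodes$service_time, topology$nodes$id)
  link_key <- paste(topology$links$from, topology$links$to)
  total <- sum(service[path])
  for (k in seq_len(length(path) - 1L)) {
    li <- match(paste(path[k], path[k + 1L]), link_key)
    if (is.na(li)) stop("topology has no link ", path[k], " -> ", path[k + 1L])
    total <- total + topology$links$propagation_delay[li] +
      message_size / topology$links$bandwidth[li]
  }
  unname(total)
}

#' Compare fog and cloud-only processing latency
#'
#' Runs the same workload (identical arrival times) through both routes and
#' returns the mean latencies and their ratio.
#'
#' @param topology A [fog_topology()].
#' @param workload A [fog_workload()].
#' @return List with `fog_mean_ms`, `cloud_mean_ms`, `ratio`
#'   (cloud / fog) and both full `latency_result`s.
#' @export
compare_architectures <- function(topology = default_fog_topology(),
                                  workload = fog_workload()) {
  fog <- simulate_fog(topology, workload, "fog")
  cloud <- simulate_fog(topology, workload, "cloud_only")
  list(fog_mean_ms = fog$mean, cloud_mean_ms = cloud$mean,
       ratio = cloud$mean / fog$mean, fog = fog, cloud = cloud)
}

#' Read a topology/workload configuration file
#'
#' JSON with optional `topology` (objects `nodes` and `links` in the
#' [fog_topology()] column layout) and `workload` (arguments of
#' [fog_workload()]); missing parts fall back to the defaults.
#'
#' @param path JSON file.
#' @return List with `topology` and `workload`.
#' @export
read_fog_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  topology <- if (is.null(cfg$topology)) default_fog_topology()
              else fog_topology(cfg$topology$nodes, cfg$topology$links)
  workload <- if (is.null(cfg$workload)) fog_workload()
              else do.call(fog_workload, cfg$workload)
  list(topology = topology, workload = workload)
}

#' Write simulation results to disk
#'
#' Per-message latencies as a tab-delimited table plus a JSON summary.
#'
#' @param results Named list of `latency_result`s (e.g. fog and cloud).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_latency_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(routing = nm, message = seq_along(r$latency_ms),
               latency_ms = r$latency_ms)
  }))
  utils::write.table(tab, file.path(dir, "latencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- lapply(results, function(r)
    list(routing = r$routing, mean_ms = r$mean, median_ms = r$median,
         max_ms = r$max, n = length(r$latency_ms)))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
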