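tiny_workload <- function(n = 1L, interval = 1000, size = 1) {
  fog_workload(n_messages = n, message_size = size,
               interarrival = "fixed", interval = interval)
}

test_that("a zero-cost topology yields zero latency", {
  topo <- default_fog_topology(fog_delay_ms = 0, cloud_delay_ms = 0,
                               bandwidth = Inf,     # no transmission time
                               fog_service_ms = 0, cloud_service_ms = 0)
  res <- simulate_fog(topo, tiny_workload(n = 5), "fog")
  expect_identical(unname(res$latency_ms), rep(0, 5))
})

test_that("a single message reproduces the closed-form path sum", {
  # links 1 ms each way, transmission 0.5 ms each way, fog service 2 ms
  topo <- default_fog_topology(fog_delay_ms = 1, bandwidth = 2,
                               fog_service_ms = 2)
  res <- simulate_fog(topo, tiny_workload(size = 1), "fog")
  expect_equal(unname(res$latency_ms), 1 + 0.5 + 2 + 0.5 + 1)
  expect_equal(res$mean, 5)
  expect_equal(path_latency(topo, "fog", message_size = 1), 5)
})

test_that("without queueing every latency equals the closed form", {
  topo <- default_fog_topology()
  wl <- fog_workload(n_messages = 50, interarrival = "fixed", interval = 500)
  for (route in c("fog", "cloud_only")) {
    res <- simulate_fog(topo, wl, route)
    cf <- path_latency(topo, route, message_size = wl$message_size)
    expect_lt(max(abs(res$latency_ms - cf)), 1e-9)
  }
})

test_that("messages are conserved and event chains are causal", {
  topo <- default_fog_topology()
  wl <- fog_workload(n_messages = 200, interarrival = "exponential",
                     rate = 0.2, seed = 4)
  res <- simulate_fog(topo, wl, "fog")
  expect_length(res$latency_ms, 200L)
  expect_true(all(is.finite(res$latency_ms)))
  # completion times never run backwards along a message's event chain,
  # and increase strictly once every node takes positive service time
  for (i in c(1, 50, 200)) {
    chain <- c(res$emit[i], res$completion[i, ])
    expect_true(all(diff(chain) >= 0))
  }
  busy <- default_fog_topology()
  busy$nodes$service_time <- c(1, 5, 5, 1)
  res_b <- simulate_fog(busy, fog_workload(n_messages = 50, seed = 4), "fog")
  for (i in c(1, 25, 50)) {
    chain <- c(res_b$emit[i], res_b$completion[i, ])
    expect_true(all(diff(chain) > 0))
  }
  expect_true(res$mean >= min(res$latency_ms) && res$mean <= max(res$latency_ms))
  expect_gte(min(res$latency_ms), path_latency(topo, "fog"))
  # identical seed reruns identically
  res2 <- simulate_fog(topo, wl, "fog")
  expect_identical(res$latency_ms, res2$latency_ms)
})

test_that("increasing a link delay never shortens any latency", {
  wl <- fog_workload(n_messages = 100, interarrival = "exponential",
                     rate = 0.1, seed = 9)
  base <- simulate_fog(default_fog_topology(fog_delay_ms = 2), wl, "fog")
  slow <- simulate_fog(default_fog_topology(fog_delay_ms = 10), wl, "fog")
  expect_true(all(slow$latency_ms >= base$latency_ms))
})

test_that("architecture comparison reflects proximity, symmetry and crossover", {
  wl <- fog_workload(n_messages = 300, seed = 2)
  cmp <- compare_architectures(default_fog_topology(), wl)
  expect_lt(cmp$fog_mean_ms, cmp$cloud_mean_ms)
  expect_gt(cmp$ratio, 1)

  sym <- default_fog_topology(fog_delay_ms = 7, cloud_delay_ms = 7)
  cmp_sym <- compare_architectures(sym, wl)
  expect_equal(cmp_sym$fog_mean_ms, cmp_sym$cloud_mean_ms)

  # a slow enough fog node flips the ordering despite proximity
  crossed <- default_fog_topology(fog_service_ms = 500, cloud_service_ms = 0)
  cmp_x <- compare_architectures(crossed, tiny_workload(n = 5, interval = 1000))
  expect_lt(cmp_x$cloud_mean_ms, cmp_x$fog_mean_ms)
})

test_that("broken topologies and workloads are rejected", {
  topo <- default_fog_topology()
  topo$links <- topo$links[topo$links$to != "actuator" | topo$links$from != "fog", ]
  expect_error(simulate_fog(topo, tiny_workload(), "fog"), "no link fog")
  expect_error(fog_workload(n_messages = 0))
  expect_error(fog_workload(message_size = 0))
  nodes <- data.frame(id = "a", kind = "fog", service_time = -1)
  links <- data.frame(from = "a", to = "a", propagation_delay = 0, bandwidth = 1)
  expect_error(fog_topology(nodes, links), "non-negative")
})

test_that("fog configuration files round-trip into topology and workload", {
  cfg <- list(
    topology = list(
      nodes = data.frame(id = c("sensor", "fog", "cloud", "actuator"),
                         kind = c("sensor", "fog", "cloud", "actuator"),
                         service_time = c(0, 7, 7, 0)),
      links = data.frame(from = c("sensor", "fog", "sensor", "cloud"),
                         to = c("fog", "actuator", "cloud", "actuator"),
                         propagation_delay = c(3, 3, 60, 60),
                         bandwidth = 1e4)),
    workload = list(n_messages = 10, interarrival = "fixed", interval = 100))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  fc <- read_fog_config(f)
  expect_s3_class(fc$topology, "fog_topology")
  res <- simulate_fog(fc$topology, fc$workload, "fog")
  expect_equal(unname(res$latency_ms), rep(3 + 1 + 7 + 3 + 1, 10))
  # defaults fill missing sections
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", f2)
  fc2 <- read_fog_config(f2)
  expect_equal(fc2$workload$n_messages, 1000L)
})

test_that("latency results export as table plus summary", {
  cmp <- compare_architectures(default_fog_topology(),
                               fog_workload(n_messages = 20, seed = 1))
  dir <- withr::local_tempdir()
  write_latency_results(list(fog = cmp$fog, cloud = cmp$cloud), dir)
  tab <- read.delim(file.path(dir, "latencies.tsv"))
  expect_identical(nrow(tab), 40L)
  summ <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  expect_equal(summ$fog$mean_ms, cmp$fog_mean_ms)
})
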