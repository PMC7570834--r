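test_that("static addressing capacity matches the closed form", {
  expect_identical(static_capacity(5, 5), 3125L)
  expect_identical(static_capacity(1, 4), 1L)
  # closed-form oracle b^l against the enumeration, over small grids
  for (b in 1:4) for (l in 1:4) {
    expect_identical(static_capacity(b, l), as.integer(b^l))
  }
})

test_that("the dynamic ID space holds exactly 254 nodes", {
  net <- network_new("DYNAMIC")
  for (id in 1:254) net <- join(net, id)
  expect_length(reachable_nodes(net), 254L)
  expect_error(join(net, 1), "collision")
  expect_error(join(net, 255), "1\\.\\.254")
  expect_error(join(net, 0), "1\\.\\.254")
  # capacity error suggests adding gateways on other channels
  net2 <- network_new("DYNAMIC")
  for (id in 1:254) net2 <- join(net2, id)
  expect_error(drop_node(net2, 0), "gateway")
})

test_that("no node ever exceeds the six-connection radio bound", {
  net <- network_new("DYNAMIC")
  for (id in 1:120) net <- join(net, id)
  set.seed(14)
  for (d in sample(1:120, 15)) net <- drop_node(net, d)
  for (id in c(0L, reachable_nodes(net))) {
    n_children <- sum(net$parent == id)
    uplink <- if (id == 0L) 0L else 1L
    expect_lte(n_children + uplink, 6L)
    expect_lte(n_children, 5L)
  }
})

test_that("static trees collapse under sudden death; dynamic ones reroute", {
  mk <- function(mode) {
    net <- network_new(mode)
    net <- join(net, 1, preferred_parent = 0)
    net <- join(net, 2, preferred_parent = 1)
    net <- join(net, 3, preferred_parent = 2)
    net <- join(net, 4, preferred_parent = 2)
    net <- join(net, 5, preferred_parent = 3)
    net
  }
  # dropping node 2 (3 descendants) strands 4 nodes in STATIC mode
  st <- drop_node(mk("STATIC"), 2)
  expect_identical(reachable_nodes(st), 1L)
  expect_identical(st$stranded, c(3L, 4L, 5L))
  # the same drop in DYNAMIC mode keeps the 3 descendants reachable
  dy <- drop_node(mk("DYNAMIC"), 2)
  expect_identical(reachable_nodes(dy), c(1L, 3L, 4L, 5L))
  # dropping a leaf removes only that node
  leaf <- drop_node(mk("DYNAMIC"), 5)
  expect_identical(reachable_nodes(leaf), 1:4)
})

test_that("dynamic networks survive arbitrary join/drop sequences", {
  set.seed(25)
  net <- network_new("DYNAMIC")
  live <- integer()
  pool <- sample(1:254)
  for (step in 1:120) {
    if (length(live) == 0L || (runif(1) < 0.7 && length(pool) > 0L)) {
      id <- pool[1]; pool <- pool[-1]
      net <- join(net, id); live <- c(live, id)
    } else {
      id <- live[sample.int(length(live), 1)]
      net <- drop_node(net, id); live <- setdiff(live, id)
    }
    expect_setequal(reachable_nodes(net), live)
    # every route in the gateway table ends at its node and starts at 0
    for (k in names(net$routing_table)) {
      r <- net$routing_table[[k]]
      expect_identical(r[1], 0L)
      expect_identical(r[length(r)], as.integer(k))
    }
  }
})

test_that("messages follow the tree path; hop counts match a graph oracle", {
  skip_if_not_installed("igraph")
  net <- run_net_scenario(make_net_scenario(40, 0, seed = 6))
  edges <- cbind(as.integer(names(net$parent)), as.integer(net$parent))
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2), directed = FALSE)
  set.seed(7)
  for (i in 1:25) {
    ends <- sample(c(0L, reachable_nodes(net)), 2)
    tr <- route_message(net, ends[1], ends[2], payload = "x")
    expect_true(tr$delivered)
    oracle <- length(igraph::shortest_paths(
      g, as.character(ends[1]), as.character(ends[2]))$vpath[[1]]) - 1L
    expect_identical(tr$n_hops, oracle)
  }
  # zero-hop self delivery and failed delivery to a dead node
  self <- route_message(net, 5, 5)
  expect_identical(self$n_hops, 0L)
  dead <- route_message(net, 5, 200)
  expect_false(dead$delivered)
})

test_that("broadcast reaches every live node exactly once", {
  net <- run_net_scenario(make_net_scenario(30, 0, seed = 2))
  tr <- route_message(net, 0, "BROADCAST", payload = "ping")
  expect_identical(tr$receipts, reachable_nodes(net))
  expect_identical(tr$n_hops, 30L)            # one incoming edge per node
  expect_false(any(duplicated(tr$receipts)))
})

test_that("firmware images page into 16-byte blocks", {
  img <- firmware_image(as.raw(1:160))
  expect_identical(img$n_pages, 10L)
  img2 <- firmware_image(as.raw(1:161))
  expect_identical(img2$n_pages, 11L)
  expect_identical(img2$pages[[11]], c(as.raw(161), raw(15)))  # zero-padded
  expect_identical(do.call(c, img$pages), img$payload)
})

test_that("OTA reassembly is byte-exact, with and without page loss", {
  net <- network_new("DYNAMIC")
  net <- join(net, 9)
  for (n in c(0L, 1L, 15L, 16L, 17L, 160L, 161L, 1024L)) {
    payload <- as.raw(sample(0:255, n, replace = TRUE))
    res <- ota_update(net, 9, firmware_image(payload))
    expect_true(res$ok)
    expect_identical(res$firmware, payload)
  }
  # 30% injected page loss: still byte-exact, watchdog bounds the gaps
  set.seed(77)
  img <- firmware_image(as.raw(sample(0:255, 400, replace = TRUE)))
  res <- ota_update(net, 9, img, loss_prob = 0.3)
  expect_true(res$ok)
  expect_identical(res$firmware, img$payload)
  expect_true(any(res$trace$outcome == "LOST"))
  expect_lte(res$max_request_interval_s, 4)
})

test_that("node IDs allocate from the printed ranges of both strategies", {
  pool <- id_pool("CURRENT")
  a <- allocate_id(pool, "METHYL")
  expect_identical(a$id, 1L)
  b <- allocate_id(a$pool, "AMIDE")
  expect_identical(b$id, 41L)
  c_ <- allocate_id(b$pool, "ALPHA_CARBON")
  expect_identical(c_$id, 81L)
  # the methyl range holds exactly 40 IDs
  p <- pool
  for (i in 1:40) { r <- allocate_id(p, "METHYL"); p <- r$pool }
  expect_identical(r$id, 40L)
  expect_error(allocate_id(p, "METHYL"), "exhausted.*1-40")
  # extended strategy relocates passive alpha-carbons beyond the 8-bit space
  ep <- id_pool("EXTENDED")
  expect_identical(allocate_id(ep, "ALPHA_CARBON")$id, 257L)
  expect_identical(allocate_id(ep, "AMIDE")$id, 86L)
  e2 <- ep
  for (i in 1:85) { r <- allocate_id(e2, "METHYL"); e2 <- r$pool }
  expect_identical(r$id, 85L)
  expect_error(allocate_id(e2, "METHYL"), "exhausted")
})
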