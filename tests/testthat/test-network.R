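toyM <- function() {
  matrix(c(0.7, 0.1, 0.55, -0.2, -0.9, 0), 3, 2,
         dimnames = list(paste0("g", 1:3), paste0("m", 1:2)))
}

test_that("thresholding keeps exactly the qualifying pairs", {
  net <- relevanceNetwork(toyM(), 0.5)
  expect_equal(nrow(netEdges(net)), 3)
  expect_equal(nrow(netNodes(net)), 5)
  expect_setequal(netNodes(net)$id, c("g1", "g2", "g3", "m1", "m2"))
  expect_equal(netEdges(net)$sign, c("+", "-", "+"))
  ## boundary is inclusive
  m <- toyM(); m[1, 1] <- 0.5
  expect_true("g1" %in% netNodes(relevanceNetwork(m, 0.5))$id)
})

test_that("threshold 0 gives the complete bipartite graph", {
  set.seed(91)
  m <- matrix(runif(12, 0.05, 1), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("m", 1:3)))
  net <- relevanceNetwork(m, 0)
  expect_equal(nrow(netEdges(net)), 12)
  expect_equal(nrow(netNodes(net)), 7)
})

test_that("a threshold above max |M| empties the network", {
  net <- relevanceNetwork(toyM(), 0.95)
  expect_equal(nrow(netEdges(net)), 0)
  expect_equal(nrow(netNodes(net)), 0)
  expect_equal(networkComponents(net), list())
})

test_that("edge sets match brute-force thresholding on random instances", {
  set.seed(93)
  for (rep in 1:100) {
    p <- sample(2:6, 1); q <- sample(2:6, 1)
    m <- matrix(runif(p * q, -1, 1), p, q,
                dimnames = list(paste0("g", 1:p), paste0("m", 1:q)))
    thr <- runif(1)
    net <- relevanceNetwork(m, thr)
    bf <- bruteEdges(m, thr)
    if (is.null(bf)) {
      expect_equal(nrow(netEdges(net)), 0)
    } else {
      got <- netEdges(net)[order(netEdges(net)$x, netEdges(net)$y), ]
      want <- bf[order(bf$x, bf$y), ]
      expect_equal(got$x, want$x)
      expect_equal(got$y, want$y)
      expect_equal(got$weight, want$weight)
    }
  }
})

test_that("raising the threshold is monotone in edges and nodes", {
  set.seed(95)
  m <- matrix(runif(30, -1, 1), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("m", 1:5)))
  thrs <- seq(0, 1, by = 0.1)
  nets <- lapply(thrs, function(t) relevanceNetwork(m, t))
  ne <- sapply(nets, function(n) nrow(netEdges(n)))
  nn <- sapply(nets, function(n) nrow(netNodes(n)))
  expect_true(all(diff(ne) <= 0))
  expect_true(all(diff(nn) <= 0))
  for (i in seq_along(thrs)[-1]) {
    prev <- nets[[i - 1]]; cur <- nets[[i]]
    key <- function(n) paste(netEdges(n)$x, netEdges(n)$y)
    expect_true(all(key(cur) %in% key(prev)))
  }
})

test_that("connected components are found and ordered deterministically", {
  ## star: one X node linked to 4 Y nodes
  m <- matrix(0, 2, 4, dimnames = list(c("g1", "g2"), paste0("m", 1:4)))
  m[1, ] <- 0.9
  comp <- networkComponents(relevanceNetwork(m, 0.5))
  expect_length(comp, 1)
  expect_equal(comp[[1]], c("g1", "m1", "m2", "m3", "m4"))
  ## two separate blocks
  m2 <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("m1", "m2")))
  m2[1, 1] <- 0.9; m2[2, 2] <- -0.8
  comp2 <- networkComponents(relevanceNetwork(m2, 0.5))
  expect_length(comp2, 2)
  expect_equal(comp2[[1]], c("g1", "m1"))
  expect_equal(comp2[[2]], c("g2", "m2"))
})

test_that("GraphML round-trip preserves nodes, edges and attributes", {
  net <- relevanceNetwork(toyM(), 0.5)
  path <- tempfile(fileext = ".graphml")
  exportNetwork(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$side, c("X", "X", "X", "Y", "Y"))
  ends <- igraph::as_data_frame(g, "edges")
  got <- ends[order(ends$from, ends$to), ]
  want <- netEdges(net)[order(netEdges(net)$x, netEdges(net)$y), ]
  expect_equal(got$from, want$x)
  expect_equal(got$to, want$y)
  expect_equal(got$weight, want$weight, tolerance = 1e-6)
  expect_equal(got$sign, want$sign)
  ## negative weight preserved to at least 6 decimals
  m <- toyM(); m[2, 2] <- -0.9123456
  net2 <- relevanceNetwork(m, 0.5)
  p2 <- tempfile(fileext = ".graphml")
  exportNetwork(net2, p2, "graphml")
  g2 <- igraph::read_graph(p2, format = "graphml")
  w <- igraph::as_data_frame(g2, "edges")
  expect_equal(min(w$weight), -0.9123456, tolerance = 1e-6)
})

test_that("empty networks export to valid files", {
  net <- relevanceNetwork(toyM(), 0.95)
  pg <- tempfile(fileext = ".graphml")
  exportNetwork(net, pg, "graphml")
  g <- igraph::read_graph(pg, format = "graphml")
  expect_equal(igraph::ecount(g), 0)
  ps <- tempfile(fileext = ".sif")
  exportNetwork(net, ps, "sif")
  expect_equal(length(readLines(ps)), 0)
})

test_that("SIF export writes pos/neg interaction lines", {
  net <- relevanceNetwork(toyM(), 0.5)
  path <- tempfile(fileext = ".sif")
  exportNetwork(net, path, "sif")
  lines <- readLines(path)
  expect_equal(sort(lines),
               sort(c("g1 pos m1", "g2 neg m2", "g3 pos m1")))
})

test_that("invalid thresholds are rejected", {
  expect_error(relevanceNetwork(toyM(), -0.1), "threshold")
  expect_error(relevanceNetwork(toyM(), 1.4), "threshold")
})
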