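test_that("diet proportions normalize internal inflow, excluding imports", {
  f <- matrix(0, 3, 3, dimnames = rep(list(c("b1", "b2", "c")), 2))
  f[1, 3] <- 3
  f[2, 3] <- 1
  net <- flow_network(c("b1", "b2", "c"),
                      c("producer", "detritus", "consumer"),
                      biomass = rep(1, 3), imports = c(3, 1, 5),
                      exports = c(0, 0, 4), respiration = c(0, 0, 5),
                      flows = f)
  p <- diet_proportions(net)
  expect_equal(p["b1", "c"], 0.75)
  expect_equal(p["b2", "c"], 0.25)
  expect_equal(sum(p[, "c"]), 1)      # columns with inflow sum to exactly 1
  expect_equal(unname(p[, "b1"]), rep(0, 3))  # import-only column is zero
})

test_that("reliance follows hand-worked diet recursions", {
  # chain b -> h -> p: everything traces to b
  f <- matrix(0, 3, 3)
  f[1, 2] <- 2; f[2, 3] <- 1
  net <- flow_network(c("b", "h", "p"), c("detritus", "consumer", "consumer"),
                      rep(1, 3), c(2, 0, 0), c(0, 0.5, 0.5), c(0, 0.5, 0.5),
                      flows = f)
  br <- basal_reliance(net)
  expect_equal(unname(br["p", "b"]), 1)

  # b1->a=1, b2->a=1, a->c=0.5, b1->c=0.5  =>  c relies (0.75, 0.25)
  f <- matrix(0, 4, 4)
  rownames(f) <- colnames(f) <- c("b1", "b2", "a", "c")
  f["b1", "a"] <- 1; f["b2", "a"] <- 1; f["a", "c"] <- 0.5; f["b1", "c"] <- 0.5
  net2 <- flow_network(colnames(f),
                       c("producer", "producer", "consumer", "consumer"),
                       rep(1, 4), c(1.5, 1, 0, 0), rep(0.2, 4), rep(0.2, 4),
                       flows = f)
  br2 <- basal_reliance(net2)
  expect_equal(unname(br2["c", ]), c(0.75, 0.25), tolerance = 1e-12)

  # consumer loop x<->y fed only by b: both rely fully on b
  f <- matrix(0, 3, 3)
  rownames(f) <- colnames(f) <- c("b", "x", "y")
  f["b", "x"] <- 0.5; f["x", "y"] <- 1; f["y", "x"] <- 0.5
  net3 <- flow_network(colnames(f), c("detritus", "consumer", "consumer"),
                       rep(1, 3), c(0.5, 0, 0), c(0, 0.1, 0.1),
                       c(0, 0.2, 0.2), flows = f)
  br3 <- basal_reliance(net3)
  expect_equal(unname(br3["x", "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(br3["y", "b"]), 1, tolerance = 1e-12)
})

test_that("linear solve agrees with the fixed-point oracle on random webs", {
  for (seed in 1:50) {
    s <- sample(6:30, 1)
    net <- random_web(s = s, n_basal = sample(2:4, 1), seed = seed)
    br <- basal_reliance(net)
    oracle <- br_fixed_point(net)
    expect_lt(max(abs(unclass(br) - oracle)), 1e-9)
    expect_true(all(abs(rowSums(br) - 1) < 1e-9))   # conservation
  }
})

test_that("node order permutation permutes reliance rows and columns", {
  net <- random_web(s = 10, n_basal = 3, seed = 99)
  br <- basal_reliance(net)
  perm <- c(4, 1, 7, 2, 9, 3, 10, 5, 8, 6)
  net2 <- flow_network(net$node_ids[perm], net$category[perm],
                       net$biomass[perm], net$imports[perm],
                       net$exports[perm], net$respiration[perm],
                       net$flows[perm, perm])
  br2 <- basal_reliance(net2)
  plain <- function(x) matrix(as.numeric(x), nrow(x), ncol(x),
                              dimnames = dimnames(x))
  expect_equal(plain(br2)[rownames(br), colnames(br)], plain(br),
               tolerance = 1e-12)
})

test_that("dominant-source grouping handles ties and unreachable nodes", {
  # c relies (0.75, 0.25) -> joins b1's subgroup; exact tie joins b1 (first)
  f <- matrix(0, 4, 4)
  rownames(f) <- colnames(f) <- c("b1", "b2", "c", "t")
  f["b1", "c"] <- 3; f["b2", "c"] <- 1
  f["b1", "t"] <- 1; f["b2", "t"] <- 1
  net <- flow_network(colnames(f),
                      c("detritus", "detritus", "consumer", "consumer"),
                      rep(1, 4), c(4, 2, 0, 0), rep(0.2, 4), rep(0.2, 4),
                      flows = f)
  g <- dominant_source_groups(basal_reliance(net))
  expect_equal(unname(g$membership[c("b1", "b2")]), c(1, 2))
  expect_equal(unname(g$membership["c"]), 1)
  expect_equal(unname(g$membership["t"]), 1)   # tie -> lowest basal index

  # import-fed node with no internal inflow is unreachable -> singleton
  f2 <- matrix(0, 3, 3)
  f2[1, 2] <- 1
  net2 <- flow_network(c("b", "c", "iso"),
                       c("producer", "consumer", "consumer"),
                       rep(1, 3), c(1, 0, 1), c(0, 0.5, 0.5),
                       c(0, 0.5, 0.5), flows = f2)
  br2 <- basal_reliance(net2)
  expect_true(attr(br2, "unreachable")[["iso"]])
  g2 <- dominant_source_groups(br2)
  expect_equal(length(unique(g2$membership)), 2)
  expect_equal(sum(g2$membership == g2$membership[["iso"]]), 1)
})

test_that("imports can be counted as a pseudo-basal source", {
  f <- matrix(0, 2, 2)
  f[1, 2] <- 1
  net <- flow_network(c("b", "c"), c("producer", "consumer"),
                      c(1, 1), c(1, 3), c(0, 2), c(0, 2), flows = f)
  br <- basal_reliance(net, imports_as_source = TRUE)
  expect_equal(unname(br["c", "b"]), 0.25)
  expect_equal(unname(br["c", "@import"]), 0.75)
})
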