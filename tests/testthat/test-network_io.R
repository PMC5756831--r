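test_that("flow networks are built from node and edge tables", {
  nd <- tempfile(fileext = ".tsv")
  ed <- tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tcategory\tbiomass\timport\texport\trespiration",
               "b\tbasal\tproducer\t2\t1\t0\t0",
               "c\tcons\tconsumer\t1\t0\t0.3\t0.7"), nd)
  writeLines(c("source\ttarget\tflux", "b\tc\t1.0"), ed)
  net <- read_flow_network(nd, ed)
  expect_s3_class(net, "flow_network")
  expect_identical(unname(net$flows), matrix(c(0, 0, 1, 0), 2, 2))
  expect_identical(net$category, c("producer", "consumer"))

  writeLines(c("source\ttarget\tflux", "b\tx\t1.0"), ed)
  expect_error(read_flow_network(nd, ed), "unknown node id")
  writeLines(c("source\ttarget\tflux", "b\tc\t-1.0"), ed)
  expect_error(read_flow_network(nd, ed), "negative flux")
  writeLines(c("source\ttarget\tflux", "b\tc\t1.0", "b\tc\t2.0"), ed)
  expect_error(read_flow_network(nd, ed), "\\(b, c\\)")
})

test_that("construction guards reject malformed networks", {
  f <- matrix(0, 2, 2)
  expect_error(flow_network(c("a", "a"), c("producer", "consumer"),
                            c(1, 1), c(0, 0), c(0, 0), c(0, 0), f),
               "duplicate")
  expect_error(flow_network(c("a", "b"), c("consumer", "consumer"),
                            c(1, 1), c(0, 0), c(0, 0), c(0, 0), f),
               "basal")
  expect_error(flow_network(c("a", "b"), c("producer", "consumer"),
                            c(-1, 1), c(0, 0), c(0, 0), c(0, 0), f),
               "non-negative")
})

test_that("TSV and JSON round trips reproduce the network exactly", {
  pw <- generate_planted_web(channels = 2, per_channel = 5, levels = 3,
                             eps = 0.1, seed = 3)
  nd <- tempfile(); ed <- tempfile(); js <- tempfile(fileext = ".json")
  write_flow_network(pw$net, nd, ed)
  back <- read_flow_network(nd, ed)
  expect_equal(back$flows, pw$net$flows, tolerance = 1e-12)
  expect_identical(back$category, pw$net$category)
  expect_equal(back$imports, pw$net$imports, tolerance = 1e-12)

  write_flow_json(pw$net, js)
  back2 <- read_flow_json(js)
  expect_equal(back2$flows, pw$net$flows, tolerance = 1e-12)
  expect_equal(back2$respiration, pw$net$respiration, tolerance = 1e-12)
  expect_identical(back2$category, pw$net$category)
})

test_that("validation reports residuals and structural warnings", {
  net <- toy_chain()
  v <- validate_network(net)
  expect_true(v$balanced)
  expect_equal(unname(v$residual), c(0, 0))

  # inflating one node's import by 10% shows up as exactly that residual
  net$imports[1] <- net$imports[1] * 1.1
  v2 <- validate_network(net)
  expect_false(v2$balanced)
  expect_equal(unname(v2$residual[1]), 0.1)

  f <- matrix(c(0.5, 0, 1, 0), 2, 2)  # self-loop on node 1
  net3 <- flow_network(c("b", "c"), c("detritus", "consumer"),
                       c(1, 0), c(1.5, 0), c(0, 1), c(0, 0), f)
  v3 <- validate_network(net3)
  expect_match(paste(v3$warnings, collapse = "; "), "self-loop")
  expect_match(paste(v3$warnings, collapse = "; "), "zero-biomass")
})

test_that("generated planted webs are balanced by construction", {
  for (seed in 1:5) {
    pw <- generate_planted_web(channels = 3, per_channel = 6, levels = 3,
                               eps = 0.2, seed = seed)
    v <- validate_network(pw$net, tol = 1e-9)
    expect_true(v$balanced)
  }
})
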