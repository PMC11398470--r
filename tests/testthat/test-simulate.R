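test_that("library simulation honors size, barcode-count and uniqueness
           contracts, deterministically", {
  cfg <- simConfig(n_constructs = 1, n_nontargeting = 0,
                   mean_barcodes_per_construct = 1, seed = 61)
  t1 <- simulateLibrary(cfg)
  # a single construct with one pair carries exactly two barcodes
  expect_gte(nrow(t1@library), 1L)
  expect_equal(length(unique(c(t1@library$bc_red, t1@library$bc_ir))),
               2L * nrow(t1@library))

  # empirical mean barcode pairs per construct near the configured mean
  cfg <- simConfig(seed = 62)
  t2 <- simulateLibrary(cfg)
  pairs_per <- table(t2@library$construct_id)
  expect_equal(mean(pairs_per), 8, tolerance = 0.5 / 8)
  expect_equal(sum(t2@library$negative_control),
               sum(pairs_per[sprintf("C%06d", 1901:2000)]))

  # same seed, same library; different seed, different library
  t3 <- simulateLibrary(cfg)
  expect_identical(as.data.frame(t2@library), as.data.frame(t3@library))
  t4 <- simulateLibrary(simConfig(seed = 63))
  expect_false(identical(t2@library$bc_red[1], t4@library$bc_red[1]))
})

test_that("invalid configurations are refused", {
  expect_error(simConfig(n_constructs = 10, seed = 1,
                         substitution_error_rate = 1.5))
  expect_error(simConfig(n_constructs = 10))        # seed mandatory
  expect_error(simConfig(n_constructs = 10, n_nontargeting = 11, seed = 1))
  expect_error(simConfig(n_constructs = 5, n_nontargeting = 0,
                         barcode_len = 2, seed = 1),
               "barcode space")
})

test_that("long-read simulation is seed-deterministic and invertible at
           zero error", {
  truth <- simulateLibrary(simConfig(n_constructs = 10, n_nontargeting = 1,
                                     seed = 64))
  r1 <- simulateLongReads(truth, readsPerPair = 2, errorRate = 0)
  r2 <- simulateLongReads(truth, readsPerPair = 2, errorRate = 0)
  expect_identical(r1, r2)

  p <- parseLongReads(r1)
  expect_true(all(is.na(p$reason)))
  got <- unique(paste(p$bc_red, p$bc_ir, p$guide_key))
  want <- paste(truth@library$bc_red, truth@library$bc_ir,
                truth@library$guide_key)
  expect_setequal(got, want)
  expect_setequal(unique(p$orientation),
                  c("forward", "reverse-complement"))
})

test_that("screen FASTQ emission is byte-identical under a fixed seed", {
  cfg <- simConfig(n_constructs = 5, n_nontargeting = 1, depth = 1500,
                   seed = 65)
  d1 <- tempfile("a"); d2 <- tempfile("b")
  t1 <- simulateScreen(simulateLibrary(cfg), conditions = "c",
                       nReplicates = 1, emitFastq = TRUE, dir = d1)
  t2 <- simulateScreen(simulateLibrary(cfg), conditions = "c",
                       nReplicates = 1, emitFastq = TRUE, dir = d2)
  f1 <- metadata(t1@libraries)$manifest$fastq_path
  f2 <- metadata(t2@libraries)$manifest$fastq_path
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  expect_identical(t1@counts, t2@counts)
})

test_that("planted effects scale the red channel as 2^effect", {
  cid <- sprintf("C%06d", 1:10)
  cfg <- simConfig(n_constructs = 40, n_nontargeting = 4, depth = 4e5,
                   dispersion = 0.01, baseline_bias_sd = 0,
                   effects = list(trt = setNames(rep(-2, 10), cid)),
                   seed = 66)
  truth <- simulateScreen(simulateLibrary(cfg),
                          conditions = c("ctrl", "trt"), nReplicates = 3)
  lib <- truth@library
  cd <- as.data.frame(truth@libraries)
  red_trt <- rownames(cd)[cd$channel == "red" & cd$condition == "trt"]
  red_ctrl <- rownames(cd)[cd$channel == "red" & cd$condition == "ctrl"]
  planted <- lib$bc_red[lib$construct_id %in% cid]
  others <- lib$bc_red[!lib$construct_id %in% cid]
  ratio <- function(bcs)
    sum(truth@counts[bcs, red_trt]) / sum(truth@counts[bcs, red_ctrl])
  expect_equal(log2(ratio(planted)), -2, tolerance = 0.15)
  expect_equal(log2(ratio(others)), 0, tolerance = 0.15)
  # ir channel untouched
  ir_trt <- rownames(cd)[cd$channel == "ir" & cd$condition == "trt"]
  ir_ctrl <- rownames(cd)[cd$channel == "ir" & cd$condition == "ctrl"]
  planted_ir <- lib$bc_ir[lib$construct_id %in% cid]
  expect_equal(log2(sum(truth@counts[planted_ir, ir_trt]) /
                      sum(truth@counts[planted_ir, ir_ctrl])),
               0, tolerance = 0.15)
})

test_that("baseline bias scales red vs ir as 2^beta0 in expectation", {
  cfg <- simConfig(n_constructs = 30, n_nontargeting = 3, depth = 1e6,
                   dispersion = 0.005, baseline_bias_sd = 0.5, seed = 67)
  truth <- simulateScreen(simulateLibrary(cfg), conditions = "c",
                          nReplicates = 2)
  lib <- truth@library
  cd <- as.data.frame(truth@libraries)
  red <- rownames(cd)[cd$channel == "red"]
  ir <- rownames(cd)[cd$channel == "ir"]
  obs <- log2(rowSums(truth@counts[lib$bc_red, red]) /
                rowSums(truth@counts[lib$bc_ir, ir]))
  b0 <- truth@baseline[paste(lib$bc_red, lib$bc_ir, sep = "|")]
  expect_gt(cor(obs, b0), 0.95)
})
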