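man2 <- data.frame(sample_id = c("s1", "s2"), condition = "a",
                   replicate = c("1", "2"), channel = "red")

test_that("tabulation takes the barcode union with zeros for absences", {
  # single cell
  m1 <- tabulateCounts(list(s1.red = DataFrame(barcode = "AAA",
                                               molecules = 5L)),
                       man2[1, ])
  expect_equal(unname(assay(m1, "counts")[1, 1]), 5L)

  # union semantics across two libraries
  cl <- list(s1.red = DataFrame(barcode = "AAA", molecules = 5L),
             s2.red = DataFrame(barcode = "CCC", molecules = 3L))
  m <- tabulateCounts(cl, man2)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(as.vector(assay(m, "counts")),
               c(5L, 0L, 0L, 3L))  # column-major, rows sorted AAA, CCC

  # duplicate (sample, channel) is a manifest error
  bad <- rbind(man2[1, ], man2[1, ])
  expect_error(tabulateCounts(cl[c(1, 1)], bad), "duplicate")
})

test_that("tabulated matrix equals simulator truth at zero error", {
  cfg <- simConfig(n_constructs = 12, n_nontargeting = 1, depth = 4000,
                   substitution_error_rate = 0, seed = 31)
  truth <- simulateScreen(simulateLibrary(cfg), conditions = c("a", "b"),
                          nReplicates = 2)
  tc <- truthCounts(truth)
  bcm <- tabulateCounts(tc, attr(tc, "manifest"))
  m <- assay(bcm, "counts")
  keep <- rowSums(truth@counts) > 0
  expect_equal(m, truth@counts[keep, , drop = FALSE][rownames(m), ])
})

test_that("the abundance filter keeps mean exactly at threshold and is
           idempotent", {
  man4 <- data.frame(sample_id = paste0("s", 1:4), condition = "a",
                     replicate = as.character(1:4), channel = "red")
  cl <- lapply(1:4, function(j)
    DataFrame(barcode = c("AAA", "CCC", "GGG"),
              molecules = c(32L, 31L, 0L)))
  names(cl) <- paste0("s", 1:4, ".red")
  bcm <- tabulateCounts(cl, man4)
  f <- filterLowAbundance(bcm, minMean = 32)
  expect_equal(rownames(f), "AAA")       # mean 32 kept, 31 and 0 dropped
  f2 <- filterLowAbundance(f, minMean = 32)
  expect_equal(assay(f2, "counts"), assay(f, "counts"))
  # removed counts are ledgered
  expect_equal(unname(metadata(f)$filtered_colsums),
               rep(31, 4))
})

test_that("filter survivors equal a brute-force row-mean check on a random
           matrix", {
  set.seed(32)
  man6 <- data.frame(sample_id = rep(paste0("s", 1:3), 2),
                     condition = "a", replicate = rep(as.character(1:3), 2),
                     channel = rep(c("red", "ir"), each = 3))
  bcs <- sort(random_dna_vec(50, 8))
  cl <- lapply(1:6, function(j)
    DataFrame(barcode = bcs, molecules = rpois(50, 40)))
  names(cl) <- paste(man6$sample_id, man6$channel, sep = ".")
  bcm <- tabulateCounts(cl, man6)
  f <- filterLowAbundance(bcm, minMean = 32)
  want <- rownames(bcm)[apply(assay(bcm, "counts"), 1, mean) >= 32]
  expect_setequal(rownames(f), want)
})

test_that("matching annotates, reports unmatched, flags channel conflicts;
           aggregation sums exactly", {
  truth <- simulateScreen(simulateLibrary(
    simConfig(n_constructs = 10, n_nontargeting = 1, depth = 4000,
              seed = 33)), conditions = c("a", "b"), nReplicates = 2)
  tc <- truthCounts(truth)
  bcm <- tabulateCounts(tc, attr(tc, "manifest"))
  lk <- truthLookup(truth)
  ann <- matchToConstructs(bcm, lk)
  rd <- rowData(ann)
  expect_true(all(!is.na(rd$construct_id)))      # zero-error: 100% matched
  expect_equal(length(metadata(ann)$unmatched), 0L)
  expect_true(!any(rd$channel_conflict))

  ccm <- aggregateByConstruct(ann)
  # brute-force grouped sums
  m <- assay(ann, "counts")
  for (i in sample(nrow(ccm), 5)) {
    cid <- rowData(ccm)$construct_id[i]
    ch <- rowData(ccm)$channel[i]
    members <- rownames(ann)[rd$construct_id == cid & rd$channel == ch]
    expect_equal(assay(ccm, "counts")[i, ],
                 colSums(m[members, , drop = FALSE]))
    expect_equal(rowData(ccm)$barcode_n[i], length(members))
  }

  # a foreign barcode lands in the unmatched report
  cl <- tc
  cl[[1]] <- rbind(cl[[1]], DataFrame(barcode = strrep("A", 25),
                                      molecules = 50L))
  bcm2 <- matchToConstructs(tabulateCounts(cl, attr(tc, "manifest")), lk)
  expect_equal(metadata(bcm2)$unmatched, strrep("A", 25))
  ccm2 <- aggregateByConstruct(bcm2)
  expect_false(strrep("A", 25) %in% rowData(ccm2)$construct_id)

  # conservation: construct sums + unmatched + filtered = raw column sums
  led <- conservationLedger(bcm2, bcm2, ccm2)
  expect_true(attr(led, "balanced"))
})

test_that("pair-level reshaping picks the matching channel per column", {
  truth <- simulateScreen(simulateLibrary(
    simConfig(n_constructs = 8, n_nontargeting = 1, depth = 4000,
              seed = 34)), conditions = "a", nReplicates = 2)
  tc <- truthCounts(truth)
  bcm <- matchToConstructs(tabulateCounts(tc, attr(tc, "manifest")),
                           truthLookup(truth))
  ccm <- aggregateByConstruct(bcm)
  pm <- channelPairMatrix(ccm)
  cidx <- colData(pm)$channel
  for (i in seq_len(nrow(pm))) {
    cid <- rownames(pm)[i]
    for (ch in c("red", "ir")) {
      row <- which(rowData(ccm)$construct_id == cid &
                     rowData(ccm)$channel == ch)
      expect_equal(assay(pm)[i, cidx == ch],
                   assay(ccm)[row, cidx == ch])
    }
  }
  bp <- barcodePairMatrix(bcm)
  rd <- rowData(bcm)
  i <- 1L
  pair <- rownames(bp)[i]
  red_bc <- sub("\\|.*", "", pair)
  expect_equal(unname(assay(bp)[i, cidx == "red"]),
               unname(assay(bcm)[red_bc, cidx == "red"]))
})
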