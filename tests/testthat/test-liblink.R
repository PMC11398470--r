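lay <- longReadLayout()

make_read <- function(bc_red, bc_ir, gA, gB, lay) {
  paste0("GG", lay@anchor_up_red, bc_red, lay@anchor_down_red, "TT",
         lay@anchor_guide_up, gA, gB, lay@anchor_guide_down, "AA",
         lay@anchor_up_ir, bc_ir, lay@anchor_down_ir, "CC")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

test_that("exact-layout reads parse on both strands", {
  set.seed(1)
  bc1 <- random_dna_vec(1, 25); bc2 <- random_dna_vec(1, 25)
  gA <- random_dna_vec(1, 20); gB <- random_dna_vec(1, 20)
  read <- make_read(bc1, bc2, gA, gB, lay)

  p <- parseLongReads(c(read, revcomp_chr(read)), lay)
  expect_true(all(is.na(p$reason)))
  expect_equal(p$bc_red, rep(bc1, 2))
  expect_equal(p$bc_ir, rep(bc2, 2))
  expect_equal(p$guide_key, rep(paste0(gA, "|", gB), 2))
  expect_equal(p$orientation, c("forward", "reverse-complement"))
})

test_that("anchor substitutions within budget are tolerated, and the
           match position agrees with an exhaustive Hamming scan", {
  set.seed(2)
  bc1 <- random_dna_vec(1, 25); bc2 <- random_dna_vec(1, 25)
  gA <- random_dna_vec(1, 20); gB <- random_dna_vec(1, 20)
  read <- make_read(bc1, bc2, gA, gB, lay)

  # mutate up to 2 bases of anchor_up_red at random positions
  for (nmut in 1:2) {
    r <- read
    pos <- 2L + sample(nchar(lay@anchor_up_red), nmut)
    for (k in pos) {
      old <- substr(r, k, k)
      substr(r, k, k) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    p <- parseLongReads(r, lay)
    expect_true(is.na(p$reason[1]))
    expect_equal(p$bc_red[1], bc1)
    # oracle: sliding-window Hamming scan finds the same anchor offset
    expect_equal(oracle_scan(r, lay@anchor_up_red, 2L), 3L)
  }

  # 3 substitutions exceed the default budget of 2
  r <- read
  for (k in 2L + 1:3) {
    old <- substr(r, k, k)
    substr(r, k, k) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(parseLongReads(r, lay)$reason[1], "anchor_missing")
})

test_that("no-parse reasons are specific", {
  set.seed(3)
  bc1 <- random_dna_vec(1, 25); bc2 <- random_dna_vec(1, 25)
  gA <- random_dna_vec(1, 20); gB <- random_dna_vec(1, 20)

  # wrong barcode length between the red anchors
  bad_len <- paste0("GG", lay@anchor_up_red, substr(bc1, 1, 24),
                    lay@anchor_down_red, "TT", lay@anchor_guide_up, gA, gB,
                    lay@anchor_guide_down, "AA", lay@anchor_up_ir, bc2,
                    lay@anchor_down_ir)
  expect_equal(parseLongReads(bad_len, lay)$reason[1], "length_mismatch")

  # N inside a barcode
  bcN <- paste0("N", substr(bc1, 2, 25))
  withN <- make_read(bcN, bc2, gA, gB, lay)
  expect_equal(parseLongReads(withN, lay)$reason[1], "ambiguous_base")

  # non-nucleotide character is an input error, not a no-parse
  expect_error(parseLongReads("ACGTX", lay), "outside")
})

test_that("buildLookup applies majority, support and purity rules", {
  set.seed(4)
  bcs <- random_dna_vec(6, 25)
  # distinct cassette keys, far beyond the error-merge tolerance
  K1 <- strrep("AC", 10); K2 <- strrep("GT", 10)
  mk <- function(bc_red, bc_ir, guide, n)
    DataFrame(bc_red = rep(bc_red, n), bc_ir = rep(bc_ir, n),
              guide_key = rep(guide, n), orientation = "forward",
              reason = NA_character_)

  # single construct, 3 error-free reads
  lk <- buildLookup(mk(bcs[1], bcs[2], K1, 3), minSupport = 3)
  e <- lookupEntries(lk)
  expect_equal(nrow(e), 1L)
  expect_equal(e$support, 3L)
  expect_equal(e$purity, 1)

  # majority 5:1 passes purity 0.8 (5/6 ~ 0.833)
  p <- rbind(mk(bcs[1], bcs[2], K1, 5), mk(bcs[1], bcs[2], K2, 1))
  e <- lookupEntries(buildLookup(p, minSupport = 3, minPurity = 0.8))
  expect_equal(e$guide_key, K1)
  expect_equal(e$purity, 5 / 6)

  # 3:2 fails purity 0.8 (0.6) and is reported as low_purity
  p <- rbind(mk(bcs[1], bcs[2], K1, 3), mk(bcs[1], bcs[2], K2, 2))
  lk <- buildLookup(p, minSupport = 3, minPurity = 0.8)
  expect_equal(nrow(lookupEntries(lk)), 0L)
  expect_equal(discardReport(lk)$category, "low_purity")
  expect_equal(discardReport(lk)$purity, 0.6)

  # support below threshold
  lk <- buildLookup(mk(bcs[1], bcs[2], K1, 2), minSupport = 3)
  expect_equal(discardReport(lk)$category, "low_support")

  # a barcode linked to two constructs is a collision: both links removed
  p <- rbind(mk(bcs[1], bcs[2], K1, 5), mk(bcs[1], bcs[3], K2, 5))
  lk <- buildLookup(p, minSupport = 3)
  expect_equal(nrow(lookupEntries(lk)), 0L)
  expect_setequal(discardReport(lk)$category, "barcode_collision")

  # empty stream gives an empty table, not an error
  lk <- buildLookup(DataFrame(bc_red = character(0), bc_ir = character(0),
                              guide_key = character(0),
                              orientation = character(0),
                              reason = character(0)))
  expect_equal(nrow(lookupEntries(lk)), 0L)
})

test_that("parsed reads are conserved between entries and discards", {
  truth <- simulateLibrary(simConfig(n_constructs = 25, n_nontargeting = 2,
                                     seed = 5))
  reads <- simulateLongReads(truth, readsPerPair = 4, errorRate = 0.01)
  parsed <- parseLongReads(reads)
  lk <- buildLookup(parsed, minSupport = 3, minPurity = 0.9)
  n_parsed <- sum(is.na(parsed$reason))
  expect_equal(sum(lookupEntries(lk)$support) +
                 sum(discardReport(lk)$support), n_parsed)
})

test_that("error-free simulated long reads reconstruct the library exactly", {
  truth <- simulateLibrary(simConfig(n_constructs = 60, n_nontargeting = 5,
                                     seed = 6))
  reads <- simulateLongReads(truth, readsPerPair = 3, errorRate = 0)
  lk <- buildLookup(parseLongReads(reads), minSupport = 3)
  got <- as.data.frame(lookupEntries(lk)[, c("guide_key", "bc_red", "bc_ir")])
  want <- as.data.frame(lookupEntries(truthLookup(truth))[,
            c("guide_key", "bc_red", "bc_ir")])
  expect_equal(got, want)
  expect_equal(nrow(discardReport(lk)), 0L)
})

test_that("at 1% read error no link is ever mis-assigned", {
  truth <- simulateLibrary(simConfig(n_constructs = 100, n_nontargeting = 5,
                                     seed = 7))
  reads <- simulateLongReads(truth, readsPerPair = 5, errorRate = 0.01)
  lk <- buildLookup(parseLongReads(reads), minSupport = 3, minPurity = 0.9)
  e <- lookupEntries(lk)
  tr <- lookupEntries(truthLookup(truth))
  truth_by_pair <- setNames(tr$guide_key, paste(tr$bc_red, tr$bc_ir))
  got_pairs <- paste(e$bc_red, e$bc_ir)
  known <- got_pairs %in% names(truth_by_pair)
  # barcodes may be dropped, never relinked
  expect_true(all(e$guide_key[known] == truth_by_pair[got_pairs[known]]))
  # error-bearing pairs that sneak in must be rare singleton artifacts
  expect_gt(mean(known), 0.95)
  # >= 99% of constructs keep at least one link
  rec <- unique(tr$construct_id[paste(tr$bc_red, tr$bc_ir) %in%
                                  got_pairs[known]])
  expect_gte(length(rec), 99L)
})

test_that("lookup TSV round trip is the identity and rejects corrupt files", {
  # empty table round trip
  p <- tempfile(fileext = ".tsv")
  empty <- buildLookup(DataFrame(bc_red = character(0),
                                 bc_ir = character(0),
                                 guide_key = character(0),
                                 orientation = character(0),
                                 reason = character(0)))
  writeLookup(empty, p)
  expect_equal(nrow(lookupEntries(readLookup(p))), 0L)

  # simulated table round trip
  truth <- simulateLibrary(simConfig(n_constructs = 30, n_nontargeting = 3,
                                     seed = 8))
  reads <- simulateLongReads(truth, readsPerPair = 4, errorRate = 0.005)
  lk <- buildLookup(parseLongReads(reads))
  writeLookup(lk, p)
  back <- readLookup(p)
  expect_equal(as.data.frame(lookupEntries(back)),
               as.data.frame(lookupEntries(lk)))

  # duplicated barcode in the file is rejected with the line number
  e <- as.data.frame(lookupEntries(lk))
  e$negative_control <- FALSE
  e$bc_red[2] <- e$bc_red[1]
  write.table(e, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readLookup(p), "more than one row")

  # wrong column set is rejected
  write.table(e[, 1:3], p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readLookup(p), "columns")
})
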