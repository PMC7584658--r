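test_that("SEG reader ingests, sorts, maps labels and tolerates dialects", {
  f <- tempfile(fileext = ".seg")
  writeLines(c(
    "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
    "S2\tchr2\t100\t5000\t12\t0.1",
    "S1\tchr1\t2000\t9000\t40\t-0.5",
    "S1\tchr1\t1\t1999\t10\t0.0"
  ), f)
  segs <- read_seg(f, labels = c(S1 = "BRCA", S2 = "PRAD"))
  expect_equal(nrow(segs), 3)
  expect_equal(segs$sample, c("S1", "S1", "S2"))
  expect_equal(segs$start, c(1, 2000, 100))
  expect_equal(segs$chrom, c("1", "1", "2"))  # chr prefix stripped
  expect_equal(segs$cancer_type, c("BRCA", "BRCA", "PRAD"))

  # same records through a shuffled, differently-spelled header
  g <- tempfile(fileext = ".seg")
  writeLines(c(
    "seg.mean\tloc.end\tID\tnum.mark\tchrom\tloc.start",
    "0.1\t5000\tS2\t12\t2\t100",
    "-0.5\t9000\tS1\t40\tchr1\t2000",
    "0.0\t1999\tS1\t10\t1\t1"
  ), g)
  segs2 <- read_seg(g, labels = c(S1 = "BRCA", S2 = "PRAD"))
  expect_equal(segs2, segs)
})

test_that("SEG reader drops non-finite means and rejects bad records", {
  f <- tempfile(fileext = ".seg")
  writeLines(c(
    "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
    "S1\t1\t1\t1000\t10\tNA",
    "S1\t1\t1001\t2000\t10\t0.2"
  ), f)
  expect_message(segs <- read_seg(f), "1 segment")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$seg_mean, 0.2)

  # missing mandatory column is named
  h <- tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes",
               "S1\t1\t1\t1000\t10"), h)
  expect_error(read_seg(h), "segment mean")

  # inverted coordinates carry the line number
  b <- tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
               "S1\t1\t5000\t1000\t10\t0.2"), b)
  expect_error(read_seg(b), "line 2")
})

test_that("state classification matches the five-bin definition everywhere", {
  # anchor values, including each bin boundary
  expect_equal(as.character(classify_state(-1.5)), "HOMDEL")
  expect_equal(as.character(classify_state(-1)), "HEMIDEL")
  expect_equal(as.character(classify_state(-0.2)), "NEUTRAL")
  expect_equal(as.character(classify_state(0)), "NEUTRAL")
  expect_equal(as.character(classify_state(0.3)), "GAIN")
  expect_equal(as.character(classify_state(0.7)), "AMP")

  # totality and exclusivity against the inequality oracle
  set.seed(101)
  x <- c(runif(2000, -4, 4), -1, -0.2, 0.3, 0.7)
  got <- classify_state(x)
  expect_false(any(is.na(got)))
  expect_equal(as.character(got), oracle_classify(x))

  expect_error(classify_state(NaN), "finite")
  expect_error(classify_state(c(0, Inf)), "finite")
})

test_that("classification respects configurable thresholds", {
  cfg <- ps_config(homdel_max = -2, hemidel_max = -0.5, neutral_max = 0.2,
                   gain_max = 1)
  expect_equal(as.character(classify_state(c(-1.5, 0.25, 0.9), cfg)),
               c("HEMIDEL", "GAIN", "GAIN"))
  expect_error(ps_config(hemidel_max = -2, homdel_max = -1), "thresholds")
})

test_that("merging joins nearby same-state segments transitively", {
  # two hemizygous deletions 10 kb apart collapse into one
  segs <- segs_from_states(c("HEMIDEL", "HEMIDEL"), gaps = 1e4)
  m <- merge_segments(segs)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$end, segs$end[2])

  # different states never merge, even when touching
  segs <- segs_from_states(c("HEMIDEL", "NEUTRAL"), gaps = 0)
  expect_equal(nrow(merge_segments(segs)), 2)

  # a chain of three gains with gaps 0 and 50 kb collapses transitively
  segs <- segs_from_states(c("GAIN", "GAIN", "GAIN"), gaps = c(0, 5e4))
  expect_equal(nrow(merge_segments(segs)), 1)

  # gap at exactly merge_gap_max does not merge
  segs <- segs_from_states(c("GAIN", "GAIN"), gaps = 1e5)
  expect_equal(nrow(merge_segments(segs)), 2)

  # merged amplitude is the probe-weighted mean
  segs <- segs_from_states(c("HEMIDEL", "HEMIDEL"), gaps = 10)
  segs$num_probes <- c(10, 30)
  segs$seg_mean <- c(-0.4, -0.8)
  expect_equal(merge_segments(segs)$seg_mean, -0.7)
  segs$num_probes <- NA_real_
  expect_equal(merge_segments(segs)$seg_mean, -0.6)

  expect_error(
    merge_segments(segs_from_states(c("GAIN", "GAIN"), gaps = -5e5)),
    "overlapping"
  )
})

test_that("merging is idempotent and leaves no mergeable neighbours", {
  set.seed(7)
  cfg <- ps_config()
  for (rep in 1:30) {
    n <- sample(2:12, 1)
    states <- sample(state_levels, n, replace = TRUE)
    gaps <- sample(c(0, 1e3, 5e4, 2e5), n - 1, replace = TRUE)
    segs <- segs_from_states(states, gaps = gaps)
    m1 <- merge_segments(segs, cfg)
    m2 <- merge_segments(m1, cfg)
    expect_equal(m1, m2)
    if (nrow(m1) > 1) {
      gap <- m1$start[-1] - m1$end[-nrow(m1)] - 1
      same <- as.character(m1$state[-1]) ==
        as.character(m1$state[-nrow(m1)])
      expect_false(any(same & gap < cfg$merge_gap_max))
    }
  }
})

test_that("gap filtering removes segments flanking large no-data regions", {
  # 150 kb no-data region removes both neighbours
  segs <- segs_from_states(c("NEUTRAL", "HEMIDEL"), gaps = 1.5e5)
  expect_equal(nrow(filter_gap_adjacent(segs)), 0)

  # a gap of exactly the threshold is tolerated
  segs <- segs_from_states(c("NEUTRAL", "HEMIDEL"), gaps = 1e5)
  expect_equal(nrow(filter_gap_adjacent(segs)), 2)

  # contiguous tiling is untouched; interior gap removes only its flanks
  segs <- segs_from_states(c("NEUTRAL", "GAIN", "NEUTRAL"), gaps = 0)
  expect_equal(filter_gap_adjacent(segs), segs)
  segs <- segs_from_states(c("NEUTRAL", "GAIN", "NEUTRAL", "HEMIDEL"),
                           gaps = c(0, 2e5, 0))
  out <- filter_gap_adjacent(segs)
  expect_equal(as.character(out$state), c("NEUTRAL", "HEMIDEL"))

  # output rows are always a subset of the input rows
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    segs <- segs_from_states(sample(state_levels, n, replace = TRUE),
                             gaps = sample(c(0, 9e4, 1.1e5, 3e5),
                                           max(0, n - 1), replace = TRUE))
    out <- filter_gap_adjacent(segs)
    expect_true(all(out$start %in% segs$start))
  }
})

test_that("genome reference round-trips and enforces its invariants", {
  ref <- data.frame(chrom = c("1", "2"), length = c(1e8, 9e7),
                    cen_start = c(4.9e7, 4e7), cen_end = c(5.1e7, 4.5e7),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_genome_ref(ref, f)
  expect_equal(read_genome_ref(f), ref)

  bad <- ref
  bad$cen_end[1] <- 2e8
  g <- tempfile(fileext = ".tsv")
  write_genome_ref(bad, g)
  expect_error(read_genome_ref(g), "centromere")
})
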