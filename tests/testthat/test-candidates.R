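## A tiny deterministic world for the filter tests: one contig carrying the
## query itself plus diverged copies at known identities.
make_filter_fixture <- function() {
  set.seed(71)
  q <- random_rna(50)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  copies <- list(exact = q, near = mutate_at(q, 1), far = mutate_at(q, 15))
  pad <- function(n) random_rna(n)
  contig <- paste0(pad(30), copies$exact, pad(20), copies$near, pad(20),
                   copies$far, pad(30))
  list(query = tibble::tibble(id = "q", seq = q, taxid = 1L),
       targets = tibble::tibble(id = "c1", seq = contig, taxid = 1L),
       starts = c(exact = 30L, near = 100L, far = 170L))
}

hit_row <- function(contig, start, end, coverage, strand = "+") {
  tibble::tibble(query_id = "q", contig = contig, start = start, end = end,
                 strand = strand, score = 1, evalue = 0.5, coverage = coverage,
                 taxid = 1L)
}

test_that("coverage filtering is strictly greater than the threshold", {
  fx <- make_filter_fixture()
  cfg <- filter_config()
  far <- hit_row("c1", fx$starts["far"], fx$starts["far"] + 50L, 1.0)
  mk <- function(cov) {
    h <- far
    h$coverage <- cov
    h
  }
  hits <- dplyr::bind_rows(mk(0.79), mk(0.81), mk(0.80))
  out <- prefilter_hits(hits, fx$query, fx$query[0, ], cfg, fx$targets)
  expect_equal(out$coverage, 0.81)
})

test_that("hits nearly identical to the query or members are redundant", {
  fx <- make_filter_fixture()
  cfg <- filter_config()
  hits <- dplyr::bind_rows(
    hit_row("c1", fx$starts["exact"], fx$starts["exact"] + 50L, 1.0),
    hit_row("c1", fx$starts["near"], fx$starts["near"] + 50L, 1.0),
    hit_row("c1", fx$starts["far"], fx$starts["far"] + 50L, 1.0))
  out <- prefilter_hits(hits, fx$query, fx$query[0, ], cfg, fx$targets)
  ## exact (identity 1.0) and near (identity 0.98 < 0.99 -> kept)
  expect_equal(unname(out$start), unname(fx$starts[c("near", "far")]))
  ## with the near copy as an existing member, its locus and its twin drop
  members <- tibble::tibble(
    id = "m1", seq = extract_region(fx$targets[1, ], fx$starts["near"],
                                    fx$starts["near"] + 50L, "+")$seq,
    contig = "c1", start = fx$starts[["near"]], end = fx$starts[["near"]] + 50L)
  out2 <- prefilter_hits(hits, fx$query, members, cfg, fx$targets)
  expect_equal(unname(out2$start), unname(fx$starts["far"]))
})

test_that("prefilter is idempotent and preserves order", {
  fx <- make_filter_fixture()
  cfg <- filter_config()
  hits <- dplyr::bind_rows(
    hit_row("c1", fx$starts["far"], fx$starts["far"] + 50L, 0.5),
    hit_row("c1", fx$starts["far"], fx$starts["far"] + 50L, 0.85),
    hit_row("c1", fx$starts["near"], fx$starts["near"] + 50L, 1.0),
    hit_row("c1", fx$starts["far"], fx$starts["far"] + 50L, 0.81),
    hit_row("c1", fx$starts["far"], fx$starts["far"] + 50L, 0.80))
  once <- prefilter_hits(hits, fx$query, fx$query[0, ], cfg, fx$targets)
  expect_equal(once$coverage, c(0.85, 1.0, 0.81))
  twice <- prefilter_hits(once, fx$query, fx$query[0, ], cfg, fx$targets)
  expect_equal(twice, once)
})

test_that("the frozen ten-hit table yields the hand-computed survivor set", {
  ## Regression fixture: hits with stated coverages; hits 1 and 6 sit on the
  ## query's own copy (identity 1.0), hit 9 on the near-copy (identity 0.98).
  fx <- make_filter_fixture()
  cfg <- filter_config()
  st <- fx$starts
  hits <- dplyr::bind_rows(
    hit_row("c1", st["exact"], st["exact"] + 50L, 1.00),  # 1 redundant
    hit_row("c1", st["far"], st["far"] + 50L, 0.95),      # 2 keep
    hit_row("c1", st["far"], st["far"] + 50L, 0.80),      # 3 coverage
    hit_row("c1", st["far"], st["far"] + 50L, 0.79),      # 4 coverage
    hit_row("c1", st["far"], st["far"] + 50L, 1.00),      # 5 keep
    hit_row("c1", st["exact"], st["exact"] + 50L, 0.85),  # 6 redundant
    hit_row("c1", st["far"], st["far"] + 45L, 0.81),      # 7 keep
    hit_row("c1", st["far"], st["far"] + 50L, 0.50),      # 8 coverage
    hit_row("c1", st["near"], st["near"] + 50L, 0.99),    # 9 keep (0.98 < 0.99)
    hit_row("c1", st["far"], st["far"] + 50L, 0.81))      # 10 keep
  out <- prefilter_hits(hits, fx$query, fx$query[0, ], cfg, fx$targets)
  expect_equal(nrow(out), 5L)
  expect_equal(out$coverage, c(0.95, 1.00, 0.81, 0.99, 0.81))
  expect_equal(unname(out$start), unname(st[c("far", "far", "far", "near", "far")]))
})

test_that("flanking expansion clips to contig bounds", {
  targets <- tibble::tibble(id = "c", seq = random_rna(1000), taxid = 1L)
  cfg <- filter_config(flank_factor = 1.0)
  h <- hit_row("c", 100L, 150L, 1.0)
  expect_equal(unlist(expand_hit(h, 50L, cfg, targets)[, c("start", "end")],
                      use.names = FALSE), c(50L, 200L))
  h2 <- hit_row("c", 10L, 60L, 1.0)
  expect_equal(unlist(expand_hit(h2, 50L, cfg, targets)[, c("start", "end")],
                      use.names = FALSE), c(0L, 110L))
  cfg0 <- filter_config(flank_factor = 0)
  expect_equal(unlist(expand_hit(h, 50L, cfg0, targets)[, c("start", "end")],
                      use.names = FALSE), c(100L, 150L))
})

test_that("truncation recovers the exact core and never rejects", {
  input <- tibble::tibble(id = "in", seq = random_rna(60), taxid = NA_integer_)
  expanded <- tibble::tibble(id = "x", seq = paste0("NNN", input$seq, "NNN"),
                             taxid = 2L, contig = "c", start = 100L,
                             end = 166L, strand = "+")
  cand <- truncate_to_input(input, expanded)
  expect_equal(cand$seq, input$seq)
  expect_equal(cand$provenance$start, 103L)
  expect_equal(cand$provenance$end, 163L)
  ## zero-similarity expansion still yields a structural candidate
  junk <- tibble::tibble(id = "j", seq = strrep("A", 80), taxid = 2L,
                         contig = "c", start = 0L, end = 80L, strand = "+")
  cand2 <- truncate_to_input(tibble::tibble(id = "in", seq = strrep("C", 40)),
                             junk)
  expect_s3_class(cand2, "candidate")
  expect_false(isTRUE(cand2$scored))
  ## candidate is always a contiguous substring of the expansion
  expect_true(grepl(cand$seq, expanded$seq, fixed = TRUE))
})

test_that("minus-strand truncation maps provenance back to plus coordinates", {
  set.seed(73)
  contig <- tibble::tibble(id = "c", seq = random_rna(400), taxid = 5L)
  core <- extract_region(contig, 150, 210, "-")
  input <- tibble::tibble(id = "in", seq = core$seq)
  expanded <- extract_region(contig, 120, 240, "-")
  cand <- truncate_to_input(input, expanded)
  expect_equal(cand$seq, core$seq)
  expect_equal(cand$provenance$start, 150L)
  expect_equal(cand$provenance$end, 210L)
  expect_equal(cand$provenance$strand, "-")
})
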