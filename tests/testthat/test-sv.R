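block_row <- function(rc, rs, re, qc, qs, qe, strand = "+", id = 99) {
  data.frame(ref_chrom = rc, ref_start = rs, ref_end = re, query_chrom = qc,
             query_start = qs, query_end = qe, strand = strand,
             identity = id, aligned_length = qe - qs + 1,
             stringsAsFactors = FALSE)
}

test_that("block TSV parsing validates and sorts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(read_alignment_blocks(f)), 0L)
  b <- rbind(block_row("chr1", 1, 100, "q1", 201, 300),
             block_row("chr1", 101, 200, "q1", 1, 100),
             block_row("chr2", 1, 50, "q2", 1, 50))
  write_alignment_blocks(b, f)
  back <- read_alignment_blocks(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$query_start, c(1, 201, 1)) # sorted within query contig
  bad <- b; bad$ref_start[1] <- 1000
  write_alignment_blocks(bad, f)
  expect_error(read_alignment_blocks(f), "malformed block at line")
})

test_that("a single collinear block yields no calls", {
  b <- block_row("chr1", 1, 100000, "q1", 1, 100000)
  expect_equal(nrow(call_svs(b)), 0L)
})

test_that("an embedded minus-strand run is called as an inversion", {
  b <- rbind(block_row("chr1", 1, 100000, "q1", 1, 100000),
             block_row("chr1", 100001, 150000, "q1", 100001, 150000, "-"),
             block_row("chr1", 150001, 200000, "q1", 150001, 200000))
  svs <- call_svs(b)
  expect_equal(svs$kind, "inversion")
  expect_equal(svs$size, 50000L)
  expect_equal(svs$ref_start, 100001L)
})

test_that("majority rule assigns the primary chromosome", {
  b <- rbind(block_row("chr2", 1, 60000, "q2", 1, 60000),
             block_row("chr7", 10001, 50000, "q2", 60001, 100000))
  svs <- pair_reciprocal(call_svs(b))
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$kind, "nonreciprocal_translocation")
  expect_equal(svs$ref_chrom, "chr7")
  expect_equal(svs$size, 40000L)
  expect_equal(svs$query_primary, "chr2")
})

test_that("gap geometry separates deletions from insertions", {
  del <- rbind(block_row("chr1", 1, 10000, "q1", 1, 10000),
               block_row("chr1", 13001, 20000, "q1", 10001, 17000))
  sv_del <- call_svs(del)
  expect_equal(sv_del$kind, "deletion")
  expect_equal(sv_del$size, 3000L)
  ins <- rbind(block_row("chr1", 1, 10000, "q1", 1, 10000),
               block_row("chr1", 10001, 17000, "q1", 13001, 20000))
  sv_ins <- call_svs(ins)
  expect_equal(sv_ins$kind, "insertion")
  expect_equal(sv_ins$size, 3000L)
  # sub-threshold gaps are breakpoint fuzz, not events
  fuzz <- rbind(block_row("chr1", 1, 10000, "q1", 1, 10000),
                block_row("chr1", 10100, 20000, "q1", 10001, 19901))
  expect_equal(nrow(call_svs(fuzz, min_size = 200)), 0L)
})

test_that("duplicated query intervals over one reference interval", {
  b <- rbind(block_row("chr1", 1, 50000, "q1", 1, 50000),
             block_row("chr1", 20001, 30000, "q1", 50001, 60000))
  svs <- call_svs(b)
  expect_true("duplication" %in% svs$kind)
})

test_that("classification is invariant to block input order", {
  b <- rbind(block_row("chr1", 1, 100000, "q1", 1, 100000),
             block_row("chr1", 100001, 150000, "q1", 100001, 150000, "-"),
             block_row("chr1", 150001, 200000, "q1", 150001, 200000),
             block_row("chr2", 1, 30000, "q1", 200001, 230000))
  s1 <- call_svs(b)
  s2 <- call_svs(b[c(3, 1, 4, 2), ])
  expect_equal(s1, s2)
})

test_that("simulated exchanges are labelled reciprocal, one-way moves not", {
  g <- generate_ancestor(30000, 3, seed = 91)
  # reciprocal exchange between chrI and chrII
  rt <- apply_svs(g, sv_spec("reciprocal_translocation", "chrI", "chrII",
                             pos_a = 20000, pos_b = 12000))$genome
  svs <- pair_reciprocal(call_svs(genome_alignment_blocks(g, rt)))
  tr <- svs[grepl("translocation", svs$kind), ]
  expect_equal(sort(unique(tr$kind)), "reciprocal_translocation")
  expect_equal(nrow(tr), 2L)
  expect_equal(sort(tr$ref_chrom), c("chrI", "chrII"))
  expect_equal(tr$partner_id, rev(tr$id))
  # one-way move: nonreciprocal, and no deletion footprint double-call
  nr <- apply_svs(g, sv_spec("nonreciprocal_translocation", "chrI", "chrIII",
                             pos_a = 8000, size = 5000))$genome
  svs2 <- pair_reciprocal(call_svs(genome_alignment_blocks(g, nr)))
  expect_equal(svs2$kind[grepl("translocation", svs2$kind)],
               "nonreciprocal_translocation")
  expect_false("deletion" %in% svs2$kind)
  expect_equal(nrow(pair_reciprocal(call_svs(
    genome_alignment_blocks(g, g)))), 0L)
})

test_that("size and exclusion filters drop events as published", {
  svs <- rbind(
    data.frame(id = 1:3, kind = "deletion", ref_chrom = "chr1",
               ref_start = c(1000, 5000, 9000),
               ref_end = c(1499, 6499, 10999),
               query_chrom = "q1", query_start = 1, query_end = 1,
               size = c(500L, 1500L, 2000L), query_primary = "chr1",
               partner_id = NA_integer_, genes_overlapped = NA_integer_))
  expect_equal(filter_svs(svs, min_size = 1000)$size, c(1500L, 2000L))
  # exactly 1000 bp is not > 1 kb
  svs$size[1] <- 1000L
  expect_equal(nrow(filter_svs(svs, 1000)), 2L)
  rdna <- data.frame(chrom = "chr1", start = 4999, end = 6500) # BED-style
  expect_equal(filter_svs(svs, 1000, rdna)$size, 2000L)
})

test_that("gene overlap counts use the any-overlap rule", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1000, 3000, 5000, 9000),
                      end = c(1999, 3999, 5999, 9999),
                      id = paste0("g", 1:4))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  svs <- data.frame(id = 1:3, kind = "deletion", ref_chrom = "chr1",
                    ref_start = c(1000, 6500, 500),
                    ref_end = c(5999, 8000, 1000),
                    query_chrom = "q", query_start = 1, query_end = 1,
                    size = 1, query_primary = "chr1",
                    partner_id = NA_integer_, genes_overlapped = NA_integer_)
  ann <- annotate_genes(svs, f)
  # event 1 covers g1-g3; event 2 spans no gene; event 3 ends 1 bp inside g1
  expect_equal(ann$genes_overlapped, c(3L, 0L, 1L))
})

test_that("the rearrangement architecture is recovered at reduced scale", {
  for (s in 1:3) {
    g <- generate_ancestor(20000, 6, seed = 110 + s)
    chroms <- names(g)
    events <- list(
      sv_spec("reciprocal_translocation", chroms[1], chroms[2],
              pos_a = 14000, pos_b = 11000),
      sv_spec("nonreciprocal_translocation", chroms[3], chroms[4],
              pos_a = 6000, size = 2500),
      sv_spec("nonreciprocal_translocation", chroms[4], chroms[5],
              pos_a = 1000, size = 2000),
      sv_spec("inversion", chroms[5], pos_a = 8000, size = 3000),
      sv_spec("deletion", chroms[6], pos_a = 5000, size = 1500),
      sv_spec("deletion", chroms[6], pos_a = 12000, size = 500))
    mutated <- apply_svs(g, events)$genome
    blocks <- genome_alignment_blocks(g, mutated)
    svs <- filter_svs(pair_reciprocal(call_svs(blocks)), min_size = 1000)
    counts <- table(svs$kind)
    expect_equal(unname(counts["reciprocal_translocation"]), 2L)
    expect_equal(unname(counts["nonreciprocal_translocation"]), 2L)
    expect_equal(unname(counts["inversion"]), 1L)
    expect_equal(unname(counts["deletion"]), 1L) # the 500 bp event is gone
    inv <- svs[svs$kind == "inversion", ]
    expect_equal(inv$ref_chrom, chroms[5])
    expect_lt(abs(inv$size - 3000), 200)
    del <- svs[svs$kind == "deletion", ]
    expect_equal(del$ref_chrom, chroms[6])
    expect_lt(abs(del$size - 1500), 200)
  }
})
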