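test_that("basal windows follow the strand-aware 5 kb / 1 kb rule", {
  sizes <- c(chr1 = 3e6)
  plus <- compute_domains(data.frame(gene_id = "g", chrom = "chr1",
                                     tss = 100000, strand = "+"), sizes)
  expect_equal(c(plus$b_start, plus$b_end), c(95000, 101000))
  expect_equal(c(plus$e_start, plus$e_end), c(0, 1101000))  # clipped at 0
  minus <- compute_domains(data.frame(gene_id = "g", chrom = "chr1",
                                      tss = 100000, strand = "-"), sizes)
  expect_equal(c(minus$b_start, minus$b_end), c(99000, 105000))
})

test_that("extension stops at a neighbouring basal window, not its extension", {
  g <- data.frame(gene_id = c("up", "down"), chrom = "chr1",
                  tss = c(100000, 120000), strand = "+")
  d <- compute_domains(g, c(chr1 = 3e6))
  expect_equal(d$e_end[d$gene_id == "up"], 115000)   # neighbour basal start
  expect_equal(d$e_start[d$gene_id == "down"], 101000)  # neighbour basal end
  # an isolated gene gets the full 1 Mb per side
  iso <- compute_domains(data.frame(gene_id = "g", chrom = "chr1",
                                    tss = 1.5e6, strand = "+"), c(chr1 = 3e6))
  expect_equal(iso$e_start, 1.5e6 - 5000 - 1e6)
  expect_equal(iso$e_end, 1.5e6 + 1000 + 1e6)
})

test_that("domains never shrink below basal and reject bad input", {
  # two genes whose basal windows overlap
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  tss = c(100000, 103000), strand = "+")
  d <- compute_domains(g, c(chr1 = 1e6))
  expect_true(all(d$e_start <= d$b_start & d$b_end <= d$e_end))
  expect_error(compute_domains(data.frame(gene_id = c("a", "a"),
                                          chrom = "chr1", tss = c(1e5, 2e5),
                                          strand = "+"), c(chr1 = 1e6)),
               "duplicate")
  expect_error(compute_domains(data.frame(gene_id = "a", chrom = "chr1",
                                          tss = 2e6, strand = "+"),
                               c(chr1 = 1e6)), "outside chromosome")
})

test_that("CNEs map to every containing domain; far CNEs stay unassigned", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  tss = c(1.0e6, 1.4e6), strand = c("+", "+"))
  d <- compute_domains(g, c(chr1 = 10e6))
  cnes <- data.frame(chrom = "chr1",
                     start = c(1.2e6, 9.0e6), end = c(1.2e6 + 200, 9.0e6 + 200),
                     cne_id = c("between", "far"))
  asn <- assign_cnes(cnes, d)
  expect_setequal(asn$gene_ids[[1]], c("a", "b"))  # overlapping extensions
  expect_length(asn$gene_ids[[2]], 0)
  expect_warning(assign_cnes(data.frame(chrom = "chrZ", start = 1, end = 10,
                                        cne_id = "z"), d), "unassigned")
})

test_that("midpoints on a half-open domain boundary fall outside", {
  d <- data.frame(gene_id = "g", chrom = "chr1", b_start = 1000, b_end = 2000,
                  e_start = 1000, e_end = 2000)
  on_end <- data.frame(chrom = "chr1", start = 1950, end = 2050,
                       cne_id = "edge")  # midpoint exactly 2000
  expect_length(assign_cnes(on_end, d)$gene_ids[[1]], 0)
  inside <- data.frame(chrom = "chr1", start = 1948, end = 2048,
                       cne_id = "in")  # midpoint 1998
  expect_identical(assign_cnes(inside, d)$gene_ids[[1]], "g")
})

test_that("assignment equals the brute-force all-pairs scan on random genomes", {
  set.seed(77)
  for (rep in 1:25) {
    n_genes <- sample(3:12, 1)
    glen <- sample(c(5e6, 2e7, 5e7), 1)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                        tss = sort(sample.int(glen - 1, n_genes)),
                        strand = sample(c("+", "-"), n_genes, replace = TRUE))
    d <- compute_domains(genes, c(chr1 = glen))
    n_cnes <- sample(10:40, 1)
    starts <- sample.int(glen - 500, n_cnes)
    cnes <- data.frame(chrom = "chr1", start = starts, end = starts + 300,
                       cne_id = sprintf("c%03d", seq_len(n_cnes)))
    asn <- assign_cnes(cnes, d)
    expect_identical(asn$gene_ids, oracle_assign(cnes, d))
  }
})

test_that("assignment count is monotone in max extension and idempotent", {
  set.seed(78)
  genes <- data.frame(gene_id = sprintf("g%d", 1:6), chrom = "chr1",
                      tss = sort(sample.int(2e7, 6)),
                      strand = sample(c("+", "-"), 6, replace = TRUE))
  starts <- sample.int(2e7 - 500, 40)
  cnes <- data.frame(chrom = "chr1", start = starts, end = starts + 300,
                     cne_id = sprintf("c%02d", 1:40))
  counts <- vapply(c(1e4, 1e5, 1e6, 5e6), function(ext) {
    d <- compute_domains(genes, c(chr1 = 2e7), max_extension = ext)
    sum(lengths(assign_cnes(cnes, d)$gene_ids))
  }, 0)
  expect_true(all(diff(counts) >= 0))
  d <- compute_domains(genes, c(chr1 = 2e7))
  expect_identical(assign_cnes(cnes, d), assign_cnes(cnes, d))
})
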