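exon_fixture <- function() {
  data.frame(gene_id = "g1", exon_index = 1:3,
             seq = c(strrep("ATG", 33) , strrep("GGA", 16), "TGC"),
             stringsAsFactors = FALSE)
}

test_that("gene assembly concatenates exons in order with offsets", {
  tab <- data.frame(gene_id = "g", exon_index = c(1, 2, 3),
                    seq = c(strrep("A", 100), strrep("C", 50),
                            strrep("G", 150)))
  gs <- assemble_gene_sequence(tab, "g")
  expect_equal(nchar(gs$sequence), 300)
  expect_equal(unname(gs$offsets), c(0, 100, 150))
  # isoform-duplicated exon supplied twice identically appears once
  dup <- rbind(tab, tab[2, ])
  expect_identical(assemble_gene_sequence(dup, "g")$sequence, gs$sequence)
  conflict <- rbind(tab, data.frame(gene_id = "g", exon_index = 2,
                                    seq = strrep("T", 50)))
  expect_error(assemble_gene_sequence(conflict, "g"), "conflicting")
  # missing exon: gap placeholder of the reference length
  ref <- data.frame(gene_id = "g", exon_index = 1:3,
                    length = c(100, 50, 150))
  part <- assemble_gene_sequence(tab[-2, ], "g", ref_exons = ref)
  expect_equal(part$missing_exons, 2L)
  expect_equal(substr(part$sequence, 101, 150), strrep("N", 50))
})

test_that("truncation calls follow the read-support and frame rules", {
  tab <- exon_fixture()
  gene <- assemble_gene_sequence(tab, "g1")
  base <- data.frame(species = "s1", gene = "g1", exon = 1:3, pos = NA,
                     ref = ".", alt = ".", support = 10, depth = 10)
  row <- function(exon, pos, ref, alt, support, depth = 10)
    data.frame(species = "s1", gene = "g1", exon = exon, pos = pos,
               ref = ref, alt = alt, support = support, depth = depth)
  # frameshift with only 2 supporting reads is not reported
  calls <- call_truncations(gene, rbind(base, row(1, 5, "T", "TA", 2)), "s1")
  expect_equal(nrow(calls), 0)
  # 3-bp in-frame deletion: no call; 4-bp deletion with 5 reads: frameshift
  calls <- call_truncations(gene,
    rbind(base, row(1, 10, "GATGA", "GA", 5),   # -3 bp, in frame
          row(2, 7, "AGGAA", "A", 5)), "s1")    # -4 bp
  expect_equal(calls$kind, "frameshift")
  expect_equal(calls$position, 99 + 7)
  expect_false(any(calls$position == 10))
  # nonsense: TGC -> TGA at the final exon is the terminal codon, excluded;
  # GGA -> TGA inside exon 2 is a premature stop
  calls <- call_truncations(gene,
    rbind(base, row(2, 9, "G", "T", 6)), "s1")  # codon GGA -> TGA
  expect_equal(calls$kind, "nonsense")
  expect_true(calls$fixed[1] == (calls$support[1] == calls$depth[1]))
  calls_term <- call_truncations(gene,
    rbind(base, row(3, 2, "C", "A", 6)), "s1")  # terminal codon TGC -> TGA
  expect_equal(nrow(calls_term), 0)
  # partial support is reported but not fixed
  calls <- call_truncations(gene, rbind(base, row(2, 9, "G", "T", 6, 10)),
                            "s1", fixed_fraction = 1)
  expect_false(calls$fixed[1])
})

test_that("whole-gene deletions need zero coverage here and data elsewhere", {
  tab <- rbind(exon_fixture(),
               within(exon_fixture(), gene_id <- "g2"))
  gene1 <- assemble_gene_sequence(tab, "g1")
  zero_here <- data.frame(species = "s1", gene = "g1", exon = 1:3, pos = NA,
                          ref = ".", alt = ".", support = 0, depth = 0)
  covered_there <- data.frame(species = "s1", gene = "g2", exon = 1:3,
                              pos = NA, ref = ".", alt = ".", support = 10,
                              depth = 10)
  calls <- call_truncations(gene1, rbind(zero_here, covered_there), "s1")
  expect_equal(calls$kind, "whole_gene_deletion")
  expect_true(calls$fixed)
  # without coverage anywhere the species simply has no data: no call
  calls2 <- call_truncations(gene1, zero_here, "s1")
  expect_equal(nrow(calls2), 0)
})

test_that("screening is invariant to pileup row order and recovers exactly
           the planted calls on simulated pileups", {
  spec <- list(
    list(species = "spA", gene = "g01", kind = "frameshift", fixed = TRUE),
    list(species = "spB", gene = "g02", kind = "nonsense", fixed = TRUE),
    list(species = "spC", gene = "g03", kind = "frameshift", fixed = TRUE,
         support = 2),   # below the 3-read rule: must not be called
    list(species = "spD", gene = "g04", kind = "whole_gene_deletion"),
    list(species = "spA", gene = "g05", kind = "missense", fixed = TRUE))
  cfg <- sim_config(seed = 14, pileup_depth = 12, variant_spec = spec)
  sp <- simulate_pileups(cfg, species = c("spA", "spB", "spC", "spD"))
  calls <- screen_truncations(sp$exon_table, sp$pileup)
  got <- sort(paste(calls$species, calls$gene_id, calls$kind))
  expect_identical(got, sort(c("spA g01 frameshift", "spB g02 nonsense",
                               "spD g04 whole_gene_deletion")))
  set.seed(15)
  shuffled <- sp$pileup[sample.int(nrow(sp$pileup)), ]
  calls2 <- screen_truncations(sp$exon_table, shuffled)
  expect_equal(calls[order(calls$gene_id), c("species", "kind")],
               calls2[order(calls2$gene_id), c("species", "kind")],
               ignore_attr = TRUE)
})

test_that("clinical-site mapping keeps only conserved homologous columns", {
  aln <- rbind(human = c("M", "R", "L", "-", "P"),
               og1 = c("M", "R", "L", "L", "P"),
               og2 = c("M", "R", "L", "L", "P"),
               og3 = c("M", "R", "I", "L", "P"),
               foc = c("M", "K", "L", "L", "P"))
  clin <- data.frame(position = c(2, 3), variant = c("K", "V"),
                     id = c("cv1", "cv2"))
  hits <- map_human_sites(aln, clin, human = "human",
                          outgroups = c("og1", "og2", "og3"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$species, "foc")
  expect_equal(hits$human_position, 2)
  expect_equal(hits$clinical_id, "cv1")
  # ancestral != human excludes the column regardless of variants
  aln2 <- aln
  aln2["human", 2] <- "P"
  expect_equal(nrow(map_human_sites(aln2, clin, human = "human",
                                    outgroups = c("og1", "og2", "og3"))), 0)
  expect_warning(map_human_sites(aln, data.frame(position = 99, variant = "K",
                                                 id = "x"),
                                 human = "human",
                                 outgroups = c("og1", "og2", "og3")),
                 "outside")
})

test_that("clinical-site mapping equals a brute-force column scan on random
           alignments", {
  set.seed(16)
  aas <- c("A", "R", "N", "D", "C", "-", "K", "L")
  for (rep in 1:10) {
    aln <- matrix(sample(aas, 7 * 25, replace = TRUE, prob = c(rep(1, 5), 0.5, 1, 1)),
                  7, 25, dimnames = list(c("human", "og1", "og2", "og3",
                                           "f1", "f2", "f3"), NULL))
    npos <- sum(aln["human", ] != "-")
    if (npos < 2) next
    clin <- data.frame(position = sample(seq_len(npos), 6, replace = TRUE),
                       variant = sample(setdiff(aas, "-"), 6, replace = TRUE),
                       id = paste0("cv", 1:6))
    got <- map_human_sites(aln, clin, human = "human",
                           outgroups = c("og1", "og2", "og3"))
    # independent scan
    want <- 0
    hpos <- 0
    for (col in seq_len(ncol(aln))) {
      h <- aln["human", col]
      if (h == "-") next
      hpos <- hpos + 1
      og <- aln[c("og1", "og2", "og3"), col]
      og <- og[og != "-"]
      if (!length(og)) next
      tb <- sort(table(og), decreasing = TRUE)
      if (tb[1] / length(og) < 2 / 3 || names(tb)[1] != h) next
      for (sp in c("f1", "f2", "f3")) {
        r <- aln[sp, col]
        if (r == "-" || r == h) next
        want <- want + sum(clin$position == hpos & clin$variant == r)
      }
    }
    expect_equal(nrow(got), want)
  }
})

dag_fixture <- function() {
  data.frame(
    term_id = c("hema", "anemia", "rbc", "cranio", "muscle", "spleen",
                 "spleno"),
    parent_id = c("root", "hema", "anemia", "root", "root", "root",
                   "spleen"))
}

test_that("pleiotropy scores count only retained non-hematopoietic terms", {
  parents <- dag_fixture()
  expect_equal(pleiotropy_score(c("anemia", "rbc"), parents, "hema"), 0)
  expect_equal(pleiotropy_score(c("anemia", "cranio"), parents, "hema"), 1)
  expect_gte(pleiotropy_score(c("cranio", "muscle"), parents, "hema"), 1)
  # excluded indirect phenotypes (and their descendants) do not count
  expect_equal(pleiotropy_score("spleno", parents, "hema",
                                excluded = "spleen"), 0)
  expect_warning(s <- pleiotropy_score(c("cranio", "unknown"), parents,
                                       "hema"), "absent")
  expect_equal(s, 1)
  expect_error(pleiotropy_score("cranio", parents, "nothere"), "root term")
  # monotonicity: adding a non-hematopoietic annotation never lowers the score
  expect_gte(pleiotropy_score(c("anemia", "cranio", "muscle"), parents,
                              "hema"),
             pleiotropy_score(c("anemia", "cranio"), parents, "hema"))
})

test_that("expression-bias flags follow the fold-threshold semantics", {
  lin <- c(erythrocyte = 100, myeloid = 10, lymphoid = 5)
  org <- c(marrow = 50, liver = 10, brain = 2)
  fl <- classify_erythroid_bias(lin, org, fold = 2)
  expect_true(fl$erythroid_biased)
  expect_true(fl$marrow_restricted)
  equal <- c(erythrocyte = 10, myeloid = 10, lymphoid = 10)
  expect_false(classify_erythroid_bias(equal, org, fold = 2)$erythroid_biased)
  # fold = 1: a (weak) maximum counts as biased
  expect_true(classify_erythroid_bias(equal, org, fold = 1)$erythroid_biased)
  expect_warning(
    fl0 <- classify_erythroid_bias(c(erythrocyte = 0, x = 0), org),
    "all-zero")
  expect_false(fl0$erythroid_biased)
})

test_that("the LOF-pleiotropy exact test matches hypergeometric enumeration", {
  balanced <- data.frame(pleiotropy_score = rep(c(0, 1), each = 10),
                         has_lof = rep(c(TRUE, FALSE), 10))
  r <- lof_pleiotropy_association(balanced)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  perfect <- data.frame(pleiotropy_score = rep(c(0, 1), each = 10),
                        has_lof = rep(c(TRUE, FALSE), each = 10))
  r2 <- lof_pleiotropy_association(perfect)
  expect_equal(r2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_gt(r2$odds_ratio, 1)  # Haldane-corrected, finite
  expect_true(is.finite(r2$odds_ratio))
  expect_error(lof_pleiotropy_association(
    data.frame(pleiotropy_score = c(0, 0), has_lof = c(TRUE, TRUE))),
    "empty margin")
  # random tables against the enumeration oracle
  set.seed(19)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ann <- data.frame(
      pleiotropy_score = rep(c(0, 0, 1, 1), c(tab[1, 1], tab[1, 2],
                                              tab[2, 1], tab[2, 2])),
      has_lof = rep(c(TRUE, FALSE, TRUE, FALSE), c(tab[1, 1], tab[1, 2],
                                                   tab[2, 1], tab[2, 2])))
    expect_equal(lof_pleiotropy_association(ann)$p_value,
                 oracle_fisher_p(tab), tolerance = 1e-9)
  }
})
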