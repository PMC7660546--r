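test_that("simulated trees honour the calibration window and are deterministic", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_tree(cfg)
  depth <- max(ape::node.depth.edgelength(sim$tree_time))
  expect_gte(depth, 18.6)
  expect_lte(depth, 23.9)
  expect_true(ape::is.ultrametric(sim$tree_time, tol = 1e-8))
  expect_true(sim$foreground %in% branch_ids(sim$tree_time))
  expect_setequal(names(sim$tip_classes), sim$tree_time$tip.label)
  expect_true(all(sim$tip_classes %in% c("HA", "SA")))

  f1 <- tempfile(); f2 <- tempfile()
  simulate_tree(cfg, file = f1)
  simulate_tree(cfg, file = f2)
  expect_identical(readLines(f1), readLines(f2))

  cherry <- simulate_tree(sim_config(seed = 5, n_species = 2))
  expect_equal(length(cherry$tree_time$tip.label), 2L)

  expect_error(simulate_tree(sim_config(seed = 1,
                                        foreground_branch = "nope")),
               "absent from generated topology")
})

test_that("locus simulation is deterministic and respects counts", {
  cfg <- sim_config(seed = 4, n_loci = 12, locus_length = 120,
                    fraction_shifted = 0.25)
  sim <- simulate_tree(cfg)
  l1 <- simulate_loci(sim, cfg)
  l2 <- simulate_loci(sim, cfg)
  expect_identical(l1$alignments, l2$alignments)
  expect_length(l1$alignments, 12)
  expect_true(all(vapply(l1$alignments, ncol, 1L) == 120))
  expect_true(all(vapply(l1$alignments, nrow, 1L) == cfg$n_species))
  expect_length(l1$truth$shifted_locus_ids, round(0.25 * 12))
  expect_true(all(l1$truth$shifted_locus_ids %in% names(l1$alignments)))

  dir <- tempfile()
  simulate_loci(sim, cfg, dir = dir)
  expect_length(list.files(dir, pattern = "\\.fasta$"), 12)
})

test_that("planted foreground multipliers are recoverable from shifted loci", {
  cfg <- sim_config(seed = 12, n_loci = 100, locus_length = 500,
                    fraction_shifted = 1, shift_scale = 4)
  sim <- simulate_tree(cfg)
  loci <- simulate_loci(sim, cfg)
  st <- cnedrift:::tree_struct(sim$tree_subs)
  fg_len <- st$tree$edge.length[match(sim$foreground, st$ids)]
  mult <- vapply(loci$alignments, function(a)
    estimate_branch_lengths(a, sim$tree_subs, sim$model)$
      lengths[sim$foreground] / fg_len, 0)
  expect_gte(stats::median(mult), 3)
  expect_lte(stats::median(mult), 5)
})

test_that("scale-1 'shifted' loci are indistinguishable from background", {
  cfg <- sim_config(seed = 13, n_loci = 60, locus_length = 300,
                    fraction_shifted = 0.5, shift_scale = 1)
  sim <- simulate_tree(cfg)
  loci <- simulate_loci(sim, cfg)
  st <- cnedrift:::tree_struct(sim$tree_subs)
  fg_len <- st$tree$edge.length[match(sim$foreground, st$ids)]
  mult <- vapply(loci$alignments, function(a)
    estimate_branch_lengths(a, sim$tree_subs, sim$model)$
      lengths[sim$foreground] / fg_len, 0)
  shifted <- names(mult) %in% loci$truth$shifted_locus_ids
  expect_gt(stats::t.test(mult[shifted], mult[!shifted])$p.value, 0.001)
})

test_that("annotation set is well-formed and the planted term matches the
           shifted CNEs by construction", {
  cfg <- sim_config(seed = 6, n_loci = 80)
  sim <- simulate_tree(cfg)
  loci <- simulate_loci(sim, cfg)
  ann <- simulate_annotation_set(cfg, loci$truth)
  expect_equal(nrow(ann$genes), cfg$n_genes)
  expect_true(all(ann$genes$strand %in% c("+", "-")))
  cnes <- ann$cnes
  expect_equal(nrow(cnes), cfg$n_cnes)
  expect_true(all(cnes$start < cnes$end))
  expect_true(all(diff(cnes$start) > 0))
  expect_true(all(cnes$start[-1] >= cnes$end[-nrow(cnes)]))  # non-overlap
  # every shifted CNE with any assignment maps to >= 1 planted-term gene
  planted_genes <- ann$ontology$gene_id[ann$ontology$term_id ==
                                          ann$planted_term]
  shifted_assigned <- ann$assignment[ann$assignment$cne_id %in%
                                       loci$truth$shifted_locus_ids, ]
  nonempty <- lengths(shifted_assigned$gene_ids) > 0
  expect_true(all(vapply(shifted_assigned$gene_ids[nonempty], function(g)
    any(g %in% planted_genes), TRUE)))
  # and ten or more decoy terms exist
  expect_gte(length(setdiff(unique(ann$ontology$term_id),
                            ann$planted_term)), 10)
  expect_error(
    simulate_annotation_set(sim_config(seed = 1, genome_length = 1e4,
                                       n_loci = 100, locus_length = 300)),
    "infeasible")
})

test_that("pileups honour the fixed/polymorphic/deletion contracts", {
  spec <- list(
    list(species = "sp01", gene = "g01", kind = "frameshift", fixed = TRUE),
    list(species = "sp02", gene = "g02", kind = "nonsense", fixed = TRUE),
    list(species = "sp03", gene = "g03", kind = "missense", fixed = FALSE,
         allele_fraction = 0.4),
    list(species = "sp04", gene = "g04", kind = "whole_gene_deletion"))
  cfg <- sim_config(seed = 10, pileup_depth = 1000, variant_spec = spec)
  sp <- simulate_pileups(cfg)
  fs <- sp$pileup[sp$pileup$species == "sp01" & sp$pileup$alt != ".", ]
  expect_equal(fs$support, fs$depth)  # fixed: all covering reads support
  # polymorphic support within the binomial 99% interval of depth * af
  mis <- sp$pileup[sp$pileup$species == "sp03" & sp$pileup$alt != ".", ]
  expect_gte(mis$support, qbinom(0.005, 1000, 0.4))
  expect_lte(mis$support, qbinom(0.995, 1000, 0.4))
  del <- sp$pileup[sp$pileup$species == "sp04" & sp$pileup$gene == "g04", ]
  expect_true(all(del$depth == 0))
  expect_error(simulate_pileups(sim_config(seed = 1, variant_spec = list(
    list(species = "sp01", gene = "g01", kind = "frameshift",
         exon = 1, pos = 500)))), "outside gene length")
})

test_that("mask images contain exactly the planted particles", {
  cfg <- sim_config(seed = 11, mask_spec = list(
    list(class = "circle", n_cells = 40, aspect_ratio = 1, radius_px = 10),
    list(class = "ellipse", n_cells = 35, aspect_ratio = 2, radius_px = 10)))
  sm1 <- simulate_masks(cfg)
  sm2 <- simulate_masks(cfg)
  expect_identical(sm1$image, sm2$image)  # determinism
  expect_equal(max(cnedrift:::label_components8(sm1$image)), 75)
  expect_equal(nrow(sm1$truth), 75)
  expect_error(simulate_masks(sim_config(seed = 1, mask_spec = list(
    list(class = "x", n_cells = 100000, aspect_ratio = 1, radius_px = 30)))),
    "cannot be placed")
})
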