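#' Run the full planted-signal analysis on synthetic data
#'
#' End-to-end pipeline at desk scale: simulate a calibrated tree with a
#' foreground branch, evolve CNE alignments with planted foreground rate
#' shifts, fit a neutral model from the elements, estimate per-locus branch
#' lengths, compute RERs, run the acceleration scan, map CNEs to genes
#' through regulatory domains, and score every ontology term by bootstrap
#' Z (on foreground RER) and SUMSTAT (on fourth-root likelihood ratios) with
#' BH q-values.
#'
#' @param config A [sim_config()]; its seed determines everything.
#' @param n_boot Bootstrap replicates for both enrichment statistics.
#' @param min_term_size Minimum CNE count for a term to be scored. The
#'   default for genome-scale CNE analyses is 1000; at desk scale use a
#'   value compatible with `n_cnes`.
#' @param neutral_max_sites Concatenation cap for the neutral-model fit.
#' @param refit_neutral Two-pass neutral fit: after a first acceleration
#'   scan, the neutral model is refit on elements without evidence of
#'   foreground acceleration (p > `refit_p`) and the scan repeated. This
#'   removes the upward bias that planted accelerated elements exert on the
#'   fitted foreground branch.
#' @param refit_p Exclusion threshold for the refit.
#' @return List with `terms` (data frame: term_id, n_cnes, z, sumstat,
#'   sumstat_p, q, planted), `planted_term`, `truth`, `rer`, `scan`,
#'   `neutral`, `sim`, `annotations`, `fg_rer` (per-CNE foreground RER).
#' @export
run_planted_analysis <- function(config = sim_config(), n_boot = 1500,
                                 min_term_size = 5,
                                 neutral_max_sites = 20000,
                                 refit_neutral = TRUE, refit_p = 0.25) {
  sim <- simulate_tree(config)
  loci <- simulate_loci(sim, config)
  ann <- simulate_annotation_set(config, loci$truth)
  neutral <- fit_neutral_model(loci$alignments, sim$tree_subs,
                               min_length = min(250, config$locus_length),
                               min_coverage = 0.85,
                               max_sites = neutral_max_sites)
  locus_bl <- lapply(names(loci$alignments), function(id)
    estimate_branch_lengths(loci$alignments[[id]], neutral$tree,
                            neutral$model, locus_id = id))
  bm <- build_branch_matrix(locus_bl, neutral$tree)
  rer <- compute_rer(bm)
  fg_rer <- rer$rer[, sim$foreground]
  scan <- accel_scan(loci$alignments, neutral, sim$foreground)
  if (refit_neutral) {
    calm <- scan$element_id[scan$testable & scan$p_value > refit_p]
    if (length(calm) >= 10) {
      neutral <- fit_neutral_model(loci$alignments[calm], neutral$tree,
                                   min_length = min(250, config$locus_length),
                                   min_coverage = 0.85,
                                   max_sites = neutral_max_sites)
      scan <- accel_scan(loci$alignments, neutral, sim$foreground)
    }
  }

  term_cnes <- term_cne_sets(ann$ontology, ann$assignment)
  term_ids <- names(term_cnes)[lengths(term_cnes) >= min_term_size]
  set.seed(config$seed + 5L)
  rows <- lapply(term_ids, function(t) {
    z <- term_zscore(fg_rer, term_cnes[[t]], n_boot = n_boot)
    ss <- sumstat_enrichment(scan, term_cnes[[t]], n_boot = n_boot)
    data.frame(term_id = t, n_cnes = length(term_cnes[[t]]), z = z$z,
               sumstat = ss$observed, sumstat_p = ss$p_value,
               stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows)
  terms$q <- fdr_correct(terms$sumstat_p)
  terms$planted <- terms$term_id == ann$planted_term
  list(terms = terms, planted_term = ann$planted_term, truth = loci$truth,
       rer = rer, scan = scan, neutral = neutral, sim = sim,
       annotations = ann, fg_rer = fg_rer)
}

#' Derive per-term CNE sets from an ontology and a CNE assignment
#'
#' A term's CNE set is the union of CNEs assigned (via regulatory domains)
#' to any of the term's genes.
#'
#' @param ontology Data frame `term_id`, `gene_id`.
#' @param assignment [assign_cnes()] output.
#' @return Named list of character vectors (CNE ids per term).
#' @export
term_cne_sets <- function(ontology, assignment) {
  cne_genes <- assignment$gene_ids
  names(cne_genes) <- assignment$cne_id
  gene2cne <- list()
  for (i in seq_along(cne_genes))
    for (g in cne_genes[[i]])
      gene2cne[[g]] <- c(gene2cne[[g]], names(cne_genes)[i])
  sets <- lapply(split(ontology$gene_id, ontology$term_id), function(genes)
    sort(unique(unlist(gene2cne[genes]))))
  sets[!vapply(sets, is.null, TRUE)]
}
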