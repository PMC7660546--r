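#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults matching
#' the study design the package targets: a clade of Antarctic notothenioid-like
#' species with a crown age in the 18.6-23.9 Ma calibration window, one
#' pre-specified internal "foreground" branch (the erythrocyte-null ancestor),
#' high-latitude (HA) vs sub-Antarctic (SA) tip classes, and a minority of
#' loci whose foreground branch evolves at an elevated rate.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines all generator output.
#' @param n_species Number of extant tips (>= 2).
#' @param root_age_interval Length-2 numeric, crown age bounds in Ma.
#' @param foreground_branch Branch id to mark as foreground, or `NULL` to pick
#'   an internal branch subtending roughly a quarter of the tips (labelled
#'   `"FG"`).
#' @param ha_tips,sa_tips Optional character vectors of tip labels; by default
#'   HA = tips descending from the foreground branch, SA = the rest.
#' @param n_loci,locus_length Locus count and alignment length (bp).
#' @param fraction_shifted Proportion of loci carrying the foreground rate
#'   shift (in `[0, 1]`).
#' @param shift_scale Rate multiplier applied to the foreground branch of
#'   shifted loci (> 0).
#' @param pi,kappa HKY base frequencies (A,C,G,T) and transition/transversion
#'   ratio used for simulation.
#' @param subst_rate Global clock, expected substitutions per site per Ma,
#'   converting the time tree to a substitution tree.
#' @param dropout Per-species, per-locus probability of missing data (the
#'   species' row becomes all `N`).
#' @param genome_length,n_genes,n_cnes Synthetic genome used by
#'   [simulate_annotation_set()]; `n_cnes` defaults to `n_loci` so CNE ids and
#'   locus ids coincide.
#' @param n_terms Number of ontology terms (1 planted + decoys; >= 11).
#' @param planted_term_size Gene-set size used for the planted term when there
#'   is no planted signal to derive it from (null simulations), and for decoys.
#' @param pileup_depth Read depth for [simulate_pileups()].
#' @param variant_spec List of planted variants, see [simulate_pileups()].
#' @param mask_spec List of particle classes for [simulate_masks()]; each a
#'   list with `class`, `n_cells`, `aspect_ratio` (>= 1) and `radius_px`.
#' @param pixel_size_um Microns per pixel for mask images.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 20,
                       root_age_interval = c(18.6, 23.9),
                       foreground_branch = NULL,
                       ha_tips = NULL, sa_tips = NULL,
                       n_loci = 300, locus_length = 300,
                       fraction_shifted = 50 / 300,
                       shift_scale = 4,
                       pi = c(0.3, 0.2, 0.2, 0.3), kappa = 2,
                       subst_rate = 0.01,
                       dropout = 0,
                       genome_length = 400e6, n_genes = 100, n_cnes = n_loci,
                       n_terms = 20, planted_term_size = 10,
                       pileup_depth = 10, variant_spec = NULL,
                       mask_spec = list(
                         list(class = "circle", n_cells = 100,
                              aspect_ratio = 1, radius_px = 24),
                         list(class = "ellipse", n_cells = 100,
                              aspect_ratio = 2, radius_px = 24)),
                       pixel_size_um = 0.25) {
  cfg <- as.list(environment())
  stopifnot(n_species >= 2,
            length(root_age_interval) == 2,
            root_age_interval[1] < root_age_interval[2],
            fraction_shifted >= 0, fraction_shifted <= 1,
            shift_scale > 0, n_loci >= 1, locus_length >= 1,
            subst_rate > 0, dropout >= 0, dropout < 1,
            n_genes >= 1, n_cnes >= 1, pileup_depth >= 1,
            all(vapply(mask_spec, function(m) m$aspect_ratio >= 1, TRUE)))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Simulate a calibrated species tree with a foreground branch
#'
#' Draws a pure-birth (Yule) topology on `n_species` tips, rescales it so the
#' crown age is uniform within `root_age_interval`, marks one internal branch
#' as foreground (node label `"FG"`), and partitions tips into HA/SA classes.
#'
#' @param config A [sim_config()].
#' @param file Optional path; when given, the time tree is written there as
#'   Newick (foreground marked via the node label).
#' @return A list of class `sim_tree`: `tree_time` (phylo, Ma),
#'   `tree_subs` (phylo, substitutions/site via `subst_rate`), `foreground`
#'   (branch id), `tip_classes` (named character, `"HA"`/`"SA"`), `model`
#'   (a [subst_model][hky_model]), `root_age`.
#' @export
simulate_tree <- function(config = sim_config(), file = NULL) {
  set.seed(config$seed)
  tr <- phytools::pbtree(n = config$n_species, quiet = TRUE)
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  root_age <- stats::runif(1, config$root_age_interval[1],
                           config$root_age_interval[2])
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  ntip <- length(tr$tip.label)
  tr$node.label <- rep("", tr$Nnode)

  if (is.null(config$foreground_branch)) {
    clade_sizes <- vapply((ntip + 2):(ntip + tr$Nnode), function(n)
      length(descendant_tips(tr, n)), 1L)
    target <- max(2, round(ntip / 4))
    fg_node <- ((ntip + 2):(ntip + tr$Nnode))[which.min(abs(clade_sizes - target))]
    tr$node.label[fg_node - ntip] <- "FG"
    fg_id <- "FG"
  } else {
    fg_id <- config$foreground_branch
    if (!fg_id %in% branch_ids(tr))
      stop("foreground branch '", fg_id, "' absent from generated topology")
    fg_node <- tr$edge[match(fg_id, branch_ids(tr)), 2]
  }

  fg_tips <- tr$tip.label[descendant_tips(tr, fg_node)]
  ha <- if (is.null(config$ha_tips)) fg_tips else config$ha_tips
  sa <- if (is.null(config$sa_tips)) setdiff(tr$tip.label, ha) else config$sa_tips
  miss <- setdiff(c(ha, sa), tr$tip.label)
  if (length(miss))
    stop("configured tips absent from tree: ", paste(miss, collapse = ", "))
  classes <- stats::setNames(rep("other", ntip), tr$tip.label)
  classes[ha] <- "HA"
  classes[sa] <- "SA"

  tr_subs <- tr
  tr_subs$edge.length <- tr$edge.length * config$subst_rate
  if (!is.null(file)) ape::write.tree(tr, file = file)
  structure(list(tree_time = tr, tree_subs = tr_subs, foreground = fg_id,
                 tip_classes = classes,
                 model = hky_model(pi = config$pi, kappa = config$kappa),
                 root_age = root_age),
            class = "sim_tree")
}

# Tip indices descending from a node (the node itself if terminal).
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == n, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Simulate locus alignments with planted foreground rate shifts
#'
#' Evolves `n_loci` alignments on the substitution tree under the configured
#' HKY model. A random subset of `round(fraction_shifted * n_loci)` loci has
#' the foreground branch length multiplied by `shift_scale`; the ground truth
#' records which.
#'
#' @param sim A `sim_tree` from [simulate_tree()].
#' @param config The same [sim_config()].
#' @param dir Optional directory; when given, one FASTA file per locus is
#'   written (`<locus_id>.fasta`).
#' @return List with `alignments` (named list of character matrices) and
#'   `truth` (list: `shifted_locus_ids`, `foreground`, `shift_scale`,
#'   `true_branch_scales`).
#' @export
simulate_loci <- function(sim, config = sim_config(), dir = NULL) {
  set.seed(config$seed + 1L)
  tree <- sim$tree_subs
  ids <- sprintf("locus_%04d", seq_len(config$n_loci))
  n_shift <- round(config$fraction_shifted * config$n_loci)
  shifted <- sort(sample(ids, n_shift))
  st <- tree_struct(tree)
  fg_edge <- match(sim$foreground, st$ids)
  if (is.na(fg_edge)) stop("foreground branch not found in tree")
  base_len <- st$tree$edge.length
  alns <- vector("list", config$n_loci)
  names(alns) <- ids
  for (i in seq_along(ids)) {
    len <- base_len
    if (ids[i] %in% shifted) len[fg_edge] <- len[fg_edge] * config$shift_scale
    aln <- sim_alignment(st, len, sim$model, config$locus_length)
    if (config$dropout > 0) {
      drop <- stats::runif(nrow(aln)) < config$dropout
      aln[drop, ] <- "N"
    }
    alns[[i]] <- aln
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(ids))
      ape::write.FASTA(ape::as.DNAbin(alns[[i]]),
                       file.path(dir, paste0(ids[i], ".fasta")))
  }
  scales <- stats::setNames(
    rep(list(stats::setNames(1, sim$foreground)), length(ids)), ids)
  for (id in shifted) scales[[id]][sim$foreground] <- config$shift_scale
  list(alignments = alns,
       truth = list(shifted_locus_ids = shifted,
                    foreground = sim$foreground,
                    shift_scale = config$shift_scale,
                    true_branch_scales = scales))
}

# Evolve one alignment down the tree; st is a tree_struct, lengths per edge.
sim_alignment <- function(st, lengths, model, nsites) {
  states <- matrix(0L, st$nnode, nsites)
  states[st$root, ] <- sample.int(4, nsites, replace = TRUE, prob = model$pi)
  for (k in rev(seq_len(nrow(st$edge)))) {  # parents before children
    p <- st$edge[k, 1]; v <- st$edge[k, 2]
    P <- transition_prob(model, lengths[k])
    sv <- integer(nsites)
    for (s in 1:4) {
      idx <- which(states[p, ] == s)
      if (length(idx))
        sv[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[v, ] <- sv
  }
  out <- matrix(DNA_STATES[states[seq_len(st$ntip), ]], st$ntip, nsites)
  rownames(out) <- st$tree$tip.label
  out
}

#' Simulate gene models, CNE intervals and an ontology with a planted term
#'
#' Places `n_genes` transcription start sites and `n_cnes` non-overlapping
#' CNE intervals (one per locus, in locus order) on a synthetic chromosome,
#' derives regulatory domains with [compute_domains()], and builds an ontology
#' in which the planted term's gene set is exactly the set of genes whose
#' extended domains contain the shifted CNEs. Decoy terms draw from the
#' remaining genes so they are true negative controls.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [simulate_loci()] (may be `NULL` for a
#'   null simulation with no shifted loci).
#' @param dir Optional directory for `genes.tsv`, `cnes.bed`,
#'   `ontology_genes.tsv`, `ontology_parents.tsv`.
#' @return List with `genes`, `cnes` (BED-like data frames), `ontology`
#'   (term_id/gene_id), `parents` (term_id/parent_id), `planted_term`,
#'   `domains`, `assignment`, `chrom_sizes`.
#' @export
simulate_annotation_set <- function(config = sim_config(), truth = NULL,
                                    dir = NULL) {
  set.seed(config$seed + 2L)
  G <- config$genome_length
  L <- config$locus_length
  if (config$n_cnes * L + config$n_genes > G / 2)
    stop("features exceed genome_length; infeasible placement")
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom = "chr1",
    tss = sort(sample.int(G - 1L, config$n_genes)),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  # non-overlapping sorted intervals via the stars-and-bars offset trick
  slack <- G - config$n_cnes * L
  starts <- sort(sample.int(slack, config$n_cnes)) +
    (seq_len(config$n_cnes) - 1L) * L
  cnes <- data.frame(chrom = "chr1", start = starts, end = starts + L,
                     cne_id = sprintf("locus_%04d", seq_len(config$n_cnes)),
                     stringsAsFactors = FALSE)
  chrom_sizes <- c(chr1 = G)
  domains <- compute_domains(genes, chrom_sizes)
  assignment <- assign_cnes(cnes, domains)

  shifted <- if (is.null(truth)) character(0) else truth$shifted_locus_ids
  planted_genes <- sort(unique(unlist(
    assignment$gene_ids[assignment$cne_id %in% shifted])))
  if (!length(planted_genes))
    planted_genes <- sort(sample(genes$gene_id,
                                 min(config$planted_term_size,
                                     nrow(genes))))
  pool <- setdiff(genes$gene_id, planted_genes)
  n_decoys <- max(10L, config$n_terms - 1L)
  # decoys are drawn without replacement across terms while the pool lasts
  # (disjoint negative controls); the pool is reshuffled when exhausted
  size <- min(config$planted_term_size, length(pool))
  bag <- sample(pool)
  decoy_sets <- lapply(seq_len(n_decoys), function(i) {
    if (length(bag) < size) bag <<- sample(pool)
    take <- bag[seq_len(size)]
    bag <<- bag[-seq_len(size)]
    sort(take)
  })
  term_ids <- c("TERM_planted", sprintf("TERM_decoy%02d", seq_len(n_decoys)))
  ontology <- data.frame(
    term_id = rep(term_ids, c(length(planted_genes),
                              lengths(decoy_sets))),
    gene_id = c(planted_genes, unlist(decoy_sets)),
    stringsAsFactors = FALSE)
  parents <- data.frame(term_id = term_ids, parent_id = "TERM_root",
                        stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cnes, file.path(dir, "cnes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(ontology, file.path(dir, "ontology_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(parents, file.path(dir, "ontology_parents.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genes = genes, cnes = cnes, ontology = ontology, parents = parents,
       planted_term = "TERM_planted", domains = domains,
       assignment = assignment, chrom_sizes = chrom_sizes)
}

#' Simulate per-exon read-support pileups with planted variants
#'
#' Emits reference gene sequences (random coding sequence free of internal
#' stops, terminal stop codon) and a pileup table of per-exon coverage plus
#' planted variant rows. Fixed variants are supported by every covering read;
#' polymorphic variants draw binomial support at their allele fraction;
#' whole-gene deletions zero the coverage of every exon of that gene for that
#' species.
#'
#' @param config A [sim_config()]; `pileup_depth` sets the per-site coverage.
#' @param genes Character vector of gene ids (default 5 synthetic genes).
#' @param species Character vector of species (default 4).
#' @param n_exons,exon_length Gene structure shared by all genes.
#' @param variant_spec List of planted variants; each a list with `species`,
#'   `gene`, `kind` (`"frameshift"`, `"nonsense"`, `"missense"`,
#'   `"whole_gene_deletion"`), and optionally `exon`, `pos` (0-based within
#'   exon), `fixed` (default `TRUE`), `allele_fraction`, `support` (overrides
#'   the drawn support count). Positions are chosen automatically when
#'   omitted (for nonsense: a site where a single substitution creates a
#'   premature stop). Defaults to `config$variant_spec`.
#' @param dir Optional directory for `pileup.tsv` and `exons.tsv`.
#' @return List with `pileup` (data frame: species, gene, exon, pos, ref,
#'   alt, support, depth), `exon_table` (gene_id, exon_index, seq),
#'   `truth` (list of planted variant records incl. resolved gene-relative
#'   position and support).
#' @export
simulate_pileups <- function(config = sim_config(), genes = sprintf("g%02d", 1:5),
                             species = sprintf("sp%02d", 1:4),
                             n_exons = 3, exon_length = 120,
                             variant_spec = config$variant_spec, dir = NULL) {
  set.seed(config$seed + 3L)
  stopifnot(config$pileup_depth >= 1, exon_length %% 3 == 0)
  exon_table <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g, exon_index = seq_len(n_exons),
               seq = vapply(seq_len(n_exons), function(i)
                 random_cds_exon(exon_length,
                                 terminal = (i == n_exons)), ""),
               stringsAsFactors = FALSE)
  }))
  depth <- config$pileup_depth
  pile <- expand.grid(species = species, gene = genes,
                      exon = seq_len(n_exons), stringsAsFactors = FALSE)
  pile$pos <- NA_integer_
  pile$ref <- "."
  pile$alt <- "."
  pile$support <- depth
  pile$depth <- depth

  truth <- list()
  for (v in variant_spec) {
    gseq <- paste(exon_table$seq[exon_table$gene_id == v$gene], collapse = "")
    if (v$kind == "whole_gene_deletion") {
      sel <- pile$species == v$species & pile$gene == v$gene
      pile$support[sel] <- 0L
      pile$depth[sel] <- 0L
      truth[[length(truth) + 1L]] <-
        list(species = v$species, gene = v$gene, kind = v$kind,
             support = 0L, fixed = TRUE)
      next
    }
    exon <- if (!is.null(v$exon)) v$exon else sample.int(n_exons - 1L, 1)
    if (is.null(v$pos)) {
      v[c("pos", "ref", "alt")] <- place_variant(gseq, exon, exon_length, v$kind)
    } else {
      if (v$pos < 0 || v$pos >= exon_length)
        stop("variant position outside gene length")
      if (is.null(v$ref))
        v$ref <- substr(gseq, (exon - 1) * exon_length + v$pos + 1,
                        (exon - 1) * exon_length + v$pos + 1)
    }
    fixed <- is.null(v$fixed) || isTRUE(v$fixed)
    support <- if (!is.null(v$support)) v$support
      else if (fixed) depth
      else stats::rbinom(1, depth, v$allele_fraction)
    row <- data.frame(species = v$species, gene = v$gene, exon = exon,
                      pos = v$pos, ref = v$ref, alt = v$alt,
                      support = support, depth = depth,
                      stringsAsFactors = FALSE)
    pile <- rbind(pile, row)
    truth[[length(truth) + 1L]] <-
      c(v[c("species", "gene", "kind", "ref", "alt")],
        list(exon = exon, pos = v$pos,
             gene_pos = (exon - 1L) * exon_length + v$pos,
             support = support, fixed = fixed))
  }
  pile <- pile[order(pile$species, pile$gene, pile$exon, pile$pos,
                     na.last = FALSE), ]
  rownames(pile) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pile, file.path(dir, "pileup.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(exon_table, file.path(dir, "exons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(pileup = pile, exon_table = exon_table, truth = truth)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random in-frame exon without internal stop codons; terminal exons end TAA.
random_cds_exon <- function(len, terminal = FALSE) {
  ncod <- len %/% 3
  codons <- character(ncod)
  for (i in seq_len(ncod)) {
    repeat {
      cd <- paste(sample(DNA_STATES, 3, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  if (terminal) codons[ncod] <- "TAA"
  paste(codons, collapse = "")
}

# Pick (pos, ref, alt) within an exon realising the requested variant kind.
place_variant <- function(gseq, exon, exon_length, kind) {
  off <- (exon - 1L) * exon_length
  if (kind == "frameshift") {
    pos <- sample.int(exon_length, 1) - 1L
    ref <- substr(gseq, off + pos + 1, off + pos + 1)
    return(list(pos = pos, ref = ref, alt = paste0(ref, "A")))
  }
  n_cod_total <- nchar(gseq) %/% 3
  cands <- list()
  for (ci in seq(off %/% 3 + 1, (off + exon_length) %/% 3)) {
    if (ci >= n_cod_total) break  # never touch the terminal codon
    codon <- substr(gseq, (ci - 1) * 3 + 1, ci * 3)
    for (p in 1:3) for (b in DNA_STATES) {
      if (substr(codon, p, p) == b) next
      mut <- codon
      substr(mut, p, p) <- b
      is_stop <- mut %in% STOP_CODONS
      if ((kind == "nonsense") == is_stop)
        cands[[length(cands) + 1L]] <-
          list(pos = (ci - 1L) * 3L + (p - 1L) - off,
               ref = substr(codon, p, p), alt = b)
    }
  }
  if (!length(cands)) stop("no site available for a ", kind, " variant")
  cands[[sample.int(length(cands), 1)]]
}

#' Simulate labelled cell-mask images
#'
#' Draws non-touching filled ellipses on a jittered grid: one particle per
#' grid cell, random orientation, semi-axes `radius_px * sqrt(AR)` and
#' `radius_px / sqrt(AR)` so area is preserved across aspect ratios.
#'
#' @param config A [sim_config()]; classes come from `config$mask_spec`.
#' @param grayscale If `TRUE`, returns a grayscale image (particles darker
#'   than background, Gaussian noise sd `noise_sd`) exercising the
#'   segmentation path; otherwise a binary mask.
#' @param noise_sd Noise level for grayscale mode.
#' @return List with `image` (matrix in `[0, 1]`), `labels` (integer matrix of
#'   particle ids), `truth` (data frame: particle_id, class, aspect_ratio),
#'   `pixel_size_um`.
#' @export
simulate_masks <- function(config = sim_config(), grayscale = FALSE,
                           noise_sd = 0.03) {
  set.seed(config$seed + 4L)
  spec <- config$mask_spec
  n_total <- sum(vapply(spec, function(s) s$n_cells, 1))
  rmax <- max(vapply(spec, function(s) s$radius_px * sqrt(s$aspect_ratio), 1))
  box <- ceiling(2 * rmax) + 8L
  ncol_grid <- ceiling(sqrt(n_total))
  nrow_grid <- ceiling(n_total / ncol_grid)
  size <- c(nrow_grid, ncol_grid) * box + 2L * box
  if (any(size > 8192L))
    stop("requested shapes cannot be placed without contact")
  img <- matrix(0L, size[1], size[2])
  labels <- matrix(0L, size[1], size[2])
  classes <- rep(vapply(spec, function(s) s$class, ""),
                 vapply(spec, function(s) s$n_cells, 1))
  ars <- rep(vapply(spec, function(s) s$aspect_ratio, 1),
             vapply(spec, function(s) s$n_cells, 1))
  radii <- rep(vapply(spec, function(s) s$radius_px, 1),
               vapply(spec, function(s) s$n_cells, 1))
  ord <- sample.int(n_total)  # shuffle classes over grid positions
  jit <- (box - 2 * ceiling(rmax) - 4) / 2
  for (i in seq_len(n_total)) {
    gi <- (i - 1L) %/% ncol_grid
    gj <- (i - 1L) %% ncol_grid
    cy <- box + gi * box + box / 2 + stats::runif(1, -jit, jit)
    cx <- box + gj * box + box / 2 + stats::runif(1, -jit, jit)
    k <- ord[i]
    a <- radii[k] * sqrt(ars[k])
    b <- radii[k] / sqrt(ars[k])
    th <- stats::runif(1, 0, pi)
    px <- fill_ellipse(cy, cx, a, b, th, dim(img))
    img[px] <- 1L
    labels[px] <- k
  }
  truth <- data.frame(particle_id = seq_len(n_total), class = classes,
                      aspect_ratio = ars, stringsAsFactors = FALSE)
  if (grayscale) {
    g <- 0.85 - 0.55 * img + stats::rnorm(length(img), 0, noise_sd)
    img <- matrix(pmin(pmax(g, 0), 1), nrow(img))
  }
  list(image = img, labels = labels, truth = truth,
       pixel_size_um = config$pixel_size_um)
}

# Linear pixel indices of a filled rotated ellipse.
fill_ellipse <- function(cy, cx, a, b, theta, dims) {
  r <- ceiling(max(a, b)) + 1L
  ys <- max(1, floor(cy - r)):min(dims[1], ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(dims[2], ceiling(cx + r))
  dy <- rep(ys - cy, times = length(xs))
  dx <- rep(xs - cx, each = length(ys))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  cbind(rep(ys, times = length(xs))[inside],
        rep(xs, each = length(ys))[inside])
}
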