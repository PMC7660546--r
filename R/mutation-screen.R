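#' Assemble a gene sequence from ordered exon pieces
#'
#' Concatenates single-copy exons in reference order into a non-redundant
#' gene sequence. Exons supplied more than once must be identical (isoform
#' duplicates are merged); conflicting copies are an error. Exons present in
#' the reference order but missing from the input are filled with `N`
#' placeholders and recorded.
#'
#' @param exon_table Data frame with `gene_id`, `exon_index`, `seq` (and
#'   optionally `species`).
#' @param gene_id Gene to assemble.
#' @param species Optional species filter when `exon_table` has a `species`
#'   column.
#' @param ref_exons Optional data frame `gene_id`, `exon_index`, `length`
#'   giving the reference exon order and lengths (needed to gap-fill missing
#'   exons); defaults to the exons present in the input.
#' @return Object of class `gene_sequence`: list with `gene_id`, `species`,
#'   `sequence`, `offsets` (0-based start of each exon in the concatenation,
#'   named by exon index), `missing_exons`.
#' @export
assemble_gene_sequence <- function(exon_table, gene_id, species = NULL,
                                   ref_exons = NULL) {
  tab <- exon_table[exon_table$gene_id == gene_id, , drop = FALSE]
  if (!is.null(species) && "species" %in% names(tab))
    tab <- tab[tab$species == species, , drop = FALSE]
  if (!nrow(tab)) stop("no exons for gene ", gene_id)
  by_idx <- split(tab$seq, tab$exon_index)
  for (i in names(by_idx)) {
    u <- unique(by_idx[[i]])
    if (length(u) > 1)
      stop("conflicting sequences for exon ", i, " of ", gene_id)
    by_idx[[i]] <- u
  }
  if (is.null(ref_exons)) {
    order_idx <- sort(as.integer(names(by_idx)))
    lens <- stats::setNames(nchar(unlist(by_idx)), names(by_idx))
  } else {
    ref <- ref_exons[ref_exons$gene_id == gene_id, , drop = FALSE]
    order_idx <- sort(ref$exon_index)
    lens <- stats::setNames(ref$length, ref$exon_index)
  }
  pieces <- character(length(order_idx))
  missing_exons <- integer(0)
  for (j in seq_along(order_idx)) {
    i <- as.character(order_idx[j])
    if (!is.null(by_idx[[i]])) {
      pieces[j] <- by_idx[[i]]
    } else {
      pieces[j] <- strrep("N", lens[[i]])
      missing_exons <- c(missing_exons, order_idx[j])
    }
  }
  seqs <- paste(pieces, collapse = "")
  offsets <- stats::setNames(c(0, cumsum(nchar(pieces)))[seq_along(pieces)],
                             order_idx)
  structure(list(gene_id = gene_id, species = species, sequence = seqs,
                 offsets = offsets, missing_exons = missing_exons),
            class = "gene_sequence")
}

#' Call truncating variants from pileup rows
#'
#' Applies the screening rules for loss-of-function calls: an indel whose
#' length is not a multiple of 3 is a frameshift; a substitution creating a
#' stop codon strictly before the annotated terminal codon is nonsense; zero
#' coverage at every exon of the gene -- while the same species has coverage
#' at other genes -- is a whole-gene deletion. Frameshift and nonsense calls
#' require at least `min_support` supporting reads (default 3). A call is
#' flagged fixed when its supporting-read fraction reaches `fixed_fraction`
#' of the covering reads (default 1: all covering reads support it).
#'
#' @param gene A [assemble_gene_sequence()] result for the reference sequence.
#' @param pileup Pileup data frame (`species`, `gene`, `exon`, `pos`, `ref`,
#'   `alt`, `support`, `depth`; `alt = "."` rows carry coverage only; `pos`
#'   is 0-based within the exon).
#' @param species Species to screen.
#' @param min_support Minimum supporting reads for frameshift/nonsense.
#' @param fixed_fraction Fraction of covering reads required to flag a call
#'   as fixed.
#' @return Data frame of calls: `species`, `gene_id`, `kind`, `position`
#'   (gene-relative, 0-based; `NA` for whole-gene deletions), `support`,
#'   `depth`, `fixed`.
#' @export
call_truncations <- function(gene, pileup, species, min_support = 3,
                             fixed_fraction = 1) {
  stopifnot(inherits(gene, "gene_sequence"))
  if (nchar(gene$sequence) %% 3 != 0)
    stop("reference frame undefined: gene length not a multiple of 3")
  rows <- pileup[pileup$gene == gene$gene_id & pileup$species == species, ,
                 drop = FALSE]
  calls <- list()
  add <- function(kind, position, support, depth) {
    fixed <- if (kind == "whole_gene_deletion") TRUE else
      depth > 0 && support / max(depth, 1) >= fixed_fraction
    calls[[length(calls) + 1L]] <<- data.frame(
      species = species, gene_id = gene$gene_id, kind = kind,
      position = position, support = support, depth = depth,
      fixed = fixed, stringsAsFactors = FALSE)
  }
  cov_rows <- rows[rows$alt == ".", , drop = FALSE]
  others <- pileup[pileup$species == species & pileup$gene != gene$gene_id &
                     pileup$alt == ".", , drop = FALSE]
  if (nrow(cov_rows) && all(cov_rows$depth == 0) &&
      nrow(others) && any(others$depth > 0)) {
    add("whole_gene_deletion", NA_integer_, 0L, 0L)
    return(do.call(rbind, calls))
  }
  var_rows <- rows[rows$alt != "." & !is.na(rows$pos), , drop = FALSE]
  n_cod <- nchar(gene$sequence) %/% 3
  for (r in seq_len(nrow(var_rows))) {
    v <- var_rows[r, ]
    if (!as.character(v$exon) %in% names(gene$offsets))
      stop("pileup row references unknown exon ", v$exon)
    gpos <- gene$offsets[[as.character(v$exon)]] + v$pos
    if (gpos < 0 || gpos >= nchar(gene$sequence))
      stop("pileup position outside gene bounds")
    indel <- nchar(v$ref) != nchar(v$alt)
    if (indel) {
      if ((abs(nchar(v$alt) - nchar(v$ref)) %% 3) != 0 &&
          v$support >= min_support)
        add("frameshift", gpos, v$support, v$depth)
    } else if (nchar(v$ref) == 1) {
      ci <- gpos %/% 3
      codon <- substr(gene$sequence, ci * 3 + 1, ci * 3 + 3)
      substr(codon, gpos %% 3 + 1, gpos %% 3 + 1) <- v$alt
      is_stop <- !grepl("N", codon) &&
        as.character(Biostrings::translate(Biostrings::DNAString(codon))) == "*"
      if (is_stop && ci < n_cod - 1 && v$support >= min_support)
        add("nonsense", gpos, v$support, v$depth)
    }
  }
  if (!length(calls))
    return(data.frame(species = character(0), gene_id = character(0),
                      kind = character(0), position = integer(0),
                      support = integer(0), depth = integer(0),
                      fixed = logical(0)))
  do.call(rbind, calls)
}

#' Screen every gene x species combination for truncating variants
#'
#' @param exon_table Reference exon table (`gene_id`, `exon_index`, `seq`).
#' @param pileup Full pileup table.
#' @param min_support,fixed_fraction As in [call_truncations()].
#' @return Combined calls data frame across all genes and species.
#' @export
screen_truncations <- function(exon_table, pileup, min_support = 3,
                               fixed_fraction = 1) {
  out <- list()
  for (g in unique(exon_table$gene_id)) {
    gene <- assemble_gene_sequence(exon_table, g)
    for (sp in unique(pileup$species)) {
      cc <- call_truncations(gene, pileup, sp, min_support, fixed_fraction)
      if (nrow(cc)) out[[length(out) + 1L]] <- cc
    }
  }
  if (!length(out))
    return(call_truncations(assemble_gene_sequence(exon_table,
                                                   exon_table$gene_id[1]),
                            pileup[0, ], "none"))
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$species, res$position, na.last = FALSE), ,
      drop = FALSE]
}

#' Map species missense variants onto human clinical-variant sites
#'
#' Scans a protein alignment that includes the human orthologue: columns are
#' used only when the inferred ancestral residue equals the human residue
#' (ensuring site homology); at such columns, a focal-species residue that
#' differs from the ancestral residue and matches a clinical-table record at
#' that human position is reported as a match. The ancestral residue is the
#' majority residue (>= `majority` of non-gap residues) among the designated
#' outgroup species; columns without such a majority are skipped.
#'
#' @param aln Character matrix of aligned amino acids (rows = sequences,
#'   incl. the human row); `-` is a gap.
#' @param clinical Data frame with `gene_id` (optional), `position` (1-based
#'   human residue number), `variant` (amino acid), `id` (record identifier).
#' @param human Row name of the human sequence.
#' @param outgroups Row names used for ancestral-state inference (>= 3).
#' @param focal Row names of focal species to screen (default: all rows
#'   except human and outgroups).
#' @param majority Required majority among outgroup residues (default 2/3).
#' @return Data frame of matches: `species`, `column`, `human_position`,
#'   `ancestral`, `human`, `variant`, `clinical_id`.
#' @export
map_human_sites <- function(aln, clinical, human = "human", outgroups,
                            focal = NULL, majority = 2 / 3) {
  stopifnot(human %in% rownames(aln), length(outgroups) >= 3,
            all(outgroups %in% rownames(aln)))
  if (is.null(focal)) focal <- setdiff(rownames(aln), c(human, outgroups))
  bad <- clinical$position > sum(aln[human, ] != "-") | clinical$position < 1
  if (any(bad)) {
    warning(sum(bad), " clinical record(s) outside the human sequence; skipped")
    clinical <- clinical[!bad, , drop = FALSE]
  }
  matches <- list()
  hpos <- 0L
  for (col in seq_len(ncol(aln))) {
    h <- aln[human, col]
    if (h == "-") next
    hpos <- hpos + 1L
    og <- aln[outgroups, col]
    og <- og[og != "-"]
    if (!length(og)) next
    tab <- sort(table(og), decreasing = TRUE)
    if (tab[1] / length(og) < majority) next
    anc <- names(tab)[1]
    if (anc != h) next  # require homologous, conserved site
    recs <- clinical[clinical$position == hpos, , drop = FALSE]
    if (!nrow(recs)) next
    for (sp in focal) {
      r <- aln[sp, col]
      if (r == "-" || r == anc) next
      hit <- recs[recs$variant == r, , drop = FALSE]
      for (k in seq_len(nrow(hit)))
        matches[[length(matches) + 1L]] <- data.frame(
          species = sp, column = col, human_position = hpos,
          ancestral = anc, human = h, variant = r,
          clinical_id = hit$id[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(matches))
    return(data.frame(species = character(0), column = integer(0),
                      human_position = integer(0), ancestral = character(0),
                      human = character(0), variant = character(0),
                      clinical_id = character(0)))
  do.call(rbind, matches)
}

#' Pleiotropy score from a phenotype ontology
#'
#' Counts a gene's phenotype annotations outside the hematopoietic system:
#' annotations that are the hematopoietic root, descendants of it, listed
#' excluded terms (indirect phenotypes secondary to anemia, e.g. pallor or
#' spleen abnormalities), or descendants of excluded terms are removed and
#' the score is the number of annotations that remain. A score of 0 means no
#' non-hematopoietic phenotype is recorded.
#'
#' @param annotations Character vector of term ids annotated to the gene.
#' @param parents Data frame with `term_id`, `parent_id` describing the
#'   ontology DAG (an edge child -> parent).
#' @param hematopoietic_root Term id of the hematopoietic-system phenotype.
#' @param excluded Character vector of additional excluded term ids.
#' @return Integer score.
#' @export
pleiotropy_score <- function(annotations, parents, hematopoietic_root,
                             excluded = character(0)) {
  all_terms <- unique(c(parents$term_id, parents$parent_id))
  if (!hematopoietic_root %in% all_terms)
    stop("hematopoietic root term absent from the ontology")
  unknown <- setdiff(annotations, all_terms)
  if (length(unknown)) {
    warning("annotation term(s) absent from the ontology ignored: ",
            paste(unknown, collapse = ", "))
    annotations <- setdiff(annotations, unknown)
  }
  g <- igraph::graph_from_data_frame(
    parents[, c("parent_id", "term_id")], directed = TRUE,
    vertices = data.frame(name = all_terms))
  if (!igraph::is_dag(g)) stop("ontology is not acyclic")
  desc_of <- function(t) {
    if (!t %in% all_terms) return(character(0))
    names(igraph::subcomponent(g, t, mode = "out"))
  }
  removed <- unique(c(unlist(lapply(c(hematopoietic_root, excluded), desc_of)),
                      excluded))
  length(setdiff(annotations, removed))
}

#' Classify erythroid-biased and marrow-restricted expression
#'
#' @param lineage_expr Named numeric vector of expression across hematopoietic
#'   cell types for one gene; `erythrocyte` names the erythroid column.
#' @param organ_expr Named numeric vector across organs; `marrow` names the
#'   bone-marrow column.
#' @param erythrocyte,marrow Column names of the focal tissues.
#' @param fold Fold threshold: flagged when the focal value is at least
#'   `fold` times the maximum of the remaining columns (ties at `fold = 1`
#'   count as biased).
#' @return List with logical `erythroid_biased` and `marrow_restricted`.
#' @export
classify_erythroid_bias <- function(lineage_expr, organ_expr,
                                    erythrocyte = "erythrocyte",
                                    marrow = "marrow", fold = 2) {
  biased <- function(v, focal) {
    stopifnot(focal %in% names(v), all(v >= 0))
    if (all(v == 0)) {
      warning("all-zero expression row")
      return(FALSE)
    }
    rest <- v[setdiff(names(v), focal)]
    if (!length(rest)) return(TRUE)
    v[[focal]] >= fold * max(rest)
  }
  list(erythroid_biased = biased(lineage_expr, erythrocyte),
       marrow_restricted = biased(organ_expr, marrow))
}

#' Association between loss-of-function and pleiotropy
#'
#' Cross-tabulates genes by pleiotropy class (score 0 vs >= 1) and presence
#' of a loss-of-function call, and tests the association with the two-sided
#' conditional exact (hypergeometric) test. The reported odds ratio is the
#' sample ratio `ad/bc`, with the Haldane 0.5 correction applied when any
#' cell is zero (the correction affects the odds ratio only, not the
#' p-value).
#'
#' @param annotations Data frame with `pleiotropy_score` (integers >= 0) and
#'   `has_lof` (logical).
#' @return List with `table` (2x2), `odds_ratio`, `p_value`.
#' @export
lof_pleiotropy_association <- function(annotations) {
  score0 <- factor(annotations$pleiotropy_score == 0, levels = c(TRUE, FALSE),
                   labels = c("score0", "score>=1"))
  lof <- factor(annotations$has_lof, levels = c(TRUE, FALSE),
                labels = c("lof", "no_lof"))
  tab <- table(score0, lof)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in the 2x2 table")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = unname(or), p_value = p)
}
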