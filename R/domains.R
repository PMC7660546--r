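#' Basal-plus-extension regulatory domains
#'
#' Assigns each gene a regulatory domain following the GREAT
#' "basal plus extension" rule: a strand-aware basal window around the TSS
#' (5 kb upstream, 1 kb downstream by default), then each flank is extended
#' up to `max_extension` or until it meets another gene's *basal* window
#' (never another gene's extension), and never shrinks below the basal
#' window. All coordinates are 0-based half-open.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   position of the first transcribed base), `strand` (`"+"`/`"-"`).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param basal_up,basal_down Basal window, bp up/downstream of the TSS.
#' @param max_extension Maximum extension beyond the basal window per side.
#' @return Data frame with `gene_id`, `chrom`, `b_start`, `b_end`,
#'   `e_start`, `e_end` (basal and extended intervals).
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000, strand = "+")
#' compute_domains(g, c(chr1 = 3e6))
#' @export
compute_domains <- function(genes, chrom_sizes, basal_up = 5000,
                            basal_down = 1000, max_extension = 1e6) {
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(genes))) stop("genes must have columns: ",
                                        paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (!all(genes$chrom %in% names(chrom_sizes)))
    stop("gene on chromosome without a known size")
  if (any(genes$tss < 0 | genes$tss >= chrom_sizes[genes$chrom]))
    stop("tss outside chromosome bounds")
  up <- ifelse(genes$strand == "+", basal_up, basal_down)
  down <- ifelse(genes$strand == "+", basal_down, basal_up)
  clen <- unname(chrom_sizes[genes$chrom])
  b_start <- pmax(genes$tss - up, 0)
  b_end <- pmin(genes$tss + down, clen)
  e_start <- pmax(b_start - max_extension, 0)
  e_end <- pmin(b_end + max_extension, clen)
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- same[same != i]
    # nearest foreign basal boundary on each side caps the extension
    left <- same[b_end[same] <= b_start[i]]
    if (length(left)) e_start[i] <- max(e_start[i], max(b_end[left]))
    right <- same[b_start[same] >= b_end[i]]
    if (length(right)) e_end[i] <- min(e_end[i], min(b_start[right]))
    e_start[i] <- min(e_start[i], b_start[i])  # never shrink below basal
    e_end[i] <- max(e_end[i], b_end[i])
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    b_start = b_start, b_end = b_end,
                    e_start = e_start, e_end = e_end,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$b_start), , drop = FALSE]
}

#' Assign CNEs to genes via regulatory domains
#'
#' A CNE is assigned to every gene whose extended regulatory domain contains
#' it; several genes may share one CNE and a CNE far from every TSS stays
#' unassigned. By default containment is tested at the CNE midpoint
#' (half-open, so a midpoint on a domain end is outside); `mode =
#' "any_overlap"` assigns on any interval overlap instead.
#'
#' @param cnes Data frame with BED-like columns `chrom`, `start`, `end`
#'   (0-based half-open) and `cne_id`.
#' @param domains Output of [compute_domains()].
#' @param mode `"midpoint"` (default) or `"any_overlap"`.
#' @return Data frame with `cne_id` and a list-column `gene_ids`
#'   (character vector per CNE, possibly empty), in input CNE order.
#' @export
assign_cnes <- function(cnes, domains, mode = c("midpoint", "any_overlap")) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "start", "end", "cne_id") %in% names(cnes)))
  if (any(cnes$start >= cnes$end)) stop("CNE with start >= end")
  unknown <- !cnes$chrom %in% domains$chrom
  if (any(unknown))
    warning(sum(unknown), " CNE(s) on chromosomes without domains; unassigned")
  if (mode == "midpoint") {
    mid <- (cnes$start + cnes$end) %/% 2
    q_start <- mid
    q_end <- mid + 1
  } else {
    q_start <- cnes$start
    q_end <- cnes$end
  }
  gene_sets <- rep(list(character(0)), nrow(cnes))
  for (ch in unique(domains$chrom)) {
    ci <- which(cnes$chrom == ch)
    di <- which(domains$chrom == ch)
    if (!length(ci) || !length(di)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = q_start[ci] + 1L, end = q_end[ci]),
      IRanges::IRanges(start = domains$e_start[di] + 1L,
                       end = domains$e_end[di]))
    by_query <- split(domains$gene_id[di[S4Vectors::subjectHits(hits)]],
                      S4Vectors::queryHits(hits))
    for (nm in names(by_query))
      gene_sets[[ci[as.integer(nm)]]] <- by_query[[nm]]
  }
  out <- data.frame(cne_id = cnes$cne_id, stringsAsFactors = FALSE)
  out$gene_ids <- lapply(gene_sets, function(g) sort(unique(g)))
  out
}
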