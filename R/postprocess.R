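#' Build the gene-set x gene leading-edge membership matrix
#'
#' Rows are the selected gene sets, columns the union of their leading-edge
#' genes restricted to genes appearing in at least \code{min_sets} selected
#' sets (default 2, ensuring every retained gene is corroborated by more
#' than one set). Row and column display orders come from the seeded
#' clustering used for the heat maps.
#'
#' @param enrichment_results a [screen_collection()] result (rows with
#'   \code{selected = TRUE} are used; pass a pre-filtered table to override).
#' @param min_sets minimum number of selected sets a gene must appear in.
#' @param seed seed for the display clustering (default 1).
#' @return list with \code{matrix} (logical sets x genes), \code{row_order},
#'   \code{col_order}; empty matrix with a warning when nothing passes.
#' @export
build_membership_matrix <- function(enrichment_results, min_sets = 2,
                                    seed = 1) {
  res <- enrichment_results
  if ("selected" %in% names(res)) res <- res[res$selected, , drop = FALSE]
  edges <- lapply(seq_len(nrow(res)), function(i)
    unique(c(res$leading_edge_up[[i]], res$leading_edge_down[[i]])))
  names(edges) <- res$name
  counts <- table(unlist(edges))
  genes <- sort(names(counts)[counts >= min_sets])
  if (length(genes) == 0 || nrow(res) == 0) {
    warning("no gene passes the membership filter")
    return(list(matrix = matrix(FALSE, nrow(res), 0,
                                dimnames = list(res$name, NULL)),
                row_order = res$name, col_order = character(0)))
  }
  M <- vapply(genes, function(g)
    vapply(edges, function(e) g %in% e, logical(1)),
    logical(length(edges)))
  M <- matrix(M, nrow = length(edges),
              dimnames = list(names(edges), genes))
  row_order <- rownames(M)
  col_order <- colnames(M)
  if (nrow(M) > 2) {
    set.seed(seed)
    row_order <- rownames(M)[stats::hclust(stats::dist(M * 1),
                                           method = "average")$order]
  }
  if (ncol(M) > 2) {
    col_order <- colnames(M)[stats::hclust(stats::dist(t(M * 1)),
                                           method = "average")$order]
  }
  list(matrix = M, row_order = row_order, col_order = col_order)
}

#' Intersect membership-matrix genes with an ANOVA response set
#'
#' Restricts the pathway-derived (leading-edge, multi-set) genes to those
#' that also individually show a significant treatment effect, yielding the
#' significantly modulated, pathway-relevant gene list.
#'
#' @param membership_genes character vector (e.g. the column names of a
#'   [build_membership_matrix()] result).
#' @param anova_set character vector of ANOVA-selected gene symbols.
#' @return sorted character vector, the exact intersection.
#' @export
pathway_relevant_intersection <- function(membership_genes, anova_set) {
  sort(intersect(unique(membership_genes), unique(anova_set)))
}

#' Derive the epileptogenic set from per-tissue HS and NBQX selections
#'
#' Per tissue, the treatment-response (HS) selection is intersected with
#' the NBQX-response selection; the union of the per-tissue intersections
#' across tissues is the epileptogenic set. Both NBQX-induced and
#' NBQX-repressed genes are retained. Provenance (tissues of origin) is
#' recorded per gene. A tissue present in only one input is skipped with a
#' warning.
#'
#' @param hs_sets_by_tissue named list of character vectors (HS-selected
#'   genes per tissue).
#' @param nbqx_sets_by_tissue named list of character vectors
#'   (NBQX-selected genes per tissue).
#' @return data.frame with columns \code{gene} and \code{tissues}
#'   (comma-separated provenance).
#' @export
derive_epileptogenic_set <- function(hs_sets_by_tissue, nbqx_sets_by_tissue) {
  tissues <- intersect(names(hs_sets_by_tissue), names(nbqx_sets_by_tissue))
  skipped <- setdiff(union(names(hs_sets_by_tissue),
                           names(nbqx_sets_by_tissue)), tissues)
  if (length(skipped) > 0)
    warning("tissue(s) present in one input only, skipped: ",
            paste(skipped, collapse = ", "))
  prov <- list()
  for (t in tissues) {
    for (g in intersect(hs_sets_by_tissue[[t]], nbqx_sets_by_tissue[[t]]))
      prov[[g]] <- c(prov[[g]], t)
  }
  genes <- sort(names(prov))
  data.frame(gene = genes,
             tissues = vapply(prov[genes], paste, character(1),
                              collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher-exact over-representation of a query set in a target set
#'
#' One-sided hypergeometric upper-tail probability of observing at least
#' the actual overlap between a query gene set and a discrete target set
#' within a fixed background universe; selection at \code{p < p_max}
#' (default 0.01).
#'
#' @param query_set,target_set character vectors of gene symbols.
#' @param universe_n background universe size (at least as large as either
#'   set).
#' @param p_max selection threshold (default 0.01).
#' @return data.frame with \code{n_query, n_target, overlap, p_value,
#'   selected}.
#' @export
fisher_enrichment <- function(query_set, target_set, universe_n,
                              p_max = 0.01) {
  q <- unique(query_set); t <- unique(target_set)
  if (universe_n < max(length(q), length(t)))
    stop("universe smaller than one of the sets")
  ov <- length(intersect(q, t))
  p <- stats::phyper(ov - 1, length(t), universe_n - length(t), length(q),
                     lower.tail = FALSE)
  data.frame(n_query = length(q), n_target = length(t), overlap = ov,
             p_value = p, selected = p < p_max)
}

#' Fisher-exact screening of a gene-set collection against a target set
#'
#' Applies [fisher_enrichment()] to every set in a collection (up- and
#' down-regulatee lists pooled, since the target is an unsigned discrete
#' set).
#'
#' @param collection list of [gene_set()] objects.
#' @param target_set character vector of gene symbols.
#' @param universe_n background universe size.
#' @param p_max selection threshold (default 0.01).
#' @return data.frame with one row per set: \code{name, source, n_set,
#'   overlap, p_value, selected}.
#' @export
fisher_screen <- function(collection, target_set, universe_n, p_max = 0.01) {
  rows <- lapply(collection, function(s) {
    memb <- unique(c(s$up_genes, s$down_genes))
    fe <- fisher_enrichment(memb, target_set, universe_n, p_max)
    data.frame(name = s$name, source = s$source, n_set = length(memb),
               overlap = fe$overlap, p_value = fe$p_value,
               selected = fe$selected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
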