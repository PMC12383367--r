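# Candidate selection and set algebra over target genes and pathways
# per acrophase cluster.

#' Select candidate miRNAs by the two-criterion rule
#'
#' A mature miRNA is a candidate when (1) it is rhythmic with mean
#' expression above the upper quartile of the mature screen
#' (`quartile_band == "75-100"`), and (2) at least one of its annotated
#' precursors is rhythmic with mean expression above the median of all
#' screened precursors ("any precursor" when a mature form has several
#' precursors). Candidates are grouped by the acrophase cluster of the
#' mature fit. Matures passing criterion 1 with no precursor link in
#' the annotation are excluded and listed in the `excluded` report.
#'
#' @param screen_mature,screen_pre screens from [screen_rhythms()]
#'   computed with the same alpha.
#' @param annotation annotation table linking mature arms to
#'   precursors.
#' @return a list with `candidates` (data.frame: `mature_id`,
#'   `cluster`, `mature_p`, `mature_band`, `precursor_id`,
#'   `precursor_p`, `precursor_above_median`) and `excluded`
#'   (data.frame with a `reason` column).
#' @export
select_candidates <- function(screen_mature, screen_pre, annotation) {
  annotation <- validate_annotation(annotation)
  pre_median <- stats::median(screen_pre$mean_expr)
  pre_ok <- screen_pre[screen_pre$rhythmic & screen_pre$mean_expr > pre_median,
                       , drop = FALSE]
  top <- screen_mature[screen_mature$rhythmic &
                       screen_mature$quartile_band == "75-100", , drop = FALSE]
  cand <- list(); excl <- list()
  for (i in seq_len(nrow(top))) {
    mid <- top$feature_id[i]
    pres <- annotation$precursor_id[annotation$mature_id == mid]
    if (length(pres) == 0) {
      excl[[mid]] <- data.frame(mature_id = mid,
                                reason = "no precursor link in annotation",
                                stringsAsFactors = FALSE)
      next
    }
    hit <- pre_ok[pre_ok$feature_id %in% pres, , drop = FALSE]
    if (nrow(hit) == 0) {
      excl[[mid]] <- data.frame(mature_id = mid,
                                reason = "no rhythmic above-median precursor",
                                stringsAsFactors = FALSE)
      next
    }
    best <- hit[which.min(hit$p_value), ]
    cand[[mid]] <- data.frame(
      mature_id = mid, cluster = top$cluster[i],
      mature_p = top$p_value[i], mature_band = top$quartile_band[i],
      precursor_id = best$feature_id, precursor_p = best$p_value,
      precursor_above_median = TRUE, stringsAsFactors = FALSE)
  }
  empty_cand <- data.frame(mature_id = character(), cluster = character(),
                           mature_p = numeric(), mature_band = character(),
                           precursor_id = character(), precursor_p = numeric(),
                           precursor_above_median = logical(),
                           stringsAsFactors = FALSE)
  empty_excl <- data.frame(mature_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  list(candidates = if (length(cand)) do.call(rbind, c(cand, list(make.row.names = FALSE)))
                    else empty_cand,
       excluded = if (length(excl)) do.call(rbind, c(excl, list(make.row.names = FALSE)))
                  else empty_excl)
}

#' Map candidate miRNAs to target-gene sets per cluster
#'
#' Takes the union of validated target genes over each cluster's
#' miRNAs. Candidate ids can be translated to the target table's id
#' space via an explicit two-column map and/or by stripping species
#' prefixes (rat ids looked up against a human-indexed catalogue).
#' Candidates absent from the target table contribute an empty set and
#' are reported in `unmatched`.
#'
#' @param candidates the `candidates` data.frame from
#'   [select_candidates()] (needs `mature_id` and `cluster`).
#' @param targets a target table from [read_targets()] (already
#'   evidence-filtered as desired).
#' @param id_map optional data.frame with columns `from`, `to`
#'   translating candidate ids.
#' @param strip_prefix drop species prefixes on both sides before
#'   matching (default TRUE).
#' @return a list with `gene_sets` (named list cluster -> character
#'   vector of genes) and `unmatched` (candidate ids with no target
#'   rows).
#' @export
map_targets <- function(candidates, targets, id_map = NULL,
                        strip_prefix = TRUE) {
  ids <- candidates$mature_id
  if (!is.null(id_map)) {
    j <- match(ids, id_map$from)
    ids <- ifelse(is.na(j), ids, id_map$to[j])
  }
  tid <- targets$mirna_id
  if (strip_prefix) {
    ids <- strip_species_prefix(ids)
    tid <- strip_species_prefix(tid)
  }
  unmatched <- candidates$mature_id[!ids %in% tid]
  gene_sets <- lapply(split(ids, candidates$cluster), function(v)
    sort(unique(targets$target_gene[tid %in% v])))
  list(gene_sets = gene_sets, unmatched = unmatched)
}

#' Venn regions of two or three labeled sets
#'
#' Exact set algebra: every element of the union is assigned to one of
#' the `2^k - 1` disjoint membership regions.
#'
#' @param sets a named list of 2 or 3 character vectors.
#' @return a list with `regions` (data.frame: `region`, `count`) and
#'   `members` (named list of the region memberships). Region labels
#'   join set names with `&` for intersections, e.g. `"A&B"` is the
#'   part of A and B outside any other set.
#' @export
venn <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) format_error("venn takes 2 or 3 sets, got %d", k)
  if (is.null(names(sets)) || any(names(sets) == ""))
    format_error("sets must be named")
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  # all 2^k - 1 regions, present or not
  idx <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  labels <- apply(idx, 1, function(row)
    paste(names(sets)[unlist(row)], collapse = "&"))
  members <- lapply(labels, function(lb) u[pattern == lb])
  names(members) <- labels
  list(regions = data.frame(region = labels,
                            count = vapply(members, length, 0L),
                            row.names = NULL, stringsAsFactors = FALSE),
       members = members)
}

#' Dark-phase versus light-phase specific gene sets
#'
#' Convenience wrapper computing the genes specific to the dark-phase
#' clusters (`(D1 u D2) \ L1`), specific to the light phase
#' (`L1 \ (D1 u D2)`) and shared, as a 2-set Venn.
#'
#' @param gene_sets named list with elements `D1`, `D2`, `L1`
#'   (missing clusters count as empty).
#' @return a [venn()] result over the D and L unions.
#' @export
phase_specific_genes <- function(gene_sets) {
  g <- function(n) if (!is.null(gene_sets[[n]])) gene_sets[[n]] else character()
  venn(list(D = union(g("D1"), g("D2")), L = g("L1")))
}

#' Pathway sets per cluster with a minimum-gene filter
#'
#' A pathway is retained for a cluster when at least `min_genes` of the
#' cluster's target genes map to it. Genes without any pathway
#' annotation are ignored and counted in the coverage report.
#'
#' @param gene_sets named list cluster -> gene vector.
#' @param pathways pathway table from [read_pathways()].
#' @param min_genes retention threshold (default 3).
#' @return a list with `pathway_sets` (named list cluster ->
#'   data.frame `pathway_accession`, `pathway_name`, `n_genes`) and
#'   `coverage` (per cluster: genes mapped / total).
#' @export
pathway_sets <- function(gene_sets, pathways, min_genes = 3) {
  if (nrow(pathways) == 0) format_error("pathway table is empty")
  res <- lapply(gene_sets, function(genes) {
    hit <- pathways[pathways$gene_symbol %in% genes, , drop = FALSE]
    if (nrow(hit) == 0)
      return(data.frame(pathway_accession = character(),
                        pathway_name = character(), n_genes = integer(),
                        stringsAsFactors = FALSE))
    tab <- stats::aggregate(gene_symbol ~ pathway_accession + pathway_name,
                            hit, function(g) length(unique(g)))
    names(tab)[3] <- "n_genes"
    tab <- tab[tab$n_genes >= min_genes, , drop = FALSE]
    tab <- tab[order(-tab$n_genes, tab$pathway_accession), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
  coverage <- lapply(gene_sets, function(genes)
    c(mapped = sum(genes %in% pathways$gene_symbol), total = length(genes)))
  list(pathway_sets = res, coverage = coverage)
}
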