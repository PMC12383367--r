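# Strand/precursor census: structural family classes, mature-vs-
# precursor correlation classes, guide-strand assignment, and the
# quartile distribution of correlating strands.

# expressed = present in the matrix with any nonzero value
.expressed <- function(ids, mat) {
  ids %in% rownames(mat) & vapply(ids, function(i)
    i %in% rownames(mat) && any(mat[i, ] > 0), logical(1))
}

# family-level view of an annotation table
.family_table <- function(annotation) {
  annotation <- validate_annotation(annotation)
  annotation$family <- mirna_family(annotation$mature_id)
  split(annotation, annotation$family)
}

#' Classify miRNA families by strand and locus structure
#'
#' Sorts mature-miRNA families into the four structural classes of the
#' strand census: both arms expressed from a single precursor
#' (`dual_single_locus`), one arm from a single precursor
#' (`single_single_locus`), both arms from several precursors
#' (`dual_multi_locus`), one arm from several precursors
#' (`single_multi_locus`). A family counts as expressed when at least
#' one of its annotated arms has nonzero expression; mature ids present
#' in the matrix but absent from the annotation are returned in an
#' `unannotated` report and excluded from percentages.
#'
#' @param annotation annotation table (see [read_annotation()]).
#' @param mature mature-arm expression matrix.
#' @return a list with `families` (data.frame: `family`, `arms`,
#'   `n_loci`, `mature_class`), `counts`, `percent` (rounded to integer
#'   percent, denominator = expressed families) and `unannotated`.
#' @export
classify_families <- function(annotation, mature) {
  fams <- .family_table(annotation)
  unannotated <- setdiff(rownames(mature), annotation$mature_id)
  rows <- lapply(names(fams), function(f) {
    a <- fams[[f]]
    arm_map <- unique(a[c("mature_id", "arm")])
    expr <- .expressed(arm_map$mature_id, mature)
    arms <- sort(unique(arm_map$arm[expr]))
    if (length(arms) == 0) return(NULL)  # nothing expressed: orphan path
    n_loci <- length(unique(a$precursor_id))
    cls <- if (length(arms) == 2 && n_loci == 1) "dual_single_locus"
      else if (length(arms) == 1 && n_loci == 1) "single_single_locus"
      else if (length(arms) == 2) "dual_multi_locus"
      else "single_multi_locus"
    data.frame(family = f, arms = paste(arms, collapse = "+"),
               n_loci = n_loci, mature_class = cls, stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  lv <- c("dual_single_locus", "single_single_locus",
          "dual_multi_locus", "single_multi_locus")
  counts <- table(factor(families$mature_class, levels = lv))
  list(families = families,
       counts = counts,
       percent = stats::setNames(round(100 * as.numeric(counts) / sum(counts)), lv),
       unannotated = unannotated)
}

#' Classify precursors by mature-form presence and gene count
#'
#' Sorts precursors into `single_locus_with_mature` (coded by one
#' gene, mature form detected), `multi_locus_with_mature` (coded by
#' more than one gene, mature form detected) and `orphan` (no mature
#' arm of the family has nonzero expression).
#'
#' @param annotation annotation table.
#' @param mature mature-arm expression matrix.
#' @return a list with `precursors` (data.frame: `precursor_id`,
#'   `n_genes`, `class`), `counts` and `percent`.
#' @export
classify_precursors <- function(annotation, mature) {
  annotation <- validate_annotation(annotation)
  sp <- split(annotation, annotation$precursor_id)
  rows <- lapply(names(sp), function(p) {
    a <- sp[[p]]
    n_genes <- length(unique(a$locus_id))
    has_mature <- any(.expressed(unique(a$mature_id), mature))
    cls <- if (!has_mature) "orphan"
      else if (n_genes == 1) "single_locus_with_mature"
      else "multi_locus_with_mature"
    data.frame(precursor_id = p, n_genes = n_genes, class = cls,
               stringsAsFactors = FALSE)
  })
  precursors <- do.call(rbind, rows)
  lv <- c("single_locus_with_mature", "multi_locus_with_mature", "orphan")
  counts <- table(factor(precursors$class, levels = lv))
  list(precursors = precursors, counts = counts,
       percent = stats::setNames(round(100 * as.numeric(counts) / sum(counts)), lv))
}

# regression slope p of y on x; zero variance in either => no verdict
.arm_regression <- function(y, x, log_scale = FALSE) {
  if (log_scale) { y <- log(y + 1); x <- log(x + 1) }
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
  fit <- stats::lm(y ~ x)
  # an exact linear dependence gives a perfect fit; the slope test is
  # still well-defined in the limit (p -> 0), so silence the warning
  sm <- suppressWarnings(summary(fit))
  p <- sm$coefficients[2, 4]
  if (is.nan(p)) p <- if (abs(stats::coef(fit)[2]) > 0) 0 else 1
  list(r = stats::cor(x, y), p = p, flagged = FALSE)
}

#' Correlation class of a single-precursor dual-arm family
#'
#' For a family expressing both arms from one precursor, regresses each
#' arm's expression on the precursor's across all samples
#' ("correlates" = regression slope p < `alpha`) and combines the two
#' verdicts into `both`, `5p_only`, `3p_only` or `neither`. Families
#' with several precursors or a single expressed arm are
#' `not_applicable`. A zero-variance series yields a "no correlation"
#' verdict and is flagged.
#'
#' @param family family id (see [mirna_family()]).
#' @param annotation annotation table.
#' @param mature,pre expression matrices.
#' @param alpha significance level (default 0.05).
#' @param log_scale regress on log(x + 1) scales instead of raw
#'   relative units.
#' @return a list with `corr_class`, `r_5p`, `p_5p`, `r_3p`, `p_3p`,
#'   `flagged`.
#' @export
correlate_mature_pre <- function(family, annotation, mature, pre,
                                 alpha = 0.05, log_scale = FALSE) {
  annotation <- validate_annotation(annotation)
  a <- annotation[mirna_family(annotation$mature_id) == family, , drop = FALSE]
  if (nrow(a) == 0) format_error("family '%s' not in annotation", family)
  arm_map <- unique(a[c("mature_id", "arm")])
  n_loci <- length(unique(a$precursor_id))
  expr <- .expressed(arm_map$mature_id, mature)
  res <- list(corr_class = "not_applicable",
              r_5p = NA_real_, p_5p = NA_real_,
              r_3p = NA_real_, p_3p = NA_real_, flagged = FALSE)
  if (n_loci != 1 || sum(expr) != 2) return(res)
  pre_id <- unique(a$precursor_id)
  if (!pre_id %in% rownames(pre)) return(res)
  x <- pre[pre_id, ]
  verdict <- c(`5p` = FALSE, `3p` = FALSE)
  for (arm in c("5p", "3p")) {
    mid <- arm_map$mature_id[arm_map$arm == arm]
    reg <- .arm_regression(mature[mid, ], x, log_scale)
    res[[paste0("r_", arm)]] <- reg$r
    res[[paste0("p_", arm)]] <- reg$p
    res$flagged <- res$flagged || reg$flagged
    verdict[arm] <- !reg$flagged && reg$p < alpha
  }
  res$corr_class <- if (verdict["5p"] && verdict["3p"]) "both"
    else if (verdict["5p"]) "5p_only"
    else if (verdict["3p"]) "3p_only" else "neither"
  res
}

#' Assign the guide arm of a dual-arm family
#'
#' The guide arm (the duplex arm loaded into the silencing complex) is
#' operationalized as the arm with greater mean expression across all
#' samples; an explicit annotation override wins when provided; an
#' exact tie is `undetermined`.
#'
#' @param family family id.
#' @param annotation annotation table.
#' @param mature expression matrix.
#' @param annotation_override optional `"5p"` or `"3p"`.
#' @return `"5p"`, `"3p"` or `"undetermined"`.
#' @export
assign_guide <- function(family, annotation, mature, annotation_override = NULL) {
  if (!is.null(annotation_override)) {
    stopifnot(annotation_override %in% c("5p", "3p"))
    return(annotation_override)
  }
  annotation <- validate_annotation(annotation)
  a <- unique(annotation[mirna_family(annotation$mature_id) == family,
                         c("mature_id", "arm")])
  means <- vapply(c("5p", "3p"), function(arm) {
    mid <- a$mature_id[a$arm == arm]
    if (length(mid) == 1 && mid %in% rownames(mature)) mean(mature[mid, ])
    else NA_real_
  }, numeric(1))
  if (any(is.na(means))) format_error("family '%s' does not have both arms", family)
  if (means["5p"] > means["3p"]) "5p"
  else if (means["3p"] > means["5p"]) "3p"
  else "undetermined"
}

#' Build the full strand atlas
#'
#' Runs the structural census, per-family mature-vs-precursor
#' correlation classification and guide-arm assignment, and summarizes
#' the correlation classes of single-precursor dual-arm families (the
#' published census reports these as counts with the share of families
#' having at least one correlating arm).
#'
#' @param annotation annotation table.
#' @param mature,pre expression matrices.
#' @param alpha correlation significance level.
#' @param log_scale see [correlate_mature_pre()].
#' @return a list with `families` (per-family table including
#'   `corr_class` and `guide_arm`), `mature_census`,
#'   `precursor_census`, `corr_counts`, `pct_any_arm`, `pct_5p_only`,
#'   `pct_3p_only`, `pct_both` (rounded percentages over applicable
#'   families) and `guide_concordance` (among single-arm-correlating
#'   families, the share whose correlating arm is the guide).
#' @export
strand_atlas <- function(annotation, mature, pre, alpha = 0.05,
                         log_scale = FALSE) {
  census <- classify_families(annotation, mature)
  pre_census <- classify_precursors(annotation, mature)
  fam_ids <- census$families$family
  corr <- lapply(fam_ids, correlate_mature_pre, annotation = annotation,
                 mature = mature, pre = pre, alpha = alpha,
                 log_scale = log_scale)
  guide <- vapply(seq_along(fam_ids), function(i) {
    if (census$families$mature_class[i] %in%
        c("dual_single_locus", "dual_multi_locus"))
      assign_guide(fam_ids[i], annotation, mature)
    else "undetermined"
  }, character(1))
  families <- cbind(census$families,
                    corr_class = vapply(corr, `[[`, "", "corr_class"),
                    r_5p = vapply(corr, `[[`, 0, "r_5p"),
                    p_5p = vapply(corr, `[[`, 0, "p_5p"),
                    r_3p = vapply(corr, `[[`, 0, "r_3p"),
                    p_3p = vapply(corr, `[[`, 0, "p_3p"),
                    guide_arm = guide,
                    stringsAsFactors = FALSE)
  app <- families$corr_class != "not_applicable"
  lv <- c("both", "5p_only", "3p_only", "neither")
  cc <- table(factor(families$corr_class[app], levels = lv))
  n_app <- sum(app)
  pct <- function(x) round(100 * x / n_app)
  one_arm_5p <- app & families$corr_class == "5p_only"
  one_arm_3p <- app & families$corr_class == "3p_only"
  guide_conc <- c(
    `5p` = if (any(one_arm_5p)) mean(families$guide_arm[one_arm_5p] == "5p")
           else NA_real_,
    `3p` = if (any(one_arm_3p)) mean(families$guide_arm[one_arm_3p] == "3p")
           else NA_real_)
  list(families = families,
       mature_census = census,
       precursor_census = pre_census,
       corr_counts = cc,
       pct_any_arm = pct(sum(cc[c("both", "5p_only", "3p_only")])),
       pct_both = pct(cc[["both"]]),
       pct_5p_only = pct(cc[["5p_only"]]),
       pct_3p_only = pct(cc[["3p_only"]]),
       guide_concordance = guide_conc)
}

#' Quartile distribution of correlating strands
#'
#' For each arm, counts how many correlating families fall into each
#' expression quartile of that arm (quartiles computed over the
#' correlation-eligible families), asking whether correlation with the
#' precursor concentrates among abundant strands.
#'
#' @param atlas result of [strand_atlas()] (or a compatible `families`
#'   data.frame inside a list).
#' @param annotation annotation table.
#' @param mature expression matrix.
#' @return a data.frame with columns `arm`, `quartile_band`,
#'   `n_correlating`, `n_families`.
#' @export
correlating_share_by_quartile <- function(atlas, annotation, mature) {
  fam <- atlas$families
  el <- fam[fam$corr_class != "not_applicable", , drop = FALSE]
  if (nrow(el) < 4) format_error("need >= 4 eligible families")
  annotation <- validate_annotation(annotation)
  arm_map <- unique(annotation[c("mature_id", "arm")])
  arm_map$family <- mirna_family(arm_map$mature_id)
  out <- list()
  for (arm in c("5p", "3p")) {
    ids <- arm_map$mature_id[arm_map$arm == arm &
                             arm_map$family %in% el$family]
    fams <- arm_map$family[match(ids, arm_map$mature_id)]
    mexp <- rowMeans(mature[ids, , drop = FALSE])
    band <- .quartile_band(mexp)
    correlating <- el$corr_class[match(fams, el$family)] %in%
      c("both", paste0(arm, "_only"))
    for (b in c("75-100", "50-75", "25-50", "0-25"))
      out[[paste(arm, b)]] <- data.frame(
        arm = arm, quartile_band = b,
        n_correlating = sum(correlating & band == b),
        n_families = sum(band == b), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
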