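# builds a deterministic mature+pre dataset where the rhythmic
# top-quartile matures (with rhythmic above-median precursors) are
# exactly the ones named in `plant`: a named list cluster -> mature ids
build_selection_dataset <- function(plant, n_background = 60) {
  meta <- design_meta()
  t <- meta$zt_hours
  w <- 2 * pi / 24
  phases <- c(D1 = 15, D2 = 21, L1 = 3, L2 = 9)
  mature <- list(); pre <- list(); ann <- list()
  for (cl in names(plant)) for (mir in plant[[cl]]) {
    mid <- paste0(mir, "-5p")
    prof <- 5000 * (1 + 0.5 * cos(w * (t - phases[[cl]])))
    mature[[mid]] <- prof
    pre[[mir]] <- prof / 5
    ann[[mid]] <- data.frame(mature_id = mid, arm = "5p",
                             precursor_id = mir,
                             locus_id = paste0(mir, "-locus"),
                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_background)) {   # flat, low-expressed background
    mid <- sprintf("miR-bg%03d-5p", i)
    fam <- sprintf("mir-bg%03d", i)
    mature[[mid]] <- rep(10 + i, length(t))
    pre[[fam]] <- rep(2 + 0.1 * i, length(t))
    ann[[mid]] <- data.frame(mature_id = mid, arm = "5p",
                             precursor_id = fam,
                             locus_id = paste0(fam, "-locus"),
                             stringsAsFactors = FALSE)
  }
  mk <- function(rows) {
    m <- do.call(rbind, rows); colnames(m) <- meta$sample_id; m
  }
  list(mature = mk(mature), pre = mk(pre),
       annotation = validate_annotation(do.call(rbind, ann)), meta = meta)
}

test_that("candidate selection applies both inclusion criteria", {
  plant <- list(D1 = c("mir-aa", "mir-ab"))
  ds <- build_selection_dataset(plant)
  sm <- screen_rhythms(ds$mature, ds$meta)
  sp <- screen_rhythms(ds$pre, ds$meta)
  cs <- select_candidates(sm, sp, ds$annotation)
  expect_setequal(cs$candidates$mature_id, c("mir-aa-5p", "mir-ab-5p"))
  expect_true(all(cs$candidates$cluster == "D1"))

  # arrhythmic precursor knocks a mature out (criterion 2)
  ds2 <- ds
  ds2$pre["mir-aa", ] <- mean(ds2$pre["mir-aa", ])
  sp2 <- screen_rhythms(ds2$pre, ds$meta)
  cs2 <- select_candidates(sm, sp2, ds$annotation)
  expect_equal(cs2$candidates$mature_id, "mir-ab-5p")
  expect_true("mir-aa-5p" %in% cs2$excluded$mature_id)

  # mature below the top quartile is excluded regardless of p (criterion 1):
  # shrink its abundance into the 50-75 band but keep it rhythmic
  ds3 <- ds
  ds3$mature["mir-aa-5p", ] <- ds3$mature["mir-aa-5p", ] / 100
  sm3 <- screen_rhythms(ds3$mature, ds$meta)
  row <- sm3[sm3$feature_id == "mir-aa-5p", ]
  expect_true(row$rhythmic && row$quartile_band != "75-100")
  cs3 <- select_candidates(sm3, sp, ds$annotation)
  expect_false("mir-aa-5p" %in% cs3$candidates$mature_id)

  # candidate with no precursor link is excluded and logged
  ann4 <- ds$annotation[ds$annotation$mature_id != "mir-aa-5p", ]
  cs4 <- select_candidates(sm, sp, ann4)
  expect_true("mir-aa-5p" %in% cs4$excluded$mature_id)
})

test_that("selection is monotone in alpha", {
  sim <- simulate_expression(sim_config(n_families = 120, frac_rhythmic = 0.3,
                                        seed = 14))
  sm1 <- screen_rhythms(sim$mature, sim$meta, alpha = 0.01)
  sp1 <- screen_rhythms(sim$pre, sim$meta, alpha = 0.01)
  sm2 <- screen_rhythms(sim$mature, sim$meta, alpha = 0.10)
  sp2 <- screen_rhythms(sim$pre, sim$meta, alpha = 0.10)
  c1 <- select_candidates(sm1, sp1, sim$annotation)$candidates$mature_id
  c2 <- select_candidates(sm2, sp2, sim$annotation)$candidates$mature_id
  expect_true(all(c1 %in% c2))
})

test_that("the acrophase-clustered candidate lists are reproduced end-to-end", {
  plant <- list(D1 = c("mir-128", "mir-129", "mir-139", "mir-150", "mir-425"),
                D2 = c("mir-148a", "mir-148b", "let-7g", "mir-185"),
                L1 = c("mir-30d"))
  ds <- build_selection_dataset(plant)
  cs <- select_candidates(screen_rhythms(ds$mature, ds$meta),
                          screen_rhythms(ds$pre, ds$meta),
                          ds$annotation)
  got <- split(cs$candidates$mature_id, cs$candidates$cluster)
  expect_setequal(got$D1, paste0(plant$D1, "-5p"))
  expect_setequal(got$D2, paste0(plant$D2, "-5p"))
  expect_setequal(got$L1, paste0(plant$L1, "-5p"))
})

test_that("target mapping unions genes per cluster and logs unmatched ids", {
  cand <- data.frame(mature_id = c("rno-miR-1-5p", "rno-miR-2-5p", "rno-miR-9-5p"),
                     cluster = c("D1", "D1", "L1"), stringsAsFactors = FALSE)
  targets <- data.frame(
    mirna_id = c("hsa-miR-1-5p", "hsa-miR-1-5p", "hsa-miR-2-5p"),
    target_gene = c("G1", "G2", "G2"),
    support_type = "Functional MTI", species = "hsa",
    stringsAsFactors = FALSE)
  mt <- map_targets(cand, targets)
  expect_setequal(mt$gene_sets$D1, c("G1", "G2"))
  expect_equal(mt$unmatched, "rno-miR-9-5p")
  expect_true(is.null(mt$gene_sets$L1) || length(mt$gene_sets$L1) == 0)
  # without prefix stripping nothing matches
  mt2 <- map_targets(cand, targets, strip_prefix = FALSE)
  expect_equal(length(mt2$gene_sets$D1), 0)
  # explicit id map wins
  mt3 <- map_targets(cand, targets,
                     id_map = data.frame(from = "rno-miR-9-5p",
                                         to = "hsa-miR-1-5p"))
  expect_setequal(mt3$gene_sets$L1, c("G1", "G2"))
})

test_that("venn regions match explicit set-operation enumeration", {
  v <- venn(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(v$regions$count[match(c("A", "B", "A&B"), v$regions$region)],
               c(1L, 1L, 1L))
  same <- venn(list(X = letters[1:4], Y = letters[1:4]))
  expect_equal(same$regions$count[same$regions$region == "X&Y"], 4L)
  expect_equal(sum(same$regions$count), 4L)

  set.seed(23)
  for (i in 1:20) {
    s <- list(A = sample(letters, sample(0:20, 1)),
              B = sample(letters, sample(0:20, 1)),
              C = sample(letters, sample(0:20, 1)))
    v3 <- venn(s)
    # brute-force oracle via setdiff/intersect algebra
    oracle <- c(
      "A" = length(setdiff(s$A, union(s$B, s$C))),
      "B" = length(setdiff(s$B, union(s$A, s$C))),
      "C" = length(setdiff(s$C, union(s$A, s$B))),
      "A&B" = length(setdiff(intersect(s$A, s$B), s$C)),
      "A&C" = length(setdiff(intersect(s$A, s$C), s$B)),
      "B&C" = length(setdiff(intersect(s$B, s$C), s$A)),
      "A&B&C" = length(intersect(intersect(s$A, s$B), s$C)))
    got <- stats::setNames(v3$regions$count, v3$regions$region)
    expect_equal(got[names(oracle)], oracle, ignore_attr = TRUE)
    # regions are disjoint and sum to the union
    expect_equal(sum(v3$regions$count), length(unique(unlist(s))))
    # order invariance
    v3r <- venn(s[c("C", "A", "B")])
    expect_equal(sum(v3r$regions$count), sum(v3$regions$count))
    expect_equal(v3r$regions$count[v3r$regions$region == "A&B&C" |
                                   v3r$regions$region == "C&A&B"],
                 v3$regions$count[v3$regions$region == "A&B&C"])
  }
})

test_that("phase-specific gene sets split dark from light targets", {
  gs <- list(D1 = c("G1", "G2"), D2 = c("G2", "G3"), L1 = c("G3", "G4"))
  v <- phase_specific_genes(gs)
  expect_setequal(v$members$D, c("G1", "G2"))       # dark-specific
  expect_setequal(v$members$L, "G4")                # light-specific
  expect_setequal(v$members$`D&L`, "G3")
})

test_that("pathway retention respects the minimum-gene threshold", {
  pw <- data.frame(
    gene_symbol = c("G1", "G2", "G3", "G4", "G5", "H1", "H2"),
    pathway_accession = c(rep("P00059", 5), "P00057", "P00057"),
    pathway_name = c(rep("p53 pathway", 5), rep("Wnt signaling", 2)),
    stringsAsFactors = FALSE)
  # exactly 3 mapped genes retained, 2 dropped
  ps <- pathway_sets(list(D1 = c("G1", "G2", "G3", "H1", "H2")), pw)
  expect_equal(ps$pathway_sets$D1$pathway_accession, "P00059")
  expect_equal(ps$pathway_sets$D1$n_genes, 3L)
  # min_genes = 1 keeps every touched pathway
  ps1 <- pathway_sets(list(D1 = c("G1", "H1")), pw, min_genes = 1)
  expect_setequal(ps1$pathway_sets$D1$pathway_accession,
                  c("P00059", "P00057"))
  # one pathway reached by disjoint gene sets appears in both clusters
  ps2 <- pathway_sets(list(D1 = c("G1", "G2", "G3"),
                           D2 = c("G3", "G4", "G5")), pw)
  expect_equal(ps2$pathway_sets$D1$pathway_accession, "P00059")
  expect_equal(ps2$pathway_sets$D2$pathway_accession, "P00059")
  # coverage report counts unmapped genes
  ps3 <- pathway_sets(list(L1 = c("G1", "ZZZ")), pw, min_genes = 1)
  expect_equal(unname(ps3$coverage$L1["mapped"]), 1)
})
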