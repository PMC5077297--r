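test_that("degenerate clustering cases behave as documented", {
  # all points identical: one cluster
  s <- make_scores(rep(0.5, 5), rep(0.5, 5))
  expect_equal(nrow(cluster_peptides(s)$clusters), 1)
  # infinite cut: everything merges
  s2 <- make_scores(runif(10), runif(10, -1, 1))
  expect_equal(nrow(cluster_peptides(s2, cut_height = Inf)$clusters), 1)
  # one peptide: trivial cluster with a warning
  expect_warning(a <- cluster_peptides(make_scores(0.5, 0.5)), "single")
  expect_equal(nrow(a$clusters), 1)
})

test_that("two separated blobs split at cut 0.2 and the top blob is selected", {
  set.seed(31)
  n <- 20
  blob_hi <- cbind(0.9 + runif(n, -0.02, 0.02), 0.9 + runif(n, -0.02, 0.02))
  blob_lo <- cbind(0.1 + runif(n, -0.02, 0.02), 0.0 + runif(n, -0.02, 0.02))
  # within-blob distances < 0.2, across-blob distances > 0.2
  all_pts <- rbind(blob_hi, blob_lo)
  d <- as.matrix(dist(all_pts))
  expect_true(all(d[1:n, 1:n] < 0.2) && all(d[n + 1:n, n + 1:n] < 0.2))
  expect_true(all(d[1:n, n + 1:n] > 0.2))
  s <- make_scores(all_pts[, 1], all_pts[, 2])
  a <- select_natural_cluster(cluster_peptides(s, cut_height = 0.2))
  expect_equal(nrow(a$clusters), 2)
  planted <- rep(1:2, each = n)
  expect_equal(length(unique(a$peptides$cluster[planted == 1])), 1)
  expect_equal(length(unique(a$peptides$cluster[planted == 2])), 1)
  sel <- a$clusters[a$clusters$selected, ]
  expect_gt(sel$centroid_r, 0.8)
  expect_gt(sel$centroid_e, 0.8)
})

test_that("natural-cluster ties break on enrichment then size", {
  # centroids (1,0) and (0,1): equal quality, higher enrichment wins
  s <- make_scores(c(rep(1, 3), rep(0, 3)), c(rep(0, 3), rep(1, 3)))
  a <- select_natural_cluster(cluster_peptides(s))
  sel <- a$clusters[a$clusters$selected, ]
  expect_equal(sel$centroid_e, 1)
  expect_equal(sel$centroid_r, 0)
  # single cluster: it is selected
  s1 <- make_scores(rep(0.2, 4), rep(0.2, 4))
  a1 <- select_natural_cluster(cluster_peptides(s1))
  expect_true(all(a1$peptides$selected))
})

test_that("clustering is invariant to peptide input order", {
  set.seed(33)
  s <- make_scores(runif(60), runif(60, -1, 1))
  a1 <- cluster_peptides(s)
  perm <- sample(nrow(s))
  a2 <- cluster_peptides(s[perm, ])
  m <- merge(a1$peptides, a2$peptides, by = "peptide_id")
  # identical partitions (labels are canonicalized, so directly comparable)
  expect_identical(m$cluster.x, m$cluster.y)
})

test_that("a lower cut refines the partition at a higher cut", {
  set.seed(34)
  s <- make_scores(runif(80), runif(80, -1, 1))
  fine <- cluster_peptides(s, cut_height = 0.1)$peptides$cluster
  coarse <- cluster_peptides(s, cut_height = 0.2)$peptides$cluster
  # each fine cluster maps into exactly one coarse cluster
  expect_true(all(tapply(coarse, fine,
                         function(x) length(unique(x))) == 1))
})

test_that("protein calls follow the selected-peptide count rule", {
  sim <- simulate_peptide_table(sim_config(n_proteins = 60, seed = 21))
  res <- run_peptide_pipeline(sim$table)
  all_sel <- tapply(res$assignment$peptides$selected,
                    res$scores$protein_group, all)
  none_sel <- tapply(res$assignment$peptides$selected,
                     res$scores$protein_group, function(x) !any(x))
  calls <- setNames(res$calls$call, res$calls$protein_group)
  expect_true(all(calls[names(all_sel)[all_sel]] == "core_glycosylated"))
  expect_true(all(calls[names(none_sel)[none_sel]] == "background"))
  # min_peptides = 2 demands two selected peptides
  calls2 <- call_protein_groups(res$assignment, impute_missing_as_zero(
    sim$table), min_peptides = 2)
  n_sel <- setNames(calls2$n_selected_peptides, calls2$protein_group)
  expect_identical(calls2$call == "core_glycosylated",
                   unname(n_sel[calls2$protein_group] >= 2))
  # unknown peptide -> error naming it
  bad <- res$assignment
  bad$peptides$peptide_id[1] <- "ghost"
  expect_error(call_protein_groups(bad, impute_missing_as_zero(sim$table)),
               "ghost")
})

test_that("retrospective KS behaves at its extremes", {
  scores <- make_scores(c(1, 1, 0.5, 0.4), c(0.9, 0.8, 0.9, 0.8),
                        protein_group = c("P1", "P1", "P2", "P2"))
  calls <- data.frame(protein_group = c("P1", "P2"),
                      call = c("core_glycosylated", "background"))
  # literally equal enrichment samples -> D = 0
  ks <- retrospective_ks(scores, calls)
  expect_equal(ks$D_enrichment, 0)
  # disjoint repeatability supports -> D = 1
  expect_equal(ks$D_repeatability, 1)
  calls_empty <- data.frame(protein_group = c("P1", "P2"),
                            call = c("background", "background"))
  expect_error(retrospective_ks(scores, calls_empty), "empty")
})

test_that("called proteins' peptides dominate the background in enrichment", {
  sim <- simulate_peptide_table(sim_config(seed = 22))
  res <- run_peptide_pipeline(sim$table)
  expect_false(is.null(res$ks))
  expect_gt(res$ks$D_enrichment, 0.5)
  expect_lt(res$ks$p_enrichment, 1e-6)
  in_core <- res$scores$protein_group %in% res$core_proteins
  expect_gt(mean(res$scores$enrichment[in_core]),
            mean(res$scores$enrichment[!in_core]))
})
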