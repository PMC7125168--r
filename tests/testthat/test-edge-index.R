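test_that("edge_count matches brute-force pair enumeration", {
  expect_identical(edge_count(90), 4005L)
  expect_identical(edge_count(2), 1L)
  # independent oracle: enumerate all unordered pairs
  expect_identical(edge_count(13), ncol(utils::combn(13, 2)))
  for (R in c(3, 7, 24)) {
    expect_identical(edge_count(R), ncol(utils::combn(R, 2)))
  }
  expect_error(edge_count(1), "must be")
})

test_that("edge index is a lexicographic bijection over unordered pairs", {
  idx <- edge_index(13)
  expect_equal(length(idx), 78)
  pairs <- idx$pairs
  expect_true(all(pairs$i < pairs$j))
  expect_false(anyDuplicated(paste(pairs$i, pairs$j)) > 0)
  # lexicographic (i, j) order
  key <- pairs$i * 1000 + pairs$j
  expect_true(all(diff(key) > 0))
  # pure function of the region list: rebuilding yields the identical order
  expect_identical(edge_index(13)$pairs, pairs)
  expect_error(edge_index(5, c("a", "b", "c", "d", "a")), "unique")
})

test_that("matrix vectorisation reads the upper triangle and round-trips", {
  idx <- edge_index(3, c("A", "B", "C"))
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.2
  M[1, 3] <- M[3, 1] <- 0.5
  M[2, 3] <- M[3, 2] <- 0.9
  expect_equal(vectorize_matrix(M, idx), c(0.2, 0.5, 0.9))
  expect_equal(unname(devectorize_edges(vectorize_matrix(M, idx), idx)), M)

  set.seed(11)
  idx90 <- edge_index(90, aal90_regions())
  v <- runif(4005)
  M90 <- devectorize_edges(v, idx90)
  expect_length(vectorize_matrix(M90, idx90), 4005)
  expect_equal(vectorize_matrix(M90, idx90), v)

  bad <- M; bad[1, 2] <- 0.3
  expect_error(vectorize_matrix(bad, idx), "asymmetric")
  bad2 <- M; diag(bad2) <- 0.1
  expect_error(vectorize_matrix(bad2, idx), "diagonal")
  bad3 <- M; bad3[1, 3] <- bad3[3, 1] <- NA
  expect_error(vectorize_matrix(bad3, idx), "missing")
})

test_that("edge labels and ids are mutually inverse", {
  idx <- edge_index(90, aal90_regions())
  expect_equal(edge_label(1, idx), paste0(aal90_regions()[1], "-", aal90_regions()[2]))
  id <- edge_id_of("Lingual.L", "Temporal.Sup.R", idx)
  expect_equal(edge_label(id, idx), "Lingual.L-Temporal.Sup.R")
  # order of the pair is irrelevant
  expect_equal(edge_id_of("Temporal.Sup.R", "Lingual.L", idx), id)
  expect_error(edge_label(4006, idx), "out of range")
  expect_error(edge_id_of("Nowhere.L", "Lingual.L", idx), "unknown region")
})

test_that("packaged AAL-90 list has 90 unique dotted labels covering the reported consensus regions", {
  labs <- aal90_regions()
  expect_length(labs, 90)
  expect_false(anyDuplicated(labs) > 0)
  expect_true(all(grepl("\\.(L|R)$", labs)))
  # every region name appearing in the published per-band consensus edge
  # lists must resolve against the packaged label set
  reported <- c(
    "Lingual.L", "Temporal.Sup.R", "Frontal.Mid.R", "Insula.L",
    "Postcentral.R", "Supp.Motor.Area.L", "Occipital.Mid.L",
    "Frontal.Inf.Tri.R", "Temporal.Mid.R", "Fusiform.L", "SupraMarginal.R",
    "Frontal.Inf.Oper.R", "Thalamus.L", "Rectus.R", "ParaHippocampal.R",
    "Parietal.Inf.L", "Frontal.Mid.L", "Temporal.Inf.R", "Parietal.Sup.R",
    "Temporal.Mid.L", "Temporal.Pole.Mid.L", "Precentral.L",
    "Frontal.Inf.Tri.L", "Frontal.Sup.Medial.R", "Temporal.Pole.Mid.R",
    "Lingual.R", "Caudate.L", "Temporal.Pole.Sup.L", "Frontal.Inf.Oper.L",
    "Olfactory.R", "Angular.R", "Thalamus.R", "Calcarine.L",
    "Frontal.Sup.Medial.L", "Cuneus.L", "Heschl.R", "Putamen.R",
    "Frontal.Mid.Orb.L", "Frontal.Inf.Orb.L", "Temporal.Inf.L", "Rectus.L",
    "Amygdala.L", "Parietal.Sup.L", "Precuneus.R", "Rolandic.Oper.L",
    "Temporal.Pole.Sup.L", "Putamen.L", "Rolandic.Oper.R", "Occipital.Sup.R",
    "Cingulum.Ant.R", "Pallidum.R", "Cingulum.Mid.R", "SupraMarginal.L",
    "Frontal.Sup.R", "Frontal.Sup.Orb.R", "Paracentral.Lobule.L",
    "Fusiform.R", "Hippocampus.R", "Cingulum.Mid.L", "Caudate.R",
    "Hippocampus.L", "Frontal.Mid.Orb.R", "ParaHippocampal.L", "Angular.L",
    "Occipital.Inf.R", "Occipital.Inf.L", "Temporal.Inf.R", "Olfactory.L",
    "Calcarine.L", "Parietal.Inf.R", "Insula.R", "Cingulum.Post.R",
    "Temporal.Pole.Sup.R", "Occipital.Mid.R", "Frontal.Inf.Orb.L",
    "Supp.Motor.Area.R", "Frontal.Inf.Oper.L", "Cuneus.L",
    "Paracentral.Lobule.R", "Precuneus.R", "Heschl.L")
  expect_true(all(reported %in% labs))
})
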