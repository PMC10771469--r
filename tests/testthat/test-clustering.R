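test_that("trivial clusterings behave as documented", {
  s <- helical_structure(30)
  # two identical interfaces: one cluster of two
  dup <- interface_set(list(interface("a-1", 3:8), interface("a-2", 3:8)))
  res <- cluster_interfaces(similarity_matrix(dup, s), dup)
  expect_identical(n_clusters(res), 1L)
  expect_identical(unname(res$assignment), c(1L, 1L))
  # two orthogonal interfaces: sin theta ~ 1 > 0.866, two singletons
  far <- interface_set(list(interface("a-1", 1:4), interface("b-1", 25:28)))
  res2 <- cluster_interfaces(similarity_matrix(far, s), far)
  expect_identical(n_clusters(res2), 2L)
  # single interface: singleton cluster, no engine invoked
  one <- interface_set(list(interface("solo-1", 5:9)))
  res3 <- cluster_interfaces(similarity_matrix(one, s), one)
  expect_identical(n_clusters(res3), 1L)
  expect_identical(res3$profiles[[1]]$members, "solo-1")
  expect_error(cluster_interfaces(similarity_matrix(one, s), one,
                                  threshold = 0),
               "threshold")
})

test_that("the dendrogram cut is inclusive at exactly the threshold", {
  sim <- new_similarity_matrix(
    matrix(c(0, 0.866, 0.866, 0), 2, 2,
           dimnames = list(c("a-1", "b-1"), c("a-1", "b-1"))))
  res <- cluster_interfaces(sim, threshold = 0.866)
  expect_identical(n_clusters(res), 1L)
  just_above <- new_similarity_matrix(
    matrix(c(0, 0.8661, 0.8661, 0), 2, 2,
           dimnames = list(c("a-1", "b-1"), c("a-1", "b-1"))))
  expect_identical(n_clusters(cluster_interfaces(just_above)), 2L)
})

test_that("planted surfaces are recovered exactly", {
  sc <- generate_scenario(k = 3, patch_size = 10, replicates = 5,
                          dropout = 0.15, seed = 11)
  sim <- similarity_matrix(sc$interfaces, sc$structure)
  res <- cluster_interfaces(sim, sc$interfaces)
  expect_identical(n_clusters(res), 3L)
  expect_true(same_partition(unname(res$assignment[names(sc$truth)]),
                             unname(sc$truth)))
})

test_that("partition matches the naive O(n^3) oracle on small instances", {
  for (trial in 1:8) {
    set.seed(700 + trial)
    m <- sample(3:8, 1)
    s <- random_structure(30, spread = 25)
    ifs <- interface_set(lapply(seq_len(m), function(i)
      random_interface(sprintf("r%d-x", i), s, sample(2:6, 1))))
    sim <- similarity_matrix(ifs, s)
    for (linkage in c("average", "single", "complete")) {
      got <- cluster_interfaces(sim, ifs, linkage = linkage)
      want <- oracle_agglomerate(sim$values, 0.866, linkage)
      expect_true(same_partition(unname(got$assignment), want),
                  label = sprintf("trial %d, %s linkage", trial, linkage))
    }
  }
})

test_that("permuting interface order changes labels, not the partition", {
  sc <- generate_scenario(k = 3, patch_size = 8, replicates = 4,
                          dropout = 0.2, seed = 5)
  sim <- cluster_interfaces(similarity_matrix(sc$interfaces, sc$structure),
                            sc$interfaces)
  set.seed(99)
  perm <- sample(length(sc$interfaces))
  shuffled <- interface_set(sc$interfaces$interfaces[perm],
                            reference = sc$structure)
  sim2 <- cluster_interfaces(similarity_matrix(shuffled, sc$structure),
                             shuffled)
  common <- names(sim$assignment)
  expect_true(same_partition(unname(sim$assignment[common]),
                             unname(sim2$assignment[common])))
})

test_that("cluster count is non-increasing in the threshold", {
  sc <- generate_scenario(k = 4, patch_size = 6, replicates = 3,
                          dropout = 0.25, seed = 21, jitter = 0.3)
  sim <- similarity_matrix(sc$interfaces, sc$structure)
  counts <- vapply(c(0.05, 0.3, 0.6, 0.866, 0.99, 1),
                   function(th) n_clusters(cluster_interfaces(sim, sc$interfaces,
                                                              threshold = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster ids are ordered by decreasing size with stable ties", {
  sim <- new_similarity_matrix(matrix(
    c(0, 1, 1, 1,
      1, 0, 0, 0,
      1, 0, 0, 0,
      1, 0, 0, 0), 4, 4,
    dimnames = list(c("solo-1", "t1-1", "t2-1", "t3-1"),
                    c("solo-1", "t1-1", "t2-1", "t3-1"))))
  res <- cluster_interfaces(sim)
  expect_identical(unname(res$assignment),
                   c(2L, 1L, 1L, 1L))  # trio is cluster 1, singleton 2
})

test_that("residue probabilities are occupancy fractions", {
  ifs <- interface_set(list(
    interface("a-1", c(10, 11, 12)), interface("a-2", c(10, 11)),
    interface("a-3", c(10, 13)), interface("a-4", 10)))
  pr <- residue_probabilities(interface_names(ifs), ifs)
  expect_equal(pr$probabilities[["10"]], 1.0)
  expect_equal(pr$probabilities[["11"]], 0.5)
  expect_equal(pr$probabilities[["13"]], 0.25)
  expect_false("99" %in% names(pr$probabilities))
  # conservation: sum(P) * members = total residue incidences
  expect_equal(sum(pr$probabilities) * 4, 3 + 2 + 2 + 1)
  # singleton cluster: all probabilities exactly 1
  solo <- residue_probabilities("a-1", ifs)
  expect_true(all(solo$probabilities == 1))
  expect_error(residue_probabilities("nope-1", ifs), "unknown")
  expect_error(residue_probabilities(character(0), ifs), "empty")
})

test_that("probability PDB encodes 50*(1+P) in the B-factor column", {
  s <- helical_structure(15)
  ifs <- interface_set(list(
    interface("a-1", c(3, 4, 5, 6)), interface("a-2", c(3, 4, 5)),
    interface("a-3", c(3, 4)), interface("a-4", 3)))
  pr <- residue_probabilities(interface_names(ifs), ifs)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_probability_pdb(s, pr, path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  b <- as.numeric(substr(lines, 61, 66))
  resnum <- as.integer(substr(lines, 23, 26))
  expect_equal(b[resnum == 3], 100.00)   # P = 1
  expect_equal(b[resnum == 5], 75.00)    # P = 0.5
  expect_equal(b[resnum == 6], 62.50)    # P = 0.25
  expect_equal(b[resnum == 10], 0.00)    # not in the cluster
  # singleton cluster: 100.00 on every member residue, 0 elsewhere
  solo <- residue_probabilities("a-1", ifs)
  write_probability_pdb(s, solo, path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  b <- as.numeric(substr(lines, 61, 66))
  resnum <- as.integer(substr(lines, 23, 26))
  expect_true(all(b[resnum %in% 3:6] == 100))
  expect_true(all(b[!resnum %in% 3:6] == 0))
  # profile residue missing from the structure: warn and skip
  off <- residue_probabilities("a-1", interface_set(list(
    interface("a-1", c(3, 999)))))
  expect_warning(write_probability_pdb(s, off, path), "999")
})

test_that("write_cluster_outputs emits the documented artifacts", {
  sc <- generate_scenario(k = 2, patch_size = 6, replicates = 3, seed = 3)
  res <- cluster_interfaces(similarity_matrix(sc$interfaces, sc$structure),
                            sc$interfaces)
  out <- withr::local_tempdir()
  write_cluster_outputs(res, sc$structure, out)
  expect_true(file.exists(file.path(out, "clusters.tsv")))
  expect_true(file.exists(file.path(out, "residue_probabilities.tsv")))
  pdbs <- list.files(out, pattern = "^surface_cluster_\\d+\\.pdb$")
  expect_length(pdbs, 2L)
  cl <- read.delim(file.path(out, "clusters.tsv"))
  expect_setequal(cl$interface_name, names(sc$truth))
})
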